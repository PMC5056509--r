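# Residue-residue contact-area maps, the per-residue difference-contact
# statistic, Shrake-Rupley solvent accessibility, the hydrophobic-exposure
# gate, and the grouping of both candidate sets into ranked aggregation
# hotspots.
#
# The contact area C_ij is defined here as the summed sphere-sphere
# intersection-disc areas of probe-expanded heavy atoms: for atoms a in i
# and b in j with van der Waals radii r_a, r_b and probe radius r_p, the
# spheres of radius r_a + r_p and r_b + r_p intersect in a circle whose
# disc area is the pair's contribution (zero once d >= r_a + r_b + 2 r_p).
# This closed-form stand-in is symmetric, rigid-motion invariant and
# testable; it is isolated behind contact_map() so an alternative contact
# definition can be swapped in.

lens_disc_area <- function(d, r1, r2) {
  # area of the circle in which two spheres of radii r1, r2 at distance d
  # intersect; 0 when surfaces do not cross
  out <- numeric(length(d))
  hit <- d < (r1 + r2) & d > abs(r1 - r2) & d > 0
  if (any(hit)) {
    dd <- d[hit]
    rc2 <- (4 * dd^2 * r1[hit]^2 - (dd^2 - r2[hit]^2 + r1[hit]^2)^2) / (4 * dd^2)
    out[hit] <- pi * pmax(rc2, 0)
  }
  out
}

new_contact_map <- function(areas, n_frames_averaged = 1, label = "",
                            type = c("raw", "difference")) {
  type <- match.arg(type)
  stopifnot(is.matrix(areas), nrow(areas) == ncol(areas))
  structure(list(areas = areas, n_frames_averaged = n_frames_averaged,
                 label = label, type = type),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d x %d residues, %s map averaged over %d frame(s)\n",
              x$label, nrow(x$areas), ncol(x$areas), x$type,
              x$n_frames_averaged))
  invisible(x)
}

#' Residue-residue contact-area map of a conformation
#'
#' @param structure A `vhh_structure` (heavy atoms are used; hydrogens are
#'   ignored).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @return A `contact_map` with the symmetric N x N matrix of contact
#'   areas in square Angstrom (diagonal zero).
#' @export
contact_map <- function(structure, probe = 1.4) {
  stopifnot(inherits(structure, "vhh_structure"), probe > 0)
  heavy <- select_atoms(structure, "heavy")
  xyz <- structure$xyz[heavy, , drop = FALSE]
  radii <- vdw_radius(structure$atoms$elesy[heavy]) + probe
  res <- structure$atoms$res_index[heavy]
  nres <- n_residues(structure)
  dmat <- as.matrix(dist(xyz))
  na <- length(heavy)
  pair <- which(upper.tri(dmat), arr.ind = TRUE)
  # different residues only; intra-residue overlap is not a contact
  pair <- pair[res[pair[, 1]] != res[pair[, 2]], , drop = FALSE]
  d <- dmat[pair]
  areas <- lens_disc_area(d, radii[pair[, 1]], radii[pair[, 2]])
  cm <- matrix(0, nres, nres)
  nz <- areas > 0
  if (any(nz)) {
    ri <- res[pair[nz, 1]]
    rj <- res[pair[nz, 2]]
    for (k in seq_along(ri)) {
      cm[ri[k], rj[k]] <- cm[ri[k], rj[k]] + areas[nz][k]
    }
    cm <- cm + t(cm)
  }
  diag(cm) <- 0
  new_contact_map(cm, n_frames_averaged = 1, label = structure$label)
}

#' Trajectory-averaged contact-area map
#'
#' Element-wise mean of the per-frame contact maps.
#'
#' @param traj A `vhh_trajectory`.
#' @param frame_ids Optional subset of frame numbers (default: all frames).
#' @param probe Probe radius in Angstrom.
#' @return A `contact_map` with `n_frames_averaged` recorded.
#' @export
mean_contact_map <- function(traj, frame_ids = NULL, probe = 1.4) {
  stopifnot(inherits(traj, "vhh_trajectory"))
  frame_ids <- frame_ids %||% seq_len(n_frames(traj))
  if (length(frame_ids) == 0) stop_vhh("empty frame set")
  if (any(frame_ids < 1 | frame_ids > n_frames(traj))) {
    stop_vhh("frame ids out of range")
  }
  maps <- lapply(frame_ids, function(i) {
    contact_map(frame_structure(traj, i), probe = probe)$areas
  })
  new_contact_map(Reduce(`+`, maps) / length(maps),
                  n_frames_averaged = length(frame_ids),
                  label = traj$label)
}

#' Difference contact map between a variant and its reference
#'
#' Signed element-wise difference of two (typically trajectory-averaged)
#' contact maps. Comparison is only meaningful between molecules sharing
#' the same number of residues.
#'
#' @param variant,reference `contact_map` objects of equal size.
#' @return A `contact_map` of type `"difference"`.
#' @export
difference_contact_map <- function(variant, reference) {
  stopifnot(inherits(variant, "contact_map"), inherits(reference, "contact_map"))
  if (!all(dim(variant$areas) == dim(reference$areas))) {
    stop_vhh("contact maps differ in size (", nrow(variant$areas), " vs ",
             nrow(reference$areas), " residues); the comparison is ",
             "restricted to molecules sharing the same number of residues")
  }
  out <- new_contact_map(variant$areas - reference$areas,
                         n_frames_averaged = variant$n_frames_averaged,
                         label = paste0(variant$label, "-", reference$label),
                         type = "difference")
  out$variant_label <- variant$label
  out$reference_label <- reference$label
  out
}

#' Per-residue global difference contact area
#'
#' For each residue i, the sum of absolute difference-map entries to all
#' partners j excluding itself and its sequence neighbours
#' (|j - i| > 1): residues scoring high are those whose interactions with
#' the rest of the molecule changed most upon mutation.
#'
#' @param diff A difference `contact_map`.
#' @param one_sided If `TRUE`, sum strictly over j > i + 1 only (each
#'   absolute entry then contributes to one residue, and late residues sum
#'   fewer terms); default is the symmetric reading.
#' @return A `perturbation_profile`: list with `values` (length-N
#'   non-negative vector, square Angstrom), `variant_label` and
#'   `reference_label`.
#' @export
global_difference <- function(diff, one_sided = FALSE) {
  stopifnot(inherits(diff, "contact_map"))
  if (diff$type != "difference") {
    stop_vhh("global_difference() expects a difference contact map")
  }
  m <- abs(diff$areas)
  n <- nrow(m)
  idx <- abs(row(m) - col(m)) <= 1
  m[idx] <- 0
  if (one_sided) m[col(m) <= row(m) + 1] <- 0
  vals <- rowSums(m)
  structure(list(values = unname(vals),
                 variant_label = diff$variant_label %||% "",
                 reference_label = diff$reference_label %||% ""),
            class = "perturbation_profile")
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf("<perturbation_profile> %s vs %s: %d residues, max %.2f A^2 at residue %d\n",
              x$variant_label, x$reference_label, length(x$values),
              max(x$values), which.max(x$values)))
  invisible(x)
}

#' Residues perturbed beyond the profile average
#'
#' Selects residues whose global difference contact area is at least
#' `factor` times the profile mean (default: 20% above the average) and
#' above an absolute floor that suppresses numerically tiny differences on
#' near-identical ensembles. The default floor of 10 square Angstrom is
#' roughly the overlap area of a single atomic contact, so residues must
#' have gained or lost at least one substantial atom-atom contact to be
#' flagged.
#'
#' @param profile A `perturbation_profile`.
#' @param factor Multiple of the mean (default 1.2).
#' @param min_value Absolute floor in square Angstrom (default 10).
#' @return Integer vector of residue indices (possibly empty).
#' @export
select_perturbed_residues <- function(profile, factor = 1.2, min_value = 10) {
  stopifnot(inherits(profile, "perturbation_profile"), factor > 0)
  v <- profile$values
  if (all(v == 0)) return(integer(0))
  which(v >= factor * mean(v) & v >= min_value)
}

golden_spiral_points <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (i - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic Shrake-Rupley sphere sampling on a golden-spiral point
#' set: for a fixed `n_points` the result is bit-reproducible. Hydrogens
#' are ignored (heavy-atom analysis).
#'
#' @param structure A `vhh_structure`.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Sampling points per atom (default 960, minimum 100).
#' @return A list with `atom` (per-atom SASA, square Angstrom; zero for
#'   hydrogens), `residue` (per-residue sums), `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "vhh_structure"), probe > 0)
  if (!is_count(n_points) || n_points < 100) {
    stop_vhh("'n_points' must be an integer >= 100")
  }
  heavy <- select_atoms(structure, "heavy")
  xyz <- structure$xyz[heavy, , drop = FALSE]
  radii <- vdw_radius(structure$atoms$elesy[heavy]) + probe
  n <- length(heavy)
  pts <- golden_spiral_points(n_points)
  dmat <- as.matrix(dist(xyz))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < radii[i] + radii & seq_len(n) != i)
    if (length(nb) == 0) {
      areas[i] <- 4 * pi * radii[i]^2
      next
    }
    surf <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dx <- sweep(surf[accessible, , drop = FALSE], 2, xyz[j, ])
      accessible[accessible] <- rowSums(dx^2) >= radii[j]^2
    }
    areas[i] <- mean(accessible) * 4 * pi * radii[i]^2
  }
  atom_sasa <- numeric(nrow(structure$atoms))
  atom_sasa[heavy] <- areas
  res_sasa <- as.numeric(rowsum(atom_sasa,
                                structure$atoms$res_index,
                                reorder = TRUE))
  list(atom = atom_sasa, residue = res_sasa, probe = probe,
       n_points = n_points)
}

# Reference maximum SASA of residue type X, from the middle residue of an
# extended Gly-X-Gly tripeptide built with the package's idealized residue
# geometry. Self-consistent with sasa(); memoized per (resname, probe,
# n_points).
.vhh_cache <- new.env(parent = emptyenv())

max_sasa_reference <- function(resname, probe = 1.4, n_points = 960) {
  key <- sprintf("%s|%g|%d", toupper(resname), probe, n_points)
  if (!is.null(.vhh_cache[[key]])) return(.vhh_cache[[key]])
  tri <- build_peptide(c("GLY", toupper(resname), "GLY"))
  val <- sasa(tri, probe = probe, n_points = n_points)$residue[2]
  .vhh_cache[[key]] <- val
  val
}

#' Solvent-exposed hydrophobic residues
#'
#' Residues whose relative solvent accessibility (observed SASA over the
#' extended Gly-X-Gly reference maximum) reaches `rel_sasa_min` and whose
#' Eisenberg consensus hydrophobicity reaches `hydrophobicity_min`: the
#' surface residues most prone to stick to another monomer.
#'
#' @param structure A `vhh_structure`.
#' @param rel_sasa_min Minimum relative SASA (default 0.20).
#' @param hydrophobicity_min Minimum Eisenberg score (default 0.0).
#' @param probe,n_points Passed to [sasa()].
#' @return Integer vector of residue indices. Residue types without an
#'   Eisenberg score are excluded with a warning.
#' @export
hydrophobic_exposed_residues <- function(structure, rel_sasa_min = 0.20,
                                         hydrophobicity_min = 0.0,
                                         probe = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "vhh_structure"))
  rt <- residue_table(structure)
  s <- sasa(structure, probe = probe, n_points = n_points)$residue
  hyd <- unname(eisenberg_score(rt$resid))
  unknown <- is.na(hyd)
  if (any(unknown)) {
    warning("excluding residue type(s) without hydrophobicity score: ",
            paste(unique(rt$resid[unknown]), collapse = ", "), call. = FALSE)
  }
  ref <- vapply(rt$resid, function(r) {
    if (toupper(r) %in% names(.eisenberg_scale)) {
      max_sasa_reference(r, probe = probe, n_points = n_points)
    } else {
      NA_real_
    }
  }, numeric(1))
  rel <- s / ref
  unname(which(!unknown & rel >= rel_sasa_min & hyd >= hydrophobicity_min))
}

min_residue_distances <- function(structure, residues) {
  heavy <- select_atoms(structure, "heavy")
  res <- structure$atoms$res_index[heavy]
  keep <- res %in% residues
  xyz <- structure$xyz[heavy[keep], , drop = FALSE]
  res <- res[keep]
  dmat <- as.matrix(dist(xyz))
  k <- length(residues)
  out <- matrix(Inf, k, k, dimnames = list(residues, residues))
  for (a in seq_len(k)) {
    ia <- which(res == residues[a])
    for (b in seq_len(k)) {
      if (b <= a) next
      ib <- which(res == residues[b])
      out[a, b] <- out[b, a] <- min(dmat[ia, ib])
    }
  }
  diag(out) <- 0
  out
}

#' Group candidate residues into ranked aggregation hotspots
#'
#' Builds a graph over the candidate residues with an edge whenever the
#' closest heavy-atom distance between two candidates is within
#' `link_distance`; the connected components are the surface patches.
#' Patches are ranked by residue count (ties by lower minimum residue
#' index) and the largest `max_patches` are retained.
#'
#' @param candidates Either an integer vector of residue indices or a list
#'   with elements `contact_selected` and `hydrophobic_exposed` (their
#'   union is used and the provenance kept).
#' @param structure The `vhh_structure` the candidates refer to.
#' @param link_distance Linking distance in Angstrom (default 8).
#' @param max_patches Maximum number of retained patches (default 5).
#' @return A `hotspot_set`: list with `patches` (list of sorted residue
#'   index vectors, largest first), `provenance`, `structure_label` and
#'   `link_distance`.
#' @export
group_hotspots <- function(candidates, structure, link_distance = 8,
                           max_patches = 5) {
  stopifnot(inherits(structure, "vhh_structure"), link_distance > 0,
            is_count(max_patches))
  if (is.list(candidates)) {
    provenance <- list(
      contact_selected = sort(unique(as.integer(candidates$contact_selected))),
      hydrophobic_exposed = sort(unique(as.integer(candidates$hydrophobic_exposed)))
    )
    cand <- sort(unique(c(provenance$contact_selected,
                          provenance$hydrophobic_exposed)))
  } else {
    cand <- sort(unique(as.integer(candidates)))
    provenance <- list(contact_selected = integer(0),
                       hydrophobic_exposed = cand)
  }
  if (length(cand) == 0) stop_vhh("no candidate residues to group")
  if (any(cand < 1 | cand > n_residues(structure))) {
    stop_vhh("candidate residue indices out of range")
  }
  dmin <- min_residue_distances(structure, cand)
  adj <- dmin <= link_distance
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  patches <- split(cand, comp)
  patches <- lapply(patches, function(p) sort(unname(p)))
  sizes <- vapply(patches, length, integer(1))
  mins <- vapply(patches, min, numeric(1))
  ord <- order(-sizes, mins)
  patches <- unname(patches[ord])
  patches <- patches[seq_len(min(max_patches, length(patches)))]
  structure(list(patches = patches, provenance = provenance,
                 structure_label = structure$label,
                 link_distance = link_distance),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> %s: %d patch(es) (link distance %.1f A)\n",
              x$structure_label, length(x$patches), x$link_distance))
  for (i in seq_along(x$patches)) {
    cat(sprintf("  patch %d (%d residues): %s\n", i, length(x$patches[[i]]),
                paste(x$patches[[i]], collapse = ",")))
  }
  invisible(x)
}

#' Write a hotspot set as two-column text
#' @param hotspots A `hotspot_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hotspots <- function(hotspots, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# aggregation hotspots of %s (link distance %.1f A)",
                     hotspots$structure_label, hotspots$link_distance), con)
  writeLines("patch\tresidues", con)
  for (i in seq_along(hotspots$patches)) {
    writeLines(sprintf("%d\t%s", i,
                       paste(hotspots$patches[[i]], collapse = ",")), con)
  }
  invisible(path)
}

#' Write a structure with hotspot patch ids in the B-factor column
#'
#' Atoms of residues in patch k get B-factor k; all others 0. Handy for
#' colouring hotspots in a molecular viewer.
#'
#' @param hotspots A `hotspot_set`.
#' @param structure The matching `vhh_structure`.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_hotspot_pdb <- function(hotspots, structure, path) {
  b <- numeric(nrow(structure$atoms))
  for (i in seq_along(hotspots$patches)) {
    b[structure$atoms$res_index %in% hotspots$patches[[i]]] <- i
  }
  write_structure(structure, path, b = b)
}

#' Per-residue rearrangement report for one hotspot
#'
#' For each hotspot residue: its global difference contact area, its five
#' largest-|difference| contact partners, the per-residue SASA change
#' (variant minus reference) and its Eisenberg hydrophobicity, sorted by
#' decreasing |global difference|. This is the backwards reading of the
#' protocol: given a hotspot implicated in low-scoring dimers, which
#' residues rearranged after the mutation.
#'
#' @param hotspot Integer vector of residue indices.
#' @param diff A difference `contact_map` (variant minus reference).
#' @param variant,reference `vhh_structure`s of equal residue count.
#' @param n_partners Number of top contact partners listed (default 5).
#' @param probe,n_points Passed to [sasa()].
#' @return A data frame, one row per hotspot residue.
#' @export
hotspot_rearrangement_report <- function(hotspot, diff, variant, reference,
                                         n_partners = 5, probe = 1.4,
                                         n_points = 960) {
  stopifnot(inherits(diff, "contact_map"),
            inherits(variant, "vhh_structure"),
            inherits(reference, "vhh_structure"))
  nv <- n_residues(variant)
  if (nv != n_residues(reference)) {
    stop_vhh("variant and reference differ in residue count; the comparison ",
             "is restricted to molecules sharing the same number of residues")
  }
  hotspot <- sort(unique(as.integer(hotspot)))
  if (any(hotspot < 1 | hotspot > nv)) {
    stop_vhh("hotspot residue indices out of range")
  }
  profile <- global_difference(diff)
  sasa_v <- sasa(variant, probe = probe, n_points = n_points)$residue
  sasa_r <- sasa(reference, probe = probe, n_points = n_points)$residue
  rt <- residue_table(variant)
  partners <- vapply(hotspot, function(r) {
    row <- diff$areas[r, ]
    row[r] <- 0
    ord <- order(-abs(row))
    top <- ord[abs(row[ord]) > 0]
    top <- head(top, n_partners)
    if (length(top) == 0) return("")
    paste(sprintf("%d:%+.1f", top, row[top]), collapse = " ")
  }, character(1))
  out <- data.frame(
    res_index = hotspot,
    resid = rt$resid[hotspot],
    resno = rt$resno[hotspot],
    delta_contact = profile$values[hotspot],
    delta_sasa = sasa_v[hotspot] - sasa_r[hotspot],
    eisenberg = unname(eisenberg_score(rt$resid[hotspot])),
    top_partners = partners,
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$delta_contact)), , drop = FALSE]
}
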