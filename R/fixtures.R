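# Seeded generators for synthetic structures, trajectories and docking
# score tables. The geometries are idealized beta-sandwich stand-ins, not
# physical VHH models: they carry the statistical structure each analysis
# stage assumes (controlled fluctuation amplitudes, localized mutation-like
# perturbations, class-separated docking score distributions) so that every
# stage is testable without external data.

# Idealized extended-strand residue geometry (Angstrom). Every residue
# carries backbone N, CA, C, O plus a CB side-chain placeholder; the CB
# pleats to alternating sides of the strand as in a real beta-strand.
.res_atom_offsets <- function(alt, cb_axis) {
  rbind(
    N  = c(-1.25,  0.45 * alt, 0),
    CA = c( 0.00,  0.00,       0),
    C  = c( 1.25, -0.45 * alt, 0),
    O  = c( 1.45, -1.60 * alt, 0),
    CB = 1.53 * alt * cb_axis
  )
}

#' Build an idealized extended peptide
#'
#' A straight strand along `direction` with 3.8 A C-alpha spacing and
#' pleating side chains; used both as a fixture building block and as the
#' extended Gly-X-Gly reference geometry for relative SASA.
#'
#' @param resnames Character vector of three-letter residue codes.
#' @param origin First C-alpha position (length-3, Angstrom).
#' @param direction Unit chain axis (default +x).
#' @param cb_axis Axis along which side chains pleat (default +/-z).
#' @param chain Chain identifier.
#' @param resno_start First author residue number.
#' @param alt_start Pleat sign of the first residue (+1 or -1).
#' @return A `vhh_structure`.
#' @export
build_peptide <- function(resnames, origin = c(0, 0, 0),
                          direction = c(1, 0, 0), cb_axis = c(0, 0, 1),
                          chain = "A", resno_start = 1, alt_start = 1) {
  stopifnot(length(resnames) >= 1)
  direction <- direction / sqrt(sum(direction^2))
  cb_axis <- cb_axis / sqrt(sum(cb_axis^2))
  # local in-plane axis perpendicular to both chain and pleat directions
  ortho <- c(direction[2] * cb_axis[3] - direction[3] * cb_axis[2],
             direction[3] * cb_axis[1] - direction[1] * cb_axis[3],
             direction[1] * cb_axis[2] - direction[2] * cb_axis[1])
  basis <- rbind(direction, ortho, cb_axis)
  rows <- list()
  xyz <- list()
  eleno <- 0
  for (t in seq_along(resnames)) {
    alt <- alt_start * (-1)^(t - 1)
    resname <- toupper(resnames[t])
    off <- .res_atom_offsets(alt, c(0, 0, 1))
    if (resname == "GLY") off <- off[rownames(off) != "CB", , drop = FALSE]
    ca <- origin + (t - 1) * 3.8 * direction
    for (k in seq_len(nrow(off))) {
      eleno <- eleno + 1
      nm <- rownames(off)[k]
      rows[[eleno]] <- data.frame(
        type = "ATOM", eleno = eleno, elety = nm, resid = resname,
        chain = chain, resno = resno_start + t - 1, insert = "",
        elesy = substr(nm, 1, 1), stringsAsFactors = FALSE
      )
      xyz[[eleno]] <- ca + as.vector(off[k, ] %*% basis)
    }
  }
  new_structure(do.call(rbind, rows), do.call(rbind, xyz),
                label = paste(resnames, collapse = "-"))
}

.hydrophobic_pool <- c("LEU", "VAL", "ILE", "PHE", "ALA", "MET")
.polar_pool <- c("ASP", "GLU", "LYS", "SER", "ASN", "GLN", "THR", "ARG")

#' Generate an idealized two-sheet toy structure
#'
#' Two parallel slabs of extended strands at a controlled separation,
#' emulating the two facing beta-sheet sets of the VHH framework. Residue
#' types are drawn (seeded) from hydrophobic and polar pools so the
#' surface carries both sticky and benign residues.
#'
#' @param n_strands_per_sheet Strands per slab (default 2).
#' @param strand_length Residues per strand (default 6).
#' @param separation Inter-slab distance in Angstrom (default 10; slabs
#'   closer than 5 A would interpenetrate and are an error).
#' @param strand_spacing In-sheet strand spacing in Angstrom (default 4.8).
#' @param hydrophobic_fraction Probability a residue is drawn from the
#'   hydrophobic pool (default 0.4).
#' @param seed RNG seed.
#' @param label Structure label.
#' @return A list with `structure` (a `vhh_structure`) and `sheets`
#'   (list of residue-index sets `set_a`, `set_b`).
#' @export
make_toy_structure <- function(n_strands_per_sheet = 2, strand_length = 6,
                               separation = 10, strand_spacing = 4.8,
                               hydrophobic_fraction = 0.4, seed = 1,
                               label = "toy") {
  stopifnot(is_count(n_strands_per_sheet), is_count(strand_length))
  if (separation < 5) {
    stop_vhh("sheet separation of ", separation,
             " A makes the slabs overlap; use >= 5 A")
  }
  n <- 2 * n_strands_per_sheet * strand_length
  resnames <- with_seed(seed, {
    hydro <- runif(n) < hydrophobic_fraction
    ifelse(hydro,
           sample(.hydrophobic_pool, n, replace = TRUE),
           sample(.polar_pool, n, replace = TRUE))
  })
  pieces <- list()
  idx <- 0
  resno <- 1
  sheets <- list(set_a = integer(0), set_b = integer(0))
  for (sheet in 1:2) {
    z0 <- if (sheet == 1) 0 else separation
    for (s in seq_len(n_strands_per_sheet)) {
      res <- resnames[seq(resno, resno + strand_length - 1)]
      pieces[[length(pieces) + 1]] <- build_peptide(
        res, origin = c(0, (s - 1) * strand_spacing, z0),
        chain = "A", resno_start = resno
      )
      key <- paste0("set_", if (sheet == 1) "a" else "b")
      sheets[[key]] <- c(sheets[[key]], seq(resno, resno + strand_length - 1))
      resno <- resno + strand_length
    }
  }
  atoms <- do.call(rbind, lapply(pieces, function(p) p$atoms))
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$res_index <- NULL
  xyz <- do.call(rbind, lapply(pieces, function(p) p$xyz))
  list(structure = new_structure(atoms, xyz, label = label), sheets = sheets)
}

#' Generate a jittered toy trajectory around a base conformation
#'
#' Frames are the base coordinates plus seeded isotropic Gaussian jitter;
#' optionally a residue subset fluctuates with a larger amplitude and a
#' sheet set drifts linearly along +z to emulate structural opening.
#'
#' @param base A `vhh_structure` (or the list from [make_toy_structure()]).
#' @param n_frames Number of frames.
#' @param sigma Per-coordinate jitter standard deviation (Angstrom).
#' @param seed RNG seed.
#' @param perturbed_residues Optional residue indices jittered with
#'   `perturbed_sigma` instead of `sigma`.
#' @param perturbed_sigma Jitter s.d. of the perturbed residues.
#' @param drift Optional total +z drift in Angstrom, applied linearly
#'   over the trajectory to `drift_residues`.
#' @param drift_residues Residues subject to `drift`.
#' @param dt Frame spacing in ps (default 10).
#' @return A `vhh_trajectory`.
#' @export
make_toy_trajectory <- function(base, n_frames, sigma, seed = 1,
                                perturbed_residues = NULL,
                                perturbed_sigma = NULL,
                                drift = NULL, drift_residues = NULL,
                                dt = 10) {
  if (is.list(base) && !inherits(base, "vhh_structure")) base <- base$structure
  stopifnot(inherits(base, "vhh_structure"), is_count(n_frames), sigma >= 0)
  na <- nrow(base$atoms)
  sig <- rep(sigma, na)
  if (!is.null(perturbed_residues)) {
    stopifnot(!is.null(perturbed_sigma))
    sig[base$atoms$res_index %in% perturbed_residues] <- perturbed_sigma
  }
  drift_mask <- if (!is.null(drift)) {
    base$atoms$res_index %in% (drift_residues %||%
                                 seq_len(n_residues(base)))
  } else {
    rep(FALSE, na)
  }
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      jitter <- matrix(rnorm(na * 3), na, 3) * sig
      xyz <- base$xyz + jitter
      if (!is.null(drift) && n_frames > 1) {
        xyz[drift_mask, 3] <- xyz[drift_mask, 3] +
          drift * (f - 1) / (n_frames - 1)
      }
      xyz
    })
  })
  new_trajectory(base, frames, times = (seq_len(n_frames) - 1) * dt,
                 label = base$label)
}

#' Generate a matched reference/variant trajectory pair
#'
#' Emulates a point mutation with long-distance rearrangement: the variant
#' trajectory is identical in jitter to the reference, but the perturbed
#' residues together with their spatial neighbours (closest heavy atoms
#' within `neighbor_cutoff`) are rigidly displaced by `amplitude` radially
#' away from the molecular centre of mass, concentrating the difference
#' contact signal near the perturbed site.
#'
#' @param base A `vhh_structure` (or [make_toy_structure()] output).
#' @param perturbed_residues Non-empty integer vector of residue indices.
#' @param amplitude Displacement in Angstrom (> 0).
#' @param seed RNG seed (shared by both trajectories so ensemble noise
#'   cancels in the difference map).
#' @param n_frames,sigma,dt Passed to [make_toy_trajectory()].
#' @param neighbor_cutoff Neighbour distance in Angstrom (default 6).
#' @return A list with `reference` and `variant` trajectories and
#'   `displaced_residues` (the moved block).
#' @export
make_mutant_pair <- function(base, perturbed_residues, amplitude, seed = 1,
                             n_frames = 60, sigma = 0.3, dt = 10,
                             neighbor_cutoff = 6) {
  if (is.list(base) && !inherits(base, "vhh_structure")) base <- base$structure
  stopifnot(inherits(base, "vhh_structure"), amplitude > 0)
  perturbed_residues <- unique(as.integer(perturbed_residues))
  if (length(perturbed_residues) == 0) {
    stop_vhh("'perturbed_residues' must be non-empty")
  }
  displaced <- displace_block(base, perturbed_residues, amplitude,
                              neighbor_cutoff = neighbor_cutoff)
  variant_base <- displaced$structure
  moved <- displaced$moved
  variant_base$label <- paste0(base$label, "_mut")
  list(
    reference = make_toy_trajectory(base, n_frames, sigma, seed = seed, dt = dt),
    variant = make_toy_trajectory(variant_base, n_frames, sigma, seed = seed,
                                  dt = dt),
    displaced_residues = moved
  )
}

#' Generate a synthetic docking score table
#'
#' Per variant and dimer combination, a combination-level score is drawn
#' from a class-dependent normal distribution (high-yield variants around
#' the wild-type band, low-yield variants shifted by `offset`), then split
#' into 2-4 docking clusters: the best cluster sits at the combination
#' score and the others at less negative values, with normalized
#' population fractions.
#'
#' @param variants A data frame with columns `label` and `class`
#'   (`"high"` or `"low"`), or a named character vector of classes.
#' @param n_pairs Combinations per variant (default 10, the count for 5
#'   hotspots).
#' @param seed RNG seed.
#' @param n_sites Number of hotspot sites the pair ids are drawn from
#'   (default 5; raised automatically when `n_pairs` needs more).
#' @param high_center Centre of the high-yield score distribution
#'   (default -60, within the observed -40..-110 docking score range).
#' @param offset Shift of the low-yield class (default -30).
#' @param spread Between-combination score s.d. (default 5).
#' @param cluster_jitter Within-combination cluster score s.d. (default 2).
#' @return A `dock_score_table` data frame with columns `variant`,
#'   `site_a`, `site_b`, `cluster_score`, `cluster_fraction`.
#' @export
make_score_table <- function(variants, n_pairs = 10, seed = 1, n_sites = 5,
                             high_center = -60, offset = -30, spread = 5,
                             cluster_jitter = 2) {
  if (is.character(variants)) {
    variants <- data.frame(label = names(variants), class = unname(variants),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(variants), all(c("label", "class") %in% names(variants)),
            all(variants$class %in% c("high", "low")), is_count(n_pairs))
  while (choose(n_sites, 2) < n_pairs) n_sites <- n_sites + 1
  pairs <- t(combn(n_sites, 2))[seq_len(n_pairs), , drop = FALSE]
  rows <- with_seed(seed, {
    out <- list()
    for (v in seq_len(nrow(variants))) {
      center <- high_center + if (variants$class[v] == "low") offset else 0
      for (p in seq_len(n_pairs)) {
        combo_score <- rnorm(1, center, spread)
        k <- sample(2:4, 1)
        scores <- combo_score + c(0, abs(rnorm(k - 1, 0, 3 * cluster_jitter)))
        g <- runif(k, 0.5, 1.5)
        frac <- g / sum(g) * runif(1, 0.85, 1)
        shuffle <- sample(k)
        out[[length(out) + 1]] <- data.frame(
          variant = variants$label[v],
          site_a = pairs[p, 1], site_b = pairs[p, 2],
          cluster_score = round(scores[shuffle], 2),
          cluster_fraction = round(frac[shuffle], 4),
          stringsAsFactors = FALSE
        )
      }
    }
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("dock_score_table", "data.frame")
  tab
}
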