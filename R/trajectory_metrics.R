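# Superposition-based order parameters: Kabsch fitting, RMSD, RMSF and the
# beta-sheet RMSD / centre-of-mass distance series used to follow thermal
# unfolding ("structural opening") of the beta-sandwich framework.

#' Least-squares (Kabsch) superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the squared
#' deviation between `mobile` and `reference` over the fit atoms, and
#' applies it to all of `mobile`.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom).
#' @param fit_indices Atom indices used for the fit (default: all).
#' @return A list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3; `fitted = mobile %*% rotation + translation`) and `coords`
#'   (the fitted copy of `mobile`).
#' @export
superpose <- function(mobile, reference, fit_indices = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  fit_indices <- fit_indices %||% seq_len(nrow(mobile))
  if (length(fit_indices) < 3) {
    stop_vhh("superposition requires at least 3 fit atoms")
  }
  p <- mobile[fit_indices, , drop = FALSE]
  q <- reference[fit_indices, , drop = FALSE]
  cp <- colMeans(p)
  cq <- colMeans(q)
  p <- sweep(p, 2, cp)
  q <- sweep(q, 2, cq)
  sv_q <- svd(q)$d
  if (sv_q[2] < 1e-8 * max(sv_q[1], 1)) {
    stop_vhh("degenerate (collinear) fit geometry; rotation is underdetermined")
  }
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- cq - as.vector(cp %*% rot)
  fitted <- mobile %*% rot + matrix(translation, nrow(mobile), 3, byrow = TRUE)
  list(rotation = rot, translation = translation, coords = fitted)
}

#' Root-mean-square deviation between two conformations
#'
#' @param a,b Congruent n x 3 coordinate matrices.
#' @param indices Atom indices entering the deviation (default: all).
#' @param fit If `TRUE`, superpose `a` onto `b` over `indices` first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, indices = NULL, fit = FALSE) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  indices <- indices %||% seq_len(nrow(a))
  if (length(indices) == 0) stop_vhh("empty index list in rmsd()")
  if (fit) a <- superpose(a, b, fit_indices = indices)$coords
  diff <- a[indices, , drop = FALSE] - b[indices, , drop = FALSE]
  sqrt(mean(rowSums(diff^2)))
}

#' Per-atom root-mean-square fluctuation of a trajectory
#'
#' Frames are superposed onto the ensemble-average structure (the fit is
#' iterated once so the average is self-consistent); the RMSF of each
#' selected atom is the root of its time-mean squared displacement from
#' its time-mean position.
#'
#' @param traj A `vhh_trajectory` with at least two frames.
#' @param indices Atom indices to report (default: all).
#' @param fit_indices Atom indices used for the superposition (default:
#'   `indices`). Fitting on a larger selection than is reported avoids the
#'   downward bias the rigid-body fit introduces on small selections.
#' @return Numeric vector of RMSF values (Angstrom), one per selected atom,
#'   named by atom index.
#' @export
rmsf <- function(traj, indices = NULL, fit_indices = NULL) {
  stopifnot(inherits(traj, "vhh_trajectory"))
  if (n_frames(traj) < 2) {
    stop_vhh("RMSF requires at least two frames")
  }
  indices <- indices %||% seq_len(nrow(traj$topology$atoms))
  fit_indices <- fit_indices %||% indices
  frames <- traj$frames
  ref <- frames[[1]]
  for (pass in 1:2) {
    fitted <- lapply(frames, function(f) superpose(f, ref, fit_indices)$coords)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  sel <- lapply(fitted, function(f) f[indices, , drop = FALSE])
  mean_xyz <- Reduce(`+`, sel) / length(sel)
  msd <- Reduce(`+`, lapply(sel, function(f) rowSums((f - mean_xyz)^2))) /
    length(sel)
  setNames(sqrt(msd), indices)
}

#' Per-residue C-alpha RMSF
#'
#' Convenience wrapper computing [rmsf()] over the C-alpha atoms (with the
#' superposition performed on all atoms) and returning one value per
#' residue.
#'
#' @param traj A `vhh_trajectory`.
#' @return Numeric vector, one RMSF (Angstrom) per residue.
#' @export
calpha_rmsf <- function(traj) {
  ca <- select_atoms(traj$topology, "calpha")
  vals <- rmsf(traj, indices = ca,
               fit_indices = seq_len(nrow(traj$topology$atoms)))
  res <- traj$topology$atoms$res_index[ca]
  out <- rep(NA_real_, n_residues(traj$topology))
  out[res] <- vals
  if (anyNA(out)) stop_vhh("structure has residues without a C-alpha atom")
  out
}

new_timeseries <- function(times, values, metric, units = "A") {
  stopifnot(length(times) == length(values))
  out <- data.frame(time_ps = as.numeric(times), value = as.numeric(values))
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  class(out) <- c("vhh_timeseries", "data.frame")
  out
}

#' Write a time series as two-column delimited text
#'
#' @param series A time series from e.g. [sheet_order_parameters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(series, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s (units: %s)",
                     attr(series, "metric") %||% "value",
                     attr(series, "units") %||% "A"), con)
  write.table(series, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Beta-sheet order parameters along a trajectory
#'
#' Each frame is superposed onto the reference over the whole-molecule
#' backbone; the two facing beta-sheet sets are then followed without
#' per-sheet re-fitting, so that sheets diverging while internally intact
#' ("structural opening") register in the series. Reported per frame:
#' backbone RMSD of each sheet set and the distance between the
#' mass-weighted centres of mass of the two sets.
#'
#' @param traj A `vhh_trajectory`.
#' @param sheets A list with integer residue-index sets `set_a` and
#'   `set_b` (disjoint, non-empty).
#' @param reference A `vhh_structure` congruent with the topology
#'   (typically the representative conformation).
#' @param refit_sheets If `TRUE`, re-fit each sheet before its RMSD
#'   (hides opening; off by default).
#' @return A list of three time series: `rmsd_a`, `rmsd_b`, `com_distance`.
#' @export
sheet_order_parameters <- function(traj, sheets, reference,
                                   refit_sheets = FALSE) {
  stopifnot(inherits(traj, "vhh_trajectory"),
            inherits(reference, "vhh_structure"))
  set_a <- unique(as.integer(sheets$set_a))
  set_b <- unique(as.integer(sheets$set_b))
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop_vhh("both sheet sets must be non-empty")
  }
  if (length(intersect(set_a, set_b)) > 0) {
    stop_vhh("sheet sets overlap: ",
             paste(intersect(set_a, set_b), collapse = ", "))
  }
  topo <- traj$topology
  if (nrow(reference$xyz) != nrow(topo$atoms)) {
    stop_vhh("reference structure is not congruent with the trajectory topology")
  }
  fit_idx <- select_atoms(topo, "backbone")
  bb_a <- select_atoms(topo, "backbone", residues = set_a)
  bb_b <- select_atoms(topo, "backbone", residues = set_b)
  com_a_idx <- select_atoms(topo, "heavy", residues = set_a)
  com_b_idx <- select_atoms(topo, "heavy", residues = set_b)
  mass_a <- atomic_mass(topo$atoms$elesy[com_a_idx])
  mass_b <- atomic_mass(topo$atoms$elesy[com_b_idx])
  ref <- reference$xyz
  vals <- vapply(traj$frames, function(f) {
    fitted <- superpose(f, ref, fit_indices = fit_idx)$coords
    com_a <- colSums(fitted[com_a_idx, , drop = FALSE] * mass_a) / sum(mass_a)
    com_b <- colSums(fitted[com_b_idx, , drop = FALSE] * mass_b) / sum(mass_b)
    c(rmsd(fitted, ref, indices = bb_a, fit = refit_sheets),
      rmsd(fitted, ref, indices = bb_b, fit = refit_sheets),
      sqrt(sum((com_a - com_b)^2)))
  }, numeric(3))
  list(
    rmsd_a = new_timeseries(traj$times, vals[1, ], "sheet_a_backbone_rmsd"),
    rmsd_b = new_timeseries(traj$times, vals[2, ], "sheet_b_backbone_rmsd"),
    com_distance = new_timeseries(traj$times, vals[3, ], "inter_sheet_com_distance")
  )
}

#' Centered running average of a time series
#'
#' Moving mean with a centered window of `n_points` samples; windows are
#' truncated at the series edges.
#'
#' @param series A time series (from [sheet_order_parameters()]) or a
#'   numeric vector.
#' @param n_points Window width in samples (default 100).
#' @return An object of the same shape as `series` with smoothed values.
#' @export
running_average <- function(series, n_points = 100) {
  if (!is_count(n_points)) stop_vhh("'n_points' must be a positive integer")
  vals <- if (is.data.frame(series)) series$value else as.numeric(series)
  len <- length(vals)
  if (n_points > len) {
    stop_vhh("'n_points' (", n_points, ") exceeds the series length (", len, ")")
  }
  lo_off <- (n_points - 1) %/% 2
  hi_off <- n_points %/% 2
  sm <- vapply(seq_len(len), function(i) {
    mean(vals[max(1, i - lo_off):min(len, i + hi_off)])
  }, numeric(1))
  if (is.data.frame(series)) {
    series$value <- sm
    series
  } else {
    sm
  }
}
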