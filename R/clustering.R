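# gromos conformational clustering of an ensemble on an RMSF-gated backbone
# selection, and extraction of the representative conformation (the centre
# of the most populated cluster).

#' Select the fluctuating residues used for clustering
#'
#' Residues whose C-alpha RMSF lies strictly above the mean RMSF over all
#' residues, excluding the first and last `n_exclude_termini` residues
#' (the mobile chain extremes carry no conformational signal).
#'
#' @param rmsf Numeric vector of per-residue RMSF values (Angstrom).
#' @param n_exclude_termini Residues dropped from each terminus (default 3).
#' @return Integer vector of residue indices.
#' @export
select_fluctuating_residues <- function(rmsf, n_exclude_termini = 3) {
  n <- length(rmsf)
  if (n == 0) stop_vhh("empty RMSF vector")
  if (2 * n_exclude_termini >= n) {
    stop_vhh("terminal exclusion (", n_exclude_termini,
             " per end) removes the whole chain of ", n, " residues")
  }
  sel <- which(rmsf > mean(rmsf))
  if (n_exclude_termini > 0) {
    terminal <- c(seq_len(n_exclude_termini), seq(n - n_exclude_termini + 1, n))
    sel <- setdiff(sel, terminal)
  }
  if (length(sel) == 0) {
    stop_vhh("no residues fluctuate above the mean RMSF after terminal ",
             "exclusion; select residues manually")
  }
  sel
}

#' Pairwise fitted RMSD matrix of a trajectory
#'
#' @param traj A `vhh_trajectory` with at least two frames.
#' @param indices Atom indices over which each pairwise fitted RMSD is
#'   computed (typically an RMSF-gated backbone selection).
#' @return An `rmsd_matrix`: list with `values` (symmetric frame x frame
#'   matrix, Angstrom, zero diagonal) and `frame_ids`.
#' @export
rmsd_matrix <- function(traj, indices = NULL) {
  stopifnot(inherits(traj, "vhh_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop_vhh("an RMSD matrix requires at least two frames")
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      m[i, j] <- m[j, i] <- rmsd(traj$frames[[i]], traj$frames[[j]],
                                 indices = indices, fit = TRUE)
    }
  }
  structure(list(values = m, frame_ids = seq_len(nf)), class = "rmsd_matrix")
}

resolve_min_size <- function(min_size, n) {
  if (!is.null(min_size)) {
    if (!is_count(min_size)) stop_vhh("'min_size' must be a positive integer")
    return(as.integer(min_size))
  }
  # the conventional floor of 100 members presumes ensembles of >= 1000
  # frames; smaller ensembles use a 10% floor instead
  if (n >= 1000) 100L else max(1L, as.integer(ceiling(0.1 * n)))
}

#' gromos clustering of an RMSD matrix
#'
#' Iteratively takes the frame with the most neighbours within `cutoff` as
#' a cluster centre, removes it together with its neighbours, and repeats
#' until no frames remain. Neighbour-count ties are broken by the lowest
#' frame index. Clusters smaller than `min_size` are moved to the
#' discarded set.
#'
#' @param matrix An `rmsd_matrix`.
#' @param cutoff Neighbour cutoff in Angstrom, or `"auto"` to use the mean
#'   of the strict upper triangle of the matrix.
#' @param min_size Minimum retained cluster size. Default (`NULL`): 100
#'   when the ensemble has at least 1000 frames, otherwise 10% of the
#'   frame count.
#' @return A `cluster_result`: list with `clusters` (each a list of
#'   `members` and `center` frame ids, ordered largest first, size ties by
#'   lower centre frame id), `cutoff_used`, `min_size`, `discarded` and
#'   `n_frames`.
#' @export
gromos_cluster <- function(matrix, cutoff = "auto", min_size = NULL) {
  stopifnot(inherits(matrix, "rmsd_matrix"))
  m <- matrix$values
  n <- nrow(m)
  if (identical(cutoff, "auto")) {
    cutoff <- mean(m[upper.tri(m)])
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0)
  min_size <- resolve_min_size(min_size, n)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0) {
    sub <- m[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff) - 1L
    center_pos <- which.max(counts) # which.max takes the first (lowest id) tie
    center <- remaining[center_pos]
    members <- remaining[sub[center_pos, ] <= cutoff]
    clusters[[length(clusters) + 1]] <- list(members = sort(members),
                                             center = center)
    remaining <- setdiff(remaining, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  ord <- order(-sizes, centers)
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  keep <- sizes >= min_size
  if (!any(keep)) {
    stop_vhh("all clusters fall below min_size = ", min_size,
             "; largest cluster found has ", max(sizes), " frame(s)")
  }
  discarded <- sort(unlist(lapply(clusters[!keep], `[[`, "members")))
  structure(
    list(clusters = clusters[keep], cutoff_used = cutoff,
         min_size = min_size,
         discarded = as.integer(discarded %||% integer(0)),
         n_frames = n),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("<cluster_result> %d cluster(s) over %d frames (cutoff %.3f A, min size %d)\n",
              length(x$clusters), x$n_frames, x$cutoff_used, x$min_size))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d: %d frames (%.1f%%), center frame %d\n",
                i, sizes[i], 100 * sizes[i] / x$n_frames,
                x$clusters[[i]]$center))
  }
  if (length(x$discarded) > 0) {
    cat(sprintf("  discarded: %d frame(s) in sub-threshold clusters\n",
                length(x$discarded)))
  }
  invisible(x)
}

#' Representative conformation of a clustered ensemble
#'
#' The centre frame of the most populated retained cluster, materialized
#' as a structure.
#'
#' @param traj The clustered `vhh_trajectory`.
#' @param result A `cluster_result` from [gromos_cluster()].
#' @return A `vhh_structure`.
#' @export
representative_conformation <- function(traj, result) {
  stopifnot(inherits(traj, "vhh_trajectory"), inherits(result, "cluster_result"))
  if (length(result$clusters) == 0) stop_vhh("no retained clusters")
  frame_structure(traj, result$clusters[[1]]$center)
}

#' Write a cluster result as delimited text
#'
#' One row per retained cluster: id, size, centre frame and the member
#' frame list; discarded frames are listed in a trailing comment.
#'
#' @param result A `cluster_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_result <- function(result, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# gromos clustering: cutoff %.4f A, min cluster size %d, %d frames",
                     result$cutoff_used, result$min_size, result$n_frames), con)
  writeLines("cluster\tsize\tcenter\tmembers", con)
  for (i in seq_along(result$clusters)) {
    cl <- result$clusters[[i]]
    writeLines(sprintf("%d\t%d\t%d\t%s", i, length(cl$members), cl$center,
                       paste(cl$members, collapse = ",")), con)
  }
  if (length(result$discarded) > 0) {
    writeLines(sprintf("# discarded: %s",
                       paste(result$discarded, collapse = ",")), con)
  }
  invisible(path)
}
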