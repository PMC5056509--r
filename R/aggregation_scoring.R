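# Docking-score aggregation: dimer-combination enumeration, docking
# cluster selection, the five-lowest-score statistic and the yield verdict
# against a wild-type reference band. Docking itself is consumed, never
# performed: scores arrive as delimited tables.

#' Enumerate dimer combinations of a hotspot set
#'
#' Each hotspot is chosen in turn as the binding site to which the others
#' are docked; symmetric dimers bound through the same site on both
#' monomers are excluded, giving k(k-1)/2 unordered combinations for k
#' hotspots (10 for the canonical 5).
#'
#' @param hotspots A `hotspot_set`, or an integer hotspot count.
#' @return A data frame with columns `site_a` < `site_b`, one row per
#'   combination (zero rows for a single hotspot).
#' @export
enumerate_dimer_pairs <- function(hotspots) {
  k <- if (inherits(hotspots, "hotspot_set")) {
    length(hotspots$patches)
  } else {
    stopifnot(is_count(hotspots))
    as.integer(hotspots)
  }
  if (k < 1) stop_vhh("at least one hotspot is required")
  if (k < 2) {
    return(data.frame(site_a = integer(0), site_b = integer(0)))
  }
  pairs <- t(combn(k, 2))
  data.frame(site_a = pairs[, 1], site_b = pairs[, 2])
}

#' Select the scoring docking cluster of one combination
#'
#' The cluster with the lowest (most negative) score among those holding
#' more than `min_fraction` of the docked structures.
#'
#' @param clusters A data frame with columns `score` and `fraction`
#'   (population fraction in 0..1), or two numeric vectors via `score` /
#'   `fraction` columns of a table slice.
#' @param min_fraction Population gate (default 0.10).
#' @return The selected score (length-1 numeric).
#' @export
select_docking_cluster <- function(clusters, min_fraction = 0.10) {
  if (is.data.frame(clusters)) {
    score <- clusters$score %||% clusters$cluster_score
    fraction <- clusters$fraction %||% clusters$cluster_fraction
  } else {
    stop_vhh("'clusters' must be a data frame with score and fraction columns")
  }
  if (length(score) == 0) stop_vhh("empty docking cluster list")
  if (sum(fraction) > 1 + 1e-8) {
    stop_vhh("cluster population fractions sum above 1")
  }
  ok <- fraction > min_fraction
  if (!any(ok)) {
    stop_vhh("no docking cluster holds more than ",
             round(100 * min_fraction), "% of the binding structures; ",
             "combination unresolved")
  }
  min(score[ok])
}

#' The n lowest docking scores
#'
#' @param scores Numeric vector of per-combination selected scores.
#' @param n How many lowest values (default 5).
#' @return The `n` smallest scores in ascending order; if fewer than `n`
#'   scores are available, all of them (with a warning).
#' @export
five_lowest <- function(scores, n = 5) {
  if (length(scores) == 0) stop_vhh("no scores supplied")
  if (!is_count(n)) stop_vhh("'n' must be a positive integer")
  if (length(scores) < n) {
    warning("only ", length(scores), " score(s) available for the ", n,
            "-lowest statistic", call. = FALSE)
  }
  head(sort(scores), n)
}

#' Wild-type reference band
#'
#' Mean and population standard deviation of the wild type's five lowest
#' per-combination scores; variants are judged against this band.
#'
#' @param wt_scores Wild-type per-combination selected scores.
#' @param n Number of lowest scores entering the band (default 5).
#' @return A list with `mean`, `sd` and the `scores` used.
#' @export
reference_band <- function(wt_scores, n = 5) {
  fl <- five_lowest(wt_scores, n = n)
  m <- mean(fl)
  list(mean = m, sd = sqrt(mean((fl - m)^2)), scores = fl)
}

#' Per-combination selected scores of one variant in a score table
#'
#' Applies [select_docking_cluster()] to every dimer combination of the
#' named variant.
#'
#' @param table A `dock_score_table` (see [read_score_table()]).
#' @param variant Variant label.
#' @param min_fraction Population gate passed on.
#' @return Named numeric vector of selected scores, one per combination.
#' @export
combination_scores <- function(table, variant, min_fraction = 0.10) {
  rows <- table[table$variant == variant, , drop = FALSE]
  if (nrow(rows) == 0) stop_vhh("variant '", variant, "' not in score table")
  key <- paste(rows$site_a, rows$site_b, sep = "-")
  vapply(split(rows, key), select_docking_cluster,
         numeric(1), min_fraction = min_fraction)
}

#' Yield classification of a variant against the wild-type band
#'
#' The variant's five lowest per-combination scores are compared with the
#' wild-type reference mean: when all five fall strictly below it the
#' variant is classified `"reduced"` (stronger predicted aggregation,
#' lower expected usable yield), when none do `"comparable"`, otherwise
#' `"indeterminate"` with the below-count reported. Because absolute
#' docking scores depend on molecular size, the comparison is refused
#' unless variant and reference have the same residue count.
#'
#' @param scores Variant per-combination selected scores (numeric), or a
#'   `dock_score_table` together with `variant`.
#' @param reference A reference band from [reference_band()].
#' @param variant Variant label (required when `scores` is a table).
#' @param variant_n,reference_n Residue counts of the two molecules; when
#'   both are given they must be equal.
#' @param n Number of lowest scores entering the verdict (default 5).
#' @return A `yield_prediction`.
#' @export
predict_yield <- function(scores, reference, variant = "variant",
                          variant_n = NULL, reference_n = NULL, n = 5) {
  if (inherits(scores, "data.frame")) {
    scores <- combination_scores(scores, variant)
  }
  stopifnot(is.numeric(scores), is.list(reference), !is.null(reference$mean))
  if (!is.null(variant_n) && !is.null(reference_n) &&
      variant_n != reference_n) {
    stop_vhh("variant has ", variant_n, " residues but the reference has ",
             reference_n, "; docking-score comparison is restricted to ",
             "molecules sharing the same number of residues")
  }
  fl <- five_lowest(scores, n = n)
  n_below <- sum(fl < reference$mean)
  verdict <- if (n_below == length(fl)) {
    "reduced"
  } else if (n_below == 0) {
    "comparable"
  } else {
    "indeterminate"
  }
  structure(
    list(variant_label = variant, residue_count = variant_n,
         five_lowest = fl, reference_mean = reference$mean,
         reference_sd = reference$sd, n_below_reference = n_below,
         verdict = verdict),
    class = "yield_prediction"
  )
}

#' @export
print.yield_prediction <- function(x, ...) {
  cat(sprintf("<yield_prediction> %s: %s (%d/%d lowest scores below the wild-type mean %.1f)\n",
              x$variant_label, x$verdict, x$n_below_reference,
              length(x$five_lowest), x$reference_mean))
  cat("  five lowest:", paste(sprintf("%.1f", x$five_lowest), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a docking score table
#'
#' Tab-delimited text with header columns `variant`, `site_a`, `site_b`,
#' `cluster_score`, `cluster_fraction`; one row per docking cluster.
#'
#' @param path Input path.
#' @return A `dock_score_table` data frame.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop_vhh("file not found: '", path, "'")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant", "site_a", "site_b", "cluster_score", "cluster_fraction")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop_vhh("score table '", path, "' lacks column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  if (any(tab$cluster_fraction < 0 | tab$cluster_fraction > 1)) {
    stop_vhh("cluster population fractions must lie in [0, 1]")
  }
  class(tab) <- c("dock_score_table", "data.frame")
  tab
}

#' Write a docking score table
#' @param table A `dock_score_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
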