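# End-to-end orchestration: trajectory -> representative conformation ->
# order parameters -> difference-contact profile -> hotspots -> dimer
# combinations -> docking-score verdicts, with all artifacts written under
# one output directory together with a machine-readable manifest.

displace_block <- function(base, perturbed_residues, amplitude,
                           neighbor_cutoff = 6) {
  perturbed_residues <- unique(as.integer(perturbed_residues))
  all_res <- seq_len(n_residues(base))
  dmin <- min_residue_distances(base, all_res)
  nb <- which(apply(dmin[, perturbed_residues, drop = FALSE], 1, min) <=
                neighbor_cutoff)
  moved <- sort(unique(c(perturbed_residues, nb)))
  com <- colMeans(base$xyz)
  out <- base
  for (r in moved) {
    atom_idx <- which(base$atoms$res_index == r)
    ca <- base$xyz[atom_idx[base$atoms$elety[atom_idx] == "CA"][1], ]
    dir <- ca - com
    dir <- dir / sqrt(sum(dir^2))
    out$xyz[atom_idx, ] <- out$xyz[atom_idx, ] +
      matrix(amplitude * dir, length(atom_idx), 3, byrow = TRUE)
  }
  list(structure = out, moved = moved)
}

time_window_trajectory <- function(traj, discard_initial_fraction) {
  if (discard_initial_fraction <= 0) return(traj)
  t0 <- min(traj$times) +
    discard_initial_fraction * (max(traj$times) - min(traj$times))
  keep <- which(traj$times >= t0)
  new_trajectory(traj$topology, traj$frames[keep], traj$times[keep],
                 label = traj$label)
}

#' Default configuration for the bundled synthetic demonstration
#'
#' Four variants on a 60-residue two-sheet toy scaffold: a wild-type
#' reference, one benign variant (small localized perturbation, high-yield
#' score class) and two disruptive variants (3 A block displacements,
#' low-yield score class). Docking scores are generated synthetically with
#' the class-separated generator. The linking distance is scaled to the
#' toy scaffold (6 A) so that surface candidates resolve into separate
#' patches rather than one chain-connected component.
#'
#' @param outdir Output directory for [run_pipeline()] artifacts.
#' @param seed Seed controlling every random stage.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(outdir = tempfile("vhhscreen_demo_"), seed = 1) {
  list(
    seed = seed,
    outdir = outdir,
    fixture = list(n_strands_per_sheet = 3, strand_length = 10,
                   separation = 12, n_frames = 40, sigma = 0.3,
                   hydrophobic_fraction = 0.2),
    variants = list(
      list(label = "WT", class = "high"),
      list(label = "HUM1", class = "high", reference = "WT",
           perturbed_residues = 12, amplitude = 1.0),
      list(label = "MUT1", class = "low", reference = "WT",
           perturbed_residues = 12, amplitude = 3.0),
      list(label = "MUT2", class = "low", reference = "WT",
           perturbed_residues = 40, amplitude = 3.0)
    ),
    clustering = list(n_exclude_termini = 3, discard_initial_fraction = 0.1),
    hotspots = list(link_distance = 6, max_patches = 5,
                    rel_sasa_min = 0.20, hydrophobicity_min = 0.0,
                    sasa_points = 480),
    docking = list(generate = TRUE)
  )
}

#' Run the complete screening pipeline
#'
#' Executes, per variant: ensemble windowing, RMSF-gated gromos
#' clustering to the representative conformation, beta-sheet order
#' parameters, the trajectory-averaged difference-contact profile against
#' the named reference, hydrophobic-exposure analysis, hotspot grouping,
#' dimer-combination enumeration and the docking-score yield verdict. All
#' artifacts are written under `config$outdir` with a JSON manifest of the
#' parameters used; any stage error aborts naming the stage and variant.
#'
#' @param config A configuration list (see [demo_config()]) or the path
#'   to a YAML file with the same fields. Trajectories are either
#'   generated from the `fixture` block or read from per-variant
#'   `trajectory` paths (with a top-level `sheets` block giving the two
#'   facing beta-sheet residue sets).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-variant results (`representative`,
#'   `clusters`, `order_parameters`, `profile`, `hotspots`,
#'   `dimer_pairs`), the `score_table`, the `predictions` and the paths
#'   written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$variants))
  seed <- config$seed %||% 1
  outdir <- config$outdir %||% tempfile("vhhscreen_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e) {
      stop_vhh("pipeline stage '", name, "' failed for variant '", label,
               "': ", conditionMessage(e))
    })
  }
  cl_cfg <- modifyList(list(n_exclude_termini = 3,
                            discard_initial_fraction = 0.1,
                            min_size = NULL),
                       config$clustering %||% list())
  hs_cfg <- modifyList(list(link_distance = 8, max_patches = 5,
                            rel_sasa_min = 0.20, hydrophobicity_min = 0.0,
                            sasa_points = 960),
                       config$hotspots %||% list())
  variants <- config$variants
  labels <- vapply(variants, function(v) v$label, character(1))
  if (anyDuplicated(labels)) stop_vhh("duplicate variant labels in config")

  # --- input ensembles -----------------------------------------------------
  trajectories <- list()
  if (!is.null(config$fixture)) {
    fx <- modifyList(list(n_strands_per_sheet = 2, strand_length = 6,
                          separation = 10, n_frames = 40, sigma = 0.3,
                          hydrophobic_fraction = 0.4),
                     config$fixture)
    toy <- make_toy_structure(
      n_strands_per_sheet = fx$n_strands_per_sheet,
      strand_length = fx$strand_length, separation = fx$separation,
      hydrophobic_fraction = fx$hydrophobic_fraction, seed = seed
    )
    sheets <- toy$sheets
    for (v in variants) {
      base_v <- toy$structure
      base_v$label <- v$label
      if (!is.null(v$perturbed_residues)) {
        base_v <- displace_block(base_v, v$perturbed_residues,
                                 v$amplitude %||% 3)$structure
        base_v$label <- v$label
      }
      # one shared jitter seed: ensemble noise is paired across variants
      trajectories[[v$label]] <- make_toy_trajectory(
        base_v, n_frames = fx$n_frames, sigma = fx$sigma, seed = seed
      )
    }
  } else {
    sheets <- config$sheets
    if (is.null(sheets)) {
      stop_vhh("a 'sheets' block (set_a, set_b) is required when ",
               "trajectories are read from files")
    }
    for (v in variants) {
      if (is.null(v$trajectory)) {
        stop_vhh("variant '", v$label, "' has no trajectory and no fixture ",
                 "block is present")
      }
      trajectories[[v$label]] <- read_trajectory(unlist(v$trajectory),
                                                 label = v$label)
    }
  }

  # --- per-variant conformational analysis ---------------------------------
  results <- list()
  for (v in variants) {
    label <- v$label
    vdir <- file.path(outdir, label)
    dir.create(vdir, showWarnings = FALSE)
    traj <- stage("windowing", label,
                  time_window_trajectory(trajectories[[label]],
                                         cl_cfg$discard_initial_fraction))
    res_rmsf <- stage("rmsf", label, calpha_rmsf(traj))
    fluct <- stage("residue-gating", label,
                   select_fluctuating_residues(res_rmsf,
                                               cl_cfg$n_exclude_termini))
    fit_idx <- select_atoms(traj$topology, "backbone", residues = fluct)
    clusters <- stage("clustering", label,
                      gromos_cluster(rmsd_matrix(traj, fit_idx),
                                     cutoff = "auto",
                                     min_size = cl_cfg$min_size))
    rep_str <- stage("representative", label,
                     representative_conformation(traj, clusters))
    ops <- stage("order-parameters", label,
                 sheet_order_parameters(traj, sheets, rep_str))
    cmap <- stage("contact-map", label, mean_contact_map(traj))
    msg("[%s] %d frames -> representative frame %d (%d clusters)", label,
        n_frames(traj), clusters$clusters[[1]]$center,
        length(clusters$clusters))
    write_structure(rep_str, file.path(vdir, "representative.pdb"))
    write_cluster_result(clusters, file.path(vdir, "clusters.tsv"))
    for (nm in names(ops)) {
      write_timeseries(ops[[nm]], file.path(vdir, paste0(nm, ".tsv")))
    }
    results[[label]] <- list(trajectory = traj, representative = rep_str,
                             clusters = clusters, order_parameters = ops,
                             contact_map = cmap, rmsf = res_rmsf)
  }

  # --- hotspots ------------------------------------------------------------
  for (v in variants) {
    label <- v$label
    vdir <- file.path(outdir, label)
    ref_label <- v$reference %||% NULL
    contact_sel <- integer(0)
    profile <- NULL
    if (!is.null(ref_label)) {
      if (is.null(results[[ref_label]])) {
        stop_vhh("variant '", label, "' names unknown reference '",
                 ref_label, "'")
      }
      diff <- stage("difference-map", label,
                    difference_contact_map(results[[label]]$contact_map,
                                           results[[ref_label]]$contact_map))
      profile <- global_difference(diff)
      contact_sel <- select_perturbed_residues(profile)
      write.table(
        data.frame(res_index = seq_along(profile$values),
                   delta_contact = round(profile$values, 4)),
        file.path(vdir, "difference_profile.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      results[[label]]$difference_map <- diff
    }
    rep_str <- results[[label]]$representative
    hydro <- stage("hydrophobic-surface", label,
                   hydrophobic_exposed_residues(
                     rep_str, rel_sasa_min = hs_cfg$rel_sasa_min,
                     hydrophobicity_min = hs_cfg$hydrophobicity_min,
                     n_points = hs_cfg$sasa_points
                   ))
    hotspots <- stage("hotspot-grouping", label,
                      group_hotspots(list(contact_selected = contact_sel,
                                          hydrophobic_exposed = hydro),
                                     rep_str,
                                     link_distance = hs_cfg$link_distance,
                                     max_patches = hs_cfg$max_patches))
    pairs <- enumerate_dimer_pairs(hotspots)
    msg("[%s] %d candidate residues -> %d hotspot(s), %d dimer combination(s)",
        label, length(unique(c(contact_sel, hydro))),
        length(hotspots$patches), nrow(pairs))
    write_hotspots(hotspots, file.path(vdir, "hotspots.tsv"))
    write_hotspot_pdb(hotspots, rep_str, file.path(vdir, "hotspots.pdb"))
    results[[label]]$profile <- profile
    results[[label]]$hotspots <- hotspots
    results[[label]]$dimer_pairs <- pairs
  }

  # --- docking scores and yield verdicts -----------------------------------
  dk <- modifyList(list(generate = is.null(config$docking$table),
                        high_center = -60, offset = -30, spread = 5),
                   config$docking %||% list())
  if (!is.null(dk$table)) {
    score_table <- read_score_table(dk$table)
  } else {
    tabs <- list()
    for (i in seq_along(variants)) {
      v <- variants[[i]]
      k <- length(results[[v$label]]$hotspots$patches)
      np <- nrow(results[[v$label]]$dimer_pairs)
      if (np == 0) {
        stop_vhh("pipeline stage 'docking' failed for variant '", v$label,
                 "': fewer than two hotspots, no dimer combination to score")
      }
      tabs[[i]] <- make_score_table(
        data.frame(label = v$label, class = v$class %||% "high"),
        n_pairs = np, n_sites = max(k, 2), seed = seed + i,
        high_center = dk$high_center, offset = dk$offset, spread = dk$spread
      )
    }
    score_table <- do.call(rbind, tabs)
    class(score_table) <- c("dock_score_table", "data.frame")
  }
  write_score_table(score_table, file.path(outdir, "docking_scores.tsv"))

  ref_labels <- unique(unlist(lapply(variants, function(v) v$reference)))
  bands <- list()
  for (rl in ref_labels) {
    if (!rl %in% score_table$variant) {
      stop_vhh("pipeline stage 'prediction' failed: reference variant '", rl,
               "' is missing from the docking score table")
    }
    bands[[rl]] <- reference_band(combination_scores(score_table, rl))
  }
  predictions <- list()
  for (v in variants) {
    if (is.null(v$reference)) next
    pred <- stage("prediction", v$label, predict_yield(
      score_table, bands[[v$reference]], variant = v$label,
      variant_n = n_residues(results[[v$label]]$representative),
      reference_n = n_residues(results[[v$reference]]$representative)
    ))
    predictions[[v$label]] <- pred
    msg("[%s] verdict: %s (%d/%d below wild-type mean %.1f)", v$label,
        pred$verdict, pred$n_below_reference, length(pred$five_lowest),
        pred$reference_mean)
  }
  if (length(predictions) > 0) {
    pred_df <- do.call(rbind, lapply(predictions, function(p) {
      data.frame(variant = p$variant_label, verdict = p$verdict,
                 n_below_reference = p$n_below_reference,
                 reference_mean = round(p$reference_mean, 3),
                 reference_sd = round(p$reference_sd, 3),
                 five_lowest = paste(round(p$five_lowest, 2), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write.table(pred_df, file.path(outdir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = seed,
    parameters = list(clustering = cl_cfg[!vapply(cl_cfg, is.null, logical(1))],
                      hotspots = hs_cfg,
                      docking = dk[c("high_center", "offset", "spread")]),
    variants = lapply(variants, function(v) {
      list(label = v$label, reference = v$reference %||% NA,
           n_hotspots = length(results[[v$label]]$hotspots$patches),
           n_dimer_combinations = nrow(results[[v$label]]$dimer_pairs),
           verdict = if (!is.null(predictions[[v$label]])) {
             predictions[[v$label]]$verdict
           } else {
             NA
           })
    }),
    files = sort(list.files(outdir, recursive = TRUE))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(variants = results, score_table = score_table,
                 predictions = predictions, outdir = outdir))
}
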