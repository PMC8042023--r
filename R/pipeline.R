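#' Run the full analysis pipeline on a simulated dataset
#'
#' Chains the stages `simulate` (ground-truthed growing/dividing cells with
#' wall-anchored motors), `render`/`detect` (optional: rendered image stacks
#' of the founding cell, spot localization and segmentation), `analyze`
#' (trace linking, per-motor velocities, the inert-zone changepoint fit,
#' pairwise expansion kinematics and the per-length growth rate, normalized
#' coordinates) and `bernoulli` (cross-generation map residuals and the
#' population distribution evolution). Each stage reads only the previous
#' stage's declared outputs; a manifest with checksums is written last, so a
#' rerun with the same config and seed yields identical checksums.
#'
#' @param config A `wm_sim_config`, or the path to a YAML config file (see
#'   [read_config()]).
#' @param out_dir Output directory (created).
#' @param seed Optional root seed override.
#' @param stages Stages to run; default `c("simulate", "analyze",
#'   "bernoulli")`. `"render"` and `"detect"` add the imaging path.
#' @param generations Number of divisions simulated (default from the
#'   config's pipeline block, or 1).
#' @return Invisibly, a list with the main results (`inert_fit`, `hubble`,
#'   `bernoulli`, file paths).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, stages = NULL,
                         generations = NULL) {
  if (is.character(config)) {
    cfgfile <- read_config(config)
    cfg <- cfgfile$sim
    pipe <- cfgfile$pipeline
  } else {
    cfg <- validate_sim_config(config)
    pipe <- list(generations = 1, new_motors_per_daughter = 0,
                 stages = c("simulate", "analyze", "bernoulli"))
  }
  if (!is.null(seed)) cfg$rng_seed <- as.integer(seed)
  if (!is.null(stages)) pipe$stages <- stages
  if (!is.null(generations)) pipe$generations <- generations
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()

  if ("simulate" %in% pipe$stages) {
    sim <- simulate_lineage(cfg, n_generations = pipe$generations,
                            new_motors_per_daughter = pipe$new_motors_per_daughter)
    obs <- add_noise_and_export(sim$truth, cfg, dir = out_dir)
    geo <- unique(sim$truth[, c("cell_id", "frame", "time_min",
                                "L_active_um", "cell_length_um", "phase")])
    write_table(geo, file.path(out_dir, "geometry.csv"), schema = "geometry")
    if (!is.null(sim$lineage)) {
      write_table(sim$lineage, file.path(out_dir, "lineage.csv"),
                  schema = "lineage")
    }
    results$sim <- sim
  }

  if ("render" %in% pipe$stages) {
    if (is.null(results$sim)) {
      # stage run on its own: re-derive the (deterministic) simulation
      results$sim <- simulate_lineage(cfg, n_generations = pipe$generations,
                                      new_motors_per_daughter =
                                        pipe$new_motors_per_daughter)
    }
    founder <- results$sim$cells[[1]]
    ren <- render_frames(founder, cfg)
    write_image_stack(ren$fluor, file.path(out_dir, "fluor.tif"))
    # the body channel is already normalized intensity in [0, 1]
    write_image_stack(ren$body, file.path(out_dir, "body.tif"), scale = 1)
    utils::write.csv(ren$meta, file.path(out_dir, "render_meta.csv"),
                     row.names = FALSE)
    results$render <- ren
  }

  if ("detect" %in% pipe$stages) {
    for (p in c("fluor.tif", "body.tif")) {
      if (!file.exists(file.path(out_dir, p))) {
        stop("missing upstream file ", p, "; rerun the 'render' stage",
             call. = FALSE)
      }
    }
    fluor <- read_image_stack(file.path(out_dir, "fluor.tif"))
    body <- read_image_stack(file.path(out_dir, "body.tif"), scale = 1)
    geoms <- align_geometries(lapply(body, function(b) {
      compute_midline(segment_cell(b), pixel_size = cfg$render$pixel_size)
    }))
    spots <- do.call(rbind, lapply(seq_along(fluor), function(i) {
      s <- detect_spots(fluor[[i]])
      if (nrow(s)) cbind(frame = i, s) else NULL
    }))
    write_table(spots, file.path(out_dir, "spots.csv"), schema = "spots")
    results$geoms <- geoms
    results$spots <- spots
  }

  if ("analyze" %in% pipe$stages) {
    obs_path <- file.path(out_dir, "observed.csv")
    geo_path <- file.path(out_dir, "geometry.csv")
    for (p in c(obs_path, geo_path)) {
      if (!file.exists(p)) {
        stop("missing upstream file ", basename(p),
             "; rerun the 'simulate' stage", call. = FALSE)
      }
    }
    obs <- read_table(obs_path, schema = "observed")
    geo <- read_table(geo_path, schema = "geometry")
    traces <- link_traces(obs, gate_um_per_10min = 0.3)
    write_table(traces, file.path(out_dir, "traces.csv"), schema = "traces")

    key <- paste(geo$cell_id, geo$frame)
    phase <- geo$phase[match(paste(traces$cell_id, traces$frame), key)]
    elong <- traces[phase == "elongation", , drop = FALSE]
    vfits <- fit_VPy_all(elong)
    fit <- fit_inert_zone(vfits$P_y0, vfits$V_Py, seed = cfg$rng_seed)
    jsonlite::write_json(
      list(P_yc = fit$P_yc, k = fit$k, rss = fit$rss,
           ci_Pyc = as.numeric(fit$ci_Pyc), n_motors = fit$n_motors),
      file.path(out_dir, "inert_zone.json"), auto_unbox = TRUE, digits = NA)

    pairs <- pair_kinematics(elong, P_yc = fit$P_yc)
    hub <- estimate_H(pairs)
    write_table(pairs, file.path(out_dir, "pairs.csv"), schema = "pairs")
    write_table(hub$estimates, file.path(out_dir, "hubble.csv"),
                schema = "hubble")

    norm <- normalize_positions(traces, geo, P_yc = fit$P_yc)
    write_table(norm$points, file.path(out_dir, "normalized.csv"),
                schema = "normalized")
    results$inert_fit <- fit
    results$hubble <- hub
    results$normalized <- norm
  }

  if ("bernoulli" %in% pipe$stages) {
    lin_path <- file.path(out_dir, "lineage.csv")
    bern <- list()
    if (file.exists(lin_path)) {
      lin <- read_table(lin_path, schema = "lineage")
      pv <- predict_vs_observed(lin$N_y_mother, lin$N_y_daughter)
      bern$fraction_on_map <- pv$fraction_on_map
      bern$max_residual <- if (pv$n) max(pv$residuals) else NA_real_
      bern$n_pairs <- pv$n
    }
    ev <- evolve_distribution(seed = cfg$rng_seed)
    hist_df <- data.frame(bin_low = ev$breaks[-length(ev$breaks)],
                          bin_high = ev$breaks[-1], ev$histograms)
    utils::write.csv(hist_df, file.path(out_dir, "bernoulli_hist.csv"),
                     row.names = FALSE)
    bern$ks_to_uniform <- ev$ks
    jsonlite::write_json(bern, file.path(out_dir, "bernoulli.json"),
                         auto_unbox = TRUE, digits = NA)
    results$bernoulli <- bern
  }

  write_manifest(out_dir, cfg, pipe)
  invisible(results)
}
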