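## Config-driven end-to-end runs: design -> stimuli -> simulated behaviour
## -> analysis, with every output reachable from a manifest and bit-identical
## under a fixed master seed.

#' Build or read a run configuration
#'
#' A run configuration names the experiment, the scene geometry, the
#' stimulus and observer parameters and the master seed. `run_config()`
#' fills defaults appropriate to the experiment; `read_run_config()` loads a
#' JSON file with the same fields. Unknown fields and invalid values fail
#' validation with the offending field named.
#'
#' @param experiment 1, 2 or 3.
#' @param seed master seed (mandatory for reproducible runs).
#' @param canvas_width,canvas_height scene size in px.
#' @param px_per_deg pixels per degree.
#' @param n_leaves number of leaf stamps per background.
#' @param pop_n size of the synthetic colour population.
#' @param n_stimuli how many of the design's trials to render as PNGs
#'   (stimulus rendering is costly; the default renders a small sample).
#' @param n_boot bootstrap resamples in the analysis.
#' @param cauchy_r Cauchy prior scale for the Bayes tests.
#' @param observer an [observer_model()].
#' @param depth_shift,depth_thresholds depth-model parameters (experiment 3).
#' @return a validated `run_config` list.
#' @export
run_config <- function(experiment = 1, seed = 1, canvas_width = 3500,
                       canvas_height = 1170,
                       px_per_deg = if (experiment == 3) exp3_px_per_deg()
                                    else exp1_px_per_deg(),
                       n_leaves = 15000, pop_n = 10000, n_stimuli = 2,
                       n_boot = 10000, cauchy_r = 1.0,
                       observer = observer_model(),
                       depth_shift = NULL,
                       depth_thresholds = c(-0.5, 0.5)) {
  cfg <- list(experiment = experiment, seed = seed,
              canvas_width = canvas_width, canvas_height = canvas_height,
              px_per_deg = px_per_deg, n_leaves = n_leaves, pop_n = pop_n,
              n_stimuli = n_stimuli, n_boot = n_boot, cauchy_r = cauchy_r,
              observer = observer, depth_shift = depth_shift,
              depth_thresholds = depth_thresholds)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(field, ok) {
    if (!ok) stop("run_config: invalid value for field '", field, "'")
  }
  known <- c("experiment", "seed", "canvas_width", "canvas_height",
             "px_per_deg", "n_leaves", "pop_n", "n_stimuli", "n_boot",
             "cauchy_r", "observer", "depth_shift", "depth_thresholds",
             "edge_variants")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("run_config: unknown field(s): ", paste(extra, collapse = ", "))
  }
  need("experiment", cfg$experiment %in% 1:3)
  need("seed", is.numeric(cfg$seed) && length(cfg$seed) == 1)
  need("canvas_width", cfg$canvas_width >= 64)
  need("canvas_height", cfg$canvas_height >= 64)
  need("px_per_deg", cfg$px_per_deg > 0)
  need("n_leaves", cfg$n_leaves >= 0)
  need("pop_n", cfg$pop_n >= 100)
  need("n_stimuli", cfg$n_stimuli >= 0)
  need("n_boot", cfg$n_boot >= 1)
  need("cauchy_r", cfg$cauchy_r > 0)
  if (!is.null(cfg$edge_variants)) {
    bad <- setdiff(cfg$edge_variants,
                   c("none", "both", "no_low", "no_high", "square"))
    if (length(bad) > 0) {
      stop("run_config: unknown edge variant in field 'edge_variants': ",
           paste(bad, collapse = ", "))
    }
  }
  if (!inherits(cfg$observer, "observer_model")) {
    cfg$observer <- do.call(observer_model, as.list(cfg$observer))
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON configuration path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(raw)
}

design_for <- function(cfg) {
  switch(cfg$experiment,
         design_exp1(seed = cfg$seed),
         design_exp2(seed = cfg$seed),
         design_exp3(seed = cfg$seed))
}

#' Run a full experiment pipeline
#'
#' Generates the trial design, renders a sample of stimulus images, simulates
#' observer behaviour, analyses it, and writes everything under `out_dir`:
#' `design.csv`, `stimuli/trial_*.png` (+ JSON sidecars), `behavior.csv`,
#' `analysis.csv`, `analysis.json`, and `manifest.json` recording the
#' package version, configuration and output files. Re-running with the same
#' configuration reproduces all tables bit-identically.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `design`, `behavior`, `analysis` (summary data frame)
#'   and `manifest`, invisibly.
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("run_experiment: cannot create output directory ", out_dir)
  }
  files <- character(0)
  rec <- function(f) files <<- c(files, f)

  design <- design_for(cfg)
  rec(write_design(design, file.path(out_dir, "design.csv")))

  pop <- filter_population(synth_forest_population(cfg$pop_n,
                                                   seed = cfg$seed))
  n_render <- min(cfg$n_stimuli, nrow(design))
  if (n_render > 0) {
    dir.create(file.path(out_dir, "stimuli"), showWarnings = FALSE)
    for (i in seq_len(n_render)) {
      tr <- design[i, ]
      stim <- render_trial_stimulus(tr, pop, cfg)
      f <- file.path(out_dir, "stimuli", sprintf("trial_%03d.png", tr$index))
      write_scene_png(stim$canvas, f,
                      meta = list(experiment = tr$experiment,
                                  index = tr$index, variant = tr$variant,
                                  offset = tr$offset, width = tr$width,
                                  shadows = tr$shadows, cell = tr$cell,
                                  orientation = tr$orientation,
                                  seed = tr$seed,
                                  target_bbox = as.list(stim$target_bbox)))
      rec(f); rec(paste0(f, ".json"))
    }
  }

  bcfg <- bayes_config(cauchy_r = cfg$cauchy_r)
  if (cfg$experiment %in% c(1, 2)) {
    behavior <- simulate_rt_dataset(design, cfg$observer, seed = cfg$seed)
    analysis <- analyze_rt_experiment(behavior, cfg = bcfg,
                                      n_boot = cfg$n_boot, seed = cfg$seed)
  } else {
    shift <- cfg$depth_shift
    if (!is.null(shift)) shift <- unlist(shift)
    behavior <- simulate_depth_dataset(design, shift = shift,
                                       thresholds = cfg$depth_thresholds,
                                       n_participants =
                                         cfg$observer$n_participants,
                                       seed = cfg$seed)
    analysis <- analyze_depth_experiment(behavior, cfg = bcfg)
  }
  rec(write_behavior(behavior, file.path(out_dir, "behavior.csv")))
  write.csv(analysis$summary, file.path(out_dir, "analysis.csv"),
            row.names = FALSE)
  rec(file.path(out_dir, "analysis.csv"))
  jsonlite::write_json(analysis$summary, file.path(out_dir, "analysis.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rec(file.path(out_dir, "analysis.json"))

  manifest <- list(package = "edgecamo",
                   version = as.character(packageVersion("edgecamo")),
                   seed = cfg$seed, experiment = cfg$experiment,
                   config = cfg[setdiff(names(cfg), "observer")],
                   observer = unclass(cfg$observer),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(design = design, behavior = behavior,
                 analysis = analysis$summary, manifest = manifest))
}

## Render the full stimulus for one design row.
render_trial_stimulus <- function(tr, pop, cfg) {
  canvas <- scene_canvas(cfg$canvas_width, cfg$canvas_height,
                         px_per_deg = cfg$px_per_deg)
  target_len <- if (cfg$experiment == 3) {
    round(deg_to_px(13.30, cfg$px_per_deg))
  } else {
    350
  }
  keepout <- NULL
  if (cfg$experiment == 3) {
    ## leaf-free central band (4.49 x 13.80 deg) so occlusion cannot act as
    ## a depth cue
    bw <- deg_to_px(4.49, cfg$px_per_deg)
    bh <- deg_to_px(13.80, cfg$px_per_deg)
    keepout <- c(cfg$canvas_width / 2 - bw / 2, cfg$canvas_width / 2 + bw / 2,
                 cfg$canvas_height / 2 - bh / 2,
                 cfg$canvas_height / 2 + bh / 2)
  }
  bg <- render_background(canvas, cfg$n_leaves, pop, shadows = tr$shadows,
                          keepout = keepout, seed = tr$seed)
  prof <- if (tr$variant == "none") edge_profile("none")
          else edge_profile(tr$variant, offset = tr$offset, width = tr$width)
  target <- make_target(pop, prof = prof, length = target_len,
                        orientation = tr$orientation, seed = tr$seed)
  compose_stimulus(bg, target, cell = tr$cell, seed = tr$seed)
}
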