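## Balanced factorial trial designs for the three experiments.
##
## Every design is a data frame with one row per trial: experiment, index
## (presentation order), variant/offset/width (the edge condition), shadows,
## cell (target region, 0 = centre), orientation and a per-trial seed
## derived from the master seed, so each trial's stimulus and simulated
## behaviour are independently reproducible.

## Documented seed-splitting rule: trial i of a design built under master
## seed s gets seed (s + 7919 * i) mod (2^31 - 1).
trial_seeds <- function(master_seed, n) {
  if (is.null(master_seed)) master_seed <- 0
  as.integer((as.numeric(master_seed) + 7919 * seq_len(n)) %% 2147483647)
}

condition_levels_exp1 <- function() {
  data.frame(variant = c("none", "both", "both", "both", "both"),
             offset = c(0, 20, 40, 20, 40),
             width = c(0, 8, 8, 16, 16))
}

condition_levels_exp2 <- function() {
  data.frame(
    variant = c("none", rep(c("no_high", "no_low", "square"), each = 2)),
    offset = c(0, rep(c(20, 40), times = 3)),
    width = c(0, rep(16, 6)))
}

condition_levels_exp3 <- function(offset = 40, width = 14) {
  data.frame(variant = c("none", "both", "no_high", "no_low"),
             offset = c(0, rep(offset, 3)),
             width = c(0, rep(width, 3)))
}

finish_design <- function(grid, experiment, seed) {
  n <- nrow(grid)
  grid <- with_seed_or_not(seed, {
    g <- grid[sample.int(n), , drop = FALSE]
    g$orientation <- runif(n, 0, 2 * pi)
    g
  })
  grid$experiment <- experiment
  grid$index <- seq_len(n)
  grid$seed <- trial_seeds(seed, n)
  rownames(grid) <- NULL
  grid[, c("experiment", "index", "variant", "offset", "width", "shadows",
           "cell", "orientation", "seed")]
}

#' Visual-search design, Experiment 1 (edge strength x shadows)
#'
#' Five edge conditions (no enhancement, and the `both` variant at widths 8
#' and 16 px crossed with offsets 20 and 40) x 2 shadow levels x 8 target
#' cells = 80 trials, presented in random order. Each condition appears once
#' per cell per shadow level, so exactly half of all trials are shadowed and
#' each cell hosts 10 trials.
#'
#' @param seed optional master seed; fixes order, orientations and per-trial
#'   seeds.
#' @return design data frame (80 rows).
#' @export
design_exp1 <- function(seed = NULL) {
  lv <- condition_levels_exp1()
  grid <- expand.grid(cond = seq_len(nrow(lv)), shadows = c(FALSE, TRUE),
                      cell = 1:8)
  grid <- cbind(lv[grid$cond, ], shadows = grid$shadows, cell = grid$cell)
  finish_design(grid, 1L, seed)
}

#' Visual-search design, Experiment 2 (edge structure x shadows)
#'
#' Seven edge conditions (control plus the `no_high`, `no_low` and `square`
#' variants at offsets 20 and 40, width fixed at 16 px = 0.5 deg) x 2 shadow
#' levels x 8 cells = 112 trials in random order.
#'
#' @inheritParams design_exp1
#' @return design data frame (112 rows).
#' @export
design_exp2 <- function(seed = NULL) {
  lv <- condition_levels_exp2()
  grid <- expand.grid(cond = seq_len(nrow(lv)), shadows = c(FALSE, TRUE),
                      cell = 1:8)
  grid <- cbind(lv[grid$cond, ], shadows = grid$shadows, cell = grid$cell)
  finish_design(grid, 2L, seed)
}

#' Depth-judgement design, Experiment 3
#'
#' Four edge types (control, `both`, `no_high`, `no_low`; no `square`
#' variant) x 2 background shadow levels x 25 repetitions = 200 trials in
#' random order. The target is central (`cell = 0`) and vertical
#' (orientation pi/2). The edge width is fixed at 0.53 deg at the monitor
#' scale (14 px); the offset is configurable (default 40).
#'
#' @inheritParams design_exp1
#' @param offset edge-enhancement offset for the non-control conditions.
#' @param width edge width in px at the Experiment-3 scale.
#' @return design data frame (200 rows).
#' @export
design_exp3 <- function(seed = NULL, offset = 40,
                        width = round(deg_to_px(0.53, exp3_px_per_deg()))) {
  lv <- condition_levels_exp3(offset, width)
  grid <- expand.grid(cond = seq_len(nrow(lv)), shadows = c(FALSE, TRUE),
                      rep = 1:25)
  grid <- cbind(lv[grid$cond, ], shadows = grid$shadows, cell = 0L)
  out <- finish_design(grid, 3L, seed)
  out$orientation <- pi / 2
  out
}

#' Condition label for an edge condition
#'
#' Canonical string key for an edge condition, e.g. `"none"` or
#' `"both_w16_o40"`; used to join designs, simulated behaviour and analysis
#' tables.
#'
#' @param variant,offset,width vectors describing the edge condition(s).
#' @return character vector.
#' @export
condition_label <- function(variant, offset, width) {
  ifelse(variant == "none", "none",
         sprintf("%s_w%g_o%g", variant, width, offset))
}

#' Write / read a trial design as CSV
#'
#' @param design a design data frame.
#' @param path CSV path.
#' @return `write_design()` returns `path` invisibly; `read_design()` the
#'   design data frame.
#' @export
write_design <- function(design, path) {
  write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
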