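## Synthetic observer behaviour.
##
## Stand-in participants with the statistical structure the analysis chain
## assumes: log-normal reaction times with additive participant and
## condition effects (so log-transform + z-scoring are exactly the right
## preprocessing in the null case), and an error probability that grows with
## the trial's latent log-RT, reproducing the positive RT-error coupling of
## real search data. Error trials are generated and later discarded by the
## analysis, exercising the exclusion path.

#' Observer model parameters
#'
#' @param n_participants number of simulated participants.
#' @param intercept_mean,intercept_sd distribution of per-participant mean
#'   log reaction times (log seconds).
#' @param participant_sd within-participant trial-to-trial SD of log RT.
#' @param condition_effects named numeric vector of additive log-RT shifts,
#'   keyed by [condition_label()]; conditions absent from the vector take
#'   effect 0 only if `condition_effects` is `NULL` (an explicitly supplied
#'   vector must cover every design condition).
#' @param error_base baseline error probability.
#' @param error_slope increase in error probability per unit of
#'   (log RT - participant intercept).
#' @return an `observer_model` list.
#' @export
observer_model <- function(n_participants = 10, intercept_mean = 1.0,
                           intercept_sd = 0.25, participant_sd = 0.4,
                           condition_effects = NULL, error_base = 0.06,
                           error_slope = 0.08) {
  stopifnot(n_participants >= 1, intercept_sd >= 0, participant_sd > 0,
            error_base >= 0, error_base <= 1)
  structure(list(n_participants = n_participants,
                 intercept_mean = intercept_mean,
                 intercept_sd = intercept_sd,
                 participant_sd = participant_sd,
                 condition_effects = condition_effects,
                 error_base = error_base, error_slope = error_slope),
            class = "observer_model")
}

lookup_effects <- function(model, labels) {
  eff <- model$condition_effects
  if (is.null(eff)) return(rep(0, length(labels)))
  missing <- setdiff(unique(labels), names(eff))
  if (length(missing) > 0) {
    stop("simulate_rt_dataset: no condition effect supplied for: ",
         paste(missing, collapse = ", "))
  }
  unname(eff[labels])
}

#' Simulate a reaction-time dataset (Experiments 1-2)
#'
#' Each participant responds to every trial of the design:
#' `log(rt) = intercept_p + effect_cond + Normal(0, participant_sd)`, and
#' the trial is an error with probability
#' `clamp(error_base + error_slope * (log rt - intercept_p), 0, 1)`.
#'
#' @param design a design from [design_exp1()] or [design_exp2()].
#' @param model an [observer_model()].
#' @param seed optional integer seed; the dataset is seed-deterministic.
#' @return data frame with one row per participant x trial: `participant`,
#'   `index`, `variant`, `offset`, `width`, `condition`, `shadows`, `cell`,
#'   `rt` (seconds), `correct`.
#' @export
simulate_rt_dataset <- function(design, model = observer_model(),
                                seed = NULL) {
  stopifnot(inherits(model, "observer_model"))
  labels <- condition_label(design$variant, design$offset, design$width)
  eff <- lookup_effects(model, labels)
  n_p <- model$n_participants
  n_t <- nrow(design)
  with_seed_or_not(seed, {
    intercepts <- rnorm(n_p, model$intercept_mean, model$intercept_sd)
    out <- do.call(rbind, lapply(seq_len(n_p), function(p) {
      logrt <- intercepts[p] + eff + rnorm(n_t, 0, model$participant_sd)
      p_err <- pmin(pmax(model$error_base +
                           model$error_slope * (logrt - intercepts[p]),
                         0), 1)
      data.frame(participant = p, index = design$index,
                 variant = design$variant, offset = design$offset,
                 width = design$width, condition = labels,
                 shadows = design$shadows, cell = design$cell,
                 rt = exp(logrt), correct = runif(n_t) >= p_err)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a depth-judgement dataset (Experiment 3)
#'
#' An ordinal-probit response model: each trial draws a latent relief
#' impression `Normal(shift_cond, 1)` and codes it -1 (flatter) below the
#' low threshold, 0 (same relief) between the thresholds, +1 (more relief)
#' above the high threshold.
#'
#' @param design a design from [design_exp3()].
#' @param shift named numeric vector of latent means keyed by
#'   [condition_label()] (conditions not named take 0), or `NULL` for the
#'   null model.
#' @param thresholds numeric `c(low, high)` with `low < high`.
#' @param n_participants number of simulated participants.
#' @param seed optional integer seed.
#' @return data frame with columns `participant`, `index`, `variant`,
#'   `offset`, `width`, `condition`, `shadows`, `depth_response` in
#'   \{-1, 0, 1\}.
#' @export
simulate_depth_dataset <- function(design, shift = NULL,
                                   thresholds = c(-0.5, 0.5),
                                   n_participants = 10, seed = NULL) {
  stopifnot(length(thresholds) == 2)
  if (thresholds[1] >= thresholds[2]) {
    stop("simulate_depth_dataset: thresholds must satisfy low < high")
  }
  labels <- condition_label(design$variant, design$offset, design$width)
  mu <- rep(0, length(labels))
  if (!is.null(shift)) {
    hit <- labels %in% names(shift)
    mu[hit] <- shift[labels[hit]]
  }
  n_t <- nrow(design)
  with_seed_or_not(seed, {
    out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
      latent <- rnorm(n_t, mu, 1)
      data.frame(participant = p, index = design$index,
                 variant = design$variant, offset = design$offset,
                 width = design$width, condition = labels,
                 shadows = design$shadows,
                 depth_response = ifelse(latent < thresholds[1], -1L,
                                         ifelse(latent > thresholds[2],
                                                1L, 0L)))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Expected mean coded depth response under the ordinal-probit model
#'
#' Closed form: `P(latent > high) - P(latent < low)` for
#' `latent ~ Normal(shift, 1)`.
#'
#' @param shift latent mean.
#' @param thresholds `c(low, high)`.
#' @return expected value of the -1/0/+1 coded response.
#' @export
expected_depth_response <- function(shift, thresholds = c(-0.5, 0.5)) {
  stats::pnorm(shift - thresholds[2]) - stats::pnorm(thresholds[1] - shift)
}

#' Write / read behaviour tables as CSV
#'
#' @param trials a behaviour data frame from [simulate_rt_dataset()] or
#'   [simulate_depth_dataset()].
#' @param path CSV path.
#' @return `write_behavior()` returns `path` invisibly; `read_behavior()`
#'   the data frame.
#' @export
write_behavior <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
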