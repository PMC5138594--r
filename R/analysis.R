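## Search-time analysis chain.
##
## Error trials are excluded, reaction times are log transformed and
## z-scored within participant, per-condition means are referenced to the
## no-enhancement control separately at each shadow level, and each
## condition's control-relative scores are tested against zero with a
## one-sample JZS Bayes-factor t-test (the paired design collapses to a
## one-sample test on the per-participant differences).

#' Preprocess reaction times
#'
#' Removes error trials, log transforms the remaining reaction times,
#' z-scores them within participant (each participant's own mean and sample
#' SD across all of their correct trials), and averages per participant x
#' condition x shadow level. Participants with fewer than two correct trials
#' cannot be z-scored and are dropped with a warning.
#'
#' @param trials data frame with columns `participant`, `variant`, `offset`,
#'   `width`, `shadows`, `rt`, `correct` (e.g. from
#'   [simulate_rt_dataset()]).
#' @return score table: one row per participant x condition x shadow level
#'   with columns `participant`, `variant`, `offset`, `width`, `condition`,
#'   `shadows`, `mean_z`.
#' @export
preprocess_rt <- function(trials) {
  stopifnot(all(c("participant", "variant", "offset", "width", "shadows",
                  "rt", "correct") %in% names(trials)))
  ok <- trials[trials$correct, , drop = FALSE]
  counts <- table(ok$participant)
  bad <- names(counts)[counts < 2]
  lost <- setdiff(unique(trials$participant), ok$participant)
  bad <- union(bad, as.character(lost))
  if (length(bad) > 0) {
    warning("preprocess_rt: dropping participant(s) with < 2 correct ",
            "trials: ", paste(bad, collapse = ", "))
    ok <- ok[!(as.character(ok$participant) %in% bad), , drop = FALSE]
  }
  if (nrow(ok) == 0) stop("preprocess_rt: no usable trials remain")
  ok$logrt <- log(ok$rt)
  z <- ave(ok$logrt, ok$participant,
           FUN = function(x) (x - mean(x)) / sd(x))
  ok$z <- z
  agg <- aggregate(z ~ participant + variant + offset + width + shadows,
                   data = ok, FUN = mean)
  names(agg)[names(agg) == "z"] <- "mean_z"
  agg$condition <- condition_label(agg$variant, agg$offset, agg$width)
  agg <- agg[order(agg$participant, agg$shadows, agg$condition), ]
  rownames(agg) <- NULL
  agg[, c("participant", "variant", "offset", "width", "condition",
          "shadows", "mean_z")]
}

#' Control-relative scores
#'
#' Subtracts, for each participant and shadow level, the participant's
#' control (no-enhancement) mean from every condition mean at the same
#' shadow level, isolating the contribution of edge enhancement from that
#' of the disruptive pattern itself. Control rows become exactly 0.
#'
#' @param scores a score table from [preprocess_rt()].
#' @return the score table with an added `rel_z` column.
#' @export
control_relative <- function(scores) {
  stopifnot(all(c("participant", "condition", "shadows", "mean_z")
                %in% names(scores)))
  key <- interaction(scores$participant, scores$shadows, drop = TRUE)
  ctrl <- scores$condition == "none"
  if (!all(unique(key) %in% unique(key[ctrl]))) {
    stop("control_relative: control condition missing for some ",
         "participant x shadow level")
  }
  ctrl_mean <- tapply(scores$mean_z[ctrl], key[ctrl], mean)
  scores$rel_z <- scores$mean_z - unname(ctrl_mean[as.character(key)])
  scores
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric vector (>= 2 values).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional integer seed; the interval is seed-deterministic.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = NULL) {
  n <- length(values)
  if (n < 2) stop("bootstrap_ci: need at least 2 values")
  stopifnot(level > 0, level < 1, n_boot >= 1)
  with_seed_or_not(seed, {
    bm <- rowMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                          nrow = n_boot))
    q <- quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    c(lo = q[1], hi = q[2])
  })
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` (statistic) and `p` (p-value).
#' @export
shapiro_wilk <- function(values) {
  n <- length(values[is.finite(values)])
  if (n < 3 || n > 5000) {
    stop("shapiro_wilk: sample size must be in [3, 5000], got ", n)
  }
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Jeffreys / Lee-Wagenmakers evidence label
#'
#' Buckets the Bayes factor magnitude at 1, 3, 10, 30 and 100 (natural-log
#' thresholds 0, ln 3, ln 10, ln 30, ln 100) into anecdotal, moderate,
#' strong, very strong and extreme evidence; the direction is H1 when
#' `log_bf10 > 0` and H0 otherwise (a Bayes factor of exactly 1 is labelled
#' anecdotal). `stars` gives the 0-4 star shorthand used on result plots.
#'
#' @param log_bf10 natural-log Bayes factor for H1 over H0 (finite).
#' @return list with `category`, `direction`, `stars`, `label` (e.g.
#'   `"Strong - H1"`).
#' @export
evidence_label <- function(log_bf10) {
  stopifnot(is.finite(log_bf10))
  a <- abs(log_bf10)
  cats <- c("anecdotal", "moderate", "strong", "very strong", "extreme")
  i <- findInterval(a, log(c(3, 10, 30, 100))) + 1
  direction <- if (log_bf10 > 0) "H1" else "H0"
  list(category = cats[i], direction = direction, stars = i - 1L,
       label = paste0(toupper(substring(cats[i], 1, 1)),
                      substring(cats[i], 2), " - ", direction))
}

#' Bayes-factor t-test configuration
#'
#' @param cauchy_r Cauchy prior scale on effect size (default 1.0).
#' @param sweep length-2 vector of prior scales for the robustness sweep
#'   (default 0.7 and 1.45).
#' @return a `bayes_config` list.
#' @export
bayes_config <- function(cauchy_r = 1.0, sweep = c(0.7, 1.45)) {
  stopifnot(cauchy_r > 0, length(sweep) == 2, sweep[1] < sweep[2])
  structure(list(cauchy_r = cauchy_r, sweep = sweep),
            class = "bayes_config")
}

## Core JZS computation from the t statistic. Uses the Rouder et al. scale
## mixture: under H1 the standardised effect has a Cauchy(0, r) prior,
## equivalently a normal prior with variance g mixed over
## g ~ InverseGamma(1/2, r^2/2). BF10 is the ratio of the two marginal
## likelihoods; writing it as a ratio inside the integrand keeps it stable
## for large t.
jzs_bf_from_t <- function(t, n, r) {
  nu <- n - 1
  integrand <- function(g) {
    (1 + n * g)^(-0.5) *
      ((1 + t^2 / ((1 + n * g) * nu)) / (1 + t^2 / nu))^(-(nu + 1) / 2) *
      r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
  }
  I <- integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 0)
  list(log_bf10 = log(I$value), num_error = I$abs.error / I$value)
}

#' One-sample JZS Bayes-factor t-test
#'
#' Two-tailed default Bayes factor for the mean of `values` against
#' `null_mean`, with a Cauchy prior of scale `cauchy_r` on the standardised
#' effect size. Computed by adaptive quadrature over the effect-variance
#' mixing parameter; the relative numerical-integration error is reported
#' alongside the Bayes factor.
#'
#' @param values numeric vector (n >= 2, non-constant).
#' @param null_mean null-hypothesis mean.
#' @param cfg a [bayes_config()].
#' @return a `bayes_result`: list with `log_bf10` (natural log), `bf10`,
#'   `t`, `n`, `cauchy_r`, `num_error`, and the [evidence_label()] fields
#'   `category`, `direction`, `stars`, `label`.
#' @export
jzs_bf_ttest <- function(values, null_mean = 0, cfg = bayes_config()) {
  stopifnot(inherits(cfg, "bayes_config"))
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("jzs_bf_ttest: need at least 2 finite values")
  s <- sd(values)
  if (s == 0) stop("jzs_bf_ttest: degenerate data (zero variance)")
  t <- (mean(values) - null_mean) / (s / sqrt(n))
  res <- jzs_bf_from_t(t, n, cfg$cauchy_r)
  lab <- evidence_label(res$log_bf10)
  structure(c(list(log_bf10 = res$log_bf10, bf10 = exp(res$log_bf10),
                   t = t, n = n, cauchy_r = cfg$cauchy_r,
                   num_error = res$num_error), lab),
            class = "bayes_result")
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("JZS Bayes t-test: log_e(BF10) = %.3f (r = %.2f, n = %d, ",
              x$log_bf10, x$cauchy_r, x$n),
      sprintf("t = %.2f, num. error %.2e)\n", x$t, x$num_error),
      sprintf("  evidence: %s\n", x$label), sep = "")
  invisible(x)
}

#' Prior-width robustness sweep
#'
#' Recomputes the Bayes factor at the sweep bounds and the default prior
#' scale; conclusions are robust when the H1/H0 direction agrees across the
#' sweep.
#'
#' @inheritParams jzs_bf_ttest
#' @return data frame with one row per prior scale: `cauchy_r`, `log_bf10`,
#'   `direction`, `category`.
#' @export
bf_robustness <- function(values, null_mean = 0, cfg = bayes_config()) {
  rs <- sort(unique(c(cfg$sweep[1], cfg$cauchy_r, cfg$sweep[2])))
  rows <- lapply(rs, function(r) {
    b <- jzs_bf_ttest(values, null_mean, bayes_config(cauchy_r = r,
                                                      sweep = cfg$sweep))
    data.frame(cauchy_r = r, log_bf10 = b$log_bf10,
               direction = b$direction, category = b$category)
  })
  do.call(rbind, rows)
}

#' Per-condition mean coded depth responses
#'
#' Averages the -1/0/+1 coded depth responses per participant x condition x
#' shadow level, then across participants.
#'
#' @param trials data frame from [simulate_depth_dataset()] (columns
#'   `participant`, `variant`, `offset`, `width`, `shadows`,
#'   `depth_response`).
#' @return list with `by_participant` (participant x condition means) and
#'   `by_condition` (group means).
#' @export
code_depth_responses <- function(trials) {
  stopifnot(all(c("participant", "variant", "offset", "width", "shadows",
                  "depth_response") %in% names(trials)))
  if (!all(trials$depth_response %in% c(-1, 0, 1))) {
    stop("code_depth_responses: depth responses must be coded -1, 0 or +1")
  }
  bp <- aggregate(depth_response ~ participant + variant + offset + width +
                    shadows, data = trials, FUN = mean)
  names(bp)[names(bp) == "depth_response"] <- "mean_coded"
  bp$condition <- condition_label(bp$variant, bp$offset, bp$width)
  bc <- aggregate(mean_coded ~ variant + offset + width + shadows +
                    condition, data = bp, FUN = mean)
  list(by_participant = bp, by_condition = bc)
}

#' Full analysis of a reaction-time experiment
#'
#' Runs the whole chain on a trial table: preprocessing, control-relative
#' scoring, per-condition group means with percentile-bootstrap confidence
#' intervals, Shapiro-Wilk normality checks, and one-sample JZS Bayes-factor
#' t-tests of each edge condition against its same-background control.
#'
#' @param trials a trial table (see [preprocess_rt()]).
#' @param cfg a [bayes_config()].
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param seed optional integer seed for the bootstrap.
#' @return list with `scores` (the control-relative score table) and
#'   `summary`: one row per non-control condition x shadow level with group
#'   mean, bootstrap CI, Shapiro-Wilk W and p, log_e BF10, numerical error,
#'   and evidence label.
#' @export
analyze_rt_experiment <- function(trials, cfg = bayes_config(),
                                  n_boot = 10000, seed = NULL) {
  scores <- control_relative(preprocess_rt(trials))
  conds <- unique(scores[scores$condition != "none",
                         c("variant", "offset", "width", "condition",
                           "shadows")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- scores$condition == conds$condition[i] &
      scores$shadows == conds$shadows[i]
    v <- scores$rel_z[sel]
    ci <- bootstrap_ci(v, n_boot = n_boot, seed = seed)
    sw <- shapiro_wilk(v)
    bf <- jzs_bf_ttest(v, 0, cfg)
    cbind(conds[i, , drop = FALSE],
          data.frame(n = length(v), mean_rel_z = mean(v), ci_lo = ci["lo"],
                     ci_hi = ci["hi"], shapiro_W = sw$W, shapiro_p = sw$p,
                     log_bf10 = bf$log_bf10, num_error = bf$num_error,
                     stars = bf$stars, evidence = bf$label))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(scores = scores, summary = summary)
}

#' Full analysis of a depth-judgement experiment
#'
#' Mirrors the per-condition Bayes tests of the depth study: each edge
#' condition's per-participant mean coded response is differenced against
#' the same-background control and tested against zero with a one-sample
#' JZS Bayes-factor t-test.
#'
#' @param trials a depth trial table (see [code_depth_responses()]).
#' @param cfg a [bayes_config()].
#' @return list with `means` (from [code_depth_responses()]) and `summary`
#'   (one row per non-control condition x shadow level with the mean coded
#'   difference and Bayes-test results).
#' @export
analyze_depth_experiment <- function(trials, cfg = bayes_config()) {
  means <- code_depth_responses(trials)
  bp <- means$by_participant
  key <- interaction(bp$participant, bp$shadows, drop = TRUE)
  ctrl <- bp$condition == "none"
  ctrl_mean <- tapply(bp$mean_coded[ctrl], key[ctrl], mean)
  bp$rel <- bp$mean_coded - unname(ctrl_mean[as.character(key)])
  conds <- unique(bp[bp$condition != "none",
                     c("variant", "offset", "width", "condition", "shadows")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- bp$condition == conds$condition[i] &
      bp$shadows == conds$shadows[i]
    v <- bp$rel[sel]
    bf <- jzs_bf_ttest(v, 0, cfg)
    cbind(conds[i, , drop = FALSE],
          data.frame(n = length(v), mean_coded_diff = mean(v),
                     log_bf10 = bf$log_bf10, num_error = bf$num_error,
                     stars = bf$stars, evidence = bf$label))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(means = means, summary = summary)
}
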