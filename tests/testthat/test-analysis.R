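make_trials <- function(participant, variant, rt, correct = TRUE,
                        shadows = FALSE, offset = 0, width = 0) {
  data.frame(participant = participant, variant = variant, offset = offset,
             width = width, shadows = shadows, cell = 1, rt = rt,
             correct = correct)
}

test_that("preprocessing log-transforms and z-scores within participant", {
  ## correct RTs 1, e, e^2 in three conditions: z-scores -1, 0, +1
  tr <- make_trials(1, c("none", "a", "b"), c(1, exp(1), exp(2)))
  sc <- preprocess_rt(tr)
  expect_equal(sort(sc$mean_z), c(-1, 0, 1))

  ## per-participant z-scores have mean 0 and sample SD 1 exactly
  set.seed(1)
  tr2 <- make_trials(rep(1:3, each = 40),
                     rep(rep(c("none", "a"), each = 20), 3),
                     exp(rnorm(120)))
  sc2 <- preprocess_rt(tr2)
  ## reconstruct from raw: z within participant
  raw <- tr2
  raw$z <- ave(log(raw$rt), raw$participant,
               FUN = function(x) (x - mean(x)) / sd(x))
  for (p in 1:3) {
    expect_equal(mean(raw$z[raw$participant == p]), 0)
    expect_equal(sd(raw$z[raw$participant == p]), 1)
  }

  ## an all-error participant is dropped with a warning, others unaffected
  tr3 <- rbind(tr2, make_trials(rep(4, 10), "none", exp(rnorm(10)),
                                correct = FALSE))
  expect_warning(sc3 <- preprocess_rt(tr3), "dropping participant")
  expect_equal(sc3, sc2)

  ## error trials are excluded before z-scoring
  tr4 <- rbind(tr, make_trials(1, "c", 1e6, correct = FALSE))
  expect_equal(sort(preprocess_rt(tr4)$mean_z), c(-1, 0, 1))
})

test_that("control-relative scoring zeroes the control and ignores shifts", {
  des <- design_exp1(seed = 1)
  beh <- simulate_rt_dataset(des, observer_model(), seed = 2)
  sc <- control_relative(preprocess_rt(beh))
  expect_true(all(sc$rel_z[sc$condition == "none"] == 0))

  ## adding a constant to one participant's scores changes nothing
  sc_shift <- sc
  sc_shift$mean_z[sc_shift$participant == 3] <-
    sc_shift$mean_z[sc_shift$participant == 3] + 5
  expect_equal(control_relative(sc_shift)$rel_z, sc$rel_z)

  ## multiplying a participant's RTs by a constant is absorbed upstream
  beh2 <- beh
  beh2$rt[beh2$participant == 2] <- beh2$rt[beh2$participant == 2] * 3.7
  sc2 <- control_relative(preprocess_rt(beh2))
  expect_equal(sc2$rel_z, sc$rel_z)

  expect_error(control_relative(sc[sc$condition != "none", ]),
               "control condition missing")
})

test_that("bootstrap intervals are deterministic and calibrated", {
  ## a constant sample gives a degenerate interval at the constant
  expect_equal(unname(bootstrap_ci(rep(2.5, 8), seed = 1)), c(2.5, 2.5))
  v <- withr::with_seed(3, rnorm(10))
  expect_identical(bootstrap_ci(v, seed = 7), bootstrap_ci(v, seed = 7))
  expect_error(bootstrap_ci(1), "at least 2")

  ## coverage of the true mean for n = 10 normal samples: the percentile
  ## bootstrap is known to undercover slightly at this n (~90%, against a
  ## nominal 95%)
  cov <- withr::with_seed(42, {
    mean(replicate(1000, {
      x <- rnorm(10)
      ci <- bootstrap_ci(x, n_boot = 1000)
      ci["lo"] <= 0 && 0 <= ci["hi"]
    }))
  })
  expect_gte(cov, 0.87)
  expect_lte(cov, 0.95)
})

test_that("normality checks behave like Shapiro-Wilk should", {
  q <- qnorm(((1:10) - 0.5) / 10)
  r <- shapiro_wilk(q)
  expect_gt(r$p, 0.05)
  expect_lte(r$W, 1)
  skewed <- exp(withr::with_seed(8, rnorm(50)))
  expect_lt(shapiro_wilk(skewed)$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "sample size")
})

test_that("the JZS Bayes factor matches the quadrature oracle", {
  ## t = 0: data maximally consistent with the null
  x0 <- sample_with_t(0, 10)
  expect_lt(jzs_bf_ttest(x0)$log_bf10, 0)

  for (t in c(0, 1, 2, 5)) {
    for (n in c(5, 10, 30)) {
      for (r in c(0.7, 1.0, 1.45)) {
        x <- sample_with_t(t, n)
        got <- jzs_bf_ttest(x, cfg = bayes_config(cauchy_r = r))
        want <- jzs_oracle(t, n, r)
        expect_equal(got$log_bf10, want, tolerance = 1e-3)
        expect_lt(got$num_error, 1e-4)
      }
    }
  }

  ## reciprocity: BF10 * BF01 = 1 within the numerical error
  b <- jzs_bf_ttest(sample_with_t(2, 10))
  expect_equal(b$bf10 * exp(-b$log_bf10), 1, tolerance = b$num_error + 1e-12)

  expect_error(jzs_bf_ttest(rep(1, 5)), "zero variance")
  expect_error(jzs_bf_ttest(c(1)), "at least 2")
})

test_that("evidence labels reproduce the published categories", {
  ## printed depth-study Bayes factors and their labels
  tab <- list(list(7.460, "extreme", "H1"),
              list(4.932, "extreme", "H1"),
              list(5.227, "extreme", "H1"),
              list(5.394, "extreme", "H1"),
              list(2.894, "strong", "H1"),
              list(5.995, "extreme", "H1"),
              ## search-study values quoted in the text
              list(3.689, "very strong", "H1"),
              list(2.589, "strong", "H1"),
              list(2.102, "moderate", "H1"),
              list(1.495, "moderate", "H1"))
  for (row in tab) {
    lab <- evidence_label(row[[1]])
    expect_equal(lab$category, row[[2]])
    expect_equal(lab$direction, row[[3]])
  }
  ## boundary and H0 side
  expect_equal(evidence_label(0)$category, "anecdotal")
  expect_equal(evidence_label(0)$direction, "H0")
  expect_equal(evidence_label(-2.5)$category, "strong")
  expect_equal(evidence_label(-2.5)$direction, "H0")
  expect_equal(evidence_label(log(150))$stars, 4L)
})

test_that("conclusions are robust across the Cauchy prior sweep", {
  ## a clear effect (d ~ 1, n = 10) points to H1 at every prior width
  x <- withr::with_seed(11, rnorm(10, 1, 1))
  sw <- bf_robustness(x)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$cauchy_r, c(0.7, 1.0, 1.45))
  expect_true(all(sw$direction == "H1"))
  ## and a null sample points to H0 throughout
  sw0 <- bf_robustness(sample_with_t(0, 10))
  expect_true(all(sw0$direction == "H0"))
})

test_that("depth responses are coded and averaged correctly", {
  des <- design_exp3(seed = 1)
  d <- simulate_depth_dataset(des, seed = 2)
  d$depth_response <- 1L
  expect_equal(unique(code_depth_responses(d)$by_condition$mean_coded), 1)
  d$depth_response <- rep(c(-1L, 0L, 1L), length.out = nrow(d))
  expect_lt(abs(mean(code_depth_responses(d)$by_condition$mean_coded)),
            0.01)
  d$depth_response[1] <- 2L
  expect_error(code_depth_responses(d), "coded -1, 0 or \\+1")
})

test_that("the full RT analysis summarises every non-control condition", {
  des <- design_exp1(seed = 3)
  beh <- simulate_rt_dataset(des, observer_model(), seed = 4)
  an <- analyze_rt_experiment(beh, n_boot = 500, seed = 5)
  expect_equal(nrow(an$summary), 8)  # 4 conditions x 2 shadow levels
  expect_true(all(c("mean_rel_z", "ci_lo", "ci_hi", "shapiro_W",
                    "log_bf10", "evidence") %in% names(an$summary)))
  expect_true(all(an$summary$ci_lo <= an$summary$mean_rel_z &
                    an$summary$mean_rel_z <= an$summary$ci_hi))
  ## deterministic under the same seed
  an2 <- analyze_rt_experiment(beh, n_boot = 500, seed = 5)
  expect_equal(an$summary, an2$summary)
})
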