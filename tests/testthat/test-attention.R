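test_that("cue-conditioned modulator variances match direct computation", {
  set.seed(31)
  tt <- 200
  cue <- rep(c("L", "R"), each = tt / 2)
  m <- cbind(rnorm(tt, 0, ifelse(cue == "R", 0.8, 1.2)),  # L-hemisphere mod
             rnorm(tt, 0, 1))
  vr <- modulator_variance_by_cue(m, cue, c("L", "R"))
  # the L modulator is "toward" when the cue is in the right hemifield
  expect_equal(vr$var_toward[1], var(m[cue == "R", 1]))
  expect_equal(vr$var_away[1], var(m[cue == "L", 1]))
  expect_equal(vr$ratio, vr$var_toward / vr$var_away)
  expect_false(any(vr$low_confidence))
  w_low <- capture_warnings(modulator_variance_by_cue(m[1:40, ], cue[1:40],
                                                      c("L", "R")))
  expect_true(any(grepl("fewer than", w_low)))

  # NA labels are assigned from the squared weight mass per hemisphere
  w <- rbind(matrix(c(1, 0), 3, 2, byrow = TRUE),
             matrix(c(0, 1), 3, 2, byrow = TRUE))
  hemi <- rep(c("L", "R"), each = 3)
  vr2 <- modulator_variance_by_cue(m, cue, c(NA, NA), W = w,
                                   unit_hemisphere = hemi)
  expect_equal(vr2$hemisphere, c("L", "R"))
  expect_error(modulator_variance_by_cue(m, cue, c(NA, NA)), "weight mass")
})

test_that("variance ratios aggregate by geometric mean", {
  expect_equal(aggregate_variance_ratios(c(2, 0.5)), 1)
  expect_equal(aggregate_variance_ratios(c(4, 4, 0.25)),
               exp(mean(log(c(4, 4, 0.25)))))
  df <- data.frame(ratio = c(0.7, 0.9))
  expect_equal(aggregate_variance_ratios(df), sqrt(0.7 * 0.9))
})

test_that("weight/d-prime summaries bin and correlate correctly", {
  set.seed(32)
  w <- sort(rnorm(50))
  dp <- 2 * w + rnorm(50, 0, 1e-6)   # essentially perfect relation
  out <- weight_vs_dprime(w, dp, n_groups = 5)
  expect_equal(out$correlation, 1, tolerance = 1e-6)
  expect_equal(nrow(out$bin_means), 5)
  expect_true(all(diff(out$bin_means$mean_dprime) > 0))
  out2 <- weight_vs_dprime(w, dp, rates = runif(50, 1, 10), n_strata = 3)
  expect_equal(nrow(out2$stratified), 3)
  expect_error(weight_vs_dprime(w[1:3], dp[1:3], n_groups = 5), "fewer")
})

test_that("predicted attention effects agree between analytics and simulation", {
  set.seed(33)
  n <- 6
  # u = 0 so the toward/away contrast isolates the modulator-variance
  # change (a cue gain also moves the mean and with it the Fano factor)
  f <- runif(n, 3, 10); u <- rep(0, n); v <- abs(rnorm(n, 0, 0.1))
  w <- matrix(abs(rnorm(n * 2, 0, 0.15)), n, 2)
  hemi <- rep(c("L", "R"), each = 3)
  an <- predicted_attention_effects(f, u, v, w, var_toward = c(0.7, 0.7),
                                    var_away = c(1, 1), hemisphere = hemi)
  # analytic Fano follows the log-normal-gain law
  s2 <- v^2 + as.vector(w^2 %*% c(0.7, 0.7))
  mu <- f * exp(u)
  expect_equal(an$units$fano_toward, (mu + mu^2 * (exp(s2) - 1)) / mu)
  # lower modulator variance means lower Fano and correlation
  expect_true(all(an$units$delta_fano < 0))
  expect_true(all(an$pairs$delta_corr < 0))
  si <- predicted_attention_effects(f, u, v, w, c(0.7, 0.7), c(1, 1), hemi,
                                    method = "simulation", n_sim = 4e4)
  expect_equal(si$units$fano_toward, an$units$fano_toward, tolerance = 0.15)
  expect_equal(si$pairs$corr_away, an$pairs$corr_away, tolerance = 0.1)
  expect_error(predicted_attention_effects(f, u, v, w, c(0.7, 0.7), c(1, 1),
                                           hemi, method = "simulation",
                                           n_sim = 100), "1e4")
})

test_that("covariance-ratio eigenvalues detect a planted variance change", {
  set.seed(34)
  tt <- 1000
  trial <- rep(1:250, each = 4)
  cue <- c("L", "R")[trial %% 2 + 1]
  m <- cbind(rnorm(tt, 0, ifelse(cue == "L", 1.3, 0.8)),
             rnorm(tt, 0, ifelse(cue == "L", 0.8, 1.3)))
  ce <- covariance_ratio_eigs(m, cue, trial, n_perm = 100)
  expect_gt(ce$lambda_max, 1)
  expect_lt(ce$lambda_min, 1)
  expect_equal(ce$lambda_max, (1.3 / 0.8)^2, tolerance = 0.25)
  expect_equal(dim(ce$null), c(100, 2))
  # the observed change exceeds the label-permutation null
  expect_gt(ce$lambda_max, quantile(ce$null[, "lambda_max"], 0.95))
  expect_error(covariance_ratio_eigs(m, cue, NULL, n_perm = 10), "trial_id")
})

test_that("modulator autocorrelation tracks the generating AR coefficient", {
  set.seed(35)
  tt <- 4000
  block <- rep(1:8, each = tt / 8)
  phi <- 0.6
  x <- as.vector(arima.sim(list(ar = phi), tt))
  ac <- modulator_autocorrelation(cbind(x), block, max_lag = 3)
  expect_equal(dim(ac), c(3, 1))
  expect_equal(unname(ac[1, 1]), phi, tolerance = 0.1)
  expect_equal(unname(ac[2, 1]), phi^2, tolerance = 0.12)
  expect_warning(modulator_autocorrelation(cbind(x), rep(1:500, each = 8),
                                           max_lag = 10), "truncated")
  expect_error(modulator_autocorrelation(cbind(x), seq_len(tt),
                                         max_lag = 10), "too short")
  expect_equal(modulator_crosscorrelation(cbind(x, x)), 1)
})
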