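test_that("synthetic truth is reproducible and calibrated to the target", {
  t1 <- synthetic_truth(seed = 3, n_units = 40, n_presentations = 500)
  t2 <- synthetic_truth(seed = 3, n_units = 40, n_presentations = 500)
  expect_identical(t1$f, t2$f)
  expect_identical(t1$lambda_scale, t2$lambda_scale)

  # calibration hits the analytic target within its stated 10% tolerance
  cal <- popgain:::analytic_median_corr(t1, t1$lambda_scale)
  expect_equal(cal, 0.05, tolerance = 0.1)

  # the analytic objective is non-decreasing in lambda on the calibrated
  # (ascending) branch
  grid <- seq(0.2, 1, length.out = 5) * t1$lambda_scale
  vals <- vapply(grid, function(l) popgain:::analytic_median_corr(t1, l),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))

  expect_error(match_noise_correlation_scale(t1, 0.9), "unreachable")
  t0 <- match_noise_correlation_scale(t1, 0)
  expect_identical(t0$lambda_scale, 0)
})

test_that("generated datasets have the documented structure", {
  # two cue blocks are needed so every unit sees a cue-away condition
  truth <- synthetic_truth(seed = 5, n_units = 30, n_presentations = 800)
  b <- generate_dataset(truth)
  ds <- b$dataset
  expect_s3_class(ds, "popgain_dataset")
  p <- ds$presentations
  # analyzable standards come out near the requested count
  n_std <- sum(p$is_standard & p$within_trial_index > 0)
  expect_gt(n_std, 640)
  expect_lt(n_std, 960)
  # alternating block cue, at most one target per trial, catch trials exist
  expect_true(all(tapply(p$cue_side, p$block_id, function(x)
    length(unique(x))) == 1))
  expect_true(all(tapply(!p$is_standard, p$trial_id, sum) <= 1))
  expect_equal(nrow(b$behavior), length(unique(p$trial_id)))
  expect_true(all(b$behavior$outcome %in% c("hit", "miss", "catch")))

  # f is the cue-away mean rate (mean-preserving gain centring)
  av <- analysis_view(ds, min_rate = 0)
  ci <- cue_indicator(av$presentations$cue_side, av$units$hemisphere)
  away_mean <- vapply(seq_len(ncol(av$counts)), function(j)
    mean(av$counts[ci[, j] == 0, j]), numeric(1))
  expect_equal(mean(away_mean / truth$f), 1, tolerance = 0.1)

  # bit-reproducible from (parameters, seed)
  b2 <- generate_dataset(truth)
  expect_identical(b2$dataset$counts, ds$counts)
})

test_that("the null preset generates unmodulated Poisson counts", {
  truth <- synthetic_truth(preset = "null", seed = 8, n_units = 20,
                           n_presentations = 300)
  expect_identical(truth$lambda_scale, 0)
  expect_identical(truth$drift_sd, 0)
  b <- generate_dataset(truth)
  av <- analysis_view(b$dataset, min_rate = 0)
  fano <- apply(av$counts, 2, var) / colMeans(av$counts)
  expect_equal(mean(fano), 1, tolerance = 0.1)
})

test_that("behavioral tables map modulators into cued/opposite coordinates", {
  truth <- synthetic_truth(seed = 7, n_units = 20, n_presentations = 250)
  b <- generate_dataset(truth)
  ds <- analysis_view(b$dataset)
  kp <- attr(ds, "kept_presentations")
  tb <- make_behavioral_table(ds, b$truth$M_true[kp, ], truth$mod_hemi)
  # rebuilding from the true modulators must reproduce the generator's
  # trial-averaged cued/opposite values
  m_direct <- t(vapply(tb$trial_id, function(i) {
    sel <- ds$presentations$trial_id == i
    colMeans(b$truth$M_true[kp, , drop = FALSE][sel, , drop = FALSE])
  }, numeric(2)))
  contra <- c(L = "R", R = "L")
  cued_col <- match(contra[tb$cue_side], truth$mod_hemi)
  expect_equal(tb$m_cued, m_direct[cbind(seq_len(nrow(tb)), cued_col)])
  # previous-reward coding lags the outcome by one trial
  expect_equal(tb$prev_reward[1], "other")
  hits_cued <- which(tb$rewarded & tb$target_side == "cued")
  hits_cued <- hits_cued[hits_cued < nrow(tb)]
  expect_true(all(tb$prev_reward[hits_cued + 1] == "hit-cued"))

  expect_error(make_behavioral_table(ds, b$truth$M_true[kp, ],
                                     c("L", "L")), "one modulator per")
})

test_that("the direct behavioral simulator follows its parameters", {
  tb <- simulate_behavior(4000, seed = 2)
  expect_equal(nrow(tb), 4000)
  expect_true(all(tb$outcome %in% c("hit", "miss", "catch")))
  expect_equal(mean(tb$outcome == "catch"), 0.05, tolerance = 0.35)
  cued <- tb$target_side == "cued"
  expect_equal(mean(cued[tb$outcome != "catch"]), 0.8, tolerance = 0.05)
  # easier targets are hit more often
  hr <- tapply(tb$outcome[cued] == "hit", tb$delta_theta_deg[cued], mean)
  expect_gt(hr[["12"]], hr[["1"]])
  expect_identical(tb, simulate_behavior(4000, seed = 2))
})
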