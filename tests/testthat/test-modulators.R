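test_that("stimulus drive and cue couplings match their closed forms", {
  set.seed(21)
  tt <- 60; nn <- 6
  ci <- matrix(rbinom(tt * nn, 1, 0.5), tt, nn)
  y <- matrix(rpois(tt * nn, 5), tt, nn)
  mask <- make_holdout_mask(tt, nn, 0.25, seed = 3)
  tr <- 1 - mask$test

  f <- fit_stimulus_drive(y, ci, mask)
  f_manual <- colSums(y * (1 - ci) * tr) / colSums((1 - ci) * tr)
  expect_equal(f, f_manual)

  u <- fit_cue_couplings(y, ci, f, mask)
  u_manual <- log(colSums(y * ci * tr) / (f * colSums(ci * tr)))
  expect_equal(u, u_manual)

  # degenerate cue indicator falls back to u = 0 with a warning
  ci0 <- ci; ci0[, 1] <- 0
  expect_warning(u0 <- fit_cue_couplings(y, ci0, f, mask), "constant cue")
  expect_identical(u0[1], 0)
})

test_that("rank projection reproduces the truncated SVD", {
  set.seed(22)
  x <- matrix(rnorm(48), 8, 6)
  pr <- popgain:::rank_project(x, 2)
  sv <- svd(x)
  expect_equal(pr$z,
               sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2]))
  expect_equal(tcrossprod(pr$M_series, pr$W), pr$z)
})

test_that("ADMM is deterministic and recovers a planted rank-1 gain", {
  set.seed(23)
  tt <- 150; nn <- 12
  f <- runif(nn, 3, 9)
  m_t <- rnorm(tt); w_t <- abs(rnorm(nn, 0, 0.3))
  off <- matrix(log(f), tt, nn, byrow = TRUE)
  y <- matrix(rpois(tt * nn, exp(off + tcrossprod(m_t, w_t))), tt, nn)

  fit1 <- fit_modulators_admm(y, off, K = 1, tau = 1)
  set.seed(999)  # no RNG is consumed; results must be identical
  fit2 <- fit_modulators_admm(y, off, K = 1, tau = 1)
  expect_identical(fit1$M_series, fit2$M_series)
  expect_true(fit1$state$converged)
  expect_gt(abs(cor(fit1$M_series[, 1], m_t)), 0.85)
  expect_error(fit_modulators_admm(y, off, K = 12, tau = 1), "smaller")
})

test_that("hemisphere-constrained modulators have disjoint weight support", {
  set.seed(24)
  tt <- 120; nn <- 10
  hemi <- rep(c("L", "R"), each = 5)
  f <- runif(nn, 3, 9)
  m2 <- matrix(rnorm(tt * 2), tt, 2)
  w2 <- matrix(0, nn, 2)
  w2[hemi == "L", 1] <- abs(rnorm(5, 0, 0.3))
  w2[hemi == "R", 2] <- abs(rnorm(5, 0, 0.3))
  off <- matrix(log(f), tt, nn, byrow = TRUE)
  y <- matrix(rpois(tt * nn, exp(off + tcrossprod(m2, w2))), tt, nn)
  fit <- fit_modulators_admm(y, off, K = 2, tau = 1, hemisphere = hemi)
  expect_equal(fit$modulator_hemisphere, c("L", "R"))
  expect_true(all(fit$W[hemi == "R", fit$modulator_hemisphere == "L"] == 0))
  expect_true(all(fit$W[hemi == "L", fit$modulator_hemisphere == "R"] == 0))
  expect_error(fit_modulators_admm(y, off, K = 3, tau = 1, hemisphere = hemi),
               "even")
})

test_that("identifiability resolution normalizes without changing the model", {
  set.seed(25)
  m <- matrix(rnorm(80), 40, 2) %*% matrix(c(2, 0.5, 0, 1.5), 2, 2)
  w <- matrix(rnorm(16, 0, 0.4), 8, 2)
  hemi <- rep(c("L", "R"), each = 4)
  before <- tcrossprod(m, w)
  res <- resolve_identifiability(m, w, hemi, mode = "rank2_joint")
  expect_equal(tcrossprod(res$M_series, res$W), before, tolerance = 1e-12)
  expect_equal(apply(res$M_series, 2, var), c(1, 1), tolerance = 1e-10)
  # joint rotation: mean left-hemisphere weights on the positive first axis
  wl <- colMeans(res$W[hemi == "L", ])
  expect_gt(wl[1], 0)
  expect_equal(wl[2], 0, tolerance = 1e-10)
  # applying the resolution twice is a no-op
  res2 <- resolve_identifiability(res$M_series, res$W, hemi, "rank2_joint")
  expect_equal(res2$W, res$W, tolerance = 1e-10)

  res1 <- resolve_identifiability(m, w, hemi, mode = "none")
  expect_equal(tcrossprod(res1$M_series, res1$W), before, tolerance = 1e-12)
  expect_true(all(colMeans(res1$W) >= 0))
})

test_that("held-out likelihood is non-decreasing across coordinate passes", {
  truth <- synthetic_truth(seed = 9, n_units = 24, n_presentations = 800)
  b <- generate_dataset(truth)
  ds <- analysis_view(b$dataset)
  mask <- make_holdout_mask(nrow(ds$counts), ncol(ds$counts), 0.2, seed = 5)
  fit <- coordinate_fit(ds, K = 2, mask = mask, n_passes = 2)
  expect_gte(fit$log$test_ll_per_obs[2], fit$log$test_ll_per_obs[1] - 1e-4)
  expect_equal(apply(fit$M_series, 2, var), c(1, 1), tolerance = 1e-8)
})
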