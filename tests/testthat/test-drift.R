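test_that("squared-exponential kernel has the correct entries and is PD", {
  ts <- c(0, 10, 30, 100)
  k <- gp_kernel_matrix(ts, timescale_s = 20, marginal_variance = 2,
                        jitter = 1e-8)
  expect_equal(k[1, 2], 2 * exp(-100 / (2 * 400)))
  expect_equal(k, t(k))
  expect_true(all(eigen(k, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(gp_kernel_matrix(ts, -1), "positive")
})

test_that("drift EM recovers a strong slow drift and normalizes it", {
  set.seed(11)
  tt <- 400; nn <- 15
  times <- cumsum(runif(tt, 0.4, 0.6))
  k <- gp_kernel_matrix(times, 30)
  d_true <- as.vector(chol(k) %*% rnorm(tt))
  d_true <- (d_true - mean(d_true)) / sd(d_true)
  v_true <- abs(rnorm(nn, 0, 0.3))
  f <- runif(nn, 3, 10)
  rate <- sweep(exp(tcrossprod(d_true, v_true)), 2, f, "*")
  y <- matrix(rpois(tt * nn, rate), tt, nn)
  off <- matrix(log(f), tt, nn, byrow = TRUE)

  fit <- fit_drift_em(y, off, times)
  expect_gt(abs(cor(fit$d, d_true)), 0.9)
  expect_equal(sd(fit$d), 1, tolerance = 1e-8)
  expect_gte(mean(fit$v), 0)
  # product is what matters; compare it directly
  expect_gt(cor(as.vector(tcrossprod(fit$d, fit$v)),
                as.vector(tcrossprod(d_true, v_true))), 0.9)
  expect_true(fit$prior$timescale_s %in% fit$diagnostics$timescale_grid)
  expect_equal(which.max(fit$diagnostics$evidence),
               match(fit$prior$timescale_s, fit$diagnostics$timescale_grid))
})

test_that("drift EM returns zero drift when the data carry none", {
  set.seed(12)
  tt <- 150; nn <- 8
  times <- cumsum(runif(tt, 0.4, 0.6))
  f <- runif(nn, 3, 8)
  y <- matrix(rpois(tt * nn, rep(f, each = tt)), tt, nn)
  off <- matrix(log(f), tt, nn, byrow = TRUE)
  fit <- suppressWarnings(fit_drift_em(y, off, times))
  # either the evidence rejects drift outright or the fitted drift explains
  # a negligible share of the log rate
  expect_lt(max(abs(tcrossprod(fit$d, fit$v))), 0.25)
})
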