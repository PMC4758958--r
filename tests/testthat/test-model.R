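test_that("compute_rate reproduces the model equation for both links", {
  set.seed(3)
  n <- 5; tt <- 7
  f <- runif(n, 1, 10); u <- rnorm(n, 0, 0.2)
  d <- rnorm(tt); v <- rnorm(n, 0, 0.1)
  m <- matrix(rnorm(tt * 2), tt, 2); w <- matrix(rnorm(n * 2, 0, 0.2), n, 2)
  ci <- matrix(rbinom(tt * n, 1, 0.5), tt, n)
  eta <- sweep(ci, 2, u, "*") + tcrossprod(d, v) + tcrossprod(m, w)

  pe <- popgain_params(f, u, d, v, m, w)
  expect_equal(compute_rate(pe, ci), sweep(exp(eta), 2, f, "*"))

  ps <- popgain_params(f, u, d, v, m, w, link = "soft-threshold")
  expect_equal(compute_rate(ps, ci), sweep(log1p(exp(eta)), 2, f, "*"))

  # drift- and modulator-free models drop their terms
  p0 <- popgain_params(f, u)
  expect_equal(compute_rate(p0, ci), sweep(exp(sweep(ci, 2, u, "*")), 2, f, "*"))
})

test_that("masked Poisson log-likelihood equals entrywise summation", {
  set.seed(4)
  y <- matrix(rpois(40, 4), 8, 5)
  r <- matrix(runif(40, 1, 8), 8, 5)
  mask <- make_holdout_mask(8, 5, 0.3, seed = 1)
  manual <- function(sel) sum(dpois(y[sel], r[sel], log = TRUE))
  expect_equal(poisson_loglik_masked(y, r, mask, "test"), manual(mask$test))
  expect_equal(poisson_loglik_masked(y, r, mask, "train"), manual(!mask$test))
  expect_equal(poisson_loglik_masked(y, r, NULL, "all"),
               manual(matrix(TRUE, 8, 5)))
  expect_error(poisson_loglik_masked(y, r * 0, NULL, "all"), "positive")
})

test_that("Fano curves follow the multiplicative and additive noise laws", {
  mu <- c(0.5, 1, 2, 5, 10)
  expect_equal(fano_curves(mu, 0.2, "multiplicative"), 1 + 0.2 * mu)
  expect_equal(fano_curves(mu, 0.2, "additive"), 1 + 0.2 / mu)
  expect_error(fano_curves(c(-1, 1), 0.2), "positive")
})

test_that("analytic count moments match the log-normal gain formulas", {
  s <- matrix(c(0.09, 0.03, 0.03, 0.16), 2, 2)
  mo <- analytic_count_moments(4, 9, s)
  expect_equal(mo$mean, c(4, 9))
  expect_equal(mo$variance, c(4 + 16 * (exp(0.09) - 1),
                              9 + 81 * (exp(0.16) - 1)))
  expect_equal(mo$fano, mo$variance / c(4, 9))
  expect_equal(mo$correlation,
               4 * 9 * (exp(0.03) - 1) / sqrt(prod(mo$variance)))
  expect_error(analytic_count_moments(4, 9, matrix(c(1, 2, 3, 4), 2)),
               "symmetric")
})

test_that("d-prime handles regular, degenerate, and per-unit cases", {
  expect_equal(dprime(c(1, 3), c(5, 7)), 4 / sqrt(2))
  expect_equal(dprime(c(2, 2), c(2, 2)), 0)
  expect_warning(dp <- dprime(c(2, 2), c(3, 3)), "infinite")
  expect_identical(dp, Inf)

  ds <- tiny_dataset()
  dp_all <- unit_dprimes(ds, condition = "both")
  expect_named(dp_all, ds$units$unit_id)
  std <- ds$presentations$is_standard & ds$presentations$within_trial_index > 0
  tgt <- !ds$presentations$is_standard
  expect_equal(unname(dp_all[1]),
               dprime(ds$counts[std, 1], ds$counts[tgt, 1]))
  expect_error(unit_dprimes(analysis_view(ds)), "target")
})
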