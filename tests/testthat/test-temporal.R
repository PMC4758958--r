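test_that("binned datasets validate their inputs", {
  arr <- array(rpois(5 * 6 * 3, 2), c(5, 6, 3))
  bd <- binned_dataset(arr, 10, window_bins = 3:6,
                       presentation_id = 1:5)
  expect_s3_class(bd, "popgain_binned")
  expect_error(binned_dataset(matrix(0, 2, 2), 10, 1), "3-d")
  expect_error(binned_dataset(arr, -1, 3:6), "positive")
  expect_error(binned_dataset(arr, 10, 5:9), "out of range")
  expect_error(binned_dataset(arr, 10, 3:6, presentation_id = 1:4),
               "length")
  arr2 <- arr; arr2[1] <- -1
  expect_error(binned_dataset(arr2, 10, 3:6), "nonnegative")
})

test_that("PSTH estimation averages bins and normalizes the population trace", {
  set.seed(51)
  tt <- 300; nb <- 8; nn <- 4
  shape <- c(0.2, 0.2, 1, 2, 1.5, 1, 0.8, 0.6)
  f <- c(2, 4, 6, 8)
  lam <- outer(shape, f)
  arr <- array(rpois(tt * nb * nn, rep(lam, each = tt)), c(tt, nb, nn))
  bd <- binned_dataset(arr, 10, window_bins = 3:8)
  ps <- estimate_psth(bd)
  expect_equal(dim(ps$psth), c(nb, nn))
  expect_equal(ps$psth, apply(arr, c(2, 3), mean))
  expect_equal(max(abs(ps$population)), 1)
  # the population trace peaks where the shape peaks
  expect_equal(which.max(ps$population), which.max(shape))
})

test_that("the fine-temporal fit needs a usable window and aligned rows", {
  ds <- analysis_view(tiny_dataset())
  f <- pmax(colMeans(ds$counts), 0.5)
  params <- popgain_params(f = f, d = rep(0, nrow(ds$counts)))
  arr <- array(rpois(nrow(ds$counts) * 4 * ncol(ds$counts), 1),
               c(nrow(ds$counts), 4, ncol(ds$counts)))
  bd <- binned_dataset(arr, 10, window_bins = 3:4)
  expect_error(fit_fine_temporal(bd, params, ds), "at least 3")
})
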