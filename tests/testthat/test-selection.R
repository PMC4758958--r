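test_that("holdout masks have the requested fraction and reproducible seeds", {
  m1 <- make_holdout_mask(200, 50, 0.2, seed = 7)
  m2 <- make_holdout_mask(200, 50, 0.2, seed = 7)
  expect_identical(m1$test, m2$test)
  expect_equal(mean(m1$test), 0.2, tolerance = 0.02)
  expect_error(make_holdout_mask(10, 10, 1.2), "fraction")

  # seeded mask creation must not disturb the caller's RNG stream
  set.seed(123); x1 <- rnorm(3)
  set.seed(123); invisible(make_holdout_mask(10, 10, 0.2, seed = 99))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("predictive log-likelihood matches direct computation", {
  ds <- analysis_view(tiny_dataset())
  mask <- make_holdout_mask(nrow(ds$counts), ncol(ds$counts), 0.4, seed = 2)
  f <- colMeans(ds$counts)
  params <- popgain_params(f = pmax(f, 0.1))
  ci <- cue_indicator(ds$presentations$cue_side, ds$units$hemisphere)
  rates <- compute_rate(params, ci)
  manual <- sum(dpois(ds$counts[mask$test], rates[mask$test], log = TRUE)) /
    sum(mask$test)
  expect_equal(predictive_ll(ds, params, mask), manual)
})

test_that("rank selection reports nested models relative to stimulus-only", {
  truth <- synthetic_truth(seed = 10, n_units = 24, n_presentations = 800)
  b <- generate_dataset(truth)
  ds <- analysis_view(b$dataset)
  mask <- make_holdout_mask(nrow(ds$counts), ncol(ds$counts), 0.2, seed = 4)
  cmp <- select_rank(ds, K_grid = 1:2, mask = mask)
  tab <- cmp$table
  expect_setequal(tab$model, c("stimulus", "cue", "cue+drift",
                               "modulators K=1", "modulators K=2"))
  expect_equal(tab$relative_ll[tab$model == "stimulus"], 0)
  expect_equal(tab$relative_ll,
               tab$predictive_ll_per_obs -
                 tab$predictive_ll_per_obs[tab$model == "stimulus"])
  expect_true(cmp$selected_K %in% c(0, 1, 2))
  best_row <- tab[!is.na(tab$K), ]
  expect_equal(cmp$selected_K,
               best_row$K[which.max(best_row$predictive_ll_per_obs)])
  expect_s3_class(cmp$fits[["modulators K=2"]], "popgain_params")
})
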