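test_that("dataset constructor validates counts and metadata", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "popgain_dataset")
  expect_equal(dim(ds), dim(ds$counts))

  bad <- ds$counts; bad[1, 1] <- -1
  expect_error(popgain_dataset(bad, ds$presentations, ds$units),
               "non-negative")
  bad <- ds$counts; bad[1, 1] <- 1.5
  expect_error(popgain_dataset(bad, ds$presentations, ds$units))

  u2 <- ds$units; u2$hemisphere[1] <- "X"
  expect_error(popgain_dataset(ds$counts, ds$presentations, u2),
               "hemisphere")

  p2 <- ds$presentations; p2$timestamp_s[2] <- p2$timestamp_s[1]
  expect_error(popgain_dataset(ds$counts, p2, ds$units),
               "strictly increasing")

  p3 <- ds$presentations[, setdiff(names(ds$presentations), "cue_side")]
  expect_error(popgain_dataset(ds$counts, p3, ds$units), "cue_side")

  p4 <- ds$presentations; p4$trial_id <- seq_len(nrow(p4)); p4$block_id <- 1
  expect_error(popgain_dataset(ds$counts[1:18, ], p4[1:18, ], ds$units),
               NA)  # 18 trials in one block is fine
  p5 <- ds$presentations
  p5$trial_id <- seq_len(nrow(p5)) + 0  # 18 distinct trials
  p5$block_id <- 1
  big <- do.call(rbind, replicate(8, p5, simplify = FALSE))
  big$trial_id <- rep(1:144, each = 18)[seq_len(nrow(big))]
  big$trial_id <- seq_len(nrow(big))  # 144 "trials" in one block
  big$timestamp_s <- seq_len(nrow(big)) * 0.5
  big$presentation_id <- seq_len(nrow(big))
  cb <- matrix(0L, nrow(big), 4)
  expect_error(popgain_dataset(cb, big, ds$units), "125")
})

test_that("analysis view drops first-of-trial standards and silent units", {
  ds <- tiny_dataset()
  ds$counts[, 2] <- 0  # silence unit b
  av <- analysis_view(ds)
  p <- av$presentations
  expect_true(all(p$is_standard))
  expect_true(all(p$within_trial_index > 0))
  expect_false("b" %in% av$units$unit_id)
  expect_equal(nrow(av$counts), 6)   # one non-first standard per trial
  kp <- attr(av, "kept_presentations")
  ku <- attr(av, "kept_units")
  expect_equal(av$counts, ds$counts[kp, ku, drop = FALSE],
               ignore_attr = TRUE)
})

test_that("cue indicator marks units contralateral to the cued hemifield", {
  ci <- cue_indicator(c("L", "R"), c("L", "R"))
  # cue L -> right-hemisphere units (representing the left hemifield) cued
  expect_equal(ci, rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
})

test_that("dataset bundles round-trip through delimited text", {
  ds <- tiny_dataset()
  dir <- file.path(tempdir(), "bundle-test")
  write_dataset_bundle(ds, dir)
  back <- read_dataset_bundle(dir)
  expect_equal(back$counts, ds$counts, ignore_attr = TRUE)
  expect_equal(back$presentations$cue_side, ds$presentations$cue_side)
  expect_equal(back$units$hemisphere, ds$units$hemisphere)
  expect_equal(back$trials$outcome, ds$trials$outcome)
  unlink(dir, recursive = TRUE)
})
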