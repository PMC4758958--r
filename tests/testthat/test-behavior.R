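test_that("the cued psychometric fit recovers its generating parameters", {
  tb <- simulate_behavior(8000, seed = 41)
  fit <- fit_psychometric_cued(tb)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["alpha"]), -0.8, tolerance = 0.25)
  expect_equal(unname(fit$coef["m_cued"]), 0.25, tolerance = 0.3)
  expect_equal(unname(fit$coef["m_opp"]), -0.3, tolerance = 0.25)
  expect_equal(unname(fit$coef["lambda_slope"]), 1.1, tolerance = 0.2)
  expect_equal(unname(fit$coef["delta"]), 0.9, tolerance = 0.1)
  expect_equal(sign(unname(fit$marginal_effects[c("m_cued", "m_opp")])),
               c(1, -1))
  # the fit uses only resolved cued-target trials
  expect_equal(fit$n, sum(tb$target_side == "cued" &
                            tb$outcome %in% c("hit", "miss")))

  op <- fit_psychometric_opposite(tb)
  expect_equal(unname(op$coef["alpha"]), 0.4, tolerance = 0.35)
  expect_equal(unname(op$coef["m_cued"]), -0.35, tolerance = 0.35)
  expect_false("delta" %in% names(op$coef))
})

test_that("reward dynamics least squares recovers the shift matrix", {
  pars <- list(B = matrix(c(0.5, -0.4, -0.6, 0.7), 2, 2), sigma = 0.5)
  tb <- simulate_behavior(6000, pars = pars, seed = 42)
  dyn <- fit_reward_dynamics(tb)
  expect_equal(dyn$B, pars$B, tolerance = 0.25)
  expect_equal(dyn$C, diag(0.3, 2), tolerance = 0.25)
  expect_equal(dyn$sigma2, 0.25, tolerance = 0.1)
  # without reward structure the estimates shrink to zero
  tb0 <- simulate_behavior(6000, pars = list(B = matrix(0, 2, 2)), seed = 43)
  dyn0 <- fit_reward_dynamics(tb0)
  expect_lt(max(abs(dyn0$B)), 0.1)
})

test_that("chained mediation multiplies the two fitted pathways", {
  # oracle check on the chaining arithmetic itself
  pc <- list(marginal_effects = c(m_cued = 0.06, m_opp = -0.04))
  po <- list(marginal_effects = c(m_cued = -0.02, m_opp = 0.05))
  dyn <- list(B = matrix(c(0.5, -0.4, -0.6, 0.7), 2, 2))
  med <- chained_reward_bias(pc, po, dyn)
  expect_equal(med$mediated_effect[med$target_side == "cued" &
                                     med$prev_reward == "hit-cued"],
               0.5 * 0.06 + (-0.4) * (-0.04))
  expect_equal(med$mediated_effect[med$target_side == "opposite" &
                                     med$prev_reward == "hit-opposite"],
               (-0.6) * (-0.02) + 0.7 * 0.05)
  # with totals supplied, fractions and the aggregate are reported
  tot <- list(effects = data.frame(
    target_side = rep(c("cued", "opposite"), each = 2),
    prev_reward = rep(c("hit-cued", "hit-opposite"), 2),
    delta_hit_prob = c(0.1, -0.1, -0.05, 0.2)))
  med2 <- chained_reward_bias(pc, po, dyn, tot)
  expect_equal(med2$fraction, med2$mediated_effect / med2$total_effect)
  expect_equal(attr(med2, "fraction_total"),
               sum(abs(med2$mediated_effect)) / sum(abs(med2$total_effect)))
})

test_that("posterior significance flags strong effects and not null ones", {
  tb <- simulate_behavior(6000, seed = 44)
  fit <- fit_psychometric_cued(tb)
  expect_lt(posterior_significance(fit, "lambda_slope"), 0.01)
  p_laplace <- posterior_significance(fit, "m_cued")
  p_mcmc <- posterior_significance(fit, "m_cued", method = "mcmc",
                                   n_mcmc = 3000, burn = 500)
  expect_lt(abs(p_laplace - p_mcmc), 0.1)
  expect_error(posterior_significance(fit, "nonexistent"), "unknown")

  dyn <- fit_reward_dynamics(tb)
  expect_lt(posterior_significance(dyn, "B22"), 0.05)
})
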