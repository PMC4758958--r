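#' Psychometric model for cued-target detection
#'
#' Maximum-likelihood fit of the lapse-scaled logistic hit model for trials
#' whose target appeared on the cued side:
#' \deqn{P(hit) = \delta \, \sigma(\alpha + \beta^T m + \lambda \log \Delta\theta)}
#' with `m = (m_cued, m_opp)` the trial-averaged modulators, `delta` the
#' lapse ceiling, and `lambda` the dependence on task difficulty. The lapse
#' is parameterized on the logit scale; standard errors come from the
#' observed information at the mode.
#'
#' @param table Behavioral table (one row per trial) with columns
#'   `outcome`, `target_side`, `delta_theta_deg`, `m_cued`, `m_opp`.
#' @param include_lapse Include the lapse ceiling (default); otherwise
#'   `delta` is fixed at 1.
#' @param difficulty `"log"` (default), `"linear"`, or `"none"` for how
#'   the orientation change enters.
#' @param ridge Ridge penalty on the regression coefficients; applied
#'   automatically (with a warning) when the unpenalized fit shows signs of
#'   complete separation.
#' @param extra_regressors Optional matrix of additional trial regressors
#'   (e.g. previous-reward indicators) replacing or supplementing the
#'   modulators; columns must be named.
#' @param use_modulators Include `m_cued`/`m_opp` as regressors.
#' @return Object of class `popgain_psychfit`: `coef` (named, natural
#'   scale), `vcov` (optimization scale), `marginal_effects` (average
#'   change in hit probability per unit increase of each regressor,
#'   difference quotient at +-0.5), `loglik`, `n`, and internal pieces for
#'   [posterior_significance()].
#' @export
fit_psychometric_cued <- function(table, include_lapse = TRUE,
                                  difficulty = c("log", "linear", "none"),
                                  ridge = 0, extra_regressors = NULL,
                                  use_modulators = TRUE) {
  difficulty <- match.arg(difficulty)
  d <- table[table$target_side == "cued" &
               table$outcome %in% c("hit", "miss"), ]
  y <- as.numeric(d$outcome == "hit")
  x <- NULL
  if (use_modulators) x <- cbind(m_cued = d$m_cued, m_opp = d$m_opp)
  if (!is.null(extra_regressors))
    x <- cbind(x, as.matrix(extra_regressors)[table$target_side == "cued" &
                 table$outcome %in% c("hit", "miss"), , drop = FALSE])
  diff_term <- switch(difficulty, log = log(d$delta_theta_deg),
                      linear = d$delta_theta_deg, none = NULL)
  fit_psychometric_mle(y, x, diff_term, include_lapse, ridge,
                       model = "cued")
}

# Shared MLE machinery for the lapse-scaled logistic.
fit_psychometric_mle <- function(y, x, diff_term, include_lapse, ridge,
                                 model) {
  nb <- if (is.null(x)) 0 else ncol(x)
  has_diff <- !is.null(diff_term)
  ok <- is.finite(y)
  if (nb) ok <- ok & rowSums(!is.finite(as.matrix(x))) == 0
  if (has_diff) ok <- ok & is.finite(diff_term)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " trial(s) with missing regressors")
    y <- y[ok]
    if (nb) x <- x[ok, , drop = FALSE]
    if (has_diff) diff_term <- diff_term[ok]
  }
  npar <- 1 + nb + has_diff + include_lapse
  nms <- c("alpha", colnames(x),
           if (has_diff) "lambda_slope", if (include_lapse) "logit_delta")
  nll <- function(th, pen = ridge) {
    lp <- th[1]
    if (nb) lp <- lp + as.vector(x %*% th[2:(1 + nb)])
    if (has_diff) lp <- lp + th[2 + nb] * diff_term
    delta <- if (include_lapse) stats::plogis(th[npar]) else 1
    p <- delta * stats::plogis(lp)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(y * log(p) + (1 - y) * log(1 - p)) +
      if (nb) pen / 2 * sum(th[2:(1 + nb)]^2) else 0
  }
  start <- c(stats::qlogis(pmin(pmax(mean(y), 0.05), 0.95)), rep(0, nb),
             if (has_diff) 0.5, if (include_lapse) 3)
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  sep <- any(abs(opt$par[seq_len(1 + nb)]) > 15)
  if (sep && ridge == 0) {
    warning("possible complete separation; refitting with a weak ridge")
    return(fit_psychometric_mle(y, x, diff_term, include_lapse,
                                ridge = 1e-2, model = model))
  }
  # invert the observed information with an eigenvalue floor: directions of
  # negligible curvature (typically the lapse ceiling when delta-hat is near
  # 1) otherwise make the whole inverse indefinite; flooring them yields
  # conservative standard errors there and correct ones elsewhere
  vc <- tryCatch({
    eg <- eigen(opt$hessian, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-8 * max(abs(eg$values)))
    eg$vectors %*% (t(eg$vectors) / ev)
  }, error = function(e) matrix(NA_real_, npar, npar))
  th <- opt$par
  names(th) <- nms
  coef <- th
  if (include_lapse) {
    coef <- coef[-npar]
    coef <- c(coef, delta = unname(stats::plogis(th[npar])))
  }
  p_hit <- function(xx, dd) {
    lp <- th[1]
    if (nb) lp <- lp + as.vector(xx %*% th[2:(1 + nb)])
    if (has_diff) lp <- lp + th[2 + nb] * dd
    (if (include_lapse) stats::plogis(th[npar]) else 1) * stats::plogis(lp)
  }
  me <- if (nb) vapply(seq_len(nb), function(j) {
    xp <- x; xm <- x
    xp[, j] <- xp[, j] + 0.5
    xm[, j] <- xm[, j] - 0.5
    mean(p_hit(xp, diff_term) - p_hit(xm, diff_term))
  }, numeric(1)) |> stats::setNames(colnames(x)) else numeric(0)
  structure(list(coef = coef, par = th, vcov = vc,
                 marginal_effects = me, loglik = -opt$value, n = length(y),
                 model = model, nll = nll, p_hit = p_hit,
                 converged = opt$convergence == 0, ridge = ridge),
            class = "popgain_psychfit")
}

#' @export
print.popgain_psychfit <- function(x, ...) {
  cat(sprintf("psychometric fit (%s targets), n=%d, logLik=%.1f\n",
              x$model, x$n, x$loglik))
  print(round(x$coef, 4))
  if (length(x$marginal_effects)) {
    cat("average marginal effects on hit probability:\n")
    print(round(x$marginal_effects, 4))
  }
  invisible(x)
}

#' Psychometric model for opposite-side targets
#'
#' Opposite-side targets occur at a single difficulty, so the model is a
#' plain logistic in the two modulators:
#' `P(hit) = sigma(alpha' + beta'^T m)`.
#'
#' @inheritParams fit_psychometric_cued
#' @return A `popgain_psychfit`.
#' @export
fit_psychometric_opposite <- function(table, ridge = 0,
                                      extra_regressors = NULL,
                                      use_modulators = TRUE) {
  sel <- table$target_side == "opposite" &
    table$outcome %in% c("hit", "miss")
  d <- table[sel, ]
  y <- as.numeric(d$outcome == "hit")
  x <- NULL
  if (use_modulators) x <- cbind(m_cued = d$m_cued, m_opp = d$m_opp)
  if (!is.null(extra_regressors))
    x <- cbind(x, as.matrix(extra_regressors)[sel, , drop = FALSE])
  fit_psychometric_mle(y, x, diff_term = NULL, include_lapse = FALSE,
                       ridge = ridge, model = "opposite")
}

#' Linear-Gaussian reward dynamics of the modulators
#'
#' Least-squares fit, per modulator dimension, of
#' `m(t) = a + B r(t-1) + C m(t-1) + noise`, where `r(t-1)` is the coded
#' previous reward: `(1,0)` after a hit on a cued target, `(0,1)` after a
#' hit on an opposite target, `(0,0)` otherwise. The columns of `B` are the
#' average shifts of `(m_cued, m_opp)` following each rewarded outcome.
#'
#' @param table Behavioral table ordered by trial, with `prev_reward`,
#'   `m_cued`, `m_opp`.
#' @param include_prev_modulator Include the `C m(t-1)` term (default).
#' @return List of class `popgain_rewarddyn`: `a` (length 2), `B` (2 x 2),
#'   `C` (2 x 2 or NULL), `sigma2`, and the per-dimension `lm` fits.
#' @export
fit_reward_dynamics <- function(table, include_prev_modulator = TRUE) {
  n <- nrow(table)
  r1 <- as.numeric(table$prev_reward == "hit-cued")
  r2 <- as.numeric(table$prev_reward == "hit-opposite")
  df <- data.frame(m_cued = table$m_cued, m_opp = table$m_opp,
                   r1 = r1, r2 = r2,
                   mp1 = c(NA, table$m_cued[-n]),
                   mp2 = c(NA, table$m_opp[-n]))
  df <- df[-1, ]
  dropped <- character(0)
  for (cn in c("r1", "r2")) {
    if (all(df[[cn]] == 0)) {
      warning("no previous-", if (cn == "r1") "cued" else "opposite",
              "-hit trials; dropping that reward column")
      dropped <- c(dropped, cn)
    }
  }
  rhs <- c(setdiff(c("r1", "r2"), dropped),
           if (include_prev_modulator) c("mp1", "mp2"))
  fml <- stats::as.formula(paste("~", paste(c("1", rhs), collapse = "+")))
  fits <- lapply(c("m_cued", "m_opp"), function(resp) {
    stats::lm(stats::update(fml, paste(resp, "~ .")), data = df)
  })
  getco <- function(fit, nm) {
    co <- stats::coef(fit)
    if (nm %in% names(co)) unname(co[nm]) else 0
  }
  b <- rbind(c(getco(fits[[1]], "r1"), getco(fits[[1]], "r2")),
             c(getco(fits[[2]], "r1"), getco(fits[[2]], "r2")))
  cm <- if (include_prev_modulator)
    rbind(c(getco(fits[[1]], "mp1"), getco(fits[[1]], "mp2")),
          c(getco(fits[[2]], "mp1"), getco(fits[[2]], "mp2"))) else NULL
  structure(list(a = c(getco(fits[[1]], "(Intercept)"),
                       getco(fits[[2]], "(Intercept)")),
                 B = b, C = cm,
                 sigma2 = mean(vapply(fits, function(f)
                   summary(f)$sigma^2, numeric(1))),
                 fits = fits, dropped = dropped),
            class = "popgain_rewarddyn")
}

#' Direct effect of previous reward on detection performance
#'
#' Model-free serial dependence: Bernoulli GLMs of the hit outcome on
#' previous-reward category indicators (difficulty and lapse terms included
#' for cued targets), without any modulator regressors. Reports, for each
#' target side and previous-reward category, the average change in hit
#' probability relative to the "other" baseline.
#'
#' @param table Behavioral table.
#' @return List with `effects` (data frame `target_side`, `prev_reward`,
#'   `delta_hit_prob`) and the two underlying fits (`cued_fit`, `opp_fit`).
#' @export
reward_effect_on_behavior <- function(table) {
  reg <- cbind(prev_hit_cued = as.numeric(table$prev_reward == "hit-cued"),
               prev_hit_opp = as.numeric(table$prev_reward == "hit-opposite"))
  cf <- fit_psychometric_cued(table, extra_regressors = reg,
                              use_modulators = FALSE)
  of <- fit_psychometric_opposite(table, extra_regressors = reg,
                                  use_modulators = FALSE)
  eff <- function(fit, side) {
    sel <- table$target_side == side & table$outcome %in% c("hit", "miss")
    x <- reg[sel, , drop = FALSE]
    dd <- if (side == "cued") log(table$delta_theta_deg[sel]) else NULL
    base <- x; base[, ] <- 0
    vapply(1:2, function(j) {
      on <- base; on[, j] <- 1
      mean(fit$p_hit(on, dd) - fit$p_hit(base, dd))
    }, numeric(1))
  }
  ec <- eff(cf, "cued"); eo <- eff(of, "opposite")
  effects <- data.frame(
    target_side = rep(c("cued", "opposite"), each = 2),
    prev_reward = rep(c("hit-cued", "hit-opposite"), 2),
    delta_hit_prob = c(ec, eo))
  list(effects = effects, cued_fit = cf, opp_fit = of)
}

#' Reward bias mediated through the modulators
#'
#' Chains the two fitted pathways: the shift each previous-reward category
#' induces in the modulators (columns of `B` from the reward dynamics) times
#' the average change in hit probability per unit modulator increase (the
#' psychometric marginal effects), giving the part of the serial dependence
#' that flows through the shared gain modulators. When the model-free
#' reward effects are supplied, the mediated fraction is reported.
#'
#' @param psych_cued,psych_opp Fits from [fit_psychometric_cued()] /
#'   [fit_psychometric_opposite()] (with modulator regressors).
#' @param dynamics Fit from [fit_reward_dynamics()].
#' @param reward_effects Optional result of [reward_effect_on_behavior()].
#' @return Data frame with `target_side`, `prev_reward`,
#'   `mediated_effect`, and (when totals are given) `total_effect` and
#'   `fraction`; attribute `fraction_total` holds the aggregate
#'   `sum(|mediated|) / sum(|total|)` (NA, with a warning, if the total
#'   bias is negligible).
#' @export
chained_reward_bias <- function(psych_cued, psych_opp, dynamics,
                                reward_effects = NULL) {
  b <- dynamics$B
  med <- function(fit, col) sum(b[, col] * fit$marginal_effects[c("m_cued", "m_opp")])
  out <- data.frame(
    target_side = rep(c("cued", "opposite"), each = 2),
    prev_reward = rep(c("hit-cued", "hit-opposite"), 2),
    mediated_effect = c(med(psych_cued, 1), med(psych_cued, 2),
                        med(psych_opp, 1), med(psych_opp, 2)))
  if (!is.null(reward_effects)) {
    tot <- reward_effects$effects
    out <- merge(out, stats::setNames(tot, c("target_side", "prev_reward",
                                             "total_effect")),
                 by = c("target_side", "prev_reward"), sort = FALSE)
    out$fraction <- out$mediated_effect / out$total_effect
    denom <- sum(abs(out$total_effect))
    ft <- if (denom < 1e-6) {
      warning("total reward bias is negligible; mediated fraction undefined")
      NA_real_
    } else sum(abs(out$mediated_effect)) / denom
    attr(out, "fraction_total") <- ft
  }
  out
}

#' Posterior tail probability of a fitted parameter
#'
#' Significance via the posterior mass on one side of zero, using a Laplace
#' approximation at the mode (Gaussian with observed-information
#' covariance) or a random-walk Metropolis cross-check on the stored
#' likelihood.
#'
#' @param fit A `popgain_psychfit` or `popgain_rewarddyn`.
#' @param parameter Parameter name (for reward dynamics: `"B11"`, `"B12"`,
#'   `"B21"`, `"B22"`).
#' @param method `"laplace"` or `"mcmc"`.
#' @param n_mcmc,burn MCMC chain length and burn-in.
#' @return `min(P(theta > 0), P(theta < 0))`.
#' @export
posterior_significance <- function(fit, parameter,
                                   method = c("laplace", "mcmc"),
                                   n_mcmc = 5000, burn = 1000) {
  method <- match.arg(method)
  if (inherits(fit, "popgain_rewarddyn")) {
    ij <- as.integer(c(substr(parameter, 2, 2), substr(parameter, 3, 3)))
    lmfit <- fit$fits[[ij[1]]]
    nm <- c("r1", "r2")[ij[2]]
    est <- stats::coef(lmfit)[nm]
    se <- summary(lmfit)$coefficients[nm, "Std. Error"]
    p <- stats::pnorm(0, est, se)
    return(unname(min(p, 1 - p)))
  }
  idx <- match(parameter, names(fit$par))
  if (is.na(idx)) stop("unknown parameter: ", parameter)
  if (method == "laplace") {
    est <- fit$par[idx]
    se <- sqrt(fit$vcov[idx, idx])
    if (!is.finite(se)) return(posterior_significance(fit, parameter, "mcmc",
                                                      n_mcmc, burn))
    p <- stats::pnorm(0, est, se)
    return(unname(min(p, 1 - p)))
  }
  th <- fit$par
  prop_sd <- sqrt(pmax(diag(fit$vcov), 1e-6)) * 0.5
  cur_lp <- -fit$nll(th)
  draws <- numeric(n_mcmc)
  for (i in seq_len(n_mcmc)) {
    cand <- th + stats::rnorm(length(th), 0, prop_sd)
    lp <- -fit$nll(cand)
    if (log(stats::runif(1)) < lp - cur_lp) { th <- cand; cur_lp <- lp }
    draws[i] <- th[idx]
  }
  draws <- draws[-seq_len(burn)]
  p <- mean(draws > 0)
  min(p, 1 - p)
}
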