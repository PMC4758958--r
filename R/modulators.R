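#' Stimulus drive from training counts
#'
#' Moment estimator of the per-unit stimulus-driven rate `f`: the mean count
#' over training entries in the reference cue condition, discounting any
#' already-estimated gain terms supplied in `log_gain_offset`.
#'
#' @param counts T x N count matrix.
#' @param cue_ind Binary T x N cue indicator.
#' @param mask Optional [holdout_mask].
#' @param log_gain_offset T x N matrix of known log gains (drift +
#'   modulators); zeros on a first pass.
#' @param condition `"away"` (the model's convention: `f` is the cue-away
#'   rate) or `"all"` (used by the stimulus-drive-only reference model).
#' @return Positive vector of length N.
#' @export
fit_stimulus_drive <- function(counts, cue_ind, mask = NULL,
                               log_gain_offset = 0,
                               condition = c("away", "all")) {
  condition <- match.arg(condition)
  tr <- if (is.null(mask)) 1 else 1 - mask$test
  sel <- if (condition == "away") (1 - cue_ind) * tr else matrix(1, nrow(counts), ncol(counts)) * tr
  g <- exp(log_gain_offset)
  if (length(g) == 1) g <- matrix(g, nrow(counts), ncol(counts))
  num <- colSums(counts * sel)
  den <- colSums(g * sel)
  if (any(den == 0))
    stop("some units have no cue-away training presentations; the data ",
         "must span both cue conditions (at least two blocks)")
  pmax(num / den, 1e-3)
}

#' Cue coupling weights by per-unit Poisson regression
#'
#' One free parameter per unit: the log gain applied when the cue is
#' directed toward the unit's hemifield. With the exponential link and a
#' fixed offset the maximum-likelihood estimate is available in closed form:
#' `u_n = log( sum(y over cued training entries) /
#'             sum(f_n * exp(offset) over cued training entries) )`.
#'
#' @param counts T x N count matrix.
#' @param cue_ind Binary T x N cue indicator.
#' @param f Stimulus drives (length N).
#' @param mask Optional [holdout_mask].
#' @param log_gain_offset Known log gains (drift + modulators), T x N or 0.
#' @return Vector `u` of length N. Units whose cue indicator never varies
#'   get `u = 0` with a warning; empty cued counts are stabilized with a
#'   half-count.
#' @export
fit_cue_couplings <- function(counts, cue_ind, f, mask = NULL,
                              log_gain_offset = 0) {
  tr <- if (is.null(mask)) 1 else 1 - mask$test
  g <- exp(log_gain_offset)
  if (length(g) == 1) g <- matrix(g, nrow(counts), ncol(counts))
  on <- cue_ind * tr
  num <- colSums(counts * on)
  den <- f * colSums(g * on)
  n_on <- colSums(cue_ind)
  degenerate <- n_on == 0 | n_on == nrow(counts)
  if (any(degenerate))
    warning(sum(degenerate), " unit(s) with constant cue indicator; u set to 0")
  u <- log(pmax(num, 0.5) / pmax(den, 1e-12))
  u[degenerate] <- 0
  u
}

# Truncated-SVD projection to rank K; returns the projected matrix and its
# factorization (time series scaled by singular values, unit-norm weights).
rank_project <- function(x, k) {
  sv <- svd(x, nu = k, nv = k)
  dk <- sv$d[seq_len(k)]
  m_series <- sv$u %*% diag(dk, k)
  w <- sv$v
  list(z = tcrossprod(m_series, w), M_series = m_series, W = w)
}

#' MAP estimation of shared modulators by ADMM
#'
#' Finds the rank-K matrix `M` (presentations x units) maximizing the
#' Poisson log posterior of the model `y ~ Poisson(exp(offset + M))` with a
#' zero-mean Gaussian prior `-(tau/2)*||M||_F^2`, over training entries
#' only. The rank constraint makes the problem non-convex, so the posterior
#' is maximized by the alternating direction method of multipliers: a
#' smooth likelihood-side copy is updated by per-entry damped Newton steps
#' (the objective is separable given the offset), the constraint-side copy
#' is the truncated-SVD projection of the smooth copy plus the scaled dual,
#' and the penalty parameter grows by one-sided residual balancing (it never
#' shrinks; see the `rho` argument). Held-out
#' entries contribute nothing to the likelihood; their values are imputed
#' by the prior and the rank constraint.
#'
#' @param counts T x N count matrix.
#' @param offset T x N matrix of fixed log rates (`log f + u*cue + v*d`).
#' @param K Number of modulators (rank); must satisfy `K < min(T, N)`.
#' @param tau Prior precision on the entries of `M`.
#' @param mask Optional [holdout_mask].
#' @param hemisphere Optional per-unit hemisphere labels ("L"/"R"). When
#'   supplied, the fit is hemisphere-constrained: the projection is applied
#'   per hemisphere block at rank `K/2` each (rank 1 per hemisphere when
#'   `K = 2`), so each modulator's weights are exactly zero outside its
#'   hemisphere.
#' @param rho Initial ADMM penalty; `NULL` (default) sets it to ten times
#'   the mean training rate, matching the curvature of the Poisson term so
#'   the smooth iterate stays near the low-rank manifold from the start
#'   (small fixed penalties stall far from consensus).
#' @param max_iter,tol Iteration cap and scaled-residual tolerance (the
#'   primal residual must drop below `tol`, the dual below `10 * tol`; the
#'   dual residual plateaus an order of magnitude higher at weak
#'   signal-to-noise without affecting the solution).
#' @param warm_start Optional state from a previous call (e.g. the previous
#'   point of a tau grid) to resume from.
#' @return List with `M_series` (T x K), `W` (N x K),
#'   `modulator_hemisphere` (per column; `NA` when unconstrained), and
#'   `state` (iterations, penalty, residuals, convergence flag, and the
#'   ADMM matrices for warm starting).
#' @export
fit_modulators_admm <- function(counts, offset, K, tau, mask = NULL,
                                hemisphere = NULL, rho = NULL,
                                max_iter = 500, tol = 1e-4,
                                warm_start = NULL) {
  y <- as.matrix(counts)
  tt <- nrow(y); nn <- ncol(y)
  if (K >= min(tt, nn)) stop("K must be smaller than min(T, N)")
  if (K < 1) stop("K must be at least 1")
  constrained <- !is.null(hemisphere)
  if (constrained) {
    if (K %% 2 != 0) stop("hemisphere-constrained fits require even K")
    blocks <- list(L = which(hemisphere == "L"), R = which(hemisphere == "R"))
    kb <- K / 2
  }
  tr <- if (is.null(mask)) matrix(1, tt, nn) else 1 - mask$test
  a <- exp(offset) * tr
  y_tr <- y * tr
  if (is.null(rho)) rho <- 10 * sum(a) / max(sum(tr), 1)
  if (!is.null(warm_start)) {
    x <- warm_start$X; z <- warm_start$Z; u_dual <- warm_start$U
    rho <- warm_start$rho
  } else {
    x <- z <- u_dual <- matrix(0, tt, nn)
  }
  scale <- sqrt(tt * nn)
  primal_prev <- Inf; n_increase <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cmat <- z - u_dual
    for (s in 1:3) {
      r <- a * exp(x)
      grad <- r - y_tr + tau * x + rho * (x - cmat)
      hess <- r + tau + rho
      x <- x - pmin(pmax(grad / hess, -2), 2)
    }
    z_old <- z
    s_in <- x + u_dual
    if (constrained) {
      z <- matrix(0, tt, nn)
      for (b in blocks)
        z[, b] <- rank_project(s_in[, b, drop = FALSE], kb)$z
    } else {
      z <- rank_project(s_in, K)$z
    }
    u_dual <- u_dual + x - z
    primal <- sqrt(sum((x - z)^2)) / scale
    dual <- rho * sqrt(sum((z - z_old)^2)) / scale
    if (primal > 1e-2 && primal > primal_prev * (1 + 1e-12))
      n_increase <- n_increase + 1L
    else n_increase <- 0L
    if (n_increase >= 20)
      stop(sprintf(
        "ADMM diverging (primal residual rose for 20 iterations at iter %d, primal=%.3g, dual=%.3g, rho=%.3g)",
        it, primal, dual, rho))
    primal_prev <- primal
    if (primal < tol && dual < 10 * tol) { converged <- TRUE; break }
    # one-sided residual balancing: rho may only grow. Decreasing it makes
    # the smooth step chase the per-entry likelihood optimum and the
    # truncated-SVD step jitter among near-tied subspaces (a limit cycle at
    # weak signal-to-noise); a stiff penalty keeps both copies together.
    if (primal > 10 * dual) { rho <- rho * 2; u_dual <- u_dual / 2 }
  }
  if (constrained) {
    m_series <- matrix(0, tt, K)
    w <- matrix(0, nn, K)
    hemi_lab <- character(K)
    col <- 1L
    for (bn in names(blocks)) {
      b <- blocks[[bn]]
      pr <- rank_project(z[, b, drop = FALSE], kb)
      m_series[, col:(col + kb - 1)] <- pr$M_series
      w[b, col:(col + kb - 1)] <- pr$W
      hemi_lab[col:(col + kb - 1)] <- bn
      col <- col + kb
    }
  } else {
    pr <- rank_project(z, K)
    m_series <- pr$M_series
    w <- pr$W
    hemi_lab <- rep(NA_character_, K)
  }
  list(M_series = m_series, W = w, modulator_hemisphere = hemi_lab,
       state = list(iterations = it, rho = rho, primal_residual = primal_prev,
                    dual_residual = dual, converged = converged,
                    X = x, Z = z, U = u_dual))
}

#' Canonicalize a modulator factorization
#'
#' The factorization `M = M_series %*% t(W)` is not unique. This resolves
#' the ambiguities without changing the product: every modulator column is
#' rescaled to unit sample variance (scale absorbed into the weights); for
#' `mode = "rank1_per_hemisphere"` (and generically) each column's sign is
#' chosen so its mean weight over coupled units is non-negative; for
#' `mode = "rank2_joint"` an orthogonal rotation first aligns the mean
#' weight vector of the left-hemisphere units with the positive first axis,
#' and the remaining reflection is chosen so the grand-mean weight vector
#' lies in the upper-right quadrant.
#'
#' @param M_series T x K modulator time courses.
#' @param W N x K weights.
#' @param hemisphere Per-unit hemisphere labels ("L"/"R"); required for
#'   `rank2_joint`, and used in `rank1_per_hemisphere` to define "coupled
#'   units" per column.
#' @param mode `"rank1_per_hemisphere"`, `"rank2_joint"`, or `"none"`
#'   (variance and sign normalization only, no rotation).
#' @return List with canonical `M_series` and `W`.
#' @export
resolve_identifiability <- function(M_series, W, hemisphere = NULL,
                                    mode = c("rank1_per_hemisphere",
                                             "rank2_joint", "none")) {
  mode <- match.arg(mode)
  m <- as.matrix(M_series); w <- as.matrix(W)
  k <- ncol(m)
  if (mode == "rank2_joint") {
    if (k != 2) stop("rank2_joint requires exactly two modulators")
    if (is.null(hemisphere)) stop("rank2_joint requires hemisphere labels")
    wl <- colMeans(w[hemisphere == "L", , drop = FALSE])
    ang <- atan2(wl[2], wl[1])
    q <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    w <- w %*% q
    m <- m %*% q
    if (mean(w[, 2]) < 0) { w[, 2] <- -w[, 2]; m[, 2] <- -m[, 2] }
  }
  for (j in seq_len(k)) {
    s <- stats::sd(m[, j])
    if (!is.finite(s) || s < 1e-12) stop("zero-variance modulator column ", j)
    m[, j] <- m[, j] / s
    w[, j] <- w[, j] * s
  }
  if (mode != "rank2_joint") {
    for (j in seq_len(k)) {
      coupled <- if (!is.null(hemisphere) && mode == "rank1_per_hemisphere") {
        nz <- abs(w[, j]) > 1e-12
        if (any(nz)) nz else rep(TRUE, nrow(w))
      } else rep(TRUE, nrow(w))
      if (mean(w[coupled, j]) < 0) { w[, j] <- -w[, j]; m[, j] <- -m[, j] }
    }
  }
  list(M_series = m, W = w)
}

#' Coordinate-descent fit of the full population model
#'
#' Runs the staged pipeline: stimulus drives from cue-away training means,
#' closed-form cue couplings, slow-drift EM, then ADMM modulators; the
#' stages are iterated (two passes by default, which suffices for
#' convergence), followed by identifiability resolution. When `tau` is a
#' vector it is treated as a grid, and the value maximizing the held-out
#' predictive log-likelihood is kept (warm-starting across the grid).
#'
#' @param dataset A [popgain_dataset] (typically an [analysis_view]).
#' @param K Number of modulators; `0` fits the cue+drift model only.
#' @param mask A [holdout_mask] (or `NULL` to train on everything).
#' @param tau Prior precision, or a grid of candidate values; default 1.
#' @param components Character subset of `c("cue", "drift", "modulators")`
#'   to include; the stimulus drive is always fitted.
#' @param hemisphere_constrained Constrain each modulator to one hemisphere
#'   (requires even `K`).
#' @param n_passes Number of coordinate passes.
#' @param refit_f Re-estimate `f` on later passes (default keeps the pass-1
#'   empirical cue-away mean fixed).
#' @param timescale_grid Drift timescale grid (seconds); see
#'   [fit_drift_em()].
#' @param identifiability `"auto"` (per-hemisphere for constrained fits,
#'   joint rotation for unconstrained rank 2, otherwise scale/sign only) or
#'   one of the [resolve_identifiability()] modes.
#' @param admm_control List overriding ADMM settings (`rho`, `max_iter`,
#'   `tol`).
#' @return A [popgain_params] with extra fields `modulator_hemisphere`,
#'   `log` (per-pass training/test log-likelihood per observation), and
#'   `drift_diagnostics`.
#' @export
coordinate_fit <- function(dataset, K = 2, mask = NULL, tau = 1,
                           components = c("cue", "drift", "modulators"),
                           hemisphere_constrained = FALSE, n_passes = 2,
                           refit_f = FALSE, timescale_grid = NULL,
                           identifiability = "auto",
                           admm_control = list()) {
  y <- dataset$counts
  tt <- nrow(y); nn <- ncol(y)
  ci <- cue_indicator(dataset$presentations$cue_side,
                      dataset$units$hemisphere)
  use_cue <- "cue" %in% components
  use_drift <- "drift" %in% components
  use_mod <- "modulators" %in% components && K > 0
  ac <- utils::modifyList(list(rho = NULL, max_iter = 500, tol = 1e-4),
                          admm_control)
  hemi <- if (hemisphere_constrained) dataset$units$hemisphere else NULL

  d <- NULL; v <- rep(0, nn)
  m_series <- NULL; w <- NULL; mod_hemi <- NULL
  d_mat <- matrix(0, tt, nn)
  m_mat <- matrix(0, tt, nn)
  f <- NULL; u <- rep(0, nn)
  tau_best <- NA_real_
  log_rows <- list()
  drift_diag <- NULL

  for (pass in seq_len(n_passes)) {
    if (is.null(f) || refit_f) {
      f <- fit_stimulus_drive(y, ci, mask, d_mat + m_mat,
                              condition = if (use_cue) "away" else "all")
    }
    if (use_cue)
      u <- fit_cue_couplings(y, ci, f, mask, d_mat + m_mat)
    base <- sweep(sweep(ci, 2, u, "*"), 2, log(f), "+")
    if (use_drift) {
      dr <- fit_drift_em(y, base + m_mat, dataset$presentations$timestamp_s,
                         mask = mask, timescale_grid = timescale_grid)
      d <- dr$d; v <- dr$v
      d_mat <- tcrossprod(d, v)
      drift_diag <- dr
    }
    if (use_mod) {
      taus <- sort(tau, decreasing = TRUE)
      best_ll <- -Inf; ws <- NULL; best_fit <- NULL
      for (tv in taus) {
        fit <- fit_modulators_admm(y, base + d_mat, K, tv, mask = mask,
                                   hemisphere = hemi, rho = ac$rho,
                                   max_iter = ac$max_iter, tol = ac$tol,
                                   warm_start = ws)
        ws <- fit$state[c("X", "Z", "U", "rho")]
        sc <- if (is.null(mask)) {
          poisson_loglik_masked(y, exp(base + d_mat +
            tcrossprod(fit$M_series, fit$W)), NULL, "all")
        } else {
          poisson_loglik_masked(y, exp(base + d_mat +
            tcrossprod(fit$M_series, fit$W)), mask, "test")
        }
        if (sc > best_ll) { best_ll <- sc; best_fit <- fit; tau_best <- tv }
      }
      m_series <- best_fit$M_series; w <- best_fit$W
      mod_hemi <- best_fit$modulator_hemisphere
      m_mat <- tcrossprod(m_series, w)
    }
    rates <- exp(base + d_mat + m_mat)
    log_rows[[pass]] <- data.frame(
      pass = pass,
      train_ll_per_obs = poisson_loglik_masked(y, rates, mask, "train") /
        if (is.null(mask)) (tt * nn) else sum(!mask$test),
      test_ll_per_obs = if (is.null(mask)) NA_real_ else
        poisson_loglik_masked(y, rates, mask, "test") / sum(mask$test))
  }

  if (use_mod) {
    mode <- if (identifiability == "auto") {
      if (hemisphere_constrained) "rank1_per_hemisphere"
      else if (K == 2) "rank2_joint" else "none"
    } else identifiability
    res <- resolve_identifiability(m_series, w, dataset$units$hemisphere,
                                   mode = mode)
    m_series <- res$M_series; w <- res$W
  }
  out <- popgain_params(f = f, u = u, d = d, v = v,
                        M_series = m_series, W = w, tau = tau_best,
                        gp_timescale_s = if (use_drift)
                          drift_diag$prior$timescale_s else NA_real_)
  out$modulator_hemisphere <- mod_hemi
  out$log <- do.call(rbind, log_rows)
  out$drift_diagnostics <- if (use_drift) drift_diag$diagnostics else NULL
  out
}
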