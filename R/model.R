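#' Model parameter container
#'
#' Collects all parameters of the modulated-Poisson population model. The
#' rate of unit n on presentation t is
#' \deqn{r_{t,n} = f_n \, h(u_n c_{t,n} + v_n d_t + \sum_k w_{n,k} m^{(k)}_t)}
#' with \eqn{h} the exponential (default) or soft-threshold
#' \eqn{\log(1+e^x)} link, \eqn{f_n} the mean rate in the cue-away
#' condition, \eqn{c_{t,n}} the per-unit binary cue indicator, \eqn{d} the
#' slow drift, and \eqn{m^{(k)}} the shared modulators.
#'
#' @param f Positive vector length N: stimulus-driven cue-away rate
#'   (spikes per window).
#' @param u Vector length N: cue coupling weights.
#' @param d Vector length T: slow drift values (unit sample variance after
#'   identifiability resolution). May be `NULL` for a drift-free model.
#' @param v Vector length N: drift coupling weights.
#' @param M_series T x K matrix of modulator time courses (unit sample
#'   variance per column after identifiability resolution); `NULL` for a
#'   modulator-free model.
#' @param W N x K matrix of modulator coupling weights.
#' @param tau Modulator prior precision (Frobenius penalty weight).
#' @param gp_timescale_s Selected drift timescale in seconds.
#' @param link `"exponential"` or `"soft-threshold"`.
#' @return An object of class `popgain_params`.
#' @export
popgain_params <- function(f, u = rep(0, length(f)), d = NULL,
                           v = rep(0, length(f)), M_series = NULL, W = NULL,
                           tau = NA_real_, gp_timescale_s = NA_real_,
                           link = c("exponential", "soft-threshold")) {
  link <- match.arg(link)
  if (any(!is.finite(f)) || any(f <= 0)) stop("f must be strictly positive")
  n <- length(f)
  if (length(u) != n || length(v) != n) stop("u, v must have length N")
  if (!is.null(M_series)) {
    M_series <- as.matrix(M_series)
    W <- as.matrix(W)
    if (nrow(W) != n || ncol(W) != ncol(M_series))
      stop("W must be N x K matching M_series")
  }
  structure(list(f = f, u = u, d = d, v = v, M_series = M_series, W = W,
                 tau = tau, gp_timescale_s = gp_timescale_s, link = link),
            class = "popgain_params")
}

#' @export
print.popgain_params <- function(x, ...) {
  k <- if (is.null(x$M_series)) 0L else ncol(x$M_series)
  cat(sprintf("popgain_params: N=%d units, %s drift, K=%d modulators, link=%s\n",
              length(x$f), if (is.null(x$d)) "no" else "with", k, x$link))
  invisible(x)
}

link_fun <- function(link) {
  if (link == "exponential") exp else function(x) log1p(exp(pmin(x, 30))) +
    pmax(x - 30, 0)
}

#' Model firing rates
#'
#' Evaluates the modulated-Poisson rate matrix
#' `f * h(u*c + v*d + M_series %*% t(W))` for every presentation and unit.
#'
#' @param params A [popgain_params].
#' @param cue_ind Binary T x N cue indicator matrix, as from
#'   [cue_indicator()] (1 = cue toward the unit's hemifield).
#' @return Strictly positive T x N rate matrix (spikes per window).
#' @export
compute_rate <- function(params, cue_ind) {
  cue_ind <- as.matrix(cue_ind)
  t_n <- dim(cue_ind)
  n <- length(params$f)
  if (t_n[2] != n) stop("cue indicator columns must match number of units")
  eta <- sweep(cue_ind, 2, params$u, "*")
  if (!is.null(params$d)) {
    if (length(params$d) != t_n[1]) stop("drift length must match presentations")
    eta <- eta + tcrossprod(params$d, params$v)
  }
  if (!is.null(params$M_series)) {
    if (nrow(params$M_series) != t_n[1])
      stop("M_series rows must match presentations")
    eta <- eta + tcrossprod(params$M_series, params$W)
  }
  h <- link_fun(params$link)
  sweep(h(eta), 2, params$f, "*")
}

#' Masked Poisson log-likelihood
#'
#' Sum over selected entries of `y*log(r) - r - log(y!)`, with `log(y!)`
#' via `lgamma(y+1)`. The selection is either the training entries (those
#' not held out) or the held-out test entries.
#'
#' @param counts Non-negative integer matrix T x N.
#' @param rates Positive matrix T x N.
#' @param mask A [holdout_mask], or `NULL` for all entries.
#' @param use `"train"`, `"test"`, or `"all"`.
#' @return Scalar log-likelihood in nats.
#' @export
poisson_loglik_masked <- function(counts, rates, mask = NULL,
                                  use = c("train", "test", "all")) {
  use <- match.arg(use)
  sel <- if (is.null(mask) || use == "all") TRUE
         else if (use == "test") mask$test else !mask$test
  y <- counts[sel]
  r <- rates[sel]
  if (any(r <= 0)) stop("non-positive rate at a selected entry")
  sum(y * log(r) - r - lgamma(y + 1))
}

#' Fano factor as a function of firing rate under gain noise
#'
#' For a Poisson process whose rate is perturbed by a noise source of
#' variance `sigma2`, the Fano factor grows with the mean when the noise is
#' multiplicative (`1 + sigma2 * mu`) and shrinks when it is additive
#' (`1 + sigma2 / mu`). These opposite trends are the diagnostic for
#' modulatory (multiplicative) variability.
#'
#' @param mu_grid Positive vector of mean rates.
#' @param sigma2 Noise variance.
#' @param kind `"multiplicative"` or `"additive"`.
#' @return Vector of Fano factors over `mu_grid`.
#' @export
fano_curves <- function(mu_grid, sigma2, kind = c("multiplicative", "additive")) {
  kind <- match.arg(kind)
  if (any(mu_grid <= 0)) stop("mu must be strictly positive")
  if (kind == "multiplicative") 1 + sigma2 * mu_grid else 1 + sigma2 / mu_grid
}

#' Analytic spike-count moments under log-normal gain
#'
#' Moments of a pair of conditionally Poisson units whose log gains
#' x = (x1, x2) are bivariate normal with covariance `log_gain_cov` and
#' means fixed to `-diag(log_gain_cov)/2` so that `E[exp(x)] = 1`
#' (mean-preserving gain). Then `E[Y_i] = f_i`,
#' `Var[Y_i] = f_i + f_i^2 (exp(s_i^2) - 1)` and
#' `Cov[Y_1, Y_2] = f_1 f_2 (exp(cov_12) - 1)`.
#'
#' @param f1,f2 Positive mean rates.
#' @param log_gain_cov Symmetric 2 x 2 positive semidefinite matrix.
#' @return List with `mean`, `variance`, `fano` (length-2 vectors) and
#'   `correlation` (scalar).
#' @export
analytic_count_moments <- function(f1, f2, log_gain_cov) {
  s <- as.matrix(log_gain_cov)
  if (any(dim(s) != 2) || max(abs(s - t(s))) > 1e-10)
    stop("log_gain_cov must be symmetric 2 x 2")
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("log_gain_cov must be positive semidefinite")
  if (f1 <= 0 || f2 <= 0) stop("rates must be positive")
  f <- c(f1, f2)
  mu <- f
  va <- f + f^2 * (exp(diag(s)) - 1)
  cv <- f1 * f2 * (exp(s[1, 2]) - 1)
  list(mean = mu, variance = va, fano = va / mu,
       correlation = cv / sqrt(va[1] * va[2]))
}

#' Model-free response statistics split by cue condition
#'
#' Per-unit Fano factors and per-pair noise correlations of raw counts,
#' computed separately within the cue-toward and cue-away presentations of
#' each unit. Noise correlations pair units within the same hemisphere by
#' default (same cue condition); set `pairs = "all"` to include
#' cross-hemisphere pairs (conditioned on the cue side of the first unit's
#' hemisphere).
#'
#' @param dataset A [popgain_dataset]; only standard, non-first
#'   presentations are used.
#' @param pairs `"within"` (same-hemisphere pairs) or `"all"`.
#' @return List with data frames `fano` (`unit_id`, `condition`, `mean`,
#'   `variance`, `fano`, `flagged`) and `correlation` (`unit_i`, `unit_j`,
#'   `condition`, `r`).
#' @export
response_statistics <- function(dataset, pairs = c("within", "all")) {
  pairs <- match.arg(pairs)
  av <- analysis_view(dataset, min_rate = 0)
  y <- av$counts
  ci <- cue_indicator(av$presentations$cue_side, av$units$hemisphere)
  n <- ncol(y)
  fano <- do.call(rbind, lapply(seq_len(n), function(j) {
    out <- lapply(c(toward = 1, away = 0), function(cond) {
      yj <- y[ci[, j] == cond, j]
      m <- mean(yj); v <- stats::var(yj)
      data.frame(unit_id = av$units$unit_id[j],
                 condition = if (cond == 1) "toward" else "away",
                 mean = m, variance = v,
                 fano = if (m > 0) v / m else NA_real_,
                 flagged = m == 0)
    })
    do.call(rbind, out)
  }))
  hemi <- av$units$hemisphere
  idx <- utils::combn(n, 2)
  if (pairs == "within") idx <- idx[, hemi[idx[1, ]] == hemi[idx[2, ]], drop = FALSE]
  corr <- do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    out <- lapply(c(toward = 1, away = 0), function(cond) {
      sel <- ci[, i] == cond
      r <- suppressWarnings(stats::cor(y[sel, i], y[sel, j]))
      data.frame(unit_i = av$units$unit_id[i], unit_j = av$units$unit_id[j],
                 condition = if (cond == 1) "toward" else "away", r = r)
    })
    do.call(rbind, out)
  }))
  rownames(fano) <- rownames(corr) <- NULL
  list(fano = fano, correlation = corr)
}

#' Discriminability (d-prime) between standard and target counts
#'
#' Difference in mean spike count between target and standard presentations,
#' divided by the square root of their average variance. This is the
#' task-relevance score of a unit.
#'
#' @param standard_counts,target_counts Integer vectors of spike counts.
#' @return Scalar d-prime. Zero when both variances are zero and means are
#'   equal; `Inf` (with a warning) when variances are zero but means differ.
#' @export
dprime <- function(standard_counts, target_counts) {
  ms <- mean(standard_counts); mt <- mean(target_counts)
  vs <- stats::var(standard_counts); vt <- stats::var(target_counts)
  if (is.na(vs)) vs <- 0
  if (is.na(vt)) vt <- 0
  pooled <- (vs + vt) / 2
  if (pooled == 0) {
    if (mt == ms) return(0)
    warning("zero variance with unequal means: d-prime is infinite")
    return(sign(mt - ms) * Inf)
  }
  (mt - ms) / sqrt(pooled)
}

#' Per-unit d-prime values for a dataset
#'
#' Applies [dprime()] to every unit, comparing counts on standard
#' presentations (excluding the first of each trial) against target
#' presentations, restricted to the cue-away condition of each unit by
#' default (the inattentive baseline used for task-relevance scoring).
#'
#' @param dataset A [popgain_dataset] containing target presentations.
#' @param condition `"away"`, `"toward"`, or `"both"`.
#' @return Named numeric vector of d-prime values per unit.
#' @export
unit_dprimes <- function(dataset, condition = c("away", "toward", "both")) {
  condition <- match.arg(condition)
  p <- dataset$presentations
  ci <- cue_indicator(p$cue_side, dataset$units$hemisphere)
  std <- p$is_standard & p$within_trial_index > 0
  tgt <- !p$is_standard
  if (!any(tgt))
    stop("dataset contains no target presentations; d-prime needs the ",
         "full dataset, not the standards-only analysis view")
  vapply(seq_len(ncol(dataset$counts)), function(j) {
    sel <- switch(condition, away = ci[, j] == 0, toward = ci[, j] == 1,
                  both = rep(TRUE, nrow(ci)))
    dprime(dataset$counts[std & sel, j], dataset$counts[tgt & sel, j])
  }, numeric(1)) |> stats::setNames(dataset$units$unit_id)
}
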