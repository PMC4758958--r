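# Fill NA modulator hemisphere labels from the weight mass per hemisphere.
assign_modulator_hemisphere <- function(modulator_hemisphere, W,
                                        unit_hemisphere) {
  vapply(seq_along(modulator_hemisphere), function(j) {
    h <- modulator_hemisphere[j]
    if (!is.na(h)) return(h)
    mass_l <- sum(W[unit_hemisphere == "L", j]^2)
    mass_r <- sum(W[unit_hemisphere == "R", j]^2)
    if (mass_l >= mass_r) "L" else "R"
  }, character(1))
}

#' Modulator variance split by cue condition
#'
#' Sample variance of each hemispheric modulator over the presentations in
#' which the cue was directed toward its hemifield versus away from it, and
#' the toward/away ratio. A ratio below 1 means cued attention stabilizes
#' that population's shared gain.
#'
#' @param M_series T x K modulator matrix (canonical, unit overall
#'   variance).
#' @param cue_side Cue side ("L"/"R" hemifield) per presentation.
#' @param modulator_hemisphere Hemisphere label per modulator column. `NA`
#'   entries (unconstrained fits) are assigned from the weights when `W`
#'   and `unit_hemisphere` are supplied: the hemisphere holding the larger
#'   share of the column's squared weight mass.
#' @param W Optional N x K weight matrix, for hemisphere assignment.
#' @param unit_hemisphere Optional per-unit hemisphere labels.
#' @param min_presentations Conditions with fewer presentations are flagged
#'   low-confidence with a warning.
#' @return Data frame with `modulator`, `hemisphere`, `var_toward`,
#'   `var_away`, `ratio`, `low_confidence`.
#' @export
modulator_variance_by_cue <- function(M_series, cue_side,
                                      modulator_hemisphere,
                                      W = NULL, unit_hemisphere = NULL,
                                      min_presentations = 30) {
  contra <- c(L = "R", R = "L")
  if (anyNA(modulator_hemisphere)) {
    if (is.null(W) || is.null(unit_hemisphere))
      stop("unlabeled modulator hemisphere; supply W and unit_hemisphere ",
           "so labels can be assigned from the weight mass")
    modulator_hemisphere <- assign_modulator_hemisphere(
      modulator_hemisphere, W, unit_hemisphere)
  }
  out <- lapply(seq_len(ncol(M_series)), function(j) {
    hemi <- modulator_hemisphere[j]
    toward <- cue_side == contra[[hemi]]
    vt <- stats::var(M_series[toward, j])
    va <- stats::var(M_series[!toward, j])
    low <- sum(toward) < min_presentations || sum(!toward) < min_presentations
    if (low) warning("fewer than ", min_presentations,
                     " presentations in a cue condition for modulator ", j)
    data.frame(modulator = j, hemisphere = hemi, var_toward = vt,
               var_away = va, ratio = vt / va, low_confidence = low)
  })
  do.call(rbind, out)
}

#' Geometric-mean aggregation of variance ratios
#'
#' Variance ratios are aggregated across days/hemispheres by geometric
#' mean, which treats a ratio and its reciprocal symmetrically.
#'
#' @param ratios Positive numeric vector, or the data frame returned by
#'   [modulator_variance_by_cue()] (its `ratio` column is used).
#' @return Scalar geometric mean.
#' @export
aggregate_variance_ratios <- function(ratios) {
  if (is.data.frame(ratios)) ratios <- ratios$ratio
  exp(mean(log(ratios)))
}

#' Coupling weight versus task discriminability
#'
#' Relates each unit's modulator coupling weight to its d-prime: units are
#' binned into `n_groups` by weight and the mean d-prime per bin is
#' reported alongside the Pearson correlation over all units. An optional
#' firing-rate stratification repeats the correlation within rate groups to
#' control for the rate confound.
#'
#' @param w Per-unit coupling weight (vector; for a weight matrix pass row
#'   norms).
#' @param dprimes Per-unit d-prime values.
#' @param n_groups Number of weight bins.
#' @param rates Optional per-unit mean rates; when given, units are split
#'   into `n_strata` rate groups and within-stratum correlations reported.
#' @param n_strata Number of rate strata.
#' @return List with `bin_means` (data frame `bin`, `mean_weight`,
#'   `mean_dprime`, `n`), `correlation`, and (if stratified)
#'   `stratified` (data frame `stratum`, `correlation`, `n`).
#' @export
weight_vs_dprime <- function(w, dprimes, n_groups = 5, rates = NULL,
                             n_strata = 6) {
  n <- length(w)
  if (n < n_groups) stop("fewer units than groups")
  grp <- cut(rank(w, ties.method = "first"), n_groups, labels = FALSE)
  bin_means <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    sel <- grp == g
    data.frame(bin = g, mean_weight = mean(w[sel]),
               mean_dprime = mean(dprimes[sel]), n = sum(sel))
  }))
  out <- list(bin_means = bin_means, correlation = stats::cor(w, dprimes))
  if (!is.null(rates)) {
    st <- cut(rank(rates, ties.method = "first"), n_strata, labels = FALSE)
    out$stratified <- do.call(rbind, lapply(seq_len(n_strata), function(s) {
      sel <- st == s
      data.frame(stratum = s,
                 correlation = if (sum(sel) > 2)
                   stats::cor(w[sel], dprimes[sel]) else NA_real_,
                 n = sum(sel))
    }))
  }
  out
}

#' Model-predicted attention effects on Fano factors and correlations
#'
#' Using fitted stimulus drives, cue couplings, and the per-condition
#' log-gain covariance implied by the drift and modulator couplings,
#' computes each unit's predicted Fano factor and each within-hemisphere
#' pair's predicted noise correlation in the cue-toward and cue-away
#' conditions (via the analytic log-normal-gain Poisson moments, or by
#' forward simulation), and their attention-induced differences.
#'
#' @param f,u Stimulus drives and cue couplings (length N).
#' @param v Drift couplings; the drift variance is taken as 1 (canonical).
#' @param W N x K modulator weights (canonical scale).
#' @param var_toward,var_away Length-K per-modulator variances in the two
#'   conditions (as from [modulator_variance_by_cue()]).
#' @param hemisphere Per-unit hemisphere labels (pairs are within
#'   hemisphere).
#' @param method `"analytic"` or `"simulation"`.
#' @param n_sim Presentations per condition for the simulation method
#'   (must be at least 1e4).
#' @return List with data frames `units` (`unit`, `fano_toward`,
#'   `fano_away`, `delta_fano`) and `pairs` (`unit_i`, `unit_j`,
#'   `corr_toward`, `corr_away`, `delta_corr`).
#' @export
predicted_attention_effects <- function(f, u, v, W, var_toward, var_away,
                                        hemisphere,
                                        method = c("analytic", "simulation"),
                                        n_sim = 2e4) {
  method <- match.arg(method)
  W <- as.matrix(W)
  n <- length(f)
  cond_stats <- function(vars, cued) {
    mu <- f * exp(u * cued)
    if (method == "analytic") {
      s2 <- v^2 + as.vector(W^2 %*% vars)
      va <- mu + mu^2 * (exp(s2) - 1)
      list(mu = mu, va = va, fano = va / mu,
           cov_fun = function(i, j) {
             cij <- v[i] * v[j] + sum(W[i, ] * W[j, ] * vars)
             mu[i] * mu[j] * (exp(cij) - 1)
           })
    } else {
      if (n_sim < 1e4) stop("simulation method requires n_sim >= 1e4")
      g <- tcrossprod(matrix(stats::rnorm(n_sim), n_sim, 1), v) +
        matrix(stats::rnorm(n_sim * ncol(W)), n_sim) %*%
          (t(W) * sqrt(vars))
      s2 <- v^2 + as.vector(W^2 %*% vars)
      g <- sweep(g, 2, s2 / 2, "-")   # mean-preserving gain, E[exp(g)] = 1
      lam <- sweep(exp(g), 2, mu, "*")
      y <- matrix(stats::rpois(length(lam), lam), n_sim, n)
      va <- apply(y, 2, stats::var)
      cv <- stats::cov(y)
      list(mu = colMeans(y), va = va, fano = va / colMeans(y),
           cov_fun = function(i, j) cv[i, j])
    }
  }
  st_t <- cond_stats(var_toward, 1)
  st_a <- cond_stats(var_away, 0)
  units <- data.frame(unit = seq_len(n), fano_toward = st_t$fano,
                      fano_away = st_a$fano,
                      delta_fano = st_t$fano - st_a$fano)
  idx <- utils::combn(n, 2)
  idx <- idx[, hemisphere[idx[1, ]] == hemisphere[idx[2, ]], drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    ct <- st_t$cov_fun(i, j) / sqrt(st_t$va[i] * st_t$va[j])
    ca <- st_a$cov_fun(i, j) / sqrt(st_a$va[i] * st_a$va[j])
    data.frame(unit_i = i, unit_j = j, corr_toward = ct, corr_away = ca,
               delta_corr = ct - ca)
  }))
  list(units = units, pairs = pairs)
}

#' Eigenvalues of the cue-conditioned modulator covariance ratio
#'
#' A coordinate-free measure of how the cue changes the modulators'
#' second-order statistics: the extreme eigenvalues of
#' `C_cueL %*% solve(C_cueR)`, where `C` are the modulator covariance
#' matrices in the cue-left and cue-right conditions. `lambda_max > 1`
#' indicates a modulation direction that became more variable when the cue
#' switched to the left, `lambda_min < 1` one that became less variable.
#' An optional permutation null shuffles cue labels at the trial level.
#'
#' @param M_series T x K modulator matrix.
#' @param cue_side Cue side per presentation.
#' @param trial_id Trial id per presentation (required for the null).
#' @param n_perm Number of cue-label permutations (0 to skip).
#' @param ridge Diagonal ridge added if the cue-right covariance is
#'   singular.
#' @return List with `lambda_max`, `lambda_min`, `eigenvalues`, and
#'   (if `n_perm > 0`) `null` (n_perm x 2 matrix of extreme eigenvalues).
#' @export
covariance_ratio_eigs <- function(M_series, cue_side, trial_id = NULL,
                                  n_perm = 0, ridge = 1e-8) {
  eig_ratio <- function(side) {
    cl <- stats::cov(M_series[side == "L", , drop = FALSE])
    cr <- stats::cov(M_series[side == "R", , drop = FALSE])
    ch <- tryCatch(chol(cr), error = function(e) {
      chol(cr + diag(ridge, ncol(cr)))
    })
    cri <- chol2inv(ch)
    # symmetric similarity transform shares the spectrum of cl %*% cri
    rh <- chol(cri)
    eigen(rh %*% cl %*% t(rh), symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- eig_ratio(cue_side)
  out <- list(lambda_max = max(ev), lambda_min = min(ev), eigenvalues = ev)
  if (n_perm > 0) {
    if (is.null(trial_id)) stop("trial_id required for the permutation null")
    ids <- unique(trial_id)
    tr_cue <- cue_side[match(ids, trial_id)]
    out$null <- t(vapply(seq_len(n_perm), function(p) {
      perm <- sample(tr_cue)
      side <- perm[match(trial_id, ids)]
      e <- eig_ratio(side)
      c(max(e), min(e))
    }, numeric(2)))
    colnames(out$null) <- c("lambda_max", "lambda_min")
  }
  out
}

#' Within-block autocorrelation of the modulators
#'
#' Autocorrelation of each modulator at lags 1..`max_lag` in presentation
#' units, computed within blocks (targets and inter-trial gaps ignored) and
#' averaged across blocks.
#'
#' @param M_series T x K modulator matrix.
#' @param block_id Block id per presentation.
#' @param max_lag Largest lag; truncated with a warning if it reaches the
#'   shortest block.
#' @return Matrix max_lag x K of average autocorrelations.
#' @export
modulator_autocorrelation <- function(M_series, block_id, max_lag = 10) {
  M_series <- as.matrix(M_series)
  blocks <- split(seq_len(nrow(M_series)), block_id)
  shortest <- min(lengths(blocks))
  if (shortest <= 1)
    stop("blocks are too short to estimate any autocorrelation lag")
  if (max_lag >= shortest) {
    warning("max_lag truncated to shortest block minus 1")
    max_lag <- shortest - 1
  }
  acf_k <- sapply(seq_len(ncol(M_series)), function(j) {
    vapply(seq_len(max_lag), function(l) {
      vals <- vapply(blocks, function(b) {
        x <- M_series[b, j]
        nb <- length(x)
        if (nb <= l + 1) return(NA_real_)
        stats::cor(x[1:(nb - l)], x[(1 + l):nb])
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
  })
  acf_k <- matrix(acf_k, nrow = max_lag)
  rownames(acf_k) <- seq_len(max_lag)
  acf_k
}

#' Zero-lag correlation between two modulators
#'
#' @param M_series T x 2 modulator matrix.
#' @return Pearson correlation of the two columns.
#' @export
modulator_crosscorrelation <- function(M_series) {
  stats::cor(M_series[, 1], M_series[, 2])
}

#' Total shared gain variance versus task relevance
#'
#' For each unit and cue condition, the variance across presentations of
#' the model-estimated total gain `exp(v_n d_t + sum_k w_nk m_t^k)` (slow
#' drift and modulators combined), summarized across d-prime bins and
#' optionally stratified by firing rate.
#'
#' @param params A fitted [popgain_params].
#' @param dataset The dataset the parameters were fitted to (for cue
#'   conditions).
#' @param dprimes Per-unit d-prime values.
#' @param n_groups Number of d-prime bins.
#' @param rates Optional per-unit rates for stratification.
#' @return List with `units` (`unit`, `condition`, `sigma_g2`, `dprime`)
#'   and `groups` (`condition`, `bin`, `mean_dprime`, `mean_sigma_g2`).
#' @export
gain_variance_by_relevance <- function(params, dataset, dprimes,
                                       n_groups = 5, rates = NULL) {
  tt <- nrow(dataset$counts)
  lg <- matrix(0, tt, length(params$f))
  if (!is.null(params$d)) lg <- lg + tcrossprod(params$d, params$v)
  if (!is.null(params$M_series))
    lg <- lg + tcrossprod(params$M_series, params$W)
  gain <- exp(lg)
  ci <- cue_indicator(dataset$presentations$cue_side,
                      dataset$units$hemisphere)
  units <- do.call(rbind, lapply(c("toward", "away"), function(cond) {
    data.frame(unit = seq_len(ncol(gain)), condition = cond,
               sigma_g2 = vapply(seq_len(ncol(gain)), function(j)
                 stats::var(gain[ci[, j] == (cond == "toward"), j]),
                 numeric(1)),
               dprime = dprimes)
  }))
  grp <- cut(rank(dprimes, ties.method = "first"), n_groups, labels = FALSE)
  groups <- do.call(rbind, lapply(c("toward", "away"), function(cond) {
    uu <- units[units$condition == cond, ]
    do.call(rbind, lapply(seq_len(n_groups), function(g) {
      sel <- grp == g
      data.frame(condition = cond, bin = g,
                 mean_dprime = mean(dprimes[sel]),
                 mean_sigma_g2 = mean(uu$sigma_g2[sel]))
    }))
  }))
  list(units = units, groups = groups)
}
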