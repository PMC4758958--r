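#' Ground truth for a synthetic recording day
#'
#' Draws all generative parameters of a synthetic dataset: the task layout
#' (blocks of 125 trials with 80% cue validity, a variable number of
#' standard presentations per trial), per-unit stimulus drives, cue and
#' drift couplings, hemisphere-specific AR(1) shared modulators whose
#' stationary variance drops under cued attention, modulator coupling
#' weights tied to a latent task-relevance score, and the behavioral
#' (psychometric, lapse, reward-dynamics) parameters. The modulator weight
#' scale is calibrated so that the median modulator-induced pairwise noise
#' correlation matches `target_median_corr` (see
#' [match_noise_correlation_scale()]).
#'
#' @param preset `"default"` (two hemisphere-specific AR(1) modulators,
#'   attention-dependent variance, relevance-coupled weights and behavior)
#'   or `"null"` (no cue, drift, or modulator effects: pure Poisson).
#' @param seed Integer seed; the bundle is bit-reproducible from
#'   (parameters, seed).
#' @param n_units Number of units (split evenly across hemispheres).
#' @param n_presentations Target number of analyzable standard
#'   presentations (non-first standards).
#' @param K Number of modulators.
#' @param modulator_style `"ar1_hemisphere"` (default preset) or `"iid"`
#'   (i.i.d. standard-normal modulator values and weights, as used in the
#'   modulator-count recovery experiment).
#' @param ar_coef AR(1) coefficient of the modulators across successive
#'   presentations.
#' @param variance_ratio Stationary modulator variance in cue-toward blocks
#'   relative to cue-away blocks (1 = no attention effect on variance).
#' @param weight_dprime_coupling Strength in `[0, 1]` with which modulator
#'   weights and target discriminability share a latent relevance score
#'   (0 = independent).
#' @param drift_sd Scale of the per-unit drift couplings (0 disables drift).
#' @param drift_timescale_s Timescale of the GP drift draw.
#' @param target_median_corr Calibration target for the median
#'   modulator-induced pairwise noise correlation; `NA` skips calibration
#'   and uses `lambda_scale` as given.
#' @param lambda_scale Global modulator weight scale; ignored when
#'   `target_median_corr` is set.
#' @param cue_validity Probability the target appears on the cued side.
#' @param catch_fraction Fraction of trials with no target.
#' @param behavior List overriding behavioral parameters: `alpha`, `beta`
#'   (length 2, effects of (m_cued, m_opp) on cued-target hits),
#'   `lambda_slope`, `delta_lapse`, `alpha_opp`, `beta_opp`, `a`, `B`
#'   (2 x 2, columns = previous hit-cued / hit-opposite shifts of
#'   (m_cued, m_opp)), `direct_serial` (2 x 2 additive logit biases:
#'   rows = cued/opposite target, columns = previous reward category;
#'   a non-modulator serial-dependence pathway).
#' @param include_binned Also generate 10-ms binned counts with a
#'   within-presentation modulation profile (see [generate_dataset()]).
#' @return An object of class `popgain_truth`.
#' @export
synthetic_truth <- function(preset = c("default", "null"), seed = 1,
                            n_units = 100, n_presentations = 3000, K = 2,
                            modulator_style = c("ar1_hemisphere", "iid"),
                            ar_coef = 0.5, variance_ratio = 0.77,
                            weight_dprime_coupling = 0.7,
                            drift_sd = 0.12, drift_timescale_s = 600,
                            target_median_corr = 0.05, lambda_scale = 1,
                            cue_validity = 0.8, catch_fraction = 0.05,
                            behavior = list(), include_binned = FALSE) {
  preset <- match.arg(preset)
  modulator_style <- match.arg(modulator_style)
  if (preset == "null") {
    variance_ratio <- 1
    weight_dprime_coupling <- 0
    drift_sd <- 0
    target_median_corr <- NA
    lambda_scale <- 0
  }
  set.seed(seed)
  n_hemi <- c(L = ceiling(n_units / 2), R = floor(n_units / 2))
  hemisphere <- rep(c("L", "R"), n_hemi)
  f <- pmin(pmax(stats::rlnorm(n_units, log(5), 0.6), 0.8), 25)
  # cue couplings: ~75% of units gain under cued attention
  u <- stats::rnorm(n_units, 0.101, 0.15)
  v <- abs(stats::rnorm(n_units, 0, drift_sd))
  relevance <- stats::runif(n_units)
  g <- weight_dprime_coupling
  if (modulator_style == "ar1_hemisphere") {
    if (K != 2) stop("ar1_hemisphere style uses K = 2 (one per hemisphere)")
    w_raw <- matrix(0, n_units, 2)
    for (j in 1:2) {
      b <- hemisphere == c("L", "R")[j]
      w_raw[b, j] <- abs(stats::rnorm(sum(b))) * (1 - g + 2 * g * relevance[b])
    }
    mod_hemi <- c("L", "R")
  } else {
    w_raw <- matrix(stats::rnorm(n_units * K), n_units, K)
    mod_hemi <- rep(NA_character_, K)
  }
  target_gain <- 0.25 + 0.5 * relevance
  beh <- utils::modifyList(list(
    alpha = -0.8, beta = c(0.25, -0.3), lambda_slope = 1.1,
    delta_lapse = 0.9, alpha_opp = 0.4, beta_opp = c(-0.35, 0.4),
    a = c(0, 0),
    B = matrix(c(0.12, -0.12, -0.18, 0.22), 2, 2),
    direct_serial = matrix(0, 2, 2)), behavior)
  truth <- structure(list(
    preset = preset, seed = seed, n_units = n_units,
    n_presentations = n_presentations, hemisphere = hemisphere,
    f = f, u = u, v = v, relevance = relevance, target_gain = target_gain,
    K = K, modulator_style = modulator_style, mod_hemi = mod_hemi,
    W_raw = w_raw, lambda_scale = lambda_scale, ar_coef = ar_coef,
    variance_ratio = variance_ratio,
    weight_dprime_coupling = weight_dprime_coupling,
    drift_sd = drift_sd, drift_timescale_s = drift_timescale_s,
    cue_validity = cue_validity, catch_fraction = catch_fraction,
    block_size = 125, standards_per_trial = 2:8,
    delta_theta_levels = c(1, 2, 4, 8, 12), opp_delta_theta = 12,
    behavior = beh, include_binned = include_binned,
    bin_width_ms = 10, n_bins = 26, window_bins = 7:26),
    class = "popgain_truth")
  if (!is.na(target_median_corr))
    truth <- match_noise_correlation_scale(truth, target_median_corr)
  truth
}

#' @export
print.popgain_truth <- function(x, ...) {
  cat(sprintf(
    "popgain_truth (%s): N=%d, ~%d presentations, K=%d (%s), lambda=%.3f, seed=%d\n",
    x$preset, x$n_units, x$n_presentations, x$K, x$modulator_style,
    x$lambda_scale, x$seed))
  invisible(x)
}

# Analytic median modulator-induced pairwise noise correlation at weight
# scale lambda. Variances include the drift contribution; the numerator is
# the modulator covariance only, so the objective is exactly 0 at lambda=0
# and strictly increasing in lambda. For signed (iid) weights the median of
# the correlation magnitudes is used; for non-negative hemispheric weights
# the two coincide, and the median is then taken over within-hemisphere
# pairs (cross-hemisphere pairs share no modulator by construction).
analytic_median_corr <- function(truth, lambda) {
  w <- truth$W_raw * lambda
  f <- truth$f
  s_i <- truth$v^2 + rowSums(w^2)        # per-unit log-gain variance
  wwt <- tcrossprod(w)                   # pairwise log-gain covariance
  # corr_ij = (e^c - 1) / sqrt(prod_i (1/f_i + e^{s_i} - 1)), computed in
  # log space so large lambda does not overflow
  log_num <- pmax(wwt, 0) + log1p(-exp(-abs(wwt)))
  log_den <- ifelse(s_i > 30, s_i, log(1 / f + expm1(s_i)))
  cr <- sign(wwt) * exp(log_num - 0.5 * outer(log_den, log_den, "+"))
  if (truth$modulator_style == "ar1_hemisphere") {
    same <- outer(truth$hemisphere, truth$hemisphere, "==")
    vals <- cr[upper.tri(cr) & same]
  } else {
    vals <- abs(cr[upper.tri(cr)])
  }
  stats::median(vals)
}

#' Calibrate the modulator weight scale to a target noise correlation
#'
#' Bisection on the global weight scale `lambda` so the analytic median
#' modulator-induced pairwise noise correlation matches `target` to within
#' 10% relative error. Within-hemisphere pairs are used for
#' hemisphere-specific modulators; for signed i.i.d. weights the median
#' correlation magnitude is matched.
#'
#' @param truth A [synthetic_truth] object.
#' @param target Target median correlation (0 gives `lambda = 0`).
#' @return The truth object with `lambda_scale` set.
#' @export
match_noise_correlation_scale <- function(truth, target) {
  if (target == 0) { truth$lambda_scale <- 0; return(truth) }
  if (target < 0) stop("target correlation must be non-negative")
  # the analytic correlation rises with lambda, peaks, then falls (the
  # per-unit variance inflation e^{s} eventually outgrows the pairwise
  # covariance); calibrate on the ascending branch, i.e. the smallest
  # lambda achieving the target
  grid <- seq(0.05, 10, by = 0.05)
  vals <- vapply(grid, function(l) analytic_median_corr(truth, l),
                 numeric(1))
  if (max(vals) < target)
    stop(sprintf("target median correlation %.3g unreachable with lambda in [0, 10]",
                 target))
  lo <- 0; hi <- grid[which.max(vals)]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    val <- analytic_median_corr(truth, mid)
    if (abs(val - target) <= 0.1 * target) break
    if (val < target) lo <- mid else hi <- mid
  }
  truth$lambda_scale <- mid
  truth
}

# Trial/block scaffold: cue sides alternate by block, standards per trial
# uniform, timestamps from presentation and inter-trial gaps.
make_task_scaffold <- function(truth) {
  n_trials <- max(8L, round(truth$n_presentations / 4))
  block_id <- (seq_len(n_trials) - 1) %/% truth$block_size + 1
  cue_side <- c("L", "R")[(block_id - 1) %% 2 + 1]
  n_std <- sample(truth$standards_per_trial, n_trials, replace = TRUE)
  is_catch <- stats::runif(n_trials) < truth$catch_fraction
  list(n_trials = n_trials, block_id = block_id, cue_side = cue_side,
       n_std = n_std, is_catch = is_catch)
}

#' Generate a synthetic dataset bundle
#'
#' Simulates a full recording day from a [synthetic_truth]: the trial/block
#' scaffold, a Gaussian-process drift draw, hemisphere-specific AR(1)
#' modulators whose stationary variance switches at block boundaries
#' (cue-toward variance = `variance_ratio` x cue-away variance) and whose
#' trial means are shifted by previous reward, Poisson spike counts for
#' standards and tuning-shifted targets, behavioral outcomes drawn from the
#' psychometric models given the trial-averaged modulators, and (optionally)
#' 10-ms binned counts carrying a stereotyped within-presentation
#' modulation profile. Log gains are centred per unit so that the expected
#' cue-away gain is 1 and `f` is the cue-away mean rate.
#'
#' @param truth A [synthetic_truth].
#' @return List with `dataset` (a [popgain_dataset] including target
#'   presentations), `behavior` (a behavioral table, one row per trial,
#'   with trial-averaged true modulators in cued/opposite coordinates),
#'   `binned` (list with `counts` array T x B x N, `bin_width_ms`,
#'   `window_bins`, `psth_shape`, `omega`; `NULL` unless
#'   `truth$include_binned`), and `truth` (with realized `d`, `M`, `W`
#'   attached as `d_true`, `M_true`, `W_true`, `omega_true`).
#' @export
generate_dataset <- function(truth) {
  set.seed(truth$seed + 1L)
  sc <- make_task_scaffold(truth)
  nu <- truth$n_units
  hemi <- truth$hemisphere
  w <- truth$W_raw * truth$lambda_scale

  # presentation table: standards then (unless catch) one target per trial
  rows <- vector("list", sc$n_trials)
  tnow <- 0
  for (i in seq_len(sc$n_trials)) {
    k <- sc$n_std[i]
    has_tgt <- !sc$is_catch[i]
    np <- k + has_tgt
    ts <- tnow + cumsum(0.2 + stats::runif(np, 0.2, 0.4))
    tnow <- ts[np] + 1.5
    rows[[i]] <- data.frame(
      trial_id = i, block_id = sc$block_id[i], cue_side = sc$cue_side[i],
      within_trial_index = seq_len(np) - 1, timestamp_s = ts,
      is_standard = c(rep(TRUE, k), if (has_tgt) FALSE))
  }
  pres <- do.call(rbind, rows)
  pres$presentation_id <- seq_len(nrow(pres))
  tp <- nrow(pres)

  # slow drift: GP draw in the Nystrom basis, standardized to unit variance
  if (truth$drift_sd > 0) {
    phi <- gp_basis(pres$timestamp_s, truth$drift_timescale_s)
    d <- as.vector(phi %*% stats::rnorm(ncol(phi)))
    d <- (d - mean(d)) / stats::sd(d)
  } else d <- rep(0, tp)

  # modulators + behavior, trial by trial (reward feeds the next trial)
  kk <- truth$K
  m <- matrix(0, tp, kk)
  iid_style <- truth$modulator_style == "iid"
  sd_block <- function(cue, hemi_mod) {
    toward <- (cue == "L" & hemi_mod == "R") | (cue == "R" & hemi_mod == "L")
    sqrt(ifelse(toward, truth$variance_ratio, 1))
  }
  beh <- truth$behavior
  x <- rep(0, kk)           # AR state (zero-mean deviation process)
  cur_block <- 0L
  r_prev <- c(0, 0)         # previous reward indicator (cued, opposite)
  beh_rows <- vector("list", sc$n_trials)
  contra <- c(L = "R", R = "L")
  for (i in seq_len(sc$n_trials)) {
    idx <- which(pres$trial_id == i)
    std_idx <- idx[pres$is_standard[idx]]
    cue <- sc$cue_side[i]
    cued_mod <- if (!iid_style) which(truth$mod_hemi == contra[[cue]]) else NA
    opp_mod <- if (!iid_style) which(truth$mod_hemi == cue) else NA
    # reward-driven mean shift, mapped from (cued, opposite) to hemispheres
    shift <- rep(0, kk)
    if (!iid_style) {
      s_co <- beh$a + as.vector(beh$B %*% r_prev)
      shift[cued_mod] <- s_co[1]
      shift[opp_mod] <- s_co[2]
    }
    for (t in idx) {
      if (iid_style) {
        m[t, ] <- stats::rnorm(kk)
      } else {
        sdv <- sd_block(cue, truth$mod_hemi)
        if (pres$block_id[t] != cur_block) {
          x <- stats::rnorm(kk) * sdv
          cur_block <- pres$block_id[t]
        } else {
          x <- truth$ar_coef * x +
            stats::rnorm(kk) * sdv * sqrt(1 - truth$ar_coef^2)
        }
        m[t, ] <- x + shift
      }
    }
    m_bar <- colMeans(m[std_idx, , drop = FALSE])
    m_cued <- if (!iid_style) m_bar[cued_mod] else 0
    m_opp <- if (!iid_style) m_bar[opp_mod] else 0
    # behavioral outcome
    if (sc$is_catch[i]) {
      outcome <- "catch"; tgt_side <- "none"; dth <- NA_real_; hit <- FALSE
    } else {
      on_cued <- stats::runif(1) < truth$cue_validity
      tgt_side <- if (on_cued) "cued" else "opposite"
      if (on_cued) {
        dth <- sample(truth$delta_theta_levels, 1)
        lp <- beh$alpha + beh$beta[1] * m_cued + beh$beta[2] * m_opp +
          beh$lambda_slope * log(dth) +
          sum(beh$direct_serial[1, ] * r_prev)
        p_hit <- beh$delta_lapse * stats::plogis(lp)
      } else {
        dth <- truth$opp_delta_theta
        lp <- beh$alpha_opp + beh$beta_opp[1] * m_cued +
          beh$beta_opp[2] * m_opp + sum(beh$direct_serial[2, ] * r_prev)
        p_hit <- stats::plogis(lp)
      }
      hit <- stats::runif(1) < p_hit
      outcome <- if (hit) "hit" else "miss"
    }
    prev_cat <- if (all(r_prev == c(1, 0))) "hit-cued"
                else if (all(r_prev == c(0, 1))) "hit-opposite" else "other"
    beh_rows[[i]] <- data.frame(
      trial_id = i, block_id = sc$block_id[i], cue_side = cue,
      outcome = outcome, target_side = tgt_side, delta_theta_deg = dth,
      rewarded = hit, prev_reward = prev_cat,
      m_cued = m_cued, m_opp = m_opp)
    r_prev <- if (hit && tgt_side == "cued") c(1, 0)
              else if (hit && tgt_side == "opposite") c(0, 1) else c(0, 0)
  }
  behavior <- do.call(rbind, beh_rows)

  # rates: mean-preserving centring in the cue-away condition
  ci <- cue_indicator(pres$cue_side, hemi)
  cent <- (truth$v^2 + rowSums(w^2)) / 2
  log_gain <- sweep(ci, 2, truth$u, "*") + tcrossprod(d, truth$v) +
    tcrossprod(m, w)
  log_gain <- sweep(log_gain, 2, cent, "-")
  rate <- sweep(exp(log_gain), 2, truth$f, "*")
  # targets: tuning-shifted response for units representing the target side
  tgt_rows <- which(!pres$is_standard)
  if (length(tgt_rows)) {
    tgt_trial <- pres$trial_id[tgt_rows]
    tside <- ifelse(behavior$target_side[tgt_trial] == "cued",
                    behavior$cue_side[tgt_trial],
                    contra[behavior$cue_side[tgt_trial]])
    sees <- outer(tside, contra[hemi], "==")  # unit's hemifield == target side
    rate[tgt_rows, ] <- rate[tgt_rows, ] *
      exp(sweep(sees * 1, 2, truth$target_gain, "*"))
    pres$delta_theta_deg <- NA_real_
    pres$delta_theta_deg[tgt_rows] <- behavior$delta_theta_deg[tgt_trial]
  }

  binned <- NULL
  if (truth$include_binned) {
    nb <- truth$n_bins
    wb <- truth$window_bins
    shape <- c(rep(0.15, 6), 0.35, 0.8, 1.2, 1.4, 1.3, 1.1,
               rep(1, nb - 12))
    omega <- pmin((wb - min(wb)) / 6, 1)      # ramp over first 60 ms of window
    omega <- omega / mean(omega)              # per-bin gain averages to 1
    std_rows <- which(pres$is_standard)
    mw <- tcrossprod(m[std_rows, , drop = FALSE], w)
    base_lg <- sweep(ci[std_rows, , drop = FALSE], 2, truth$u, "*") +
      tcrossprod(d[std_rows], truth$v)
    base_lg <- sweep(base_lg, 2, cent, "-")
    f_bin <- outer(shape / sum(shape[wb]), truth$f)   # B x N
    counts_b <- array(0L, c(length(std_rows), nb, nu))
    for (b in seq_len(nb)) {
      og <- if (b %in% wb) omega[match(b, wb)] else 0
      rb <- sweep(exp(base_lg + og * mw), 2, f_bin[b, ], "*")
      counts_b[, b, ] <- stats::rpois(length(rb), rb)
    }
    counts <- matrix(stats::rpois(length(rate), rate), tp, nu)
    counts[std_rows, ] <- apply(counts_b[, wb, , drop = FALSE], c(1, 3), sum)
    binned <- list(counts = counts_b, bin_width_ms = truth$bin_width_ms,
                   window_bins = wb, psth_shape = shape, omega = omega,
                   presentation_id = pres$presentation_id[std_rows])
    truth$omega_true <- omega
  } else {
    counts <- matrix(stats::rpois(length(rate), rate), tp, nu)
  }

  units <- data.frame(unit_id = sprintf("u%03d", seq_len(nu)),
                      hemisphere = hemi,
                      sua_mua = rep(c("sua", "mua"), length.out = nu))
  trials <- behavior[, c("trial_id", "outcome", "target_side",
                         "delta_theta_deg", "rewarded")]
  dataset <- popgain_dataset(counts, pres, units, trials)
  truth$d_true <- d
  truth$M_true <- m
  truth$W_true <- w
  list(dataset = dataset, behavior = behavior, binned = binned, truth = truth)
}

#' Behavioral table from a fitted (or true) modulator series
#'
#' Builds the per-trial table used by the behavioral GLMs: outcome, target
#' side, difficulty, previous-reward category, and the two hemispheric
#' modulators averaged across the trial's standard presentations and mapped
#' to cued/opposite coordinates via the block cue (the cued modulator is
#' the one for the hemisphere contralateral to the cued hemifield).
#'
#' @param dataset A [popgain_dataset] with a `trials` component. When the
#'   dataset is an [analysis_view], `M_series` rows must match its
#'   presentations.
#' @param M_series T x 2 modulator matrix.
#' @param modulator_hemisphere Length-2 labels ("L"/"R") naming each
#'   column's hemisphere.
#' @return Data frame, one row per trial with at least one standard
#'   presentation in `dataset`.
#' @export
make_behavioral_table <- function(dataset, M_series, modulator_hemisphere,
                                  W = NULL) {
  p <- dataset$presentations
  tr <- dataset$trials
  if (is.null(tr)) stop("dataset has no trial outcomes")
  contra <- c(L = "R", R = "L")
  if (anyNA(modulator_hemisphere)) {
    if (is.null(W))
      stop("unlabeled modulator hemisphere; supply W so labels can be ",
           "assigned from the weight mass")
    modulator_hemisphere <- assign_modulator_hemisphere(
      modulator_hemisphere, W, dataset$units$hemisphere)
  }
  if (anyDuplicated(modulator_hemisphere))
    stop("behavioral table needs exactly one modulator per hemisphere")
  ids <- sort(unique(p$trial_id))
  out <- lapply(ids, function(i) {
    sel <- p$trial_id == i & p$is_standard
    if (!any(sel)) return(NULL)
    cue <- p$cue_side[sel][1]
    m_bar <- colMeans(M_series[sel, , drop = FALSE])
    ti <- tr[tr$trial_id == i, ]
    data.frame(trial_id = i, cue_side = cue, outcome = ti$outcome,
               target_side = ti$target_side,
               delta_theta_deg = ti$delta_theta_deg,
               rewarded = ti$rewarded,
               m_cued = m_bar[modulator_hemisphere == contra[[cue]]],
               m_opp = m_bar[modulator_hemisphere == cue])
  })
  tab <- do.call(rbind, out)
  prev <- tab$rewarded & tab$target_side == "cued"
  prev_o <- tab$rewarded & tab$target_side == "opposite"
  tab$prev_reward <- c("other",
                       ifelse(prev, "hit-cued",
                              ifelse(prev_o, "hit-opposite", "other"))[-nrow(tab)])
  tab
}

#' Simulate a trial-level behavioral table directly
#'
#' Lightweight generator for testing the behavioral GLMs in isolation: the
#' trial-averaged modulators follow the linear-Gaussian reward dynamics
#' `m(t) = a + B r(t-1) + C m(t-1) + noise` and outcomes are drawn from the
#' psychometric models, without simulating spike counts.
#'
#' @param n_trials Number of trials.
#' @param pars List overriding any of: `alpha`, `beta`, `lambda_slope`,
#'   `delta_lapse`, `alpha_opp`, `beta_opp`, `a`, `B`, `C`, `sigma`,
#'   `direct_serial`, `cue_validity`, `catch_fraction`,
#'   `delta_theta_levels`, `opp_delta_theta`.
#' @param seed Integer seed.
#' @return Behavioral data frame as from [make_behavioral_table()].
#' @export
simulate_behavior <- function(n_trials, pars = list(), seed = 1) {
  p <- utils::modifyList(list(
    alpha = -0.8, beta = c(0.25, -0.3), lambda_slope = 1.1,
    delta_lapse = 0.9, alpha_opp = 0.4, beta_opp = c(-0.35, 0.4),
    a = c(0, 0), B = matrix(c(0.12, -0.12, -0.18, 0.22), 2, 2),
    C = diag(0.3, 2), sigma = 0.8, direct_serial = matrix(0, 2, 2),
    cue_validity = 0.8, catch_fraction = 0.05,
    delta_theta_levels = c(1, 2, 4, 8, 12), opp_delta_theta = 12), pars)
  set.seed(seed)
  m_prev <- c(0, 0); r_prev <- c(0, 0)
  outcome <- character(n_trials); side <- character(n_trials)
  dth <- rep(NA_real_, n_trials); hit <- logical(n_trials)
  prev <- character(n_trials)
  m1 <- numeric(n_trials); m2 <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    m <- p$a + as.vector(p$B %*% r_prev) + as.vector(p$C %*% m_prev) +
      stats::rnorm(2, 0, p$sigma)
    m1[i] <- m[1]; m2[i] <- m[2]
    prev[i] <- if (r_prev[1] == 1) "hit-cued"
               else if (r_prev[2] == 1) "hit-opposite" else "other"
    if (stats::runif(1) < p$catch_fraction) {
      outcome[i] <- "catch"; side[i] <- "none"
    } else {
      on_cued <- stats::runif(1) < p$cue_validity
      side[i] <- if (on_cued) "cued" else "opposite"
      if (on_cued) {
        dth[i] <- sample(p$delta_theta_levels, 1)
        ph <- p$delta_lapse * stats::plogis(
          p$alpha + sum(p$beta * m) + p$lambda_slope * log(dth[i]) +
            sum(p$direct_serial[1, ] * r_prev))
      } else {
        dth[i] <- p$opp_delta_theta
        ph <- stats::plogis(p$alpha_opp + sum(p$beta_opp * m) +
                              sum(p$direct_serial[2, ] * r_prev))
      }
      hit[i] <- stats::runif(1) < ph
      outcome[i] <- if (hit[i]) "hit" else "miss"
    }
    m_prev <- m
    r_prev <- if (hit[i] && side[i] == "cued") c(1, 0)
              else if (hit[i] && side[i] == "opposite") c(0, 1) else c(0, 0)
  }
  data.frame(trial_id = seq_len(n_trials), cue_side = "L", outcome = outcome,
             target_side = side, delta_theta_deg = dth, rewarded = hit,
             prev_reward = prev, m_cued = m1, m_opp = m2)
}
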