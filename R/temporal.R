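#' Binned within-presentation dataset
#'
#' Container for spike counts resolved in short bins within each stimulus
#' presentation, used by the fine-temporal extension of the model.
#'
#' @param counts Nonnegative integer array, presentations x bins x units.
#' @param bin_width_ms Positive bin width in milliseconds.
#' @param window_bins Integer indices of the bins inside the analysis
#'   window (the main response period); at least 3.
#' @param presentation_id Optional identifiers aligning rows to a
#'   [popgain_dataset]'s presentations.
#' @return List of class `popgain_binned`.
#' @export
binned_dataset <- function(counts, bin_width_ms = 10, window_bins,
                           presentation_id = NULL) {
  if (length(dim(counts)) != 3) stop("counts must be a 3-d array")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (bin_width_ms <= 0) stop("bin_width_ms must be positive")
  window_bins <- as.integer(window_bins)
  if (any(window_bins < 1) || any(window_bins > dim(counts)[2]))
    stop("window_bins out of range")
  if (!is.null(presentation_id) &&
      length(presentation_id) != dim(counts)[1])
    stop("presentation_id length must match the first array dimension")
  structure(list(counts = counts, bin_width_ms = bin_width_ms,
                 window_bins = window_bins,
                 presentation_id = presentation_id),
            class = "popgain_binned")
}

#' Peri-stimulus time histogram from binned counts
#'
#' Per-bin, per-unit mean counts across presentations, plus a normalized
#' population-average trace: units are averaged after subtracting each
#' unit's spontaneous rate (its mean count in the pre-window bins), and the
#' population trace is scaled to a peak of 1.
#'
#' @param binned A binned dataset (list with `counts` and `window_bins`).
#' @return List with `psth` (bins x units matrix of mean counts) and
#'   `population` (length-B normalized vector; all-zero if the response
#'   never exceeds the spontaneous baseline).
#' @export
estimate_psth <- function(binned) {
  y <- binned$counts
  psth <- apply(y, c(2, 3), mean)
  pre <- setdiff(seq_len(nrow(psth)), binned$window_bins)
  spont <- if (length(pre)) colMeans(psth[pre, , drop = FALSE]) else
    rep(0, ncol(psth))
  pop <- rowMeans(sweep(psth, 2, spont, "-"))
  pk <- max(abs(pop))
  list(psth = psth, population = if (pk > 0) pop / pk else pop)
}

#' Fit the shared within-presentation modulation profile
#'
#' Extends the coarse modulator model to binned counts: within the analysis
#' window, \eqn{Y_{t,b,n} \sim Poiss(F_{b,n} e^{C_{t,n} + D_{t,n} +
#' \omega_b (M W^T)_{t,n}})}, where the cue couplings and slow drift
#' (`C + D`) are frozen from the coarse fit, `F` is the per-bin mean-rate
#' profile (PSTH), and a single stereotyped profile `omega` scales the
#' low-rank modulation in every bin. Fitting alternates rank-K updates of
#' the modulation matrix (ADMM with a Poisson data term summed over bins)
#' and gradient-ascent updates of `omega` with backtracking line search.
#' `omega` is canonicalized to unit Euclidean norm with nonnegative mean;
#' its scale and sign are absorbed into the matrix factor, leaving the
#' product `m * w * omega` unchanged.
#'
#' @param binned A binned dataset covering (a subset of) the dataset's
#'   standard presentations; `presentation_id` is used for alignment when
#'   present.
#' @param coarse_params Coarse-model [popgain_params] fitted on `dataset`
#'   (supplies `u`, `d`, `v`).
#' @param dataset The [popgain_dataset] the coarse model was fitted on.
#' @param K Modulation rank (default 2).
#' @param tau Ridge precision on the modulation matrix.
#' @param mask Optional [holdout_mask] at the presentation x unit level
#'   (all bins of a held-out entry are excluded from training).
#' @param max_outer,tol Outer-loop iteration cap and relative
#'   log-likelihood tolerance.
#' @param omega_steps Gradient steps per `omega` update.
#' @param admm_iter ADMM iterations per matrix update.
#' @return List of class `popgain_finetemporal`: `M_series`, `W`,
#'   `profile` (list `omega`, `psth`), `loglik_trace`, `converged`, and
#'   `presentation_id` of the fitted rows.
#' @export
fit_fine_temporal <- function(binned, coarse_params, dataset, K = 2,
                              tau = 1, mask = NULL, max_outer = 30,
                              tol = 1e-5, omega_steps = 20,
                              admm_iter = 60) {
  wb <- binned$window_bins
  if (length(wb) < 3) stop("analysis window must contain at least 3 bins")
  # align binned rows with dataset presentations
  rows_ds <- seq_len(nrow(dataset$counts))
  rows_b <- seq_len(dim(binned$counts)[1])
  if (!is.null(binned$presentation_id)) {
    idx <- match(binned$presentation_id, dataset$presentations$presentation_id)
    keep <- !is.na(idx)
    rows_b <- which(keep)
    rows_ds <- idx[keep]
  }
  tn <- length(rows_b)
  nu <- ncol(dataset$counts)
  b_n <- length(wb)
  y <- binned$counts[rows_b, wb, , drop = FALSE]          # T x B x N

  ci <- cue_indicator(dataset$presentations$cue_side,
                      dataset$units$hemisphere)[rows_ds, , drop = FALSE]
  off <- sweep(ci, 2, coarse_params$u, "*") +
    tcrossprod(coarse_params$d[rows_ds], coarse_params$v)  # C + D
  train <- if (is.null(mask)) matrix(TRUE, tn, nu) else
    !mask$test[rows_ds, , drop = FALSE]
  tw <- train * 1

  eoff <- exp(off)
  # per-bin rate profile: maximum-likelihood estimate given the frozen
  # cue/drift offset (a raw bin mean would count the cue gain twice)
  denom <- pmax(colSums(eoff * tw), 1e-12)                 # length N
  psth <- t(vapply(seq_len(b_n), function(b)
    colSums(y[, b, ] * tw) / denom, numeric(nu)))          # B x N (window)
  psth <- pmax(psth, 1e-4)
  a_list <- lapply(seq_len(b_n), function(b)
    sweep(eoff, 2, psth[b, ], "*") * tw)                   # A_b, zero on test
  y_list <- lapply(seq_len(b_n), function(b) y[, b, ] * tw)

  loglik <- function(x, omega) {
    ll <- 0
    for (b in seq_len(b_n)) {
      e <- omega[b] * x
      ll <- ll + sum(y_list[[b]] * e) - sum(a_list[[b]] * exp(e))
    }
    ll
  }

  omega <- rep(1 / sqrt(b_n), b_n)
  x <- matrix(0, tn, nu)
  z <- x; u_dual <- x
  # initial penalty matched to the Poisson curvature of the bin-summed data
  # term (sum_b omega_b^2 A_b), as in the coarse ADMM; small penalties let
  # the smooth copy drift from the low-rank manifold
  curv <- Reduce(`+`, Map(function(ab, ob) ob^2 * ab, a_list,
                          as.list(omega)))
  rho <- 10 * sum(curv) / max(sum(tw), 1)
  ll_prev <- -Inf; trace <- numeric(0); converged <- FALSE

  for (outer in seq_len(max_outer)) {
    # --- matrix update: ADMM with bin-summed Poisson data term ---
    s_wy <- Reduce(`+`, Map(function(yb, ob) yb * ob, y_list,
                            as.list(omega)))
    for (it in seq_len(admm_iter)) {
      for (nw in 1:3) {
        g1 <- matrix(0, tn, nu); g2 <- g1
        for (b in seq_len(b_n)) {
          e <- a_list[[b]] * exp(omega[b] * x)
          g1 <- g1 + omega[b] * e
          g2 <- g2 + omega[b]^2 * e
        }
        step <- (g1 - s_wy + tau * x + rho * (x - z + u_dual)) /
          (g2 + tau + rho)
        x <- x - pmin(pmax(step, -2), 2)
      }
      sv <- svd(x + u_dual, nu = K, nv = K)
      z_new <- sv$u %*% (t(sv$v) * sv$d[seq_len(K)])
      prim <- sqrt(sum((x - z_new)^2))
      dual <- rho * sqrt(sum((z_new - z)^2))
      z <- z_new
      u_dual <- u_dual + x - z
      scale_ref <- max(sqrt(sum(x^2)), sqrt(sum(z^2)), 1e-12)
      if (prim / scale_ref < 1e-4 && dual / scale_ref < 1e-4) break
      # one-sided balancing, as in the coarse ADMM: rho may only grow
      if (prim > 10 * dual) { rho <- rho * 2; u_dual <- u_dual / 2 }
    }
    x <- z   # use the exactly low-rank iterate

    # --- omega update: gradient ascent with backtracking ---
    ll_cur <- loglik(x, omega)
    for (gs in seq_len(omega_steps)) {
      grad <- vapply(seq_len(b_n), function(b)
        sum(x * (y_list[[b]] - a_list[[b]] * exp(omega[b] * x))),
        numeric(1))
      gn <- sqrt(sum(grad^2))
      if (gn < 1e-8) break
      step <- 0.5 / max(1, gn)
      repeat {
        cand <- omega + step * grad
        ll_new <- loglik(x, cand)
        if (ll_new >= ll_cur || step < 1e-10) break
        step <- step / 2
      }
      if (ll_new < ll_cur) break
      omega <- cand; ll_cur <- ll_new
    }
    # canonicalize omega each pass; scale/sign moves into the matrix factor
    s <- sqrt(sum(omega^2))
    if (s > 0) {
      sgn <- if (mean(omega) < 0) -1 else 1
      x <- x * (s * sgn); z <- x; u_dual <- u_dual * (s * sgn)
      omega <- omega / (s * sgn)
    }
    trace <- c(trace, ll_cur)
    if (is.finite(ll_prev) &&
        abs(ll_cur - ll_prev) <= tol * (abs(ll_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll_cur
  }
  if (!converged)
    warning("fine-temporal fit did not converge within ", max_outer,
            " outer iterations; returning best iterate")

  rp <- rank_project(z, K)
  res <- resolve_identifiability(rp$M_series, rp$W,
                                 hemisphere = dataset$units$hemisphere,
                                 mode = if (K == 2) "rank2_joint" else "none")
  structure(list(M_series = res$M_series, W = res$W,
                 profile = list(omega = omega, psth = psth),
                 loglik_trace = trace, converged = converged,
                 presentation_id =
                   dataset$presentations$presentation_id[rows_ds]),
            class = "popgain_finetemporal")
}

#' @export
print.popgain_finetemporal <- function(x, ...) {
  cat(sprintf("fine-temporal fit: rank %d, %d presentations, %d window bins\n",
              ncol(x$W), nrow(x$M_series), length(x$profile$omega)))
  cat("omega:", paste(sprintf("%.3f", x$profile$omega), collapse = " "), "\n")
  invisible(x)
}
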