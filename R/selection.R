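#' Entry-wise holdout mask
#'
#' Marks a random subset of the spike-count entries as a test set, drawn
#' independently across units and presentations (Bernoulli per entry), as
#' used for all cross-validated model comparisons.
#'
#' @param T_pres,N_units Matrix dimensions.
#' @param fraction Expected test fraction, in (0, 1); default 0.2.
#' @param seed Optional integer seed (local RNG state; does not disturb the
#'   caller's stream).
#' @return An object of class `holdout_mask`: list with logical matrix
#'   `test` and `fraction`.
#' @export
make_holdout_mask <- function(T_pres, N_units, fraction = 0.2, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  draw <- function() matrix(stats::runif(T_pres * N_units) < fraction,
                            T_pres, N_units)
  test <- if (is.null(seed)) draw() else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    draw()
  }
  structure(list(test = test, fraction = fraction), class = "holdout_mask")
}

#' @export
print.holdout_mask <- function(x, ...) {
  cat(sprintf("holdout_mask: %d x %d, %d test entries (%.1f%%)\n",
              nrow(x$test), ncol(x$test), sum(x$test), 100 * mean(x$test)))
  invisible(x)
}

#' Predictive log-likelihood on held-out entries
#'
#' Poisson log-likelihood of the model's rates on the test entries, in nats
#' per held-out observation. Model comparisons report this relative to the
#' stimulus-drive-only model.
#'
#' @param dataset A [popgain_dataset].
#' @param params A [popgain_params].
#' @param mask A [holdout_mask] with a non-empty test set.
#' @return Scalar nats per observation.
#' @export
predictive_ll <- function(dataset, params, mask) {
  n_test <- sum(mask$test)
  if (n_test == 0) stop("empty test set")
  ci <- cue_indicator(dataset$presentations$cue_side,
                      dataset$units$hemisphere)
  rates <- compute_rate(params, ci)
  poisson_loglik_masked(dataset$counts, rates, mask, "test") / n_test
}

#' Cross-validated comparison of nested models and modulator ranks
#'
#' Fits the stimulus-only, +cue, +cue+drift, and +K-modulator models on the
#' training entries and scores each by held-out predictive log-likelihood,
#' expressed relative to the stimulus-drive-only model. Returns the rank
#' with the best score.
#'
#' @param dataset A [popgain_dataset] (analysis view).
#' @param K_grid Integer vector of modulator counts to try (0 allowed and
#'   scored as the cue+drift model).
#' @param mask A [holdout_mask]; created at `fraction = 0.2` if `NULL`.
#' @param tau Prior precision or grid, passed to [coordinate_fit()].
#' @param hemisphere_constrained Also fit the hemisphere-constrained variant
#'   at each even K (reported with suffix `"hc"`)? Default `FALSE`.
#' @param seed Seed for mask creation when `mask` is `NULL`.
#' @param ... Further arguments to [coordinate_fit()].
#' @return List of class `popgain_model_comparison`: data frame `table`
#'   (`model`, `K`, `predictive_ll_per_obs`, `relative_ll`), `selected_K`,
#'   and `fits` (the fitted parameter objects, named by model label).
#' @export
select_rank <- function(dataset, K_grid = 1:4, mask = NULL, tau = 1,
                        hemisphere_constrained = FALSE, seed = NULL, ...) {
  if (is.null(mask))
    mask <- make_holdout_mask(nrow(dataset$counts), ncol(dataset$counts),
                              0.2, seed = seed)
  fits <- list(); rows <- list()
  add <- function(label, k, fit) {
    ll <- predictive_ll(dataset, fit, mask)
    fits[[label]] <<- fit
    rows[[label]] <<- data.frame(model = label, K = k,
                                 predictive_ll_per_obs = ll)
  }
  f_all <- fit_stimulus_drive(dataset$counts,
                              cue_indicator(dataset$presentations$cue_side,
                                            dataset$units$hemisphere),
                              mask, condition = "all")
  add("stimulus", NA, popgain_params(f = f_all))
  add("cue", NA, coordinate_fit(dataset, K = 0, mask = mask,
                                components = "cue", n_passes = 1, ...))
  base_fit <- coordinate_fit(dataset, K = 0, mask = mask,
                             components = c("cue", "drift"), n_passes = 1, ...)
  add("cue+drift", 0, base_fit)
  for (k in K_grid) {
    if (k == 0) next
    lab <- sprintf("modulators K=%d", k)
    fit_k <- tryCatch(
      coordinate_fit(dataset, K = k, mask = mask, tau = tau, ...),
      error = function(e) {
        warning("fit failed for K=", k, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit_k)) add(lab, k, fit_k)
    if (hemisphere_constrained && k %% 2 == 0) {
      fit_h <- coordinate_fit(dataset, K = k, mask = mask, tau = tau,
                              hemisphere_constrained = TRUE, ...)
      add(sprintf("modulators K=%d hc", k), k, fit_h)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$relative_ll <- tab$predictive_ll_per_obs -
    tab$predictive_ll_per_obs[tab$model == "stimulus"]
  kt <- tab[!is.na(tab$K), ]
  sel <- kt$K[which.max(kt$predictive_ll_per_obs)]
  structure(list(table = tab, selected_K = sel, fits = fits, mask = mask),
            class = "popgain_model_comparison")
}

#' @export
print.popgain_model_comparison <- function(x, ...) {
  cat("Cross-validated model comparison (nats/observation, relative to stimulus-only):\n")
  print(x$table[, c("model", "K", "relative_ll")], row.names = FALSE)
  cat("selected K:", x$selected_K, "\n")
  invisible(x)
}

#' Modulator-count recovery experiment
#'
#' Simulates populations under a known number of i.i.d. Gaussian modulators
#' (time courses and weights both standard normal, scaled by a global
#' factor calibrated to a target median noise correlation), fits modulator
#' models over a grid of ranks, and records the held-out predictive
#' log-likelihood of each. Recovery is declared when the best-scoring
#' fitted rank equals the simulated rank. The cue, drift, and stimulus
#' stages are fitted once per simulated dataset and shared across ranks.
#'
#' @param K_true_grid Ground-truth modulator counts to simulate.
#' @param K_fit_grid Ranks to fit, or `NULL` for `K_true + (-2:2)` per
#'   `K_true` (clipped at 1).
#' @param seeds Integer vector of simulation seeds.
#' @param n_units,n_presentations Population scale (defaults match one
#'   recording day).
#' @param target_median_corr Median pairwise noise correlation the gain
#'   scale is calibrated to.
#' @param tau Prior precision (or grid) for the modulator fits.
#' @param preset Base synthetic preset supplying stimulus drives, cue gains
#'   and drift (modulator settings are overridden).
#' @return Data frame with one row per (K_true, seed, K_fit):
#'   `K_true`, `seed`, `K_fit`, `predictive_ll_per_obs`, `recovered`
#'   (logical, constant within (K_true, seed)).
#' @export
modulator_recovery_experiment <- function(K_true_grid = c(1, 2, 4, 8),
                                          K_fit_grid = NULL, seeds = 1:5,
                                          n_units = 100,
                                          n_presentations = 3000,
                                          target_median_corr = 0.05,
                                          tau = 1, preset = "default") {
  rows <- list()
  for (k_true in K_true_grid) {
    kf <- if (is.null(K_fit_grid)) pmax(k_true + (-2:2), 1) else K_fit_grid
    kf <- sort(unique(kf))
    for (sd_i in seeds) {
      truth <- synthetic_truth(preset = preset, seed = sd_i,
                               n_units = n_units,
                               n_presentations = n_presentations,
                               K = k_true, modulator_style = "iid",
                               weight_dprime_coupling = 0,
                               variance_ratio = 1)
      truth <- match_noise_correlation_scale(truth, target_median_corr)
      bundle <- generate_dataset(truth)
      ds <- analysis_view(bundle$dataset)
      mask <- make_holdout_mask(nrow(ds$counts), ncol(ds$counts), 0.2,
                                seed = sd_i * 1000L + k_true)
      # shared preprocessing: stimulus drive, cue couplings, drift
      ci <- cue_indicator(ds$presentations$cue_side, ds$units$hemisphere)
      f <- fit_stimulus_drive(ds$counts, ci, mask)
      u <- fit_cue_couplings(ds$counts, ci, f, mask)
      base <- sweep(sweep(ci, 2, u, "*"), 2, log(f), "+")
      dr <- fit_drift_em(ds$counts, base, ds$presentations$timestamp_s,
                         mask = mask)
      off <- base + tcrossprod(dr$d, dr$v)
      ws_rank <- NULL   # warm start carried across the (sorted) rank grid
      lls <- vapply(kf, function(k) {
        best <- -Inf; ws <- ws_rank
        for (tv in sort(tau, decreasing = TRUE)) {
          fit <- fit_modulators_admm(ds$counts, off, k, tv, mask = mask,
                                     warm_start = ws)
          ws <- fit$state[c("X", "Z", "U", "rho")]
          ws_rank <<- ws
          ll <- poisson_loglik_masked(
            ds$counts, exp(off + tcrossprod(fit$M_series, fit$W)),
            mask, "test") / sum(mask$test)
          best <- max(best, ll)
        }
        best
      }, numeric(1))
      rec <- kf[which.max(lls)] == k_true
      rows[[length(rows) + 1]] <- data.frame(
        K_true = k_true, seed = sd_i, K_fit = kf,
        predictive_ll_per_obs = lls, recovered = rec)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
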