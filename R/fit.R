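#' Simulate one FCD sample from a model
#'
#' Runs the full forward chain — DMF simulation, Balloon-Windkessel
#' haemodynamics, band-pass filtering, sliding-window FCD — and returns
#' the FCD value sample, matching the empirical scan length in TRs.
#'
#' @param model a tuned `dmf_model`.
#' @param n_trs number of TRs to emit (scan length).
#' @param TR repetition time (s).
#' @param seed integer seed.
#' @param burn_in_s discarded model seconds.
#' @param dt integration step (ms).
#' @param window,step FCD window length and increment (TRs).
#' @param low,high band-pass edges (Hz).
#' @return an `fcd_sample`.
#' @export
simulate_fcd_sample <- function(model, n_trs, TR = 2, seed = 1,
                                burn_in_s = 10, dt = 0.1,
                                window = 30, step = 3,
                                low = 0.008, high = 0.09) {
  tr <- simulate_dmf(model, duration_s = n_trs * TR,
                     burn_in_s = burn_in_s, dt = dt, seed = seed)
  b <- balloon_windkessel(tr, TR = TR)
  b <- bandpass_bold(b, low = low, high = high)
  fcd_sample(fcd_matrix(b, window = window, step = step))
}

new_sweep_result <- function(grid, ks, j_fic = NULL, config = list()) {
  mean_ks <- rowMeans(ks, na.rm = TRUE)
  sd_ks <- apply(ks, 1, sd, na.rm = TRUE)
  n_ok <- rowSums(!is.na(ks))
  eligible <- n_ok >= 0.8 * ncol(ks)
  if (!any(eligible)) stop("no grid value with enough surviving simulations")
  cand <- mean_ks
  cand[!eligible] <- Inf
  argmin <- grid[which.min(cand)]  # which.min takes the first (smallest) tie
  structure(list(grid = grid, ks_per_sim = ks, mean_ks = mean_ks,
                 sd_ks = sd_ks, n_ok = n_ok, eligible = eligible,
                 argmin = argmin, j_fic = j_fic, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", length(x$grid), "grid values x",
      ncol(x$ks_per_sim), "sims; argmin =", x$argmin,
      "(mean KS", format(min(x$mean_ks[x$eligible]), digits = 3), ")\n")
  invisible(x)
}

#' Global coupling (G) calibration sweep
#'
#' For every value of G on the grid: rebuilds the model, re-tunes
#' feedback inhibition, runs `n_sims` seeded simulations matching the
#' empirical scan length, and scores each against the empirical FCD
#' sample with the KS distance.  The calibrated G is the grid value
#' minimising the mean KS distance (ties to the smallest G; a grid value
#' needs >= 80% surviving simulations to be eligible).
#'
#' @param connectome a `connectome`.
#' @param empirical an `fcd_sample` (pooled group-wise empirical FCD).
#' @param grid G values (default 0.1 to 2.5 in steps of 0.1).
#' @param n_sims simulations per grid value.
#' @param n_trs scan length to match (TRs).
#' @param TR repetition time (s).
#' @param gain per-region inhibitory gain (default all 1).
#' @param params `dmf_params`.
#' @param seed master seed; per-G and per-simulation streams derive
#'   from it.
#' @param sc_max connectome rescaling convention (see [dmf_model()]).
#' @param ... forwarded to [simulate_fcd_sample()] (e.g. `dt`, `window`).
#' @param tune_args named list of overrides for [tune_fic()].
#' @return a `sweep_result`; element `j_fic` holds the tuned weights per
#'   grid value so the calibrated model can be rebuilt without re-tuning.
#' @export
sweep_g <- function(connectome, empirical, grid = seq(0.1, 2.5, by = 0.1),
                    n_sims = 10, n_trs = 250, TR = 2, gain = NULL,
                    params = dmf_parameters(), seed = 1, sc_max = 0.2,
                    tune_args = list(), ...) {
  stopifnot(length(grid) > 0, length(empirical$values %||% empirical) > 0)
  seeds <- matrix(derive_seeds(seed, length(grid) * (n_sims + 1)),
                  nrow = length(grid))
  ks <- matrix(NA_real_, length(grid), n_sims)
  j_fic <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    model <- dmf_model(connectome, G = grid[gi], params = params,
                       gain = gain, sc_max = sc_max)
    model <- tryCatch(
      do.call(tune_fic, c(list(model, seed = seeds[gi, 1]), tune_args)),
      error = function(e) NULL)
    if (is.null(model)) next
    j_fic[[gi]] <- model$J_fic
    for (k in seq_len(n_sims)) {
      ks[gi, k] <- tryCatch(
        ks_distance(simulate_fcd_sample(model, n_trs = n_trs, TR = TR,
                                        seed = seeds[gi, k + 1], ...),
                    empirical),
        error = function(e) NA_real_)
    }
    if (all(is.na(ks[gi, ]))) {
      stop("all simulations failed at G = ", grid[gi])
    }
  }
  new_sweep_result(grid, ks, j_fic,
                   config = list(parameter = "G", n_sims = n_sims,
                                 n_trs = n_trs, TR = TR, seed = seed))
}

#' Inhibitory gain scaling (s_I) sweep
#'
#' Holds the calibrated model fixed (G and tuned feedback inhibition)
#' and sweeps the inhibitory gain scaling s_I, applying the regional
#' gain `1 + s_I * d_n` from the receptor map at each grid value and
#' scoring simulated against empirical FCD with the KS distance.
#'
#' @param model a calibrated (FIC-tuned) `dmf_model`.
#' @param map a `receptor_map` (empirical, shuffled or uniform variant).
#' @param empirical an `fcd_sample`.
#' @param grid s_I values (default 0 to 1 in steps of 0.02).
#' @param n_sims simulations per grid value (default 10).
#' @inheritParams sweep_g
#' @return a `sweep_result`.
#' @export
sweep_si <- function(model, map, empirical, grid = seq(0, 1, by = 0.02),
                     n_sims = 10, n_trs = 250, TR = 2, seed = 1, ...) {
  stopifnot(inherits(model, "dmf_model"), !is.null(model$J_fic))
  seeds <- matrix(derive_seeds(seed, length(grid) * n_sims),
                  nrow = length(grid))
  ks <- matrix(NA_real_, length(grid), n_sims)
  for (gi in seq_along(grid)) {
    m <- model
    m$gain <- gain_vector(map, grid[gi])
    for (k in seq_len(n_sims)) {
      ks[gi, k] <- tryCatch(
        ks_distance(simulate_fcd_sample(m, n_trs = n_trs, TR = TR,
                                        seed = seeds[gi, k], ...),
                    empirical),
        error = function(e) NA_real_)
    }
    if (all(is.na(ks[gi, ]))) {
      stop("all simulations failed at s_I = ", grid[gi])
    }
  }
  new_sweep_result(grid, ks,
                   config = list(parameter = "s_I", n_sims = n_sims,
                                 n_trs = n_trs, TR = TR, seed = seed))
}

#' Compare a model's fit to two empirical conditions
#'
#' Generates `n_sims` simulations from the model and computes each
#' simulation's KS distance to two empirical FCD samples (conditions A
#' and B).  Reports the per-simulation difference `delta = ks_A - ks_B`
#' (negative when the model fits condition A better), a
#' permutation-based two-sample t-test between the two KS distributions,
#' and Cohen's d / Hedges' g effect sizes.
#'
#' @param model a calibrated `dmf_model`.
#' @param empirical_A,empirical_B `fcd_sample` objects.
#' @param n_sims simulations (default 100).
#' @param n_perm permutations for the t-test.
#' @inheritParams sweep_g
#' @return object of class `comparison_result` with elements `ks_A`,
#'   `ks_B`, `delta`, `t_stat`, `p_perm`, `cohens_d`, `hedges_g`,
#'   `n_failed`.
#' @export
evaluate_model <- function(model, empirical_A, empirical_B, n_sims = 100,
                           n_trs = 250, TR = 2, seed = 1,
                           n_perm = 10000, ...) {
  stopifnot(length(empirical_A$values) > 0, length(empirical_B$values) > 0)
  seeds <- derive_seeds(seed, n_sims + 1)
  ks_A <- ks_B <- rep(NA_real_, n_sims)
  for (k in seq_len(n_sims)) {
    s <- tryCatch(
      simulate_fcd_sample(model, n_trs = n_trs, TR = TR,
                          seed = seeds[k], ...),
      error = function(e) NULL)
    if (is.null(s)) next
    ks_A[k] <- ks_distance(s, empirical_A)
    ks_B[k] <- ks_distance(s, empirical_B)
  }
  ok <- !is.na(ks_A)
  if (sum(ok) < 2) stop("fewer than 2 surviving simulations")
  tt <- permutation_ttest(ks_A[ok], ks_B[ok], n_perm = n_perm,
                          seed = seeds[n_sims + 1])
  es <- effect_sizes(mean(ks_A[ok]), sd(ks_A[ok]), sum(ok),
                     mean(ks_B[ok]), sd(ks_B[ok]), sum(ok))
  structure(list(ks_A = ks_A[ok], ks_B = ks_B[ok],
                 delta = ks_A[ok] - ks_B[ok],
                 t_stat = tt$t, p_perm = tt$p,
                 cohens_d = es$cohens_d, hedges_g = es$hedges_g,
                 n_failed = sum(!ok)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison_result:", length(x$delta), "sims, mean delta =",
      format(mean(x$delta), digits = 3), ", t =",
      format(x$t_stat, digits = 3), ", perm p =",
      format(x$p_perm, digits = 3), "\n")
  invisible(x)
}

#' Connectome-replacement experiment
#'
#' Swaps the structural connectome of a calibrated model for a perturbed
#' one (patient consensus, weight-preserving random null, or lattice
#' null) while holding the calibrated G, tuned feedback inhibition and
#' gain fixed, then re-evaluates the model's fit to two empirical
#' conditions.
#'
#' @param model a calibrated `dmf_model`.
#' @param new_connectome a `connectome` over the same region set.
#' @inheritParams evaluate_model
#' @return a `comparison_result`.
#' @export
connectome_replacement <- function(model, new_connectome, empirical_A,
                                   empirical_B, n_sims = 100, n_trs = 250,
                                   TR = 2, seed = 1, ...) {
  evaluate_model(swap_connectome(model, new_connectome),
                 empirical_A, empirical_B, n_sims = n_sims,
                 n_trs = n_trs, TR = TR, seed = seed, ...)
}

#' Permutation-based two-sample t-test
#'
#' Pooled-variance two-sample t statistic with a permutation null: group
#' labels are shuffled `n_perm` times and the two-sided p-value is
#' `(1 + #(|t_perm| >= |t_obs|)) / (1 + n_perm)` (add-one estimator,
#' never exactly zero).
#'
#' @param x,y numeric vectors (>= 2 each).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list with `t` and `p`.
#' @export
permutation_ttest <- function(x, y, n_perm = 10000, seed = 1) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("both groups need at least 2 observations")
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    if (sp2 == 0) stop("zero pooled variance")
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  t_obs <- pooled_t(x, y)
  z <- c(x, y)
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(nx + ny, nx)
      pooled_t(z[idx], z[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm)
  list(t = t_obs, p = p)
}

#' Effect sizes from group summary statistics
#'
#' Pooled-SD two-sample t statistic, Cohen's d (standardised difference
#' of means) and the small-sample-corrected Hedges' g
#' `g = d (1 - 3 / (4 (n1 + n2 - 2) - 1))`.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `cohens_d`, `hedges_g`.
#' @examples
#' # age comparison from two group summaries
#' es <- effect_sizes(35.75, 11.42, 20, 38.24, 15.96, 21)
#' round(c(es$t, es$hedges_g), 2)
#' @export
effect_sizes <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  d <- (m1 - m2) / sp
  g <- d * (1 - 3 / (4 * df - 1))
  list(t = t, df = df, cohens_d = d, hedges_g = g)
}
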