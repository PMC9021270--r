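#' Dynamic mean field model parameters
#'
#' Returns the fixed biophysical constants of the two-population
#' (excitatory NMDA / inhibitory GABA-A) dynamic mean field model.
#' Defaults are the standard parameterisation of the reduced Wong-Wang
#' model with feedback inhibition control.  Units: currents nA, gains
#' nC^-1, curve shapes s, time constants ms, noise nA.
#'
#' @param ... named overrides of any constant.
#' @return a named list of class `dmf_params` with elements `I0`, `W_E`,
#'   `W_I`, `w_plus`, `J_NMDA`, `g_E`, `g_I`, `I_thr_E`, `I_thr_I`,
#'   `d_E`, `d_I`, `gamma`, `sigma`, `tau_NMDA`, `tau_GABA`.
#' @export
dmf_parameters <- function(...) {
  p <- list(
    I0      = 0.382,  # external current (nA)
    W_E     = 1,      # excitatory scaling of I0
    W_I     = 0.7,    # inhibitory scaling of I0
    w_plus  = 1.4,    # local excitatory recurrence
    J_NMDA  = 0.15,   # excitatory synaptic coupling (nA)
    g_E     = 310,    # excitatory gain (nC^-1)
    g_I     = 615,    # inhibitory gain (nC^-1)
    I_thr_E = 0.403,  # excitatory threshold (nA)
    I_thr_I = 0.288,  # inhibitory threshold (nA)
    d_E     = 0.16,   # excitatory curve shape (s)
    d_I     = 0.087,  # inhibitory curve shape (s)
    gamma   = 0.641,  # excitatory kinetic parameter
    sigma   = 0.01,   # noise amplitude (nA)
    tau_NMDA = 100,   # NMDA time constant (ms)
    tau_GABA = 10     # GABA-A time constant (ms)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(over)] <- over
  stopifnot(p$tau_NMDA > 0, p$tau_GABA > 0, p$sigma >= 0)
  structure(p, class = "dmf_params")
}

#' Regional neuromodulatory gain vector
#'
#' Computes the multiplicative inhibitory gain `1 + s_I * d_n` from a
#' normalised receptor-density map: regions dense in the receptor get a
#' proportionally larger inhibitory gain.  `s_I = 0` recovers the
#' unmodulated model (all gains 1).
#'
#' @param map a `receptor_map`, or a numeric vector of normalised
#'   densities in \[0, 1\].
#' @param s_I inhibitory gain scaling, >= 0.
#' @return numeric vector of per-region gains (>= 1).
#' @export
gain_vector <- function(map, s_I) {
  d <- if (inherits(map, "receptor_map")) map$normalised else as.numeric(map)
  if (s_I < 0) stop("s_I must be non-negative")
  1 + s_I * d
}

#' Population transfer function (F-I curve)
#'
#' The sigmoidal rate function `F(I) = m g (I - I_thr) /
#' (1 - exp(-d m g (I - I_thr)))` mapping input current to firing rate.
#' At the removable singularity `I = I_thr` the analytic (L'Hopital)
#' limit `1/d` is returned.
#'
#' @param I input current (nA); vectorised.
#' @param gain_factor gain g (nC^-1).
#' @param threshold threshold current I_thr (nA).
#' @param shape curve-shape constant d (s).
#' @param modulator multiplicative gain modulator m (1 for excitatory
#'   populations; the regional neuromodulatory gain for inhibitory ones).
#' @return firing rate (Hz), same length as `I`.
#' @examples
#' transfer_rate(0.382, 310, 0.403, 0.16)  # 3.55 Hz at the external drive
#' transfer_rate(0.403, 310, 0.403, 0.16)  # 6.25 Hz, the limit at threshold
#' @export
transfer_rate <- function(I, gain_factor, threshold, shape, modulator = 1) {
  if (any(!is.finite(I))) stop("non-finite input current")
  stopifnot(shape > 0, gain_factor > 0, all(modulator > 0))
  x <- modulator * gain_factor * (I - threshold)
  y <- shape * x
  out <- ifelse(abs(y) < 1e-6,
                (1 / shape) / (1 - 0.5 * y + y^2 / 6),
                x / (1 - exp(-y)))
  as.numeric(out)
}

#' Build a whole-brain DMF model
#'
#' Binds a connectome, the biophysical constants, the global coupling G,
#' a regional inhibitory gain vector and (optionally) tuned feedback
#' inhibition weights into one simulation-ready object.  Connectome
#' weights are rescaled so their maximum equals `sc_max` (default 0.2, a
#' common convention that fixes the otherwise arbitrary tract-strength
#' units; G absorbs the scale).
#'
#' @param connectome a `connectome`.
#' @param G global coupling (dimensionless).
#' @param params a `dmf_params` list.
#' @param gain per-region inhibitory gain vector (default all 1); see
#'   [gain_vector()].
#' @param J_fic per-region feedback inhibition weights (nA); `NULL`
#'   until tuned with [tune_fic()], in which case simulation uses 1 nA
#'   everywhere.
#' @param sc_max connectome rescaling target for the maximum weight.
#' @return object of class `dmf_model`.
#' @export
dmf_model <- function(connectome, G, params = dmf_parameters(),
                      gain = NULL, J_fic = NULL, sc_max = 0.2) {
  stopifnot(inherits(connectome, "connectome"), G >= 0, sc_max > 0)
  n <- length(connectome$labels)
  W <- connectome$weights
  mx <- max(W)
  C <- if (mx > 0) W * (sc_max / mx) else W
  gain <- gain %||% rep(1, n)
  if (length(gain) != n) stop("gain must have one entry per region")
  if (any(gain <= 0)) stop("gains must be positive")
  if (!is.null(J_fic)) {
    if (length(J_fic) != n) stop("J_fic must have one entry per region")
    if (any(J_fic < 0)) stop("J_fic must be non-negative")
  }
  structure(list(C = C, labels = connectome$labels,
                 coordinates = connectome$coordinates,
                 G = G, params = params, gain = as.numeric(gain),
                 J_fic = J_fic, sc_max = sc_max, sc_scale_raw_max = mx),
            class = "dmf_model")
}

#' @export
print.dmf_model <- function(x, ...) {
  cat("dmf_model:", length(x$labels), "regions, G =", x$G,
      if (is.null(x$J_fic)) "(FIC untuned)" else "(FIC tuned)", "\n")
  invisible(x)
}

model_J <- function(model) model$J_fic %||% rep(1, length(model$labels))

#' Replace the connectome of a model, keeping everything else fixed
#'
#' Used by connectome-replacement experiments: the calibrated G, tuned
#' feedback inhibition weights and gain vector are retained while the
#' structural coupling matrix is swapped for a perturbed one with the
#' same region set (rescaled with the same `sc_max` convention).
#'
#' @param model a `dmf_model`.
#' @param connectome a `connectome` with identical labels.
#' @return a `dmf_model`.
#' @export
swap_connectome <- function(model, connectome) {
  stopifnot(inherits(model, "dmf_model"), inherits(connectome, "connectome"))
  if (!identical(connectome$labels, model$labels)) {
    stop("replacement connectome has a different region set")
  }
  dmf_model(connectome, G = model$G, params = model$params,
            gain = model$gain, J_fic = model$J_fic, sc_max = model$sc_max)
}

#' Regional input currents
#'
#' Evaluates the excitatory and inhibitory input currents of every
#' region given the synaptic gating state: external drive, local
#' recurrence, global coupling through the (scaled) connectome, and
#' feedback inhibition.
#'
#' @param model a `dmf_model`.
#' @param S_E,S_I synaptic gating vectors in \[0, 1\].
#' @return list with numeric vectors `I_E` and `I_I` (nA).
#' @export
dmf_currents <- function(model, S_E, S_I) {
  n <- length(model$labels)
  if (length(S_E) != n || length(S_I) != n) {
    stop("state dimension does not match the model's ", n, " regions")
  }
  p <- model$params
  J <- model_J(model)
  net <- as.numeric(model$C %*% S_E)
  I_E <- p$W_E * p$I0 + p$w_plus * p$J_NMDA * S_E +
    model$G * p$J_NMDA * net - J * S_I
  I_I <- p$W_I * p$I0 + p$J_NMDA * S_E - S_I
  list(I_E = I_E, I_I = I_I)
}

#' Single Euler-Maruyama step of the DMF equations
#'
#' Reference (pure R) implementation of one integration step: rates from
#' the transfer functions, saturating NMDA gating drift, linear GABA
#' gating drift, additive noise, and clipping of the gating variables to
#' \[0, 1\].  The compiled integrator used by [simulate_dmf()] performs
#' exactly this update; this function exists for inspection and testing.
#'
#' @param model a `dmf_model`.
#' @param state list with elements `S_E` and `S_I`.
#' @param dt step (ms).
#' @param noise optional vector of `2n` standard normal draws (first n
#'   excitatory, last n inhibitory); zeros when omitted.
#' @return list with `S_E`, `S_I`, and the step's `r_E`, `r_I` (Hz),
#'   `I_E`, `I_I` (nA).
#' @export
dmf_step <- function(model, state, dt = 0.1, noise = NULL) {
  stopifnot(dt > 0)
  p <- model$params
  n <- length(model$labels)
  S_E <- state$S_E
  S_I <- state$S_I
  noise <- noise %||% numeric(2 * n)
  if (length(noise) != 2 * n) stop("need 2n noise draws")
  cur <- dmf_currents(model, S_E, S_I)
  if (any(!is.finite(cur$I_E)) || any(!is.finite(cur$I_I))) {
    stop("integration blow-up: non-finite currents")
  }
  r_E <- transfer_rate(cur$I_E, p$g_E, p$I_thr_E, p$d_E)
  r_I <- transfer_rate(cur$I_I, p$g_I, p$I_thr_I, p$d_I,
                       modulator = model$gain)
  dSE <- -S_E / p$tau_NMDA + (1 - S_E) * p$gamma * r_E / 1000
  dSI <- -S_I / p$tau_GABA + r_I / 1000
  S_E <- S_E + dt * dSE + p$sigma * sqrt(dt) * noise[seq_len(n)]
  S_I <- S_I + dt * dSI + p$sigma * sqrt(dt) * noise[n + seq_len(n)]
  list(S_E = pmin(1, pmax(0, S_E)), S_I = pmin(1, pmax(0, S_I)),
       r_E = r_E, r_I = r_I, I_E = cur$I_E, I_I = cur$I_I)
}

# Low-level wrapper around the compiled integrator.
dmf_run <- function(model, duration_ms, burn_ms, dt, seed, record_ms = 1,
                    init = NULL, return_trace = TRUE) {
  n <- length(model$labels)
  s_e0 <- init$S_E %||% rep(0.001, n)
  s_i0 <- init$S_I %||% rep(0.001, n)
  res <- dmf_integrate_cpp(model$C, model$G, model_J(model), model$gain,
                           unclass(model$params), dt, duration_ms, burn_ms,
                           record_ms, as.integer(seed), s_e0, s_i0,
                           return_trace)
  if (!isTRUE(res$ok)) {
    stop("integration blow-up at step ", res$step %||% NA)
  }
  res
}

#' Tune feedback inhibition control (FIC)
#'
#' Iteratively adjusts each region's feedback inhibitory weight so that
#' its long-run average excitatory firing rate sits at the target
#' (default 3 Hz).  Each round simulates `round_duration_s` of model
#' time continuing from the previous round's state and applies the
#' proportional update `J <- J + eta * (<r_E> - target) / target`,
#' floored at zero, until every region is within `tol` of the target.
#'
#' @param model a `dmf_model`.
#' @param target_rate target excitatory rate (Hz).
#' @param tol convergence tolerance (Hz) on every region's mean rate.
#' @param eta learning rate (nA per unit relative rate error).
#' @param max_rounds maximum tuning rounds.
#' @param round_duration_s simulated seconds per round.
#' @param dt integration step (ms).
#' @param seed integer seed.
#' @return the model with tuned `J_fic` and a `tuning` element holding
#'   diagnostics (rounds used, final per-region rates, rate history).
#' @export
tune_fic <- function(model, target_rate = 3, tol = 0.5, eta = 0.01,
                     max_rounds = 200, round_duration_s = 10, dt = 0.1,
                     seed = 1) {
  stopifnot(inherits(model, "dmf_model"))
  n <- length(model$labels)
  J <- model_J(model)
  seeds <- derive_seeds(seed, max_rounds + 1)
  m <- model
  init <- NULL
  rates <- NULL
  history <- numeric(0)
  converged <- FALSE
  rounds <- 0
  for (k in seq_len(max_rounds)) {
    rounds <- k
    m$J_fic <- J
    # first round: settle 1 s before measuring; later rounds continue
    burn <- if (k == 1) 1000 else 0
    res <- dmf_run(m, duration_ms = round_duration_s * 1000 + burn,
                   burn_ms = burn, dt = dt, seed = seeds[k],
                   record_ms = 1, init = init, return_trace = FALSE)
    init <- list(S_E = res$s_e, S_I = res$s_i)
    rates <- res$r_mean
    history <- c(history, mean(rates))
    if (max(abs(rates - target_rate)) <= tol) {
      converged <- TRUE
      break
    }
    J <- pmax(0, J + eta * (rates - target_rate) / target_rate)
  }
  if (!converged) {
    worst <- which.max(abs(rates - target_rate))
    stop("FIC tuning did not converge in ", max_rounds,
         " rounds; worst region ", model$labels[worst], " at ",
         format(rates[worst], digits = 4), " Hz")
  }
  m$J_fic <- J
  m$tuning <- list(rounds = rounds, rates = rates,
                   mean_rate_history = history,
                   target_rate = target_rate, tol = tol, eta = eta,
                   seed = seed)
  m
}

#' Simulate the DMF model
#'
#' Integrates the coupled stochastic equations with the Euler-Maruyama
#' scheme and returns the excitatory firing-rate trace after discarding
#' a burn-in, bin-averaged to `record_ms` resolution (default 1 ms, the
#' resolution consumed by the haemodynamic model).
#'
#' @param model a `dmf_model` (FIC-tuned for realistic regimes).
#' @param duration_s simulated seconds *after* burn-in.
#' @param burn_in_s discarded initial seconds (default 10).
#' @param dt integration step (ms, default 0.1).
#' @param record_ms output resolution (ms).
#' @param seed integer seed; trajectories are bitwise reproducible.
#' @return object of class `neural_trace`: matrix regions x time of
#'   excitatory rates (Hz) with attributes `dt_ms` (= `record_ms`),
#'   `labels`, `seed`.
#' @export
simulate_dmf <- function(model, duration_s, burn_in_s = 10, dt = 0.1,
                         record_ms = 1, seed = 1) {
  stopifnot(duration_s > 0)
  res <- dmf_run(model, duration_ms = (duration_s + burn_in_s) * 1000,
                 burn_ms = burn_in_s * 1000, dt = dt, seed = seed,
                 record_ms = record_ms, return_trace = TRUE)
  trace <- res$trace
  rownames(trace) <- model$labels
  structure(trace, class = c("neural_trace", "matrix"),
            dt_ms = record_ms, labels = model$labels, seed = seed,
            r_mean = res$r_mean)
}

#' Mean excitatory firing rate of a simulated trace
#'
#' @param trace a `neural_trace`.
#' @param per_region return the per-region time averages instead of the
#'   grand mean.
#' @return mean rate(s) in Hz.
#' @export
mean_rate <- function(trace, per_region = FALSE) {
  r <- attr(trace, "r_mean") %||% rowMeans(trace)
  if (per_region) r else mean(r)
}
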