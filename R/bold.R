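#' Balloon-Windkessel haemodynamic constants
#'
#' Canonical parameterisation of the single-compartment
#' Balloon-Windkessel model: signal decay `kappa` (s^-1), flow-dependent
#' elimination `gamma_h` (s^-1), haemodynamic transit time `tau_h` (s),
#' Grubb exponent `alpha`, resting oxygen extraction `rho`, resting
#' venous volume fraction `V0`, and the BOLD weights `k1 = 7 rho`,
#' `k2 = 2`, `k3 = 2 rho - 0.2`.
#'
#' @param ... named overrides.
#' @return named list of class `bw_params`.
#' @export
bw_parameters <- function(...) {
  p <- list(kappa = 0.65, gamma_h = 0.41, tau_h = 0.98, alpha = 0.32,
            rho = 0.34, V0 = 0.02, k1 = 7 * 0.34, k2 = 2,
            k3 = 2 * 0.34 - 0.2)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(over)] <- over
  structure(p, class = "bw_params")
}

#' BOLD time-series container
#'
#' @param signal region-by-TR numeric matrix (arbitrary units).
#' @param TR repetition time (s).
#' @param labels region identifiers (default from rownames).
#' @return object of class `bold_ts`.
#' @export
bold_ts <- function(signal, TR, labels = NULL) {
  signal <- as.matrix(signal)
  if (TR <= 0) stop("TR must be positive")
  if (ncol(signal) < 2) stop("BOLD series needs at least 2 TRs")
  if (any(!is.finite(signal))) stop("non-finite BOLD signal")
  labels <- labels %||% rownames(signal) %||%
    paste0("R", seq_len(nrow(signal)))
  rownames(signal) <- labels
  structure(signal, class = c("bold_ts", "matrix"), TR = TR,
            labels = labels)
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("bold_ts:", nrow(x), "regions x", ncol(x), "TRs, TR =",
      attr(x, "TR"), "s\n")
  invisible(x)
}

#' Balloon-Windkessel forward model
#'
#' Converts an excitatory firing-rate trace into simulated BOLD.  The
#' neural drive of each region is its rate normalised to its own
#' baseline, `z = r / <r> - 1`, so a model resting at its tuned firing
#' rate sits at the haemodynamic fixed point (s, f, v, q) = (0, 1, 1, 1)
#' and produces zero BOLD.  The four state equations are
#' Euler-integrated at the trace resolution and the nonlinear BOLD
#' readout `V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` is sampled once
#' per TR.
#'
#' @param trace a `neural_trace` (regions x time, Hz), or a plain matrix
#'   with a `dt_ms` attribute.
#' @param TR repetition time (s) of the output series.
#' @param hrf_params a `bw_params` list.
#' @param baseline per-region baseline rate used for drive
#'   normalisation; defaults to each region's own time average.
#' @return a `bold_ts` (regions x TRs).
#' @export
balloon_windkessel <- function(trace, TR = 2, hrf_params = bw_parameters(),
                               baseline = NULL) {
  dt_ms <- attr(trace, "dt_ms") %||% 1
  z <- unclass(trace)
  baseline <- baseline %||% rowMeans(z)
  if (any(baseline <= 0)) {
    stop("baseline rate must be positive in every region")
  }
  z <- sweep(z, 1, baseline, "/") - 1
  dt_s <- dt_ms / 1000
  tr_steps <- round(TR / dt_s)
  if (tr_steps < 1 || ncol(z) < tr_steps) {
    stop("trace shorter than one TR")
  }
  h <- hrf_params
  res <- bw_integrate_cpp(z, dt_s, as.integer(tr_steps), h$kappa,
                          h$gamma_h, h$tau_h, h$alpha, h$rho, h$V0,
                          h$k1, h$k2, h$k3)
  if (!isTRUE(res$ok)) {
    stop("haemodynamic blow-up in region ", res$region,
         " at step ", res$step)
  }
  bold_ts(res$bold, TR = TR,
          labels = attr(trace, "labels") %||% rownames(trace))
}

#' Band-pass filter a BOLD series
#'
#' Zero-phase (forward-backward) order-2 Butterworth band-pass in the
#' standard resting-state band, applied per region after demeaning; any
#' residual DC is removed so filtered signals have negligible mean.
#'
#' @param b a `bold_ts`.
#' @param low,high band edges (Hz); defaults 0.008 and 0.09.
#' @return a `bold_ts` of filtered signals.
#' @export
bandpass_bold <- function(b, low = 0.008, high = 0.09) {
  TR <- attr(b, "TR")
  fs <- 1 / TR
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("infeasible band [", low, ", ", high, "] Hz for TR = ", TR,
         " s (Nyquist ", nyq, " Hz)")
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  x <- unclass(b)
  out <- t(apply(x, 1, function(row) {
    row <- row - mean(row)
    f <- signal::filtfilt(bf, row)
    f - mean(f)
  }))
  bold_ts(out, TR = TR, labels = attr(b, "labels"))
}
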