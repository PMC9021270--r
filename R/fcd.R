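#' Functional connectivity dynamics (FCD) matrix
#'
#' Computes sliding-window functional connectivity (Pearson correlation
#' between regional BOLD time series within each window) and correlates
#' the vectorised upper triangles of every pair of window FC matrices,
#' giving a window-by-window matrix of time-versus-time FC similarity.
#'
#' @param b a `bold_ts` (regions x TRs), typically band-pass filtered.
#' @param window window length in TRs (default 30).
#' @param step window increment in TRs (default 3).
#' @return object of class `fcd_matrix`: the window x window correlation
#'   matrix with attributes `window_starts` (first TR index of each
#'   window), `window` and `step`.
#' @export
fcd_matrix <- function(b, window = 30, step = 3) {
  x <- unclass(b)
  n <- nrow(x)
  T <- ncol(x)
  if (n < 3) stop("FCD needs at least 3 regions")
  if (T < window) stop("series (", T, " TRs) shorter than window (",
                       window, " TRs)")
  n_win <- floor((T - window) / step) + 1
  starts <- 1 + (seq_len(n_win) - 1) * step
  ut <- upper.tri(diag(n))
  P <- matrix(NA_real_, sum(ut), n_win)
  for (k in seq_len(n_win)) {
    seg <- x[, starts[k]:(starts[k] + window - 1), drop = FALSE]
    sds <- apply(seg, 1, sd)
    if (any(sds == 0)) {
      stop("zero-variance region ", which(sds == 0)[1],
           " in window ", k)
    }
    fc <- cor(t(seg))
    P[, k] <- fc[ut]
  }
  vals <- cor(P)
  structure(vals, class = c("fcd_matrix", "matrix"),
            window_starts = starts, window = window, step = step)
}

#' @export
print.fcd_matrix <- function(x, ...) {
  cat("fcd_matrix:", nrow(x), "windows (window",
      attr(x, "window"), "TRs, step", attr(x, "step"), "TRs)\n")
  invisible(x)
}

#' Extract the FCD value sample (upper triangle)
#'
#' Collects the upper-triangular FCD entries together with their window
#' lags `|i - j|`, the sample whose distribution is compared across
#' conditions.  Optionally excludes pairs of overlapping windows
#' (lag < window/step).
#'
#' @param f an `fcd_matrix`.
#' @param exclude_overlap drop window pairs that share TRs (default
#'   FALSE: all upper-triangle entries enter the sample).
#' @return object of class `fcd_sample`: list with `values` and `lags`.
#' @export
fcd_sample <- function(f, exclude_overlap = FALSE) {
  stopifnot(inherits(f, "fcd_matrix"))
  nw <- nrow(f)
  idx <- which(upper.tri(f), arr.ind = TRUE)
  lags <- idx[, 2] - idx[, 1]
  values <- f[idx]
  if (exclude_overlap) {
    keep <- lags >= attr(f, "window") / attr(f, "step")
    values <- values[keep]
    lags <- lags[keep]
  }
  structure(list(values = as.numeric(values), lags = as.numeric(lags)),
            class = "fcd_sample")
}

#' @export
print.fcd_sample <- function(x, ...) {
  cat("fcd_sample:", length(x$values), "values, lag range [",
      min(x$lags), ",", max(x$lags), "]\n")
  invisible(x)
}

as_fcd_values <- function(x) {
  if (inherits(x, "fcd_sample")) x$values
  else if (inherits(x, "fcd_matrix")) fcd_sample(x)$values
  else as.numeric(x)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum absolute difference between the empirical cumulative
#' distributions of two value samples (no binning); the goodness-of-fit
#' measure comparing simulated and empirical FCD distributions.
#'
#' @param a,b `fcd_sample` objects or numeric vectors.
#' @return KS distance in \[0, 1\].
#' @examples
#' ks_distance(c(1, 2, 3), c(1, 2, 4))  # 1/3
#' @export
ks_distance <- function(a, b) {
  va <- sort(as_fcd_values(a))
  vb <- sort(as_fcd_values(b))
  if (length(va) == 0 || length(vb) == 0) stop("empty sample")
  pts <- sort(c(va, vb))
  fa <- findInterval(pts, va) / length(va)
  fb <- findInterval(pts, vb) / length(vb)
  max(abs(fa - fb))
}

#' Two-dimensional (value, lag) Kolmogorov-Smirnov distance
#'
#' Peacock-style two-sample 2-D KS statistic over the joint distribution
#' of FCD value and window lag: the maximum, over all data points of
#' both samples and all four quadrant orientations, of the absolute
#' difference between the two empirical quadrant CDFs.  Sensitive to
#' differences in the association between FC similarity and temporal
#' separation that the marginal KS distance cannot see.
#'
#' @param a,b `fcd_sample` objects (values and lags required).
#' @return 2-D KS distance in \[0, 1\].
#' @export
ks2d_distance <- function(a, b) {
  stopifnot(inherits(a, "fcd_sample"), inherits(b, "fcd_sample"))
  if (length(a$values) == 0 || length(b$values) == 0) stop("empty sample")
  ks2d_cpp(a$values, a$lags, b$values, b$lags)
}

#' Pool FCD samples across subjects or scans
#'
#' Concatenates the upper-triangle FCD values (and lags) of several
#' samples into one group-wise sample.
#'
#' @param samples list of `fcd_sample` objects.
#' @return an `fcd_sample`.
#' @export
pool_fcd <- function(samples) {
  if (inherits(samples, "fcd_sample")) samples <- list(samples)
  if (length(samples) < 1) stop("need at least one sample")
  stopifnot(all(vapply(samples, inherits, logical(1), "fcd_sample")))
  structure(list(values = unlist(lapply(samples, `[[`, "values")),
                 lags = unlist(lapply(samples, `[[`, "lags"))),
            class = "fcd_sample")
}
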