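#' Normalise a regional receptor-density map
#'
#' Z-scores the raw densities (population SD) and then min-max rescales
#' them to lie in \[0, 1\], the convention used to feed PET-derived
#' receptor densities into regional gain modulation.  Constant maps are
#' rejected because the z-score is undefined.
#'
#' @param raw numeric vector of per-region densities (tracer-binding
#'   units), or an existing `receptor_map` whose raw values are re-used.
#' @param labels optional region identifiers (default `R1..Rn`).
#' @return an object of class `receptor_map` with elements `labels`,
#'   `raw` and `normalised` (min 0, max 1).
#' @examples
#' normalise_receptor_map(c(1, 2, 3))$normalised  # 0, 0.5, 1
#' @export
normalise_receptor_map <- function(raw, labels = NULL) {
  if (inherits(raw, "receptor_map")) {
    labels <- raw$labels
    raw <- raw$raw
  }
  raw <- as.numeric(raw)
  n <- length(raw)
  if (n < 2) stop("receptor map needs at least 2 regions")
  if (any(!is.finite(raw))) stop("non-finite receptor density")
  s <- sqrt(mean((raw - mean(raw))^2))  # population SD
  if (s == 0) stop("constant receptor map: z-score undefined")
  z <- (raw - mean(raw)) / s
  nv <- (z - min(z)) / (max(z) - min(z))
  receptor_map(labels %||% paste0("R", seq_len(n)), raw, nv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Receptor map container
#'
#' @param labels region identifiers.
#' @param raw raw densities.
#' @param normalised densities in \[0, 1\].
#' @return object of class `receptor_map`.
#' @export
receptor_map <- function(labels, raw, normalised) {
  labels <- as.character(labels)
  raw <- as.numeric(raw)
  normalised <- as.numeric(normalised)
  if (length(labels) != length(normalised) ||
      length(raw) != length(normalised)) {
    stop("labels, raw and normalised must have equal length")
  }
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (any(normalised < -1e-12 | normalised > 1 + 1e-12)) {
    stop("normalised densities must lie in [0, 1]")
  }
  structure(list(labels = labels, raw = raw,
                 normalised = pmin(1, pmax(0, normalised))),
            class = "receptor_map")
}

#' @export
print.receptor_map <- function(x, ...) {
  cat("receptor_map:", length(x$labels), "regions, normalised range [",
      format(min(x$normalised), digits = 3), ",",
      format(max(x$normalised), digits = 3), "]\n")
  invisible(x)
}

#' Uniform control map
#'
#' Replaces every region's effective density with the mean of the
#' normalised distribution, removing all regional heterogeneity while
#' conserving the map mean — the uniform control for regional gain
#' modulation.
#'
#' @param map a `receptor_map`.
#' @return a `receptor_map` with constant normalised values.
#' @export
uniform_receptor_map <- function(map) {
  stopifnot(inherits(map, "receptor_map"))
  receptor_map(map$labels, map$raw,
               rep(mean(map$normalised), length(map$normalised)))
}

# Distance-binned empirical semivariance: gamma(h) = 0.5 mean (x_i - x_j)^2
# over pairs whose distance falls in bin h.
variogram <- function(values, dmat, n_bins = 25) {
  ut <- upper.tri(dmat)
  d <- dmat[ut]
  sq <- 0.5 * outer(values, values, "-")^2
  sq <- sq[ut]
  breaks <- seq(0, max(d) * (1 + 1e-9), length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  vapply(seq_len(n_bins), function(b) {
    v <- sq[bin == b]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Autocorrelation-preserving shuffle of a receptor map
#'
#' Generates a surrogate map whose values are a permutation of the input
#' values (rank-remapping preserves the multiset exactly) but whose
#' spatial autocorrelation — summarised as a distance-binned variogram —
#' matches the input's.  Candidate surrogates are built by smoothing
#' white noise over the region coordinates with Gaussian kernels of
#' varying width; the candidate whose variogram is closest (mean
#' absolute deviation) to the input's is returned.
#'
#' @param map a `receptor_map` (normalised values are shuffled).
#' @param coordinates n-by-3 matrix of region centroids (mm).
#' @param n_candidates candidate surrogates scored (default 100).
#' @param seed integer seed.
#' @param n_bins variogram distance bins (default 25).
#' @param kernel_widths grid of Gaussian kernel widths (mm); defaults to
#'   distance quantiles between 0.05 and 0.9.
#' @return a `receptor_map` whose normalised values are a surrogate
#'   permutation of the input's.
#' @export
shuffle_receptor_map <- function(map, coordinates, n_candidates = 100,
                                 seed = 1, n_bins = 25,
                                 kernel_widths = NULL) {
  stopifnot(inherits(map, "receptor_map"))
  n <- length(map$normalised)
  if (n < 10) stop("too few regions for a spatial surrogate (need >= 10)")
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != n || ncol(coordinates) != 3) {
    stop("coordinates must be available for every region (n-by-3)")
  }
  if (any(!is.finite(coordinates))) stop("missing coordinates")
  dmat <- as.matrix(dist(coordinates))
  if (is.null(kernel_widths)) {
    kernel_widths <- unname(quantile(dmat[upper.tri(dmat)],
                                     probs = seq(0.05, 0.9, length.out = 10)))
  }
  target <- variogram(map$normalised, dmat, n_bins)
  vals <- sort(map$normalised)
  best <- NULL
  best_score <- Inf
  with_seed(seed, {
    for (k in seq_len(n_candidates)) {
      w <- sample(kernel_widths, 1)
      K <- exp(-dmat^2 / (2 * w^2))
      field <- as.numeric(K %*% rnorm(n))
      cand <- numeric(n)
      cand[order(field)] <- vals
      vg <- variogram(cand, dmat, n_bins)
      score <- mean(abs(vg - target), na.rm = TRUE)
      if (score < best_score) {
        best_score <- score
        best <- cand
      }
    }
  })
  # permutation mapping surrogate positions to original regions, used to
  # carry the raw values along with their normalised counterparts
  perm <- order(map$normalised)[rank(best, ties.method = "first")]
  receptor_map(map$labels, map$raw[perm], best)
}
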