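#' Specification for synthetic fixtures
#'
#' Bundles the parameters of the synthetic-data generators: a
#' distance-dependent connectome on a sphere, a noisy cohort around it,
#' a spatially smooth receptor map, and pseudo-empirical BOLD produced
#' by the model itself.  Defaults emulate the statistical structure of a
#' cortical parcellation study: 68 regions, ~30% connection density, an
#' exponential distance rule, and a smooth receptor gradient.
#'
#' @param n_regions number of regions (>= 10; default 68).
#' @param edge_density fraction of region pairs connected (default 0.3).
#' @param distance_decay exponential decay rate of weight with distance
#'   (mm^-1; default 0.05).
#' @param radius_mm sphere radius for region placement (default 70).
#' @param cohort_size subjects in a synthetic cohort (default 10).
#' @param subject_noise SD of per-subject multiplicative log-normal
#'   weight noise (default 0.2).
#' @param dropout per-subject probability that an edge is missing
#'   (default 0.2).
#' @param map_smoothness Gaussian kernel width (mm) of the receptor
#'   field (default 30).
#' @param seed master seed recorded with the fixture.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_regions = 68, edge_density = 0.3,
                         distance_decay = 0.05, radius_mm = 70,
                         cohort_size = 10, subject_noise = 0.2,
                         dropout = 0.2, map_smoothness = 30, seed = 1) {
  stopifnot(n_regions >= 10, edge_density > 0, edge_density <= 1,
            distance_decay > 0, cohort_size >= 1, subject_noise >= 0,
            dropout >= 0, dropout < 1, map_smoothness > 0)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Synthetic distance-dependent connectome
#'
#' Places regions at random on a sphere and connects the closest
#' `edge_density` fraction of pairs with weights `exp(-decay *
#' distance)`, so weights decrease strictly with distance — giving the
#' distance-dependent topology that makes lattice and random nulls
#' distinguishable.  Coordinates are attached for surrogate maps.
#'
#' @param spec a `fixture_spec`.
#' @param seed integer seed (defaults to the spec's).
#' @return a `connectome` with coordinates.
#' @export
synth_connectome <- function(spec = fixture_spec(), seed = spec$seed) {
  n <- spec$n_regions
  with_seed(seed, {
    xyz <- matrix(rnorm(3 * n), n, 3)
    xyz <- xyz / sqrt(rowSums(xyz^2)) * spec$radius_mm
    # label regions in azimuthal order so that label order (the ring
    # order used by the lattice null) tracks spatial adjacency
    xyz <- xyz[order(atan2(xyz[, 2], xyz[, 1])), , drop = FALSE]
    dmat <- as.matrix(dist(xyz))
    ut <- upper.tri(dmat)
    n_pairs <- sum(ut)
    n_edges <- round(spec$edge_density * n_pairs)
    if (n_edges < 4) stop("density too low: fewer than 4 edges")
    thr <- sort(dmat[ut])[n_edges]
    W <- exp(-spec$distance_decay * dmat)
    W[dmat > thr] <- 0
    diag(W) <- 0
    validate_connectome(W, paste0("R", seq_len(n)), coordinates = xyz)
  })
}

#' Synthetic cohort of individual connectomes
#'
#' Perturbs a base connectome per subject with multiplicative log-normal
#' weight noise and independent symmetric edge dropout, emulating
#' between-subject tractography variability; the cohort exercises the
#' strict-majority consensus rule.
#'
#' @param spec a `fixture_spec`.
#' @param base a `connectome` (defaults to `synth_connectome(spec)`).
#' @param seed integer seed.
#' @return a `cohort_connectomes`; attribute `subject_seeds` records the
#'   per-subject seeds.
#' @export
synth_cohort <- function(spec = fixture_spec(),
                         base = synth_connectome(spec),
                         seed = spec$seed) {
  seeds <- derive_seeds(seed, spec$cohort_size)
  subjects <- lapply(seeds, function(s) {
    with_seed(s, {
      W <- base$weights
      ut <- which(upper.tri(W) & W > 0)
      noise <- exp(rnorm(length(ut), 0, spec$subject_noise))
      keep <- runif(length(ut)) >= spec$dropout
      w <- W[ut] * noise * keep
      W2 <- matrix(0, nrow(W), ncol(W))
      W2[ut] <- w
      W2 <- W2 + t(W2)
      validate_connectome(W2, base$labels, base$coordinates)
    })
  })
  out <- cohort_connectomes(subjects)
  attr(out, "subject_seeds") <- seeds
  out
}

#' Synthetic receptor-density map
#'
#' Generates a spatially smooth positive field over the region
#' coordinates (Gaussian-kernel-smoothed white noise, shifted positive)
#' and normalises it, emulating a regional receptor-density atlas with
#' realistic spatial autocorrelation.
#'
#' @param spec a `fixture_spec`.
#' @param coordinates n-by-3 region centroids (mm).
#' @param seed integer seed.
#' @return a `receptor_map`.
#' @export
synth_receptor_map <- function(spec, coordinates, seed = spec$seed) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  with_seed(seed, {
    dmat <- as.matrix(dist(coordinates))
    K <- exp(-dmat^2 / (2 * spec$map_smoothness^2))
    field <- as.numeric(K %*% rnorm(n))
    raw <- field - min(field) + 1  # positive, tracer-binding-like units
    normalise_receptor_map(raw, labels = rownames(coordinates) %||%
                             paste0("R", seq_len(n)))
  })
}

#' Pseudo-empirical BOLD from the model itself
#'
#' Runs the full simulate / Balloon-Windkessel / band-pass chain at
#' known parameters once per subject, producing the pseudo-empirical
#' scans used as ground truth in parameter-recovery and
#' condition-contrast experiments.  Circular by design: these fixtures
#' validate the inference machinery, not biology.
#'
#' @param model a tuned `dmf_model` at the generating parameters.
#' @param n_subjects number of scans.
#' @param n_trs TRs per scan (250 for awake/anaesthesia-style scans, 155
#'   for the truncated clinical-style scans).
#' @param TR repetition time (s, default 2).
#' @param seed master seed; per-subject seeds derive from it.
#' @param ... forwarded to [simulate_fcd_sample()]'s underlying chain
#'   (`burn_in_s`, `dt`, `low`, `high`).
#' @return list of `bold_ts`, one per subject; attribute
#'   `subject_seeds` records the per-subject seeds.
#' @export
synth_empirical_bold <- function(model, n_subjects, n_trs = 250, TR = 2,
                                 seed = 1, burn_in_s = 10, dt = 0.1,
                                 low = 0.008, high = 0.09) {
  seeds <- derive_seeds(seed, n_subjects)
  scans <- lapply(seeds, function(s) {
    tr <- simulate_dmf(model, duration_s = n_trs * TR,
                       burn_in_s = burn_in_s, dt = dt, seed = s)
    bandpass_bold(balloon_windkessel(tr, TR = TR), low = low, high = high)
  })
  attr(scans, "subject_seeds") <- seeds
  scans
}

#' Pooled group-wise FCD sample from a list of scans
#'
#' @param scans list of `bold_ts`.
#' @param window,step FCD window and increment (TRs).
#' @return an `fcd_sample` pooling all scans' upper-triangle values.
#' @export
pooled_fcd_from_scans <- function(scans, window = 30, step = 3) {
  pool_fcd(lapply(scans, function(b)
    fcd_sample(fcd_matrix(b, window = window, step = step))))
}
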