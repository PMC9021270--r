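# Shared fixtures, built once per test run and cached.  The heavy
# objects (tuned models, pseudo-empirical scans) are lazily constructed
# the first time a test asks for them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 20-region distance-dependent connectome + smooth receptor map
small_spec <- function() fixture_spec(n_regions = 20, seed = 42)

small_connectome <- function() {
  cached("small_connectome", function() synth_connectome(small_spec()))
}

small_map <- function() {
  cached("small_map", function() {
    synth_receptor_map(small_spec(), small_connectome()$coordinates)
  })
}

# calibrated (FIC-tuned) 20-region model at the fixture's generating G
small_model <- function() {
  cached("small_model", function() {
    tune_fic(dmf_model(small_connectome(), G = 1.2), seed = 1)
  })
}

# a tiny hand-made connectome for exact/structural tests
toy_connectome <- function(n = 10, seed = 3, density = 0.4) {
  with_seed_local(seed, {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- sample(ut, round(density * length(ut)))
    W[on] <- runif(length(on), 0.5, 2)
    W <- W + t(W)
    validate_connectome(W)
  })
}

# run expr under a temporary seed without clobbering the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# brute-force two-sample KS oracle: double loop over all evaluation
# points, independent of the package's sorted-merge implementation
ks_oracle <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (p in pts) {
    fa <- sum(a <= p) / length(a)
    fb <- sum(b <= p) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# exhaustive quadrant-scan oracle for the 2-D KS statistic
ks2d_oracle <- function(x1, y1, x2, y2) {
  d <- 0
  quad <- function(x, y, px, py, qx, qy) {
    cx <- if (qx) x <= px else x > px
    cy <- if (qy) y <= py else y > py
    mean(cx & cy)
  }
  for (k in seq_along(c(x1, x2))) {
    px <- c(x1, x2)[k]
    py <- c(y1, y2)[k]
    for (qx in c(TRUE, FALSE)) {
      for (qy in c(TRUE, FALSE)) {
        d <- max(d, abs(quad(x1, y1, px, py, qx, qy) -
                        quad(x2, y2, px, py, qx, qy)))
      }
    }
  }
  d
}
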