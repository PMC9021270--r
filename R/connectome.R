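#' Validate and construct a structural connectome
#'
#' A connectome is a symmetric, non-negative, zero-diagonal region-by-region
#' matrix of tract strengths, with unique region labels and (optionally)
#' region centroid coordinates in mm.  Asymmetries beyond `1e-9` and
#' non-zero diagonals beyond `1e-12` are errors, not silently repaired.
#'
#' @param weights square numeric matrix of non-negative tract strengths.
#' @param labels character vector of unique region identifiers; defaults to
#'   `R1..Rn` (or the matrix dimnames when present).
#' @param coordinates optional n-by-3 numeric matrix of region centroids (mm).
#' @return an object of class `connectome` with elements `weights`,
#'   `labels` and `coordinates`.
#' @export
validate_connectome <- function(weights, labels = NULL, coordinates = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weights must be a square matrix, got ",
         nrow(weights), "x", ncol(weights))
  }
  n <- nrow(weights)
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite connectome weight at (", bad[1, 1], ",", bad[1, 2], ")")
  }
  bad <- which(weights < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative connectome weight at (", bad[1, 1], ",", bad[1, 2], ")")
  }
  asym <- abs(weights - t(weights))
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("asymmetric connectome: |w[", ij[1], ",", ij[2], "] - w[",
         ij[2], ",", ij[1], "]| = ", format(max(asym)))
  }
  dg <- diag(weights)
  if (any(abs(dg) >= 1e-12)) {
    k <- which.max(abs(dg))
    stop("non-zero diagonal entry at region ", k, ": ", format(dg[k]))
  }
  diag(weights) <- 0
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(weights))) rownames(weights)
              else paste0("R", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("expected ", n, " labels, got ", length(labels))
  }
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n || ncol(coordinates) != 3) {
      stop("coordinates must be an n-by-3 matrix")
    }
    rownames(coordinates) <- labels
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels,
                 coordinates = coordinates),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("connectome:", length(x$labels), "regions,", m, "edges",
      if (!is.null(x$coordinates)) "(with coordinates)" else "", "\n")
  invisible(x)
}

n_regions <- function(c) length(c$labels)

#' Group-consensus connectome from a cohort
#'
#' For each region pair, the consensus keeps the connection only when a
#' strict majority of subjects (> half) have a non-zero weight there, in
#' which case it takes the mean over the subjects with non-zero weight;
#' otherwise the consensus weight is zero.  Ties at exactly half are
#' dropped.
#'
#' @param cohort a list of `connectome` objects sharing one label set
#'   (class `cohort_connectomes` or a plain list).
#' @return a `connectome`.
#' @export
consensus_connectome <- function(cohort) {
  subjects <- unclass(cohort)
  if (length(subjects) < 1) stop("cohort must contain at least one subject")
  subjects <- lapply(subjects, function(s) {
    if (!inherits(s, "connectome")) validate_connectome(s) else s
  })
  ref <- subjects[[1]]$labels
  for (k in seq_along(subjects)) {
    if (!identical(subjects[[k]]$labels, ref)) {
      stop("subject ", k, " label set does not match subject 1")
    }
  }
  W <- vapply(subjects, function(s) s$weights, subjects[[1]]$weights)
  dim(W) <- c(length(ref), length(ref), length(subjects))
  nz <- W > 0
  count <- apply(nz, c(1, 2), sum)
  total <- apply(W, c(1, 2), sum)
  keep <- count > length(subjects) / 2
  out <- matrix(0, length(ref), length(ref))
  out[keep] <- total[keep] / count[keep]
  validate_connectome(out, labels = ref,
                      coordinates = subjects[[1]]$coordinates)
}

#' Cohort container
#'
#' @param subjects list of `connectome` objects with identical labels.
#' @return object of class `cohort_connectomes`.
#' @export
cohort_connectomes <- function(subjects) {
  if (length(subjects) < 1) stop("cohort must be non-empty")
  structure(subjects, class = "cohort_connectomes")
}

# Edge list of the upper triangle: data.frame(i, j, w) with i < j.
edge_list <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
}

edges_to_matrix <- function(n, i, j, w, labels) {
  W <- matrix(0, n, n)
  W[cbind(i, j)] <- w
  W[cbind(j, i)] <- w
  dimnames(W) <- list(labels, labels)
  W
}

ring_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# Maslov-Sneppen degree-preserving double-edge swaps.  With
# `lattice = TRUE` a swap is accepted only when it strictly reduces the
# summed ring distance of the two edges (regions on a ring in label
# order); otherwise every legal swap is accepted.
double_edge_swap <- function(W, n_swaps_per_edge, seed,
                             lattice = FALSE) {
  n <- nrow(W)
  el <- edge_list(W)
  m <- nrow(el)
  if (m < 4) {
    stop("graph too small to rewire: needs at least 4 edges, has ", m)
  }
  A <- W > 0
  i <- el$i; j <- el$j; w <- el$w
  n_attempts <- ceiling(n_swaps_per_edge * m)
  with_seed(seed, {
    e1s <- sample.int(m, n_attempts, replace = TRUE)
    e2s <- sample.int(m, n_attempts, replace = TRUE)
    flip <- runif(n_attempts) < 0.5
    for (k in seq_len(n_attempts)) {
      e1 <- e1s[k]; e2 <- e2s[k]
      if (e1 == e2) next
      a <- i[e1]; b <- j[e1]; c <- i[e2]; d <- j[e2]
      if (flip[k]) { tmp <- c; c <- d; d <- tmp }
      # propose (a,d) and (c,b)
      if (a == d || c == b) next
      if (length(unique(c(a, b, c, d))) < 4) next
      if (A[a, d] || A[c, b]) next
      if (lattice) {
        old_cost <- ring_distance(a, b, n) + ring_distance(c, d, n)
        new_cost <- ring_distance(a, d, n) + ring_distance(c, b, n)
        if (new_cost >= old_cost) next
      }
      A[a, b] <- A[b, a] <- FALSE
      A[c, d] <- A[d, c] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c, b] <- A[b, c] <- TRUE
      i[e1] <- min(a, d); j[e1] <- max(a, d)
      i[e2] <- min(c, b); j[e2] <- max(c, b)
    }
    list(i = i, j = j, w = w)
  })
}

#' Weight-preserving randomisation of a connectome
#'
#' Rewires the topology with degree-preserving double-edge swaps
#' (Maslov-Sneppen) and then randomly reassigns the original multiset of
#' edge weights to the rewired edges.  Edge count, total weight, weight
#' multiset and degree sequence are preserved exactly; average
#' connectivity is therefore unchanged while topology is destroyed.
#'
#' @param c a `connectome`.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed; the same seed reproduces the same null.
#' @return a `connectome`.
#' @export
randomise_connectome <- function(c, n_swaps_per_edge = 10, seed = 1) {
  sw <- double_edge_swap(c$weights, n_swaps_per_edge, seed, lattice = FALSE)
  seeds <- derive_seeds(seed, 2)
  w_perm <- with_seed(seeds[2], sample(sw$w))
  W <- edges_to_matrix(n_regions(c), sw$i, sw$j, w_perm, c$labels)
  validate_connectome(W, c$labels, c$coordinates)
}

#' Latticisation of a connectome
#'
#' Applies the same double-edge-swap machinery as [randomise_connectome()],
#' but accepts a swap only when it strictly reduces the total ring
#' distance of edge placements, with regions arranged on a ring in label
#' order.  Weights travel with their edges, so the weight multiset, edge
#' count and degree sequence are preserved while the topology becomes
#' lattice-like.
#'
#' @inheritParams randomise_connectome
#' @return a `connectome`.
#' @export
latticise <- function(c, n_swaps_per_edge = 10, seed = 1) {
  sw <- double_edge_swap(c$weights, n_swaps_per_edge, seed, lattice = TRUE)
  W <- edges_to_matrix(n_regions(c), sw$i, sw$j, sw$w, c$labels)
  validate_connectome(W, c$labels, c$coordinates)
}
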