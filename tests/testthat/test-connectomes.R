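test_that("validation accepts clean matrices and reports defects", {
  W <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  cn <- validate_connectome(W, c("a", "b", "c"))
  expect_identical(unname(cn$weights), W)
  expect_identical(cn$labels, c("a", "b", "c"))

  bad <- W; bad[1, 2] <- 2; bad[2, 1] <- 3
  expect_error(validate_connectome(bad), "asymmetric")
  bad <- W; bad[1, 3] <- bad[3, 1] <- NaN
  expect_error(validate_connectome(bad), "non-finite")
  bad <- W; bad[1, 3] <- bad[3, 1] <- -1
  expect_error(validate_connectome(bad), "negative")
  bad <- W; diag(bad) <- 0.5
  expect_error(validate_connectome(bad), "diagonal")
  expect_error(validate_connectome(W, c("a", "a", "b")), "unique")
  expect_error(validate_connectome(matrix(0, 2, 3)), "square")
})

test_that("consensus keeps strict-majority edges, averaging non-zero weights", {
  base <- matrix(0, 4, 4)
  mk <- function(w12, w13, w24) {
    W <- base
    W[1, 2] <- W[2, 1] <- w12
    W[1, 3] <- W[3, 1] <- w13
    W[2, 4] <- W[4, 2] <- w24
    validate_connectome(W, letters[1:4])
  }
  # edge (1,2): present in 2/3 subjects with weights 2 and 4 -> mean 3
  # edge (1,3): present in all -> mean
  # edge (2,4): present in 1/3 -> dropped
  cons <- consensus_connectome(list(mk(2, 1, 5), mk(4, 2, 0), mk(0, 3, 0)))
  expect_equal(cons$weights[1, 2], 3)
  expect_equal(cons$weights[1, 3], 2)
  expect_equal(cons$weights[2, 4], 0)

  # exactly half is not a majority
  cons4 <- consensus_connectome(list(mk(5, 1, 1), mk(7, 1, 1),
                                     mk(0, 1, 1), mk(0, 1, 1)))
  expect_equal(cons4$weights[1, 2], 0)

  # single-subject cohort returns the subject unchanged
  one <- mk(2, 1, 5)
  expect_equal(consensus_connectome(list(one))$weights, one$weights)

  # identical cohort reproduces the member
  cn <- toy_connectome()
  expect_equal(consensus_connectome(list(cn, cn, cn))$weights, cn$weights)

  # label mismatch across subjects
  other <- validate_connectome(mk(1, 1, 1)$weights, LETTERS[1:4])
  expect_error(consensus_connectome(list(one, other)), "label")
})

test_that("random null preserves weights, edges and degrees but rewires", {
  cn <- toy_connectome(n = 20, seed = 7)
  nul <- randomise_connectome(cn, seed = 11)
  w0 <- sort(cn$weights[upper.tri(cn$weights) & cn$weights > 0])
  w1 <- sort(nul$weights[upper.tri(nul$weights) & nul$weights > 0])
  expect_equal(w1, w0)
  expect_equal(rowSums(nul$weights > 0), rowSums(cn$weights > 0))
  expect_false(identical(nul$weights > 0, cn$weights > 0))
  # seeded determinism
  expect_identical(randomise_connectome(cn, seed = 11)$weights, nul$weights)
  expect_error(validate_connectome(nul$weights), NA)
})

test_that("complete graphs cannot be rewired but weights are permuted", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(1, 2, 3, 4, 5, 6)
  W <- W + t(W)
  cn <- validate_connectome(W)
  nul <- randomise_connectome(cn, seed = 2)
  expect_equal(sort(nul$weights[upper.tri(W)]), 1:6)
  expect_equal(nul$weights > 0, cn$weights > 0)
  expect_false(identical(nul$weights, cn$weights))
})

test_that("latticisation reduces total ring distance, preserving weights", {
  cn <- toy_connectome(n = 12, seed = 5, density = 0.35)
  lat <- latticise(cn, seed = 9)
  ringsum <- function(c) {
    el <- which(upper.tri(c$weights) & c$weights > 0, arr.ind = TRUE)
    d <- abs(el[, 1] - el[, 2])
    sum(pmin(d, nrow(c$weights) - d))
  }
  expect_lte(ringsum(lat), ringsum(cn))
  expect_equal(sort(lat$weights[lat$weights > 0]),
               sort(cn$weights[cn$weights > 0]))
  expect_equal(rowSums(lat$weights > 0), rowSums(cn$weights > 0))

  # a perfect ring is already optimal: topology unchanged
  n <- 10
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- i
  }
  ring <- validate_connectome(W)
  lat2 <- latticise(ring, seed = 3)
  expect_equal(lat2$weights > 0, ring$weights > 0)
})

test_that("rewiring refuses graphs with too few edges", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 2
  cn <- validate_connectome(W)
  expect_error(randomise_connectome(cn, seed = 1), "4 edges")
})

test_that("null-model conservation holds across many seeded fixtures", {
  # weight multiset, edge count and degree sequence preserved exactly
  for (s in 1:25) {
    cn <- toy_connectome(n = 14, seed = s, density = 0.3)
    for (nul in list(randomise_connectome(cn, seed = s + 100),
                     latticise(cn, seed = s + 200))) {
      expect_equal(sort(nul$weights[nul$weights > 0]),
                   sort(cn$weights[cn$weights > 0]))
      expect_equal(rowSums(nul$weights > 0), rowSums(cn$weights > 0))
      expect_equal(sum(nul$weights), sum(cn$weights))
    }
  }
})
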