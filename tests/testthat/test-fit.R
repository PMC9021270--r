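test_that("pooled-variance t and effect sizes match hand computation", {
  # worked example: two groups with known summary statistics
  es <- effect_sizes(35.75, 11.42, 20, 38.24, 15.96, 21)
  sp <- sqrt((19 * 11.42^2 + 20 * 15.96^2) / 39)
  expect_equal(es$t, (35.75 - 38.24) / (sp * sqrt(1 / 20 + 1 / 21)))
  expect_equal(es$df, 39)
  expect_equal(es$cohens_d, (35.75 - 38.24) / sp)
  expect_equal(es$hedges_g, es$cohens_d * (1 - 3 / (4 * 39 - 1)))
  # equal means: all effect measures vanish
  z <- effect_sizes(5, 1, 10, 5, 2, 12)
  expect_equal(z$t, 0); expect_equal(z$cohens_d, 0); expect_equal(z$hedges_g, 0)
  expect_error(effect_sizes(1, 0, 5, 2, 1, 5), "positive")
  expect_error(effect_sizes(1, 1, 1, 2, 1, 5), "at least 2")
})

test_that("permutation t-test matches the analytic t on known input", {
  # hand pooled-t: x = 1,2,3 vs y = 4,5,6
  res <- permutation_ttest(1:3, 4:6, n_perm = 500, seed = 1)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  res0 <- permutation_ttest(c(1, 2, 3), c(1, 2, 3), n_perm = 200, seed = 1)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(permutation_ttest(c(1, 1), c(1, 1)), "variance")
  # permutation p approximates the classic t-test p for normal samples
  with_seed_local(3, {
    x <- rnorm(30); y <- rnorm(30, 0.5)
    p_perm <- permutation_ttest(x, y, n_perm = 4000, seed = 9)$p
    p_t <- t.test(x, y, var.equal = TRUE)$p.value
    expect_lt(abs(p_perm - p_t), 0.02)
  })
  # p is never exactly zero (add-one estimator)
  far <- permutation_ttest(rnorm(10), rnorm(10, 50), n_perm = 100, seed = 2)
  expect_gt(far$p, 0)
})

test_that("sweep bookkeeping: argmin, ties, eligibility", {
  grid <- c(0.5, 1.0, 1.5)
  ks <- rbind(c(0.3, 0.4), c(0.1, 0.2), c(0.1, 0.2))
  sw <- gabadmf:::new_sweep_result(grid, ks)
  expect_equal(sw$mean_ks, c(0.35, 0.15, 0.15))
  expect_equal(sw$argmin, 1.0)  # tie broken to the smaller parameter
  # a grid value with <80% surviving sims cannot win
  ks2 <- rbind(c(0.05, NA, NA, NA, NA), rep(0.2, 5), rep(0.5, 5))
  sw2 <- gabadmf:::new_sweep_result(grid, ks2)
  expect_false(sw2$eligible[1])
  expect_equal(sw2$argmin, 1.0)
})

test_that("default sweep grids have the standard sizes", {
  expect_length(seq(0.1, 2.5, by = 0.1), 25)
  expect_length(formals(sweep_si)$grid |> eval(), 51)
  expect_equal(eval(formals(sweep_g)$grid)[1], 0.1)
})

test_that("model comparison is antisymmetric and self-consistent", {
  model <- small_model()
  scans <- cached("eval_scans", function() {
    synth_empirical_bold(model, 3, n_trs = 80, TR = 2, seed = 31,
                         dt = 0.2)
  })
  emp <- pooled_fcd_from_scans(scans)
  res <- evaluate_model(model, emp, emp, n_sims = 4, n_trs = 80, TR = 2,
                        seed = 5, n_perm = 200, dt = 0.2)
  # A = B: delta identically zero and p = 1
  expect_equal(res$delta, rep(0, 4))
  # antisymmetry against a different condition
  scans2 <- cached("eval_scans2", function() {
    m2 <- model; m2$gain <- rep(1.3, length(model$labels))
    synth_empirical_bold(m2, 3, n_trs = 80, TR = 2, seed = 32,
                         dt = 0.2)
  })
  emp2 <- pooled_fcd_from_scans(scans2)
  ab <- evaluate_model(model, emp, emp2, n_sims = 4, n_trs = 80, TR = 2,
                       seed = 5, n_perm = 200, dt = 0.2)
  ba <- evaluate_model(model, emp2, emp, n_sims = 4, n_trs = 80, TR = 2,
                       seed = 5, n_perm = 200, dt = 0.2)
  expect_equal(ab$delta, -ba$delta)
  # determinism under the same seed
  ab2 <- evaluate_model(model, emp, emp2, n_sims = 4, n_trs = 80, TR = 2,
                        seed = 5, n_perm = 200, dt = 0.2)
  expect_identical(ab$delta, ab2$delta)
})

test_that("sweeps are reproducible bit-for-bit under a fixed master seed", {
  model <- small_model()
  emp <- pooled_fcd_from_scans(cached("eval_scans", function() {
    synth_empirical_bold(model, 3, n_trs = 80, TR = 2, seed = 31,
                         dt = 0.2)
  }))
  run <- function() {
    sweep_si(model, small_map(), emp, grid = c(0, 0.3), n_sims = 2,
             n_trs = 60, TR = 2, seed = 41, dt = 0.2)
  }
  a <- run(); b <- run()
  expect_identical(a$ks_per_sim, b$ks_per_sim)
  expect_identical(a$argmin, b$argmin)
})

test_that("connectome replacement validates the region set", {
  model <- small_model()
  other <- toy_connectome(n = 8)
  expect_error(swap_connectome(model, other), "region set")
  # no-op replacement by the original connectome reproduces the model
  same <- swap_connectome(model, small_connectome())
  expect_equal(same$C, model$C)
  expect_equal(same$J_fic, model$J_fic)
})
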