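test_that("curve area integrates the absolute effect with trapezoids", {
  d <- seq(0, 1, length.out = 101)
  expect_equal(effect_auc(d, rep(3, 101)), 3)
  expect_equal(effect_auc(d, rep(-3, 101)), 3)
  expect_equal(effect_auc(d, d), 0.5, tolerance = 1e-4)
  expect_equal(effect_auc(d, rep(0, 101)), 0)
  # homogeneity: auc(c * curve) == |c| * auc(curve)
  set.seed(1)
  v <- rnorm(101)
  for (c0 in c(-2.5, 0.3, 4)) {
    expect_equal(effect_auc(d, c0 * v), abs(c0) * effect_auc(d, v))
  }
})

test_that("sign classification follows the min/max rule", {
  expect_equal(classify_sign(c(0.1, 0.5, 2)), "+")
  expect_equal(classify_sign(c(-0.2, -1)), "-")
  expect_equal(classify_sign(seq(-0.5, 0.5, length.out = 11)), "0")
  expect_equal(classify_sign(c(0, 1, 2)), "0")  # touching zero is mixed
})

test_that("dose-effect Spearman correlation tracks monotonicity", {
  d <- seq(0.01, 1, length.out = 51)
  expect_equal(spearman_dose_effect(d, exp(d)), 1)
  expect_equal(spearman_dose_effect(d, -d^3), -1)
  # exactly symmetric parabola on an odd symmetric grid: zero by rank symmetry
  dg <- 0:100
  vals <- -(abs(dg - 50L))^2
  expect_lt(abs(spearman_dose_effect(dg, vals)), 1e-10)
  flat <- spearman_dose_effect(d, rep(1, 51))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "constant"))
})

test_that("bootstrap summaries are reproducible and degenerate without noise", {
  # all truths (including the z effects, hence n_tissues = 1) lie inside the
  # spline space, so noiseless refits are exact and resampling is degenerate
  sim <- small_sim(n = 30, G = 8, active = 2, sigma = 0, n_tissues = 1,
                   active_shapes = c("constant", "linear"), amplitude = c(1, -1),
                   seed = 3)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas, structure = "independence")
  fit <- fit_gscad(p, bas, sim$truth$active, wm, lambda = 0.01)
  b1 <- bootstrap_summaries(p, fit, wm, B = 15, seed = 42, grid_size = 41)
  b2 <- bootstrap_summaries(p, fit, wm, B = 15, seed = 42, grid_size = 41)
  expect_identical(b1, b2)
  expect_true(all(b1$auc_sd < 1e-6))        # zero-noise panel
  expect_error(bootstrap_summaries(p, fit, wm, B = 1), "at least 2")
})

test_that("predicted trajectories are additive in covariates and expression", {
  sim <- small_sim(n = 30, G = 6, active = 2, seed = 4)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas)
  fit <- fit_gscad(p, bas, 1:6, wm, lambda = 0.01)
  d <- seq(bas$boundary[1], bas$boundary[2], length.out = 21)
  z0 <- c(1, rep(0, ncol(p$Z) - 1))
  x0 <- rep(0, 6)
  base <- predict_response(fit, z0, x0, d)
  expect_equal(base, as.numeric(evaluate_basis(bas, d) %*% fit$zeta[, 1]))
  x1 <- rnorm(6); x2 <- rnorm(6)
  z <- c(1, rep(0, ncol(p$Z) - 1)); z[2] <- 1
  lhs <- predict_response(fit, z, x1 + x2, d) - predict_response(fit, z, x1, d)
  rhs <- predict_response(fit, z0, x2, d) - predict_response(fit, z0, x0, d)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("prediction evaluation scores the four effectiveness scenarios", {
  set.seed(2)
  df <- expand.grid(cell_line = sprintf("c%04d", 1:2000),
                    drug = paste0("d", 1:5),
                    dose = c(0.125, 0.25, 0.5, 1),
                    stringsAsFactors = FALSE)
  df$observed <- runif(nrow(df))
  df$predicted <- df$observed
  perfect <- evaluate_predictions(df)
  expect_equal(perfect$mae, 0)
  expect_equal(unname(perfect$accuracy), rep(100, 4))

  # constant predictor, uniformly random observed winners: best-drug
  # accuracy is the 1-in-5 baseline
  df$predicted <- 0.5
  rand <- evaluate_predictions(df)
  expect_lt(abs(rand$accuracy[["drug"]] - 20), 4)

  # the 31.25% dose-range rule buckets dose 0.25 as low
  df2 <- data.frame(cell_line = "c", drug = "d", dose = c(0.25, 1),
                    observed = c(0.1, 0.9), predicted = c(0.4, 0.2))
  ev <- evaluate_predictions(df2)
  # observed best dose 0.25 (low bucket), predicted best dose 1 (high)
  expect_equal(unname(ev$accuracy[["dose_range"]]), 0)
})

test_that("sigmoid IC50 fitting recovers the midpoint and flags flat curves", {
  d <- seq(0.004, 1, length.out = 101)
  y <- 0.05 + (1 - 0.05) / (1 + (d / 0.2)^2)
  f <- fit_sigmoid_ic50(d, y)
  expect_lt(abs(f$ic50 - 0.2), 1e-3)
  expect_false(f$extrapolated)

  flat <- fit_sigmoid_ic50(d, rep(1, 101))
  expect_true(flat$extrapolated)

  # shifting the curve down moves the crossing earlier: m decreases
  prev <- Inf
  for (shift in seq(0, 0.45, length.out = 10)) {
    fs <- fit_sigmoid_ic50(d, y - shift)
    expect_lte(fs$ic50, prev + 1e-6)
    prev <- fs$ic50
  }
})

test_that("fold change is the mutant to wild-type mean expression ratio", {
  E <- matrix(c(2, 2, 1, 1), 4, 1, dimnames = list(paste0("c", 1:4), "g1"))
  mut <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(fold_change(E, mut, "g1"), 2)
  expect_equal(fold_change(E, !mut, "g1"), 0.5)
  E2 <- matrix(rep(1.5, 4), 4, 1, dimnames = list(paste0("c", 1:4), "g1"))
  expect_equal(fold_change(E2, mut, "g1"), 1)
  expect_error(fold_change(E, rep(TRUE, 4), "g1"), "non-empty")
})

test_that("summary table is stable under grid refinement for spline curves", {
  sim <- small_sim(n = 40, G = 10, active = 2, seed = 6)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas)
  fit <- fit_gscad(p, bas, 1:10, wm, lambda = 0.05)
  if (length(fit$selected)) {
    c1 <- coefficient_curves(fit, 101)
    c2 <- coefficient_curves(fit, 1001)
    for (j in seq_len(ncol(c1$gamma))) {
      expect_equal(classify_sign(c1$gamma[, j]), classify_sign(c2$gamma[, j]))
      # rank correlations on refined grids agree up to the discretization
      # of the grade transform (O(1/grid) for non-monotone spline curves)
      expect_lt(abs(as.numeric(spearman_dose_effect(c1$d, c1$gamma[, j])) -
                    as.numeric(spearman_dose_effect(c2$d, c2$gamma[, j]))),
                0.05)
    }
  }
  tab <- summarize_genes(p, fit, wm, B = 10, seed = 1, grid_size = 51,
                         mutant = rep(c(TRUE, FALSE),
                                      length.out = nrow(p$expression)))
  expect_true(all(c("gene", "area", "sd", "sign", "spearman",
                    "fold_change") %in% names(tab)))
  expect_equal(order(tab$area, decreasing = TRUE), seq_len(nrow(tab)))
})
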