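test_that("low-dimensional fit interpolates noiseless z-only data", {
  # linear beta functions lie inside the cubic spline space
  sim <- small_sim(n = 40, G = 3, active = 0, sigma = 0, n_tissues = 1, seed = 2)
  low <- fit_low_dim_model(sim$panel, panel_basis(sim$panel))
  expect_lt(max(abs(low$residuals)), 1e-10)
})

test_that("low-dimensional residuals are orthogonal to the design", {
  sim <- small_sim(n = 40, G = 3, active = 0, sigma = 0.5, seed = 3)
  low <- fit_low_dim_model(sim$panel, panel_basis(sim$panel))
  expect_lt(max(abs(crossprod(low$design$X, low$residuals))), 1e-8)
})

test_that("variance function recovers homoscedastic and dose-increasing variance", {
  # 500 units on a 9-point series, iid unit-variance residuals
  set.seed(7)
  d <- rep(2^(-(8:0)), 500)
  b <- dose_basis(3, interior = stats::median(d), boundary = range(d))
  vf <- estimate_variance_function(rnorm(length(d)), d, b)
  grid <- seq(min(d), max(d), length.out = 50)
  expect_lt(max(abs(predict(vf, grid) - 1)), 0.15)

  # all-zero residuals floor at the configured epsilon
  vf0 <- estimate_variance_function(rep(0, length(d)), d, b, floor = 1e-8)
  expect_equal(predict(vf0, grid), rep(1e-8, 50))

  # V(d) = (1 + d)^2 truth: estimated variance increases with dose
  r <- (1 + d) * rnorm(length(d))
  vf2 <- estimate_variance_function(r, d, b)
  v <- predict(vf2, sort(unique(d)))
  expect_gt(cor(sort(unique(d)), v, method = "spearman"), 0.9)
})

test_that("working correlation estimation recovers structure parameters", {
  # independence requested: identity for every unit
  sim <- small_sim(n = 30, G = 2, active = 0, sigma = 0.3, seed = 5)
  bas <- panel_basis(sim$panel)
  low <- fit_low_dim_model(sim$panel, bas)
  vf <- estimate_variance_function(low$residuals, sim$panel$obs$dose, bas)
  wc <- estimate_correlation(low$residuals, sim$panel$obs$dose,
                             sim$panel$obs$unit, vf, structure = "independence")
  expect_equal(wc$structure, "independence")
  expect_equal(dosevc:::correlation_matrix(wc, c(0.1, 0.5, 1)), diag(3))

  # uncorrelated noise: fitted rational quadratic stays near identity
  des <- simulation_design(n = 500, G = 2, active = 0, sigma = 0.3,
                           correlation = "independence")
  sim2 <- simulate_panel(des, seed = 6)
  b2 <- panel_basis(sim2$panel)
  low2 <- fit_low_dim_model(sim2$panel, b2)
  vf2 <- estimate_variance_function(low2$residuals, sim2$panel$obs$dose, b2)
  wc2 <- estimate_correlation(low2$residuals, sim2$panel$obs$dose,
                              sim2$panel$obs$unit, vf2,
                              structure = "rational_quadratic")
  R <- dosevc:::correlation_matrix(wc2, 2^(-(8:0)))
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)

  # rational quadratic truth (a = 2, l = 0.3): length scale recovered
  des3 <- simulation_design(n = 1000, G = 2, active = 0, sigma = 0.2,
                            correlation = "rational_quadratic",
                            corr_a = 2, corr_l = 0.3)
  sim3 <- simulate_panel(des3, seed = 8)
  b3 <- panel_basis(sim3$panel)
  low3 <- fit_low_dim_model(sim3$panel, b3)
  vf3 <- estimate_variance_function(low3$residuals, sim3$panel$obs$dose, b3)
  wc3 <- estimate_correlation(low3$residuals, sim3$panel$obs$dose,
                              sim3$panel$obs$unit, vf3)
  expect_lt(abs(wc3$phi[["l"]] - 0.3), 0.1)
})

test_that("weight matrices have the V^(-1/2) R^(-1) V^(-1/2) / n_i structure", {
  b <- dose_basis(3, interior = 0.5, boundary = c(0.01, 1))
  wm <- identity_weight_model(b)
  expect_equal(build_weight_matrix(wm, c(0.1, 0.3, 0.6, 1)), diag(4) / 4)

  # scalar case: constant variance 4, single dose
  vf4 <- structure(list(coef = rep(4, b$L), basis = b, floor = 1e-8),
                   class = "variance_function")
  wm4 <- weight_model(vf4, dosevc:::new_working_correlation("independence",
                                                            numeric(0), NULL))
  expect_equal(build_weight_matrix(wm4, 0.5), matrix(1 / 4, 1, 1))

  # correlated weights: symmetric PSD, permutation-equivariant
  wc <- dosevc:::new_working_correlation("rational_quadratic",
                                         c(a = 2, l = 0.3), NULL)
  wm5 <- weight_model(vf4, wc)
  d <- c(0.05, 0.2, 0.45, 0.9)
  W <- build_weight_matrix(wm5, d)
  expect_equal(W, t(W))
  expect_true(all(eigen(W, symmetric = TRUE)$values >= -1e-12))
  perm <- c(3, 1, 4, 2)
  expect_equal(build_weight_matrix(wm5, d[perm]), W[perm, perm])
})

test_that("identity weights reduce the utility to per-unit mean squared error", {
  sim <- small_sim(n = 20, G = 4, seed = 9)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- identity_weight_model(bas)
  yhat <- rep(0, nrow(p$obs))
  u <- compute_utility(p, yhat, wm)
  manual <- mean(vapply(seq_along(p$unit_rows), function(i) {
    r <- p$obs$y[p$unit_rows[[i]]]
    sum(r^2) / length(r)
  }, numeric(1)))
  expect_equal(u, manual)
})
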