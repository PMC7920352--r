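test_that("SCAD penalty matches its closed form on all three branches", {
  expect_equal(scad_penalty(0, 1), 0)
  # continuity at u = lambda: both branches give lambda^2
  lam <- 1.3; al <- 3.7
  expect_equal(scad_penalty(lam, lam, al), lam^2)
  expect_equal(-(lam^2 - 2 * al * lam * lam + lam^2) / (2 * (al - 1)), lam^2)
  # middle branch, hand evaluation
  expect_equal(scad_penalty(2, 1, 3.7), -(4 - 2 * 3.7 * 2 + 1) / (2 * 2.7))
  expect_equal(scad_penalty(2, 1, 3.7), 1.8148148148, tolerance = 1e-9)
  # plateau
  expect_equal(scad_penalty(3.7, 1, 3.7), 2.35)
  expect_equal(scad_penalty(10, 1, 3.7), 2.35)
  expect_error(scad_penalty(-1, 1), "u >= 0")
})

test_that("SCAD derivative is continuous and matches numerical differentiation", {
  lam <- 0.8; al <- 3.7; h <- 1e-7
  for (u in c(lam, al * lam)) {
    left <- (scad_penalty(u, lam, al) - scad_penalty(u - h, lam, al)) / h
    right <- (scad_penalty(u + h, lam, al) - scad_penalty(u, lam, al)) / h
    expect_lt(abs(left - right), 1e-6)
    expect_lt(abs(scad_derivative(u, lam, al) - right), 1e-6)
  }
  expect_equal(scad_derivative(0.5 * lam, lam, al), lam)
  expect_equal(scad_derivative(2 * lam, lam, al), (al * lam - 2 * lam) / (al - 1))
  expect_equal(scad_derivative(10 * lam, lam, al), 0)
})

test_that("unpenalized gSCAD equals the closed-form weighted least squares solve", {
  sim <- small_sim(n = 20, G = 4, seed = 2)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas)
  fit <- fit_gscad(p, bas, 1:4, wm, lambda = 0, tol = 1e-9)
  oracle <- dosevc:::refit_unpenalized(p, bas, 1:4, wm)
  expect_lt(max(abs(fit$zeta - oracle$zeta)), 1e-6)
  expect_lt(max(abs(fit$eta - oracle$eta)), 1e-6)
  expect_true(fit$converged)
})

test_that("penalties above lambda_max zero every gene and reduce to the z-only fit", {
  sim <- small_sim(n = 25, G = 6, seed = 3)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas)
  lmax <- gscad_lambda_max(p, bas, 1:6, wm)
  fit <- fit_gscad(p, bas, 1:6, wm, lambda = lmax * 1.001)
  expect_true(all(fit$eta == 0))
  expect_length(fit$selected, 0)
  wh <- dosevc:::whiten_panel(p, bas, wm)
  zonly <- qr.coef(qr(wh$Zw), wh$yw)
  expect_lt(max(abs(as.numeric(fit$zeta) - zonly)), 1e-6)
})

test_that("the optimizer objective trace is non-increasing", {
  sim <- small_sim(n = 30, G = 8, seed = 4)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas)
  lmax <- gscad_lambda_max(p, bas, 1:8, wm)
  for (lam in lmax * c(0.5, 0.1, 0.02)) {
    fit <- fit_gscad(p, bas, 1:8, wm, lambda = lam, init = "zero")
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
})

test_that("total group norm shrinks as lambda grows", {
  for (seed in 1:10) {
    sim <- small_sim(n = 20, G = 5, seed = 100 + seed)
    p <- sim$panel
    bas <- panel_basis(p)
    wm <- estimate_weight_model(p, bas)
    lmax <- gscad_lambda_max(p, bas, 1:5, wm)
    lams <- lmax * c(0.05, 0.3, 0.9)
    norms <- vapply(lams, function(l) {
      sum(fit_gscad(p, bas, 1:5, wm, lambda = l, init = "zero")$group_norms)
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("cross-validation is deterministic and honours a fixed grid", {
  sim <- small_sim(n = 30, G = 8, seed = 5)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas)
  single <- cv_gscad(p, bas, 1:8, wm, lambda = 0.25, seed = 11)
  expect_equal(single$lambda, 0.25)
  a <- cv_gscad(p, bas, 1:8, wm, nlambda = 12, seed = 11)
  b <- cv_gscad(p, bas, 1:8, wm, nlambda = 12, seed = 11)
  expect_identical(a$fold_of_unit, b$fold_of_unit)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$fit$eta, b$fit$eta)
  expect_error(cv_gscad(dosevc:::subset_panel(p, 1:3), bas, 1:8, wm, folds = 5),
               "fewer units")
})

test_that("cross-validated gSCAD recovers the active set on noiseless data", {
  des <- simulation_design(n = 60, G = 25, active = 3, sigma = 0,
                           active_shapes = c("constant", "linear", "sine"),
                           amplitude = c(1, -1, 1))
  sim <- simulate_panel(des, seed = 5)
  p <- sim$panel
  bas <- panel_basis(p)
  wm <- estimate_weight_model(p, bas, structure = "independence")
  cv <- cv_gscad(p, bas, 1:25, wm, seed = 9, nlambda = 30)
  expect_setequal(cv$fit$selected, sim$truth$active)
})
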