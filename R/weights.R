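#' Fit the low-dimensional (z-only) varying-coefficient model
#'
#' Ordinary (unweighted) least squares of the responses on the z-covariate
#' spline blocks only. Its residuals feed the variance-function and working
#' correlation estimators; it is the one-time preliminary step of the
#' weighting scheme.
#'
#' @param panel a `dose_panel`.
#' @param basis a `dose_basis`.
#' @return List with `coef` (matrix L x (p+1), one column per z-covariate),
#'   `fitted`, `residuals` (per observation, panel row order), `design`.
#' @export
fit_low_dim_model <- function(panel, basis) {
  des <- build_vc_design(panel, basis, genes = integer(0))
  if (ncol(des$X) >= nrow(des$X)) {
    stop("low-dimensional design has at least as many columns as observations")
  }
  fit <- stats::lm.fit(des$X, panel$obs$y)
  if (fit$rank < ncol(des$X)) {
    bad <- unique(sub("\\.b[0-9]+$", "",
                      colnames(des$X)[is.na(fit$coefficients)]))
    stop("singular low-dimensional fit; rank-deficient block(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- matrix(fit$coefficients, nrow = basis$L,
                 dimnames = list(NULL, des$blocks$label))
  list(coef = coef, fitted = unname(fit$fitted.values),
       residuals = unname(fit$residuals), design = des)
}

#' Estimate the dose-varying variance function V(d)
#'
#' Squared residuals are averaged within each distinct dose fraction (the
#' dilution designs put doses on a small discrete set), then smoothed across
#' doses by unpenalized projection onto the spline basis, and floored at a
#' small positive constant.
#'
#' @param residuals per-observation residuals (from [fit_low_dim_model()]).
#' @param doses matching dose fractions.
#' @param basis a `dose_basis`.
#' @param floor lower bound for the variance (default 1e-8).
#' @return Object of class `variance_function`; evaluate with `predict()`.
#' @export
estimate_variance_function <- function(residuals, doses, basis, floor = 1e-8) {
  stopifnot(length(residuals) == length(doses), floor > 0)
  key <- round(doses, 10)
  if (length(unique(key)) < 2L) stop("fewer than 2 distinct doses")
  mean_sq <- tapply(residuals^2, key, mean)
  cnt <- tapply(rep(1, length(key)), key, sum)
  d_lev <- as.numeric(names(mean_sq))
  B <- evaluate_basis(basis, d_lev)
  # weighted unpenalized projection (weights = observation counts per dose);
  # a tiny ridge keeps the solve stable when distinct doses are few
  W <- as.numeric(cnt)
  A <- crossprod(B * W, B) + diag(1e-10, basis$L)
  b <- crossprod(B * W, as.numeric(mean_sq))
  coef <- solve(A, b)
  structure(list(coef = as.numeric(coef), basis = basis, floor = floor),
            class = "variance_function")
}

#' @param object a `variance_function`.
#' @param d doses at which to evaluate.
#' @param ... unused.
#' @rdname estimate_variance_function
#' @export
predict.variance_function <- function(object, d, ...) {
  v <- as.numeric(evaluate_basis(object$basis, d) %*% object$coef)
  pmax(v, object$floor)
}

#' Rational quadratic correlation at dose lag h
#'
#' `R(h) = (1 + h^2 / (2 a l^2))^(-a)` with amplitude-shape parameter `a > 0`
#' and length-scale `l > 0`.
#'
#' @param h nonnegative dose lags.
#' @param a shape parameter.
#' @param l length scale (dose-fraction units).
#' @return Correlation values in (0, 1].
#' @export
rational_quadratic <- function(h, a, l) {
  stopifnot(a > 0, l > 0)
  (1 + h^2 / (2 * a * l^2))^(-a)
}

#' Estimate the working within-unit correlation
#'
#' For the `independence` structure returns the identity working
#' correlation. For `rational_quadratic`, residuals are standardized by the
#' estimated variance, products `e_ij e_ik` are pooled over all within-unit
#' pairs at each distinct dose lag `h = |d_ij - d_ik|`, and the parameters
#' `(a, l)` are fitted by (pair-count weighted) least squares of the
#' rational quadratic curve against the pooled lag correlations.
#'
#' @param residuals per-observation residuals.
#' @param doses matching dose fractions.
#' @param unit matching unit indices.
#' @param variance a `variance_function` (used to standardize residuals).
#' @param structure `"independence"` or `"rational_quadratic"`.
#' @return Object of class `working_correlation` with fields `structure`,
#'   `phi` (named numeric, `c(a, l)` for rational quadratic) and `lags`
#'   (the pooled empirical lag correlations).
#' @export
estimate_correlation <- function(residuals, doses, unit, variance,
                                 structure = c("rational_quadratic",
                                               "independence")) {
  structure <- match.arg(structure)
  if (structure == "independence") {
    return(new_working_correlation("independence", numeric(0), NULL))
  }
  if (all(tabulate(unit) <= 1L)) {
    warning("all units have a single observation; falling back to independence")
    return(new_working_correlation("independence", numeric(0), NULL))
  }
  e <- residuals / sqrt(predict(variance, doses))
  ord <- order(unit)
  e <- e[ord]; d <- doses[ord]; u <- unit[ord]
  runs <- split(seq_along(u), u)
  hs <- vector("list", length(runs))
  ps <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    idx <- runs[[k]]
    if (length(idx) < 2L) next
    cmb <- utils::combn(length(idx), 2L)
    hs[[k]] <- abs(d[idx[cmb[1L, ]]] - d[idx[cmb[2L, ]]])
    ps[[k]] <- e[idx[cmb[1L, ]]] * e[idx[cmb[2L, ]]]
  }
  h <- unlist(hs); pr <- unlist(ps)
  key <- round(h, 10)
  rho <- tapply(pr, key, mean)
  cnt <- tapply(rep(1, length(key)), key, sum)
  lag_tab <- data.frame(h = as.numeric(names(rho)),
                        rho = as.numeric(rho),
                        n_pairs = as.numeric(cnt))
  loss <- function(theta) {
    a <- exp(theta[1L]); l <- exp(theta[2L])
    sum(lag_tab$n_pairs * (rational_quadratic(lag_tab$h, a, l) - lag_tab$rho)^2)
  }
  starts <- rbind(c(log(1), log(0.3)), c(log(2), log(0.1)),
                  c(log(0.5), log(0.5)), c(log(5), log(0.2)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[s, ], loss, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  phi <- c(a = exp(best$par[1L]), l = exp(best$par[2L]))
  new_working_correlation("rational_quadratic", phi, lag_tab)
}

new_working_correlation <- function(structure, phi, lags) {
  structure(list(structure = structure, phi = phi, lags = lags),
            class = "working_correlation")
}

#' @export
print.working_correlation <- function(x, ...) {
  if (x$structure == "independence") {
    cat("Working correlation: independence\n")
  } else {
    cat(sprintf("Working correlation: rational quadratic (a = %.4g, l = %.4g)\n",
                x$phi["a"], x$phi["l"]))
  }
  invisible(x)
}

# Correlation matrix implied for one unit's dose vector.
correlation_matrix <- function(correlation, d) {
  n <- length(d)
  if (correlation$structure == "independence") return(diag(n))
  H <- abs(outer(d, d, "-"))
  R <- rational_quadratic(H, correlation$phi["a"], correlation$phi["l"])
  diag(R) <- 1
  R
}

#' Bundle variance and correlation into a weight model
#'
#' @param variance a `variance_function`.
#' @param correlation a `working_correlation`.
#' @param condition_cap bound on the condition number of each unit's
#'   working correlation when it is inverted (default 100). Dilution
#'   designs place neighbouring doses very close on the dose-fraction
#'   scale, so a strongly correlated working structure can make `R_i`
#'   numerically singular and let its inverse amplify near-duplicate dose
#'   contrasts by many orders of magnitude; capping the eigenvalue spread
#'   bounds that amplification while leaving well-conditioned correlations
#'   untouched.
#' @return Object of class `weight_model`.
#' @export
weight_model <- function(variance, correlation, condition_cap = 100) {
  stopifnot(inherits(variance, "variance_function"),
            inherits(correlation, "working_correlation"),
            condition_cap >= 1)
  structure(list(variance = variance, correlation = correlation,
                 condition_cap = condition_cap),
            class = "weight_model")
}

#' Estimate the full weight model from a panel
#'
#' Convenience driver: fits the z-only model, estimates the variance
#' function from its residuals and then the working correlation, returning
#' the assembled `weight_model`.
#'
#' @param panel a `dose_panel`.
#' @param basis a `dose_basis`.
#' @param structure correlation structure, `"rational_quadratic"` (default)
#'   or `"independence"`.
#' @param variance_floor lower bound for the variance estimate.
#' @return A `weight_model`, with the low-dimensional fit attached as
#'   attribute `low_dim_fit`.
#' @export
estimate_weight_model <- function(panel, basis,
                                  structure = c("rational_quadratic",
                                                "independence"),
                                  variance_floor = 1e-8) {
  structure <- match.arg(structure)
  low <- fit_low_dim_model(panel, basis)
  vf <- estimate_variance_function(low$residuals, panel$obs$dose, basis,
                                   floor = variance_floor)
  wc <- estimate_correlation(low$residuals, panel$obs$dose, panel$obs$unit,
                             vf, structure = structure)
  wm <- weight_model(vf, wc)
  attr(wm, "low_dim_fit") <- low
  wm
}

#' Per-unit weight matrix
#'
#' `W_i = (1/n_i) V_i^(-1/2) R_i(phi)^(-1) V_i^(-1/2)` where `V_i` is the
#' diagonal matrix of estimated variances at the unit's doses and `R_i` the
#' working correlation. The inverse of `R_i` is computed from its
#' eigendecomposition with the eigenvalues floored at (leading eigenvalue /
#' `condition_cap`), so a near-singular working correlation cannot blow up
#' the weights (see [weight_model()]).
#'
#' @param model a `weight_model`.
#' @param d the unit's dose vector.
#' @return Symmetric positive semi-definite matrix `length(d) x length(d)`.
#' @export
build_weight_matrix <- function(model, d) {
  stopifnot(inherits(model, "weight_model"))
  n_i <- length(d)
  v <- predict(model$variance, d)
  R <- correlation_matrix(model$correlation, d)
  cap <- if (is.null(model$condition_cap)) 100 else model$condition_cap
  if (n_i == 1L) {
    Rinv <- matrix(1 / R[1L, 1L], 1L, 1L)
  } else {
    e <- eigen(R, symmetric = TRUE)
    vals <- pmax(e$values, e$values[1L] / cap)
    Rinv <- e$vectors %*% (t(e$vectors) / vals)
  }
  s <- 1 / sqrt(v)
  W <- (outer(s, s) * Rinv) / n_i
  (W + t(W)) / 2
}

#' Identity weight model (unit variance, independence)
#'
#' Weight model with `V(d)` identically 1 and independence working
#' correlation, so `W_i = I / n_i`: the weighted objective reduces to the
#' per-unit-normalized residual sum of squares. Useful for unweighted fits
#' and as a cross-check oracle.
#'
#' @param basis a `dose_basis` (defines the dose domain).
#' @return A `weight_model`.
#' @export
identity_weight_model <- function(basis) {
  # partition of unity: coefficient vector of ones represents V(d) = 1
  vf <- structure(list(coef = rep(1, basis$L), basis = basis, floor = 1e-8),
                  class = "variance_function")
  weight_model(vf, new_working_correlation("independence", numeric(0), NULL))
}

# Upper-triangular U with U'U = W_i, used to whiten one unit's rows.
weight_cholesky <- function(model, d) {
  W <- build_weight_matrix(model, d)
  U <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(U)) U <- chol(W + diag(1e-10, nrow(W)))
  U
}

# Whiten the panel once for a given basis and weight model: returns the
# whitened response, z-design and basis rows (gene blocks are obtained by
# scaling the whitened basis rows with the unit's expression value).
whiten_panel <- function(panel, basis, model) {
  B <- evaluate_basis(basis, panel$obs$dose)
  Zdes <- build_vc_design(panel, basis, genes = integer(0))
  yw <- panel$obs$y
  Bw <- B
  Zw <- Zdes$X
  for (i in seq_along(panel$unit_rows)) {
    rows <- panel$unit_rows[[i]]
    U <- weight_cholesky(model, panel$obs$dose[rows])
    yw[rows] <- U %*% yw[rows]
    Bw[rows, ] <- U %*% Bw[rows, , drop = FALSE]
    Zw[rows, ] <- U %*% Zw[rows, , drop = FALSE]
  }
  list(yw = yw, Zw = Zw, Bw = Bw, blocks = Zdes$blocks, basis = basis,
       unit_rows = panel$unit_rows, unit_of_row = panel$obs$unit)
}
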