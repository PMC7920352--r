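#' Evaluate estimated coefficient curves on a dose grid
#'
#' @param fit a `gscad_fit` (or any list with `zeta`, `eta`, `basis`).
#' @param grid_size number of equispaced grid points over the basis domain
#'   (default 101).
#' @return List with `d` (grid), `beta` (grid x (p+1) matrix) and `gamma`
#'   (grid x selected-gene matrix; only genes with nonzero norm).
#' @export
coefficient_curves <- function(fit, grid_size = 101L) {
  basis <- fit$basis
  d <- seq(basis$boundary[1], basis$boundary[2], length.out = grid_size)
  B <- evaluate_basis(basis, d)
  keep <- if (length(fit$group_norms)) fit$group_norms > 0 else logical(0)
  list(d = d,
       beta = B %*% fit$zeta,
       gamma = B %*% fit$eta[, keep, drop = FALSE])
}

#' Area under the absolute coefficient curve
#'
#' Trapezoidal integral of `|curve|` over the dose grid. The absolute value
#' ensures that mixed-sign effect curves still receive a positive area, so
#' genes can be ranked by effect magnitude regardless of direction.
#'
#' @param d dose grid (strictly increasing, >= 2 points).
#' @param values curve values on the grid.
#' @return Scalar area.
#' @export
effect_auc <- function(d, values) {
  stopifnot(length(d) >= 2L, length(d) == length(values), all(diff(d) > 0))
  v <- abs(values)
  sum(diff(d) * (v[-length(v)] + v[-1L]) / 2)
}

#' Classify the sign of an effect curve
#'
#' `"+"` if the curve is positive over the whole grid, `"-"` if negative
#' everywhere, `"0"` (mixed/dose-dependent) otherwise.
#'
#' @param values curve values on a dose grid.
#' @return One of `"+"`, `"-"`, `"0"`.
#' @export
classify_sign <- function(values) {
  if (min(values) > 0) "+"
  else if (max(values) < 0) "-"
  else "0"
}

#' Spearman correlation between dose and effect-curve value
#'
#' Rank correlation of the curve values against the dose grid, used as a
#' monotonicity index of the dose-varying effect. A constant curve has no
#' defined rank correlation; 0 is returned with attribute
#' `constant = TRUE`.
#'
#' @param d dose grid (>= 3 points).
#' @param values curve values on the grid.
#' @return Scalar in \[-1, 1\].
#' @export
spearman_dose_effect <- function(d, values) {
  stopifnot(length(d) >= 3L, length(d) == length(values))
  if (stats::sd(values) == 0) {
    return(structure(0, constant = TRUE))
  }
  unname(stats::cor(d, values, method = "spearman"))
}

# Unpenalized weighted refit on a fixed gene set; returns zeta/eta like a
# gscad_fit (used by the bootstrap).
refit_unpenalized <- function(panel, basis, genes, model) {
  wh <- whiten_panel(panel, basis, model)
  Xg <- do.call(cbind, lapply(genes, function(g) {
    panel$X[wh$unit_of_row, g] * wh$Bw
  }))
  M <- cbind(wh$Zw, Xg)
  # qr.coef returns coefficients in original column order (NA for columns
  # dropped by pivoting, e.g. under bootstrap-duplicated units)
  co <- qr.coef(qr(M), wh$yw)
  L <- basis$L
  nz <- ncol(wh$Zw)
  co[is.na(co)] <- 0
  list(zeta = matrix(co[seq_len(nz)], nrow = L,
                     dimnames = list(NULL, wh$blocks$label)),
       eta = if (length(genes)) matrix(co[-seq_len(nz)], nrow = L,
                                       dimnames = list(NULL, colnames(panel$X)[genes]))
       else matrix(0, L, 0L))
}

#' Bootstrap uncertainty for selected-gene effect curves
#'
#' Resamples experimental units with replacement `B` times and refits the
#' unpenalized weighted model on the fixed selected gene set (no
#' re-screening or re-selection per replicate). Returns the bootstrap SD of
#' each selected gene's curve area and pointwise 2.5/97.5 percentile bands.
#'
#' @param panel a `dose_panel`.
#' @param fit a `gscad_fit` with a nonempty selected set (or any fixed gene
#'   set via `genes`).
#' @param model a `weight_model`.
#' @param B bootstrap replicates (>= 2, default 200).
#' @param seed integer seed.
#' @param grid_size dose-grid size for curves (default 101).
#' @param genes optional explicit gene set overriding `fit$selected`.
#' @return List with `auc_sd` (named numeric), `auc_boot` (B x genes),
#'   `bands` (per gene: list with `d`, `lower`, `upper`), `seed`.
#' @export
bootstrap_summaries <- function(panel, fit, model, B = 200L, seed = 1L,
                                grid_size = 101L, genes = NULL) {
  if (B < 2L) stop("B must be at least 2")
  if (is.null(genes)) genes <- fit$selected
  basis <- fit$basis
  n <- n_units(panel)
  d <- seq(basis$boundary[1], basis$boundary[2], length.out = grid_size)
  Bmat <- evaluate_basis(basis, d)
  gene_names <- colnames(panel$X)[genes]
  set.seed(seed)
  auc_boot <- matrix(NA_real_, B, length(genes),
                     dimnames = list(NULL, gene_names))
  curves <- array(NA_real_, c(B, grid_size, length(genes)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- subset_panel(panel, idx)
    rf <- refit_unpenalized(pb, basis, genes, model)
    g_curves <- Bmat %*% rf$eta
    for (j in seq_along(genes)) {
      auc_boot[b, j] <- effect_auc(d, g_curves[, j])
      curves[b, , j] <- g_curves[, j]
    }
  }
  bands <- lapply(seq_along(genes), function(j) {
    qs <- apply(curves[, , j, drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975))
    list(d = d, lower = qs[1L, ], upper = qs[2L, ])
  })
  names(bands) <- gene_names
  list(auc_sd = apply(auc_boot, 2L, stats::sd),
       auc_boot = auc_boot, bands = bands, seed = seed)
}

#' Mean fold change of a gene's expression, mutant vs wild type
#'
#' Ratio of the mean raw-scale expression over mutant cell lines to the
#' mean over wild-type cell lines.
#'
#' @param expression cell-line x gene matrix on the original scale.
#' @param mutant logical vector (one per cell line).
#' @param gene gene column (index or name).
#' @return Scalar fold change.
#' @export
fold_change <- function(expression, mutant, gene) {
  stopifnot(nrow(expression) == length(mutant))
  mutant <- as.logical(mutant)
  if (!any(mutant) || all(mutant)) stop("both mutant and wild-type groups must be non-empty")
  m1 <- mean(expression[mutant, gene])
  m0 <- mean(expression[!mutant, gene])
  if (m0 == 0) stop("zero wild-type mean expression")
  m1 / m0
}

#' Per-gene effect summary table
#'
#' One row per selected gene: curve area (AUC of the absolute coefficient
#' curve), bootstrap SD of the area, sign classification, Spearman
#' dose-effect correlation and (when mutation annotations are supplied)
#' the mutant vs wild-type mean fold change. Rows are ordered by
#' decreasing area.
#'
#' @param panel a `dose_panel`.
#' @param fit a `gscad_fit`.
#' @param model a `weight_model`.
#' @param B bootstrap replicates for the area SD (default 200).
#' @param seed integer seed for the bootstrap.
#' @param grid_size dose-grid size (default 101).
#' @param mutant optional logical vector over `rownames(panel$expression)`
#'   flagging mutant cell lines.
#' @return data.frame with columns `gene`, `area`, `sd`, `sign`,
#'   `spearman`, and `fold_change` when `mutant` is given.
#' @export
summarize_genes <- function(panel, fit, model, B = 200L, seed = 1L,
                            grid_size = 101L, mutant = NULL) {
  sel <- fit$selected
  if (!length(sel)) {
    return(data.frame(gene = character(0), area = numeric(0),
                      sd = numeric(0), sign = character(0),
                      spearman = numeric(0)))
  }
  cc <- coefficient_curves(fit, grid_size)
  boot <- bootstrap_summaries(panel, fit, model, B = B, seed = seed,
                              grid_size = grid_size)
  gene_names <- colnames(cc$gamma)
  out <- data.frame(
    gene = gene_names,
    area = vapply(seq_along(sel), function(j) effect_auc(cc$d, cc$gamma[, j]),
                  numeric(1)),
    sd = as.numeric(boot$auc_sd[gene_names]),
    sign = vapply(seq_along(sel), function(j) classify_sign(cc$gamma[, j]),
                  character(1)),
    spearman = vapply(seq_along(sel), function(j) {
      as.numeric(spearman_dose_effect(cc$d, cc$gamma[, j]))
    }, numeric(1))
  )
  if (!is.null(mutant) && !is.null(panel$expression)) {
    out$fold_change <- vapply(gene_names, function(g) {
      fold_change(panel$expression, mutant, g)
    }, numeric(1))
  }
  out[order(-out$area), , drop = FALSE]
}

#' Predict the mean dose-response trajectory
#'
#' `yhat(d) = sum_k z_k beta_k(d) + sum_g x_g gamma_g(d)` over the selected
#' genes, for one or several covariate configurations.
#'
#' @param fit a `gscad_fit`.
#' @param z covariate vector (length p+1, first entry 1) or matrix with one
#'   row per configuration.
#' @param x expression values for the fit's candidate genes (length
#'   `length(fit$genes)` in fit order, or named by gene) or matching matrix.
#' @param d dose fractions at which to evaluate.
#' @return Numeric vector (single configuration) or matrix
#'   (configurations x doses).
#' @export
predict_response <- function(fit, z, x, d) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(z) != nrow(fit$zeta) && ncol(z) != ncol(fit$zeta)) {
    stop("z has wrong length")
  }
  if (ncol(x) != ncol(fit$eta)) {
    if (!is.null(colnames(x)) && all(fit$gene_names %in% colnames(x))) {
      x <- x[, fit$gene_names, drop = FALSE]
    } else {
      stop("x must supply one value per candidate gene of the fit")
    }
  }
  B <- evaluate_basis(fit$basis, d)
  beta_d <- B %*% fit$zeta   # doses x (p+1)
  gamma_d <- B %*% fit$eta   # doses x genes
  out <- z %*% t(beta_d) + x %*% t(gamma_d)
  if (nrow(out) == 1L) as.numeric(out) else out
}

# Predicted responses at every observation of a panel.
predict_panel <- function(fit, panel) {
  B <- evaluate_basis(fit$basis, panel$obs$dose)
  row_unit <- panel$obs$unit
  yhat <- rowSums((B %*% fit$zeta) * panel$Z[row_unit, , drop = FALSE])
  if (length(fit$genes)) {
    yhat <- yhat + rowSums((B %*% fit$eta) *
                             panel$X[row_unit, fit$genes, drop = FALSE])
  }
  yhat
}

#' Predictive evaluation: MAE and four argmin-matching scenarios
#'
#' Given observed and predicted responses over (cell line, drug, dose)
#' combinations, computes the mean absolute error and four accuracies,
#' where "most effective" always means the lowest (observed resp.
#' predicted) normalized response:
#' (a) the best drug-dose pair per cell line;
#' (b) the best drug per cell line (the drug attaining the lowest response
#'     over its tested doses; skipped for cell lines with a single drug);
#' (c) the best dose per experimental unit (cell line-drug pair);
#' (d) the best dose range per unit, split at 31.25\% of the maximum dose.
#' Accuracy is the percentage of cell lines (a, b) or units (c, d) whose
#' predicted argmin matches the observed argmin; ties resolve to the first
#' row in input order for both.
#'
#' @param predictions data.frame with columns `cell_line`, `drug`, `dose`
#'   (dose fraction), `observed`, `predicted`.
#' @param dose_split dose-fraction split for scenario (d), default 0.3125.
#' @return List with `mae` and `accuracy` (named numeric, percent:
#'   `drug_dose`, `drug`, `dose`, `dose_range`).
#' @export
evaluate_predictions <- function(predictions, dose_split = 0.3125) {
  req <- c("cell_line", "drug", "dose", "observed", "predicted")
  stopifnot(all(req %in% names(predictions)))
  p <- predictions
  mae <- mean(abs(p$observed - p$predicted))
  unit_key <- paste(p$cell_line, p$drug, sep = "\r")

  # (a) best drug-dose pair per cell line
  by_cl <- split(seq_len(nrow(p)), p$cell_line)
  acc_a <- mean(vapply(by_cl, function(idx) {
    idx[which.min(p$observed[idx])] == idx[which.min(p$predicted[idx])]
  }, logical(1)))

  # (b) best drug per cell line (min over each drug's doses)
  acc_b_parts <- vapply(by_cl, function(idx) {
    drugs <- unique(p$drug[idx])
    if (length(drugs) < 2L) return(NA)
    obs_min <- vapply(drugs, function(dr) min(p$observed[idx][p$drug[idx] == dr]),
                      numeric(1))
    pred_min <- vapply(drugs, function(dr) min(p$predicted[idx][p$drug[idx] == dr]),
                       numeric(1))
    drugs[which.min(obs_min)] == drugs[which.min(pred_min)]
  }, logical(1))
  acc_b <- mean(acc_b_parts, na.rm = TRUE)

  # (c) best dose per unit; (d) best dose range per unit
  by_unit <- split(seq_len(nrow(p)), unit_key)
  cd <- vapply(by_unit, function(idx) {
    io <- idx[which.min(p$observed[idx])]
    ip <- idx[which.min(p$predicted[idx])]
    c(io == ip,
      (p$dose[io] <= dose_split) == (p$dose[ip] <= dose_split))
  }, logical(2))
  list(mae = mae,
       accuracy = c(drug_dose = 100 * acc_a,
                    drug = 100 * acc_b,
                    dose = 100 * mean(cd[1L, ]),
                    dose_range = 100 * mean(cd[2L, ])))
}

#' Predictive evaluation of a fit on a (held-out) panel
#'
#' Convenience wrapper building the prediction table from a fitted model
#' and a panel and delegating to [evaluate_predictions()].
#'
#' @param fit a `gscad_fit`.
#' @param panel a `dose_panel` whose covariates were encoded with the
#'   training codebook.
#' @param dose_split see [evaluate_predictions()].
#' @return See [evaluate_predictions()].
#' @export
evaluate_fit <- function(fit, panel, dose_split = 0.3125) {
  row_unit <- panel$obs$unit
  tab <- data.frame(
    cell_line = panel$units$cell_line_id[row_unit],
    drug = panel$units$drug_id[row_unit],
    dose = panel$obs$dose,
    observed = panel$obs$y,
    predicted = predict_panel(fit, panel)
  )
  evaluate_predictions(tab, dose_split = dose_split)
}

#' Sigmoid (4-parameter logistic) IC50 from a predicted dose-response curve
#'
#' Least-squares fit of `y(d) = lower + (upper - lower) / (1 + (d/m)^h)`
#' to a dose-response curve; the midpoint `m` is the IC50 on the dose-
#' fraction scale. When the fitted curve never crosses the half-viability
#' level inside the observed dose domain (for instance, a flat curve), the
#' returned IC50 is clipped to the domain and flagged as extrapolated.
#'
#' @param d dose fractions (>= 4 points).
#' @param y response values at `d`.
#' @return List with `ic50`, `hill`, `lower`, `upper`, `extrapolated`.
#' @export
fit_sigmoid_ic50 <- function(d, y) {
  stopifnot(length(d) >= 4L, length(d) == length(y))
  if (any(!is.finite(y))) stop("non-finite curve values")
  rng <- range(d)
  if (stats::sd(y) < 1e-12) {
    return(list(ic50 = rng[2L], hill = NA_real_, lower = min(y),
                upper = max(y), extrapolated = TRUE))
  }
  mid <- (min(y) + max(y)) / 2
  m0 <- d[which.min(abs(y - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + (d / m)^h),
      start = list(lower = min(y), upper = max(y),
                   m = max(m0, 1e-4), h = 1),
      lower = c(-Inf, -Inf, 1e-8, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(ic50 = rng[2L], hill = NA_real_, lower = min(y),
                upper = max(y), extrapolated = TRUE))
  }
  cf <- stats::coef(fit)
  m <- unname(cf["m"])
  extrapolated <- m < rng[1L] || m > rng[2L] ||
    abs(cf["upper"] - cf["lower"]) < 1e-8
  list(ic50 = unname(min(max(m, rng[1L]), rng[2L])),
       hill = unname(cf["h"]),
       lower = unname(cf["lower"]),
       upper = unname(cf["upper"]),
       extrapolated = extrapolated)
}
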