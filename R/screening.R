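#' Screening threshold from the sample-size fraction rule
#'
#' `tau_n = floor(nu * n / log(n))` with the natural logarithm; `n` counts
#' experimental units. At the reference panel size n = 3805 and nu = 2 this
#' gives 923 retained genes.
#'
#' @param n number of experimental units (>= 2).
#' @param nu positive integer multiplier.
#' @return Integer threshold.
#' @examples
#' screening_threshold(3805, 2) # 923
#' @export
screening_threshold <- function(n, nu) {
  stopifnot(n >= 2, nu >= 1)
  as.integer(floor(nu * n / log(n) + 1e-9))
}

#' Fit the marginal dose-varying model for one gene
#'
#' Weighted least squares of the response on the z-covariate spline blocks
#' plus the single gene's spline block, under the whitened objective implied
#' by the weight model.
#'
#' @param panel a `dose_panel`.
#' @param basis a `dose_basis`.
#' @param gene gene column (index or name) of `panel$X`.
#' @param model a `weight_model`.
#' @return List with `zeta` (matrix L x (p+1)), `eta` (length-L gene
#'   coefficients), `fitted` (on the original, unwhitened scale is not
#'   returned; `fitted_w` is on the whitened scale), `utility`.
#' @export
fit_marginal_model <- function(panel, basis, gene, model) {
  wh <- whiten_panel(panel, basis, model)
  if (is.character(gene)) gene <- match(gene, colnames(panel$X))
  fit <- marginal_fit_one(wh, panel, gene)
  fit
}

# Workhorse shared with screen_genes: wh is a whiten_panel() cache.
marginal_fit_one <- function(wh, panel, gene) {
  x <- panel$X[wh$unit_of_row, gene]
  drop_gene <- all(x == 0)
  Xg <- if (drop_gene) NULL else x * wh$Bw
  M <- cbind(wh$Zw, Xg)
  fit <- stats::.lm.fit(M, wh$yw)
  if (fit$rank < ncol(M)) stop("singular marginal fit for gene ", gene)
  L <- wh$basis$L
  nz <- ncol(wh$Zw)
  coefs <- fit$coefficients
  if (!is.null(fit$pivot)) coefs[fit$pivot] <- fit$coefficients
  zeta <- matrix(coefs[seq_len(nz)], nrow = L,
                 dimnames = list(NULL, wh$blocks$label))
  eta <- if (drop_gene) rep(0, L) else coefs[nz + seq_len(L)]
  res <- fit$residuals
  list(gene = gene, zeta = zeta, eta = as.numeric(eta),
       fitted_w = wh$yw - res,
       utility = sum(res^2) / length(panel$unit_rows))
}

#' Weighted mean squared error utility of a candidate marginal fit
#'
#' `u = (1/n) sum_i (y_i - yhat_i)' W_i (y_i - yhat_i)`; smaller utilities
#' indicate stronger marginal association.
#'
#' @param panel a `dose_panel`.
#' @param fitted fitted responses, one per observation (panel row order).
#' @param model a `weight_model`.
#' @return Scalar utility.
#' @export
compute_utility <- function(panel, fitted, model) {
  stopifnot(length(fitted) == nrow(panel$obs))
  r <- panel$obs$y - fitted
  u <- 0
  for (i in seq_along(panel$unit_rows)) {
    rows <- panel$unit_rows[[i]]
    W <- build_weight_matrix(model, panel$obs$dose[rows])
    u <- u + as.numeric(crossprod(r[rows], W %*% r[rows]))
  }
  u / length(panel$unit_rows)
}

#' Rank utilities and retain the screened set
#'
#' Genes are sorted by ascending utility (ties broken by ascending gene
#' index, for determinism) and the first `min(tau, G)` retained.
#'
#' @param utilities numeric vector of per-gene utilities.
#' @param tau screening threshold (>= 1).
#' @return Object of class `screening_result` with `utilities`, `ranking`
#'   (permutation of gene indices, best first), `screened` (retained gene
#'   indices, in ranking order), `tau`.
#' @export
rank_and_screen <- function(utilities, tau) {
  stopifnot(tau >= 1)
  G <- length(utilities)
  ranking <- order(utilities, seq_len(G))
  screened <- ranking[seq_len(min(tau, G))]
  structure(list(utilities = utilities, ranking = ranking,
                 screened = screened, tau = as.integer(tau)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening: %d of %d genes retained (tau = %d)\n",
              length(x$screened), length(x$utilities), x$tau))
  invisible(x)
}

#' Stage one: marginal screening of all genes
#'
#' Fits the marginal dose-varying model of every gene under the whitened
#' weighted objective, computes the utilities and returns the ranked,
#' thresholded screening result. The weight model is estimated once (from
#' the z-only fit) and shared across genes.
#'
#' @param panel a `dose_panel`.
#' @param basis a `dose_basis`.
#' @param model a `weight_model`.
#' @param nu threshold multiplier (used when `tau` is `NULL`).
#' @param tau explicit threshold, overriding the `nu` rule.
#' @return A `screening_result` (see [rank_and_screen()]); the utilities
#'   are named by gene.
#' @export
screen_genes <- function(panel, basis, model, nu = 2, tau = NULL) {
  wh <- whiten_panel(panel, basis, model)
  G <- ncol(panel$X)
  n <- length(panel$unit_rows)
  u <- numeric(G)
  for (g in seq_len(G)) {
    x <- panel$X[wh$unit_of_row, g]
    M <- cbind(wh$Zw, x * wh$Bw)
    fit <- stats::.lm.fit(M, wh$yw)
    u[g] <- sum(fit$residuals^2) / n
  }
  names(u) <- colnames(panel$X)
  if (is.null(tau)) tau <- screening_threshold(n, nu)
  rank_and_screen(u, tau)
}

#' Screening result as a ranking table
#'
#' @param result a `screening_result`.
#' @return data.frame with columns `gene`, `utility`, `rank`, `screened`.
#' @export
screening_table <- function(result) {
  stopifnot(inherits(result, "screening_result"))
  G <- length(result$utilities)
  rk <- integer(G)
  rk[result$ranking] <- seq_len(G)
  gene <- names(result$utilities)
  if (is.null(gene)) gene <- as.character(seq_len(G))
  data.frame(gene = gene,
             utility = as.numeric(result$utilities),
             rank = rk,
             screened = as.integer(seq_len(G) %in% result$screened))
}
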