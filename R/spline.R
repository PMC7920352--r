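#' Rule-of-thumb number of interior knots
#'
#' `floor(n^(1 / (2q + 3)))` for sample size `n` and spline degree `q`, the
#' usual rate-optimal knot count for basis-approximation smoothing of
#' varying-coefficient models. Callers may always override with an explicit
#' count; the package default configuration is one interior knot with cubic
#' splines.
#'
#' @param n sample size.
#' @param degree spline degree (q >= 1).
#' @return Integer knot count (>= 1).
#' @examples
#' interior_knot_count(512, 3) # 2
#' @export
interior_knot_count <- function(n, degree) {
  stopifnot(n >= 1, degree >= 1)
  # guard against pow() landing infinitesimally below an exact integer
  max(1L, as.integer(floor(n^(1 / (2 * degree + 3)) + 1e-9)))
}

#' Interior knot locations from observed dose fractions
#'
#' For `K = 1` the knot sits at the median of the pooled observed doses; for
#' `K > 1` knots sit at the equally spaced sample quantiles `i / (K + 1)`.
#'
#' @param doses numeric vector of observed dose fractions (pooled over units).
#' @param K number of interior knots (>= 1).
#' @return Numeric vector of `K` interior knot locations.
#' @export
knots_from_data <- function(doses, K) {
  stopifnot(K >= 1)
  if (length(unique(doses)) < 2L) {
    stop("degenerate dose domain: fewer than 2 distinct doses")
  }
  if (K == 1L) {
    stats::median(doses)
  } else {
    unname(stats::quantile(doses, probs = seq_len(K) / (K + 1)))
  }
}

#' Construct a clamped B-spline basis over the dose domain
#'
#' Standard clamped (repeated-boundary-knot) B-splines of the given degree.
#' With `K` interior knots the basis has `L = K + degree + 1` functions;
#' they are nonnegative and sum to one everywhere on the domain.
#'
#' @param degree spline degree (default 3, cubic).
#' @param interior numeric vector of interior knot locations (may be empty).
#' @param boundary length-2 numeric, the domain endpoints.
#' @return An object of class `dose_basis` with fields `degree`, `interior`,
#'   `boundary`, `knots` (full clamped knot vector) and `L`.
#' @export
dose_basis <- function(degree = 3, interior = numeric(0), boundary) {
  stopifnot(degree >= 1, length(boundary) == 2L, boundary[1] < boundary[2])
  interior <- sort(as.numeric(interior))
  if (length(interior) &&
      (min(interior) <= boundary[1] || max(interior) >= boundary[2])) {
    stop("interior knots must lie strictly inside the boundary")
  }
  knots <- c(rep(boundary[1], degree + 1L), interior, rep(boundary[2], degree + 1L))
  structure(list(
    degree = as.integer(degree),
    interior = interior,
    boundary = as.numeric(boundary),
    knots = knots,
    L = length(interior) + degree + 1L
  ), class = "dose_basis")
}

#' Basis tailored to a panel's observed doses
#'
#' Convenience wrapper: boundary knots at the min/max observed dose fraction
#' and interior knots from [knots_from_data()].
#'
#' @param panel a `dose_panel`.
#' @param degree spline degree (default 3).
#' @param interior_knots number of interior knots (default 1, knot at the
#'   median observed dose).
#' @return A `dose_basis`.
#' @export
panel_basis <- function(panel, degree = 3, interior_knots = 1) {
  d <- panel$obs$dose
  dose_basis(degree = degree,
             interior = knots_from_data(d, interior_knots),
             boundary = range(d))
}

#' @export
print.dose_basis <- function(x, ...) {
  cat(sprintf("B-spline basis: degree %d, %d interior knot(s), L = %d on [%.4g, %.4g]\n",
              x$degree, length(x$interior), x$L, x$boundary[1], x$boundary[2]))
  invisible(x)
}

#' Evaluate all basis functions at dose fractions
#'
#' @param basis a `dose_basis`.
#' @param d numeric vector of doses within the basis domain (no
#'   extrapolation is supported).
#' @return Matrix `length(d) x L`; rows are nonnegative and sum to 1.
#' @export
evaluate_basis <- function(basis, d) {
  stopifnot(inherits(basis, "dose_basis"))
  if (any(d < basis$boundary[1] - 1e-12) || any(d > basis$boundary[2] + 1e-12)) {
    stop("dose outside basis domain; extrapolation is not supported")
  }
  d <- pmin(pmax(d, basis$boundary[1]), basis$boundary[2])
  splines::splineDesign(knots = basis$knots, x = d, ord = basis$degree + 1L)
}

#' Assemble the varying-coefficient design matrix
#'
#' Stacks, for every observation (unit i, dose j), one block of `L` columns
#' per z-covariate (entries `z_ik * B_l(d_ij)`) followed by one block of `L`
#' columns per requested gene (entries `x_ig * B_l(d_ij)`).
#'
#' @param panel a `dose_panel`.
#' @param basis a `dose_basis`.
#' @param genes integer or character vector of gene columns of `panel$X` to
#'   include (may be empty for the low-dimensional design).
#' @return List with `X` (design matrix), `blocks` (data.frame: block label,
#'   type, first and last column), `basis`, `genes`.
#' @export
build_vc_design <- function(panel, basis, genes = integer(0)) {
  stopifnot(inherits(panel, "dose_panel"), inherits(basis, "dose_basis"))
  if (is.character(genes)) genes <- match(genes, colnames(panel$X))
  genes <- as.integer(genes)
  if (anyNA(genes)) stop("unknown gene in design request")
  B <- evaluate_basis(basis, panel$obs$dose)
  L <- basis$L
  zn <- colnames(panel$Z)
  if (is.null(zn)) zn <- paste0("z", seq_len(ncol(panel$Z)) - 1L)
  gn <- colnames(panel$X)[genes]
  unit_of_row <- panel$obs$unit
  nblocks <- ncol(panel$Z) + length(genes)
  X <- matrix(0, nrow(panel$obs), nblocks * L)
  labels <- character(nblocks)
  types <- character(nblocks)
  col <- 0L
  for (k in seq_len(ncol(panel$Z))) {
    X[, col + seq_len(L)] <- panel$Z[unit_of_row, k] * B
    labels[k] <- zn[k]
    types[k] <- "z"
    col <- col + L
  }
  for (j in seq_along(genes)) {
    X[, col + seq_len(L)] <- panel$X[unit_of_row, genes[j]] * B
    labels[ncol(panel$Z) + j] <- gn[j]
    types[ncol(panel$Z) + j] <- "gene"
    col <- col + L
  }
  blocks <- data.frame(
    label = labels, type = types,
    first = (seq_len(nblocks) - 1L) * L + 1L,
    last = seq_len(nblocks) * L
  )
  colnames(X) <- paste(rep(labels, each = L), rep(seq_len(L), nblocks), sep = ".b")
  list(X = X, blocks = blocks, basis = basis, genes = genes)
}
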