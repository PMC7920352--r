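#' Normalize a raw viability response against blank and zero-dose control
#'
#' Rescales a raw fluorescence readout `R` to the unitless viability scale
#' using the plate blank `BR` (no cells) and the zero-dose control `CR`
#' (cells, no drug): `(R - BR) / (CR - BR)`. A value of 1 corresponds to
#' untreated growth and 0 to the blank. Values are deliberately not clamped
#' to \[0, 1\]: assay noise can legitimately push observations outside that
#' interval and truncation would bias downstream fits.
#'
#' @param R numeric vector of raw responses (fluorescence units).
#' @param BR blank response(s), same units as `R`; scalar or vector.
#' @param CR zero-dose control response(s); scalar or vector.
#' @return Numeric vector of normalized responses.
#' @examples
#' normalize_response(5, 1, 9) # 0.5
#' @export
normalize_response <- function(R, BR, CR) {
  stopifnot(is.numeric(R), is.numeric(BR), is.numeric(CR))
  if (any(CR == BR)) {
    stop("degenerate control: CR == BR for at least one record")
  }
  if (any(CR < BR)) {
    stop("invalid unit: control response below blank (CR < BR)")
  }
  (R - BR) / (CR - BR)
}

#' Rescale an administered dose to a fraction of the drug's maximum dose
#'
#' Drugs in a panel are screened up to drug-specific maximum concentrations;
#' dose fractions in (0, 1] put all drugs on a common axis.
#'
#' @param dose administered concentration (same units as `max_dose`).
#' @param max_dose maximum screening concentration for the drug.
#' @return `dose / max_dose`, in (0, 1].
#' @examples
#' rescale_dose(2.5, 10) # 0.25
#' @export
rescale_dose <- function(dose, max_dose) {
  stopifnot(is.numeric(dose), is.numeric(max_dose))
  if (any(dose <= 0)) stop("dose must be strictly positive")
  if (any(dose > max_dose)) stop("dose exceeds max_dose")
  dose / max_dose
}

#' Build a covariate codebook with reference levels
#'
#' Records, for every annotation factor (drug, tissue, mutation flag, ...),
#' its observed levels and the reference level that maps to the model
#' baseline. Encoding is treatment (dummy) coding: a unit at the reference
#' level of every factor has covariate vector z = (1, 0, ..., 0).
#'
#' @param annotations data.frame with a `unit_id` column and one column per
#'   factor (character or factor valued).
#' @param reference optional named list/character vector giving the reference
#'   level per factor; defaults to the first level in sort order.
#' @return An object of class `covariate_codebook`.
#' @export
covariate_codebook <- function(annotations, reference = NULL) {
  stopifnot(is.data.frame(annotations), "unit_id" %in% names(annotations))
  fac_cols <- setdiff(names(annotations), "unit_id")
  if (length(fac_cols) == 0L) stop("no annotation factors present")
  factors <- lapply(fac_cols, function(fc) {
    lev <- sort(unique(as.character(annotations[[fc]])))
    ref <- if (!is.null(reference) && fc %in% names(reference)) {
      as.character(reference[[fc]])
    } else {
      lev[1L]
    }
    if (!ref %in% lev) {
      stop(sprintf("reference level '%s' not observed for factor '%s'", ref, fc))
    }
    list(levels = lev, reference = ref)
  })
  names(factors) <- fac_cols
  structure(list(factors = factors), class = "covariate_codebook")
}

#' @export
print.covariate_codebook <- function(x, ...) {
  cat("Covariate codebook:\n")
  for (fc in names(x$factors)) {
    f <- x$factors[[fc]]
    cat(sprintf("  %s: %d levels, reference '%s'\n",
                fc, length(f$levels), f$reference))
  }
  invisible(x)
}

#' Encode unit annotations as dummy covariate vectors
#'
#' Produces the low-dimensional covariate matrix Z (one row per unit, first
#' column an intercept of ones) under the treatment coding stored in the
#' codebook. Each non-reference level of each factor contributes one 0/1
#' column.
#'
#' @param annotations data.frame with `unit_id` plus the codebook's factors.
#' @param codebook a [covariate_codebook()].
#' @return Numeric matrix with `nrow(annotations)` rows and p + 1 columns;
#'   rownames are unit ids.
#' @export
encode_covariates <- function(annotations, codebook) {
  stopifnot(inherits(codebook, "covariate_codebook"))
  fac_cols <- names(codebook$factors)
  missing_cols <- setdiff(fac_cols, names(annotations))
  if (length(missing_cols)) {
    stop("annotations lack factor column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(annotations)
  cols <- list(intercept = rep(1, n))
  for (fc in fac_cols) {
    f <- codebook$factors[[fc]]
    vals <- as.character(annotations[[fc]])
    unseen <- setdiff(unique(vals), f$levels)
    if (length(unseen)) {
      stop(sprintf("factor '%s' has level(s) not in codebook: %s",
                   fc, paste(unseen, collapse = ", ")))
    }
    for (lev in setdiff(f$levels, f$reference)) {
      cols[[paste(fc, lev, sep = "=")]] <- as.numeric(vals == lev)
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- as.character(annotations$unit_id)
  Z
}

#' Assemble a dose-response panel from raw assay records
#'
#' Joins long-format raw assay records with a cell-line expression matrix and
#' unit annotations into the panel object consumed by all modelling
#' functions. Responses are normalized with [normalize_response()], doses
#' rescaled to fractions of the per-drug maximum, and gene expression columns
#' standardized (mean 0, sd 1 across cell lines) so that screening utilities
#' and group penalties are scale-fair. Zero-dose rows (dose <= 0) serve only
#' to supply the control response and never enter the modeled observations.
#'
#' Units whose control does not exceed the blank (CR <= BR) and units with
#' fewer than two positive-dose observations are dropped with a warning.
#'
#' @param records data.frame with columns `unit_id`, `cell_line_id`,
#'   `drug_id`, `dose`, `max_dose`, `response`, `blank`, `control`. The
#'   `control` entry may be `NA` when the unit carries a zero-dose row whose
#'   `response` is the control readout.
#' @param expression numeric matrix, cell lines x genes, with rownames the
#'   cell-line ids and colnames the gene names (raw, unstandardized scale).
#' @param annotations data.frame with `unit_id` plus factor columns.
#' @param codebook optional [covariate_codebook()]; built from `annotations`
#'   with default references when `NULL`.
#' @param standardize_expression standardize gene columns (default `TRUE`).
#' @return An object of class `dose_panel`: a list with elements `obs`
#'   (data.frame `unit`, `dose`, `y`; doses strictly increasing within
#'   unit), `units` (unit_id, cell_line_id, drug_id), `Z`, `X` (unit-level
#'   expression, standardized), `expression` (raw cell-line matrix),
#'   `x_center`, `x_scale`, `annotations`, `codebook`, `unit_rows`.
#' @export
assemble_panel <- function(records, expression, annotations, codebook = NULL,
                           standardize_expression = TRUE) {
  req <- c("unit_id", "cell_line_id", "drug_id", "dose", "max_dose",
           "response", "blank", "control")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  records$unit_id <- as.character(records$unit_id)
  records$cell_line_id <- as.character(records$cell_line_id)
  records$drug_id <- as.character(records$drug_id)

  # canonical unit order: panels are invariant to input row order
  unit_ids <- sort(unique(records$unit_id))
  keep_obs <- vector("list", length(unit_ids))
  unit_meta <- vector("list", length(unit_ids))
  dropped <- character(0)
  for (k in seq_along(unit_ids)) {
    uid <- unit_ids[k]
    rec <- records[records$unit_id == uid, , drop = FALSE]
    cl <- unique(rec$cell_line_id)
    dr <- unique(rec$drug_id)
    if (length(cl) != 1L || length(dr) != 1L) {
      stop(sprintf("unit '%s' maps to multiple cell lines or drugs", uid))
    }
    BR <- unique(rec$blank)
    if (length(BR) != 1L) stop(sprintf("unit '%s' has non-constant blank", uid))
    CR <- unique(rec$control[!is.na(rec$control)])
    zero_rows <- rec$dose <= 0
    if (length(CR) == 0L && any(zero_rows)) CR <- rec$response[zero_rows][1L]
    if (length(CR) != 1L) {
      stop(sprintf("unit '%s': control response missing or non-constant", uid))
    }
    dosed <- rec[!zero_rows, , drop = FALSE]
    if (CR <= BR) {
      dropped <- c(dropped, uid)
      next
    }
    if (nrow(dosed) < 2L) {
      dropped <- c(dropped, uid)
      next
    }
    d <- rescale_dose(dosed$dose, dosed$max_dose)
    if (anyDuplicated(d)) {
      stop(sprintf("unit '%s' has duplicated dose fractions", uid))
    }
    o <- order(d)
    keep_obs[[k]] <- data.frame(
      unit_id = uid,
      dose = d[o],
      y = normalize_response(dosed$response[o], BR, CR)
    )
    unit_meta[[k]] <- data.frame(unit_id = uid, cell_line_id = cl, drug_id = dr)
  }
  if (length(dropped)) {
    warning("dropped unit(s) with degenerate control or < 2 positive doses: ",
            paste(dropped, collapse = ", "))
  }
  unit_meta <- do.call(rbind, unit_meta[!vapply(unit_meta, is.null, TRUE)])
  if (is.null(unit_meta) || nrow(unit_meta) == 0L) stop("no usable units")
  obs <- do.call(rbind, keep_obs[!vapply(keep_obs, is.null, TRUE)])

  missing_cl <- setdiff(unique(unit_meta$cell_line_id), rownames(expression))
  if (length(missing_cl)) {
    stop("cell line(s) absent from expression matrix: ",
         paste(missing_cl, collapse = ", "))
  }
  annotations$unit_id <- as.character(annotations$unit_id)
  if (!all(unit_meta$unit_id %in% annotations$unit_id)) {
    stop("annotations missing for some units")
  }
  ann <- annotations[match(unit_meta$unit_id, annotations$unit_id), ,
                     drop = FALSE]
  if (is.null(codebook)) codebook <- covariate_codebook(ann)
  Z <- encode_covariates(ann, codebook)

  if (standardize_expression) {
    x_center <- colMeans(expression)
    x_scale <- apply(expression, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xstd <- sweep(sweep(expression, 2L, x_center), 2L, x_scale, "/")
  } else {
    x_center <- rep(0, ncol(expression))
    x_scale <- rep(1, ncol(expression))
    names(x_center) <- names(x_scale) <- colnames(expression)
    Xstd <- expression
  }
  X <- Xstd[unit_meta$cell_line_id, , drop = FALSE]
  rownames(X) <- unit_meta$unit_id

  obs$unit <- match(obs$unit_id, unit_meta$unit_id)
  obs <- obs[order(obs$unit, obs$dose), c("unit", "dose", "y")]
  rownames(obs) <- NULL
  unit_rows <- split(seq_len(nrow(obs)), obs$unit)

  structure(list(
    obs = obs,
    units = unit_meta,
    Z = Z,
    X = X,
    expression = expression,
    x_center = x_center,
    x_scale = x_scale,
    annotations = ann,
    codebook = codebook,
    unit_rows = unname(unit_rows)
  ), class = "dose_panel")
}

#' Construct a dose_panel directly from model-scale components
#'
#' Lower-level constructor used by the synthetic-data generator and by tests
#' that already hold normalized responses and dose fractions.
#'
#' @param obs data.frame with columns `unit` (1..n), `dose` (fraction in
#'   (0,1\]) and `y` (normalized response).
#' @param units data.frame with `unit_id`, `cell_line_id`, `drug_id`.
#' @param Z covariate matrix (n x (p+1), first column ones).
#' @param X unit-level expression matrix (n x G, analysis scale).
#' @param expression optional raw cell-line expression matrix.
#' @param annotations,codebook optional annotation table and codebook.
#' @param x_center,x_scale standardization applied to reach `X`.
#' @return A `dose_panel`.
#' @export
new_dose_panel <- function(obs, units, Z, X, expression = NULL,
                           annotations = NULL, codebook = NULL,
                           x_center = NULL, x_scale = NULL) {
  stopifnot(all(c("unit", "dose", "y") %in% names(obs)),
            nrow(units) == nrow(Z), nrow(Z) == nrow(X),
            all(Z[, 1L] == 1))
  obs <- obs[order(obs$unit, obs$dose), c("unit", "dose", "y")]
  rownames(obs) <- NULL
  for (rows in split(obs$dose, obs$unit)) {
    if (any(diff(rows) <= 0)) stop("dose fractions must be strictly increasing within unit")
  }
  if (is.null(x_center)) x_center <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (is.null(x_scale)) x_scale <- stats::setNames(rep(1, ncol(X)), colnames(X))
  structure(list(
    obs = obs, units = units, Z = Z, X = X,
    expression = expression,
    x_center = x_center, x_scale = x_scale,
    annotations = annotations, codebook = codebook,
    unit_rows = unname(split(seq_len(nrow(obs)), obs$unit))
  ), class = "dose_panel")
}

#' @export
print.dose_panel <- function(x, ...) {
  cat(sprintf("Dose-response panel: %d units, %d observations, %d genes, %d z-covariates\n",
              nrow(x$units), nrow(x$obs), ncol(x$X), ncol(x$Z)))
  cat(sprintf("  dose fractions in [%.4g, %.4g], %d to %d doses per unit\n",
              min(x$obs$dose), max(x$obs$dose),
              min(lengths(x$unit_rows)), max(lengths(x$unit_rows))))
  invisible(x)
}

#' Number of experimental units in a panel
#' @param panel a `dose_panel`.
#' @return Integer count of units.
#' @export
n_units <- function(panel) nrow(panel$units)

#' Serialize a panel to a single JSON file
#'
#' Numbers are written at full IEEE precision so that
#' `read_panel(write_panel(p))` reproduces `p` bit-exactly.
#'
#' @param panel a `dose_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dose_panel"))
  payload <- list(
    format = "dosevc_panel",
    version = 1L,
    obs = panel$obs,
    units = panel$units,
    Z = list(values = unname(panel$Z), colnames = colnames(panel$Z)),
    X = list(values = unname(panel$X), colnames = colnames(panel$X)),
    expression = if (is.null(panel$expression)) NULL else list(
      values = unname(panel$expression),
      rownames = rownames(panel$expression),
      colnames = colnames(panel$expression)
    ),
    x_center = as.list(panel$x_center),
    x_scale = as.list(panel$x_scale),
    annotations = panel$annotations,
    codebook = if (is.null(panel$codebook)) NULL else panel$codebook$factors
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' Read a panel serialized by [write_panel()]
#' @param path file written by [write_panel()].
#' @return A `dose_panel`.
#' @export
read_panel <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
  if (!identical(p$format, "dosevc_panel")) stop("not a dosevc panel file")
  rebuild <- function(m, rn = NULL) {
    mat <- m$values
    if (!is.matrix(mat)) mat <- matrix(mat, ncol = length(m$colnames))
    storage.mode(mat) <- "double"  # whole numbers parse as integer
    colnames(mat) <- m$colnames
    if (!is.null(rn)) rownames(mat) <- rn
    mat
  }
  obs <- as.data.frame(p$obs)
  units <- as.data.frame(p$units)
  Z <- rebuild(p$Z, units$unit_id)
  X <- rebuild(p$X, units$unit_id)
  expression <- NULL
  if (!is.null(p$expression)) {
    expression <- rebuild(p$expression, p$expression$rownames)
  }
  codebook <- NULL
  if (!is.null(p$codebook)) {
    factors <- lapply(p$codebook, function(f) {
      list(levels = as.character(f$levels), reference = as.character(f$reference))
    })
    codebook <- structure(list(factors = factors), class = "covariate_codebook")
  }
  annotations <- if (is.null(p$annotations)) NULL else as.data.frame(p$annotations)
  new_dose_panel(obs, units, Z, X, expression = expression,
                 annotations = annotations, codebook = codebook,
                 x_center = unlist(p$x_center), x_scale = unlist(p$x_scale))
}

# Response vector of one unit, in dose order.
panel_unit_y <- function(panel, i) panel$obs$y[panel$unit_rows[[i]]]

# Dose vector of one unit, in dose order.
panel_unit_d <- function(panel, i) panel$obs$dose[panel$unit_rows[[i]]]
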