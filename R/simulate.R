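#' Coefficient-function shape library for the generator
#'
#' Smooth dose-effect shapes used as ground truth: `"constant"` (`a`),
#' `"linear"` (`a*d`), `"sine"` (`a*sin(pi*d)`) and `"bump"`
#' (`a*exp(-(d - 0.5)^2 / 0.05)`).
#'
#' @param shape one of `"constant"`, `"linear"`, `"sine"`, `"bump"`.
#' @param amplitude scale factor `a`.
#' @return A function of the dose fraction.
#' @export
shape_function <- function(shape = c("constant", "linear", "sine", "bump"),
                           amplitude = 1) {
  shape <- match.arg(shape)
  force(amplitude)
  switch(shape,
         constant = function(d) rep(amplitude, length(d)),
         linear = function(d) amplitude * d,
         sine = function(d) amplitude * sin(pi * d),
         bump = function(d) amplitude * exp(-(d - 0.5)^2 / 0.05))
}

#' Design of a synthetic dose-response study
#'
#' Describes a panel emulating a large drug-screen: experimental units are
#' cell line-drug pairs measured over 2-fold (9 doses) or 4-fold (5 doses)
#' dilution series down from the maximum dose, gene expression is
#' multivariate normal with exchangeable correlation across genes, a small
#' active gene set has smooth dose-varying effects, and the within-unit
#' errors have dose-increasing variance with an optional rational quadratic
#' correlation.
#'
#' @param n number of experimental units.
#' @param G number of genes.
#' @param active number of active genes, or an explicit index vector.
#' @param active_shapes character vector of shapes for the active genes
#'   (recycled from the library order when `NULL`).
#' @param amplitude effect amplitude(s) for the active genes (recycled;
#'   default alternates +1/-1 so the panel carries both resistance- and
#'   sensitization-type effects). Each true effect function is the library
#'   shape rescaled to unit root-mean-square over the design's pooled dose
#'   distribution, so an amplitude of `a` always means a per-unit-SD
#'   expression change shifts the response by `a` response-SD-equivalents
#'   on average over the tested doses, regardless of shape.
#' @param n_drugs,n_tissues numbers of drug and tissue levels encoded in z.
#' @param n_cell_lines size of the cell-line pool units are drawn from;
#'   default `ceiling(0.9 * n)`, emulating a subsample of a large screen in
#'   which nearly every unit comes from a distinct cell line while some
#'   cell lines recur across drugs.
#' @param nine_point_fraction fraction of units on the 9-point 2-fold
#'   series (the rest use the 5-point 4-fold series); default 0.66.
#' @param sigma baseline error SD; the error variance is
#'   `V(d) = sigma^2 * (1 + d)^2` (dose-increasing, as in heteroscedastic
#'   viability assays).
#' @param correlation `"rational_quadratic"` or `"independence"` errors.
#' @param corr_a,corr_l rational quadratic parameters of the error process.
#' @param rho_x exchangeable correlation of the gene expression vectors.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n = 190L, G = 886L, active = 6L,
                              active_shapes = NULL,
                              amplitude = c(1, -1),
                              n_drugs = 5L, n_tissues = 3L,
                              n_cell_lines = NULL,
                              nine_point_fraction = 0.66,
                              sigma = 0.1,
                              correlation = c("rational_quadratic",
                                              "independence"),
                              corr_a = 2, corr_l = 0.3, rho_x = 0.2) {
  correlation <- match.arg(correlation)
  stopifnot(G >= 1, n >= 2, rho_x >= 0, rho_x < 1, sigma >= 0)
  if (length(active) == 1L && active <= G) {
    n_active <- as.integer(active)
  } else {
    n_active <- length(active)
  }
  if (is.null(active_shapes)) {
    # paired shapes: with the default alternating +1/-1 amplitudes each
    # shape appears once up- and once down-regulating, so the aggregate
    # expression-response association over the active set is null and no
    # global confound leaks through correlated inactive genes
    active_shapes <- rep(rep(c("constant", "linear", "sine", "bump"),
                             each = 2L), length.out = n_active)
  }
  structure(list(
    n = as.integer(n), G = as.integer(G), active = active,
    active_shapes = rep(active_shapes, length.out = n_active),
    amplitude = rep(amplitude, length.out = n_active),
    n_drugs = as.integer(n_drugs), n_tissues = as.integer(n_tissues),
    n_cell_lines = if (is.null(n_cell_lines)) ceiling(0.9 * n) else
      as.integer(n_cell_lines),
    nine_point_fraction = nine_point_fraction,
    sigma = sigma, correlation = correlation,
    corr_a = corr_a, corr_l = corr_l, rho_x = rho_x
  ), class = "simulation_design")
}

# True z-covariate coefficient functions: a declining intercept trajectory
# plus modest smooth offsets for the drug and tissue dummies.
design_beta_functions <- function(design) {
  p_drug <- design$n_drugs - 1L
  p_tissue <- design$n_tissues - 1L
  fns <- list(function(d) 1 - 0.6 * d)
  for (j in seq_len(p_drug)) {
    local({
      s <- 0.25 * (-1)^j
      fns[[length(fns) + 1L]] <<- function(d) s * d
    })
  }
  for (j in seq_len(p_tissue)) {
    local({
      s <- 0.15 * (-1)^j
      fns[[length(fns) + 1L]] <<- function(d) s * sin(pi * d / 2)
    })
  }
  fns
}

# RMS of a raw shape over the pooled observation-level dose distribution of
# the design (9-point 2-fold and 5-point 4-fold series, mixture-weighted).
shape_rms <- function(shape, design) {
  d9 <- 2^(-(8:0))
  d5 <- 4^(-(4:0))
  f <- shape_function(shape, amplitude = 1)
  w <- design$nine_point_fraction
  sqrt(w * mean(f(d9)^2) + (1 - w) * mean(f(d5)^2))
}

# Truth effect functions: library shapes normalized to unit RMS over the
# design's dose distribution, scaled by the (signed) amplitudes.
design_gamma_functions <- function(design) {
  mapply(function(sh, am) {
    s <- am / shape_rms(sh, design)
    f <- shape_function(sh, amplitude = 1)
    function(d) s * f(d)
  }, design$active_shapes, design$amplitude, SIMPLIFY = FALSE)
}

#' Simulate a dose-response panel with known truth
#'
#' Generates responses from the dose-varying coefficient model
#' `y_ij = sum_k z_ik beta_k(d_ij) + sum_{g in A} x_ig gamma_g(d_ij) +
#' e_ij` under the given design. Identical seeds give bit-identical panels.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed.
#' @return List with `panel` (a `dose_panel`) and `truth` (active gene
#'   indices, shape/amplitude per active gene, the beta and gamma functions
#'   and the noiseless mean response per observation).
#' @export
simulate_panel <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  n <- design$n
  G <- design$G
  active <- if (length(design$active) == 1L) {
    sort(sample.int(G, design$active))
  } else {
    sort(as.integer(design$active))
  }
  n_cl <- max(design$n_cell_lines, ceiling(n / design$n_drugs) + 1L)
  combos <- expand.grid(cl = seq_len(n_cl), drug = seq_len(design$n_drugs))
  pick <- sort(sample.int(nrow(combos), n))
  cl_of_unit <- combos$cl[pick]
  drug_of_unit <- combos$drug[pick]
  tissue_of_cl <- sample.int(design$n_tissues, n_cl, replace = TRUE)

  # exchangeable-correlation expression, standard normal marginals
  shared <- stats::rnorm(n_cl)
  E <- sqrt(design$rho_x) * shared +
    sqrt(1 - design$rho_x) * matrix(stats::rnorm(n_cl * G), n_cl, G)
  colnames(E) <- sprintf("g%04d", seq_len(G))
  rownames(E) <- sprintf("cl%03d", seq_len(n_cl))

  ann <- data.frame(
    unit_id = sprintf("u%04d", seq_len(n)),
    drug = sprintf("drug%d", drug_of_unit),
    tissue = sprintf("tissue%d", tissue_of_cl[cl_of_unit])
  )
  codebook <- covariate_codebook(
    ann, reference = list(drug = "drug1", tissue = "tissue1"))
  Z <- encode_covariates(ann, codebook)
  beta_fns <- design_beta_functions(design)
  gamma_fns <- design_gamma_functions(design)

  nine <- stats::runif(n) < design$nine_point_fraction
  d9 <- 2^(-(8:0))
  d5 <- 4^(-(4:0))
  wc <- if (design$correlation == "rational_quadratic") {
    new_working_correlation("rational_quadratic",
                            c(a = design$corr_a, l = design$corr_l), NULL)
  } else {
    new_working_correlation("independence", numeric(0), NULL)
  }
  obs_list <- vector("list", n)
  mean_list <- vector("list", n)
  for (i in seq_len(n)) {
    d <- if (nine[i]) d9 else d5
    mu <- numeric(length(d))
    for (k in seq_along(beta_fns)) mu <- mu + Z[i, k] * beta_fns[[k]](d)
    for (j in seq_along(active)) {
      mu <- mu + E[cl_of_unit[i], active[j]] * gamma_fns[[j]](d)
    }
    sds <- design$sigma * (1 + d)
    if (design$sigma > 0) {
      Rm <- correlation_matrix(wc, d)
      eps <- sds * as.numeric(t(chol(Rm)) %*% stats::rnorm(length(d)))
    } else {
      eps <- numeric(length(d))
    }
    obs_list[[i]] <- data.frame(unit = i, dose = d, y = mu + eps)
    mean_list[[i]] <- mu
  }
  obs <- do.call(rbind, obs_list)
  units <- data.frame(unit_id = ann$unit_id,
                      cell_line_id = rownames(E)[cl_of_unit],
                      drug_id = ann$drug)
  panel <- new_dose_panel(obs, units, Z,
                          X = E[cl_of_unit, , drop = FALSE],
                          expression = E,
                          annotations = ann, codebook = codebook)
  rownames(panel$X) <- units$unit_id
  truth <- list(active = active,
                shapes = design$active_shapes,
                amplitude = design$amplitude,
                beta_functions = beta_fns,
                gamma_functions = gamma_fns,
                mean = unlist(mean_list, use.names = FALSE),
                design = design, seed = seed)
  list(panel = panel, truth = truth)
}

#' Confusion counts of a selection against the true active set
#'
#' @param selected selected gene indices.
#' @param active true active gene indices.
#' @param G total number of genes.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN` (sums to `G`).
#' @export
evaluate_selection <- function(selected, active, G) {
  selected <- as.integer(selected)
  active <- as.integer(active)
  if (length(selected) && (min(selected) < 1L || max(selected) > G)) {
    stop("selected indices outside 1..G")
  }
  if (length(active) && (min(active) < 1L || max(active) > G)) {
    stop("active indices outside 1..G")
  }
  TP <- length(intersect(selected, active))
  FP <- length(setdiff(selected, active))
  FN <- length(setdiff(active, selected))
  c(TP = TP, FP = FP, TN = G - TP - FP - FN, FN = FN)
}

#' Monte Carlo study of two-stage selection performance
#'
#' Runs the full pipeline (weight estimation, marginal screening at the
#' `floor(nu * n / log n)` threshold, cross-validated group-SCAD selection)
#' on repeated synthetic panels and aggregates confusion counts per
#' scenario. Panels are shared across scenarios within a replicate (paired
#' comparisons); per-replicate seeds are drawn once from the master seed.
#'
#' @param design a [simulation_design()].
#' @param reps number of replicates.
#' @param scenarios data.frame with columns `nu` and `structure`; default:
#'   nu in \{1, 2\} crossed with the design's correlation structure.
#' @param seed master seed.
#' @param nlambda,folds tuning controls passed to [cv_gscad()].
#' @return List with `summary` (per scenario: mean and SD of TP/FP/TN/FN,
#'   screening coverage rate, mean TPR and FPR) and `details` (one row per
#'   scenario x replicate).
#' @export
run_simulation_study <- function(design, reps = 50L, scenarios = NULL,
                                 seed = 1L, nlambda = 50L, folds = 5L) {
  stopifnot(reps >= 1)
  if (is.null(scenarios)) {
    scenarios <- expand.grid(nu = c(1, 2),
                             structure = design$correlation,
                             stringsAsFactors = FALSE)
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  details <- vector("list", nrow(scenarios) * reps)
  row <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_panel(design, seed = rep_seeds[r])
    panel <- sim$panel
    basis <- panel_basis(panel)
    n <- n_units(panel)
    G <- ncol(panel$X)
    for (s in seq_len(nrow(scenarios))) {
      nu <- scenarios$nu[s]
      structure <- as.character(scenarios$structure[s])
      wm <- estimate_weight_model(panel, basis, structure = structure)
      scr <- screen_genes(panel, basis, wm, nu = nu)
      cover <- all(sim$truth$active %in% scr$screened)
      cv <- cv_gscad(panel, basis, scr$screened, wm,
                     nlambda = nlambda, folds = folds,
                     seed = rep_seeds[r] %% 1000000L + 1L)
      conf <- evaluate_selection(cv$fit$selected, sim$truth$active, G)
      row <- row + 1L
      details[[row]] <- data.frame(
        scenario = s, rep = r, nu = nu, structure = structure,
        tau = scr$tau, screen_cover = cover,
        TP = conf["TP"], FP = conf["FP"], TN = conf["TN"], FN = conf["FN"],
        lambda = cv$lambda, row.names = NULL)
    }
  }
  details <- do.call(rbind, details)
  n_active <- length(if (length(design$active) == 1L)
    seq_len(design$active) else design$active)
  agg <- do.call(rbind, lapply(split(details, details$scenario), function(d) {
    data.frame(
      scenario = d$scenario[1L], nu = d$nu[1L], structure = d$structure[1L],
      tau = d$tau[1L],
      screen_coverage = mean(d$screen_cover),
      mean_TP = mean(d$TP), sd_TP = stats::sd(d$TP),
      mean_FP = mean(d$FP), sd_FP = stats::sd(d$FP),
      mean_TN = mean(d$TN), mean_FN = mean(d$FN),
      TPR = mean(d$TP) / n_active,
      FPR = mean(d$FP) / (design$G - n_active))
  }))
  rownames(agg) <- NULL
  list(summary = agg, details = details)
}
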