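# Shared fixture builders; everything is generated in code.

# Long-format raw assay records for a toy screen: `n_units` units on a
# 5-point 4-fold dilution series, plus one zero-dose control row per unit.
toy_records <- function(n_units = 4, max_dose = 10, blank = 1, control = 9,
                        seed = 1) {
  set.seed(seed)
  doses <- max_dose * 4^(-(4:0))
  out <- list()
  for (i in seq_len(n_units)) {
    uid <- sprintf("u%02d", i)
    cl <- sprintf("cl%02d", i)
    drug <- sprintf("drug%d", (i - 1) %% 2 + 1)
    resp <- blank + (control - blank) * (1 - 0.6 * doses / max_dose) +
      rnorm(length(doses), sd = 0.05)
    out[[length(out) + 1L]] <- data.frame(
      unit_id = uid, cell_line_id = cl, drug_id = drug,
      dose = c(0, doses), max_dose = max_dose,
      response = c(control, resp), blank = blank, control = NA_real_)
  }
  do.call(rbind, out)
}

toy_expression <- function(cell_lines, G = 10, seed = 2) {
  set.seed(seed)
  E <- matrix(rnorm(length(cell_lines) * G), length(cell_lines), G,
              dimnames = list(cell_lines, sprintf("g%02d", seq_len(G))))
  E
}

toy_annotations <- function(records) {
  u <- unique(records[, c("unit_id", "drug_id")])
  data.frame(unit_id = u$unit_id, drug = u$drug_id,
             tissue = rep(c("skin", "lung"), length.out = nrow(u)))
}

# A small simulated panel (defaults sized for fast unit tests).
small_sim <- function(n = 50, G = 20, active = 3, sigma = 0.1, seed = 1, ...) {
  simulate_panel(simulation_design(n = n, G = G, active = active,
                                   sigma = sigma, ...), seed = seed)
}
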