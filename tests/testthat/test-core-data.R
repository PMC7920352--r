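test_that("response normalization matches the affine control/blank rescaling", {
  expect_equal(normalize_response(5, 1, 9), 0.5)
  expect_equal(normalize_response(1, 1, 9), 0)   # R == BR
  expect_equal(normalize_response(9, 1, 9), 1)   # R == CR
  # not clamped: values outside [0, 1] are preserved
  expect_gt(normalize_response(11, 1, 9), 1)
  expect_lt(normalize_response(0, 1, 9), 0)
  expect_error(normalize_response(5, 3, 3), "degenerate")
  expect_error(normalize_response(5, 9, 1), "below blank")
})

test_that("normalization is invariant to affine transformations of the assay scale", {
  set.seed(4)
  for (k in 1:20) {
    R <- runif(1, 0, 10); BR <- runif(1, 0, 2); CR <- runif(1, 3, 12)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1); b <- runif(1, -3, 3)
    ref <- normalize_response(R, BR, CR)
    if (a > 0) {
      expect_equal(normalize_response(a * R + b, a * BR + b, a * CR + b), ref)
    } else {
      # negative scale flips blank/control ordering; the ratio is still equal
      expect_equal((a * R + b - (a * BR + b)) / (a * CR + b - (a * BR + b)), ref)
    }
  }
})

test_that("dose rescaling produces fractions of the maximum dose", {
  expect_equal(rescale_dose(10, 10), 1)
  expect_equal(rescale_dose(2.5, 10), 0.25)
  expect_equal(rescale_dose(10 * 2^(-(8:0)), 10), 2^(-(8:0)))
  expect_error(rescale_dose(11, 10), "exceeds")
  expect_error(rescale_dose(0, 10), "positive")
})

test_that("covariate encoding uses treatment coding against the codebook reference", {
  ann <- data.frame(unit_id = c("a", "b", "c"),
                    drug = c("dab", "plx", "dab"),
                    tissue = c("skin", "skin", "lung"))
  cb <- covariate_codebook(ann, reference = list(drug = "dab", tissue = "skin"))
  Z <- encode_covariates(ann, cb)
  expect_equal(dim(Z), c(3L, 3L))          # intercept + 1 drug + 1 tissue dummy
  expect_equal(unname(Z["a", ]), c(1, 0, 0))  # reference unit
  expect_equal(unname(Z["b", ]), c(1, 1, 0))
  expect_equal(unname(Z["c", ]), c(1, 0, 1))
  # permuting rows permutes the encoding, not the values
  Zp <- encode_covariates(ann[c(3, 1, 2), ], cb)
  expect_equal(Zp[rownames(Z), ], Z)
  ann2 <- ann; ann2$drug[1] <- "unknown"
  expect_error(encode_covariates(ann2, cb), "not in codebook")
})

test_that("panel assembly consumes zero-dose rows as controls and drops degenerate units", {
  rec <- toy_records(n_units = 4)
  ann <- toy_annotations(rec)
  E <- toy_expression(unique(rec$cell_line_id), G = 10)
  panel <- assemble_panel(rec, E, ann)
  expect_s3_class(panel, "dose_panel")
  expect_equal(nrow(panel$obs), 4 * 5)      # zero-dose rows excluded
  expect_equal(n_units(panel), 4)
  expect_true(all(vapply(split(panel$obs$dose, panel$obs$unit),
                         function(d) all(diff(d) > 0), TRUE)))
  expect_equal(unname(panel$Z[, 1]), rep(1, 4))

  # a unit whose only record is the zero-dose control is excluded
  extra <- rec[1, ]; extra$unit_id <- "u99"; extra$cell_line_id <- "cl01"
  extra$dose <- 0; extra$response <- 9
  ann99 <- rbind(ann, data.frame(unit_id = "u99", drug = "drug1", tissue = "skin"))
  expect_warning(p2 <- assemble_panel(rbind(rec, extra), E, ann99), "u99")
  expect_equal(n_units(p2), 4)

  # control below blank invalidates the unit
  bad <- rec; bad$response[bad$unit_id == "u01" & bad$dose == 0] <- 0.5
  expect_warning(p3 <- assemble_panel(bad, E, ann), "u01")
  expect_equal(n_units(p3), 3)

  expect_error(assemble_panel(rec, E[-1, , drop = FALSE], ann), "absent")
})

test_that("assembly is invariant to input row order and round-trips through serialization", {
  rec <- toy_records(n_units = 4)
  ann <- toy_annotations(rec)
  E <- toy_expression(unique(rec$cell_line_id), G = 6)
  p1 <- assemble_panel(rec, E, ann)
  set.seed(9)
  p2 <- assemble_panel(rec[sample(nrow(rec)), ], E, ann[sample(nrow(ann)), ])
  expect_equal(nrow(p1$obs), nrow(p2$obs))
  expect_equal(p1$obs, p2$obs)
  expect_equal(p1$Z, p2$Z)
  expect_equal(p1$X, p2$X)

  path <- tempfile(fileext = ".json")
  write_panel(p1, path)
  p3 <- read_panel(path)
  expect_identical(p3$obs$dose, p1$obs$dose)
  expect_identical(p3$obs$y, p1$obs$y)
  expect_identical(unname(p3$Z), unname(p1$Z))
  expect_identical(unname(p3$X), unname(p1$X))
  expect_identical(p3$codebook$factors, p1$codebook$factors)
})

test_that("mixed 9- and 5-point dilution series survive the generator round-trip", {
  sim <- small_sim(n = 30, G = 5, seed = 11)
  ni <- lengths(sim$panel$unit_rows)
  expect_setequal(unique(ni), c(5L, 9L))
  expect_equal(nrow(sim$panel$obs), sum(ni))
})
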