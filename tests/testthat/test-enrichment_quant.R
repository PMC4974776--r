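test_that("natural-abundance pair probability is second order", {
  expect_identical(pair_probability(natural_abundance(0.011)), 0.011^2)
  expect_identical(pair_probability(0), 0)
  expect_identical(pair_probability(0.5), 0.25)
  expect_error(natural_abundance(0.05), "0, 0.02")
  for (p in seq(0.001, 0.019, by = 0.002)) {
    expect_lt(pair_probability(natural_abundance(p)), p)
  }
})

test_that("enrichment inversion handles the boundary pools", {
  expect_equal(enrichment_from_components(c(1, 0, 0, 0), k = 2), 0)
  expect_equal(enrichment_from_components(c(0, 0, 0, 1), k = 2), 1)
  expect_equal(enrichment_from_components(c(0, 0, 0, 0), k = 2), 0)
  # equal singlet and fully coupled areas, k = 2: frozen closed-form value
  expect_equal(enrichment_from_components(c(1, 0, 0, 1), k = 2),
               0.0106448, tolerance = 1e-5)
  expect_error(enrichment_from_components(c(0, 1, 1, 0), k = 2),
               "not the tracer")
  expect_error(enrichment_from_components(c(1, 0, 0), k = 2), "component areas")
})

test_that("X is increasing in the area ratio and bounded in [0, 1]", {
  set.seed(13)
  ratios <- sort(10^runif(50, -4, 4))
  xs <- vapply(ratios, function(r) {
    enrichment_from_components(c(1, 0, 0, r), k = 2)
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
  expect_true(all(xs >= 0 & xs <= 1))
})

test_that("partially labelled species trigger a warning, not a bogus X", {
  # one-labelled-neighbour components far above natural expectation
  expect_warning(
    X <- enrichment_from_components(c(1, 0.5, 0.5, 1), k = 2),
    "partially labelled")
  expect_equal(X, 0.0106448, tolerance = 1e-5)  # mid components excluded
})

test_that("natural-abundance correction removes the pair term at X = 0", {
  na <- natural_abundance(0.011)
  w <- expected_component_weights(0, 2, na)   # pure natural pool
  x_plain <- enrichment_from_components(w, k = 2, na = na)
  x_corr <- enrichment_from_components(w, k = 2, na = na, na_correct = TRUE)
  expect_gt(x_plain, 0)            # pair contamination reads as tiny X
  expect_lt(x_plain, 2e-4)         # ...of order p^2
  expect_equal(x_corr, 0)
  # and at a tracer-level X the two conventions differ by < 2.5% relative
  w5 <- expected_component_weights(0.05, 2, na)
  x5p <- enrichment_from_components(w5, k = 2, na = na)
  x5c <- enrichment_from_components(w5, k = 2, na = na, na_correct = TRUE)
  expect_lt(abs(x5p - x5c) / x5c, 0.025)
  expect_equal(x5c, 0.05, tolerance = 1e-9)
})

test_that("labelled concentration and amount follow the product rule", {
  out <- labelled_amount(0.0325, 1.51, 0.6e-3)
  expect_equal(out$labelled_conc_mm, 0.049075)
  expect_equal(out$amount_nmol, 0.049075 * 0.6 * 1000)

  expect_equal(labelled_amount(0, 5, 1e-3)$amount_nmol, 0)
  # X = 1, 2 mM, 1 mL -> 2 mM labelled, 2000 nmol
  out2 <- labelled_amount(1, 2, 1e-3)
  expect_equal(out2$labelled_conc_mm, 2)
  expect_equal(out2$amount_nmol, 2000)
  expect_error(labelled_amount(-0.1, 1, 1), "non-negative")
  expect_error(labelled_amount(1.2, 1, 1), "exceed 1")
})

test_that("1D ratio quantification is exact on identical peaks and scale-free", {
  ppm <- seq(-0.25, 3, by = 5e-4)
  lor <- function(c0, area, fw = 0.002) {
    area * (fw / 2 / pi) / ((ppm - c0)^2 + (fw / 2)^2)
  }
  y <- lor(0.0, 2 * 9) + lor(1.31, 1.51 * 3)
  sp <- spectrum_1d(ppm, y)
  ref <- list(region = c(-0.05, 0.05), concentration = 2, n_protons = 9)

  # same integral, same proton count -> the reference concentration itself
  sp_id <- spectrum_1d(ppm, lor(0.0, 5) + lor(1.31, 5))
  ref_id <- list(region = c(-0.05, 0.05), concentration = 1.7, n_protons = 3)
  expect_equal(quantify_1d(sp_id, c(1.26, 1.36), 3, ref_id), 1.7,
               tolerance = 1e-6)

  conc <- quantify_1d(sp, c(1.26, 1.36), 3, ref)
  expect_equal(conc, 1.51, tolerance = 0.02)
  sp2 <- spectrum_1d(ppm, 2 * y)
  expect_equal(quantify_1d(sp2, c(1.26, 1.36), 3, ref), conc, tolerance = 1e-12)

  expect_error(quantify_1d(spectrum_1d(ppm, rep(0, length(ppm))),
                           c(1.2, 1.4), 3, ref),
               "not positive")
})

test_that("synthetic 1D spectra quantify within 2% of truth", {
  set.seed(77)
  sp <- hsqcdecon:::synth_1d_spectrum(c("lactate", "alanine"), c(1.51, 0.24))
  win <- default_1d_windows()
  lac <- quantify_1d(sp, c(1.23, 1.39), 3, win$reference)
  ala <- quantify_1d(sp, c(1.39, 1.55), 3, win$reference)
  expect_lt(abs(lac - 1.51) / 1.51, 0.02)
  expect_lt(abs(ala - 0.24) / 0.24, 0.02)
})

test_that("enrichment records are unit-consistent", {
  rec <- enrichment_record("s1", "lactate", 2, 0.0325, 1.51, 0.6e-3)
  expect_equal(rec$labelled_mm, rec$enrichment * rec$total_mm)
  expect_equal(rec$amount_nmol, rec$labelled_mm * rec$volume_l * 1e6)
})
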