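test_that("ring and complex counting follow plain stoichiometric division", {
  expect_equal(rings_per_cell(6.84e6, 32), 213750)
  expect_equal(signif(rings_per_cell(6.84e6, 32), 3), 2.14e5)
  expect_equal(rings_per_cell(32, 32), 1)
  expect_equal(rings_per_cell(6.84e6, 11) * 11, 6.84e6)
  expect_error(rings_per_cell(1e6, 0), class = "mitobell_invalid_parameter")

  expect_equal(complexes_per_crista(0, 11, 0.795, 11510.6), 0)
  # with ring stoichiometry the complex chain reduces to the ring chain
  expect_equal(
    complexes_per_crista(6.84e6, 32, 0.795, 11510.6),
    rings_per_crista(rings_on_cm(rings_per_cell(6.84e6, 32), 0.795),
                     11510.6),
    tolerance = 1e-10)
})

test_that("void correction and cristae count reproduce the measured chain", {
  expect_equal(corrected_crista_spacing(74, 0.21), 74 / 0.79)
  expect_equal(round(corrected_crista_spacing(74, 0.21)), 94)
  expect_equal(corrected_crista_spacing(100, 0), 100)
  expect_equal(corrected_crista_spacing(50, 0.5), 100)
  expect_error(corrected_crista_spacing(74, 1),
               class = "mitobell_invalid_parameter")

  expect_equal(cristae_per_cell(1082, 94), 1082000 / 94)
  expect_equal(trunc(cristae_per_cell(1082, 94)), 11510)
  expect_equal(cristae_per_cell(1, 100), 10)
  expect_equal(cristae_per_cell(1082, 74), 1082000 / 74)
  expect_error(cristae_per_cell(0, 94),
               class = "mitobell_invalid_parameter")
})

test_that("membrane allocation and per-crista counts behave linearly", {
  expect_equal(rings_on_cm(213750, 0.795), 169931.25)
  expect_equal(signif(rings_on_cm(213750, 0.795), 2), 1.7e5)
  expect_equal(rings_on_cm(12345, 1), 12345)
  expect_equal(rings_on_cm(213750, 0.75), 160312.5)
  expect_equal(rings_on_cm(213750, 0.84), 179550)
  expect_error(rings_on_cm(1, 1.2), class = "mitobell_invalid_parameter")

  expect_equal(round(rings_per_crista(1.7e5, 11510)), 15)
  expect_equal(rings_per_crista(0, 11510), 0)
  expect_equal(rings_per_crista(1.7e5, 11510, per_side = TRUE),
               rings_per_crista(1.7e5, 11510) / 2)
  # "7 or 8" per side
  expect_true(rings_per_crista(1.7e5, 11510, per_side = TRUE) > 7 &&
                rings_per_crista(1.7e5, 11510, per_side = TRUE) < 8)
})

test_that("membrane areas and coverage match the circular-crista model", {
  area <- crista_membrane_area(564)
  expect_equal(area$single, pi * 282^2)
  expect_lt(abs(area$single - 249832) / 249832, 5e-4)
  expect_lt(abs(area$total - 499664) / 499664, 5e-4)
  expect_equal(crista_membrane_area(2)$single, pi)

  expect_equal(ring_footprint_area(20), pi * 100)
  expect_equal(round(ring_footprint_area(20)), 314)
  expect_equal(ring_footprint_area(4 / sqrt(pi)), 4)
  expect_equal(ring_footprint_area(19.02), pi * 9.51^2)

  expect_equal(signif(coverage_percent(1, pi * 100, 499664), 2), 0.063)
  expect_equal(coverage_percent(0, 314.16, 499664), 0)
  expect_equal(signif(coverage_percent(22, pi * 100, 499664), 2), 1.4)
  # dimensional sanity: invariant under a common rescaling of the areas
  expect_equal(coverage_percent(7, 314, 499664),
               coverage_percent(7, 314 * 3.7, 499664 * 3.7))
  expect_error(coverage_percent(1, 314, 0),
               class = "mitobell_invalid_parameter")
})

test_that("crista-membrane enrichment converts fractions to density ratios", {
  expect_equal(cm_enrichment(0.5, 1.0), 1.0)
  expect_equal(cm_enrichment(0.849, 0.64), 0.849 / 0.151 * 0.64)
  expect_equal(round(cm_enrichment(0.849, 0.64), 2), 3.60)
  expect_equal(round(cm_enrichment(0.886, 0.64), 2), 4.97)
  expect_error(cm_enrichment(1, 0.64),
               class = "mitobell_invalid_parameter")
})

test_that("per-crista counts are monotone in molecules, fraction, cristae", {
  base <- complexes_per_crista(6.84e6, 11, 0.795, 11510)
  for (mult in c(1.1, 2, 5)) {
    expect_gte(complexes_per_crista(6.84e6 * mult, 11, 0.795, 11510), base)
    expect_lte(complexes_per_crista(6.84e6, 11, 0.795, 11510 * mult), base)
  }
  for (f in c(0.8, 0.9, 1.0))
    expect_gte(complexes_per_crista(6.84e6, 11, f, 11510), base)
})

test_that("pipeline chains the operations deterministically", {
  p <- default_study_params()
  rep1 <- run_quant_pipeline(p)
  rep2 <- run_quant_pipeline(p)
  expect_identical(rep1[names(rep1) != "params"],
                   rep2[names(rep2) != "params"])
  expect_equal(rep1$cm_fraction, 0.795)
  expect_equal(rep1$total_molecules, 6.84e6)

  # doubled network length: cristae double, per-crista counts halve
  p2 <- p
  p2$network_length <- measured_quantity(2 * 1082, 360, "um")
  rep_d <- run_quant_pipeline(p2)
  expect_equal(rep_d$cristae_per_cell, 2 * rep1$cristae_per_cell)
  expect_equal(rep_d$rings_per_crista, rep1$rings_per_crista / 2)
  expect_equal(rep_d$complexes_per_crista, rep1$complexes_per_crista / 2)
  expect_equal(rep_d$coverage_percent_complexes,
               rep1$coverage_percent_complexes / 2)
})

zero_sd_params <- function() {
  p <- default_study_params()
  for (f in c("phb1_per_cell", "phb2_per_cell", "network_length",
              "raw_crista_spacing", "void_fraction"))
    p[[f]]$sd <- 0
  p
}

test_that("Monte-Carlo intervals collapse to points at zero sd", {
  p <- zero_sd_params()
  mc <- monte_carlo_intervals(p, n_draws = 200, seed = 7)
  rep <- run_quant_pipeline(p)
  for (nm in names(mc)) {
    expect_equal(mc[[nm]][1], mc[[nm]][2])
    expect_equal(mc[[nm]][1], rep[[nm]], tolerance = 1e-12)
  }
})

test_that("Monte-Carlo intervals are reproducible and contain the points", {
  p <- default_study_params()
  mc1 <- monte_carlo_intervals(p, n_draws = 2000, seed = 42)
  mc2 <- monte_carlo_intervals(p, n_draws = 2000, seed = 42)
  expect_identical(mc1, mc2)

  rep <- run_quant_pipeline(p)
  for (nm in names(mc1)) {
    expect_lte(mc1[[nm]][1], rep[[nm]])
    expect_gte(mc1[[nm]][2], rep[[nm]])
  }
  expect_error(monte_carlo_intervals(p, 100, 1, level = 1.2),
               class = "mitobell_invalid_parameter")
})

test_that("study params validate, serialize and round-trip", {
  p <- default_study_params()
  expect_s3_class(p, "study_params")
  path <- tempfile(fileext = ".json")
  write_study_params(p, path)
  q <- read_study_params(path)
  expect_equal(q$phb1_per_cell$value, 3.38e6)
  expect_equal(q$cm_fraction_range, c(0.75, 0.84))
  expect_equal(run_quant_pipeline(q)[c("cristae_per_cell",
                                       "complexes_per_crista")],
               run_quant_pipeline(p)[c("cristae_per_cell",
                                       "complexes_per_crista")])
  expect_error(measured_quantity(1, -1),
               class = "mitobell_invalid_parameter")
  expect_error(study_params(
    phb1_per_cell = 1e6, phb2_per_cell = 1e6,
    cm_fraction_range = c(0.9, 0.8), network_length = 1000,
    raw_crista_spacing = 74, void_fraction = measured_quantity(0.2),
    tubule_inner_diameter = 564, ring_diameter = 20,
    molecules_per_ring = 32, subunits_per_complex = 11,
    ibm_cm_length_ratio = 0.64),
    class = "mitobell_invalid_parameter")
})

test_that("report JSON export records derived values and conventions", {
  rep <- run_quant_pipeline(default_study_params(), mc_draws = 100,
                            seed = 3)
  path <- tempfile(fileext = ".json")
  write_quant_report(rep, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$derived$complexes_per_crista, rep$complexes_per_crista)
  expect_true(!is.null(x$rounding))
  expect_true(!is.null(x$mc_intervals$cristae_per_cell))
})
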