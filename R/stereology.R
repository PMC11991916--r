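# Stereological chain: from measured cell-level quantities to prohibitin
# complexes per crista and crista-membrane coverage.

#' Number of prohibitin rings per cell
#'
#' Divides the total number of prohibitin molecules in a cell by the assumed
#' stoichiometry of one ring. With the measured ~6.84 x 10^6 PHB1 + PHB2
#' molecules and 16-dimer rings (32 molecules), a U2OS cell holds about
#' 2.14 x 10^5 rings.
#'
#' @param total_molecules Total prohibitin molecules per cell, `>= 0`.
#' @param molecules_per_ring Molecules per ring, integer `>= 1`.
#' @return Unrounded ring count (presentation rounding is left to the report
#'   layer).
#' @export
rings_per_cell <- function(total_molecules, molecules_per_ring) {
  check_scalar(total_molecules, "total_molecules", 0)
  check_scalar(molecules_per_ring, "molecules_per_ring", 1, integer = TRUE)
  total_molecules / molecules_per_ring
}

#' Void-corrected crista spacing
#'
#' Stacked lamellar cristae are interrupted by crista-free membrane voids;
#' the average spacing measured inside stacks therefore underestimates the
#' spacing along the whole tubule. Correcting 74 nm for 21% voids gives
#' 94 nm.
#'
#' @param raw_spacing_nm Measured inter-membrane distance within stacks, nm.
#' @param void_fraction Fraction of tubule length occupied by voids,
#'   in `[0, 1)`.
#' @return Corrected spacing `raw / (1 - void_fraction)` in nm.
#' @export
corrected_crista_spacing <- function(raw_spacing_nm, void_fraction) {
  check_scalar(raw_spacing_nm, "raw_spacing_nm", 0, strict_lower = TRUE)
  check_scalar(void_fraction, "void_fraction", 0, upper = 1,
               strict_upper = TRUE)
  raw_spacing_nm / (1 - void_fraction)
}

#' Cristae per cell from network length and spacing
#'
#' @param network_length_um Total mitochondrial network length, micrometres.
#' @param spacing_nm Corrected crista spacing, nanometres.
#' @return Estimated number of cristae, `network_length / spacing` after unit
#'   conversion.
#' @export
cristae_per_cell <- function(network_length_um, spacing_nm) {
  check_scalar(network_length_um, "network_length_um", 0, strict_lower = TRUE)
  check_scalar(spacing_nm, "spacing_nm", 0, strict_lower = TRUE)
  (network_length_um * 1000) / spacing_nm
}

#' Rings allocated to crista membranes
#'
#' @param rings_total Total rings per cell.
#' @param cm_fraction Fraction of prohibitin localized to crista membranes,
#'   in `[0, 1]`. The pipeline default is the midpoint of the measured
#'   75-84% range.
#' @return `rings_total * cm_fraction`.
#' @export
rings_on_cm <- function(rings_total, cm_fraction) {
  check_scalar(rings_total, "rings_total", 0)
  check_scalar(cm_fraction, "cm_fraction", 0, upper = 1)
  rings_total * cm_fraction
}

#' Rings per crista (and per crista side)
#'
#' @param rings_on_cm Rings located on crista membranes.
#' @param cristae Number of cristae per cell, `> 0`.
#' @param per_side If `TRUE`, halve the result: each lamellar crista exposes
#'   two membrane sides.
#' @return Average rings per crista (or per side).
#' @export
rings_per_crista <- function(rings_on_cm, cristae, per_side = FALSE) {
  check_scalar(rings_on_cm, "rings_on_cm", 0)
  check_scalar(cristae, "cristae", 0, strict_lower = TRUE)
  r <- rings_on_cm / cristae
  if (per_side) r / 2 else r
}

#' Membrane area of a lamellar crista
#'
#' Models a lamellar crista as a disc spanning the tubule: one circular
#' membrane has area pi r^2; the crista consists of two opposing membranes.
#' At the measured 564 nm tubule inner diameter this gives 249,832 nm^2 and
#' 499,664 nm^2.
#'
#' @param tubule_inner_diameter_nm Tubule inner diameter, nm.
#' @return List with `single` (one membrane, nm^2) and `total`
#'   (both membranes, nm^2).
#' @export
crista_membrane_area <- function(tubule_inner_diameter_nm) {
  check_scalar(tubule_inner_diameter_nm, "tubule_inner_diameter_nm", 0,
               strict_lower = TRUE)
  single <- pi * (tubule_inner_diameter_nm / 2)^2
  list(single = single, total = 2 * single)
}

#' Membrane footprint of one prohibitin ring
#'
#' @param ring_diameter_nm Ring diameter, nm (20 nm gives ~314 nm^2).
#' @return Projected area `pi (d/2)^2` in nm^2.
#' @export
ring_footprint_area <- function(ring_diameter_nm) {
  check_scalar(ring_diameter_nm, "ring_diameter_nm", 0, strict_lower = TRUE)
  pi * (ring_diameter_nm / 2)^2
}

#' Percentage of crista membrane covered by rings
#'
#' @param n_rings Number of rings on the crista, `>= 0`.
#' @param ring_area_nm2 Footprint per ring, nm^2.
#' @param crista_area_total_nm2 Total crista membrane area
#'   (both sides), nm^2, `> 0`.
#' @return Coverage in percent.
#' @export
coverage_percent <- function(n_rings, ring_area_nm2, crista_area_total_nm2) {
  check_scalar(n_rings, "n_rings", 0)
  check_scalar(ring_area_nm2, "ring_area_nm2", 0)
  check_scalar(crista_area_total_nm2, "crista_area_total_nm2", 0,
               strict_lower = TRUE)
  100 * n_rings * ring_area_nm2 / crista_area_total_nm2
}

#' Prohibitin complexes per crista
#'
#' The bell-complex analogue of [rings_per_crista()]: total molecules are
#' grouped into 11-subunit complexes, allocated to crista membranes and
#' divided over the cristae. With the measured inputs this yields about 43
#' complexes per crista.
#'
#' @param total_molecules Total prohibitin molecules per cell.
#' @param subunits_per_complex Subunits per complex, integer `>= 1`.
#' @param cm_fraction Crista-membrane localization fraction in `[0, 1]`.
#' @param cristae Cristae per cell, `> 0`.
#' @return Average complexes per crista.
#' @export
complexes_per_crista <- function(total_molecules, subunits_per_complex,
                                 cm_fraction, cristae) {
  check_scalar(total_molecules, "total_molecules", 0)
  check_scalar(subunits_per_complex, "subunits_per_complex", 1,
               integer = TRUE)
  check_scalar(cm_fraction, "cm_fraction", 0, upper = 1)
  check_scalar(cristae, "cristae", 0, strict_lower = TRUE)
  (total_molecules / subunits_per_complex) * cm_fraction / cristae
}

#' Crista-membrane enrichment of prohibitins
#'
#' Converts an immunogold crista-membrane localization fraction into a
#' per-unit-membrane-length concentration ratio CM:IBM, given the length
#' ratio of inner boundary membrane to crista membrane. At the measured
#' fractions (84.9-90.6%) and IBM:CM = 0.64 this is three- to five-fold.
#'
#' @param cm_fraction Fraction of label at crista membranes, in `(0, 1)`.
#' @param ibm_cm_length_ratio IBM:CM membrane length ratio, `> 0`.
#' @return Density ratio `(cm_fraction / (1 - cm_fraction)) *
#'   ibm_cm_length_ratio`.
#' @export
cm_enrichment <- function(cm_fraction, ibm_cm_length_ratio) {
  check_scalar(cm_fraction, "cm_fraction", 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(ibm_cm_length_ratio, "ibm_cm_length_ratio", 0,
               strict_lower = TRUE)
  (cm_fraction / 1) / ((1 - cm_fraction) / ibm_cm_length_ratio)
}

quant_chain <- function(total_molecules, molecules_per_ring,
                        subunits_per_complex, cm_fraction,
                        network_length_um, raw_spacing_nm, void_fraction,
                        tubule_inner_diameter_nm, ring_diameter_nm) {
  spacing <- corrected_crista_spacing(raw_spacing_nm, void_fraction)
  cristae <- cristae_per_cell(network_length_um, spacing)
  rings <- rings_per_cell(total_molecules, molecules_per_ring)
  rings_cm <- rings_on_cm(rings, cm_fraction)
  rpc <- rings_per_crista(rings_cm, cristae)
  cpc <- complexes_per_crista(total_molecules, subunits_per_complex,
                              cm_fraction, cristae)
  area <- crista_membrane_area(tubule_inner_diameter_nm)
  foot <- ring_footprint_area(ring_diameter_nm)
  c(corrected_spacing_nm = spacing,
    cristae_per_cell = cristae,
    rings_per_cell = rings,
    rings_on_cm = rings_cm,
    rings_per_crista = rpc,
    rings_per_crista_side = rpc / 2,
    complexes_per_crista = cpc,
    crista_area_single_nm2 = area$single,
    crista_area_total_nm2 = area$total,
    ring_footprint_nm2 = foot,
    coverage_percent_per_ring = coverage_percent(1, foot, area$total),
    coverage_percent_complexes = coverage_percent(cpc, foot, area$total))
}

#' Run the full abundance and coverage pipeline
#'
#' Deterministic chaining of the stereology operations: void correction of
#' the crista spacing, cristae per cell, ring and complex counts, allocation
#' to crista membranes at the midpoint of the localization range, per-crista
#' counts, membrane areas and coverage percentages. All intermediate values
#' are kept unrounded; [print.quant_report()] applies presentation rounding.
#'
#' @param params A [study_params()] object.
#' @param mc_draws If `> 0`, also compute Monte-Carlo uncertainty intervals
#'   with this many draws (see [monte_carlo_intervals()]).
#' @param seed,level Passed to [monte_carlo_intervals()] when
#'   `mc_draws > 0`.
#' @return An object of class `quant_report`: a list of named derived
#'   quantities plus `params`, the `cm_fraction` used, the coverage range
#'   over the localization range, and optionally `mc_intervals`.
#' @examples
#' rep <- run_quant_pipeline(default_study_params())
#' rep$complexes_per_crista   # ~ 43
#' @export
run_quant_pipeline <- function(params, mc_draws = 0, seed = 1,
                               level = 0.95) {
  stopifnot(inherits(params, "study_params"))
  total <- params$phb1_per_cell$value + params$phb2_per_cell$value
  cm_mid <- mean(params$cm_fraction_range)
  vals <- quant_chain(
    total_molecules = total,
    molecules_per_ring = params$molecules_per_ring,
    subunits_per_complex = params$subunits_per_complex,
    cm_fraction = cm_mid,
    network_length_um = params$network_length$value,
    raw_spacing_nm = params$raw_crista_spacing$value,
    void_fraction = params$void_fraction$value,
    tubule_inner_diameter_nm = params$tubule_inner_diameter,
    ring_diameter_nm = params$ring_diameter)

  # coverage over the printed localization range, complex stoichiometry
  rng <- vapply(params$cm_fraction_range, function(f) {
    cpc <- complexes_per_crista(total, params$subunits_per_complex, f,
                                vals[["cristae_per_cell"]])
    coverage_percent(cpc, vals[["ring_footprint_nm2"]],
                     vals[["crista_area_total_nm2"]])
  }, numeric(1))

  report <- c(as.list(vals), list(
    coverage_percent_range = rng,
    cm_fraction = cm_mid,
    total_molecules = total,
    params = params,
    mc_intervals = NULL))
  class(report) <- "quant_report"
  if (mc_draws > 0)
    report$mc_intervals <- monte_carlo_intervals(params, mc_draws, seed,
                                                 level)
  report
}

#' Monte-Carlo uncertainty propagation through the pipeline
#'
#' Draws each measured quantity independently from a normal distribution
#' with its reported (value, sd), truncated to its validity domain
#' (fractions clipped to `[0, 0.999]`, lengths to positive), re-runs the
#' derivation chain for each draw and returns central intervals. With all
#' sd = 0 every interval degenerates to the point estimate.
#'
#' @param params A [study_params()] object.
#' @param n_draws Number of Monte-Carlo draws, `>= 1`.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param level Central interval coverage in `(0, 1)`.
#' @return Named list mapping each derived quantity to `c(low, high)`.
#' @export
monte_carlo_intervals <- function(params, n_draws = 10000, seed = 1,
                                  level = 0.95) {
  stopifnot(inherits(params, "study_params"))
  check_scalar(n_draws, "n_draws", 1, integer = TRUE)
  check_scalar(level, "level", 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  cm_mid <- mean(params$cm_fraction_range)

  draw <- function(mq, kind) {
    x <- stats::rnorm(n_draws, mq$value, mq$sd)
    if (kind == "fraction") pmin(pmax(x, 0), 0.999)
    else pmax(x, .Machine$double.eps)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  phb1 <- draw(params$phb1_per_cell, "positive")
  phb2 <- draw(params$phb2_per_cell, "positive")
  net <- draw(params$network_length, "positive")
  spac <- draw(params$raw_crista_spacing, "positive")
  void <- draw(params$void_fraction, "fraction")

  mat <- vapply(seq_len(n_draws), function(i) {
    quant_chain(
      total_molecules = phb1[i] + phb2[i],
      molecules_per_ring = params$molecules_per_ring,
      subunits_per_complex = params$subunits_per_complex,
      cm_fraction = cm_mid,
      network_length_um = net[i],
      raw_spacing_nm = spac[i],
      void_fraction = void[i],
      tubule_inner_diameter_nm = params$tubule_inner_diameter,
      ring_diameter_nm = params$ring_diameter)
  }, numeric(12))

  a <- (1 - level) / 2
  out <- apply(mat, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  stats::setNames(
    lapply(seq_len(ncol(out)), function(j) as.numeric(out[, j])),
    rownames(mat))
}

# Preserve the caller's RNG state so seeded helpers do not perturb it.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

round_sig <- function(x, digits) signif(x, digits)

#' @export
print.quant_report <- function(x, ...) {
  # presentation rounding mirrors the study's reporting conventions:
  # 3 s.f. for ring counts, integer part for cristae, nearest integer for
  # per-crista counts, 2 s.f. for percentages
  cat("Prohibitin abundance report\n")
  cat(sprintf("  corrected crista spacing : %.0f nm\n",
              round(x$corrected_spacing_nm)))
  cat(sprintf("  cristae per cell         : %d\n",
              trunc(x$cristae_per_cell)))
  cat(sprintf("  rings per cell           : %.3g\n",
              round_sig(x$rings_per_cell, 3)))
  cat(sprintf("  rings on CM              : %.2g\n",
              round_sig(x$rings_on_cm, 2)))
  cat(sprintf("  rings per crista         : %.0f (%.1f per side)\n",
              round(x$rings_per_crista), x$rings_per_crista_side))
  cat(sprintf("  complexes per crista     : %.0f\n",
              round(x$complexes_per_crista)))
  cat(sprintf("  crista membrane area     : %.0f nm^2 (total %.0f nm^2)\n",
              x$crista_area_single_nm2, x$crista_area_total_nm2))
  cat(sprintf("  ring footprint           : %.0f nm^2\n",
              round(x$ring_footprint_nm2)))
  cat(sprintf("  coverage per ring        : %.2g %%\n",
              round_sig(x$coverage_percent_per_ring, 2)))
  cat(sprintf("  coverage, all complexes  : %.2g %% (range %.2g-%.2g %%)\n",
              round_sig(x$coverage_percent_complexes, 2),
              round_sig(x$coverage_percent_range[1], 2),
              round_sig(x$coverage_percent_range[2], 2)))
  if (!is.null(x$mc_intervals)) {
    cat("  Monte-Carlo intervals:\n")
    for (nm in names(x$mc_intervals))
      cat(sprintf("    %-26s [%.4g, %.4g]\n", nm,
                  x$mc_intervals[[nm]][1], x$mc_intervals[[nm]][2]))
  }
  invisible(x)
}

#' Write a quant_report as JSON
#'
#' Exports every derived quantity (unrounded), the inputs used and the
#' rounding conventions applied by the print method.
#'
#' @param report A `quant_report` from [run_quant_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_quant_report <- function(report, path) {
  stopifnot(inherits(report, "quant_report"))
  numeric_fields <- Filter(is.numeric, report[setdiff(names(report),
                                                      "params")])
  x <- list(
    derived = numeric_fields,
    mc_intervals = report$mc_intervals,
    inputs = lapply(unclass(report$params), function(f)
      if (inherits(f, "measured_quantity")) unclass(f) else f),
    rounding = list(
      ring_counts = "3 significant figures",
      cristae = "integer part",
      per_crista_counts = "nearest integer",
      percentages = "2 significant figures"),
    assumptions = paste("complexes per crista = total molecules /",
                        "subunits_per_complex * cm_fraction / cristae"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
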