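#' Measured quantity with standard deviation
#'
#' A measured input to the stereology pipeline: a point value, its standard
#' deviation and a unit label. These are the "value +/- sd" numbers obtained
#' from quantitative western blotting, light microscopy and electron
#' microscopy of U2OS cells.
#'
#' @param value Finite numeric point estimate, in `units`.
#' @param sd Standard deviation (same units), `>= 0`. Defaults to 0 for
#'   quantities reported without uncertainty.
#' @param units Unit label (informational).
#' @return An object of class `measured_quantity` with fields `value`, `sd`
#'   and `units`.
#' @examples
#' measured_quantity(1082, 360, "um")
#' @export
measured_quantity <- function(value, sd = 0, units = "") {
  check_scalar(value, "value")
  check_scalar(sd, "sd", lower = 0)
  structure(list(value = value, sd = sd, units = units),
            class = "measured_quantity")
}

#' @export
print.measured_quantity <- function(x, ...) {
  cat(format(x$value), if (x$sd > 0) paste0("+/- ", format(x$sd)),
      x$units, "\n")
  invisible(x)
}

#' Study parameters for the prohibitin abundance pipeline
#'
#' Bundles every measured cell-level input needed to estimate prohibitin
#' ring/complex abundance per crista and crista-membrane coverage.
#'
#' @param phb1_per_cell,phb2_per_cell [measured_quantity()] PHB1 and PHB2
#'   molecules per cell.
#' @param cm_fraction_range Numeric length-2, fraction of prohibitin molecules
#'   localized to crista membranes (low, high), both in `[0, 1]`.
#' @param network_length [measured_quantity()] total mitochondrial network
#'   length per cell, micrometres.
#' @param raw_crista_spacing [measured_quantity()] raw distance between
#'   stacked crista membranes, nanometres (before void correction).
#' @param void_fraction [measured_quantity()] fraction of the mitochondrial
#'   tubule occupied by crista-free membrane voids, in `[0, 1)`.
#' @param tubule_inner_diameter Inner diameter of an average mitochondrial
#'   tubule, nanometres.
#' @param ring_diameter Assumed diameter of a ring-like prohibitin complex,
#'   nanometres.
#' @param molecules_per_ring Prohibitin molecules per hypothetical large ring
#'   (16 dimers = 32 molecules by default).
#' @param subunits_per_complex Subunits in the bell-shaped complex
#'   (11 alternating PHB1/PHB2 molecules by default).
#' @param ibm_cm_length_ratio Length ratio of inner boundary membrane to
#'   crista membrane (IBM:CM), `> 0`.
#' @return An object of class `study_params`.
#' @seealso [default_study_params()] for the measured U2OS values,
#'   [run_quant_pipeline()] for the derived estimate chain.
#' @export
study_params <- function(phb1_per_cell, phb2_per_cell, cm_fraction_range,
                         network_length, raw_crista_spacing, void_fraction,
                         tubule_inner_diameter, ring_diameter,
                         molecules_per_ring, subunits_per_complex,
                         ibm_cm_length_ratio) {
  as_mq <- function(x, nm) {
    if (inherits(x, "measured_quantity")) return(x)
    if (is.numeric(x) && length(x) == 1L) return(measured_quantity(x))
    stop_invalid(nm, " must be a measured_quantity or numeric scalar")
  }
  phb1_per_cell <- as_mq(phb1_per_cell, "phb1_per_cell")
  phb2_per_cell <- as_mq(phb2_per_cell, "phb2_per_cell")
  network_length <- as_mq(network_length, "network_length")
  raw_crista_spacing <- as_mq(raw_crista_spacing, "raw_crista_spacing")
  void_fraction <- as_mq(void_fraction, "void_fraction")

  if (!is.numeric(cm_fraction_range) || length(cm_fraction_range) != 2L)
    stop_invalid("cm_fraction_range must be numeric length 2")
  if (cm_fraction_range[1] > cm_fraction_range[2])
    stop_invalid("cm_fraction_range must satisfy low <= high")
  if (any(cm_fraction_range < 0) || any(cm_fraction_range > 1))
    stop_invalid("cm_fraction_range values must lie in [0, 1]")
  if (void_fraction$value < 0 || void_fraction$value >= 1)
    stop_invalid("void_fraction value must lie in [0, 1)")
  check_scalar(network_length$value, "network_length", 0, strict_lower = TRUE)
  check_scalar(raw_crista_spacing$value, "raw_crista_spacing", 0,
               strict_lower = TRUE)
  check_scalar(tubule_inner_diameter, "tubule_inner_diameter", 0,
               strict_lower = TRUE)
  check_scalar(ring_diameter, "ring_diameter", 0, strict_lower = TRUE)
  check_scalar(molecules_per_ring, "molecules_per_ring", 1, integer = TRUE)
  check_scalar(subunits_per_complex, "subunits_per_complex", 1, integer = TRUE)
  check_scalar(ibm_cm_length_ratio, "ibm_cm_length_ratio", 0,
               strict_lower = TRUE)

  structure(list(
    phb1_per_cell = phb1_per_cell,
    phb2_per_cell = phb2_per_cell,
    cm_fraction_range = as.numeric(cm_fraction_range),
    network_length = network_length,
    raw_crista_spacing = raw_crista_spacing,
    void_fraction = void_fraction,
    tubule_inner_diameter = tubule_inner_diameter,
    ring_diameter = ring_diameter,
    molecules_per_ring = as.integer(molecules_per_ring),
    subunits_per_complex = as.integer(subunits_per_complex),
    ibm_cm_length_ratio = ibm_cm_length_ratio
  ), class = "study_params")
}

#' Default measured study parameters (U2OS cells)
#'
#' Returns the measured inputs of the quantitative prohibitin study verbatim:
#' (3.38 +/- 0.23) x 10^6 PHB1 and (3.46 +/- 0.15) x 10^6 PHB2 molecules per
#' cell, a 1,082 +/- 360 um mitochondrial network, 74 +/- 15 nm raw crista
#' spacing, 21 +/- 8% membrane voids, 75-84% crista-membrane localization,
#' a 564 nm tubule inner diameter, a 20 nm ring diameter, 32 molecules per
#' 16-dimer ring, 11 subunits per bell complex, and an IBM:CM length ratio
#' of 0.64.
#'
#' @return A [study_params()] object.
#' @examples
#' p <- default_study_params()
#' run_quant_pipeline(p)
#' @export
default_study_params <- function() {
  study_params(
    phb1_per_cell = measured_quantity(3.38e6, 0.23e6, "molecules"),
    phb2_per_cell = measured_quantity(3.46e6, 0.15e6, "molecules"),
    cm_fraction_range = c(0.75, 0.84),
    network_length = measured_quantity(1082, 360, "um"),
    raw_crista_spacing = measured_quantity(74, 15, "nm"),
    void_fraction = measured_quantity(0.21, 0.08, ""),
    tubule_inner_diameter = 564,
    ring_diameter = 20,
    molecules_per_ring = 32L,
    subunits_per_complex = 11L,
    ibm_cm_length_ratio = 0.64
  )
}

#' Serialize / deserialize study parameters as JSON
#'
#' @param params A [study_params()] object.
#' @param path File path for the JSON document.
#' @return `write_study_params` returns `path` invisibly; `read_study_params`
#'   returns a [study_params()] object.
#' @export
write_study_params <- function(params, path) {
  stopifnot(inherits(params, "study_params"))
  x <- lapply(unclass(params), function(f) {
    if (inherits(f, "measured_quantity")) unclass(f) else f
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_study_params
#' @export
read_study_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mq <- function(f) measured_quantity(f$value, f$sd, f$units %||% "")
  study_params(
    phb1_per_cell = mq(x$phb1_per_cell),
    phb2_per_cell = mq(x$phb2_per_cell),
    cm_fraction_range = x$cm_fraction_range,
    network_length = mq(x$network_length),
    raw_crista_spacing = mq(x$raw_crista_spacing),
    void_fraction = mq(x$void_fraction),
    tubule_inner_diameter = x$tubule_inner_diameter,
    ring_diameter = x$ring_diameter,
    molecules_per_ring = x$molecules_per_ring,
    subunits_per_complex = x$subunits_per_complex,
    ibm_cm_length_ratio = x$ibm_cm_length_ratio
  )
}
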