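# Parametric n-fold cyclic assemblies of alternating subunits, matching the
# bell-shaped geometry of the membrane-embedded prohibitin complex.

#' Subunit model: a labelled set of atoms
#'
#' Minimal coordinate model of one subunit (e.g. a CA trace of PHB1 or
#' PHB2). Coordinates are in Angstrom, in the subunit's local frame: the
#' assembly builder translates the subunit to its placement radius and
#' rotates copies about +z.
#'
#' @param identity Chain identity label, `"A"` or `"B"` (representing PHB1
#'   and PHB2).
#' @param atoms `data.frame` with columns `resno` (positive integer residue
#'   index), `atom` (role label, e.g. `"CA"`), `x`, `y`, `z` (Angstrom).
#' @return Object of class `subunit_model`.
#' @export
subunit_model <- function(identity, atoms) {
  if (!identity %in% c("A", "B"))
    stop_invalid("identity must be 'A' or 'B'")
  req <- c("resno", "atom", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop_input("atoms must be a data.frame with columns ",
               paste(req, collapse = ", "))
  if (nrow(atoms) == 0L) stop_input("subunit has an empty atom list")
  if (any(atoms$resno < 1) || any(atoms$resno != round(atoms$resno)))
    stop_input("resno must be positive integers")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop_input("atom positions must be finite")
  ca <- atoms$resno[atoms$atom == "CA"]
  if (anyDuplicated(ca)) stop_input("at most one CA per residue index")
  structure(list(identity = identity, atoms = atoms),
            class = "subunit_model")
}

#' Ring specification
#'
#' @param n Cyclic symmetry order, integer `>= 3` (C11 for the prohibitin
#'   bell).
#' @param radius Placement radius of the subunit reference point, Angstrom,
#'   `> 0`.
#' @param start_identity Identity of chain 0 (`"A"` or `"B"`).
#' @return Object of class `ring_spec`. Convention: subunit `k` (0-based) is
#'   rotated by `2 pi k / n` about +z, counter-clockwise viewed from +z.
#' @export
ring_spec <- function(n, radius, start_identity = "A") {
  check_scalar(n, "n", 3, integer = TRUE)
  check_scalar(radius, "radius", 0, strict_lower = TRUE)
  if (!start_identity %in% c("A", "B"))
    stop_invalid("start_identity must be 'A' or 'B'")
  structure(list(n = as.integer(n), radius = radius,
                 start_identity = start_identity),
            class = "ring_spec")
}

#' Strictly alternating identity pattern around a ring
#'
#' For odd `n` the wrap-around neighbours (chain `n-1`, chain 0) share an
#' identity: an uneven ring of two alternating molecules is forced to
#' contain exactly one homotypic interface. Counts are `ceiling(n/2)` of the
#' start identity and `floor(n/2)` of the other (6 + 5 for C11).
#'
#' @param n Ring size, integer `>= 3`.
#' @param start Identity of chain 0, `"A"` or `"B"`.
#' @return Character vector of length `n` over `{"A", "B"}`.
#' @examples
#' table(alternating_identities(11, "A"))  # 6 A, 5 B
#' @export
alternating_identities <- function(n, start = "A") {
  check_scalar(n, "n", 3, integer = TRUE)
  if (!start %in% c("A", "B")) stop_invalid("start must be 'A' or 'B'")
  other <- if (start == "A") "B" else "A"
  rep_len(c(start, other), n)
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Build an n-fold cyclic assembly of alternating subunits
#'
#' Chain `k` receives the subunit named by the alternating identity pattern,
#' translated by the placement radius along +x and rotated by `2 pi k / n`
#' about +z.
#'
#' @param subunit_a,subunit_b [subunit_model()] objects for identities A and
#'   B, sharing a residue-numbering convention.
#' @param spec A [ring_spec()].
#' @return Object of class `ring_assembly` with fields `spec`,
#'   `identity_pattern` and `chains` (a list of length `n`; each element has
#'   `identity` and transformed `atoms`).
#' @export
build_ring <- function(subunit_a, subunit_b, spec) {
  stopifnot(inherits(spec, "ring_spec"))
  if (!inherits(subunit_a, "subunit_model") ||
      !inherits(subunit_b, "subunit_model"))
    stop_input("subunit_a and subunit_b must be subunit_model objects")
  pattern <- alternating_identities(spec$n, spec$start_identity)
  subs <- list(A = if (subunit_a$identity == "A") subunit_a else subunit_b,
               B = if (subunit_b$identity == "B") subunit_b else subunit_a)
  chains <- lapply(seq_len(spec$n) - 1L, function(k) {
    id <- pattern[k + 1L]
    at <- subs[[id]]$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    xyz[, 1] <- xyz[, 1] + spec$radius
    xyz <- xyz %*% t(rot_z(2 * pi * k / spec$n))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    list(identity = id, atoms = at)
  })
  structure(list(spec = spec, identity_pattern = pattern, chains = chains),
            class = "ring_assembly")
}

#' @export
print.ring_assembly <- function(x, ...) {
  cat(sprintf("C%d assembly: %s\n", x$spec$n,
              paste(x$identity_pattern, collapse = "")))
  cat(sprintf("  %d chains, %d atoms each, placement radius %.1f A\n",
              x$spec$n, nrow(x$chains[[1]]$atoms), x$spec$radius))
  invisible(x)
}

#' Indices of homotypic (same-identity) neighbouring interfaces
#'
#' @param assembly A [build_ring()] assembly.
#' @return 0-based chain indices `k` such that chains `k` and
#'   `(k + 1) mod n` share an identity. Odd alternating rings have exactly
#'   one; even rings none.
#' @export
homotypic_interfaces <- function(assembly) {
  stopifnot(inherits(assembly, "ring_assembly"))
  ids <- assembly$identity_pattern
  n <- length(ids)
  which(ids == ids[c(2:n, 1)]) - 1L
}

#' Extract CA coordinates of an assembly
#'
#' @param assembly A `ring_assembly`.
#' @return `data.frame` with columns `chain` (0-based), `identity`, `resno`,
#'   `x`, `y`, `z` for every CA atom.
#' @export
assembly_ca <- function(assembly) {
  stopifnot(inherits(assembly, "ring_assembly"))
  do.call(rbind, lapply(seq_along(assembly$chains), function(i) {
    ch <- assembly$chains[[i]]
    ca <- ch$atoms[ch$atoms$atom == "CA", , drop = FALSE]
    data.frame(chain = i - 1L, identity = ch$identity, resno = ca$resno,
               x = ca$x, y = ca$y, z = ca$z)
  }))
}

#' Bell envelope geometry
#'
#' Dimensions of the bell-shaped complex as measured from the density map:
#' 190.2 A diameter directly above the lipid bilayer, 84.0 A height from the
#' bilayer to the top, and an 89.0 A top diameter.
#'
#' @param base_diameter,height,top_diameter,membrane_thickness Dimensions in
#'   Angstrom; `top_diameter < base_diameter`, all `> 0`.
#' @return Object of class `bell_geometry`.
#' @export
bell_geometry <- function(base_diameter = 190.2, height = 84.0,
                          top_diameter = 89.0, membrane_thickness = 40) {
  check_scalar(base_diameter, "base_diameter", 0, strict_lower = TRUE)
  check_scalar(height, "height", 0, strict_lower = TRUE)
  check_scalar(top_diameter, "top_diameter", 0, strict_lower = TRUE)
  check_scalar(membrane_thickness, "membrane_thickness", 0,
               strict_lower = TRUE)
  if (top_diameter >= base_diameter)
    stop_invalid("top_diameter must be smaller than base_diameter")
  structure(list(base_diameter = base_diameter, height = height,
                 top_diameter = top_diameter,
                 membrane_thickness = membrane_thickness),
            class = "bell_geometry")
}

#' Synthetic CA-trace subunit fitting the bell envelope
#'
#' Generates a placeholder monomer when no predicted structure is supplied:
#' a CA trace with a membrane-anchored base segment at the bilayer interface
#' and an arm rising and leaning inwards to the narrowed top, such that the
#' assembled n-fold ring stays inside the bell envelope (radial extent at
#' most the base radius, CA z-span at most the bell height). Deterministic
#' for a fixed seed.
#'
#' @param geometry A [bell_geometry()].
#' @param n_residues Number of CA positions, `>= 10`.
#' @param seed Integer seed for the small coordinate jitter.
#' @param identity Identity label for the returned subunit.
#' @return A [subunit_model()] whose coordinates are in the local frame of a
#'   chain placed at `default_placement_radius(geometry)`.
#' @export
synthetic_bell_subunit <- function(geometry, n_residues = 60, seed = 1,
                                   identity = "A") {
  stopifnot(inherits(geometry, "bell_geometry"))
  check_scalar(n_residues, "n_residues", 10, integer = TRUE)
  r_base <- geometry$base_diameter / 2
  r_top <- geometry$top_diameter / 2
  if (r_top >= r_base) stop_invalid("impossible geometry: top >= base")
  r_place <- default_placement_radius(geometry)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_anchor <- max(3L, round(n_residues * 0.2))
  n_arm <- n_residues - n_anchor
  jit <- 1.0  # A, kept well below the envelope margin

  # membrane anchor: near the placement radius, hugging the bilayer
  # interface (z ~ 0) so the full CA z-span stays within the bell height
  za <- seq(0.5, 2.5, length.out = n_anchor)
  ra <- rep(r_place, n_anchor)
  # arm: rises towards the bell top while leaning inwards from the
  # placement radius to the top radius
  t <- seq(0, 1, length.out = n_arm)
  zr <- 3 + t * (geometry$height - 7)
  rr <- r_place + t * (r_top - r_place)
  r_all <- c(ra, rr) + stats::runif(n_residues, -jit, jit)
  z_all <- c(za, zr) + stats::runif(n_residues, -jit, jit)
  # keep strictly inside the envelope after jitter
  r_all <- pmin(r_all, r_base - 0.5)
  z_all <- pmin(pmax(z_all, 0), geometry$height - 0.5)
  y_all <- stats::runif(n_residues, -jit, jit)

  atoms <- data.frame(resno = seq_len(n_residues), atom = "CA",
                      x = r_all - r_place, y = y_all, z = z_all)
  subunit_model(identity, atoms)
}

#' Default placement radius for a bell geometry
#'
#' The subunit reference point is placed at the base radius minus a margin
#' for the subunit's own radial extent, so the assembled ring stays inside
#' the envelope.
#'
#' @param geometry A [bell_geometry()].
#' @param subunit_extent Radial half-extent reserved for the subunit,
#'   Angstrom.
#' @return Placement radius in Angstrom.
#' @export
default_placement_radius <- function(geometry, subunit_extent = 8) {
  stopifnot(inherits(geometry, "bell_geometry"))
  geometry$base_diameter / 2 - subunit_extent
}

#' Net charge of a sequence segment
#'
#' Simple side-chain charge count used to characterize the coiled-coil
#' interface segments: lysine and arginine count +1, aspartate and glutamate
#' -1, histidine 0, termini ignored.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @return Integer net charge `(#K + #R) - (#D + #E)`.
#' @examples
#' segment_net_charge("KKRDD")  # +1
#' @export
segment_net_charge <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_input("sequence must be a single string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
  bad <- setdiff(aa, alphabet)
  if (length(bad))
    stop_input("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  as.integer(sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E")))
}

# ---- coordinate I/O ---------------------------------------------------------

#' Write an assembly to PDB or mmCIF
#'
#' Chain identities map to chain IDs `A`-`Z` in ring order (A-K for n = 11).
#' PDB output goes through bio3d; mmCIF output writes a minimal `atom_site`
#' loop.
#'
#' @param assembly A `ring_assembly`.
#' @param path Output path; format chosen by extension (`.pdb` vs
#'   `.cif`/`.mmcif`) unless `format` is given.
#' @param format `"pdb"`, `"cif"` or `NULL` (from extension).
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path, format = NULL) {
  stopifnot(inherits(assembly, "ring_assembly"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  ca <- assembly_ca(assembly)
  chain_id <- LETTERS[ca$chain + 1L]
  if (format == "pdb") {
    n <- nrow(ca)
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(ca[, c("x", "y", "z")]))),
      resno = ca$resno, chain = chain_id,
      resid = rep("ALA", n), eleno = seq_len(n),
      elety = rep("CA", n))
  } else {
    lines <- c(
      "data_ring_assembly",
      "#",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_seq_id",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      sprintf("ATOM %d C CA ALA %s %d %.3f %.3f %.3f",
              seq_len(nrow(ca)), chain_id, ca$resno, ca$x, ca$y, ca$z),
      "#")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a subunit CA trace from a PDB file
#'
#' Reads one chain of a PDB file (via bio3d) and returns its CA trace as a
#' [subunit_model()].
#'
#' @param path PDB file path.
#' @param identity Identity label to assign.
#' @param chain Chain ID to extract; default takes the first chain.
#' @return A [subunit_model()].
#' @export
read_subunit_pdb <- function(path, identity = "A", chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop_input("no CA atoms found for chain ", chain)
  subunit_model(identity, data.frame(
    resno = at$resno, atom = "CA", x = at$x, y = at$y, z = at$z))
}
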