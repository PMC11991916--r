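# Generators with planted ground truth: crosslink tables, tomogram scenes
# and complete fixture sets. Every generator is deterministic for a fixed
# seed and returns machine-readable truth alongside the data.

#' Specification for the synthetic crosslink generator
#'
#' @param n_satisfied,n_violated Numbers of planted inter-subunit links
#'   whose shortest assembly distance is below / above the cutoff.
#' @param n_self_a,n_self_b Numbers of planted self-links on identities A
#'   and B, placed on residues whose only sub-cutoff same-identity
#'   inter-chain distance is a homotypic adjacency.
#' @param n_studies Number of emulated source studies.
#' @param overlap_probabilities Probability of a link appearing in exactly
#'   1, 2, ... studies (length `n_studies`, normalized internally).
#' @param seed Integer seed.
#' @return Object of class `xl_generator_spec`.
#' @export
xl_generator_spec <- function(n_satisfied = 10, n_violated = 5,
                              n_self_a = 0, n_self_b = 0, n_studies = 1,
                              overlap_probabilities = NULL, seed = 1) {
  for (v in c(n_satisfied, n_violated, n_self_a, n_self_b))
    check_scalar(v, "counts", 0, integer = TRUE)
  check_scalar(n_studies, "n_studies", 1, integer = TRUE)
  if (is.null(overlap_probabilities))
    overlap_probabilities <- c(1, rep(0, n_studies - 1L))
  if (length(overlap_probabilities) != n_studies ||
      any(overlap_probabilities < 0) || any(overlap_probabilities > 1))
    stop_invalid("overlap_probabilities must be length n_studies in [0,1]")
  structure(list(n_satisfied = n_satisfied, n_violated = n_violated,
                 n_self_a = n_self_a, n_self_b = n_self_b,
                 n_studies = as.integer(n_studies),
                 overlap_probabilities = overlap_probabilities,
                 seed = seed),
            class = "xl_generator_spec")
}

# per residue-pair minimum CA distance between two identities, minimized
# over all chain pairs (all ordered pairs incl. same chain when identities
# coincide)
min_dist_by_residue <- function(assembly, id_a, id_b) {
  ca <- assembly_ca(assembly)
  a <- ca[ca$identity == id_a, ]
  b <- ca[ca$identity == id_b, ]
  res_a <- sort(unique(a$resno)); res_b <- sort(unique(b$resno))
  m <- matrix(Inf, length(res_a), length(res_b),
              dimnames = list(res_a, res_b))
  for (i in seq_along(res_a)) {
    pa <- a[a$resno == res_a[i], c("x", "y", "z")]
    for (j in seq_along(res_b)) {
      pb <- b[b$resno == res_b[j], c("x", "y", "z")]
      d2 <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(u, v)
        (pa$x[u] - pb$x[v])^2 + (pa$y[u] - pb$y[v])^2 +
          (pa$z[u] - pb$z[v])^2)
      m[i, j] <- sqrt(min(d2))
    }
  }
  m
}

# residues whose same-identity inter-chain distance is below `cutoff` at a
# homotypic adjacency but above it for chains two steps apart. Two chains
# carrying the same subunit are exact rotational copies, so the distance
# between residue r in chains k steps apart is the chord 2 rho sin(pi k/n)
# at that residue's radial position rho -- computed exactly, per identity,
# and intersected so a planted residue discriminates for both identities.
discriminating_self_residues <- function(assembly, cutoff) {
  n <- assembly$spec$n
  ids <- vapply(assembly$chains, `[[`, "", "identity")
  per_identity <- lapply(unique(ids), function(id) {
    at <- assembly$chains[[match(id, ids)]]$atoms
    at <- at[at$atom == "CA", ]
    rho <- sqrt(at$x^2 + at$y^2)
    d_adj <- 2 * rho * sin(pi / n)
    d_two <- 2 * rho * sin(2 * pi / n)
    at$resno[d_adj <= cutoff & d_two > cutoff]
  })
  Reduce(intersect, per_identity)
}

#' Generate a synthetic crosslink table with planted ground truth
#'
#' Plants inter-subunit residue pairs whose shortest assembly distance is
#' by construction at most (`satisfied`) or above (`violated`) the cutoff,
#' and self-links on residues whose only sub-cutoff same-identity contact
#' is a homotypic adjacency, so that downstream mapping and
#' arrangement-testing recover the generator labels exactly. Study
#' membership is drawn from the overlap probabilities.
#'
#' @param assembly A `ring_assembly`.
#' @param spec An [xl_generator_spec()].
#' @param config An [xl_config()] providing the distance cutoff.
#' @return List with `records` (a `crosslink_records` data.frame, one row
#'   per study membership) and `truth` (per unique link: `planted` label
#'   and `multiplicity`).
#' @export
generate_crosslink_table <- function(assembly, spec, config = xl_config()) {
  stopifnot(inherits(assembly, "ring_assembly"),
            inherits(spec, "xl_generator_spec"))
  cutoff <- config$max_ca_distance

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  need_inter <- spec$n_satisfied > 0 || spec$n_violated > 0
  m <- if (need_inter) min_dist_by_residue(assembly, "A", "B")
       else matrix(numeric(0), 0, 0)
  sat_idx <- which(m <= cutoff, arr.ind = TRUE)
  vio_idx <- which(m > cutoff, arr.ind = TRUE)
  self_res <- discriminating_self_residues(assembly, cutoff)

  achieved <- c(satisfied = min(nrow(sat_idx), spec$n_satisfied),
                violated = min(nrow(vio_idx), spec$n_violated),
                self_a = if (spec$n_self_a > 0)
                  min(length(self_res), spec$n_self_a) else 0L,
                self_b = if (spec$n_self_b > 0)
                  min(length(self_res), spec$n_self_b) else 0L)
  if (achieved["satisfied"] < spec$n_satisfied ||
      achieved["violated"] < spec$n_violated ||
      achieved["self_a"] < spec$n_self_a ||
      achieved["self_b"] < spec$n_self_b)
    stop_invalid("requested planted links unconstructible in this ",
                 "geometry; achievable counts: ",
                 paste(names(achieved), achieved, sep = "=",
                       collapse = ", "))

  pick <- function(idx, k) idx[sample.int(nrow(idx), k), , drop = FALSE]
  sat <- pick(sat_idx, spec$n_satisfied)
  vio <- pick(vio_idx, spec$n_violated)
  res_a <- as.integer(rownames(m)); res_b <- as.integer(colnames(m))

  links <- data.frame(
    protein_a = character(0), residue_a = integer(0),
    protein_b = character(0), residue_b = integer(0),
    planted = character(0))
  add <- function(links, pa, ra, pb, rb, label)
    rbind(links, data.frame(protein_a = pa, residue_a = ra, protein_b = pb,
                            residue_b = rb, planted = label))
  if (spec$n_satisfied > 0)
    links <- add(links, "A", res_a[sat[, 1]], "B", res_b[sat[, 2]],
                 "satisfied")
  if (spec$n_violated > 0)
    links <- add(links, "A", res_a[vio[, 1]], "B", res_b[vio[, 2]],
                 "violated")
  if (spec$n_self_a > 0) {
    r <- sample(self_res, spec$n_self_a)
    links <- add(links, "A", r, "A", r, "self_a")
  }
  if (spec$n_self_b > 0) {
    r <- sample(self_res, spec$n_self_b)
    links <- add(links, "B", r, "B", r, "self_b")
  }
  links <- links[!duplicated(links[, 1:4]), , drop = FALSE]

  # study membership per unique link
  p <- spec$overlap_probabilities
  if (sum(p) == 0) p <- c(1, rep(0, spec$n_studies - 1L))
  p <- p / sum(p)
  mult <- sample.int(spec$n_studies, nrow(links), replace = TRUE, prob = p)
  rows <- do.call(rbind, lapply(seq_len(nrow(links)), function(i) {
    studies <- sort(sample.int(spec$n_studies, mult[i]))
    data.frame(protein_a = links$protein_a[i],
               residue_a = links$residue_a[i],
               protein_b = links$protein_b[i],
               residue_b = links$residue_b[i],
               study_id = paste0("study", studies))
  }))
  records <- crosslink_records(rows$protein_a, rows$residue_a,
                               rows$protein_b, rows$residue_b,
                               rows$study_id)
  truth <- cbind(links, multiplicity = mult)
  list(records = records, truth = truth)
}

#' Write crosslink records as a TSV table
#'
#' @param records A `crosslink_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosslink_table <- function(records, path) {
  cols <- c("protein_a", "residue_a", "protein_b", "residue_b", "study_id")
  utils::write.table(as.data.frame(records)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a homogeneous-Poisson tomogram scene
#'
#' Places particles uniformly at random in a cubic box with a
#' Poisson-distributed count, emulating particle-density quantification in
#' tomograms: the realized density estimator `count / volume` is unbiased
#' across seeds.
#'
#' @param density_per_um3 Expected particle density, particles per cubic
#'   micrometre, `>= 0`.
#' @param box_um Box edge length, micrometres, `> 0`.
#' @param seed Integer seed.
#' @return List with `positions` (matrix n x 3, micrometres), `count`,
#'   `volume_um3` and `density` (realized `count / volume`).
#' @export
generate_tomogram_scene <- function(density_per_um3, box_um = 1, seed = 1) {
  check_scalar(density_per_um3, "density_per_um3", 0)
  check_scalar(box_um, "box_um", 0, strict_lower = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vol <- box_um^3
  count <- stats::rpois(1, density_per_um3 * vol)
  positions <- matrix(stats::runif(3 * count, 0, box_um), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  list(positions = positions, count = count, volume_um3 = vol,
       density = particle_density(count, vol))
}

#' Write a complete fixture set
#'
#' Generates and writes every input the pipeline consumes: study
#' parameters (`params.json`), a C11 assembly (`ring.pdb`), a crosslink
#' table (`links.tsv`) with its ground truth (`truth.json`), and a small
#' particle stack (`stack/particle_*.mrc`).
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed governing all generators.
#' @param n_particles Particles in the demonstration stack.
#' @param n Grid side for the stack volumes.
#' @return Invisibly, a list of the generated objects.
#' @export
make_fixtures <- function(dir, seed = 1, n_particles = 4, n = 32) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "stack"), showWarnings = FALSE)
  params <- default_study_params()
  write_study_params(params, file.path(dir, "params.json"))

  geom <- bell_geometry()
  sub_a <- synthetic_bell_subunit(geom, seed = seed, identity = "A")
  sub_b <- synthetic_bell_subunit(geom, seed = seed + 1, identity = "B")
  ring <- build_ring(sub_a, sub_b,
                     ring_spec(11, default_placement_radius(geom)))
  write_assembly(ring, file.path(dir, "ring.pdb"))

  gen <- generate_crosslink_table(
    ring, xl_generator_spec(n_satisfied = 8, n_violated = 4, n_self_a = 2,
                            n_studies = 3,
                            overlap_probabilities = c(0.6, 0.25, 0.15),
                            seed = seed))
  write_crosslink_table(gen$records, file.path(dir, "links.tsv"))
  jsonlite::write_json(gen$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  tmpl <- synth_bell_volume(geom, n_fold = 11, n = n,
                            voxel_size = ceiling(260 / n))
  stack <- simulate_stack(tmpl, n_particles, noise_sd = 0.5, seed = seed)
  for (i in seq_along(stack$particles))
    write_mrc(density_volume(stack$particles[[i]], stack$voxel_size),
              file.path(dir, "stack", sprintf("particle_%03d.mrc", i)))
  invisible(list(params = params, ring = ring, crosslinks = gen,
                 stack = stack))
}
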