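# Mapping crosslinking-MS residue pairs onto cyclic assemblies and
# classifying them under the Calpha-Calpha distance constraint.

#' Crosslink mapping configuration
#'
#' @param max_ca_distance Maximum Calpha-Calpha distance (Angstrom) for a
#'   crosslink to be considered in agreement with the structure; the
#'   empirical upper bound for common crosslinkers is 30 A (inclusive).
#' @param ambiguity_margin Chain pairs whose distance lies within this
#'   margin of the minimum are reported as co-candidate assignments
#'   (default 2 A).
#' @return Object of class `xl_config`.
#' @export
xl_config <- function(max_ca_distance = 30, ambiguity_margin = 2) {
  check_scalar(max_ca_distance, "max_ca_distance", 0)
  check_scalar(ambiguity_margin, "ambiguity_margin", 0)
  structure(list(max_ca_distance = max_ca_distance,
                 ambiguity_margin = ambiguity_margin),
            class = "xl_config")
}

xl_category <- function(protein_a, residue_a, protein_b, residue_b) {
  ifelse(protein_a == protein_b & residue_a == residue_b, "self",
         ifelse(protein_a == protein_b, "intra-subunit", "inter-subunit"))
}

#' Construct crosslink records
#'
#' @param protein_a,protein_b Identity labels (`"A"`/`"B"`).
#' @param residue_a,residue_b Positive integer residue indices
#'   (per-protein numbering).
#' @param study_id Study label per record.
#' @return `data.frame` of class `crosslink_records` with a derived
#'   `category` column: `self` when both sides name the same residue of the
#'   same protein (diagnostic of homomeric contacts), otherwise
#'   `intra-subunit` (same protein) or `inter-subunit`.
#' @export
crosslink_records <- function(protein_a, residue_a, protein_b, residue_b,
                              study_id = "study1") {
  df <- data.frame(protein_a = as.character(protein_a),
                   residue_a = as.integer(residue_a),
                   protein_b = as.character(protein_b),
                   residue_b = as.integer(residue_b),
                   study_id = rep_len(as.character(study_id),
                                      length(protein_a)))
  if (any(df$residue_a < 1) || any(df$residue_b < 1))
    stop_input("residue indices must be positive")
  df$category <- xl_category(df$protein_a, df$residue_a,
                             df$protein_b, df$residue_b)
  class(df) <- c("crosslink_records", "data.frame")
  df
}

# canonical unordered-pair key: (protein, residue) sides sorted
xl_pair_key <- function(df) {
  a <- paste(df$protein_a, df$residue_a, sep = ":")
  b <- paste(df$protein_b, df$residue_b, sep = ":")
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Parse a crosslink table (CSV or TSV)
#'
#' Expects a header with columns `protein_a`, `residue_a`, `protein_b`,
#' `residue_b`, `study_id`. Duplicate rows are collapsed to unique
#' unordered residue pairs per study (a link A:12--B:40 equals B:40--A:12).
#'
#' @param path File path; the delimiter is sniffed from the header line
#'   (tab if present, comma otherwise).
#' @return A `crosslink_records` data.frame.
#' @export
parse_crosslinks <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("protein_a", "residue_a", "protein_b", "residue_b", "study_id")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop_input("crosslink table is missing column(s): ",
               paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$residue_a) | !is.finite(df$residue_b) |
                 df$residue_a < 1 | df$residue_b < 1)
  if (length(bad))
    stop_input("nonpositive or missing residue index at row(s): ",
               paste(bad, collapse = ", "))
  rec <- crosslink_records(df$protein_a, df$residue_a, df$protein_b,
                           df$residue_b, df$study_id)
  key <- paste(xl_pair_key(rec), rec$study_id, sep = "@")
  out <- rec[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map one crosslink onto an assembly
#'
#' Finds the shortest Calpha-Calpha distance over all admissible chain
#' pairs. Admissible pairs: for self-links, distinct chains of the same
#' identity (a residue cannot crosslink to itself within one chain); for
#' all other links, every ordered pair of chains whose identities match the
#' record (including the same chain, which covers the intra-subunit
#' reading). The link is satisfied when the minimum distance is at most
#' `config$max_ca_distance` (inclusive). Chain pairs within
#' `config$ambiguity_margin` of the minimum are reported as ambiguous
#' co-candidates.
#'
#' @param record One-row `crosslink_records` data.frame (or a list with the
#'   same fields).
#' @param assembly A `ring_assembly`.
#' @param config An [xl_config()].
#' @return Object of class `xl_mapping`: list with `record`,
#'   `best_distance`, `best_chain_pair` (0-based), `satisfied`,
#'   `ambiguous_assignments` (list of 0-based chain pairs) and `unmappable`
#'   (TRUE when a residue lacks a CA atom in the stated subunit or no
#'   admissible chain pair exists, in which case the other fields are NA).
#' @export
map_crosslink <- function(record, assembly, config = xl_config()) {
  stopifnot(inherits(assembly, "ring_assembly"))
  if (is.data.frame(record)) record <- as.list(record[1, ])
  ca <- assembly_ca(assembly)
  pa <- record$protein_a; pb <- record$protein_b
  ra <- record$residue_a; rb <- record$residue_b
  is_self <- pa == pb && ra == rb

  ca_a <- ca[ca$identity == pa & ca$resno == ra, , drop = FALSE]
  ca_b <- ca[ca$identity == pb & ca$resno == rb, , drop = FALSE]
  if (nrow(ca_a) == 0L || nrow(ca_b) == 0L) {
    return(structure(list(record = record, best_distance = NA_real_,
                          best_chain_pair = c(NA_integer_, NA_integer_),
                          satisfied = NA, ambiguous_assignments = list(),
                          unmappable = TRUE),
                     class = "xl_mapping"))
  }

  # all admissible (chain_i, chain_j) combinations and their distances
  grid <- expand.grid(i = seq_len(nrow(ca_a)), j = seq_len(nrow(ca_b)))
  if (is_self)
    grid <- grid[ca_a$chain[grid$i] != ca_b$chain[grid$j], , drop = FALSE]
  if (nrow(grid) == 0L) {
    # e.g. a self-link on an identity with a single chain copy
    return(structure(list(record = record, best_distance = NA_real_,
                          best_chain_pair = c(NA_integer_, NA_integer_),
                          satisfied = NA, ambiguous_assignments = list(),
                          unmappable = TRUE),
                     class = "xl_mapping"))
  }
  d <- sqrt((ca_a$x[grid$i] - ca_b$x[grid$j])^2 +
              (ca_a$y[grid$i] - ca_b$y[grid$j])^2 +
              (ca_a$z[grid$i] - ca_b$z[grid$j])^2)
  best <- which.min(d)
  amb <- which(d <= d[best] + config$ambiguity_margin)
  structure(list(
    record = record,
    best_distance = d[best],
    best_chain_pair = c(ca_a$chain[grid$i[best]], ca_b$chain[grid$j[best]]),
    satisfied = d[best] <= config$max_ca_distance,
    ambiguous_assignments = lapply(amb, function(k)
      c(ca_a$chain[grid$i[k]], ca_b$chain[grid$j[k]])),
    unmappable = FALSE), class = "xl_mapping")
}

#' Map a table of crosslinks onto an assembly
#'
#' @param records A `crosslink_records` data.frame.
#' @param assembly A `ring_assembly`.
#' @param config An [xl_config()].
#' @return List of [map_crosslink()] results, one per record.
#' @export
map_crosslinks <- function(records, assembly, config = xl_config()) {
  lapply(seq_len(nrow(records)), function(i)
    map_crosslink(as.list(records[i, ]), assembly, config))
}

#' Summarize crosslink satisfaction
#'
#' @param results List of [map_crosslink()] results.
#' @return List with a `counts` table (category x
#'   satisfied/violated/unmappable), `n`, and `fraction_satisfied` among
#'   mappable links (NaN when none).
#' @export
satisfaction_summary <- function(results) {
  cats <- c("intra-subunit", "inter-subunit", "self")
  states <- c("satisfied", "violated", "unmappable")
  counts <- matrix(0L, length(cats), length(states),
                   dimnames = list(cats, states))
  for (r in results) {
    cat_i <- xl_category(r$record$protein_a, r$record$residue_a,
                         r$record$protein_b, r$record$residue_b)
    st <- if (isTRUE(r$unmappable)) "unmappable"
    else if (isTRUE(r$satisfied)) "satisfied" else "violated"
    counts[cat_i, st] <- counts[cat_i, st] + 1L
  }
  n_map <- sum(counts[, c("satisfied", "violated")])
  list(counts = counts, n = length(results),
       fraction_satisfied = sum(counts[, "satisfied"]) / n_map)
}

#' Test subunit-arrangement hypotheses with self-links
#'
#' Self-links are satisfiable only where two chains of the same identity
#' fall under the distance cutoff; in an odd alternating ring that happens
#' only at the single homotypic interface. Mapping the same self-links onto
#' the two alternative arrangements (6A/5B, with an A-A interface, vs
#' 5A/6B, with a B-B interface) therefore discriminates between them.
#'
#' @param selflinks `crosslink_records` rows of category `self`.
#' @param assembly_6a5b,assembly_5a6b Two `ring_assembly` objects sharing
#'   `n` and geometry, differing only in identity pattern.
#' @param config An [xl_config()].
#' @return List with one element per arrangement (`arrangement_1`,
#'   `arrangement_2`), each a data.frame with per-link `identity`,
#'   `best_distance`, `satisfied` and the best chain pair; plus
#'   `n_satisfied` per arrangement.
#' @export
arrangement_test <- function(selflinks, assembly_6a5b, assembly_5a6b,
                             config = xl_config()) {
  if (assembly_6a5b$spec$n != assembly_5a6b$spec$n)
    stop_input("assemblies must share the symmetry order n")
  if (any(selflinks$category != "self"))
    stop_input("arrangement_test expects self-links only")
  eval_one <- function(assembly) {
    res <- map_crosslinks(selflinks, assembly, config)
    data.frame(
      identity = selflinks$protein_a,
      residue = selflinks$residue_a,
      best_distance = vapply(res, `[[`, 0, "best_distance"),
      chain_i = vapply(res, function(r) r$best_chain_pair[1], 0L),
      chain_j = vapply(res, function(r) r$best_chain_pair[2], 0L),
      satisfied = vapply(res, `[[`, NA, "satisfied"))
  }
  v1 <- eval_one(assembly_6a5b)
  v2 <- eval_one(assembly_5a6b)
  list(arrangement_1 = v1, arrangement_2 = v2,
       n_satisfied = c(arrangement_1 = sum(v1$satisfied, na.rm = TRUE),
                       arrangement_2 = sum(v2$satisfied, na.rm = TRUE)))
}

#' Cross-study overlap of unique residue pairs
#'
#' @param sets List of per-study character vectors (or `crosslink_records`
#'   data.frames) of unique unordered residue pairs.
#' @return Integer table: number of pairs found in exactly m studies, for
#'   m = 1 .. number of studies.
#' @export
study_overlap <- function(sets) {
  if (length(sets) < 1L) stop_input("need at least one study set")
  keys <- lapply(sets, function(s) {
    if (is.data.frame(s)) unique(xl_pair_key(s)) else unique(as.character(s))
  })
  mult <- table(unlist(keys))
  out <- integer(length(sets))
  names(out) <- as.character(seq_along(sets))
  tab <- table(factor(as.integer(mult), levels = seq_along(sets)))
  out[] <- as.integer(tab)
  out
}

#' Export mapping results as TSV plus a JSON summary
#'
#' @param results List of [map_crosslink()] results.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @param config The [xl_config()] used, recorded in the JSON metadata.
#' @return Invisibly, the results data.frame.
#' @export
write_mapping_results <- function(results, tsv_path = NULL,
                                  json_path = NULL, config = xl_config()) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(protein_a = r$record$protein_a, residue_a = r$record$residue_a,
               protein_b = r$record$protein_b, residue_b = r$record$residue_b,
               study_id = r$record$study_id %||% NA_character_,
               category = xl_category(r$record$protein_a, r$record$residue_a,
                                      r$record$protein_b, r$record$residue_b),
               best_distance = r$best_distance,
               chain_i = r$best_chain_pair[1], chain_j = r$best_chain_pair[2],
               satisfied = r$satisfied, unmappable = r$unmappable,
               n_ambiguous = length(r$ambiguous_assignments))
  }))
  if (!is.null(tsv_path))
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path)) {
    s <- satisfaction_summary(results)
    jsonlite::write_json(list(
      summary = list(counts = as.data.frame(as.table(s$counts)),
                     n = s$n, fraction_satisfied = s$fraction_satisfied),
      policy = list(
        max_ca_distance = config$max_ca_distance,
        ambiguity_margin = config$ambiguity_margin,
        admissible_pairs = paste(
          "self-links: distinct chains of the same identity;",
          "other links: all ordered identity-matching chain pairs",
          "including the same chain"),
        distance_rule = "global minimum; satisfied iff <= max_ca_distance")),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
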