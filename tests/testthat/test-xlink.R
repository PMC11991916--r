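test_that("crosslink tables parse, deduplicate and derive categories", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_a\tresidue_a\tprotein_b\tresidue_b\tstudy_id",
    "A\t12\tB\t40\ts1",
    "B\t40\tA\t12\ts1",          # duplicate with swapped sides
    "A\t7\tA\t7\ts1"), path)
  rec <- parse_crosslinks(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$category, c("inter-subunit", "self"))

  csv <- tempfile(fileext = ".csv")
  writeLines(c("protein_a,residue_a,protein_b,residue_b,study_id",
               "A,3,A,9,s2"), csv)
  rec2 <- parse_crosslinks(csv)
  expect_equal(rec2$category, "intra-subunit")

  bad <- tempfile()
  writeLines(c("protein_a,residue_a,protein_b,residue_b", "A,1,B,2"), bad)
  expect_error(parse_crosslinks(bad), "study_id",
               class = "mitobell_invalid_input")
  neg <- tempfile()
  writeLines(c("protein_a,residue_a,protein_b,residue_b,study_id",
               "A,1,B,2,s1", "A,-4,B,2,s1"), neg)
  expect_error(parse_crosslinks(neg), "row",
               class = "mitobell_invalid_input")
})

test_that("a synthetic 60-pair table parses to 60 unique records", {
  pair <- bell_assembly_pair(seed = 8, n_residues = 40)
  gen <- generate_crosslink_table(
    pair$a6b5,
    xl_generator_spec(n_satisfied = 40, n_violated = 20, seed = 4))
  path <- tempfile(fileext = ".tsv")
  write_crosslink_table(gen$records, path)
  expect_equal(nrow(parse_crosslinks(path)), 60)
})

test_that("shortest-distance mapping agrees exactly with brute force", {
  cfg <- xl_config()
  for (seed in 1:40) {
    asm <- random_toy_assembly(seed)
    set.seed(seed + 5000)
    n_atoms <- max(asm$chains[[1]]$atoms$resno)
    for (k in 1:3) {
      rec <- list(protein_a = sample(c("A", "B"), 1),
                  residue_a = sample(n_atoms, 1),
                  protein_b = sample(c("A", "B"), 1),
                  residue_b = sample(n_atoms, 1),
                  study_id = "s")
      res <- map_crosslink(rec, asm, cfg)
      oracle <- brute_force_best_distance(rec, asm)
      if (is.infinite(oracle)) {
        expect_true(res$unmappable)
        next
      }
      expect_identical(res$best_distance, oracle)
      # side-swap symmetry
      swapped <- list(protein_a = rec$protein_b, residue_a = rec$residue_b,
                      protein_b = rec$protein_a, residue_b = rec$residue_a,
                      study_id = "s")
      expect_equal(map_crosslink(swapped, asm, cfg)$best_distance,
                   res$best_distance)
    }
  }
})

test_that("the 30 A threshold is inclusive at the boundary", {
  asm <- build_ring(toy_subunit("A", 2, 1), toy_subunit("B", 2, 2),
                    ring_spec(3, 20))
  # overwrite two CA positions so the only A-A inter-chain distance is known
  asm$chains[[1]]$atoms[1, c("x", "y", "z")] <- c(0, 0, 0)
  asm$chains[[3]]$atoms[1, c("x", "y", "z")] <- c(30, 0, 0)
  asm$chains[[1]]$atoms[2, c("x", "y", "z")] <- c(500, 0, 0)
  asm$chains[[3]]$atoms[2, c("x", "y", "z")] <- c(900, 0, 0)
  rec <- list(protein_a = "A", residue_a = 1, protein_b = "A",
              residue_b = 1, study_id = "s")
  res <- map_crosslink(rec, asm, xl_config())
  expect_identical(res$best_distance, 30)
  expect_true(res$satisfied)

  asm$chains[[3]]$atoms[1, "x"] <- 30 + 1e-9
  res2 <- map_crosslink(rec, asm, xl_config())
  expect_gt(res2$best_distance, 30)
  expect_false(res2$satisfied)
})

test_that("self-links require distinct chains; intra links may be 0 A", {
  asm <- build_ring(toy_subunit("A", 4, 1), toy_subunit("B", 4, 2),
                    ring_spec(6, 25))
  rec <- list(protein_a = "A", residue_a = 1, protein_b = "A",
              residue_b = 1, study_id = "s")
  res <- map_crosslink(rec, asm, xl_config())
  expect_gt(res$best_distance, 0)  # same chain excluded for self-links
  # an intra-subunit record on one residue pair includes the same chain:
  # make residues 2 and 3 coincide so the same-chain distance is zero
  asm$chains[[1]]$atoms[3, c("x", "y", "z")] <-
    asm$chains[[1]]$atoms[2, c("x", "y", "z")]
  rec2 <- list(protein_a = "A", residue_a = 2, protein_b = "A",
               residue_b = 3, study_id = "s")
  res2 <- map_crosslink(rec2, asm, xl_config())
  expect_identical(res2$best_distance, 0)
  expect_true(res2$satisfied)
})

test_that("mapping results are invariant under a global rigid rotation", {
  asm <- random_toy_assembly(12)
  rot <- mitobell:::rot_z(37.5 * pi / 180)
  asm_rot <- asm
  for (i in seq_along(asm_rot$chains)) {
    xyz <- as.matrix(asm_rot$chains[[i]]$atoms[, c("x", "y", "z")]) %*%
      t(rot)
    asm_rot$chains[[i]]$atoms$x <- xyz[, 1]
    asm_rot$chains[[i]]$atoms$y <- xyz[, 2]
    asm_rot$chains[[i]]$atoms$z <- xyz[, 3]
  }
  rec <- list(protein_a = "A", residue_a = 1, protein_b = "B",
              residue_b = 2, study_id = "s")
  r1 <- map_crosslink(rec, asm, xl_config())
  r2 <- map_crosslink(rec, asm_rot, xl_config())
  expect_equal(r1$best_distance, r2$best_distance, tolerance = 1e-9)
  expect_identical(r1$satisfied, r2$satisfied)
  expect_identical(r1$best_chain_pair, r2$best_chain_pair)
})

test_that("ambiguous assignments list all pairs within the margin", {
  # C4 ring of a single-atom subunit: all adjacent distances equal
  sub <- subunit_model("A", data.frame(resno = 1, atom = "CA",
                                       x = 0, y = 0, z = 0))
  asm <- build_ring(sub, subunit_model("B", sub$atoms), ring_spec(4, 10))
  rec <- list(protein_a = "A", residue_a = 1, protein_b = "A",
              residue_b = 1, study_id = "s")
  res <- map_crosslink(rec, asm, xl_config(max_ca_distance = 30,
                                           ambiguity_margin = 2))
  # the two A chains are opposite: single admissible ordered pair each way
  expect_length(res$ambiguous_assignments, 2)
  expect_equal(res$best_distance, 20)
})

test_that("satisfaction summaries count categories and fractions", {
  s0 <- satisfaction_summary(list())
  expect_equal(sum(s0$counts), 0)
  expect_true(is.nan(s0$fraction_satisfied))

  pair <- bell_assembly_pair(seed = 5, n_residues = 30)
  gen <- generate_crosslink_table(
    pair$a6b5, xl_generator_spec(n_satisfied = 12, n_violated = 4,
                                 seed = 2))
  res <- map_crosslinks(gen$records, pair$a6b5)
  s <- satisfaction_summary(res)
  expect_equal(sum(s$counts["inter-subunit", c("satisfied", "violated")]),
               16)
  expect_equal(s$counts["inter-subunit", "satisfied"], 12)
  expect_equal(s$fraction_satisfied, 0.75)

  # planted 80%-satisfiable set recovers exactly by construction
  gen80 <- generate_crosslink_table(
    pair$a6b5, xl_generator_spec(n_satisfied = 16, n_violated = 4,
                                 seed = 3))
  s80 <- satisfaction_summary(map_crosslinks(gen80$records, pair$a6b5))
  expect_equal(s80$fraction_satisfied, 0.8)

  # unmappable records are counted, not fatal
  rec_un <- list(protein_a = "A", residue_a = 999, protein_b = "B",
                 residue_b = 1, study_id = "s")
  res_un <- map_crosslink(rec_un, pair$a6b5)
  expect_true(res_un$unmappable)
  s_un <- satisfaction_summary(list(res_un))
  expect_equal(s_un$counts["inter-subunit", "unmappable"], 1)
})

test_that("self-links discriminate the 6A/5B from the 5A/6B arrangement", {
  pair <- bell_assembly_pair(seed = 21, n_residues = 40)
  gen <- generate_crosslink_table(
    pair$a6b5, xl_generator_spec(n_satisfied = 0, n_violated = 0,
                                 n_self_a = 2, n_self_b = 2, seed = 21))
  self_a <- gen$records[gen$records$protein_a == "A", ]
  self_b <- gen$records[gen$records$protein_a == "B", ]

  v <- arrangement_test(gen$records, pair$a6b5, pair$a5b6)
  av <- v$arrangement_1
  bv <- v$arrangement_2
  # A self-links satisfied only where an A-A adjacency exists
  expect_true(all(av$satisfied[av$identity == "A"]))
  expect_false(any(av$satisfied[av$identity == "B"]))
  expect_true(all(bv$satisfied[bv$identity == "B"]))
  expect_false(any(bv$satisfied[bv$identity == "A"]))

  # limiting case: tiny ring, every chain pair under the cutoff
  tiny <- list(
    a6b5 = build_ring(synthetic_bell_subunit(bell_geometry(40, 20, 20, 10),
                                             12, seed = 1, "A"),
                      synthetic_bell_subunit(bell_geometry(40, 20, 20, 10),
                                             12, seed = 2, "B"),
                      ring_spec(11, 5, "A")),
    a5b6 = build_ring(synthetic_bell_subunit(bell_geometry(40, 20, 20, 10),
                                             12, seed = 1, "A"),
                      synthetic_bell_subunit(bell_geometry(40, 20, 20, 10),
                                             12, seed = 2, "B"),
                      ring_spec(11, 5, "B")))
  rec <- crosslink_records("A", 6, "A", 6)
  v2 <- arrangement_test(rec, tiny$a6b5, tiny$a5b6)
  expect_true(v2$arrangement_1$satisfied)
  expect_true(v2$arrangement_2$satisfied)

  expect_error(
    arrangement_test(rec, tiny$a6b5,
                     build_ring(toy_subunit("A", 2, 1),
                                toy_subunit("B", 2, 2), ring_spec(5, 10))),
    class = "mitobell_invalid_input")
})

test_that("study overlap histograms match a brute-force recount", {
  out <- study_overlap(list(c("p", "q", "r"), c("q", "r"), "r"))
  expect_equal(as.integer(out), c(1, 1, 1))

  same <- replicate(3, c("u", "v"), simplify = FALSE)
  expect_equal(as.integer(study_overlap(same)), c(0, 0, 2))

  set.seed(31)
  pool <- replicate(30, paste0("pair", sample(1e6, 1)))
  sets <- lapply(1:4, function(i) unique(sample(pool, 12)))
  out2 <- study_overlap(sets)
  # oracle: count multiplicity per pair by direct membership tests
  all_pairs <- unique(unlist(sets))
  mult <- vapply(all_pairs, function(p)
    sum(vapply(sets, function(s) p %in% s, logical(1))), integer(1))
  expect_equal(as.integer(out2),
               as.integer(table(factor(mult, levels = 1:4))))
})

test_that("mapping results export to TSV and JSON with policy metadata", {
  pair <- bell_assembly_pair(seed = 2, n_residues = 20)
  gen <- generate_crosslink_table(
    pair$a6b5, xl_generator_spec(n_satisfied = 3, n_violated = 2,
                                 seed = 5))
  res <- map_crosslinks(gen$records, pair$a6b5)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  df <- write_mapping_results(res, tsv, js)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(gen$records))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$policy$max_ca_distance, 30)
  expect_match(meta$policy$admissible_pairs, "distinct chains")
})
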