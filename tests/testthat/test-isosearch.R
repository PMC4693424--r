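test_that("a residue equal to the polymer matches at least identically", {
  g <- parse_smiles("NCC(=O)O")
  idx <- build_index(g, uniform_frequencies())
  hits <- search_root(idx, to_line_graph(g), mode = "strict")
  expect_gte(length(hits), 1L)
  expect_true(paste(seq_len(nrow(g$atoms)), collapse = ",") %in%
                vapply(hits, `[[`, "", "key"))
})

test_that("the glycine root occurs three times in tri-glycine", {
  gly <- aa_graphs()["glycine"]
  tri <- generate_polymer(gly, default_rules(), n_units = 3,
                          topology = "linear", seed = 7)
  fam <- aa_db()$families$glycine
  idx <- aa_db()$indexes$glycine[[as.character(fam$root_id)]]
  hits <- search_root(idx, to_line_graph(tri$graph), mode = "strict")
  expect_length(hits, 3L)
  # and they agree with the independent oracle
  root <- fam$residues[[fam$root_id]]
  expect_equal(match_atom_sets(hits),
               naive_substructure(root$graph, tri$graph, "strict"))
})

test_that("family search equals independent per-residue search", {
  db <- aa_db()
  pool <- aa_graphs()[c("cysteine", "glycine", "alanine", "serine")]
  for (s in 1:5) {
    target <- generate_polymer(pool, default_rules(), n_units = 3,
                               topology = "linear", seed = 200 + s)$graph
    tlg <- to_line_graph(target)
    for (nm in names(pool)) {
      fam <- db$families[[nm]]
      got <- search_family(fam, tlg, mode = "strict",
                           indexes = db$indexes[[nm]], freq = db$freq)
      for (rid in seq_along(fam$residues)) {
        expect_equal(match_atom_sets(got[[rid]]),
                     naive_substructure(fam$residues[[rid]]$graph, target,
                                        "strict"),
                     info = sprintf("%s residue %d seed %d", nm, rid, s))
      }
    }
  }
})

test_that("di-cysteine: singly-truncated residues and the root all match", {
  cysg <- aa_graphs()["cysteine"]
  di <- generate_polymer(cysg, default_rules(), n_units = 2,
                         topology = "linear", seed = 5)
  db <- aa_db()
  fam <- db$families$cysteine
  got <- search_family(fam, to_line_graph(di$graph), mode = "strict",
                       indexes = db$indexes$cysteine, freq = db$freq)
  lvl1 <- which(vapply(fam$residues, `[[`, 0L, "level") == 1L)
  for (rid in lvl1) expect_gte(length(got[[rid]]), 1L)
  expect_equal(length(got[[fam$root_id]]), 2L)   # root at both positions
})

test_that("an absent root prunes the whole family", {
  db <- aa_db()
  fam <- db$families$tryptophan
  target <- parse_smiles("CCCCCC")     # no nitrogen at all
  got <- search_family(fam, to_line_graph(target), mode = "strict",
                       indexes = db$indexes$tryptophan, freq = db$freq)
  expect_true(all(lengths(got) == 0L))
})

test_that("region-restricted search matches the oracle and the full search", {
  db <- aa_db()
  pool <- aa_graphs()[c("glycine", "alanine")]
  target <- generate_polymer(pool, default_rules(), n_units = 4,
                             topology = "linear", seed = 31)$graph
  tlg <- to_line_graph(target)
  fam <- db$families$glycine
  full <- search_family(fam, tlg, mode = "strict",
                        indexes = db$indexes$glycine, freq = db$freq)
  allatoms <- seq_len(nrow(target$atoms))
  same <- search_local(fam, tlg, region = allatoms, mode = "strict",
                       indexes = db$indexes$glycine, freq = db$freq)
  for (rid in seq_along(fam$residues))
    expect_equal(match_atom_sets(same[[rid]]), match_atom_sets(full[[rid]]))
  # a region excluding every occurrence yields nothing
  none <- search_local(fam, tlg, region = 1:2, mode = "strict",
                       indexes = db$indexes$glycine, freq = db$freq)
  expect_true(all(lengths(none) == 0L))
  # restricted region agrees with the restricted oracle
  half <- allatoms[allatoms <= nrow(target$atoms) %/% 2]
  part <- search_local(fam, tlg, region = half, mode = "strict",
                       indexes = db$indexes$glycine, freq = db$freq)
  for (rid in seq_along(fam$residues))
    expect_equal(match_atom_sets(part[[rid]]),
                 naive_substructure(fam$residues[[rid]]$graph, target,
                                    "strict", region = half))
})

test_that("index-guided search is complete on random molecule pairs", {
  freq <- uniform_frequencies()
  for (s in 1:25) {
    target <- rand_molecule(12 + (s %% 14), seed = 6000 + s,
                            extra_edges = s %% 3)
    query <- if (s %% 4 == 0) rand_molecule(4, seed = 7000 + s)
    else rand_query(target, 3 + (s %% 4), seed = 7000 + s)
    if (nrow(query$bonds) == 0) next
    idx <- build_index(query, freq)
    tlg <- to_line_graph(target)
    for (mode in c("strict", "light")) {
      got <- match_atom_sets(search_root(idx, tlg, mode = mode))
      expect_equal(got, naive_substructure(query, target, mode),
                   info = sprintf("seed %d mode %s", s, mode))
    }
    strict <- match_atom_sets(search_root(idx, tlg, mode = "strict"))
    light <- match_atom_sets(search_root(idx, tlg, mode = "light"))
    expect_true(all(strict %in% light))
  }
})

test_that("the match cap truncates pathological searches with a warning", {
  # a methane query in a long alkane: many single-atom matches
  target <- parse_smiles(paste(rep("C", 30), collapse = ""))
  query <- rand_query(target, 2, seed = 1)
  idx <- build_index(query, uniform_frequencies())
  expect_warning(
    hits <- search_root(idx, to_line_graph(target), mode = "light",
                        max_matches = 5L),
    "cap")
  expect_lte(length(hits), 5L)
})
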