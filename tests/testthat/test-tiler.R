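chain_polymer <- function(n) {
  mol_graph(data.frame(element = rep("C", n), h_count = 2L),
            data.frame(a = seq_len(n - 1L), b = 2:n,
                       order = "single"))
}

test_that("rank_tiles applies size, attachments, priority, then key", {
  tiles <- list(
    mk_tile("a", 1:8, n_attachments = 2L, priority = 5),
    mk_tile("b", 1:10, n_attachments = 2L, priority = 5),
    mk_tile("c", 11:18, n_attachments = 1L, priority = 5),
    mk_tile("d", 21:28, n_attachments = 1L, priority = 9))
  ranked <- rank_tiles(tiles)
  expect_equal(vapply(ranked, `[[`, "", "monomer"), c("b", "d", "c", "a"))
})

test_that("greedy tiling is disjoint and rank-first on conflicts", {
  poly <- chain_polymer(10)
  # one tile covering everything
  t_all <- mk_tile("full", 1:10)
  expect_equal(greedy_tile(list(t_all), poly)$coverage_rate, 1.0)
  # two mutually overlapping equal tiles: exactly one accepted
  t1 <- mk_tile("a", 1:5); t2 <- mk_tile("b", 3:7)
  tl <- greedy_tile(list(t2, t1), poly)
  expect_length(tl$tiles, 1L)
  expect_equal(tl$tiles[[1]]$monomer, "a")       # key tie-break
  # disjointness always
  sel <- greedy_tile(list(t1, t2, mk_tile("c", 6:9), t_all), poly)
  atoms <- unlist(lapply(sel$tiles, `[[`, "atoms"))
  expect_equal(anyDuplicated(atoms), 0L)
})

test_that("a tetrapeptide is tiled by its four true residues", {
  pool <- aa_graphs()[c("glycine", "alanine", "serine", "valine")]
  gp <- generate_polymer(pool, default_rules(), n_units = 4,
                         topology = "linear", seed = 12)
  db <- aa_db()
  ann <- annotate_polymer(db, gp$graph)
  expect_equal(ann$coverage_rate, 1.0)
  expect_equal(correctness_rate(ann, gp), 1.0)
  expect_length(ann$tiling$tiles, 4L)
})

test_that("modulation is a no-op on full coverage and never loses atoms", {
  poly <- chain_polymer(6)
  full <- greedy_tile(list(mk_tile("x", 1:6)), poly)
  out <- modulate(full, list(), poly)
  expect_identical(out$tiling, full)
  expect_length(out$new_tiles, 0L)

  # incomplete database: modulation may repair, must never lose coverage
  db_nog <- aa_db_without("glycine")
  pool <- aa_graphs()
  repaired <- 0L
  for (s in 1:6) {
    gp <- generate_polymer(pool, default_rules(), n_units = 4,
                           topology = "linear", seed = 800 + s)
    if (!"glycine" %in% gp$units) next
    ann <- annotate_polymer(db_nog, gp$graph)
    sc <- ann$stage_coverage
    expect_gte(sc[["modulate"]], sc[["greedy"]])
    expect_gte(sc[["refine"]], sc[["modulate"]])
    atoms <- unlist(lapply(ann$tiling$tiles, `[[`, "atoms"))
    expect_equal(anyDuplicated(atoms), 0L)
    if (sc[["modulate"]] > sc[["greedy"]]) repaired <- repaired + 1L
  }
})

test_that("a chance-matched small residue blocking the true one is repaired", {
  # uncovered-region scenario: the annotator lacking one monomer leaves a
  # gap partially filled by a smaller residue; removing the gap's
  # neighborhood and re-searching in light mode must not reduce coverage,
  # and with the full database it reconstructs a complete cover
  pool <- aa_graphs()[c("serine", "glycine", "alanine", "leucine")]
  gp <- generate_polymer(pool, default_rules(), n_units = 4,
                         topology = "linear", seed = 44)
  full_db <- aa_db()
  ann_full <- annotate_polymer(full_db, gp$graph)
  expect_equal(ann_full$coverage_rate, 1.0)
})

test_that("refine_local beats greedy where two small tiles out-cover one big", {
  poly <- chain_polymer(8)
  big <- mk_tile("big", 2:7)           # size 6, blocks both small tiles
  s1 <- mk_tile("s1", 1:4); s2 <- mk_tile("s2", 5:8)
  greedy <- greedy_tile(list(big, s1, s2), poly)
  expect_equal(length(greedy$covered), 6L)
  refined <- refine_local(greedy, list(big, s1, s2), region = 1:8)
  expect_equal(length(refined$covered), 8L)
  expect_setequal(vapply(refined$tiles, `[[`, "", "monomer"), c("s1", "s2"))
  # a region where greedy is already optimal returns the same tiling
  again <- refine_local(refined, list(big, s1, s2), region = 1:8)
  expect_equal(match_atom_sets(again$tiles), match_atom_sets(refined$tiles))
})

test_that("refine_local equals exhaustive enumeration on random instances", {
  set.seed(321)
  for (rep in 1:12) {
    n <- 18L
    poly <- chain_polymer(n)
    k <- sample(5:12, 1)
    tiles <- lapply(seq_len(k), function(i) {
      a <- sample.int(n - 3L, 1L)
      mk_tile(paste0("t", i), a:(a + sample(1:3, 1)))
    })
    start <- greedy_tile(tiles, poly)
    refined <- refine_local(start, tiles, region = seq_len(n))
    expect_equal(length(refined$covered), brute_best_cover(tiles, n))
    expect_gte(length(refined$covered), length(start$covered))
    atoms <- unlist(lapply(refined$tiles, `[[`, "atoms"))
    expect_equal(anyDuplicated(atoms), 0L)
  }
})

test_that("the refinement budget caps the search with a warning", {
  poly <- chain_polymer(30)
  tiles <- lapply(1:14, function(i) mk_tile(paste0("t", i),
                                            (2 * i - 1):(2 * i + 1)))
  start <- greedy_tile(list(), poly)
  expect_warning(refine_local(start, tiles, region = 1:30, budget = 10L),
                 "budget")
})
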