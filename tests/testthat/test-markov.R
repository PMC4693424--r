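test_that("frequency learning counts strict labels with smoothing", {
  # single-label corpus: ethane has one C-C single bond
  f <- learn_frequencies(list(parse_smiles("CC")))
  expect_length(f$counts, 1L)
  expect_equal(unname(f$counts[[1]]), 1L)
  # probability of the seen label before smoothing would be 1; smoothed < 1
  lab <- names(f$counts)
  expect_lt(label_prob(f, lab), 1)
  expect_gt(label_prob(f, lab), label_prob(f, "X|Y|single|0|0"))
  # unseen labels keep positive mass
  expect_gt(label_prob(f, "unseen|label"), 0)
  expect_error(learn_frequencies(list()), "empty learning set")
})

test_that("counts agree with direct label tabulation on a peptide corpus", {
  gly <- aa_graphs()["glycine"]
  chains <- lapply(1:5, function(i)
    generate_polymer(gly, default_rules(), n_units = 3 + i,
                     topology = "linear", seed = 40 + i)$graph)
  f <- learn_frequencies(chains, smoothing = 1)
  # oracle: re-count labels straight from the line graphs
  expected <- table(unlist(lapply(chains, function(g)
    to_line_graph(g)$label_strict)))
  expect_equal(sum(f$counts), sum(expected))
  for (l in names(expected)) expect_equal(unname(f$counts[[l]]),
                                          unname(expected[[l]]))
  # the amide C-N bond label is the single most frequent N-containing label
  nlabs <- grep("N", names(f$counts), value = TRUE)
  top <- nlabs[which.max(f$counts[nlabs])]
  expect_match(top, "^C\\|N\\|single")
})

test_that("index ordering starts from the rarest label", {
  # two-bond path with a rare S-S label and a common C-C label
  g <- mol_graph(data.frame(element = c("C", "C", "S"),
                            h_count = c(3L, 2L, 1L)),
                 data.frame(a = c(1L, 2L), b = c(2L, 3L),
                            order = c("single", "single")))
  corpus <- c(lapply(1:10, function(i) parse_smiles("CCCC")),
              list(parse_smiles("CSSC")))
  f <- learn_frequencies(corpus)
  idx <- build_index(g, f)
  lab1 <- to_line_graph(g)$label_strict[idx$order[1]]
  expect_match(lab1, "S")          # rare sulfur bond first
  expect_length(idx$order, 2L)
  # one-bond residue: trivial order
  g1 <- parse_smiles("CO")
  expect_length(build_index(g1, f)$order, 1L)
})

test_that("every index order is a connected permutation", {
  db <- aa_db()
  for (nm in c("tryptophan", "arginine", "histidine", "glycine")) {
    for (idx in db$indexes[[nm]]) {
      expect_setequal(idx$order, seq_along(idx$order))
      lg <- idx$lg
      for (k in seq_along(idx$order)[-1]) {
        # adjacent to at least one earlier node unless a new component starts
        earlier <- idx$order[seq_len(k - 1L)]
        has_link <- any(earlier %in% lg$adj[[idx$order[k]]])
        expect_true(has_link || length(idx$connectivity[[k]]) == 0L)
      }
    }
  }
})

test_that("DP order cost equals the exhaustive minimum on small residues", {
  f <- learn_frequencies(lapply(aa_graphs()[c("glycine", "alanine", "serine",
                                              "cysteine")],
                                identity))
  # residues with <= 6 bonds from several families + random molecules
  small <- list(
    parse_smiles("NCC(=O)O"), parse_smiles("CC(N)C(=O)O"),
    parse_smiles("NC(CS)C(=O)O"),
    rand_molecule(5, 901), rand_molecule(6, 902), rand_molecule(7, 903))
  tested <- 0L
  for (g in small) {
    if (nrow(g$bonds) > 6) next
    lg <- to_line_graph(g)
    p <- label_prob(f, lg$label_strict)
    idx <- build_index(g, f)
    expect_equal(idx$expected_cost, brute_best_order_cost(lg, p),
                 tolerance = 1e-12)
    tested <- tested + 1L
  }
  expect_gte(tested, 4L)
})

test_that("search results are identical under any valid connected order", {
  set.seed(77)
  db <- aa_db()
  fam <- db$families$cysteine
  root <- fam$residues[[fam$root_id]]
  target <- generate_polymer(aa_graphs()[c("cysteine", "glycine", "alanine")],
                             default_rules(), n_units = 4,
                             topology = "linear", seed = 99)$graph
  tlg <- to_line_graph(target)
  ref <- match_atom_sets(search_root(db$indexes$cysteine[[as.character(fam$root_id)]],
                                     tlg, mode = "strict"))
  lg <- to_line_graph(root$graph)
  nb <- length(lg$adj)
  for (rep in 1:10) {
    # random connected order
    ord <- sample.int(nb, 1L)
    while (length(ord) < nb) {
      fr <- setdiff(unique(unlist(lg$adj[ord])), ord)
      if (!length(fr)) fr <- setdiff(seq_len(nb), ord)
      ord <- c(ord, fr[sample.int(length(fr), 1L)])
    }
    conn <- lapply(seq_len(nb), function(k)
      if (k == 1) integer() else
        which(vapply(seq_len(k - 1L), function(j)
          ord[j] %in% lg$adj[[ord[k]]], TRUE)))
    shuffled <- structure(list(order = ord, connectivity = conn,
                               graph = root$graph,
                               residue_id = root$id,
                               monomer = root$monomer_name),
                          class = "markov_index")
    expect_equal(match_atom_sets(search_root(shuffled, tlg, mode = "strict")),
                 ref)
  }
})
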