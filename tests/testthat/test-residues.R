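rules3 <- default_rules()
names(rules3) <- vapply(rules3, `[[`, "", "name")

test_that("find_sites locates functional groups and collapses automorphic hits", {
  cys <- cysteine()
  expect_length(find_sites(cys, rules3[["peptide bond from NH2"]]), 1L)
  expect_length(find_sites(cys, rules3[["peptide bond from C(=O)OH"]]), 1L)
  expect_length(find_sites(cys, rules3[["SH bond"]]), 1L)

  # lysine: alpha and epsilon amines
  lys <- parse_smiles("NCCCCC(N)C(=O)O")
  expect_length(find_sites(lys, rules3[["peptide bond from NH2"]]), 2L)

  # no site on an alkane
  expect_length(find_sites(parse_smiles("CCC"),
                           rules3[["peptide bond from C(=O)OH"]]), 0L)
})

test_that("the amine rule skips amide nitrogens", {
  asn <- parse_smiles("NC(=O)CC(N)C(=O)O")
  sites <- find_sites(asn, rules3[["peptide bond from NH2"]])
  expect_length(sites, 1L)                       # alpha amine only
  # the surviving site is the backbone N (bonded to a CH, not a carbonyl)
  nbrs <- with(asn$bonds, c(b[a == sites[[1]]$attach],
                            a[b == sites[[1]]$attach]))
  carbonyl <- any(vapply(nbrs, function(c)
    any(asn$bonds$order[(asn$bonds$a == c | asn$bonds$b == c) &
                          (asn$atoms$element[asn$bonds$a] == "O" |
                             asn$atoms$element[asn$bonds$b] == "O")] == "double"),
    TRUE))
  expect_false(carbonyl)
})

test_that("apply_rule truncates and rejects stale sites", {
  cys <- cysteine()
  acid <- rules3[["peptide bond from C(=O)OH"]]
  site <- find_sites(cys, acid)[[1]]
  res <- apply_rule(cys, acid, site)
  expect_equal(sum(res$atoms$element == "O"), 1L)      # one O fewer
  expect_equal(nrow(res$atoms), 6L)
  expect_error(apply_rule(res, acid, site), "site-invalid")

  # amine rule on glycine: heavy atoms unchanged, N loses one hydrogen
  gly <- glycine()
  amine <- rules3[["peptide bond from NH2"]]
  s <- find_sites(gly, amine)[[1]]
  res2 <- apply_rule(gly, amine, s)
  expect_equal(nrow(res2$atoms), nrow(gly$atoms))
  expect_equal(res2$atoms$h_count[s$attach],
               gly$atoms$h_count[s$attach] - 1L)
})

test_that("cysteine family has six residues over three levels", {
  fam <- cysteine_family()
  expect_length(fam$residues, 6L)
  lv <- table(vapply(fam$residues, `[[`, 0L, "level"))
  expect_equal(as.integer(lv[c("1", "2", "3")]), c(2L, 3L, 1L))
  expect_length(fam$root_id, 1L)
  expect_equal(fam$residues[[fam$root_id]]$level, 3L)
  # the disulfide rule never appears alone (not standalone)
  lvl1 <- Filter(function(r) r$level == 1L, fam$residues)
  expect_false(any(vapply(lvl1, function(r) "SH bond" %in% r$rules, TRUE)))
})

test_that("glycine with two peptide rules gives three residues", {
  fam <- build_family(glycine(), rules3[c("peptide bond from NH2",
                                          "peptide bond from C(=O)OH")])
  expect_length(fam$residues, 3L)
  expect_equal(fam$residues[[fam$root_id]]$level, 2L)
  root <- fam$residues[[fam$root_id]]$graph
  expect_equal(nrow(root$atoms), 4L)      # N CA C =O
})

test_that("residue sizes decrease along the DAG and children embed in parents", {
  for (fam in list(cysteine_family(),
                   build_family(parse_smiles("NCCCCC(N)C(=O)O",
                                             name = "lysine"),
                                default_rules(), name = "lysine"))) {
    size <- function(r) nrow(r$graph$atoms) + sum(r$graph$atoms$h_count)
    for (i in seq_len(nrow(fam$edges))) {
      p <- fam$residues[[fam$edges$parent[i]]]
      ch <- fam$residues[[fam$edges$child[i]]]
      expect_lt(size(ch), size(p))
      # independent oracle: the child's graph embeds in the parent's
      expect_gt(length(naive_substructure(ch$graph, p$graph, "strict")), 0)
    }
    sizes <- vapply(fam$residues, size, 0)
    expect_equal(which.min(sizes), fam$root_id)
    # every residue reaches down to a level-1 residue via parents
    expect_true(all(vapply(fam$residues, function(r)
      r$level == 1L || r$id %in% fam$edges$child, TRUE)))
  }
})

test_that("build_family is invariant to rule order", {
  skeleton <- function(fam)
    sort(vapply(fam$residues, function(r)
      paste(r$level, nrow(r$graph$atoms), sum(r$graph$atoms$h_count),
            paste(sort(r$rules), collapse = "+")), ""))
  ref <- skeleton(cysteine_family())
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    fam <- build_family(cysteine(), default_rules()[perm])
    expect_equal(skeleton(fam), ref)
  }
})

test_that("a monomer matching no rule yields an empty, flagged family", {
  fam <- build_family(parse_smiles("CCCC", name = "butane"), default_rules(),
                      name = "butane")
  expect_length(fam$residues, 0L)
  expect_true(is.na(fam$root_id))
})

test_that("rules survive a JSON round trip", {
  path <- tempfile(fileext = ".json")
  write_rules(default_rules(), path)
  back <- load_rules(path)
  expect_equal(vapply(back, `[[`, "", "name"),
               vapply(default_rules(), `[[`, "", "name"))
  fam <- build_family(cysteine(), back)
  expect_length(fam$residues, 6L)
})
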