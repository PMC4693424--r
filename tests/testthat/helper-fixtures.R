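# Shared fixtures: cached molecule parses, a lazily-built amino-acid
# database, random molecular graphs, and independent oracles used to
# cross-check the package's search and tiling algorithms.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

aa_smiles <- function() proteinogenic_amino_acids()

aa_graphs <- function() memo("aa_graphs", {
  g <- lapply(aa_smiles(), parse_smiles)
  for (nm in names(g)) g[[nm]]$name <- nm
  g
})

aa_db <- function() memo("aa_db", build_monomer_db(aa_smiles()))

aa_db_without <- function(nm) memo(paste0("aa_db_no_", nm), {
  s <- aa_smiles()
  build_monomer_db(s[names(s) != nm])
})

cysteine <- function() memo("cysteine", parse_smiles("NC(CS)C(=O)O",
                                                     name = "cysteine"))
glycine <- function() memo("glycine", parse_smiles("NCC(=O)O",
                                                   name = "glycine"))

cysteine_family <- function() memo("cysteine_family",
                                   build_family(cysteine(), default_rules()))

# ---- random molecular graphs ------------------------------------------------

# Random connected molecule respecting element valences. All randomness
# comes from the supplied seed.
rand_molecule <- function(n, seed, extra_edges = 1L, p_double = 0.15) {
  set.seed(seed)
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  el <- sample(names(valence), n, replace = TRUE,
               prob = c(0.6, 0.2, 0.15, 0.05))
  cap <- valence[el]
  a <- integer(); b <- integer(); ord <- character()
  used <- integer(n)
  for (v in seq_len(n)[-1]) {
    cand <- which(seq_len(n) < v & used[seq_len(n)] < cap[seq_len(n)])
    cand <- cand[cand < v]
    if (!length(cand)) cand <- v - 1L
    u <- cand[sample.int(length(cand), 1L)]
    o <- if (runif(1) < p_double && cap[u] - used[u] >= 2 &&
             cap[v] - used[v] >= 2) "double" else "single"
    k <- if (o == "double") 2L else 1L
    a <- c(a, u); b <- c(b, v); ord <- c(ord, o)
    used[u] <- used[u] + k; used[v] <- used[v] + k
  }
  for (e in seq_len(extra_edges)) {
    free <- which(used < cap)
    if (length(free) < 2) break
    uv <- sample(free, 2L)
    key <- paste(sort(uv), collapse = "-")
    if (key %in% paste(pmin(a, b), pmax(a, b), sep = "-")) next
    a <- c(a, uv[1]); b <- c(b, uv[2]); ord <- c(ord, "single")
    used[uv] <- used[uv] + 1L
  }
  atoms <- data.frame(element = el, h_count = pmax(0L, unname(cap - used)),
                      aromatic = FALSE, charge = 0L, stringsAsFactors = FALSE)
  mol_graph(atoms, data.frame(a = a, b = b, order = ord,
                              stringsAsFactors = FALSE))
}

# Connected induced subgraph on k atoms, as a query molecule.
rand_query <- function(g, k, seed) {
  set.seed(seed)
  adj <- lapply(seq_len(nrow(g$atoms)), function(i)
    unique(c(g$bonds$b[g$bonds$a == i], g$bonds$a[g$bonds$b == i])))
  start <- sample.int(nrow(g$atoms), 1L)
  sel <- start
  while (length(sel) < k) {
    fr <- setdiff(unique(unlist(adj[sel])), sel)
    if (!length(fr)) break
    sel <- c(sel, fr[sample.int(length(fr), 1L)])
  }
  keep <- sort(sel)
  newid <- rep(NA_integer_, nrow(g$atoms)); newid[keep] <- seq_along(keep)
  bsel <- g$bonds$a %in% keep & g$bonds$b %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  if (nrow(bonds)) { bonds$a <- newid[bonds$a]; bonds$b <- newid[bonds$b] }
  mol_graph(g$atoms[keep, , drop = FALSE], bonds)
}

# ---- independent oracles ----------------------------------------------------

# Naive backtracking substructure search, written independently of the
# package's line-graph engine: plain atom-by-atom assignment in input
# order, with incremental bond checks. Returns sorted-atom-set keys.
naive_substructure <- function(qg, tg, mode = "strict", region = NULL) {
  nq <- nrow(qg$atoms); nt <- nrow(tg$atoms)
  allowed <- rep(TRUE, nt)
  if (!is.null(region)) { allowed[] <- FALSE; allowed[region] <- TRUE }
  tbond <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tg$bonds)))
    assign(paste(tg$bonds$a[i], tg$bonds$b[i]), tg$bonds$order[i],
           envir = tbond)
  get_tbond <- function(x, y) {
    k <- if (x < y) paste(x, y) else paste(y, x)
    if (exists(k, envir = tbond, inherits = FALSE)) get(k, envir = tbond)
    else NA_character_
  }
  ok_atom <- function(q, t) {
    if (qg$atoms$element[q] != tg$atoms$element[t]) return(FALSE)
    if (mode == "strict" && qg$atoms$h_count[q] > tg$atoms$h_count[t])
      return(FALSE)
    TRUE
  }
  found <- character()
  map <- integer(nq)
  recurse <- function(q) {
    if (q > nq) {
      found <<- c(found, paste(sort(map), collapse = ","))
      return(invisible(NULL))
    }
    for (t in which(allowed)) {
      if (t %in% map[seq_len(q - 1L)]) next
      if (!ok_atom(q, t)) next
      fine <- TRUE
      for (i in which((qg$bonds$a == q & qg$bonds$b < q) |
                      (qg$bonds$b == q & qg$bonds$a < q))) {
        other <- if (qg$bonds$a[i] == q) qg$bonds$b[i] else qg$bonds$a[i]
        to <- get_tbond(t, map[other])
        if (is.na(to) ||
            (mode == "strict" && to != qg$bonds$order[i])) { fine <- FALSE; break }
      }
      if (!fine) next
      map[q] <<- t
      recurse(q + 1L)
      map[q] <<- 0L
    }
  }
  recurse(1L)
  sort(unique(found))
}

match_atom_sets <- function(matches) {
  sort(unique(vapply(matches, function(m) paste(m$atoms, collapse = ","), "")))
}

# Brute-force line graph: every unordered pair of bonds sharing an atom.
naive_line_graph_edges <- function(g) {
  nb <- nrow(g$bonds)
  out <- character()
  if (nb < 2) return(out)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    share <- length(intersect(c(g$bonds$a[i], g$bonds$b[i]),
                              c(g$bonds$a[j], g$bonds$b[j]))) > 0
    if (share) out <- c(out, paste(i, j))
  }
  out
}

# Exhaustive best connected order of a line graph under the prefix-product
# cost (independent of the package's DP).
brute_best_order_cost <- function(lg, p) {
  n <- length(lg$adj)
  best <- Inf
  recurse <- function(order, remaining) {
    if (!length(remaining)) {
      best <<- min(best, sum(cumprod(p[order])))
      return(invisible(NULL))
    }
    cand <- if (length(order))
      intersect(unique(unlist(lg$adj[order])), remaining) else remaining
    for (v in cand) recurse(c(order, v), setdiff(remaining, v))
  }
  recurse(integer(), seq_len(n))
  best
}

# Exhaustive maximum-coverage disjoint subset of tiles (for refine_local).
brute_best_cover <- function(tiles, n_total) {
  best <- 0L
  m <- length(tiles)
  recurse <- function(i, covered) {
    if (i > m) { best <<- max(best, length(covered)); return(invisible(NULL)) }
    t <- tiles[[i]]
    if (!length(intersect(covered, t$atoms)))
      recurse(i + 1L, union(covered, t$atoms))
    recurse(i + 1L, covered)
  }
  recurse(1L, integer())
  best
}

# minimal hand-made tile
mk_tile <- function(monomer, atoms, n_attachments = 1L, priority = 10) {
  list(monomer = monomer, residue_id = 1L, atoms = sort(atoms),
       size = length(atoms), n_attachments = n_attachments,
       priority = priority, mode = "strict",
       key = paste(monomer, paste(sort(atoms), collapse = ","), sep = "|"))
}
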