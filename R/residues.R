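# Reaction rules and residue families.
#
# A monomer incorporated in a polymer has lost atoms to every bond it
# formed. Each reaction rule names a functional group (an explicit small
# graph pattern), the atoms lost when the bond forms (whole heavy atoms
# and/or hydrogens), and the atom that becomes the link point. Applying
# subsets of (rule, site) combinations recursively yields the residue
# family of a monomer, organised as a DAG whose smallest member is the
# root residue.

#' Create a chemical reaction rule
#'
#' @param name rule name, e.g. `"peptide bond from NH2"`.
#' @param pattern_atoms data.frame describing the functional-group atoms:
#'   columns `element` (required), `min_h` (minimum hydrogen count,
#'   default 0), `max_h` (maximum, default `NA` = unbounded), `aromatic`
#'   (`NA` = either).
#' @param pattern_bonds data.frame with `a`, `b` (pattern atom indices) and
#'   `order` (a bond order or `"any"`); may be `NULL` for one-atom patterns.
#' @param attach pattern atom index that becomes the attachment (link) point.
#' @param remove_atoms pattern atom indices deleted (with their hydrogens)
#'   on bond formation, e.g. the hydroxyl oxygen of a carboxyl.
#' @param remove_h named list/vector: pattern atom index -> number of
#'   hydrogens deleted from it.
#' @param standalone can this bond type be the only bond a monomer forms?
#'   Disulfide-like bonds cannot, and are skipped at family level 1.
#' @param priority positive number; higher = more frequent bond type in the
#'   target polymer class, used as the third tiling criterion.
#' @param exclude optional list of negative sub-patterns: each is a
#'   `list(atoms =, bonds =, anchor =)` in the same format as the positive
#'   pattern; a site is discarded when the exclude pattern embeds into the
#'   monomer with its anchor atom on the site's attachment atom. Used e.g.
#'   to keep the amine rule off amide nitrogens, which are not
#'   nucleophilic.
#' @return an object of class `reaction_rule`.
#' @export
reaction_rule <- function(name, pattern_atoms, pattern_bonds = NULL, attach,
                          remove_atoms = integer(), remove_h = NULL,
                          standalone = TRUE, priority = 1, exclude = NULL) {
  pattern_atoms <- as.data.frame(pattern_atoms, stringsAsFactors = FALSE)
  stopifnot("element" %in% names(pattern_atoms))
  np <- nrow(pattern_atoms)
  if (is.null(pattern_atoms$min_h)) pattern_atoms$min_h <- 0L
  if (is.null(pattern_atoms$max_h)) pattern_atoms$max_h <- NA_integer_
  if (is.null(pattern_atoms$aromatic)) pattern_atoms$aromatic <- NA
  if (is.null(pattern_bonds) || NROW(pattern_bonds) == 0)
    pattern_bonds <- data.frame(a = integer(), b = integer(),
                                order = character(), stringsAsFactors = FALSE)
  pattern_bonds <- as.data.frame(pattern_bonds, stringsAsFactors = FALSE)
  if (!all(pattern_bonds$order %in% c(BOND_ORDERS, "any")))
    stop("bad pattern bond order")
  remove_atoms <- as.integer(remove_atoms)
  rh <- integer()
  if (!is.null(remove_h) && length(remove_h)) {
    rh <- setNames(as.integer(unlist(remove_h)), names(unlist(remove_h)))
    if (is.null(names(rh)) || any(!nzchar(names(rh))))
      stop("remove_h must be named by pattern atom index")
  }
  if (length(remove_atoms) == 0 && length(rh) == 0)
    stop("a rule must delete something (atoms and/or hydrogens)")
  if (!all(remove_atoms %in% seq_len(np))) stop("remove_atoms out of pattern")
  if (attach %in% remove_atoms) stop("attachment atom cannot be deleted")
  if (any(as.integer(names(rh)) %in% remove_atoms))
    stop("remove_h atom is already wholly deleted")
  exclude <- lapply(exclude %||% list(), function(x) {
    ea <- as.data.frame(x$atoms, stringsAsFactors = FALSE)
    if (is.null(ea$min_h)) ea$min_h <- 0L
    if (is.null(ea$max_h)) ea$max_h <- NA_integer_
    if (is.null(ea$aromatic)) ea$aromatic <- NA
    eb <- if (is.null(x$bonds) || NROW(x$bonds) == 0)
      data.frame(a = integer(), b = integer(), order = character(),
                 stringsAsFactors = FALSE)
    else as.data.frame(x$bonds, stringsAsFactors = FALSE)
    list(atoms = ea, bonds = eb, anchor = as.integer(x$anchor))
  })
  structure(list(name = name, pattern_atoms = pattern_atoms,
                 pattern_bonds = pattern_bonds, attach = as.integer(attach),
                 remove_atoms = remove_atoms, remove_h = rh,
                 standalone = isTRUE(standalone), priority = as.numeric(priority),
                 exclude = exclude),
            class = "reaction_rule")
}

#' @export
print.reaction_rule <- function(x, ...) {
  cat(sprintf("<reaction_rule> %s: %d-atom pattern, attach %d, standalone %s, priority %g\n",
              x$name, nrow(x$pattern_atoms), x$attach, x$standalone, x$priority))
  invisible(x)
}

#' Default reaction rules for peptide-like polymers
#'
#' The three bond types of the classical amino-acid case: a peptide bond
#' seen from the amine side (one N-H lost), a peptide bond seen from the
#' carboxyl side (the hydroxyl OH lost), and the disulfide bond (one S-H
#' lost; cannot be the only bond a monomer forms, hence not standalone).
#' Peptide rules carry the higher priority: peptide-like polymers are
#' chiefly assembled by peptide bonds, other linkages being occasional.
#'
#' @return a list of [reaction_rule] objects.
#' @export
default_rules <- function() {
  list(
    reaction_rule("peptide bond from NH2",
                  data.frame(element = "N", min_h = 1L),
                  attach = 1L, remove_h = c("1" = 1L),
                  standalone = TRUE, priority = 10,
                  exclude = list(list(    # amide N: not nucleophilic
                    atoms = data.frame(element = c("N", "C", "O"),
                                       stringsAsFactors = FALSE),
                    bonds = data.frame(a = c(1L, 2L), b = c(2L, 3L),
                                       order = c("any", "double"),
                                       stringsAsFactors = FALSE),
                    anchor = 1L))),
    reaction_rule("peptide bond from C(=O)OH",
                  data.frame(element = c("C", "O", "O"),
                             min_h = c(0L, 0L, 1L),
                             max_h = c(NA, 0L, NA)),
                  data.frame(a = c(1L, 1L), b = c(2L, 3L),
                             order = c("double", "single")),
                  attach = 1L, remove_atoms = 3L,
                  standalone = TRUE, priority = 10),
    reaction_rule("SH bond",
                  data.frame(element = "S", min_h = 1L, max_h = 1L),
                  attach = 1L, remove_h = c("1" = 1L),
                  standalone = FALSE, priority = 5)
  )
}

#' Read / write reaction rules as JSON
#'
#' @param path file path.
#' @return `load_rules` returns a list of [reaction_rule]; `write_rules`
#'   writes and returns `path` invisibly.
#' @export
load_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    pa <- do.call(rbind, lapply(r$pattern$atoms, function(a)
      data.frame(element = a$element,
                 min_h = if (is.null(a$min_h)) 0L else as.integer(a$min_h),
                 max_h = if (is.null(a$max_h)) NA_integer_ else as.integer(a$max_h),
                 aromatic = if (is.null(a$aromatic)) NA else isTRUE(a$aromatic),
                 stringsAsFactors = FALSE)))
    pb <- NULL
    if (length(r$pattern$bonds))
      pb <- do.call(rbind, lapply(r$pattern$bonds, function(b)
        data.frame(a = as.integer(b$a), b = as.integer(b$b), order = b$order,
                   stringsAsFactors = FALSE)))
    rh <- NULL
    if (length(r$remove_h))
      rh <- setNames(vapply(r$remove_h, function(x) as.integer(x$count), 0L),
                     vapply(r$remove_h, function(x) as.character(x$atom), ""))
    ex <- lapply(r$exclude %||% list(), function(x) list(
      atoms = do.call(rbind, lapply(x$atoms, function(a)
        data.frame(element = a$element,
                   min_h = if (is.null(a$min_h)) 0L else as.integer(a$min_h),
                   max_h = if (is.null(a$max_h)) NA_integer_ else as.integer(a$max_h),
                   aromatic = if (is.null(a$aromatic)) NA else isTRUE(a$aromatic),
                   stringsAsFactors = FALSE))),
      bonds = do.call(rbind, lapply(x$bonds, function(b)
        data.frame(a = as.integer(b$a), b = as.integer(b$b), order = b$order,
                   stringsAsFactors = FALSE))),
      anchor = as.integer(x$anchor)))
    reaction_rule(r$name, pa, pb, attach = r$attach,
                  remove_atoms = unlist(r$remove_atoms) %||% integer(),
                  remove_h = rh, standalone = isTRUE(r$standalone),
                  priority = r$priority %||% 1, exclude = ex)
  })
}

#' @rdname load_rules
#' @param rules list of [reaction_rule] objects.
#' @export
write_rules <- function(rules, path) {
  out <- lapply(rules, function(r) {
    atoms <- lapply(seq_len(nrow(r$pattern_atoms)), function(i) {
      a <- r$pattern_atoms[i, ]
      x <- list(element = a$element, min_h = a$min_h)
      if (!is.na(a$max_h)) x$max_h <- a$max_h
      if (!is.na(a$aromatic)) x$aromatic <- a$aromatic
      x
    })
    bonds <- lapply(seq_len(nrow(r$pattern_bonds)), function(i)
      list(a = r$pattern_bonds$a[i], b = r$pattern_bonds$b[i],
           order = r$pattern_bonds$order[i]))
    rh <- lapply(seq_along(r$remove_h), function(i)
      list(atom = as.integer(names(r$remove_h)[i]), count = r$remove_h[[i]]))
    ex <- lapply(r$exclude %||% list(), function(x) list(
      atoms = lapply(seq_len(nrow(x$atoms)), function(i) {
        a <- x$atoms[i, ]
        y <- list(element = a$element, min_h = a$min_h)
        if (!is.na(a$max_h)) y$max_h <- a$max_h
        if (!is.na(a$aromatic)) y$aromatic <- a$aromatic
        y
      }),
      bonds = lapply(seq_len(NROW(x$bonds)), function(i)
        list(a = x$bonds$a[i], b = x$bonds$b[i], order = x$bonds$order[i])),
      anchor = x$anchor))
    list(name = r$name, pattern = list(atoms = atoms, bonds = bonds),
         attach = r$attach, remove_atoms = as.list(r$remove_atoms),
         remove_h = rh, standalone = r$standalone, priority = r$priority,
         exclude = ex)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- generic atom-level backtracking embedder -------------------------------

# Enumerate embeddings of query graph qg into target graph tg.
# atom_ok(q, t) and bond_ok(qbond_row, tbond_row) decide local
# compatibility; init_map may pre-assign query atoms; region restricts the
# image. Non-induced subgraph semantics: every query bond must be realised,
# extra target bonds between image atoms are allowed.
atom_backtrack <- function(qg, tg, atom_ok, bond_ok,
                           init_map = NULL, region = NULL,
                           max_matches = Inf, find_one = FALSE) {
  nq <- n_atoms(qg); nt <- n_atoms(tg)
  qadj <- mg_adjacency(qg); tadj <- mg_adjacency(tg)
  tlookup <- mg_bond_lookup(tg)
  in_region <- rep(TRUE, nt)
  if (!is.null(region)) { in_region[] <- FALSE; in_region[region] <- TRUE }
  map <- if (is.null(init_map)) rep(NA_integer_, nq) else init_map
  used <- rep(FALSE, nt)
  pre <- which(!is.na(map))
  if (length(pre)) {
    if (anyDuplicated(map[pre])) return(list())
    for (v in pre) {
      t <- map[v]
      if (!in_region[t] || !atom_ok(v, t)) return(list())
    }
    qlk <- mg_bond_lookup(qg)
    for (i in seq_len(n_bonds(qg))) {
      a <- qg$bonds$a[i]; b <- qg$bonds$b[i]
      if (is.na(map[a]) || is.na(map[b])) next
      ti <- mg_bond_between(tlookup, map[a], map[b])
      if (is.na(ti) || !bond_ok(i, ti)) return(list())
    }
  }
  used[map[pre]] <- TRUE

  # visiting order: BFS preferring atoms adjacent to already-mapped ones
  order <- integer(0)
  pending <- which(is.na(map))
  seeded <- which(!is.na(map))
  while (length(pending)) {
    frontier <- unique(unlist(lapply(c(seeded, order), function(v)
      qadj[[v]]$nbr)))
    nxt <- intersect(frontier, pending)
    if (!length(nxt)) nxt <- pending[1]   # new component
    v <- nxt[1]
    order <- c(order, v)
    pending <- setdiff(pending, v)
  }

  results <- list()
  assign_ok <- function(v, t) {
    if (!in_region[t] || used[t] || !atom_ok(v, t)) return(FALSE)
    for (k in seq_along(qadj[[v]]$nbr)) {
      u <- qadj[[v]]$nbr[k]
      if (is.na(map[u])) next
      ti <- mg_bond_between(tlookup, t, map[u])
      if (is.na(ti)) return(FALSE)
      if (!bond_ok(qadj[[v]]$bond[k], ti)) return(FALSE)
    }
    TRUE
  }
  recurse <- function(pos) {
    if (length(results) >= max_matches) return(TRUE)
    if (pos > length(order)) {
      results[[length(results) + 1L]] <<- map
      return(find_one)
    }
    v <- order[pos]
    mapped_nb <- qadj[[v]]$nbr[!is.na(map[qadj[[v]]$nbr])]
    cands <- if (length(mapped_nb)) tadj[[map[mapped_nb[1]]]]$nbr
             else which(in_region & !used)
    for (t in cands) {
      if (!assign_ok(v, t)) next
      map[v] <<- t; used[t] <<- TRUE
      stop_now <- recurse(pos + 1L)
      map[v] <<- NA_integer_; used[t] <<- FALSE
      if (stop_now) return(TRUE)
    }
    FALSE
  }
  if (nq > 0) recurse(1L) else results <- list(integer())
  results
}

# Embedder specialised to mol_graph queries under strict/light residue
# semantics (query h_count is a minimum in strict mode).
embed_graph <- function(qg, tg, mode = c("strict", "light"), init_map = NULL,
                        region = NULL, max_matches = Inf, find_one = FALSE) {
  mode <- match.arg(mode)
  atom_ok <- function(q, t) atom_compatible(qg, q, tg, t, mode)
  bond_ok <- function(qi, ti)
    bond_order_compatible(qg$bonds$order[qi], tg$bonds$order[ti], mode)
  atom_backtrack(qg, tg, atom_ok, bond_ok, init_map = init_map,
                 region = region, max_matches = max_matches,
                 find_one = find_one)
}

# ---- sites ------------------------------------------------------------------

# Embed a structured pattern (atoms: element/min_h/max_h/aromatic; bonds
# with order possibly "any") into a target mol_graph.
match_pattern <- function(pattern_atoms, pattern_bonds, target,
                          init_map = NULL, find_one = FALSE) {
  pa <- pattern_atoms
  pg <- mol_graph(
    data.frame(element = pa$element, h_count = 0L, stringsAsFactors = FALSE),
    if (NROW(pattern_bonds))
      data.frame(a = pattern_bonds$a, b = pattern_bonds$b,
                 order = ifelse(pattern_bonds$order == "any", "single",
                                pattern_bonds$order),
                 stringsAsFactors = FALSE) else NULL)
  atom_ok <- function(q, t) {
    if (pa$element[q] != target$atoms$element[t]) return(FALSE)
    h <- target$atoms$h_count[t]
    if (h < pa$min_h[q]) return(FALSE)
    if (!is.na(pa$max_h[q]) && h > pa$max_h[q]) return(FALSE)
    if (!is.na(pa$aromatic[q]) && pa$aromatic[q] != target$atoms$aromatic[t])
      return(FALSE)
    TRUE
  }
  bond_ok <- function(qi, ti) {
    po <- pattern_bonds$order[qi]
    po == "any" || po == target$bonds$order[ti]
  }
  atom_backtrack(pg, target, atom_ok, bond_ok, init_map = init_map,
                 find_one = find_one,
                 max_matches = if (find_one) 1 else Inf)
}

#' Find the sites where a reaction rule can apply
#'
#' Enumerates embeddings of the rule's functional-group pattern into the
#' monomer; embeddings differing only by a pattern automorphism (and hence
#' deleting the same atoms) are collapsed into one site.
#'
#' @param monomer a [mol_graph].
#' @param rule a [reaction_rule].
#' @return list of site objects, each with fields `rule`, `mapping`
#'   (pattern atom -> monomer atom), `attach`, `del_atoms`, `del_h` (named
#'   counts), `priority`, `standalone`, and a canonical `key`.
#' @export
find_sites <- function(monomer, rule) {
  maps <- match_pattern(rule$pattern_atoms, rule$pattern_bonds, monomer)
  excluded_attach <- function(t) {
    for (ex in rule$exclude) {
      init <- rep(NA_integer_, nrow(ex$atoms)); init[ex$anchor] <- t
      if (length(match_pattern(ex$atoms, ex$bonds, monomer,
                               init_map = init, find_one = TRUE)))
        return(TRUE)
    }
    FALSE
  }
  sites <- list()
  seen <- character()
  for (m in maps) {
    if (length(rule$exclude) && excluded_attach(m[rule$attach])) next
    del_atoms <- sort(m[rule$remove_atoms])
    del_h <- integer()
    if (length(rule$remove_h))
      del_h <- setNames(as.integer(rule$remove_h),
                        as.character(m[as.integer(names(rule$remove_h))]))
    key <- paste(rule$name, m[rule$attach],
                 paste(del_atoms, collapse = ","),
                 paste(sprintf("%s:%d", names(del_h), del_h), collapse = ","),
                 sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    sites[[length(sites) + 1L]] <- list(
      rule = rule$name, mapping = m, attach = m[rule$attach],
      del_atoms = del_atoms, del_h = del_h,
      priority = rule$priority, standalone = rule$standalone, key = key)
  }
  sites[order(vapply(sites, `[[`, "", "key"))]
}

# ---- rule application -------------------------------------------------------

# Validate + apply a set of applications in the coordinates of `g`.
# Returns list(graph, old_ids) or NULL if invalid.
truncate_graph <- function(g, apps) {
  del <- unlist(lapply(apps, `[[`, "del_atoms"))
  if (anyDuplicated(del)) return(NULL)
  hdec <- integer(n_atoms(g))
  for (app in apps) {
    if (length(app$del_h))
      for (k in seq_along(app$del_h)) {
        a <- as.integer(names(app$del_h)[k])
        hdec[a] <- hdec[a] + app$del_h[[k]]
      }
  }
  attach <- vapply(apps, `[[`, 0L, "attach")
  touched <- unique(c(attach, which(hdec > 0)))
  if (any(touched %in% del)) return(NULL)       # a needed atom was deleted
  if (any(hdec > g$atoms$h_count)) return(NULL) # not enough hydrogens
  keep <- setdiff(seq_len(n_atoms(g)), del)
  sub <- mg_induced(g, keep)
  ng <- sub$graph
  ng$atoms$h_count <- ng$atoms$h_count - hdec[sub$old_ids]
  list(graph = ng, old_ids = sub$old_ids)
}

#' Apply a reaction rule at a site
#'
#' Returns a truncated copy of the graph: whole deleted atoms are removed
#' (with their hydrogens) and hydrogen deletions decrement `h_count`.
#' Attributes `old_ids` (new atom id -> previous atom id) and `attachment`
#' (attachment atom in the new ids) are attached to the result.
#'
#' @param g a [mol_graph] (a monomer or an already-truncated residue).
#' @param rule the [reaction_rule] applied.
#' @param site a site from [find_sites] expressed in `g`'s atom ids.
#' @return the truncated [mol_graph].
#' @export
apply_rule <- function(g, rule, site) {
  ok <- all(site$del_atoms <= n_atoms(g)) &&
    all(as.integer(names(site$del_h)) <= n_atoms(g))
  if (ok) {
    els <- g$atoms$element[site$mapping]
    ok <- !anyNA(els) && all(els == rule$pattern_atoms$element)
  }
  res <- if (ok) truncate_graph(g, list(site)) else NULL
  if (is.null(res))
    stop("site-invalid: the site no longer exists on this (truncated) graph")
  out <- res$graph
  attr(out, "old_ids") <- res$old_ids
  attr(out, "attachment") <- match(site$attach, res$old_ids)
  out
}

# ---- family construction ----------------------------------------------------

#' Build the residue family of a monomer
#'
#' Applies every valid subset of (rule, site) combinations to the monomer,
#' breadth-first by level (= number of applications). Non-standalone rules
#' are excluded at level 1 and any residue must involve at least one
#' standalone application (deeper levels are reached by extending a level-1
#' residue). Residues with isomorphic graphs at the same level are merged
#' into a single DAG node; edges connect a residue to each residue carrying
#' exactly one more application, with the atom correspondence of the
#' inclusion stored on the edge. The root is the residue with the fewest
#' atoms (hydrogens included).
#'
#' @param monomer a [mol_graph].
#' @param rules list of [reaction_rule] objects.
#' @param name monomer name (defaults to the graph's name).
#' @return an object of class `residue_family` with fields `monomer_name`,
#'   `monomer`, `residues` (list), `edges` (data.frame `parent`, `child`
#'   and list-column `cmap`), `root_id`, `n_levels`.
#' @export
build_family <- function(monomer, rules, name = monomer$name) {
  stopifnot(inherits(monomer, "mol_graph"), length(rules) > 0)
  apps <- list()
  for (rule in rules) apps <- c(apps, find_sites(monomer, rule))
  if (!length(apps)) {
    fam <- structure(list(monomer_name = name, monomer = monomer,
                          residues = list(),
                          edges = data.frame(parent = integer(),
                                             child = integer()),
                          root_id = NA_integer_, n_levels = 0L),
                     class = "residue_family")
    return(fam)
  }
  m <- length(apps)
  standalone <- vapply(apps, `[[`, TRUE, "standalone")

  # enumerate valid application subsets level by level (canonical order)
  subsets <- list()           # key -> list(idx, trunc)
  frontier <- list()
  for (i in seq_len(m)) {
    if (!standalone[i]) next
    tr <- truncate_graph(monomer, apps[i])
    if (!is.null(tr)) frontier[[paste(i)]] <- list(idx = i, trunc = tr)
  }
  level_sets <- list()
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    level_sets[[lvl]] <- frontier
    nxt <- list()
    for (s in frontier) {
      top <- max(s$idx)
      for (j in seq_len(m)) {
        if (j <= top || j %in% s$idx) next
        idx <- c(s$idx, j)
        tr <- truncate_graph(monomer, apps[idx])
        if (!is.null(tr)) nxt[[paste(idx, collapse = ",")]] <-
          list(idx = idx, trunc = tr)
      }
    }
    frontier <- nxt
  }
  # canonical extension misses subsets whose only standalone app is not the
  # smallest index; recover them by also extending with smaller indices
  all_sets <- list()
  for (L in seq_along(level_sets)) for (s in level_sets[[L]])
    all_sets[[paste(s$idx, collapse = ",")]] <- s
  repeat {
    added <- FALSE
    for (key in names(all_sets)) {
      s <- all_sets[[key]]
      for (j in setdiff(seq_len(m), s$idx)) {
        idx <- sort(c(s$idx, j))
        k2 <- paste(idx, collapse = ",")
        if (!is.null(all_sets[[k2]])) next
        tr <- truncate_graph(monomer, apps[idx])
        if (!is.null(tr)) { all_sets[[k2]] <- list(idx = idx, trunc = tr); added <- TRUE }
      }
    }
    if (!added) break
  }

  # group by level, deduplicate by graph isomorphism
  residues <- list()
  node_of_subset <- list()    # subset key -> residue id
  by_level <- split(all_sets, vapply(all_sets, function(s) length(s$idx), 0L))
  for (L in sort(as.integer(names(by_level)))) {
    sets <- by_level[[as.character(L)]]
    keys <- names(sets)[order(names(sets))]
    reps <- list()            # residue ids introduced at this level
    for (key in keys) {
      s <- sets[[key]]
      g <- s$trunc$graph
      hit <- NA_integer_
      for (rid in reps)
        if (graphs_isomorphic(g, residues[[rid]]$graph)) { hit <- rid; break }
      if (is.na(hit)) {
        rid <- length(residues) + 1L
        sel <- apps[s$idx]
        residues[[rid]] <- list(
          id = rid, monomer_name = name, graph = g,
          atom_origin = s$trunc$old_ids,
          applied = vapply(sel, `[[`, "", "key"),
          rules = vapply(sel, `[[`, "", "rule"),
          level = L,
          attachments = sort(unique(stats::na.omit(match(
            vapply(sel, `[[`, 0L, "attach"), s$trunc$old_ids)))),
          n_attachments = L,
          bond_priority = sum(vapply(sel, `[[`, 0, "priority")),
          subset_keys = key)
        reps <- c(reps, rid)
        hit <- rid
      } else {
        residues[[hit]]$subset_keys <- c(residues[[hit]]$subset_keys, key)
      }
      node_of_subset[[key]] <- hit
    }
  }

  # DAG edges: parent (k apps) -> child (k+1 apps); store child->parent
  # atom correspondence (an embedding of the child graph in the parent's)
  ep <- integer(); ec <- integer(); cmaps <- list()
  seen_edge <- character()
  for (key in names(all_sets)) {
    s <- all_sets[[key]]
    if (length(s$idx) < 2) next
    child_id <- node_of_subset[[key]]
    for (drop in s$idx) {
      pkey <- paste(setdiff(s$idx, drop), collapse = ",")
      pid <- node_of_subset[[pkey]]
      if (is.null(pid)) next
      ekey <- paste(pid, child_id)
      if (ekey %in% seen_edge) next
      seen_edge <- c(seen_edge, ekey)
      cg <- residues[[child_id]]$graph
      pg <- residues[[pid]]$graph
      cmap <- embed_graph(cg, pg, mode = "strict", find_one = TRUE,
                          max_matches = 1)
      if (!length(cmap)) next   # cannot happen for a true inclusion
      ep <- c(ep, pid); ec <- c(ec, child_id)
      cmaps[[length(cmaps) + 1L]] <- cmap[[1]]
    }
  }
  edges <- data.frame(parent = ep, child = ec)
  edges$cmap <- cmaps

  sizes <- vapply(residues, function(r)
    n_atoms(r$graph) + sum(r$graph$atoms$h_count), 0)
  root_id <- which(sizes == min(sizes))
  if (length(root_id) > 1) root_id <- root_id[1]
  structure(list(monomer_name = name, monomer = monomer, residues = residues,
                 edges = edges, root_id = root_id,
                 n_levels = if (length(residues))
                   max(vapply(residues, `[[`, 0L, "level")) else 0L),
            class = "residue_family")
}

#' @export
print.residue_family <- function(x, ...) {
  lv <- table(vapply(x$residues, `[[`, 0L, "level"))
  cat(sprintf("<residue_family> %s: %d residues (levels: %s), root #%s\n",
              x$monomer_name, length(x$residues),
              paste(sprintf("%s:%d", names(lv), lv), collapse = " "),
              x$root_id))
  invisible(x)
}

#' Export a residue family to JSON
#'
#' Residue atoms are written 0-based with their SMILES, levels and DAG
#' edges, matching the package's external interchange format.
#'
#' @param family a `residue_family`.
#' @param path output path.
#' @export
write_family <- function(family, path) {
  res <- lapply(family$residues, function(r) list(
    id = r$id, monomer = r$monomer_name,
    smiles = graph_to_smiles(r$graph), level = r$level,
    applied = as.list(r$rules),
    attachment_atoms = as.list(r$attachments - 1L)))
  edges <- lapply(seq_len(nrow(family$edges)), function(i)
    list(parent = family$edges$parent[i], child = family$edges$child[i]))
  jsonlite::write_json(list(monomer = family$monomer_name,
                            residues = res, dag_edges = edges,
                            root = family$root_id),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
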