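# Branch-and-bound subgraph isomorphism on line graphs.
#
# A residue is located in a polymer by assigning its bond nodes, in index
# order, to compatible bond nodes of the polymer's line graph. Because
# every node after the first is adjacent (in the residue's line graph) to
# an earlier one, candidates always come from the neighborhood of an
# already-mapped polymer bond; any partial assignment violating the
# matching predicate, atom-map consistency or injectivity is pruned
# immediately. The enumeration is complete: every embedding of the residue
# is reported (embeddings covering the same polymer atom set are collapsed
# to one match - the tiler consumes atom sets).

new_match <- function(residue_id, monomer, atom_map, mode) {
  atoms <- sort(unname(atom_map))
  list(residue_id = residue_id, monomer = monomer, atom_map = atom_map,
       atoms = atoms, mode = mode, key = paste(atoms, collapse = ","))
}

#' Search all occurrences of a root residue in a polymer
#'
#' Complete branch-and-bound enumeration of the embeddings of the indexed
#' residue into the polymer, walking the residue's bond nodes in index
#' order. Matches identical as atom sets are reported once.
#'
#' @param index a [build_index] result (carries the residue graph).
#' @param polymer_lg the polymer's [to_line_graph]; for a bond-free
#'   polymer pass the [mol_graph] itself.
#' @param mode `"strict"` or `"light"`.
#' @param region optional atom-id set restricting the polymer image.
#' @param max_matches per-residue cap; exceeding it keeps the matches found
#'   so far and raises a warning.
#' @return list of matches, each with `residue_id`, `monomer`, `atom_map`
#'   (residue atom -> polymer atom), `atoms` (sorted image), `mode`.
#' @export
search_root <- function(index, polymer_lg, mode = c("strict", "light"),
                        region = NULL, max_matches = 10000L) {
  mode <- match.arg(mode)
  qg <- index$graph
  search_residue_lg(qg, index$order, index$connectivity, polymer_lg, mode,
                    region, max_matches,
                    residue_id = index$residue_id, monomer = index$monomer)
}

# core engine: qg with its line-graph visit order + connectivity
search_residue_lg <- function(qg, qorder, connectivity, polymer_lg, mode,
                              region = NULL, max_matches = 10000L,
                              residue_id = NA_integer_,
                              monomer = NA_character_) {
  tg <- if (inherits(polymer_lg, "line_graph")) polymer_lg$parent else polymer_lg
  if (n_bonds(qg) == 0)
    return(search_atoms_only(qg, tg, mode, region, residue_id, monomer))
  if (!inherits(polymer_lg, "line_graph"))
    return(list())                      # bonded residue, bond-free polymer
  nt_atoms <- n_atoms(tg)
  in_region <- rep(TRUE, nt_atoms)
  if (!is.null(region)) { in_region[] <- FALSE; in_region[region] <- TRUE }

  t_at_adj <- mg_adjacency(tg)          # polymer atom -> incident bonds
  nq_atoms <- n_atoms(qg)
  amap <- rep(NA_integer_, nq_atoms)    # residue atom -> polymer atom
  used_atom <- rep(FALSE, nt_atoms)
  used_bond <- rep(FALSE, n_bonds(tg))
  K <- length(qorder)
  results <- list()
  seen <- new.env(parent = emptyenv())
  overflow <- FALSE

  # isolated residue atoms (degree 0) completed after all bonds are placed
  deg <- tabulate(c(qg$bonds$a, qg$bonds$b), nbins = nq_atoms)
  isolated <- which(deg == 0L)

  try_assign <- function(qa, ta) {
    # returns "new" if newly assigned, "ok" if already consistent, FALSE
    if (!is.na(amap[qa])) return(if (amap[qa] == ta) "ok" else FALSE)
    if (used_atom[ta] || !in_region[ta]) return(FALSE)
    if (!atom_compatible(qg, qa, tg, ta, mode)) return(FALSE)
    "new"
  }

  emit <- function() {
    if (!length(isolated)) {
      k <- paste(sort(amap), collapse = ",")
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        results[[length(results) + 1L]] <<- new_match(residue_id, monomer,
                                                      amap, mode)
      }
      return(invisible(NULL))
    }
    # place isolated atoms on any compatible unused polymer atoms
    place <- function(i) {
      if (i > length(isolated)) {
        k <- paste(sort(amap), collapse = ",")
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          results[[length(results) + 1L]] <<- new_match(residue_id, monomer,
                                                        amap, mode)
        }
        return(invisible(NULL))
      }
      qa <- isolated[i]
      for (ta in which(in_region & !used_atom)) {
        if (!atom_compatible(qg, qa, tg, ta, mode)) next
        amap[qa] <<- ta; used_atom[ta] <<- TRUE
        place(i + 1L)
        amap[qa] <<- NA_integer_; used_atom[ta] <<- FALSE
      }
    }
    place(1L)
  }

  recurse <- function(k) {
    if (length(results) >= max_matches) { overflow <<- TRUE; return(invisible(NULL)) }
    if (k > K) { emit(); return(invisible(NULL)) }
    qi <- qorder[k]
    qa <- qg$bonds$a[qi]; qb <- qg$bonds$b[qi]
    earlier <- connectivity[[k]]
    cands <- if (length(earlier)) {
      # bonds incident to the image of a shared, already-mapped atom
      anchor <- if (!is.na(amap[qa])) amap[qa] else amap[qb]
      t_at_adj[[anchor]]$bond
    } else seq_len(n_bonds(tg))
    for (ti in cands) {
      if (used_bond[ti]) next
      ta <- tg$bonds$a[ti]; tb <- tg$bonds$b[ti]
      if (!bond_order_compatible(qg$bonds$order[qi], tg$bonds$order[ti], mode))
        next
      for (flip in c(FALSE, TRUE)) {
        x <- if (flip) tb else ta
        y <- if (flip) ta else tb
        s1 <- try_assign(qa, x)
        if (isFALSE(s1)) next
        if (s1 == "new") { amap[qa] <<- x; used_atom[x] <<- TRUE }
        s2 <- try_assign(qb, y)
        if (!isFALSE(s2)) {
          if (s2 == "new") { amap[qb] <<- y; used_atom[y] <<- TRUE }
          used_bond[ti] <<- TRUE
          recurse(k + 1L)
          used_bond[ti] <<- FALSE
          if (s2 == "new") { amap[qb] <<- NA_integer_; used_atom[y] <<- FALSE }
        }
        if (s1 == "new") { amap[qa] <<- NA_integer_; used_atom[x] <<- FALSE }
        if (ta == tb) break
      }
    }
  }
  recurse(1L)
  if (overflow)
    warning(sprintf("match cap (%d) reached for residue %s; results truncated",
                    max_matches, residue_id))
  results[order(vapply(results, `[[`, "", "key"))]
}

# bond-free residue: match atoms directly on the polymer's atoms
search_atoms_only <- function(qg, tg, mode, region, residue_id, monomer) {
  stopifnot(n_atoms(qg) == 1L)   # multi-atom bond-free residues do not arise
  ok <- vapply(seq_len(n_atoms(tg)), function(t)
    atom_compatible(qg, 1L, tg, t, mode), TRUE)
  if (!is.null(region)) ok[setdiff(seq_len(n_atoms(tg)), region)] <- FALSE
  lapply(which(ok), function(t) new_match(residue_id, monomer, c(t), mode))
}

#' Search a whole residue family in a polymer
#'
#' Seeds the traversal at the family's deepest (childless) residues - the
#' root in the usual single-root case - found with the index-guided
#' branch-and-bound. Each larger residue is then searched only as
#' extensions of the matches of a residue one rule-application deeper
#' (its child in the DAG): the child's atom map anchors the embedding and
#' only the few added atoms are branched on. The contrapositive prune
#' applies throughout: a residue none of whose children matched cannot
#' match and is skipped; if the root is absent the family is absent.
#'
#' @param family a `residue_family`.
#' @param polymer_lg the polymer's line graph (or the polymer graph when it
#'   has no bonds).
#' @param mode `"strict"` or `"light"`.
#' @param indexes optional named list (residue id -> [build_index] result)
#'   for the seed residues; built on the fly from `freq` otherwise.
#' @param freq frequency model used when an index must be built
#'   (default [uniform_frequencies]).
#' @param region optional atom-id set restricting all embeddings.
#' @param max_matches per-residue match cap.
#' @return list over residues: each element is the match list of one
#'   residue (named by residue id); empty lists for unmatched residues.
#' @export
search_family <- function(family, polymer_lg, mode = c("strict", "light"),
                          indexes = NULL, freq = NULL, region = NULL,
                          max_matches = 10000L) {
  mode <- match.arg(mode)
  if (!length(family$residues)) return(list())
  if (is.null(freq)) freq <- uniform_frequencies()
  tg <- if (inherits(polymer_lg, "line_graph")) polymer_lg$parent else polymer_lg
  n <- length(family$residues)
  has_child <- rep(FALSE, n)
  if (nrow(family$edges)) has_child[unique(family$edges$parent)] <- TRUE
  levels <- vapply(family$residues, `[[`, 0L, "level")
  matches <- rep(list(list()), n)

  for (rid in order(-levels, seq_len(n))) {
    r <- family$residues[[rid]]
    if (!has_child[rid]) {
      idx <- indexes[[as.character(rid)]]
      if (is.null(idx) && n_bonds(r$graph) > 0) idx <- build_index(r, freq)
      matches[[rid]] <- if (n_bonds(r$graph) == 0)
        search_atoms_only(r$graph, tg, mode, region, rid, r$monomer_name)
      else search_root(idx, polymer_lg, mode, region, max_matches)
      next
    }
    # extensions of child matches along every outgoing DAG edge
    out <- list(); seen <- character()
    esel <- which(family$edges$parent == rid)
    for (ei in esel) {
      cid <- family$edges$child[ei]
      cmap <- family$edges$cmap[[ei]]    # child atom -> parent atom
      for (cm in matches[[cid]]) {
        init <- rep(NA_integer_, n_atoms(r$graph))
        init[cmap] <- cm$atom_map
        exts <- embed_graph(r$graph, tg, mode = mode, init_map = init,
                            region = region,
                            max_matches = max_matches - length(out))
        for (e in exts) {
          m <- new_match(rid, r$monomer_name, e, mode)
          if (m$key %in% seen) next
          seen <- c(seen, m$key)
          out[[length(out) + 1L]] <- m
        }
        if (length(out) >= max_matches) break
      }
    }
    matches[[rid]] <- out[order(vapply(out, `[[`, "", "key"))]
  }
  names(matches) <- as.character(seq_len(n))
  matches
}

#' Search a residue family inside a restricted polymer region
#'
#' Identical to [search_family] with every embedding confined to the given
#' atom set. Used by the modulation step, which re-searches the uncovered
#' neighborhood in light mode only, keeping the repair local and cheap.
#'
#' @inheritParams search_family
#' @param region non-empty atom-id set.
#' @export
search_local <- function(family, polymer_lg, region,
                         mode = c("strict", "light"), indexes = NULL,
                         freq = NULL, max_matches = 10000L) {
  stopifnot(length(region) > 0)
  search_family(family, polymer_lg, mode = match.arg(mode),
                indexes = indexes, freq = freq, region = region,
                max_matches = max_matches)
}

#' Flatten family match lists into a single match list
#'
#' @param matches result of [search_family].
#' @return one list of matches.
#' @export
flatten_matches <- function(matches) {
  out <- list()
  for (m in matches) out <- c(out, m)
  out
}

#' Export matches as JSON
#'
#' Atom ids are written 0-based, in input-SMILES coordinates.
#'
#' @param matches a flat list of matches (see [flatten_matches]).
#' @param family the `residue_family` the matches refer to.
#' @param path output path.
#' @export
write_matches <- function(matches, family, path) {
  out <- lapply(matches, function(m) list(
    monomer = m$monomer,
    residue_level = family$residues[[m$residue_id]]$level,
    atoms = as.list(m$atoms - 1L),
    mode = m$mode))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
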