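# Monomer tiling: choosing, among the many overlapping residue matches,
# a pairwise-disjoint subset covering as much of the polymer as possible.
# A greedy pass ordered by an Occam's-razor ranking gives the pre-solution;
# modulation repairs uncovered neighborhoods with a local light re-search;
# a local branch-and-bound makes the final selection exact within a region.

#' Turn residue matches into tiles
#'
#' A tile is a residue match annotated with the three greedy criteria:
#' its size (heavy atoms), its number of attachment points (rule
#' applications of the residue), and the aggregate priority of the bond
#' types those rules represent.
#'
#' @param matches flat list of matches (see [flatten_matches]).
#' @param families named list of `residue_family` objects (by monomer name).
#' @return list of tiles.
#' @export
make_tiles <- function(matches, families) {
  tiles <- lapply(matches, function(m) {
    r <- families[[m$monomer]]$residues[[m$residue_id]]
    list(monomer = m$monomer, residue_id = m$residue_id,
         atoms = m$atoms, size = length(m$atoms),
         n_attachments = r$n_attachments, priority = r$bond_priority,
         mode = m$mode,
         key = paste(m$monomer, paste(m$atoms, collapse = ","), sep = "|"))
  })
  # same monomer + same atom set reached through different residues of the
  # family: keep the most plausible (fewest attachments, then priority)
  if (length(tiles) > 1) {
    keys <- vapply(tiles, `[[`, "", "key")
    keep <- logical(length(tiles))
    for (k in unique(keys)) {
      ids <- which(keys == k)
      if (length(ids) > 1) {
        o <- order(vapply(tiles[ids], `[[`, 0L, "n_attachments"),
                   -vapply(tiles[ids], `[[`, 0, "priority"))
        ids <- ids[o]
      }
      keep[ids[1]] <- TRUE
    }
    tiles <- tiles[keep]
  }
  tiles
}

#' Rank tiles by the greedy criteria
#'
#' Total order: larger tiles first (big residues rarely match by chance);
#' among equal sizes, fewer attachment points first (more probable in real
#' polymers); then higher bond priority (polymers are mostly assembled by
#' one dominant bond type); remaining ties broken by a canonical key
#' (monomer name, sorted atom ids) so the whole pipeline is deterministic.
#'
#' @param tiles list of tiles from [make_tiles].
#' @return the tiles, in rank order.
#' @export
rank_tiles <- function(tiles) {
  if (!length(tiles)) return(tiles)
  tiles[order(-vapply(tiles, `[[`, 0L, "size"),
              vapply(tiles, `[[`, 0L, "n_attachments"),
              -vapply(tiles, `[[`, 0, "priority"),
              vapply(tiles, `[[`, "", "key"))]
}

new_tiling <- function(selected, n_total) {
  covered <- sort(unique(unlist(lapply(selected, `[[`, "atoms"))))
  structure(list(tiles = selected, covered = covered,
                 coverage_rate = length(covered) / n_total,
                 n_total = n_total), class = "tiling")
}

#' @export
print.tiling <- function(x, ...) {
  cat(sprintf("<tiling> %d tiles, %d/%d atoms covered (%.3f)\n",
              length(x$tiles), length(x$covered), x$n_total, x$coverage_rate))
  invisible(x)
}

#' Greedy tiling
#'
#' Scans tiles in rank order and accepts each tile that shares no atom
#' with the tiles already accepted.
#'
#' @param tiles list of tiles.
#' @param polymer the [mol_graph] they map onto.
#' @return a `tiling` object (fields `tiles`, `covered`, `coverage_rate`).
#' @export
greedy_tile <- function(tiles, polymer) {
  n <- n_atoms(polymer)
  taken <- rep(FALSE, n)
  selected <- list()
  for (t in rank_tiles(tiles)) {
    if (any(taken[t$atoms])) next
    taken[t$atoms] <- TRUE
    selected[[length(selected) + 1L]] <- t
  }
  new_tiling(selected, n)
}

# lexicographic comparison of equal-coverage tilings by ranked tile keys
tiling_rank_signature <- function(tiling) {
  rt <- rank_tiles(tiling$tiles)
  vapply(rt, function(t) sprintf("%05d|%05d|%012.4f|%s",
                                 99999L - t$size, t$n_attachments,
                                 999999 - t$priority, t$key), "")
}

# pick the better tiling: coverage first, then the greedy rank order
better_tiling <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (length(a$covered) != length(b$covered))
    return(if (length(a$covered) > length(b$covered)) a else b)
  sa <- tiling_rank_signature(a); sb <- tiling_rank_signature(b)
  la <- max(length(sa), length(sb))
  sa <- c(sa, rep("~", la - length(sa)))  # "~" sorts after ranked keys
  sb <- c(sb, rep("~", la - length(sb)))
  for (i in seq_len(la)) {
    if (sa[i] < sb[i]) return(a)
    if (sa[i] > sb[i]) return(b)
  }
  a
}

#' Modulation: local repair of an incomplete tiling
#'
#' Tiles adjacent (sharing a covalent bond) to an uncovered atom are
#' removed; the enlarged uncovered region is re-searched in light mode,
#' which tolerates tautomeric differences; a greedy tiling over the new
#' candidates refills the region. The better of the tilings before and
#' after (coverage first) is returned, so modulation never loses coverage.
#'
#' @param tiling the current `tiling`.
#' @param families named list of `residue_family` objects.
#' @param polymer the polymer [mol_graph].
#' @param polymer_lg its line graph (computed if `NULL`).
#' @param freq optional frequency model for on-the-fly indexes.
#' @param max_matches per-residue match cap of the local search.
#' @return list with fields `tiling` (the retained tiling), `new_tiles`
#'   (the light-search candidates, for later refinement) and `region`.
#' @export
modulate <- function(tiling, families, polymer, polymer_lg = NULL,
                     freq = NULL, max_matches = 10000L) {
  n <- n_atoms(polymer)
  if (length(tiling$covered) == n)
    return(list(tiling = tiling, new_tiles = list(), region = integer()))
  uncovered <- setdiff(seq_len(n), tiling$covered)
  # atoms bonded to an uncovered atom
  adj <- mg_adjacency(polymer)
  fringe <- unique(unlist(lapply(uncovered, function(a) adj[[a]]$nbr)))
  removed <- vapply(tiling$tiles, function(t) any(t$atoms %in% fringe), TRUE)
  retained <- tiling$tiles[!removed]
  region <- sort(unique(c(uncovered,
                          unlist(lapply(tiling$tiles[removed], `[[`, "atoms")))))
  if (is.null(polymer_lg) && n_bonds(polymer) > 0)
    polymer_lg <- to_line_graph(polymer)
  cand <- list()
  for (fam in families) {
    if (!length(fam$residues)) next
    fm <- search_local(fam, polymer_lg, region, mode = "light", freq = freq,
                       max_matches = max_matches)
    cand <- c(cand, make_tiles(flatten_matches(fm), families))
  }
  taken <- rep(FALSE, n)
  for (t in retained) taken[t$atoms] <- TRUE
  selected <- retained
  for (t in rank_tiles(cand)) {
    if (any(taken[t$atoms])) next
    taken[t$atoms] <- TRUE
    selected[[length(selected) + 1L]] <- t
  }
  out <- better_tiling(new_tiling(selected, n), tiling)
  list(tiling = out, new_tiles = cand, region = region)
}

#' Local branch-and-bound refinement
#'
#' Exact maximisation of covered atoms over subsets of the candidate tiles
#' intersecting a region, with the greedy rank order as tie-break. Tiles of
#' the current tiling lying outside the region are frozen; tiles
#' intersecting it re-enter the pool. The search tree is truncated at
#' `budget` nodes (a warning is raised and the best solution found is
#' kept); within the budget the result equals exhaustive subset
#' enumeration.
#'
#' @param tiling the current `tiling`.
#' @param candidate_tiles tiles considered for the region (typically every
#'   match discovered so far).
#' @param region atom-id set (an uncovered neighborhood).
#' @param budget node limit of the branch-and-bound (default 100000).
#' @param polymer the polymer [mol_graph] (for atom count); optional when
#'   `tiling` already carries it.
#' @return the refined `tiling` (never worse than the input).
#' @export
refine_local <- function(tiling, candidate_tiles, region, budget = 100000L,
                         polymer = NULL) {
  n <- tiling$n_total
  in_region <- rep(FALSE, n); in_region[region] <- TRUE
  frozen <- list(); pool <- list()
  for (t in tiling$tiles) {
    if (any(in_region[t$atoms])) pool[[length(pool) + 1L]] <- t
    else frozen[[length(frozen) + 1L]] <- t
  }
  fcov <- rep(FALSE, n)
  for (t in frozen) fcov[t$atoms] <- TRUE
  seen_keys <- vapply(pool, `[[`, "", "key")
  for (t in candidate_tiles) {
    if (!any(in_region[t$atoms])) next
    if (any(fcov[t$atoms])) next
    if (t$key %in% seen_keys) next
    seen_keys <- c(seen_keys, t$key)
    pool[[length(pool) + 1L]] <- t
  }
  pool <- rank_tiles(pool)
  np <- length(pool)
  if (np == 0) return(tiling)

  # optimistic remaining cover: union of atoms of tiles i..np
  rem_atoms <- vector("list", np + 1L)
  rem_atoms[[np + 1L]] <- integer()
  for (i in rev(seq_len(np)))
    rem_atoms[[i]] <- sort(unique(c(rem_atoms[[i + 1L]], pool[[i]]$atoms)))

  best <- NULL
  nodes <- 0L
  over_budget <- FALSE
  taken <- fcov
  sel <- logical(np)

  consider <- function() {
    cur <- new_tiling(c(frozen, pool[sel]), n)
    best <<- better_tiling(cur, best)
  }
  bb <- function(i, cov_now) {
    nodes <<- nodes + 1L
    if (nodes > budget) { over_budget <<- TRUE; return(invisible(NULL)) }
    if (i > np) { consider(); return(invisible(NULL)) }
    ub <- cov_now + sum(!taken[rem_atoms[[i]]])
    if (!is.null(best) && ub < length(best$covered)) return(invisible(NULL))
    t <- pool[[i]]
    if (!any(taken[t$atoms])) {          # include branch first (greedy-like)
      taken[t$atoms] <<- TRUE; sel[i] <<- TRUE
      bb(i + 1L, cov_now + t$size)
      taken[t$atoms] <<- FALSE; sel[i] <<- FALSE
      if (over_budget) return(invisible(NULL))
    }
    bb(i + 1L, cov_now)
  }
  bb(1L, sum(fcov))
  if (over_budget)
    warning(sprintf("refinement budget (%d nodes) exhausted; best found kept",
                    budget))
  better_tiling(best, tiling)
}
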