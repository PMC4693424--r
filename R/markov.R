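# Selectivity index over line-graph bond labels.
#
# The cost of a subgraph search depends on how many partial embeddings
# survive each extension step. Bond-label frequencies learned on a
# representative polymer corpus let us order the bond nodes of a residue so
# that the rarest (most selective) sub-patterns come first. Under a
# first-order independence approximation, the expected number of surviving
# partial matches of the length-k prefix is proportional to the product of
# the label probabilities of its k nodes, so the expected total work of an
# order is the sum of these products over all prefixes. That quantity is
# minimised exactly by dynamic programming over connected prefix sets
# (small residues) or greedily (large ones). Any connected order yields the
# same matches - the index changes speed only, never results.

#' Learn bond-label frequencies from a polymer corpus
#'
#' Counts every strict bond-node label (element pair + bond order +
#' hydrogen counts) over the line graphs of the learning polymers. Add-one
#' style pseudo-counts keep unseen labels at a small positive probability,
#' so rare query labels stay maximally selective without ever being
#' impossible.
#'
#' @param polymers non-empty list of [mol_graph] polymers.
#' @param smoothing pseudo-count added to every label (default 1).
#' @return an object of class `frequency_model` with `counts`, `total`,
#'   `smoothing`.
#' @export
learn_frequencies <- function(polymers, smoothing = 1) {
  if (!length(polymers))
    stop("empty learning set: supply polymers or use uniform_frequencies()")
  counts <- integer()
  for (g in polymers) {
    if (n_bonds(g) == 0) next
    lab <- to_line_graph(g)$label_strict
    tab <- table(lab)
    for (l in names(tab))
      counts[l] <- (if (is.na(counts[l])) 0L else counts[l]) + tab[[l]]
  }
  structure(list(counts = counts, total = sum(counts),
                 smoothing = smoothing), class = "frequency_model")
}

#' A uniform frequency model
#'
#' All labels equally probable; useful when no learning corpus is at hand.
#' Index orders are then driven by connectivity alone.
#'
#' @return a `frequency_model`.
#' @export
uniform_frequencies <- function() {
  structure(list(counts = integer(), total = 0L, smoothing = 1),
            class = "frequency_model")
}

#' Probability of a strict bond label under a frequency model
#'
#' @param freq a `frequency_model`.
#' @param labels character vector of strict labels.
#' @return numeric probabilities in (0, 1].
#' @export
label_prob <- function(freq, labels) {
  v <- length(freq$counts)
  denom <- freq$total + freq$smoothing * (v + 1)
  cnt <- freq$counts[labels]
  cnt[is.na(cnt)] <- 0L
  unname((cnt + freq$smoothing) / denom)
}

#' @export
print.frequency_model <- function(x, ...) {
  cat(sprintf("<frequency_model> %d labels, %d observations, smoothing %g\n",
              length(x$counts), x$total, x$smoothing))
  invisible(x)
}

# expected cost of a connected order: sum over prefixes of prod(p)
order_cost <- function(p, order) {
  sum(cumprod(p[order]))
}

# ---- index construction -----------------------------------------------------

#' Build the selectivity index of a residue
#'
#' Chooses the connected ordering of the residue's line-graph nodes that
#' minimises the expected number of surviving partial embeddings (see the
#' cost model above). Exact dynamic programming over connected prefix sets
#' is used up to `exact_limit` nodes; beyond that a greedy
#' rarest-extension heuristic. Ties are broken toward the lexicographically
#' smallest node order, making index construction deterministic. A residue
#' whose graph is disconnected gets one sub-order per component,
#' concatenated rarest-first.
#'
#' @param residue a residue (from [build_family]) or any object with a
#'   `graph` field; a bare [mol_graph] is also accepted.
#' @param freq a `frequency_model`.
#' @param exact_limit exact-DP size threshold (default 12 line-graph nodes).
#' @return an object of class `markov_index` with `order` (line-graph node
#'   ids), `connectivity` (per position, earlier positions adjacent in the
#'   line graph), `expected_cost`, `labels`, `exact`.
#' @export
build_index <- function(residue, freq, exact_limit = 12L) {
  g <- if (inherits(residue, "mol_graph")) residue else residue$graph
  if (n_bonds(g) == 0)
    stop("residue has no bonds; single-atom residues are matched directly")
  lg <- to_line_graph(g)
  p <- label_prob(freq, lg$label_strict)
  nb <- length(p)

  # line-graph components
  comp <- lg_components(lg)
  orders <- list(); costs <- numeric()
  for (cid in sort(unique(comp))) {
    nodes <- which(comp == cid)
    o <- if (length(nodes) <= exact_limit)
      index_dp(lg, p, nodes) else index_greedy(lg, p, nodes)
    orders[[length(orders) + 1L]] <- o
    costs <- c(costs, order_cost(p, o))
  }
  ord <- order(vapply(orders, function(o) p[o[1]], 0),
               vapply(orders, function(o) o[1], 0L))
  full <- unlist(orders[ord])

  connectivity <- lapply(seq_along(full), function(k) {
    if (k == 1) return(integer())
    which(vapply(seq_len(k - 1L),
                 function(j) full[j] %in% lg$adj[[full[k]]], TRUE))
  })
  structure(list(order = full, connectivity = connectivity,
                 expected_cost = sum(costs),
                 labels = lg$label_strict[full],
                 p = p[full],
                 graph = g, lg = lg,
                 exact = all(vapply(orders, length, 0L) <= exact_limit),
                 residue_id = if (is.list(residue) && !is.null(residue$id))
                   residue$id else NA_integer_,
                 monomer = if (is.list(residue) && !is.null(residue$monomer_name))
                   residue$monomer_name else NA_character_),
            class = "markov_index")
}

#' @export
print.markov_index <- function(x, ...) {
  cat(sprintf("<markov_index> %d bond nodes, expected cost %.4g (%s)\n",
              length(x$order), x$expected_cost,
              if (x$exact) "exact DP" else "greedy"))
  invisible(x)
}

lg_components <- function(lg) {
  n <- length(lg$adj)
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L; queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in lg$adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# exact forward DP over connected prefix subsets (bitmask states)
index_dp <- function(lg, p, nodes) {
  n <- length(nodes)
  if (n == 1) return(nodes)
  pos <- setNames(seq_len(n), nodes)   # node id -> local index
  padj <- lapply(nodes, function(v) unname(pos[as.character(
    intersect(lg$adj[[v]], nodes))]))
  pl <- p[nodes]
  states <- new.env(parent = emptyenv()) # mask -> list(cost, prod, order)
  by_size <- rep(list(character()), n)
  for (i in seq_len(n)) {
    key <- as.character(bitwShiftL(1L, i - 1L))
    assign(key, list(cost = pl[i], prod = pl[i], order = i), envir = states)
    by_size[[1]] <- c(by_size[[1]], key)
  }
  for (sz in seq_len(n - 1L)) {
    for (key in by_size[[sz]]) {
      st <- get(key, envir = states)
      mask <- as.integer(key)
      cand <- sort(unique(unlist(padj[st$order])))
      for (v in cand) {
        bit <- bitwShiftL(1L, v - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        nk <- as.character(bitwOr(mask, bit))
        nprod <- st$prod * pl[v]
        ncost <- st$cost + nprod
        norder <- c(st$order, v)
        old <- if (exists(nk, envir = states, inherits = FALSE))
          get(nk, envir = states) else NULL
        better <- is.null(old) || ncost < old$cost - 1e-15 ||
          (abs(ncost - old$cost) <= 1e-15 &&
             lex_less(nodes[norder], nodes[old$order]))
        if (better) {
          if (is.null(old)) by_size[[sz + 1L]] <- c(by_size[[sz + 1L]], nk)
          assign(nk, list(cost = ncost, prod = nprod, order = norder),
                 envir = states)
        }
      }
    }
  }
  full_key <- as.character(bitwShiftL(1L, n) - 1L)
  nodes[get(full_key, envir = states)$order]
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# greedy rarest-extension heuristic for large residues
index_greedy <- function(lg, p, nodes) {
  start <- nodes[order(p[nodes], nodes)][1]
  ordered <- start
  remaining <- setdiff(nodes, start)
  while (length(remaining)) {
    frontier <- intersect(unique(unlist(lg$adj[ordered])), remaining)
    if (!length(frontier)) frontier <- remaining   # safety, disconnected
    nxt <- frontier[order(p[frontier], frontier)][1]
    ordered <- c(ordered, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  ordered
}
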