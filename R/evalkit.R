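# Synthetic polymers with known ground truth, and evaluation metrics.
#
# Real curated polymer/monomer databases need external downloads, so the
# package evaluates itself on polymers it assembles: known monomers joined
# by the same reaction rules the annotator uses, which makes the true
# monomeric structure available by construction.

#' The twenty proteinogenic amino acids
#'
#' SMILES without stereochemistry (matching modes ignore stereo anyway).
#'
#' @return named character vector of SMILES.
#' @export
proteinogenic_amino_acids <- function() {
  c(alanine       = "CC(N)C(=O)O",
    arginine      = "NC(CCCNC(=N)N)C(=O)O",
    asparagine    = "NC(=O)CC(N)C(=O)O",
    aspartate     = "OC(=O)CC(N)C(=O)O",
    cysteine      = "NC(CS)C(=O)O",
    glutamine     = "NC(=O)CCC(N)C(=O)O",
    glutamate     = "OC(=O)CCC(N)C(=O)O",
    glycine       = "NCC(=O)O",
    histidine     = "NC(Cc1c[nH]cn1)C(=O)O",
    isoleucine    = "CCC(C)C(N)C(=O)O",
    leucine       = "CC(C)CC(N)C(=O)O",
    lysine        = "NCCCCC(N)C(=O)O",
    methionine    = "CSCCC(N)C(=O)O",
    phenylalanine = "NC(Cc1ccccc1)C(=O)O",
    proline       = "OC(=O)C1CCCN1",
    serine        = "NC(CO)C(=O)O",
    threonine     = "CC(O)C(N)C(=O)O",
    tryptophan    = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
    tyrosine      = "NC(Cc1ccc(O)cc1)C(=O)O",
    valine        = "CC(C)C(N)C(=O)O")
}

#' Which rule applications pair into an inter-monomer bond
#'
#' A bond consumes one rule application on each side. The default catalog
#' covers the shipped rules: a peptide bond joins a carboxyl application to
#' an amine application; a disulfide joins two thiol applications.
#'
#' @return list of pairs, each `list(a =, b =, order =)`.
#' @export
default_bond_pairs <- function() {
  list(list(a = "peptide bond from C(=O)OH", b = "peptide bond from NH2",
            order = "single"),
       list(a = "SH bond", b = "SH bond", order = "single"))
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic polymer with known monomeric structure
#'
#' Draws `n_units` monomers (uniformly, with replacement) and joins them by
#' reaction-rule pairs: each bond deletes the atoms both rules specify and
#' adds a covalent bond between the two attachment atoms. The surviving
#' atoms of each unit are recorded as ground-truth tiles. Linear topology
#' chains unit i to unit i+1; branched attaches each new unit to a random
#' earlier unit with a free site; cyclic closes the linear chain.
#'
#' @param monomers named character vector of SMILES (or named list of
#'   [mol_graph]).
#' @param rules list of [reaction_rule] objects.
#' @param n_units number of monomer units (>= 1).
#' @param topology `"linear"`, `"branched"` or `"cyclic"`.
#' @param seed integer seed; the same seed reproduces the same polymer.
#' @param pairs bond-pair catalog (see [default_bond_pairs]); tried in
#'   order, so the first pair is the dominant bond type.
#' @param max_retries resampling attempts when a drawn monomer cannot bond.
#' @return an object of class `gt_polymer`: `graph` (the polymer as a
#'   [mol_graph]), `truth` (list of `list(monomer, atoms)` tiles, disjoint),
#'   `units` (monomer names), `smiles`, `seed`.
#' @export
generate_polymer <- function(monomers, rules, n_units,
                             topology = c("linear", "branched", "cyclic"),
                             seed = 1L, pairs = default_bond_pairs(),
                             max_retries = 20L) {
  topology <- match.arg(topology)
  stopifnot(n_units >= 1)
  if (topology == "cyclic" && n_units < 2)
    stop("cyclic topology needs at least 2 units")
  graphs <- if (inherits(monomers[[1]], "mol_graph")) monomers
  else lapply(monomers, parse_smiles)
  for (nm in names(graphs)) graphs[[nm]]$name <- nm
  with_seed(seed, generate_polymer_impl(graphs, rules, n_units, topology,
                                        pairs, max_retries, seed))
}

generate_polymer_impl <- function(graphs, rules, n_units, topology, pairs,
                                  max_retries, seed) {
  site_cache <- list()
  unit_sites <- function(nm) {
    if (is.null(site_cache[[nm]])) {
      s <- list()
      for (rule in rules) s <- c(s, find_sites(graphs[[nm]], rule))
      site_cache[[nm]] <<- s
    }
    site_cache[[nm]]
  }

  units <- character(0)      # monomer name per unit
  offsets <- integer(0)      # global atom offset per unit
  consumed <- list()         # per unit: site keys used
  atoms <- NULL; bonds <- NULL
  del_global <- integer()    # atoms deleted by bond formation (global ids)
  hdec_global <- integer(0)  # per global atom, hydrogens removed
  extra_bonds <- NULL        # inter-monomer bonds (global ids)

  add_unit <- function(nm) {
    g <- graphs[[nm]]
    off <- if (is.null(atoms)) 0L else nrow(atoms)
    units <<- c(units, nm)
    offsets <<- c(offsets, off)
    consumed[[length(units)]] <<- character()
    atoms <<- rbind(atoms, g$atoms)
    b <- g$bonds
    if (nrow(b)) { b$a <- b$a + off; b$b <- b$b + off }
    bonds <<- rbind(bonds, b)
    hdec_global <<- c(hdec_global, integer(n_atoms(g)))
    invisible(NULL)
  }

  # free, conflict-free sites of a rule on a unit
  free_sites <- function(u, rule_name) {
    nm <- units[u]
    keep <- list()
    for (s in unit_sites(nm)) {
      if (s$rule != rule_name || s$key %in% consumed[[u]]) next
      off <- offsets[u]
      ga <- s$del_atoms + off
      if (any(ga %in% del_global)) next
      if ((s$attach + off) %in% del_global) next
      ok <- TRUE
      if (length(s$del_h)) {
        ids <- as.integer(names(s$del_h)) + off
        if (any(ids %in% del_global)) ok <- FALSE
        else if (any(hdec_global[ids] + s$del_h > atoms$h_count[ids]))
          ok <- FALSE
      }
      if (ok) keep[[length(keep) + 1L]] <- s
    }
    keep
  }

  apply_site <- function(u, s) {
    off <- offsets[u]
    consumed[[u]] <<- c(consumed[[u]], s$key)
    del_global <<- c(del_global, s$del_atoms + off)
    if (length(s$del_h)) {
      ids <- as.integer(names(s$del_h)) + off
      hdec_global[ids] <<- hdec_global[ids] + as.integer(s$del_h)
    }
    s$attach + off
  }

  bond_units <- function(u, v) {
    # try pairs in catalog order, both orientations, random site choice
    for (p in pairs) {
      for (orient in list(c(u, v), c(v, u))) {
        sa <- free_sites(orient[1], p$a)
        sb <- free_sites(orient[2], p$b)
        if (!length(sa) || !length(sb)) next
        s1 <- sa[[sample.int(length(sa), 1L)]]
        s2 <- sb[[sample.int(length(sb), 1L)]]
        if (orient[1] == orient[2]) next
        a1 <- apply_site(orient[1], s1)
        a2 <- apply_site(orient[2], s2)
        extra_bonds <<- rbind(extra_bonds,
                              data.frame(a = a1, b = a2, order = p$order,
                                         stringsAsFactors = FALSE))
        return(TRUE)
      }
    }
    FALSE
  }

  nms <- names(graphs)
  add_unit(nms[sample.int(length(nms), 1L)])
  while (length(units) < n_units) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      nm <- nms[sample.int(length(nms), 1L)]
      add_unit(nm)
      v <- length(units)
      if (topology == "branched") {
        for (u in sample.int(v - 1L)) if (bond_units(u, v)) { ok <- TRUE; break }
      } else ok <- bond_units(v - 1L, v)
      if (ok) break
      # undo the unit that could not be bonded
      stop_at <- offsets[v]
      atoms <- atoms[seq_len(stop_at), , drop = FALSE]
      bonds <- bonds[bonds$a <= stop_at & bonds$b <= stop_at, , drop = FALSE]
      hdec_global <- hdec_global[seq_len(stop_at)]
      units <- units[-v]; offsets <- offsets[-v]
      consumed[[v]] <- NULL
    }
    if (!ok) stop("could not bond a new unit after ", max_retries, " retries")
  }
  if (topology == "cyclic" && length(units) >= 2) {
    if (!bond_units(length(units), 1L))
      stop("could not close the cycle")
  }

  # assemble: drop deleted atoms, renumber, decrement hydrogens
  n <- nrow(atoms)
  keep <- setdiff(seq_len(n), del_global)
  newid <- rep(NA_integer_, n); newid[keep] <- seq_along(keep)
  atoms2 <- atoms[keep, , drop = FALSE]
  atoms2$h_count <- atoms2$h_count - hdec_global[keep]
  allb <- rbind(bonds, extra_bonds)
  bsel <- !(allb$a %in% del_global) & !(allb$b %in% del_global)
  allb <- allb[bsel, , drop = FALSE]
  allb$a <- newid[allb$a]; allb$b <- newid[allb$b]
  g <- mol_graph(atoms2, allb, name = sprintf("synthetic_%d", seed))
  truth <- lapply(seq_along(units), function(u) {
    lo <- offsets[u] + 1L
    hi <- if (u < length(units)) offsets[u + 1L] else n
    list(monomer = units[u], atoms = sort(newid[intersect(lo:hi, keep)]))
  })
  structure(list(graph = g, truth = truth, units = units,
                 smiles = graph_to_smiles(g), seed = seed),
            class = "gt_polymer")
}

#' @export
print.gt_polymer <- function(x, ...) {
  cat(sprintf("<gt_polymer> %d units (%s), %d heavy atoms\n  %s\n",
              length(x$units), paste(x$units, collapse = "-"),
              n_atoms(x$graph), x$smiles))
  invisible(x)
}

# ---- metrics ----------------------------------------------------------------

#' Coverage and correctness of a predicted tiling against ground truth
#'
#' The coverage rate is covered atoms over total heavy atoms. The
#' correctness rate counts atoms lying in a predicted tile that agrees
#' with a curated/ground-truth tile - same monomer name and same atom set;
#' a partially overlapping tile contributes nothing (all-or-nothing per
#' tile, the stricter reading of per-atom agreement).
#'
#' @param predicted a `tiling` or `annotation`.
#' @param truth a `gt_polymer` (or any list with `graph` and `truth`).
#' @return `correctness_rate`: a fraction in `[0, 1]`.
#' @export
correctness_rate <- function(predicted, truth) {
  if (inherits(predicted, "annotation")) predicted <- predicted$tiling
  n <- n_atoms(truth$graph)
  if (predicted$n_total != n)
    stop("tiling and ground truth refer to different polymers")
  truth_keys <- vapply(truth$truth, function(t)
    paste(t$monomer, paste(t$atoms, collapse = ","), sep = "|"), "")
  good <- 0L
  for (t in predicted$tiles) {
    key <- paste(t$monomer, paste(t$atoms, collapse = ","), sep = "|")
    if (key %in% truth_keys) good <- good + length(t$atoms)
  }
  good / n
}

#' Evaluate one prediction: coverage, correctness and TP/FP/FN class
#'
#' True positive: full coverage and full correctness. False positive: full
#' coverage but some wrongly identified monomers. False negative:
#' incomplete coverage.
#'
#' @inheritParams correctness_rate
#' @return list with `coverage_rate`, `correctness_rate`, `cls`.
#' @export
eval_record <- function(predicted, truth) {
  if (inherits(predicted, "annotation")) predicted <- predicted$tiling
  cov <- predicted$coverage_rate
  cor <- correctness_rate(predicted, truth)
  eps <- 1e-9
  cls <- if (cov >= 1 - eps && cor >= 1 - eps) "TP"
  else if (cov >= 1 - eps) "FP" else "FN"
  list(coverage_rate = cov, correctness_rate = cor, cls = cls)
}

#' Classify evaluation records into recall and precision
#'
#' @param records either a list of [eval_record] results, or named counts
#'   `c(TP =, FP =, FN =)`.
#' @return list with `counts` (named integer), `recall` = TP/(TP+FN),
#'   `precision` = TP/(TP+FP), and `undefined` (character vector naming
#'   any rate whose denominator is zero; that rate is `NA`, never NaN).
#' @export
classify <- function(records) {
  if (is.list(records) && !is.null(records[[1]]$cls)) {
    cls <- vapply(records, `[[`, "", "cls")
    counts <- c(TP = sum(cls == "TP"), FP = sum(cls == "FP"),
                FN = sum(cls == "FN"))
  } else {
    records <- unlist(records)
    counts <- c(TP = 0L, FP = 0L, FN = 0L)
    counts[names(records)] <- as.integer(records)
  }
  undefined <- character()
  recall <- if (counts[["TP"]] + counts[["FN"]] > 0)
    counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
  else { undefined <- c(undefined, "recall"); NA_real_ }
  precision <- if (counts[["TP"]] + counts[["FP"]] > 0)
    counts[["TP"]] / (counts[["TP"]] + counts[["FP"]])
  else { undefined <- c(undefined, "precision"); NA_real_ }
  list(counts = counts, recall = recall, precision = precision,
       undefined = undefined)
}

# ---- monomer database JSON --------------------------------------------------

#' Read / write a monomer database (JSON records of name + SMILES)
#'
#' @param path file path.
#' @return `read_monomer_smiles`: named character vector of SMILES.
#' @export
read_monomer_smiles <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  setNames(vapply(raw, `[[`, "", "smiles"),
           vapply(raw, `[[`, "", "name"))
}

#' @rdname read_monomer_smiles
#' @param monomers named character vector of SMILES.
#' @export
write_monomer_smiles <- function(monomers, path) {
  out <- lapply(names(monomers), function(nm)
    list(name = nm, smiles = unname(monomers[[nm]])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
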