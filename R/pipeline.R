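# End-to-end pipeline: build an indexed monomer database once, then
# annotate target polymers against it.

#' Build an indexed monomer database
#'
#' The preliminary step of the method: every monomer is expanded into its
#' residue family by the reaction rules, bond-label frequencies are learned
#' from the polymer corpus (when given), and a selectivity index is built
#' for each family's seed residues (the root in the usual case). The
#' result is a cacheable object that [annotate_polymer] consumes.
#'
#' @param monomers named character vector (or data.frame with `name`,
#'   `smiles`) of monomer SMILES.
#' @param rules list of [reaction_rule] objects (default [default_rules]).
#' @param learning_polymers optional list of polymer [mol_graph]s (or
#'   SMILES strings) for frequency learning; uniform frequencies otherwise.
#' @param smoothing pseudo-count of [learn_frequencies].
#' @param exact_limit exact-DP threshold of [build_index].
#' @return an object of class `monomer_db` with `families`, `freq`,
#'   `indexes`, `rules`.
#' @export
build_monomer_db <- function(monomers, rules = default_rules(),
                             learning_polymers = NULL, smoothing = 1,
                             exact_limit = 12L) {
  if (is.data.frame(monomers))
    monomers <- setNames(monomers$smiles, monomers$name)
  stopifnot(!is.null(names(monomers)), all(nzchar(names(monomers))))
  freq <- if (is.null(learning_polymers)) uniform_frequencies()
  else {
    polys <- lapply(learning_polymers, function(p)
      if (inherits(p, "mol_graph")) p else parse_smiles(p))
    learn_frequencies(polys, smoothing = smoothing)
  }
  families <- list(); indexes <- list()
  for (nm in names(monomers)) {
    g <- parse_smiles(monomers[[nm]], name = nm)
    fam <- build_family(g, rules, name = nm)
    families[[nm]] <- fam
    if (!length(fam$residues)) {
      warning("monomer cannot be bonded by any rule: ", nm)
      next
    }
    has_child <- rep(FALSE, length(fam$residues))
    if (nrow(fam$edges)) has_child[unique(fam$edges$parent)] <- TRUE
    idx <- list()
    for (rid in which(!has_child)) {
      r <- fam$residues[[rid]]
      if (n_bonds(r$graph) > 0)
        idx[[as.character(rid)]] <- build_index(r, freq,
                                                exact_limit = exact_limit)
    }
    indexes[[nm]] <- idx
  }
  structure(list(families = families, freq = freq, indexes = indexes,
                 rules = rules), class = "monomer_db")
}

#' @export
print.monomer_db <- function(x, ...) {
  cat(sprintf("<monomer_db> %d monomers, %d residues total\n",
              length(x$families),
              sum(vapply(x$families, function(f) length(f$residues), 0L))))
  invisible(x)
}

#' Annotate a polymer with its monomeric structure
#'
#' Runs the full method: strict index-guided search of every residue
#' family, greedy tiling, then - if atoms remain uncovered - one or more
#' modulation rounds (local light re-search) and a final local
#' branch-and-bound refinement over the uncovered neighborhood. Coverage
#' never decreases across stages.
#'
#' @param db a `monomer_db`.
#' @param polymer a [mol_graph] or SMILES string.
#' @param max_matches per-residue match cap.
#' @param budget node budget of the final refinement.
#' @param modulation_rounds number of modulation rounds attempted while
#'   atoms remain uncovered (default 1).
#' @return an object of class `annotation`: `polymer`, `tiling`,
#'   `coverage_rate`, `uncovered_atoms`, and `stage_coverage` (named
#'   vector: greedy / modulate / refine).
#' @export
annotate_polymer <- function(db, polymer, max_matches = 10000L,
                             budget = 100000L, modulation_rounds = 1L) {
  if (!inherits(polymer, "mol_graph")) polymer <- parse_smiles(polymer)
  n <- n_atoms(polymer)
  lg <- if (n_bonds(polymer) > 0) to_line_graph(polymer) else polymer

  all_tiles <- list()
  for (nm in names(db$families)) {
    fam <- db$families[[nm]]
    if (!length(fam$residues)) next
    fm <- search_family(fam, lg, mode = "strict",
                        indexes = db$indexes[[nm]], freq = db$freq,
                        max_matches = max_matches)
    all_tiles <- c(all_tiles, make_tiles(flatten_matches(fm), db$families))
  }
  tiling <- greedy_tile(all_tiles, polymer)
  stages <- c(greedy = tiling$coverage_rate)

  light_tiles <- list()
  rounds <- 0L
  while (tiling$coverage_rate < 1 && rounds < modulation_rounds) {
    rounds <- rounds + 1L
    mod <- modulate(tiling, db$families, polymer, polymer_lg = lg,
                    freq = db$freq, max_matches = max_matches)
    tiling <- mod$tiling
    light_tiles <- c(light_tiles, mod$new_tiles)
  }
  stages <- c(stages, modulate = tiling$coverage_rate)

  if (tiling$coverage_rate < 1) {
    uncovered <- setdiff(seq_len(n), tiling$covered)
    adj <- mg_adjacency(polymer)
    fringe <- unique(unlist(lapply(uncovered, function(a) adj[[a]]$nbr)))
    near <- vapply(tiling$tiles, function(t) any(t$atoms %in% fringe), TRUE)
    region <- sort(unique(c(uncovered,
                            unlist(lapply(tiling$tiles[near], `[[`, "atoms")))))
    tiling <- refine_local(tiling, c(all_tiles, light_tiles), region,
                           budget = budget, polymer = polymer)
  }
  stages <- c(stages, refine = tiling$coverage_rate)

  structure(list(polymer = polymer, tiling = tiling,
                 coverage_rate = tiling$coverage_rate,
                 uncovered_atoms = setdiff(seq_len(n), tiling$covered),
                 stage_coverage = stages),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s: coverage %.3f, %d tiles\n",
              if (is.na(x$polymer$name)) "(unnamed polymer)" else x$polymer$name,
              x$coverage_rate, length(x$tiling$tiles)))
  for (t in x$tiling$tiles)
    cat(sprintf("  %-20s atoms [%s]\n", t$monomer,
                paste(t$atoms, collapse = " ")))
  if (length(x$uncovered_atoms))
    cat("  uncovered:", paste(x$uncovered_atoms, collapse = " "), "\n")
  invisible(x)
}

#' Export an annotation as JSON
#'
#' Atom ids are 0-based, in the polymer's input coordinates.
#'
#' @param annotation an `annotation`.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  tiles <- lapply(annotation$tiling$tiles, function(t)
    list(monomer = t$monomer, atoms = as.list(t$atoms - 1L)))
  jsonlite::write_json(
    list(polymer = if (is.na(annotation$polymer$name)) NULL
         else annotation$polymer$name,
         tiles = tiles,
         coverage_rate = annotation$coverage_rate,
         uncovered_atoms = as.list(annotation$uncovered_atoms - 1L)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
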