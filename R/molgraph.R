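#' @importFrom stats setNames
NULL

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Construct a molecular graph
#'
#' A molecular graph is the common substrate of the package: heavy (non-H)
#' atoms as nodes, covalent bonds as edges. Hydrogens are never vertices;
#' they are folded into a per-atom `h_count`.
#'
#' @param atoms data.frame with columns `element` (character, never "H"),
#'   `h_count` (non-negative integer), `aromatic` (logical), `charge`
#'   (integer formal charge). Atom ids are the row positions (1-based).
#' @param bonds data.frame with columns `a`, `b` (atom ids, `a < b`) and
#'   `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' @param name optional molecule name.
#' @param smiles optional originating SMILES string.
#' @return an object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds = NULL, name = NA_character_,
                      smiles = NA_character_) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "h_count") %in% names(atoms)))
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (any(atoms$element == "H"))
    stop("hydrogens must be folded into h_count, not stored as atoms")
  if (any(atoms$h_count < 0)) stop("negative h_count")
  n <- nrow(atoms)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(a = integer(), b = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    swap <- bonds$a > bonds$b
    tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
    if (any(bonds$a == bonds$b)) stop("self-bond")
    if (any(bonds$a < 1L | bonds$b > n)) stop("bond endpoint out of range")
    if (anyDuplicated(paste(bonds$a, bonds$b))) stop("duplicate bond")
    if (!all(bonds$order %in% BOND_ORDERS))
      stop("unknown bond order: ", paste(setdiff(bonds$order, BOND_ORDERS),
                                         collapse = ", "))
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds, name = name, smiles = smiles),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds\n",
              if (is.na(x$name)) "(unnamed)" else x$name,
              nrow(x$atoms), nrow(x$bonds)))
  if (!is.na(x$smiles)) cat("  smiles:", x$smiles, "\n")
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)
n_bonds <- function(g) nrow(g$bonds)

# adjacency: list over atoms; each entry data.frame(nbr, bond)
mg_adjacency <- function(g) {
  n <- n_atoms(g)
  adj <- rep(list(list(nbr = integer(), bond = integer())), n)
  if (n_bonds(g) == 0) return(adj)
  for (i in seq_len(n_bonds(g))) {
    a <- g$bonds$a[i]; b <- g$bonds$b[i]
    adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$bond <- c(adj[[a]]$bond, i)
    adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$bond <- c(adj[[b]]$bond, i)
  }
  adj
}

# bond index lookup: named vector "a-b" -> bond row
mg_bond_lookup <- function(g) {
  if (n_bonds(g) == 0) return(setNames(integer(), character()))
  setNames(seq_len(n_bonds(g)), paste0(g$bonds$a, "-", g$bonds$b))
}

mg_bond_between <- function(lookup, a, b) {
  key <- if (a < b) paste0(a, "-", b) else paste0(b, "-", a)
  idx <- lookup[key]
  if (is.na(idx)) NA_integer_ else unname(idx)
}

# ---- SMILES input (OpenBabel via ChemmineOB) --------------------------------

# Convert one SMILES through OpenBabel; empty output means a parse failure.
ob_convert <- function(smiles, to, add_h = TRUE) {
  src <- paste0(smiles, "\tmol\n")
  opts <- if (add_h) data.frame(names = "h", args = "")
          else data.frame(names = character(), args = character())
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", to, source = src, options = opts))
  if (!nzchar(out)) stop("invalid SMILES: ", smiles)
  out
}

# Read the @<TRIPOS>ATOM / @<TRIPOS>BOND tables of a MOL2 block.
mol2_tables <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  b0 <- grep("^@<TRIPOS>BOND", lines)[1]
  ends <- grep("^@<TRIPOS>", lines)
  a1 <- min(c(ends[ends > a0], length(lines) + 1L)) - 1L
  b1 <- if (is.na(b0)) 0L else min(c(ends[ends > b0], length(lines) + 1L)) - 1L
  atom_lines <- lines[seq(a0 + 1L, a1)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  atoms <- data.frame(
    type = vapply(af, `[`, "", 6L),
    stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.na(b0) && b1 > b0) {
    bond_lines <- lines[seq(b0 + 1L, b1)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bonds <- data.frame(
        a = as.integer(vapply(bf, `[`, "", 2L)),
        b = as.integer(vapply(bf, `[`, "", 3L)),
        type = vapply(bf, `[`, "", 4L),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(bonds))
    bonds <- data.frame(a = integer(), b = integer(), type = character(),
                        stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# Formal charges from the SDF "M  CHG" lines (atom index -> charge).
sdf_formal_charges <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  chg <- lines[grepl("^M  CHG", lines)]
  out <- integer()
  for (l in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)),
                             "[[:space:]]+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) out[as.character(f[2 * i])] <- f[2 * i + 1]
  }
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' Interpretation of the SMILES (valence model, implicit hydrogens, aromatic
#' perception) is delegated to OpenBabel; the resulting explicit-hydrogen
#' structure is folded back into heavy atoms with `h_count`. Atom order
#' follows the order of appearance in the input string, so downstream match
#' coordinates refer to the input as written (no canonicalization).
#'
#' @param smiles a syntactically valid SMILES string.
#' @param name optional molecule name attached to the graph.
#' @return a [mol_graph]. Aromatic bonds carry order `"aromatic"`; Sybyl
#'   amide bonds are recorded as `"single"`.
#' @examples
#' \dontrun{
#' cys <- parse_smiles("NC(CS)C(=O)O", name = "cysteine")
#' }
#' @export
parse_smiles <- function(smiles, name = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  mol2 <- ob_convert(smiles, "MOL2", add_h = TRUE)
  tb <- mol2_tables(mol2)
  type <- tb$atoms$type
  element <- sub("\\..*$", "", type)
  is_h <- element == "H"
  heavy <- which(!is_h)
  if (!length(heavy)) stop("no heavy atoms in SMILES: ", smiles)
  newid <- rep(NA_integer_, length(element))
  newid[heavy] <- seq_along(heavy)

  h_count <- integer(length(heavy))
  keep_a <- integer(); keep_b <- integer(); keep_t <- character()
  for (i in seq_len(nrow(tb$bonds))) {
    a <- tb$bonds$a[i]; b <- tb$bonds$b[i]
    if (is_h[a] && is_h[b]) next            # H2 never expected
    if (is_h[a] || is_h[b]) {
      hv <- if (is_h[a]) b else a
      h_count[newid[hv]] <- h_count[newid[hv]] + 1L
    } else {
      keep_a <- c(keep_a, newid[a]); keep_b <- c(keep_b, newid[b])
      keep_t <- c(keep_t, tb$bonds$type[i])
    }
  }
  order <- vapply(keep_t, function(t) switch(t,
    "1" = "single", "2" = "double", "3" = "triple",
    "ar" = "aromatic", "am" = "single", "du" = "single",
    stop("unexpected MOL2 bond type: ", t)), "")

  charges <- sdf_formal_charges(ob_convert(smiles, "SDF", add_h = FALSE))
  charge <- integer(length(heavy))
  if (length(charges)) {
    for (k in names(charges)) {
      idx <- as.integer(k)           # SDF without H: heavy-atom order matches
      if (idx >= 1 && idx <= length(heavy)) charge[idx] <- charges[[k]]
    }
  }
  atoms <- data.frame(element = element[heavy], h_count = h_count,
                      aromatic = grepl("\\.ar$", type[heavy]),
                      charge = charge, stringsAsFactors = FALSE)
  bonds <- data.frame(a = keep_a, b = keep_b, order = unname(order),
                      stringsAsFactors = FALSE)
  mol_graph(atoms, bonds, name = name, smiles = smiles)
}

# ---- molfile output + SMILES emission ---------------------------------------

# V2000 molfile with explicit hydrogens (forces exact h_count round-trip).
write_molfile <- function(g, name = "mol") {
  nh <- sum(g$atoms$h_count)
  na <- n_atoms(g) + nh
  nb <- n_bonds(g) + nh
  lines <- c(name, " monomerize", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (i in seq_len(n_atoms(g)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, g$atoms$element[i]))
  for (i in seq_len(nh))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, "H"))
  ordnum <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  for (i in seq_len(n_bonds(g)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", g$bonds$a[i],
                              g$bonds$b[i], ordnum[[g$bonds$order[i]]]))
  hid <- n_atoms(g)
  for (i in seq_len(n_atoms(g))) {
    hc <- g$atoms$h_count[i]
    if (hc > 0) for (k in seq_len(hc)) {
      hid <- hid + 1L
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", i, hid, 1L))
    }
  }
  chg <- which(g$atoms$charge != 0L)
  for (i in chg)
    lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, i, g$atoms$charge[i]))
  paste0(paste(c(lines, "M  END", "$$$$"), collapse = "\n"), "\n")
}

#' Emit a SMILES string for a molecular graph
#'
#' Serializes the graph (with its exact hydrogen counts) to a molfile and
#' lets OpenBabel write SMILES. Used mainly to export generated synthetic
#' polymers; the written string is canonical to OpenBabel, not to the
#' original input order.
#'
#' @param g a [mol_graph].
#' @return a SMILES string.
#' @export
graph_to_smiles <- function(g) {
  # "i": no stereo markings (the graph model carries none, and stereo
  # perception on coordinate-free molfiles is needlessly expensive)
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "SMI", source = write_molfile(g),
                              options = data.frame(names = "i", args = "")))
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}

# ---- line graph -------------------------------------------------------------

#' Transform a molecular graph into its line (bond) graph
#'
#' Each covalent bond becomes a node; two nodes are adjacent when their
#' bonds share an atom. Bond nodes keep the identity of their origin atoms,
#' which keeps structures unambiguous (a triangle and a 3-star have
#' different line-graph expansions of the same node multiset). Working on
#' bond labels (two elements + bond order + hydrogen counts) rather than
#' atom labels greatly enlarges the label alphabet, which is what makes the
#' selectivity index effective.
#'
#' @param g a [mol_graph] with at least one bond.
#' @return an object of class `line_graph` with fields `nodes` (the bond
#'   table of `g`), `adj` (list of adjacent node ids), `label_strict`,
#'   `label_light` (per-node label strings) and `parent` (the graph).
#' @export
to_line_graph <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  if (n_bonds(g) == 0)
    stop("no-bond molecule: line graph undefined; use atom-level matching")
  nb <- n_bonds(g)
  adj <- rep(list(integer()), nb)
  at_adj <- mg_adjacency(g)
  for (a in seq_len(n_atoms(g))) {
    inc <- at_adj[[a]]$bond
    if (length(inc) > 1) {
      for (i in inc) adj[[i]] <- c(adj[[i]], setdiff(inc, i))
    }
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(
    nodes = g$bonds,
    adj = adj,
    label_strict = vapply(seq_len(nb), function(i) bond_label(g, i, "strict"), ""),
    label_light = vapply(seq_len(nb), function(i) bond_label(g, i, "light"), ""),
    parent = g), class = "line_graph")
}

#' @export
print.line_graph <- function(x, ...) {
  cat(sprintf("<line_graph> %d bond nodes over %d atoms\n",
              length(x$adj), n_atoms(x$parent)))
  invisible(x)
}

# Canonical label of bond i: endpoints sorted by (element, h_count).
bond_label <- function(g, i, mode = c("strict", "light")) {
  mode <- match.arg(mode)
  a <- g$bonds$a[i]; b <- g$bonds$b[i]
  ea <- g$atoms$element[a]; eb <- g$atoms$element[b]
  ha <- g$atoms$h_count[a]; hb <- g$atoms$h_count[b]
  if (ea > eb || (ea == eb && ha > hb)) {
    tmp <- ea; ea <- eb; eb <- tmp; tmp <- ha; ha <- hb; hb <- tmp
  }
  if (mode == "light") paste(ea, eb, sep = "|")
  else paste(ea, eb, g$bonds$order[i], ha, hb, sep = "|")
}

# ---- matching predicates ----------------------------------------------------

# Atom-level compatibility: query atom q of qg against target atom t of tg.
# Strict: same element and the query hydrogen count is a *minimum* on the
# target. Light: element only. Charge and aromatic atom flags never matter.
atom_compatible <- function(qg, q, tg, t, mode) {
  if (qg$atoms$element[q] != tg$atoms$element[t]) return(FALSE)
  if (mode == "strict" && qg$atoms$h_count[q] > tg$atoms$h_count[t])
    return(FALSE)
  TRUE
}

bond_order_compatible <- function(qorder, torder, mode) {
  mode == "light" || qorder == torder
}

#' Strict bond-node matching
#'
#' A query bond node matches a target bond node when an endpoint pairing
#' exists under which elements agree, the bond order is identical (aromatic
#' is its own order), and each query endpoint's hydrogen count is met or
#' exceeded by its target endpoint (the query count is a lower bound — a
#' residue atom that must carry at least one hydrogen can match a polymer
#' atom carrying two).
#'
#' @param qg,qi query [mol_graph] and bond id.
#' @param tg,ti target [mol_graph] and bond id.
#' @return logical.
#' @export
match_strict <- function(qg, qi, tg, ti) bond_match(qg, qi, tg, ti, "strict")

#' Light bond-node matching
#'
#' Element pairs only: bond multiplicity, aromaticity and hydrogen counts
#' are ignored. This tolerates tautomeric shifts (proton and electron moves)
#' and residues engaged in unusual bonds.
#'
#' @inheritParams match_strict
#' @return logical.
#' @export
match_light <- function(qg, qi, tg, ti) bond_match(qg, qi, tg, ti, "light")

bond_match <- function(qg, qi, tg, ti, mode) {
  qa <- qg$bonds$a[qi]; qb <- qg$bonds$b[qi]
  ta <- tg$bonds$a[ti]; tb <- tg$bonds$b[ti]
  if (!bond_order_compatible(qg$bonds$order[qi], tg$bonds$order[ti], mode))
    return(FALSE)
  (atom_compatible(qg, qa, tg, ta, mode) && atom_compatible(qg, qb, tg, tb, mode)) ||
  (atom_compatible(qg, qa, tg, tb, mode) && atom_compatible(qg, qb, tg, ta, mode))
}

# ---- misc graph utilities ---------------------------------------------------

# Induced subgraph on `keep` atom ids; returns list(graph, old_ids).
mg_induced <- function(g, keep) {
  keep <- sort(unique(keep))
  newid <- rep(NA_integer_, n_atoms(g)); newid[keep] <- seq_along(keep)
  bsel <- g$bonds$a %in% keep & g$bonds$b %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  if (nrow(bonds)) { bonds$a <- newid[bonds$a]; bonds$b <- newid[bonds$b] }
  list(graph = mol_graph(g$atoms[keep, , drop = FALSE], bonds,
                         name = g$name, smiles = NA_character_),
       old_ids = keep)
}

# Connected components over atoms; returns integer membership vector.
mg_components <- function(g) {
  n <- n_atoms(g)
  comp <- rep(NA_integer_, n)
  adj <- mg_adjacency(g)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# Whole-graph isomorphism with atom labels (element,h_count) and bond orders.
# Used to deduplicate residues; delegates to igraph's VF2.
graphs_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2) || n_bonds(g1) != n_bonds(g2)) return(FALSE)
  sig <- function(g) sort(paste(g$atoms$element, g$atoms$h_count))
  if (!identical(sig(g1), sig(g2))) return(FALSE)
  lab_all <- unique(c(paste(g1$atoms$element, g1$atoms$h_count),
                      paste(g2$atoms$element, g2$atoms$h_count)))
  vcol <- function(g) match(paste(g$atoms$element, g$atoms$h_count), lab_all)
  ecol <- function(g) match(g$bonds$order, BOND_ORDERS)
  ig <- function(g) igraph::make_graph(
    edges = as.vector(t(cbind(g$bonds$a, g$bonds$b))),
    n = n_atoms(g), directed = FALSE)
  i1 <- ig(g1); i2 <- ig(g2)
  igraph::isomorphic(i1, i2, method = "vf2",
                     vertex.color1 = vcol(g1), vertex.color2 = vcol(g2),
                     edge.color1 = ecol(g1), edge.color2 = ecol(g2))
}
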