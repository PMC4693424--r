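---
title: "Inferring monomeric structures of small polymers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring monomeric structures of small polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monomerize)
```

# The problem

Small biological polymers — nonribosomal peptides, glycopeptides,
lipopeptides — are assembled enzymatically from a few hundred possible
building blocks. Mass spectrometry and chemical databases describe them as
atomic structures (SMILES); biological analyses need the monomeric
structure: which monomer occupies which atoms, i.e. a tiling of the
polymer's heavy atoms by named, non-overlapping residues. `monomerize`
computes that tiling from three inputs: a monomer database (name + SMILES),
a set of chemical reaction rules, and optionally a corpus of polymers for
frequency learning.

# Molecular graphs

`parse_smiles()` produces a graph over heavy atoms only. Hydrogens are
folded into a per-atom count: matching never needs them as vertices, and
the hydrogen count is exactly what the strict matching predicate consumes.
SMILES interpretation — valence model, implicit hydrogens, aromatic
perception — is delegated to OpenBabel (via ChemmineOB); the package reads
back an explicit-hydrogen MOL2 block, which preserves the input atom order,
so all reported atom ids refer to the polymer SMILES as written. Targets
are deliberately *not* canonicalized. Aromatic bonds are a bond order of
their own (`"aromatic"`); formal charges and stereochemistry are parsed but
ignored by both matching modes, since neither participates in the
residue-matching model.

Internally atom ids are 1-based, the natural R convention; every JSON
export (annotations, match dumps, family exports) writes 0-based ids, the
convention of the interchange format.

# Reaction rules and residue families

A monomer inside a polymer has lost atoms to every bond it formed. A
`reaction_rule` describes one bond type from the point of view of one
functional group:

* a small explicit graph **pattern** (atoms with element, hydrogen bounds,
  optional aromaticity; bonds with order or `"any"`). We chose a structured
  JSON pattern over a SMARTS string because site enumeration needs the full
  pattern-to-monomer atom mapping, and the explicit form keeps the matcher
  small and auditable;
* the atoms **deleted** when the bond forms — whole heavy atoms (the
  carboxyl's hydroxyl oxygen) and/or hydrogens (one amine H, one thiol H);
* the **attachment** atom that will carry the new inter-monomer bond;
* a **standalone** flag: a disulfide bridge never occurs as a monomer's
  only bond, so such rules are excluded at family level 1;
* a **priority**: how frequent this bond type is in the target polymer
  class (peptide bonds dominate peptide-like polymers), used as the third
  tiling criterion;
* optional **exclude** sub-patterns anchored at the attachment atom. The
  shipped amine rule excludes amide nitrogens (`N-C=O`): an amide N is not
  nucleophilic, and letting the rule fire on asparagine/glutamine side
  chains would generate residues able to capture the backbone peptide
  nitrogen of a neighboring unit — a systematic mis-tiling.

`build_family()` applies every valid subset of (rule, site) applications
breadth-first. Subsets are valid when their deletions do not collide, every
attachment atom survives, and at least one application is standalone.
Residues with isomorphic graphs at the same level are merged into one DAG
node (whole-graph isomorphism is checked with igraph's VF2 on
element/hydrogen vertex colors and bond-order edge colors); each DAG edge
stores an embedding of the child (smaller) residue into its parent, used
later by the extension search. The *root* is the residue with the fewest
atoms, hydrogens included. With the shipped rules the root is unique for
every proteinogenic amino acid; if several maximal residues ever tie, the
family records all childless residues and each seeds its own search.

# Line graphs and matching modes

Organic molecules use few element labels, so atom-labelled search is poorly
selective. The package therefore searches *line graphs*: one node per
covalent bond, adjacent when two bonds share an atom, each node labelled by
(element pair, bond order, hydrogen counts). Bond-node origins (the two
atom ids) are kept, which disambiguates structures such as cyclopropane
vs. isobutane whose bond multisets agree.

Two predicates compare a residue bond to a polymer bond:

* **strict** — element pair, bond order, and hydrogen counts all at once;
  a residue hydrogen count is a *minimum* on the polymer atom (a residue N
  that must still carry one hydrogen also matches a polymer N carrying
  two). This is the fast, selective mode used in the global pass.
* **light** — element pair only. Multiplicity, aromaticity and hydrogens
  are ignored, tolerating tautomeric proton/electron moves and residues
  engaged in unusual bonds. Light mode is reserved for the local
  modulation step; a flag on `search_family()` lets a caller run a global
  light pass if desired.

Strict implies light, so strict match sets are always subsets of light
ones — a property the test suite asserts over generated label pairs and
whole searches.

# The selectivity index

Searching a residue means growing a connected partial embedding one bond
node at a time; its cost is driven by how many partial embeddings survive
each step. With label probabilities `p` estimated from a learning corpus
(add-one smoothing keeps unseen labels rare-but-possible), we score an
order as the expected number of surviving prefix embeddings under a
first-order independence approximation:

    cost(order) = sum over k of  prod over j <= k of  p(label_j)

Because the k-prefix product is order-independent, the optimum satisfies a
subset recurrence, and a forward dynamic program over *connected* prefix
sets solves it exactly; states are bitmasks, so the exact solver is applied
to residues of at most `exact_limit = 12` line-graph nodes (sub-second in
R), with a greedy rarest-extension order beyond. Ties are broken toward the
lexicographically smallest node order, so index construction is
deterministic. Disconnected residue graphs get one sub-order per component,
concatenated rarest-first.

Correctness never depends on the order: any connected order enumerates the
same embeddings. The test suite verifies this by re-running searches under
random valid orders, and verifies DP optimality against exhaustive
enumeration of all connected orders for residues with at most 6 bonds.

# Branch-and-bound search and DAG extension

`search_root()` assigns the residue's bond nodes in index order to
compatible polymer bond nodes, pruning any partial assignment that violates
the matching predicate, the shared-atom structure, or injectivity of the
atom map. The enumeration is complete, and embeddings covering the same
polymer atom set are reported once (the tiler consumes atom sets; residue
automorphisms would otherwise multiply matches without adding
information).

Larger residues are not searched from scratch: a parent residue is searched
only as *extensions* of the matches of one of its children, anchored
through the stored child-to-parent embedding, branching only on the few
atoms the parent adds. Since a child embeds in its parent, a parent match
restricted to the child is a child match — so extending the complete child
match set is itself complete, and the contrapositive prune (child absent ⇒
parent absent) is sound. The same argument holds within a restricted
region, which is why the region-local search needs no fallback to full
search: any parent embedding inside the region restricts to a child
embedding inside the region.

A per-residue match cap (default 10 000) converts pathological inputs into
a warning plus truncated results instead of unbounded runtime.

# Tiling

Tiles are ranked by three criteria in order: size (large residues rarely
match by chance), number of attachment points (fewer is more probable in
real polymers), aggregate bond priority (a polymer class has a dominant
bond type). Remaining ties are broken by a canonical key (monomer name,
sorted atom ids), making the entire pipeline deterministic — the ranking
criteria themselves say nothing about ties between, say, two equal-size
residues of different monomers on the same atoms.

* `greedy_tile()` scans rank order and accepts disjoint tiles.
* `modulate()` — when atoms remain uncovered — removes the tiles sharing a
  covalent bond with an uncovered atom, re-searches the enlarged region in
  light mode, re-tiles, and keeps the better of before/after (coverage
  first, then the rank order of the selected tiles). One round by default;
  in most cases one round either completes the cover or nothing in the
  database can.
* `refine_local()` finishes with an exact branch-and-bound over the
  candidate tiles intersecting the uncovered neighborhood (tiles outside
  are frozen): objective is covered-atom count, bound is current cover plus
  the optimistic union of remaining candidates, tie-break is the greedy
  rank signature. A node budget (default 100 000) truncates adversarial
  instances, keeping the best solution found with a warning; within the
  budget the result provably equals exhaustive subset enumeration, which
  the tests check up to 15 candidate tiles. We implement branch-and-bound
  (no cutting planes are involved anywhere in the model).

Coverage is non-decreasing across greedy → modulation → refinement by
construction, and disjointness is asserted after every stage.

# The synthetic evaluation kit

Real curated polymer databases require external downloads, so the package
measures itself on polymers it assembles: `generate_polymer()` draws
monomers uniformly, joins consecutive (linear), randomly attached
(branched) or cycle-closing (cyclic) units through complementary rule
applications — peptide bonds dominate, as the first pair in the catalog —
and records each unit's surviving atoms as ground truth. Defaults mirror a
peptide-like study: 3–8 units per polymer, the 20 proteinogenic amino
acids as the database, 100 polymers per run, all randomness derived from
one seed.

What the generator emulates: residue truncation consistent with the rules,
mixed topologies, shared sub-structures between monomers (every backbone
contains glycine's). What it does not: tautomeric drawing variants between
the database and the polymer (light matching is exercised only through
database-incompleteness experiments), unusual bond types beyond the rule
catalog, non-amino-acid monomers, and annotation errors in curated data.
A perfect score on synthetic polymers is therefore an upper bound on
real-data behavior, not a prediction of it; on real collections the
reported coverage and correctness are expected to drop with database
completeness and drawing conventions.

Correctness is counted all-or-nothing per tile: an atom contributes only
if its predicted tile matches a ground-truth tile in both monomer name and
exact atom set. A fractional per-atom credit would be the laxer reading;
the strict one penalizes near-misses, which is the behavior a database
curator wants. Rates are computed over heavy atoms, consistent with the
graph model. Classes follow the usual contingency: TP (coverage 1,
correctness 1), FP (coverage 1, correctness < 1), FN (coverage < 1);
recall = TP/(TP+FN), precision = TP/(TP+FP), with zero denominators
reported as undefined rather than propagated as NaN.

# Numerical and degenerate-input choices

* Bond-free molecules (single heavy atom) have no line graph; single-atom
  residues are matched directly on polymer atoms by element and hydrogen
  count.
* Stale rule sites (atoms already deleted) raise a `site-invalid` error
  rather than silently skipping.
* A monomer matching no rule yields an empty family and a warning: it can
  never be part of a polymer under the given rule set.
* The DP/greedy switch (`exact_limit`), the match cap and the refinement
  budget are ordinary arguments, not constants.
* `set.seed`-style RNG state is saved and restored around generation, so
  `generate_polymer()` is reproducible without clobbering the caller's
  stream.

# Known limitations

* No inference of unknown monomers: uncovered regions are reported, not
  explained.
* Inter-monomer bonds are not labelled with their bond type, and no
  polymer-type classification is attempted.
* Stereochemistry and formal charge never influence matching; two
  stereoisomers are indistinguishable.
* The cost model behind the index is a first-order approximation;
  it provably cannot affect results, only speed.
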