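---
title: "Canonical semantic encoding of chemical entities: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical semantic encoding of chemical entities: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chessr)
```

## The problem this package addresses

Chemical information lives in databases whose internal identifiers are
sequential accession numbers: the same compound is `CID 2160` in one
repository and `CHEMBL1628227` in another, and nothing below the molecule —
an individual atom, a bond, a functional group — can be referred to at all.
Merging annotations across sources therefore requires curated cross-links,
and fine-grained annotations (say, a computed dissociation enthalpy of one
particular O–H bond) have nowhere to attach.

`chessr` implements a semantic encoding in which every chemical entity
receives a *deterministic, database-independent* URI computed from the
entity itself. Two groups who independently encode the same compound — from
a SMILES string, an SDF record, or an InChI — mint byte-identical URIs, so
their RDF graphs collapse into a single graph when merged, annotations
included. On top of the encoding sits the query repertoire such graphs
support: substructure search, fragment-based similarity ranking,
provenance-filtered descriptor retrieval, a Rule-of-Five filter, bond
dissociation enthalpy (BDE) window queries, and reaction-candidate matching.

## The identifier model

All identifiers are anchored on standard InChI canonicalization:

| entity        | local name                                    |
|---------------|-----------------------------------------------|
| molecule      | `INCHIKEY`                                    |
| atom          | `INCHIKEY-A<symbol><canonical index>`         |
| bond          | `INCHIKEY-B<sym1><sym2><idx1><idx2>`          |
| fragment      | `INCHIKEY-FG<sha1>`                           |
| descriptor    | `OWNERLOCAL-D<sha1>`                          |
| configuration | `CC<sha1>`                                    |
| reaction      | `RX<sha1>`                                    |

```{r identifiers}
mol <- parse_molecule("CCO", "smiles")
num <- canonical_numbering(mol)
molecule_uri(num)$local
atom_uri(num, 3)$local     # the oxygen: canonical index 3
bond_uri(num, 2, 3)$local  # the C-O bond, endpoints in ascending index
```

Hash-based identifiers are 40-character lowercase SHA-1 digests. Hash inputs
are joined with an ASCII unit separator before digesting, so adjacent parts
can never be confused (`("ab","c")` vs `("a","bc")`); absent optional parts
serialize as the empty string; numeric values are hashed in their source
lexical form (`"1.55"` is never reformatted), which keeps digests identical
across platforms and floating-point settings.

### Canonical numbering: three subtleties

**Hydrogens.** InChI numbers heavy atoms only. Explicit hydrogens receive
derived indices `n_heavy + k`, ordered by the canonical index of their
attached heavy atom (input order breaking ties). This is a package
convention — no community convention exists — and it is what makes bond URIs
like ethanol's hydroxyl `-BOH39` possible at all.

**Symmetry.** InChI canonical indices are unique only up to molecular
automorphism: in phenol, the two ortho carbons may swap indices between two
input orderings (the InChI AuxInfo `/E:` layer records these orbits). The
full identifier *set* of a molecule is invariant regardless; only the
pairing of indices to specific input atoms moves within an orbit.

**Tautomer-equivalent atoms with unequal bonds.** InChI deliberately treats
the two carboxylic-acid oxygens as equivalent (mobile hydrogen), yet their
bond orders differ (C=O vs C–O). Left alone, which oxygen received which
index would depend on input order and leak into any identifier that sees
bond orders (fragment class keys). The package therefore refines the
assignment within each `/E:` equivalence class deterministically, keying
atoms by the sorted multiset of (bond order, neighbour canonical index) and
iterating to a fixed point. Atoms whose keys still tie are automorphic
*including* bond orders, where either assignment yields identical
identifier sets.

### Aromaticity

Kekulé structures are not canonical: the alternating single/double pattern
OpenBabel assigns to an aromatic ring depends on input atom order. Aromatic
bonds are therefore re-marked with the distinct order `"aromatic"` using
OpenBabel's perception (read from its SYBYL MOL2 output, which preserves
atom order), for SMILES and InChI input alike; an input SDF declaring V2000
order 4 keeps it. The four bond orders — single, double, triple, aromatic —
each have their own bond class and direct bidirectional predicate in the
emitted graph.

## Fragments and fragment classes

The fragment vocabulary is atom-centric: for each heavy atom and each depth
d ∈ {1, 2, 3}, the subgraph induced by all heavy atoms within d bonds of the
center. For n-propanol's oxygen the depth-1/2/3 fragments are the
hydrogen-suppressed graphs `CO`, `CCO`, `CCCO`. Fragments with identical
member sets are collapsed (a methanol molecule yields one fragment, not
three); the *class* of a fragment is the canonical SMILES of its induced
subgraph, so constitutionally identical fragments anywhere in the corpus
share one class URI — the fingerprint-style vocabulary used for similarity
ranking and reaction matching.

Two design choices deserve note. Bond orders are retained inside class keys
(an aldehyde `CC=O` class is distinct from an alcohol `CCO` class), because
reaction matching depends on the distinction. And fragment mol blocks are
written with members in canonical-index order, making the class key a pure
function of canonical structure. A consequence of canonicalizing fragments
as standalone molecules is that sub-ring fragments lose ring context: a
two-carbon fragment of benzene keys as `C=C`, the same as a vinyl fragment.
This is deterministic and symmetric — the cost is a slightly coarser class
vocabulary for partial aromatic fragments, and such fragments do not
receive class-level atom typing (their class graph kekulizes differently
than the ring context).

## Descriptors, configurations, provenance

Descriptors follow the CHEMINF pattern. *Invariant* descriptors (heavy-atom
count, molecular mass) depend only on constitution and hash
`(value, uncertainty, unit)`. *Variable* descriptors (computed logP, atomic
coordinates) additionally reference a *chemical configuration* — the bundle
of conditions under which the value holds: data provider, temperature,
conformer, electronic state. Configurations hash their `key=value`
annotations in lexicographic order, so insertion order is irrelevant and
equal conditions collapse to one node. *Composite* descriptors (a 3-D
coordinate with x/y/z components) hash the sorted local names of their
constituents.

One extension to the hashing rule: when provenance is attached, the method
term, software identity and sorted parameters join the digest. Without
this, two BDE values of `104.5 kcal/mol` computed by different methods
would collide on one descriptor URI, contradicting the requirement that
descriptor identifiers never clash with previously assigned data.

Computational provenance records the algorithm (e.g. the AM1 method class),
a parameterized software execution with its parameters (e.g. temperature
298 K), and the software name and version. Experimentally derived
descriptors reuse the same structure with an observation process in place
of the software execution; no separate schema exists.

```{r bde}
molh <- add_hydrogens(mol)
numh <- canonical_numbering(molh)
kb <- encode_molecule(molh, numh, encoding_options(include_hydrogens = TRUE))
oh <- bond_uri(numh, 3, 9)          # O3-H9 under the hydrogen convention
kb <- attach_descriptor(kb, oh, make_bde_annotation(oh, "104.5"))
retrieve_descriptors(kb, type_term = "bde_descriptor",
                     method = "AM1", unit = "kcal/mol")[, c("value", "unit")]
```

## The emitted graph and its queries

`encode_molecule()` emits: molecule typing (both the molecular-entity and
molecule classes — the literature uses both for the same role), element
typing per atom, bond individuals typed by order, *and* direct
bidirectional bond-type predicates between bonded atoms. Bond entities are
what descriptors attach to; the direct predicates are what make graph
pattern queries fast — encoding bonds only as entities forces every query
through two extra joins per bond. Both are on by default. Parthood
(`has proper part`) links molecule→atoms/bonds/fragments, bond→its two
atoms, fragment→member atoms, with the inverse `is part of` from parts.

Queries run against the in-process triple store; `substructure_query()`
also emits standard SPARQL 1.1 text for external endpoints. Matching
semantics are subgraph *monomorphism* with pairwise-distinct variables —
exactly what the generated `FILTER(?a0 != ?a1)` pattern computes — not
induced-subgraph matching. The test suite holds the triple-store search
equal to an independent matcher (igraph's LAD solver over bond-labeled
expansions) across the fixture corpus.

Similarity ranking counts *distinct shared fragment classes* (not
instances), descending, ties broken by URI order. Counting classes rather
than instances keeps scores independent of molecule size on the database
side. A queried molecule present in the knowledgebase attains the maximal
score, though a superstructure can legitimately tie with it.

The Rule-of-Five filter is evaluated closed-world over loaded descriptors:
a molecule passes when at least one witness descriptor satisfies each
constraint — mass strictly below 500, acceptor count at most 10, donor
count at most 5, logP strictly inside (−5, 5) — and a molecule missing any
required descriptor is excluded. (A description-logic reasoner would treat
the missing-descriptor case open-world; a query-based filter needs
witnesses, and the closed-world reading is the deliberate divergence.)

The BDE window query combines structure and annotation: molecules carrying
a phenol-class fragment and an O–H single bond whose BDE descriptor matches
the method and unit and lies *strictly* inside the window — by default
(67, 78) kcal/mol, the range in which a phenolic antioxidant is weak enough
to be recycled by ascorbate yet stronger than α-tocopherol.

## Reactions

Reactions are abstract processes identified solely by role-tagged
participants and stoichiometry — no kinetics, thermodynamics or likelihood.
Generic transformations (primary alcohol → aldehyde) use functional-group
and atom *classes* as participants; `transforms into` statements pair each
reacting group and atom with its product counterpart, which is what makes
atom-history tracing possible. Class-level atom nodes follow the form
`<classlocal>A<index><symbol>`; stoichiometric coefficients other than 1
ride on reified participation statements, keeping participant nodes
reusable across reactions. A matter-balance validator over the atom maps
warns (never errors) on imbalance, since generic class-level reactions
cannot always be balanced.

```{r reactions}
rxn <- build_generic_reaction(
  "CCO", "CC=O",
  agents = "KJFCCLURYALNSL-UHFFFAOYSA-N",
  atom_maps = data.frame(from_group = 1, from_atom = 3,
                         to_group = 1, to_atom = 3))
kb <- graph_union(
  encode_knowledgebase(c("CCO", "C"), encoding_options(type_class_atoms = TRUE)),
  encode_reaction(rxn))
eth <- paste0(chess_base(), "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
reaction_candidates(kb, eth)   # ethanol matches via its CCO fragment and oxygen

```

## Vocabulary is data, not code

Every ontology identifier resolves through one editable table
(`inst/extdata/chess_vocabulary.tsv`). The shipped defaults bind the CHEBI,
SIO, CHEMINF and UO terms the encoding relies on; relations for which no
community identifier is established (bond classes beyond single, 'has
provider', coordinate terms, the Lipinski descriptor types) are bound to
provisional CamelCase locals and can be rebound wholesale by supplying a
replacement table to `chess_vocabulary()`.

## The fixture generator

`generate_fixtures()` emulates the kind of small-organic collections this
encoding targets — alkanes, alcohols, phenols, fatty-like chains, ring
systems — and always includes the worked-example molecules (ethanol,
n-propanol, phenol, acetaldehyde). It is a pure function of
`(n, seed, families, plan)`. Two annotation plans ship: `lipinski-boundary`
assigns synthetic descriptor profiles that straddle each Rule-of-Five
threshold (a 499.9/10/5/4.9 molecule that passes on every boundary, a 500.0
mass that fails, a missing-logP profile, …), and `bde` assigns synthetic
O–H dissociation enthalpies around the (67, 78) window plus ethanol's
aliphatic 104.5. All values are test constructions chosen to exercise the
comparison semantics, not measurements; what passing tests demonstrate is
the correctness of encoding, merging and querying — not chemical accuracy
of the annotations, which this package never computes.

Test and acceptance runs use fixture corpora of 8–50 molecules, 100 random
atom-order permutations per molecule for identifier-stability checks, and
8 query patterns against a 50-molecule knowledgebase for the search/oracle
equivalence — sizes at which the brute-force oracle is still exact.

## Numerical and degenerate-input choices

* Values, uncertainties and units are stored and serialized as strings in
  their source lexical form; no normalization (`"1.50"` ≠ `"1.5"`).
* Serialization sorts statements, so output files are byte-deterministic
  and diffable; Turtle locals that would be invalid (leading digits) fall
  back to full IRIs, while generated SPARQL may use the digit-leading
  compact forms its grammar allows.
* Multi-component structures (salts, mixtures) are rejected at numbering
  time rather than heuristically split.
* Bond-less single-atom molecules are handled throughout (methane has one
  fragment and no bonds).
* Molecules with no heavy atoms yield an empty similarity ranking with a
  warning.
* Ties in similarity ranking break by URI lexicographic order.

## Known limitations

* Scope is limited to compounds representable by standard InChI as single
  covalent units; polymers, Markush structures and multi-component salts
  are out of scope.
* Fragment class keys canonicalize fragments as standalone molecules, so
  sub-ring fragments lose aromatic context (see above).
* The hydrogen-index convention is package-defined; other implementations
  of the same identifier grammar may number hydrogens differently.
* The in-process store evaluates the generated basic graph patterns; it is
  not a general SPARQL engine, and no OWL reasoning is performed — DL-safe
  rules are emitted as text only.
* InChIKeys can drift between InChI software releases; the toolkit version
  is recorded on every molecule node for exactly this reason.
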