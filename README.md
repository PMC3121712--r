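# chessr

Canonical semantic identifiers and RDF encodings for chemical entities in R.

## The problem

Chemical databases index compounds by sequential accession numbers, so the
same molecule carries unrelated identifiers in every repository, and nothing
below the molecule — an atom, a bond, a functional group — can be referred to
or annotated at all. Integrating annotations across sources then needs
curated cross-links and human reconciliation.

`chessr` is for cheminformaticians and semantic-web practitioners who want
chemical knowledge as RDF with *deterministic, database-independent*
identifiers. Every entity's URI is computed from the entity itself, anchored
on standard InChI canonicalization:

| entity        | local name                                | example                             |
|---------------|-------------------------------------------|-------------------------------------|
| molecule      | `INCHIKEY`                                | `LFQSCWFLJHTTHZ-UHFFFAOYSA-N`       |
| atom          | `INCHIKEY-A<symbol><canonical index>`     | `…-AO3` (ethanol's oxygen)          |
| bond          | `INCHIKEY-B<sym1><sym2><idx1><idx2>`      | `…-BCO23` (ethanol's C–O bond)      |
| fragment      | `INCHIKEY-FG<sha1>`                       | `…-FG2621392877e9…`                 |
| descriptor    | `OWNERLOCAL-D<sha1>`                      |                                     |
| configuration | `CC<sha1>`                                |                                     |
| reaction      | `RX<sha1>`                                |                                     |

Digests are 40-character lowercase SHA-1 over unit-separator-joined parts;
descriptor hashes cover value, uncertainty, unit, configuration and
provenance; reaction hashes cover role-tagged participants with
stoichiometry, sorted within each role. Because identifiers are
deterministic, independently produced graphs for one compound collapse into
a single graph when merged — annotations, bond-level data and all.

On top of the encoding sits the query repertoire such graphs support:
substructure search (as SPARQL text and as an in-process evaluator),
fragment-class similarity ranking, provenance-filtered descriptor
retrieval, a Rule-of-Five filter, bond-dissociation-enthalpy window
queries, and reaction-candidate matching with atom tracing.

## Worked example

```r
library(chessr)

mol <- parse_molecule("CCO", "smiles")     # ethanol
num <- canonical_numbering(mol)
num$inchikey
#> [1] "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"
atom_uri(num, 3)$local                     # the oxygen (canonical index 3)
#> [1] "LFQSCWFLJHTTHZ-UHFFFAOYSA-N-AO3"
bond_uri(num, 2, 3)$local                  # the C-O bond
#> [1] "LFQSCWFLJHTTHZ-UHFFFAOYSA-N-BCO23"

vapply(atom_centered_fragments(mol, num), function(f) f$class_key, "")
#> [1] "CC"  "CCO" "CO"
```

Ethanol's atom-centered fragments at depths 1–3 are the hydrogen-suppressed
graphs `CC`, `CO` and `CCO`; each is typed to a structural class shared by
every constitutionally identical fragment in the corpus.

```r
kb <- encode_knowledgebase(c("C", "CC", "CCO", "CCCO"))
kb
#> <chess_graph> 174 triples, 6 namespaces

# which molecules contain an ethyl subgraph?
sub(".*CHESS_", "", run_substructure_search(kb, chain_query(2)))
#> [1] "BDERNNFJNOPAEC-UHFFFAOYSA-N" "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"
#> [3] "OTMSDBZUPAUEDD-UHFFFAOYSA-N"   # n-propanol, ethanol, ethane; not methane

# rank by shared fragment classes with an ethanol query
similarity_rank(kb, "CCO", limit = 3)
#>                      molecule shared
#> 1 BDERNNFJNOPAEC-UHFFFAOYSA-N      3
#> 2 LFQSCWFLJHTTHZ-UHFFFAOYSA-N      3
#> 3 OTMSDBZUPAUEDD-UHFFFAOYSA-N      1
```

n-Propanol ties with ethanol itself at 3 shared classes (`CC`, `CO`, `CCO`
are all substructures of it); ethane shares one; methane none. Descriptors
attach to any entity — molecules, atoms, or individual bonds:

```r
molh <- add_hydrogens(mol)
numh <- canonical_numbering(molh)
kb   <- encode_molecule(molh, numh, encoding_options(include_hydrogens = TRUE))
oh   <- bond_uri(numh, 3, 9)               # the O-H bond
kb   <- attach_descriptor(kb, oh, make_bde_annotation(oh, "104.5"))
retrieve_descriptors(kb, type_term = "bde_descriptor",
                     method = "AM1", unit = "kcal/mol")[, c("value", "unit")]
#>   value     unit
#> 1 104.5 kcal/mol
```

`write_graph()` / `load_knowledgebase()` serialize to sorted, diffable
Turtle or N-Triples; `substructure_query()` emits standard SPARQL 1.1 for
external endpoints; `generate_fixtures()` provides deterministic test
corpora with Rule-of-Five and BDE annotation plans. A thin command-line
interface (`inst/cli/chess.R`) wraps encode / search / similar / lipinski /
bde-window / reactions / validate / fixtures. The methods vignette
(`vignettes/chess-encoding.Rmd`) documents the model, the canonicalization
subtleties (symmetry orbits, tautomer-equivalent atoms, aromaticity) and
the design decisions.

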