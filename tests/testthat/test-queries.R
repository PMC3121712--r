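test_that("generated SPARQL matches the canonical pattern shape", {
  q <- chain_query(2)
  txt <- substructure_query(q)
  expect_equal(length(gregexpr("rdf:type chebi:CHEBI_27594", txt)[[1]]), 2L)
  expect_equal(length(gregexpr("sio:000053 \\?a", txt)[[1]]), 2L)
  expect_match(txt, "FILTER\\(\\?a0 != \\?a1\\)")
  expect_match(txt, "SELECT DISTINCT \\?m")
  expect_match(txt, "hasSingleBondWith")

  single <- substructure_query(query_graph(data.frame(var = "a0", element = "O")))
  expect_false(grepl("BondWith", single))
  expect_false(grepl("FILTER", single))

  ring <- standard_patterns()$ring5_ene
  ring_txt <- substructure_query(ring)
  expect_equal(length(gregexpr("BondWith", ring_txt)[[1]]), 5L)
  expect_equal(length(gregexpr("hasDoubleBondWith", ring_txt)[[1]]), 1L)

  disconnected <- query_graph(data.frame(var = c("a0", "a1"), element = "C"))
  expect_error(substructure_query(disconnected), class = "chess_pattern_error")
})

test_that("ethyl search over the toy knowledgebase finds ethane and ethanol", {
  kb <- encode_knowledgebase(c("C", "CC", "CCO"))
  idx <- attr(kb, "index")
  hits <- run_substructure_search(kb, chain_query(2))
  expect_setequal(hits, idx$uri[idx$smiles %in% c("CC", "CCO")])
})

test_that("every molecule matches its own full-graph query", {
  smiles <- c("CCO", "CC(C)O", "C1=CCCC1", "CC=O")
  kb <- encode_knowledgebase(smiles)
  idx <- attr(kb, "index")
  for (i in seq_along(smiles)) {
    q <- query_from_mol(parse_molecule(smiles[i], "smiles"))
    expect_true(idx$uri[i] %in% run_substructure_search(kb, q),
                info = smiles[i])
  }
})

test_that("triple-store search agrees with the independent matcher", {
  smiles <- c("C", "CC", "CCC", "CCCC", "CCO", "CC=O", "C1=CCCC1", "C1CCCC1",
              "CC(C)O", "Oc1ccccc1", "CCCCCC", "CCCC=O")
  kb <- encode_knowledgebase(smiles)
  idx <- attr(kb, "index")
  mols <- chessr:::parse_smiles_batch(smiles)
  for (nm in c("ethyl", "butyl", "ring5_ene", "carbonyl", "hydroxyl")) {
    q <- standard_patterns()[[nm]]
    got <- run_substructure_search(kb, q)
    pm <- pattern_mol_of(q)
    want <- idx$uri[vapply(mols, oracle_has_substructure, logical(1),
                           pattern_mol = pm)]
    expect_setequal(got, sort(want))
  }
})

test_that("similarity ranking is self-maximal and orders by shared classes", {
  kb <- encode_knowledgebase(c("CCO", "CCCO", "C", "CC=O"))
  idx <- attr(kb, "index")
  # a knowledgebase molecule queried against the kb is rank 1 or tied-first
  # (a superstructure can legitimately share every class of the query)
  for (s in c("CCO", "CCCO")) {
    r <- similarity_rank(kb, s, limit = 10)
    self <- r$shared[r$molecule == idx$uri[idx$smiles == s]]
    expect_equal(self, max(r$shared))
    expect_true(all(diff(r$shared) <= 0))
  }
  # ethanol query: n-propanol (shares CO, CCO, CC) above methane (shares none)
  r <- similarity_rank(kb, "CCO", limit = 10)
  pos <- match(idx$uri, r$molecule)
  expect_lt(pos[idx$smiles == "CCCO"], pos[idx$smiles == "C"])
  expect_equal(r$shared[pos[idx$smiles == "C"]], 0L)

  expect_equal(nrow(similarity_rank(kb, "CCO", limit = 1)), 1L)
  expect_warning(similarity_rank(kb, chess_mol(data.frame(element = "H")),
                                 limit = 5),
                 "no fragments")
})

test_that("two conformer configurations never mix within a result row", {
  mol <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(mol)
  g <- encode_molecule(mol, num)
  cfg1 <- chemical_configuration(provider = "http://pubchem.ncbi.nlm.nih.gov",
                                 conformer = "1")
  cfg2 <- chemical_configuration(provider = "http://pubchem.ncbi.nlm.nih.gov",
                                 conformer = "2")
  g <- attach_descriptor(g, atom_uri(num, 3),
                         make_coordinate_descriptor("1.55", "0.0", "0.1", config = cfg1))
  g <- attach_descriptor(g, atom_uri(num, 3),
                         make_coordinate_descriptor("9.99", "8.8", "7.7", config = cfg2))
  rows <- retrieve_descriptors(g, molecule = molecule_uri(num),
                               type_term = "coordinate_3d")
  expect_equal(nrow(rows), 2L)
  expect_setequal(paste(rows$x, rows$y, rows$z),
                  c("1.55 0.0 0.1", "9.99 8.8 7.7"))
  only1 <- retrieve_descriptors(g, molecule = molecule_uri(num),
                                type_term = "coordinate_3d",
                                configuration = c(conformer = "1"))
  expect_equal(nrow(only1), 1L)
  expect_equal(only1$x, "1.55")
})

test_that("Rule-of-Five boundary semantics are exact", {
  enc <- function(vals) {
    mol <- parse_molecule("CCO", "smiles")
    num <- canonical_numbering(mol)
    g <- encode_molecule(mol, num)
    terms <- c(mass = "mass_descriptor", hba = "hba_count",
               hbd = "hbd_count", logp = "logp_descriptor")
    for (k in names(vals))
      g <- attach_descriptor(g, molecule_uri(num),
                             descriptor("invariant", terms[[k]], value = vals[[k]]))
    g
  }
  expect_length(lipinski_pass(enc(c(mass = "499.9", hba = "10", hbd = "5",
                                    logp = "4.9"))), 1L)
  expect_length(lipinski_pass(enc(c(mass = "500.0", hba = "10", hbd = "5",
                                    logp = "4.9"))), 0L)
  expect_length(lipinski_pass(enc(c(mass = "499.9", hba = "10", hbd = "5",
                                    logp = "5.0"))), 0L)
  expect_length(lipinski_pass(enc(c(mass = "499.9", hba = "10", hbd = "5",
                                    logp = "-5.0"))), 0L)
  # missing any required descriptor excludes the molecule
  expect_length(lipinski_pass(enc(c(mass = "499.9", hba = "10", hbd = "5"))), 0L)
})

test_that("relaxing any Rule-of-Five threshold never shrinks the result", {
  fx <- generate_fixtures(8, seed = 3, plan = "lipinski-boundary")
  kb <- fixture_knowledgebase(fx)
  strict <- lipinski_pass(kb)
  relaxed <- list(lipinski_criteria(mass_max = 600),
                  lipinski_criteria(hba_max = 12L),
                  lipinski_criteria(hbd_max = 7L),
                  lipinski_criteria(logp_min = -6, logp_max = 6))
  for (cr in relaxed)
    expect_true(all(strict %in% lipinski_pass(kb, cr)))
})

test_that("BDE window boundaries are strict and require a phenol group", {
  fx <- generate_fixtures(20, seed = 1, families = c("phenols", "alcohols"),
                          plan = "bde")
  kb <- fixture_knowledgebase(fx)
  idx <- attr(kb, "index")
  hits <- bde_window_search(kb, 67, 78)
  hit_names <- idx$name[match(hits$molecule, idx$uri)]
  expect_true("phenol" %in% hit_names)            # 72, inside
  expect_false("p-cresol" %in% hit_names)         # exactly 67, excluded
  expect_false("hydroquinone" %in% hit_names)     # exactly 78, excluded
  expect_false("ethanol" %in% hit_names)          # 104.5 and not phenolic
})

test_that("window query results are disjoint and nest in the enclosing window", {
  fx <- generate_fixtures(20, seed = 1, families = c("phenols", "alcohols"),
                          plan = "bde")
  kb <- fixture_knowledgebase(fx)
  lowwin <- bde_window_search(kb, 67, 72)$molecule
  highwin <- bde_window_search(kb, 72, 78)$molecule
  wide <- bde_window_search(kb, 67, 78)$molecule
  expect_length(intersect(lowwin, highwin), 0L)
  expect_true(all(c(lowwin, highwin) %in% wide))
})

test_that("DL-safe rules mirror the query structure", {
  rule <- emit_dl_safe_rule(chain_query(2), "ethyl containing molecule")
  expect_match(rule, "'single bond'\\(\\?a0, \\?a1\\), 'different from'\\(\\?a0, \\?a1\\)",
               fixed = FALSE)
  expect_match(rule, "-> 'ethyl containing molecule'\\(\\?m1\\)")
  expect_equal(length(gregexpr("'carbon atom'", rule)[[1]]), 2L)

  single <- emit_dl_safe_rule(query_graph(data.frame(var = "a0", element = "O")),
                              "oxygen containing molecule")
  expect_false(grepl("bond", single))
  expect_match(single, "'oxygen atom'\\(\\?a0\\)")

  ring <- standard_patterns()$ring5_ene
  ring_rule <- emit_dl_safe_rule(ring, "cyclopentene-like molecule")
  expect_equal(length(gregexpr("bond'\\(", ring_rule)[[1]]), nrow(ring$edges))
  expect_equal(length(gregexpr("'different from'", ring_rule)[[1]]),
               nrow(ring$distinct))
})
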