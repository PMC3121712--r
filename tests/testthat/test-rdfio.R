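test_that("the ethanol graph contains the canonical typing and parthood statements", {
  mol <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(mol)
  g <- encode_molecule(mol, num)
  tr <- g$triples
  m <- format(molecule_uri(num))
  o <- format(atom_uri(num, 3))
  co <- format(bond_uri(num, 2, 3))
  rdf_type <- chess_term("rdf_type")
  has <- function(s, p, obj) any(tr$s == s & tr$p == p & tr$o == obj)
  expect_true(has(m, rdf_type, chess_term("molecular_entity")))
  expect_true(has(o, rdf_type, chess_term("atom_O")))
  expect_true(has(co, rdf_type, chess_term("bond_single")))
  expect_true(has(m, chess_term("has_proper_part"), o))
  frag_types <- tr$o[grepl("-FG[0-9a-f]{40}$", tr$s) & tr$p == rdf_type]
  expect_true(chess_term("organic_group") %in% frag_types)
})

test_that("direct bond predicates are bidirectional and mirror bond entities", {
  mol <- parse_molecule("CC=O", "smiles")
  num <- canonical_numbering(mol)
  g <- encode_molecule(mol, num)
  tr <- g$triples
  preds <- c(chess_term("has_single_bond_with"), chess_term("has_double_bond_with"))
  direct <- tr[tr$p %in% preds, , drop = FALSE]
  # every directed statement has its reverse with the same predicate
  expect_true(all(paste(direct$o, direct$p, direct$s) %in%
                    paste(direct$s, direct$p, direct$o)))
  # adjacency from bond entities equals adjacency from direct predicates
  hpp <- chess_term("has_proper_part")
  bond_nodes <- unique(grep("-B[A-Z]", tr$s, value = TRUE))
  ends <- lapply(bond_nodes, function(b) sort(tr$o[tr$s == b & tr$p == hpp]))
  direct_pairs <- unique(t(apply(direct[, c("s", "o")], 1, sort)))
  expect_setequal(vapply(ends, paste, "", collapse = "|"),
                  apply(direct_pairs, 1, paste, collapse = "|"))
})

test_that("triple counts for carbon chains follow the closed form", {
  # per the documented encoding (both bond representations, depth-1
  # fragments with class typing, hydrogens suppressed):
  expected_count <- function(k) {
    nf <- if (k <= 2) 1L else k
    members <- if (k == 1) 1L else if (k == 2) 2L else 3L * k - 2L
    nc <- if (k <= 2) 1L else 2L
    4L + 4L * k + 5L * max(0L, k - 1L) + 2L * max(0L, k - 1L) +
      4L * nf + members + 2L * nc
  }
  smiles <- vapply(1:6, function(k) paste(rep("C", k), collapse = ""), "")
  mols <- chessr:::parse_smiles_batch(smiles)
  nums <- canonical_numberings(mols)
  for (k in 1:6) {
    g <- encode_molecule(mols[[k]], nums[[k]],
                         encoding_options(depths = 1))
    expect_equal(nrow(g$triples), expected_count(k), info = paste("k =", k))
  }
})

test_that("turtle and n-triples serializations round-trip losslessly", {
  mol <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(mol)
  g <- encode_molecule(mol, num)
  for (dialect in c("turtle", "ntriples")) {
    f <- tempfile(fileext = if (dialect == "turtle") ".ttl" else ".nt")
    write_graph(g, f, dialect)
    g2 <- read_graph(f)
    expect_identical(g2$triples, g$triples)
  }
  # prefix declarations match the canonical namespaces
  f <- tempfile(fileext = ".ttl")
  write_graph(g, f)
  header <- readLines(f, n = 6)
  expect_true(any(grepl("^@prefix sio: <http://semanticscience.org/resource/SIO_>",
                        header)))
  expect_true(any(grepl("^@prefix chess: ", header)))

  # an empty graph is a valid document
  fe <- tempfile(fileext = ".ttl")
  write_graph(triple_graph(), fe)
  ge <- read_graph(fe)
  expect_equal(nrow(ge$triples), 0L)
})

test_that("serialized output is parseable by an independent RDF stack", {
  mol <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(mol)
  g <- encode_molecule(mol, num)
  g <- attach_descriptor(g, molecule_uri(num),
                         descriptor("invariant", "mass_descriptor",
                                    value = "46.07", unit = "g/mol"))
  for (spec in list(c("turtle", ".ttl"), c("nt", ".nt"))) {
    f <- tempfile(fileext = spec[2])
    write_graph(g, f, if (spec[1] == "turtle") "turtle" else "ntriples")
    out <- system2("python", c("-c",
      shQuote(paste0("import rdflib,sys; g=rdflib.Graph(); ",
                     "g.parse(sys.argv[1], format='", spec[1], "'); print(len(g))")),
      shQuote(f)), stdout = TRUE, stderr = FALSE)
    expect_equal(as.integer(out[length(out)]), nrow(g$triples))
  }
})

test_that("independently encoded graphs for one molecule collapse on merge", {
  mol <- parse_molecule("CC1(C)c2ccccc2C(=CCCN(C)C)c2ccccc21", "smiles")
  num <- canonical_numbering(mol)
  g1 <- attach_descriptor(encode_molecule(mol, num), molecule_uri(num),
                          descriptor("invariant", "mass_descriptor",
                                     value = "291.4", unit = "g/mol"))
  g2 <- attach_descriptor(encode_molecule(mol, num), molecule_uri(num),
                          descriptor("invariant", "logp_descriptor", value = "4.7"))
  f1 <- tempfile(fileext = ".ttl"); f2 <- tempfile(fileext = ".ttl")
  write_graph(g1, f1); write_graph(g2, f2)
  merged <- load_knowledgebase(c(f1, f2))
  expect_length(kb_molecules(merged), 1L)
  rows <- retrieve_descriptors(merged, molecule = molecule_uri(num))
  expect_setequal(rows$value, c("291.4", "4.7"))
  # idempotence: loading the same file twice changes nothing
  again <- load_knowledgebase(c(f1, f1))
  expect_identical(again$triples, read_graph(f1)$triples)
})

test_that("union of single-molecule encodings equals the batch encoding", {
  smiles <- c("CCO", "CC=O", "C")
  single <- lapply(chessr:::parse_smiles_batch(smiles), encode_molecule)
  merged <- graph_union(single)
  batch <- encode_knowledgebase(smiles)
  expect_identical(merged$triples, batch$triples)
})

test_that("conflicting descriptor values are retained and flagged", {
  g <- triple_graph()
  d <- paste0(chess_base(), "XXX-D", strrep("a", 40))
  g <- chessr:::tg_add(g, d, chess_term("rdf_type"), chess_term("mass_descriptor"))
  g <- chessr:::tg_add(g, d, chess_term("has_value"), c("1.0", "2.0"), lit = TRUE)
  g <- chessr:::tg_add(g, d, chess_term("has_unit"), "g/mol", lit = TRUE)
  g <- chessr:::tg_finalize(g)
  expect_equal(sum(g$triples$p == chess_term("has_value")), 2L)
  report <- validate_graph(g)
  expect_true(any(grepl("conflicting values", report$message)))
})

test_that("a variable descriptor without configuration fails validation", {
  g <- triple_graph()
  d <- paste0(chess_base(), "XXX-D", strrep("b", 40))
  g <- chessr:::tg_add(g, d, chess_term("rdf_type"),
                       paste0(chess_base(), "VariableChemicalDescriptor"))
  g <- chessr:::tg_add(g, d, chess_term("has_value"), "1.5", lit = TRUE)
  report <- validate_graph(g)
  expect_true(any(report$level == "error" &
                    grepl("lacks a chemical configuration", report$message)))
})

test_that("parse failures name the file and line", {
  f <- tempfile(fileext = ".ttl")
  writeLines(c("@prefix chess: <http://semanticscience.org/resource/CHESS_> .",
               "chess:a chess:b"), f)
  expect_error(read_graph(f), "line 2")
})
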