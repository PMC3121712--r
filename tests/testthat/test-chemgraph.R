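test_that("SMILES parsing yields the expected chemical graphs", {
  eth <- parse_molecule("CCO", "smiles")
  expect_equal(nrow(eth$atoms), 3L)
  expect_equal(sort(eth$atoms$element), c("C", "C", "O"))
  expect_equal(nrow(eth$bonds), 2L)
  expect_true(all(eth$bonds$order == "single"))

  prop <- parse_molecule("CCCO", "smiles")
  expect_equal(nrow(prop$atoms), 4L)
  deg <- tabulate(c(prop$bonds$a, prop$bonds$b), nbins = 4L)
  expect_equal(sort(deg), c(1L, 1L, 2L, 2L))   # chain topology

  ald <- parse_molecule("CC=O", "smiles")
  expect_true("double" %in% ald$bonds$order)
})

test_that("malformed or empty structure input raises format errors", {
  expect_error(parse_molecule("C(", "smiles"), class = "chess_format_error")
  expect_error(parse_molecule("C1CC", "smiles"), class = "chess_format_error")
  expect_error(parse_molecule("C)O", "smiles"), class = "chess_format_error")
  expect_error(parse_molecule("", "smiles"), class = "chess_empty_input_error")
  expect_error(parse_molecule("not-an-inchi", "inchi"), class = "chess_format_error")
})

test_that("SDF and InChI inputs parse to the same graph as SMILES", {
  eth <- parse_molecule("CCO", "smiles")
  via_inchi <- parse_molecule("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", "inchi")
  expect_equal(sort(via_inchi$atoms$element), sort(eth$atoms$element))
  expect_equal(nrow(via_inchi$bonds), nrow(eth$bonds))

  sdf_path <- tempfile(fileext = ".sdf")
  writeLines(strsplit(chessr:::as_molblock(eth), "\n")[[1]], sdf_path)
  via_sdf <- parse_molecule(sdf_path, "sdf")
  expect_equal(via_sdf$atoms$element, eth$atoms$element)
  expect_equal(via_sdf$bonds, eth$bonds)
})

test_that("graph invariants are enforced at construction", {
  a <- data.frame(element = c("C", "C"))
  expect_error(chess_mol(a, data.frame(a = 1, b = 1, order = "single")), "self-bond")
  expect_error(chess_mol(a, data.frame(a = c(1, 2), b = c(2, 1),
                                       order = "single")), "duplicate")
  expect_error(chess_mol(a, data.frame(a = 1, b = 3, order = "single")),
               "out of range")
  expect_error(chess_mol(data.frame(element = character())))
})

test_that("canonical numbering reproduces standard InChI order and is input-order invariant", {
  eth <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(eth)
  expect_equal(num$inchikey, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  expect_equal(unname(num$heavy_map), c(1L, 2L, 3L))   # C C O -> 1 2 3

  rev_eth <- parse_molecule("OCC", "smiles")
  num2 <- canonical_numbering(rev_eth)
  expect_equal(num2$inchikey, num$inchikey)
  expect_equal(unname(num2$heavy_map[c("3", "2", "1")]), c(1L, 2L, 3L))
})

test_that("canonical identity survives random atom permutations", {
  # Canonical indices are unique up to molecular automorphism: in symmetric
  # molecules (isopropanol's two methyls, phenol's ring) equivalent atoms may
  # swap indices between input orderings while the identifier set is fixed.
  # Asymmetric molecules must reproduce the index per atom identity exactly;
  # all molecules must reproduce the (element, index) multiset.
  asymmetric <- c("CCO", "CCCO", "CC=O")
  smiles <- c(asymmetric, "CC(C)O", "Oc1ccccc1")
  mols <- chessr:::parse_smiles_batch(smiles)
  nums <- canonical_numberings(mols)
  old <- local_seed(42)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_along(mols)) {
    n <- nrow(mols[[i]]$atoms)
    perms <- replicate(10, sample(n), simplify = FALSE)
    pmols <- lapply(perms, function(p) permute_atoms(mols[[i]], p))
    pnums <- canonical_numberings(pmols)
    for (k in seq_along(perms)) {
      expect_equal(pnums[[k]]$inchikey, nums[[i]]$inchikey)
      labelled <- function(m, nn) sort(paste0(m$atoms$element[as.integer(names(nn$heavy_map))],
                                              nn$heavy_map))
      expect_equal(labelled(pmols[[k]], pnums[[k]]), labelled(mols[[i]], nums[[i]]))
      if (smiles[i] %in% asymmetric) {
        old_to_new <- attr(pmols[[k]], "old_to_new")
        expect_equal(
          unname(pnums[[k]]$heavy_map[as.character(old_to_new[as.integer(names(nums[[i]]$heavy_map))])]),
          unname(nums[[i]]$heavy_map))
      }
    }
  }
})

test_that("InChIKeys match the canonical key pattern", {
  smiles <- c("C", "CCO", "Oc1ccccc1", "CC1(C)c2ccccc2C(=CCCN(C)C)c2ccccc21")
  nums <- canonical_numberings(chessr:::parse_smiles_batch(smiles))
  for (n in nums)
    expect_match(n$inchikey, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("multi-component structures are rejected, not split", {
  salt <- chess_mol(data.frame(element = c("Na", "Cl")))
  expect_error(canonical_numbering(salt), class = "chess_representability_error")
})

test_that("hydrogens get derived indices beyond the heavy range", {
  eth <- add_hydrogens(parse_molecule("CCO", "smiles"))
  expect_equal(nrow(eth$atoms), 9L)
  num <- canonical_numbering(eth)
  expect_equal(length(num$heavy_map), 3L)
  expect_equal(sort(unname(num$hydrogen_map)), 4:9)
  expect_true(all(num$hydrogen_map > max(num$heavy_map)))
  # the hydroxyl hydrogen is attached to the highest-numbered heavy atom (O),
  # so under the attached-heavy ordering it receives the last index
  oh <- chessr:::find_oh_bond(eth)
  expect_equal(chessr:::canonical_index(num, oh[2]), 9L)
})

test_that("encode then reconstitute returns an isomorphic graph", {
  for (s in c("CCO", "CC(C)O", "CC=O", "C1=CCCC1")) {
    mol <- parse_molecule(s, "smiles")
    num <- canonical_numbering(mol)
    kb <- encode_molecule(mol, num)
    back <- reconstitute_graph(kb, molecule_uri(num))
    expect_equal(sort(back$atoms$element),
                 sort(mol$atoms$element[mol$atoms$element != "H"]))
    expect_equal(nrow(back$bonds), nrow(mol$bonds))
    expect_equal(sort(table(back$bonds$order)), sort(table(mol$bonds$order)))
    # mutual substructure => isomorphic under element/order-preserving matching
    expect_true(oracle_has_substructure(back, mol))
    expect_true(oracle_has_substructure(mol, back))
  }
})

test_that("incomplete graphs are reported with the offending entities", {
  mol <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(mol)
  kb <- encode_molecule(mol, num)
  # drop the oxygen's parthood: a bond now references a non-member atom
  o_uri <- format(atom_uri(num, 3))
  kb$triples <- kb$triples[!(kb$triples$s == format(molecule_uri(num)) &
                               kb$triples$o == o_uri), , drop = FALSE]
  expect_error(reconstitute_graph(kb, molecule_uri(num)),
               class = "chess_incomplete_graph_error")
})
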