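test_that("hash components are 40 lowercase hex digits and delimiter-safe", {
  h <- chess_hash(c("a", "b"))
  expect_match(h, "^[0-9a-f]{40}$")
  expect_identical(h, chess_hash(c("a", "b")))
  expect_false(chess_hash(c("ab", "c")) == chess_hash(c("a", "bc")))
})

test_that("molecule, atom and bond URIs reproduce the ethanol worked example", {
  num <- canonical_numbering(parse_molecule("CCO", "smiles"))
  expect_equal(molecule_uri(num)$local, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  expect_equal(atom_uri(num, 3)$local, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N-AO3")
  expect_equal(bond_uri(num, 2, 3)$local, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N-BCO23")
  expect_equal(bond_uri(num, 3, 2)$local, bond_uri(num, 2, 3)$local)
})

test_that("the same compound from different sources collapses onto one URI", {
  k1 <- canonical_numbering(parse_molecule("CC1(C)c2ccccc2C(=CCCN(C)C)c2ccccc21",
                                           "smiles"))
  expect_equal(molecule_uri(k1)$local, "GWWLWDURRGNSRS-UHFFFAOYSA-N")
  k2 <- canonical_numbering(parse_molecule(k1$inchi, "inchi"))
  expect_equal(format(molecule_uri(k2)), format(molecule_uri(k1)))
})

test_that("atom and bond URIs are pairwise distinct within a molecule", {
  mol <- parse_molecule("CC(C)O", "smiles")
  num <- canonical_numbering(mol)
  atoms <- vapply(seq_len(nrow(mol$atoms)), function(i) atom_uri(num, i)$local, "")
  expect_equal(anyDuplicated(atoms), 0L)
  bonds <- vapply(seq_len(nrow(mol$bonds)), function(k)
    bond_uri(num, mol$bonds$a[k], mol$bonds$b[k])$local, "")
  expect_equal(anyDuplicated(bonds), 0L)
})

test_that("fragment URIs are structural, deterministic and permutation-invariant", {
  mol <- parse_molecule("CCO", "smiles")
  num <- canonical_numbering(mol)
  frags <- atom_centered_fragments(mol, num)
  locals <- vapply(frags, function(f) f$uri$local, "")
  expect_true(all(grepl("-FG[0-9a-f]{40}$", locals)))
  expect_equal(anyDuplicated(locals), 0L)

  perm <- permute_atoms(mol, c(3, 1, 2))
  pfrags <- atom_centered_fragments(perm, canonical_numbering(perm))
  expect_setequal(vapply(pfrags, function(f) f$uri$local, ""), locals)
})

test_that("configuration URIs sort annotations and separate distinct conditions", {
  c1 <- chemical_configuration(provider = "http://pubchem.ncbi.nlm.nih.gov",
                               temperature = "298")
  c2 <- chemical_configuration(temperature = "298",
                               provider = "http://pubchem.ncbi.nlm.nih.gov")
  expect_equal(configuration_uri(c1)$local, configuration_uri(c2)$local)
  expect_match(configuration_uri(c1)$local, "^CC[0-9a-f]{40}$")
  c3 <- chemical_configuration(provider = "http://www.ebi.ac.uk/chembl")
  expect_false(configuration_uri(c3)$local == configuration_uri(c1)$local)
  expect_error(chemical_configuration(),
               class = "chess_degenerate_configuration_error")
})

test_that("descriptor URIs separate owners, configurations and methods", {
  owner_a <- chess_uri("AAAAAAAAAAAAAA-UHFFFAOYSA-N")
  owner_b <- chess_uri("BBBBBBBBBBBBBB-UHFFFAOYSA-N")
  d <- descriptor("invariant", "heavy_atom_count", value = "3")
  ua <- descriptor_uri(d, owner_a); ub <- descriptor_uri(d, owner_b)
  expect_equal(sub("^.*-D", "", ua$local), sub("^.*-D", "", ub$local))
  expect_false(format(ua) == format(ub))

  cfg1 <- chemical_configuration(provider = "p1")
  cfg2 <- chemical_configuration(provider = "p2")
  v1 <- descriptor("variable", "logp_descriptor", value = "1.5", configuration = cfg1)
  v2 <- descriptor("variable", "logp_descriptor", value = "1.5", configuration = cfg2)
  expect_false(descriptor_uri(v1, owner_a)$local == descriptor_uri(v2, owner_a)$local)

  b1 <- make_bde_annotation(owner_a, "104.5", method_term = "AM1")
  b2 <- make_bde_annotation(owner_a, "104.5", method_term = "PM3")
  expect_false(descriptor_uri(b1, owner_a)$local == descriptor_uri(b2, owner_a)$local)
})

test_that("composite descriptor digest equals an independent recomputation", {
  cfg <- chemical_configuration(provider = "http://pubchem.ncbi.nlm.nih.gov")
  d <- make_coordinate_descriptor("1.55", "0.01", "-0.2", config = cfg)
  owner <- chess_uri("LFQSCWFLJHTTHZ-UHFFFAOYSA-N-AO3")
  got <- descriptor_uri(d, owner)$local

  # oracle: recompute the concatenation-and-digest by hand
  comp_local <- function(value, unit, cfg_local) {
    h <- digest::digest(paste(c(value, "", unit, cfg_local), collapse = "\x1f"),
                        algo = "sha1", serialize = FALSE)
    paste0(owner$local, "-D", h)
  }
  cfg_local <- paste0("CC", digest::digest(
    "provider=http://pubchem.ncbi.nlm.nih.gov", algo = "sha1", serialize = FALSE))
  unit <- chess_term("unit_angstrom")
  locals <- sort(c(comp_local("1.55", unit, cfg_local),
                   comp_local("0.01", unit, cfg_local),
                   comp_local("-0.2", unit, cfg_local)))
  expected <- paste0(owner$local, "-D",
                     digest::digest(paste(locals, collapse = "\x1f"),
                                    algo = "sha1", serialize = FALSE))
  expect_equal(got, expected)

  # component order at construction does not matter
  d_rev <- descriptor("composite", chess_term("coordinate_3d"),
                      components = rev(d$components), configuration = cfg)
  expect_equal(descriptor_uri(d_rev, owner)$local, got)
})

test_that("reaction URIs ignore listing order but respect stoichiometry", {
  r1 <- reaction_spec(inputs = c("FGaaa", "FGbbb"), products = "FGccc")
  r2 <- reaction_spec(inputs = c("FGbbb", "FGaaa"), products = "FGccc")
  expect_equal(reaction_uri(r1)$local, reaction_uri(r2)$local)
  expect_match(reaction_uri(r1)$local, "^RX[0-9a-f]{40}$")

  r3 <- reaction_spec(inputs = data.frame(ref = c("FGaaa", "FGbbb"),
                                          coefficient = c(2L, 1L)),
                      products = "FGccc")
  expect_false(reaction_uri(r3)$local == reaction_uri(r1)$local)
})

test_that("no two distinct entities share a URI across a fixture corpus", {
  fx <- generate_fixtures(12, seed = 7)
  mols <- chessr:::parse_smiles_batch(fx$molecules$smiles)
  nums <- canonical_numberings(mols)
  locals <- character()
  for (i in seq_along(mols)) {
    mol <- mols[[i]]; num <- nums[[i]]
    locals <- c(locals, molecule_uri(num)$local,
                vapply(seq_len(nrow(mol$atoms)), function(k)
                  atom_uri(num, k)$local, ""),
                vapply(seq_len(nrow(mol$bonds)), function(k)
                  bond_uri(num, mol$bonds$a[k], mol$bonds$b[k])$local, ""),
                vapply(atom_centered_fragments(mol, num),
                       function(f) f$uri$local, ""))
  }
  expect_equal(anyDuplicated(locals), 0L)
})
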