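#' @title Deterministic fixture generation
#' @description Generates small organic test sets — alkanes, alcohols,
#'   phenols, fatty-like chains and ring systems — emulating the kind of
#'   lipid- and drug-like collections the encoding scheme targets, together
#'   with synthetic annotation plans (Rule-of-Five boundary descriptors, O-H
#'   BDE values). Everything is a pure function of its arguments: the same
#'   `(n, seed, families, plan)` always yields byte-identical output. The
#'   worked-example molecules (ethanol, n-propanol, phenol, an aldehyde) are
#'   always included. All descriptor values in the plans are synthetic test
#'   values, not measurements.
#' @name fixtures
NULL

fixture_pools <- function() {
  list(
    "alkanes" = c(methane = "C", ethane = "CC", propane = "CCC",
                  butane = "CCCC", isobutane = "CC(C)C", pentane = "CCCCC",
                  neopentane = "CC(C)(C)C", hexane = "CCCCCC",
                  heptane = "CCCCCCC", octane = "CCCCCCCC",
                  nonane = "CCCCCCCCC"),
    "alcohols" = c(methanol = "CO", isopropanol = "CC(C)O",
                   "n-butanol" = "CCCCO", isobutanol = "OCC(C)C",
                   "2-butanol" = "CCC(C)O", "ethylene glycol" = "OCCO",
                   "n-pentanol" = "CCCCCO", "allyl alcohol" = "C=CCO",
                   cyclohexanol = "OC1CCCCC1", "benzyl alcohol" = "OCc1ccccc1"),
    "phenols" = c("p-cresol" = "Cc1ccc(O)cc1", hydroquinone = "Oc1ccc(O)cc1",
                  catechol = "Oc1ccccc1O", "4-methoxyphenol" = "COc1ccc(O)cc1",
                  resorcinol = "Oc1cccc(O)c1",
                  "2,6-dimethylphenol" = "Cc1cccc(C)c1O"),
    "fatty-chains" = c(butanal = "CCCC=O", hexanal = "CCCCCC=O",
                       octanal = "CCCCCCCC=O", "1-octanol" = "CCCCCCCCO",
                       "octanoic acid" = "CCCCCCCC(=O)O",
                       "hexanoic acid" = "CCCCCC(=O)O", decane = "CCCCCCCCCC",
                       "1-dodecanol" = "CCCCCCCCCCCCO", decanal = "CCCCCCCCCC=O",
                       "lauric acid" = "CCCCCCCCCCCC(=O)O"),
    "ring-systems" = c(benzene = "c1ccccc1", toluene = "Cc1ccccc1",
                       cyclohexane = "C1CCCCC1", cyclopentene = "C1=CCCC1",
                       cyclopentane = "C1CCCC1", tetrahydrofuran = "C1CCOC1",
                       styrene = "C=Cc1ccccc1", naphthalene = "c1ccc2ccccc2c1",
                       indane = "C1Cc2ccccc2C1", anisole = "COc1ccccc1",
                       melitracene = "CC1(C)c2ccccc2C(=CCCN(C)C)c2ccccc21"))
}

mandatory_fixtures <- function() {
  c(ethanol = "CCO", "n-propanol" = "CCCO", phenol = "Oc1ccccc1",
    acetaldehyde = "CC=O")
}

#' Generate a deterministic fixture set
#'
#' @param n Total number of molecules (>= 4; the four worked-example
#'   molecules are always present).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param families Families to draw from.
#' @param plan Annotation plan: `"none"`, `"lipinski-boundary"` (synthetic
#'   mass/HBA/HBD/logP profiles straddling each Rule-of-Five threshold) or
#'   `"bde"` (synthetic O-H bond dissociation enthalpies around the 67-78
#'   kcal/mol antioxidant window, plus ethanol's 104.5).
#' @return List of class `chess_fixtures`: `molecules` (data.frame `name`,
#'   `smiles`, `family`), `annotations` (plan-dependent data.frame), `seed`,
#'   `plan`.
#' @export
generate_fixtures <- function(n = 10L, seed = 1L,
                              families = c("alkanes", "alcohols", "phenols",
                                           "fatty-chains", "ring-systems"),
                              plan = c("none", "lipinski-boundary", "bde")) {
  plan <- match.arg(plan)
  stopifnot(n >= 1L)
  pools <- fixture_pools()
  unknown <- setdiff(families, names(pools))
  if (length(unknown))
    stop_chess("config", paste0("unknown fixture family: ",
                                paste(unknown, collapse = ", ")))
  mand <- mandatory_fixtures()
  pool <- unlist(unname(pools[families]))
  pool <- pool[!pool %in% mand]
  extra_n <- max(0L, n - length(mand))
  if (extra_n > length(pool)) extra_n <- length(pool)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  picked <- if (extra_n) sample(names(pool), extra_n) else character()
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  fam_of <- function(nm) {
    for (f in names(pools)) if (nm %in% names(pools[[f]])) return(f)
    "worked-examples"
  }
  mols <- data.frame(
    name = c(names(mand), picked),
    smiles = c(unname(mand), unname(pool[picked])),
    stringsAsFactors = FALSE)
  mols$family <- vapply(mols$name, fam_of, "")
  rownames(mols) <- NULL

  annotations <- switch(plan,
    "none" = data.frame(),
    "lipinski-boundary" = lipinski_boundary_plan(mols),
    "bde" = bde_plan(mols))
  structure(list(molecules = mols, annotations = annotations,
                 seed = seed, plan = plan),
            class = "chess_fixtures")
}

# Synthetic descriptor profiles straddling every Rule-of-Five threshold:
# mass is strict-below-500, acceptor/donor counts are inclusive, logP is a
# strict open interval.
lipinski_boundary_plan <- function(mols) {
  profiles <- list(
    list(tag = "boundary-pass", mass = "499.9", hba = "10", hbd = "5", logp = "4.9"),
    list(tag = "mass-fail",     mass = "500.0", hba = "9",  hbd = "4", logp = "3.0"),
    list(tag = "hba-fail",      mass = "350.0", hba = "11", hbd = "4", logp = "2.0"),
    list(tag = "hbd-fail",      mass = "350.0", hba = "8",  hbd = "6", logp = "2.0"),
    list(tag = "logp-high-fail", mass = "350.0", hba = "8", hbd = "4", logp = "5.0"),
    list(tag = "logp-low-fail", mass = "350.0", hba = "8",  hbd = "4", logp = "-5.0"),
    list(tag = "missing-logp",  mass = "350.0", hba = "8",  hbd = "4", logp = NA),
    list(tag = "typical-pass",  mass = "180.2", hba = "4",  hbd = "2", logp = "1.3856"))
  rows <- list()
  for (i in seq_len(nrow(mols))) {
    p <- profiles[[(i - 1L) %% length(profiles) + 1L]]
    for (d in c("mass", "hba", "hbd", "logp")) {
      if (is.na(p[[d]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = mols$name[i], profile = p$tag, descriptor = d, value = p[[d]],
        unit = if (d == "mass") "g/mol" else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Synthetic O-H BDE values: phenolic fixtures inside, on, and outside the
# (67, 78) antioxidant window; ethanol's aliphatic O-H at 104.5.
bde_plan <- function(mols) {
  values <- c(phenol = "72", "p-cresol" = "67", hydroquinone = "78",
              catechol = "80", resorcinol = "74.5", "4-methoxyphenol" = "70",
              "2,6-dimethylphenol" = "76", ethanol = "104.5")
  here <- intersect(names(values), mols$name)
  data.frame(name = here, descriptor = "bde", value = unname(values[here]),
             unit = "kcal/mol", method = "AM1", software = "MOPAC",
             software_version = "7.1.11", temperature = "298",
             stringsAsFactors = FALSE)
}

#' Encode a fixture set as an annotated knowledgebase
#'
#' Encodes all fixture molecules and applies the fixture's annotation plan:
#' Rule-of-Five descriptors attach to the molecule nodes; BDE annotations
#' re-encode the annotated molecules with explicit hydrogens, register their
#' phenol groups (detected by subgraph matching against the phenol pattern)
#' under the phenol class, and attach the BDE descriptor with full AM1 /
#' software / temperature provenance to the O-H bond entity.
#' @param fixtures A [generate_fixtures()] result.
#' @param opts [encoding_options()].
#' @param base Base IRI.
#' @return A `chess_graph` (index attribute as in [encode_knowledgebase()]).
#' @export
fixture_knowledgebase <- function(fixtures, opts = encoding_options(),
                                  base = chess_base()) {
  stopifnot(inherits(fixtures, "chess_fixtures"))
  mols <- fixtures$molecules
  need_h <- fixtures$plan == "bde"
  if (need_h) opts$include_hydrogens <- TRUE
  kb <- encode_knowledgebase(mols$smiles, opts, base, names = mols$name)
  idx <- attr(kb, "index")
  ann <- fixtures$annotations
  if (!nrow(ann)) return(kb)

  if (fixtures$plan == "lipinski-boundary") {
    term_of <- c(mass = "mass_descriptor", hba = "hba_count",
                 hbd = "hbd_count", logp = "logp_descriptor")
    for (k in seq_len(nrow(ann))) {
      owner <- chess_uri(idx$inchikey[match(ann$name[k], idx$name)], base)
      d <- descriptor("invariant", term_of[[ann$descriptor[k]]],
                      value = ann$value[k],
                      unit = if (!is.na(ann$unit[k])) ann$unit[k])
      kb <- attach_descriptor(kb, owner, d, base)
    }
  } else if (fixtures$plan == "bde") {
    phenol_pattern <- parse_molecule("Oc1ccccc1", "smiles")
    for (k in seq_len(nrow(ann))) {
      i <- match(ann$name[k], idx$name)
      mol <- add_hydrogens(parse_molecule(idx$smiles[i], "smiles"))
      num <- canonical_numbering(mol)
      m <- match_graph(phenol_pattern, mol)
      if (length(m)) {
        frag <- register_custom_group(mol, num, m[[1]],
                                      chess_uri("FGPhenol", base), base)
        g <- triple_graph(chess_namespaces())
        g <- tg_add(g, format(frag$uri), chess_term("rdf_type"),
                    paste0(base, "FGPhenol"))
        g <- tg_add(g, format(frag$uri), chess_term("rdf_type"),
                    chess_term("organic_group"))
        g <- tg_add(g, format(molecule_uri(num, base)),
                    chess_term("has_proper_part"), format(frag$uri))
        kb <- graph_union(kb, g)
      }
      oh <- find_oh_bond(mol)
      if (is.null(oh)) next
      buri <- bond_uri(num, oh[1], oh[2], base)
      d <- make_bde_annotation(buri, ann$value[k], unit = ann$unit[k],
                               method_term = ann$method[k],
                               software = c(ann$software[k], ann$software_version[k]),
                               parameters = list(list(term = chess_term("temperature"),
                                                      value = ann$temperature[k],
                                                      unit = chess_term("unit_kelvin"))))
      kb <- attach_descriptor(kb, buri, d, base)
    }
  }
  attr(kb, "index") <- idx
  kb
}

# first O-H bond of a molecule with explicit hydrogens: c(o_idx, h_idx)
find_oh_bond <- function(mol) {
  el <- mol$atoms$element
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    if (el[a] == "O" && el[b] == "H") return(c(a, b))
    if (el[b] == "O" && el[a] == "H") return(c(b, a))
  }
  NULL
}
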