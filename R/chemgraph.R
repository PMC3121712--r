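#' @title Molecular graphs and canonical numbering
#' @description A molecule is held as a plain chemical graph: a table of atoms
#'   (element, formal charge, isotope, explicit-hydrogen flag) and a table of
#'   bonds (endpoint indices and order, one of single/double/triple/aromatic).
#'   Every identifier the package mints is anchored on the canonical heavy-atom
#'   order produced by standard InChI canonicalization, so identical molecules
#'   entered in any atom order receive byte-identical identifiers.
#' @name chemgraph
NULL

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Construct a molecular graph
#'
#' @param atoms data.frame with columns `element` (symbol), and optionally
#'   `charge` (integer, default 0) and `isotope` (integer mass number or NA).
#' @param bonds data.frame with columns `a`, `b` (1-based atom indices) and
#'   `order` (`"single"`, `"double"`, `"triple"` or `"aromatic"`, or the V2000
#'   numeric codes 1-4).
#' @param source_format Provenance tag, one of `"SMILES"`, `"SDF"`, `"InChI"`
#'   or `"constructed"`.
#' @return An object of class `chess_mol`.
#' @export
chess_mol <- function(atoms, bonds = NULL, source_format = "constructed") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(nrow(atoms) >= 1L, "element" %in% names(atoms))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$isotope)) atoms$isotope <- NA_integer_
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$isotope <- as.integer(atoms$isotope)
  atoms <- atoms[, c("element", "charge", "isotope")]

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b", "order") %in% names(bonds)))
    if (is.numeric(bonds$order)) bonds$order <- BOND_ORDERS[bonds$order]
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    if (!all(bonds$order %in% BOND_ORDERS))
      stop("invalid bond order(s): ",
           paste(setdiff(bonds$order, BOND_ORDERS), collapse = ", "))
    n <- nrow(atoms)
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n))
      stop("bond endpoint index out of range")
    if (any(bonds$a == bonds$b)) stop("self-bonds are not allowed")
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("duplicate bonds between the same atom pair")
    bonds <- bonds[, c("a", "b", "order")]
  }
  structure(list(atoms = atoms, bonds = bonds, source_format = source_format),
            class = "chess_mol")
}

#' @export
print.chess_mol <- function(x, ...) {
  cat("<chess_mol> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$element != "H"), " heavy), ",
      nrow(x$bonds), " bonds, from ", x$source_format, "\n", sep = "")
  invisible(x)
}

n_heavy <- function(mol) sum(mol$atoms$element != "H")
heavy_indices <- function(mol) which(mol$atoms$element != "H")

# ---- SMILES syntactic validation -------------------------------------------
# OpenBabel silently repairs some malformed SMILES, so the format-error
# contract is enforced here before delegation.
validate_smiles <- function(s) {
  if (!nzchar(trimws(s))) stop_chess("empty_input", "empty SMILES input")
  bad <- regmatches(s, regexpr("[^A-Za-z0-9()\\[\\]=#$:+\\-/\\\\.%@*]", s))
  if (length(bad) && nzchar(bad))
    stop_chess("format", sprintf("invalid character '%s' in SMILES \"%s\"", bad, s))
  chars <- strsplit(s, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop_chess("format", sprintf("unbalanced ')' at position %d in \"%s\"",
                                 which(depth < 0)[1], s))
  if (utils::tail(depth, 1) != 0)
    stop_chess("format", sprintf("unbalanced '(' in \"%s\"", s))
  bdepth <- cumsum((chars == "[") - (chars == "]"))
  if (any(bdepth < 0) || utils::tail(bdepth, 1) != 0)
    stop_chess("format", sprintf("unbalanced brackets in \"%s\"", s))
  # ring-closure labels must pair up (digits outside atom brackets, plus %nn)
  labels <- character(); i <- 1L; inbracket <- 0L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") inbracket <- inbracket + 1L
    else if (ch == "]") inbracket <- inbracket - 1L
    else if (inbracket == 0L) {
      if (ch == "%" && i + 2L <= length(chars)) {
        labels <- c(labels, paste0(chars[i + 1:2], collapse = ""))
        i <- i + 2L
      } else if (ch %in% as.character(0:9)) labels <- c(labels, ch)
    }
    i <- i + 1L
  }
  counts <- table(labels)
  if (any(counts %% 2 != 0))
    stop_chess("format", sprintf("unpaired ring closure '%s' in \"%s\"",
                                 names(counts)[counts %% 2 != 0][1], s))
  invisible(TRUE)
}

stop_chess <- function(class, msg, ...) {
  stop(structure(class = c(paste0("chess_", class, "_error"), "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# ---- V2000 mol block I/O ----------------------------------------------------

as_molblock <- function(mol, title = "") {
  a <- mol$atoms; b <- mol$bonds
  ord <- match(b$order, BOND_ORDERS)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, a$element)
  bond_lines <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$a, b$b, ord) else character()
  prop <- character()
  chg <- which(a$charge != 0L)
  if (length(chg))
    prop <- c(prop, sprintf("M  CHG%3d%s", length(chg),
                            paste0(sprintf(" %3d %3d", chg, a$charge[chg]), collapse = "")))
  iso <- which(!is.na(a$isotope))
  if (length(iso))
    prop <- c(prop, sprintf("M  ISO%3d%s", length(iso),
                            paste0(sprintf(" %3d %3d", iso, a$isotope[iso]), collapse = "")))
  paste(c(title, "  chessr", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
          atom_lines, bond_lines, prop, "M  END", "$$$$"),
        collapse = "\n")
}

# Parse one V2000 mol block (text) into a chess_mol via ChemmineR.
# Bond-less records (single atoms) fall back to fixed-width field slicing:
# ChemmineR's SDF model treats molecules without bonds as invalid.
molblock_to_mol <- function(block, source_format = "SDF") {
  lines <- unlist(strsplit(block, "\n"))
  lines <- lines[!grepl("^\\$\\$\\$\\$", lines)]
  counts_at <- grep(" V2000", lines)[1]
  n_atoms <- as.integer(substr(lines[counts_at], 1, 3))
  if (is.na(counts_at) || is.na(n_atoms))
    stop_chess("format", "not a V2000 mol block")
  bond_count <- as.integer(substr(lines[counts_at], 4, 6))
  if (!is.na(bond_count) && bond_count == 0L) {
    atom_lines <- lines[counts_at + seq_len(n_atoms)]
    elements <- trimws(substr(atom_lines, 32, 34))
    bb <- NULL
  } else {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(lines, "$$$$"), tmp)
    sdf <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    sdfobj <- sdf[[1]]
    ab <- ChemmineR::atomblock(sdfobj)
    bb <- ChemmineR::bondblock(sdfobj)
    elements <- sub("_.*$", "", rownames(ab))
  }
  atoms <- data.frame(element = elements, charge = 0L, isotope = NA_integer_,
                      stringsAsFactors = FALSE)
  # formal charges / isotopes from the authoritative M CHG / M ISO lines
  for (ln in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    nums <- as.integer(regmatches(ln, gregexpr("-?[0-9]+", ln))[[1]])
    n <- nums[1]; pairs <- matrix(nums[-1], ncol = 2, byrow = TRUE)
    if (grepl("CHG", ln)) atoms$charge[pairs[, 1]] <- pairs[, 2]
    else atoms$isotope[pairs[, 1]] <- pairs[, 2]
  }
  counts_line <- lines[grep(" V2000", lines)[1]]
  n_bonds <- as.integer(substr(counts_line, 4, 6))
  bonds <- if (!is.na(n_bonds) && n_bonds > 0L && length(bb) && nrow(bb)) {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), stringsAsFactors = FALSE)
  } else NULL
  mol <- chess_mol(atoms, bonds, source_format = source_format)
  perceive_aromaticity(mol, paste0(lines, collapse = "\n"))
}

# Kekule structures are input-order dependent, so aromatic ring bonds are
# re-marked with the distinct "aromatic" order using OpenBabel's perception
# (read from the SYBYL MOL2 bond block, which preserves atom order). Only
# molecules that can contain a ring are converted.
perceive_aromaticity <- function(mol, block) {
  if (nrow(mol$bonds) < nrow(mol$atoms)) return(mol)
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "MOL2", paste0(block, "\n$$$$\n")),
    error = function(e) NULL)
  if (is.null(out)) return(mol)
  lines <- unlist(strsplit(out, "\n"))
  at <- grep("^@<TRIPOS>BOND", lines)
  if (!length(at)) return(mol)
  lines <- lines[-seq_len(at[1])]
  stop_at <- grep("^@<TRIPOS>", lines)
  if (length(stop_at)) lines <- lines[seq_len(stop_at[1] - 1L)]
  for (ln in lines[nzchar(trimws(lines))]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 4L || f[4] != "ar") next
    a <- as.integer(f[2]); b <- as.integer(f[3])
    hit <- (mol$bonds$a == a & mol$bonds$b == b) |
      (mol$bonds$a == b & mol$bonds$b == a)
    mol$bonds$order[hit] <- "aromatic"
  }
  mol
}

# ---- parsing ----------------------------------------------------------------

#' Parse a chemical structure into a molecular graph
#'
#' @param input A SMILES string, an InChI string, or SDF/MOL V2000 content
#'   (text or path to a file).
#' @param format One of `"smiles"`, `"sdf"`, `"inchi"`.
#' @return A [chess_mol]. Hydrogens remain implicit unless the input declares
#'   them explicitly.
#' @examples
#' \dontrun{
#' parse_molecule("CCO", "smiles")
#' }
#' @export
parse_molecule <- function(input, format = c("smiles", "sdf", "inchi")) {
  format <- match.arg(format)
  if (length(input) != 1L || !nzchar(trimws(input %||% "")))
    stop_chess("empty_input", "empty structure input")
  switch(format,
    smiles = {
      input <- trimws(input)
      validate_smiles(input)
      block <- ob_smiles_to_molblocks(input)[[1]]
      molblock_to_mol(block, "SMILES")
    },
    inchi = {
      input <- trimws(input)
      if (!startsWith(input, "InChI="))
        stop_chess("format", "InChI input must start with 'InChI='")
      molblock_to_mol(ob_inchi_to_molblock(input), "InChI")
    },
    sdf = {
      text <- if (!grepl("\n", input) && file.exists(input))
        paste(readLines(input, warn = FALSE), collapse = "\n") else input
      blocks <- split_sdf(text)
      if (!length(blocks)) stop_chess("format", "no records in SDF input")
      molblock_to_mol(blocks[[1]], "SDF")
    })
}

# Batch-parse SMILES into a list of chess_mol (one ChemmineOB call).
parse_smiles_batch <- function(smiles) {
  invisible(lapply(smiles, validate_smiles))
  blocks <- ob_smiles_to_molblocks(smiles)
  lapply(blocks, molblock_to_mol, source_format = "SMILES")
}

#' Materialize implicit hydrogens
#'
#' Adds explicit hydrogen atoms (needed e.g. to annotate O-H bonds); the heavy
#' skeleton and its canonical numbering are unchanged.
#' @param mol A [chess_mol].
#' @return A [chess_mol] with explicit hydrogens appended after the heavy atoms.
#' @export
add_hydrogens <- function(mol) {
  out <- ob_run(unlist(strsplit(as_molblock(mol), "\n")), "sdf", "sdf", "-h")
  molblock_to_mol(split_sdf(paste(out, collapse = "\n"))[[1]], mol$source_format)
}

#' Permute atom order
#'
#' Rebuilds the same molecule with atoms listed in a different order; used to
#' demonstrate that canonical identifiers do not depend on input order.
#' @param mol A [chess_mol].
#' @param perm Permutation of `seq_len(n_atoms)`: new position `i` holds old
#'   atom `perm[i]`.
#' @return A [chess_mol]; attribute `"old_to_new"` maps old indices to new.
#' @export
permute_atoms <- function(mol, perm) {
  n <- nrow(mol$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  old_to_new <- integer(n); old_to_new[perm] <- seq_len(n)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds)) { bonds$a <- old_to_new[bonds$a]; bonds$b <- old_to_new[bonds$b] }
  out <- chess_mol(atoms, bonds, mol$source_format)
  attr(out, "old_to_new") <- old_to_new
  out
}

# ---- canonical numbering ----------------------------------------------------

#' Canonical atom numbering from standard InChI
#'
#' Heavy atoms receive the 1-based canonical indices of the standard-InChI
#' canonicalization (read from the InChI AuxInfo `/N:` layer). Explicit
#' hydrogens receive derived indices `n_heavy + k`, ordered by the canonical
#' index of their attached heavy atom (input order breaking ties): InChI
#' numbers heavy atoms only, so hydrogen indices are a package convention.
#'
#' @param mol A [chess_mol] representing a single covalently bonded unit.
#' @return An object of class `chess_numbering` with fields `heavy_map`
#'   (input index -> canonical index), `hydrogen_map`, `inchi`, `inchikey`,
#'   `elements`, and `version` (toolkit provenance, since InChIKeys can drift
#'   between InChI releases).
#' @examples
#' \dontrun{
#' canonical_numbering(parse_molecule("CCO", "smiles"))$inchikey
#' # "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"
#' }
#' @export
canonical_numbering <- function(mol) canonical_numberings(list(mol))[[1]]

#' @rdname canonical_numbering
#' @param mols List of [chess_mol] objects (batched: one InChI process call).
#' @export
canonical_numberings <- function(mols) {
  stopifnot(length(mols) > 0)
  for (mol in mols) {
    g <- igraph::graph_from_data_frame(
      if (nrow(mol$bonds)) mol$bonds[, c("a", "b")] else data.frame(a = integer(), b = integer()),
      directed = FALSE, vertices = data.frame(name = seq_len(nrow(mol$atoms))))
    if (igraph::components(g)$no > 1L)
      stop_chess("representability",
                 "multi-component structure (salt/mixture) cannot be assigned a single canonical numbering")
  }
  blocks <- vapply(mols, as_molblock, "")
  res <- ob_inchi(blocks)
  keys <- ob_inchikey(res$inchi)
  out <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    nstr <- regmatches(res$aux[i], regexpr("/N:[0-9,;]+", res$aux[i]))
    if (grepl(";", nstr) || grepl("\\.", strsplit(res$inchi[i], "/")[[1]][2]))
      stop_chess("representability", "multi-component InChI")
    if (!length(nstr)) stop_chess("representability",
                                  paste0("no canonical numbering layer for: ", res$inchi[i]))
    norder <- as.integer(strsplit(sub("^/N:", "", nstr), "[,;]")[[1]])
    hv <- heavy_indices(mol)
    if (length(norder) != length(hv))
      stop_chess("representability", "canonical numbering does not cover all heavy atoms")
    heavy_map <- integer(0)
    heavy_map[norder] <- seq_along(norder)      # original index -> canonical
    heavy_map <- stats::setNames(heavy_map[hv], hv)
    heavy_map <- refine_equivalent_indices(mol, heavy_map, res$aux[i])
    hydrogen_map <- integer(0)
    hs <- setdiff(seq_len(nrow(mol$atoms)), hv)
    if (length(hs)) {
      attached <- vapply(hs, function(h) {
        nb <- c(mol$bonds$b[mol$bonds$a == h], mol$bonds$a[mol$bonds$b == h])
        nbh <- nb[mol$atoms$element[nb] != "H"]
        if (length(nbh)) unname(heavy_map[as.character(nbh[1])]) else .Machine$integer.max
      }, integer(1))
      ord <- order(attached, hs)
      hydrogen_map <- stats::setNames(length(hv) + seq_along(hs), hs[ord])
    }
    out[[i]] <- structure(
      list(heavy_map = heavy_map, hydrogen_map = hydrogen_map,
           inchi = res$inchi[i], inchikey = keys[i],
           elements = mol$atoms$element,
           version = paste0("standard InChI via ", ob_version())),
      class = "chess_numbering")
    if (!grepl(inchikey_pattern, keys[i]))
      stop_chess("representability", paste0("malformed InChIKey: ", keys[i]))
  }
  out
}

#' @export
print.chess_numbering <- function(x, ...) {
  cat("<chess_numbering> ", x$inchikey, "\n  ", x$inchi, "\n  heavy atoms: ",
      length(x$heavy_map), ", explicit hydrogens: ", length(x$hydrogen_map),
      "\n", sep = "")
  invisible(x)
}

# InChI assigns interchangeable canonical indices to atoms it considers
# equivalent (AuxInfo /E: layer) — e.g. the two carboxylic-acid oxygens,
# whose bond orders nevertheless differ (C=O vs C-O). Which input atom gets
# which index then depends on input order, which would leak into
# bond-order-bearing identifiers (fragment class keys). The assignment
# within each equivalence class is therefore refined deterministically by a
# bond-order-aware invariant: atoms are keyed by the sorted multiset of
# (bond order, neighbour canonical index) and the class's indices are
# re-dealt in key order, iterating to a fixed point. Atoms whose keys still
# tie are automorphic including bond orders, where any assignment yields
# identical identifier sets.
refine_equivalent_indices <- function(mol, heavy_map, aux) {
  estr <- regmatches(aux, regexpr("/E:[0-9,()]+", aux))
  if (!length(estr)) return(heavy_map)
  groups <- lapply(regmatches(estr, gregexpr("\\([0-9,]+\\)", estr))[[1]],
                   function(s) as.integer(strsplit(gsub("[()]", "", s), ",")[[1]]))
  b <- mol$bonds
  el <- mol$atoms$element
  hb <- b[el[b$a] != "H" & el[b$b] != "H", , drop = FALSE]
  nbrs <- function(a) {
    rbind(data.frame(n = hb$b[hb$a == a], o = hb$order[hb$a == a]),
          data.frame(n = hb$a[hb$b == a], o = hb$order[hb$b == a]))
  }
  for (pass in seq_len(10L)) {
    changed <- FALSE
    for (grp in groups) {
      atoms_in <- as.integer(names(heavy_map))[heavy_map %in% grp]
      if (length(atoms_in) < 2L) next
      key <- vapply(atoms_in, function(a) {
        nb <- nbrs(a)
        paste(sort(paste0(nb$o, ":", heavy_map[as.character(nb$n)])),
              collapse = "|")
      }, "")
      ord <- order(key, heavy_map[as.character(atoms_in)])
      prev <- unname(heavy_map[as.character(atoms_in[ord])])
      target <- sort(grp)
      if (!identical(prev, target)) {
        heavy_map[as.character(atoms_in[ord])] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  heavy_map
}

# canonical index of any atom (heavy or explicit hydrogen), by input index
canonical_index <- function(numbering, atom) {
  key <- as.character(atom)
  idx <- numbering$heavy_map[key]
  if (is.na(idx)) idx <- numbering$hydrogen_map[key]
  if (is.na(idx)) stop_chess("numbering", paste0("atom ", atom, " has no canonical index"))
  unname(idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
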