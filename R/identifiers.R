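#' @title Canonical entity identifiers
#' @description Every entity kind gets a deterministic, database-independent
#'   URI. Molecules use their InChIKey as local name; atoms, bonds and
#'   fragments append suffixes built from canonical indices; descriptors,
#'   configurations and reactions use 40-character lowercase SHA-1 digests of
#'   their semantic content. Hash inputs are joined with an ASCII unit
#'   separator so adjacent parts can never be confused, and absent optional
#'   parts serialize as the empty string.
#' @name identifiers
NULL

#' SHA-1 digest of an ordered part list
#'
#' @param parts Character vector; joined with the ASCII unit separator
#'   (`\\x1f`) before digesting. Numeric values should be passed in their
#'   source lexical form (no re-formatting).
#' @return 40 lowercase hexadecimal characters.
#' @export
chess_hash <- function(parts) {
  digest::digest(paste(as.character(parts), collapse = "\x1f"),
                 algo = "sha1", serialize = FALSE)
}

#' Entity URI
#'
#' @param local Local name.
#' @param base Base IRI prefix (default [chess_base()]).
#' @return Object of class `chess_uri`.
#' @export
chess_uri <- function(local, base = chess_base()) {
  stopifnot(is.character(local), length(local) == 1L, nzchar(local))
  structure(list(base = base, local = local), class = "chess_uri")
}

#' @export
format.chess_uri <- function(x, ...) paste0(x$base, x$local)

#' @export
print.chess_uri <- function(x, ...) { cat("<", format(x), ">\n", sep = ""); invisible(x) }

#' @export
as.character.chess_uri <- function(x, ...) format(x)

uri_str <- function(x) if (inherits(x, "chess_uri")) format(x) else as.character(x)
uri_local <- function(x, base = chess_base()) {
  if (inherits(x, "chess_uri")) return(x$local)
  sub(base, "", as.character(x), fixed = TRUE)
}

#' Molecule URI
#'
#' The local name is the molecule's InChIKey, so independently encoded graphs
#' for the same compound collapse onto a single node when merged.
#' @param numbering A [canonical_numbering()] result.
#' @param base Base IRI.
#' @return A [chess_uri].
#' @export
molecule_uri <- function(numbering, base = chess_base()) {
  stopifnot(inherits(numbering, "chess_numbering"))
  chess_uri(numbering$inchikey, base)
}

#' Atom URI
#'
#' Local name `INCHIKEY-A<symbol><canonical index>` (e.g. ethanol's oxygen is
#' `...-AO3`). Explicit hydrogens use their derived indices.
#' @inheritParams molecule_uri
#' @param atom Input atom index.
#' @export
atom_uri <- function(numbering, atom, base = chess_base()) {
  idx <- canonical_index(numbering, atom)
  chess_uri(paste0(numbering$inchikey, "-A", numbering$elements[atom], idx), base)
}

#' Bond URI
#'
#' Endpoints are ordered by ascending canonical index; local name
#' `INCHIKEY-B<sym1><sym2><idx1><idx2>` (ethanol's C-O bond: `...-BCO23`).
#' @inheritParams atom_uri
#' @param a,b Input indices of the bonded atoms.
#' @export
bond_uri <- function(numbering, a, b, base = chess_base()) {
  ia <- canonical_index(numbering, a); ib <- canonical_index(numbering, b)
  if (ia > ib) { tmp <- a; a <- b; b <- tmp; tmp <- ia; ia <- ib; ib <- tmp }
  chess_uri(paste0(numbering$inchikey, "-B",
                   numbering$elements[a], numbering$elements[b], ia, ib), base)
}

#' Fragment URI
#'
#' Local name `INCHIKEY-FG<sha1>` where the digest covers the fragment's class
#' key (canonical SMILES of the hydrogen-suppressed induced subgraph), the
#' ascending canonical indices of its member heavy atoms, and the molecule of
#' origin.
#' @inheritParams molecule_uri
#' @param fragment A `chess_fragment` (see [atom_centered_fragments()]), or a
#'   list with fields `class_key` and `members` (canonical indices).
#' @export
fragment_uri <- function(numbering, fragment, base = chess_base()) {
  members <- sort(as.integer(fragment$members))
  h <- chess_hash(c(fragment$class_key, paste(members, collapse = ","),
                    numbering$inchikey))
  chess_uri(paste0(numbering$inchikey, "-FG", h), base)
}

#' Chemical-configuration URI
#'
#' Local name `CC<sha1>`: annotations are serialized as `key=value` pairs,
#' sorted lexicographically, then hashed — so the identifier does not depend on
#' insertion order.
#' @param config A [chemical_configuration()].
#' @param base Base IRI.
#' @export
configuration_uri <- function(config, base = chess_base()) {
  stopifnot(inherits(config, "chess_configuration"))
  ann <- config$annotations
  if (!length(ann)) stop_chess("degenerate_configuration",
                               "configuration has no annotations")
  pairs <- sort(paste0(names(ann), "=", unlist(ann)))
  chess_uri(paste0("CC", chess_hash(pairs)), base)
}

#' Descriptor URI
#'
#' Invariant descriptors hash `(value, uncertainty, unit)`; variable
#' descriptors additionally include their configuration's local name;
#' composite descriptors hash the lexicographically sorted local names of
#' their constituent descriptors. When provenance is attached, its algorithm
#' term, software identity and sorted parameters also enter the digest, so
#' e.g. two BDE values computed by different methods mint distinct
#' descriptors. The digest is appended to the owning entity's local name:
#' `OWNERLOCAL-D<sha1>`.
#' @param descriptor A [descriptor()].
#' @param owner A [chess_uri] of the entity the descriptor refers to.
#' @param base Base IRI.
#' @export
descriptor_uri <- function(descriptor, owner, base = chess_base()) {
  stopifnot(inherits(descriptor, "chess_descriptor"))
  local <- paste0(uri_local(owner, base), "-D", descriptor_hash(descriptor, owner, base))
  chess_uri(local, base)
}

descriptor_hash <- function(d, owner, base = chess_base()) {
  parts <- if (d$kind == "composite") {
    locals <- vapply(d$components, function(cmp)
      descriptor_uri(cmp, owner, base)$local, "")
    sort(locals)
  } else {
    p <- c(d$value, d$uncertainty %||% "", unit_token(d$unit))
    if (d$kind == "variable")
      p <- c(p, configuration_uri(d$configuration, base)$local)
    p
  }
  if (!is.null(d$provenance)) parts <- c(parts, provenance_parts(d$provenance))
  chess_hash(parts)
}

unit_token <- function(unit) {
  if (is.null(unit)) "" else uri_str(unit)
}

provenance_parts <- function(p) {
  alg <- p$algorithm_term
  c(if (is.null(alg)) "" else if (is.list(alg)) uri_str(alg$iri %||% "") else uri_str(alg),
    if (!is.null(p$software)) paste(p$software, collapse = "/") else "",
    if (length(p$parameters))
      sort(vapply(p$parameters, function(pp)
        paste(uri_str(pp$term %||% ""), pp$value %||% "",
              unit_token(pp$unit), sep = "="), ""))
    else character())
}

#' Reaction URI
#'
#' Local name `RX<sha1>`: the digest covers role-tagged participant
#' identifiers with their stoichiometric coefficients, participants sorted
#' lexicographically within each role — so listing order is irrelevant but
#' stoichiometry is not.
#' @param reaction A [reaction_spec()].
#' @param base Base IRI.
#' @export
reaction_uri <- function(reaction, base = chess_base()) {
  stopifnot(inherits(reaction, "chess_reaction"))
  tag <- function(role) {
    df <- reaction[[role]]
    if (!nrow(df)) return(character())
    c(role, sort(paste0(df$coefficient, "*", df$ref)))
  }
  chess_uri(paste0("RX", chess_hash(c(tag("inputs"), tag("products"), tag("agents")))),
            base)
}
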