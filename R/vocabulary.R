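#' @title Ontology vocabulary
#' @description Every ontology identifier used by the package resolves through a
#'   single editable table mapping concept names to IRIs. The defaults bind the
#'   CHEBI / SIO / CHEMINF / UO terms the encoding scheme relies on; relations
#'   for which no community identifier exists are bound to provisional locals in
#'   the CHESS namespace and can be rebound by supplying a replacement table.
#' @name vocabulary
NULL

.chess_env <- new.env(parent = emptyenv())

#' Load or replace the vocabulary table
#'
#' @param path Path to a tab-separated table with columns `concept`, `iri`,
#'   `label`. `NULL` (default) loads the table shipped with the package.
#' @return Invisibly, the vocabulary as a data.frame.
#' @export
chess_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.chess_env$vocab)) return(invisible(.chess_env$vocab))
    path <- system.file("extdata", "chess_vocabulary.tsv", package = "chessr")
  }
  v <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("concept", "iri", "label") %in% names(v)))
  if (anyDuplicated(v$concept))
    stop("duplicate concepts in vocabulary table: ",
         paste(unique(v$concept[duplicated(v$concept)]), collapse = ", "))
  .chess_env$vocab <- v
  invisible(v)
}

#' Resolve a vocabulary concept to its IRI
#'
#' @param concept Concept name, e.g. `"has_proper_part"` or `"atom_O"`.
#' @return The bound IRI as a character scalar.
#' @examples
#' chess_term("has_proper_part")
#' @export
chess_term <- function(concept) {
  v <- chess_vocabulary()
  i <- match(concept, v$concept)
  if (anyNA(i)) stop("unknown vocabulary concept: ",
                     paste(concept[is.na(i)], collapse = ", "))
  v$iri[i]
}

#' Human-readable label of a vocabulary concept
#' @inheritParams chess_term
#' @return Label string.
#' @export
chess_label <- function(concept) {
  v <- chess_vocabulary()
  i <- match(concept, v$concept)
  if (anyNA(i)) stop("unknown vocabulary concept: ",
                     paste(concept[is.na(i)], collapse = ", "))
  v$label[i]
}

# Element -> atom-class IRI; elements without a curated CHEBI binding get a
# deterministic CHESS-namespace class so typing never fails.
element_term <- function(symbol) {
  v <- chess_vocabulary()
  key <- paste0("atom_", symbol)
  i <- match(key, v$concept)
  out <- v$iri[i]
  missing <- is.na(i)
  out[missing] <- paste0(chess_base(), "Atom", symbol[missing])
  out
}

#' Base IRI for minted entities
#'
#' The default is the semanticscience CHESS prefix; override globally with
#' `options(chessr.base_uri = ...)`.
#' @return Base IRI string.
#' @export
chess_base <- function() {
  getOption("chessr.base_uri", "http://semanticscience.org/resource/CHESS_")
}

#' Default namespace prefix map
#' @return Named character vector, prefix -> namespace IRI.
#' @export
chess_namespaces <- function() {
  c(rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    sio     = "http://semanticscience.org/resource/SIO_",
    chess   = chess_base(),
    chebi   = "http://purl.org/obo/owl/CHEBI#",
    cheminf = "http://semanticscience.org/resource/CHEMINF_",
    uo      = "http://purl.org/obo/owl/UO#")
}
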