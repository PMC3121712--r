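#' @title Descriptors, configurations and provenance
#' @description Descriptors follow the CHEMINF pattern: an information entity
#'   with a mandatory value (or constituent descriptors, for composites),
#'   optional uncertainty and unit, optional computational or experimental
#'   provenance, and — for variable descriptors — a chemical configuration
#'   bundling the conditions (provider, temperature, geometry, electronic
#'   state, ...) under which the value holds. Values are stored and hashed in
#'   their source lexical form: `"104.5"` stays `"104.5"`.
#' @name annotations
NULL

#' Chemical configuration
#'
#' @param ... Named annotation values (e.g. `provider = "http://..."`,
#'   `temperature = "298"`). Order is irrelevant: the identifier sorts the
#'   `key=value` pairs before hashing.
#' @return Object of class `chess_configuration`.
#' @export
chemical_configuration <- function(...) {
  ann <- list(...)
  if (length(ann) == 1L && is.list(ann[[1]]) && !is.null(names(ann[[1]])))
    ann <- ann[[1]]
  if (!length(ann) || is.null(names(ann)) || any(!nzchar(names(ann))))
    stop_chess("degenerate_configuration",
               "a chemical configuration needs at least one named annotation")
  ann <- lapply(ann, as.character)
  structure(list(annotations = ann[order(names(ann))]),
            class = "chess_configuration")
}

#' @export
print.chess_configuration <- function(x, ...) {
  cat("<chess_configuration>\n")
  for (k in names(x$annotations)) cat("  ", k, " = ", x$annotations[[k]], "\n", sep = "")
  invisible(x)
}

#' Computational / experimental provenance
#'
#' @param algorithm_term Vocabulary concept name or IRI of the method class
#'   (e.g. the AM1 semi-empirical method for BDE values).
#' @param software Character vector `c(name, version)`.
#' @param parameters List of parameter records, each a list with `term`
#'   (optional), `value`, `unit` (optional).
#' @return Object of class `chess_provenance`.
#' @export
provenance <- function(algorithm_term = NULL, software = NULL, parameters = list()) {
  if (length(parameters) && is.null(software))
    stop_chess("provenance", "parameterized execution requires a software identity")
  if (!is.null(software)) stopifnot(length(software) >= 1L)
  structure(list(algorithm_term = algorithm_term, software = software,
                 parameters = parameters),
            class = "chess_provenance")
}

#' Construct a descriptor
#'
#' @param kind `"invariant"` (depends only on constitution), `"variable"`
#'   (condition-dependent; requires a configuration) or `"composite"`
#'   (contains other descriptors instead of a direct value).
#' @param type_term Vocabulary concept name (resolved through
#'   [chess_term()]) or an IRI string typing the descriptor.
#' @param value Scalar value in source lexical form (character recommended).
#' @param uncertainty Optional scalar.
#' @param unit Optional unit: IRI, [chess_uri], or literal like `"kcal/mol"`.
#' @param components For composites, a list of descriptors.
#' @param configuration A [chemical_configuration()] (required for variable
#'   descriptors, forbidden for invariant ones).
#' @param provenance A [provenance()].
#' @return Object of class `chess_descriptor`.
#' @export
descriptor <- function(kind = c("invariant", "variable", "composite"),
                       type_term, value = NULL, uncertainty = NULL, unit = NULL,
                       components = NULL, configuration = NULL,
                       provenance = NULL) {
  kind <- match.arg(kind)
  iri <- if (grepl("^https?://", type_term)) type_term else chess_term(type_term)
  if (kind == "composite") {
    if (!is.null(value) || !length(components))
      stop("composite descriptors carry components, not a direct value")
  } else {
    if (is.null(value) || length(components))
      stop("non-composite descriptors must have a value and no components")
    value <- as.character(value)
  }
  if (kind == "variable" && is.null(configuration))
    stop_chess("missing_configuration",
               "variable descriptors must reference a chemical configuration")
  if (kind == "invariant" && !is.null(configuration))
    stop("invariant descriptors must not reference a configuration")
  if (!is.null(uncertainty)) uncertainty <- as.character(uncertainty)
  structure(list(kind = kind, type_term = iri, value = value,
                 uncertainty = uncertainty, unit = unit,
                 components = components, configuration = configuration,
                 provenance = provenance),
            class = "chess_descriptor")
}

#' @export
print.chess_descriptor <- function(x, ...) {
  cat("<chess_descriptor> ", x$kind, " <", x$type_term, ">",
      if (!is.null(x$value)) paste0(" = ", x$value),
      if (!is.null(x$unit)) paste0(" [", unit_token(x$unit), "]"),
      if (!is.null(x$components)) paste0(" (", length(x$components), " components)"),
      "\n", sep = "")
  invisible(x)
}

#' Three-dimensional coordinate descriptor
#'
#' A composite descriptor with x/y/z Cartesian components, each carrying the
#' value and unit, linked to the chemical configuration (conformer + source)
#' under which the coordinates hold. Component order at construction does not
#' affect the identifier (components are sorted lexicographically for
#' hashing).
#' @param x,y,z Finite scalars (pass characters for exact lexical control).
#' @param unit Unit reference; default the angstrom unit term.
#' @param config A [chemical_configuration()].
#' @return A composite `chess_descriptor`.
#' @export
make_coordinate_descriptor <- function(x, y, z,
                                       unit = chess_term("unit_angstrom"),
                                       config) {
  vals <- c(x = x, y = y, z = z)
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num) || any(!is.finite(num)))
    stop("coordinate components must be finite numbers")
  comp <- function(axis, v)
    descriptor("variable", chess_term(paste0("coordinate_", axis)),
               value = as.character(v), unit = unit, configuration = config)
  descriptor("composite", chess_term("coordinate_3d"),
             components = list(comp("x", vals[["x"]]), comp("y", vals[["y"]]),
                               comp("z", vals[["z"]])),
             configuration = config)
}

#' Bond dissociation enthalpy annotation
#'
#' Builds a BDE descriptor for a bond entity, with full computational
#' provenance: the method class (e.g. AM1), the parameterized software
#' execution, the software name/version, and the calculation parameters
#' (e.g. temperature 298 K).
#' @param bond A [chess_uri] of the bond entity (see [bond_uri()]).
#' @param value BDE value in source lexical form, e.g. `"104.5"`.
#' @param unit Unit literal or IRI, default `"kcal/mol"`.
#' @param method_term Vocabulary concept or IRI of the method; a plain name
#'   like `"AM1"` mints a CHESS-namespace method individual.
#' @param software `c(name, version)`.
#' @param parameters List of parameter records (`term`, `value`, `unit`).
#' @return A `chess_descriptor` of the BDE type carrying the provenance; the
#'   bond it annotates is attached as attribute `"owner"`.
#' @export
make_bde_annotation <- function(bond, value, unit = "kcal/mol",
                                method_term = "AM1",
                                software = c("MOPAC", "7.1.11"),
                                parameters = list(list(term = chess_term("temperature"),
                                                       value = "298",
                                                       unit = chess_term("unit_kelvin")))) {
  prov <- provenance(algorithm_term = method_term, software = software,
                     parameters = parameters)
  d <- descriptor("invariant", "bde_descriptor", value = value, unit = unit,
                  provenance = prov)
  attr(d, "owner") <- bond
  d
}
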