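#' @title Reaction specifications
#' @description Reactions are abstract processes identified solely by their
#'   participants and stoichiometry — no kinetics or likelihood is modelled.
#'   Participants fill input / product / agent roles at either the class
#'   level (functional-group and atom types, for generic transformations like
#'   primary alcohol to aldehyde) or the instance level (concrete molecules).
#'   Transforms-into mappings pair each reacting group or atom with its
#'   product counterpart, enabling atom-history tracing.
#' @name reactions
NULL

normalize_participants <- function(x, base = chess_base()) {
  if (is.null(x)) return(data.frame(ref = character(), coefficient = integer(),
                                    level = character(), stringsAsFactors = FALSE))
  if (is.character(x))
    x <- data.frame(ref = x, stringsAsFactors = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot("ref" %in% names(x))
  x$ref <- vapply(x$ref, uri_local, "", base = base)
  if (is.null(x$coefficient)) x$coefficient <- rep(1L, nrow(x))
  x$coefficient <- as.integer(x$coefficient)
  if (any(is.na(x$coefficient) | x$coefficient < 1L))
    stop_chess("malformed_reaction", "stoichiometric coefficients must be positive integers")
  if (is.null(x$level))
    x$level <- ifelse(grepl("^FG", x$ref), "class", "instance")
  stopifnot(all(x$level %in% c("class", "instance")))
  x[, c("ref", "coefficient", "level")]
}

#' Construct a reaction specification
#'
#' @param inputs,products,agents Participants: character vector of local
#'   names / URIs, or data.frame with columns `ref`, `coefficient`, `level`.
#'   Inputs and products must be non-empty.
#' @param mappings Optional data.frame with columns `source`, `target`:
#'   transforms-into pairs between participants or their declared parts.
#' @param parts Optional data.frame with columns `parent`, `child`,
#'   `element`: part declarations (e.g. class-level atoms of a group).
#' @param base Base IRI.
#' @return Object of class `chess_reaction`.
#' @export
reaction_spec <- function(inputs, products, agents = NULL, mappings = NULL,
                          parts = NULL, base = chess_base()) {
  inputs <- normalize_participants(inputs, base)
  products <- normalize_participants(products, base)
  agents <- normalize_participants(agents, base)
  if (!nrow(inputs) || !nrow(products))
    stop_chess("malformed_reaction", "a reaction needs at least one input and one product")
  if (is.null(parts))
    parts <- data.frame(parent = character(), child = character(),
                        element = character(), stringsAsFactors = FALSE)
  parts <- as.data.frame(parts, stringsAsFactors = FALSE)
  if (nrow(parts) && is.null(parts$element)) parts$element <- ""
  if (is.null(mappings))
    mappings <- data.frame(source = character(), target = character(),
                           stringsAsFactors = FALSE)
  mappings <- as.data.frame(mappings, stringsAsFactors = FALSE)
  declared <- c(inputs$ref, products$ref, agents$ref, parts$child)
  if (nrow(mappings)) {
    mappings$source <- vapply(mappings$source, uri_local, "", base = base)
    mappings$target <- vapply(mappings$target, uri_local, "", base = base)
    dangling <- setdiff(c(mappings$source, mappings$target), declared)
    if (length(dangling))
      stop_chess("mapping", paste0("transforms-into endpoints are not participants ",
                                   "or their parts: ", paste(dangling, collapse = ", ")))
    cross <- mappings$source %in% inputs$ref[inputs$level == "instance"] &
      mappings$target %in% products$ref[products$level == "class"]
    if (any(cross))
      warning("cross-level mapping (instance -> class) flagged for review")
  }
  structure(list(inputs = inputs, products = products, agents = agents,
                 mappings = mappings, parts = parts),
            class = "chess_reaction")
}

#' @export
print.chess_reaction <- function(x, ...) {
  fmt <- function(df) paste(sprintf("%d*%s", df$coefficient, df$ref), collapse = " + ")
  cat("<chess_reaction> ", fmt(x$inputs), " -> ", fmt(x$products),
      if (nrow(x$agents)) paste0("  [agent: ", fmt(x$agents), "]"),
      "\n  mappings: ", nrow(x$mappings), ", uri ",
      format(reaction_uri(x)), "\n", sep = "")
  invisible(x)
}

#' Build a generic (class-level) reaction
#'
#' Participants are functional-group classes given as class keys (canonical
#' SMILES like `"CCO"` and `"CC=O"`) or [fragment_class()] objects. Input
#' group i is mapped to product group i with transforms-into; atom-level
#' maps pair class atoms by canonical index within their class graphs.
#'
#' @param input_groups,product_groups Class keys or `chess_fragment_class`
#'   objects; non-empty lists.
#' @param agents Optional agent references (e.g. a catalyst's InChIKey).
#' @param atom_maps Optional data.frame with columns `from_group`,
#'   `from_atom`, `to_group`, `to_atom`: group positions (integers into the
#'   input/product lists) and canonical atom indices within each class graph.
#' @param coefficients Optional list with `inputs` / `products` integer
#'   vectors (default all 1).
#' @param base Base IRI.
#' @return A [reaction_spec()].
#' @export
build_generic_reaction <- function(input_groups, product_groups, agents = NULL,
                                   atom_maps = NULL, coefficients = NULL,
                                   base = chess_base()) {
  as_class <- function(x) {
    if (inherits(x, "chess_fragment_class")) return(x)
    structure(list(class_key = x, class_uri = fragment_class_uri(x, base)),
              class = "chess_fragment_class")
  }
  ins <- lapply(input_groups, as_class)
  outs <- lapply(product_groups, as_class)
  if (!length(ins) || !length(outs))
    stop_chess("malformed_reaction", "input and product group lists must be non-empty")
  ref_of <- function(cls) uri_local(cls$class_uri, base)
  inputs <- data.frame(ref = vapply(ins, ref_of, ""),
                       coefficient = coefficients$inputs %||% 1L, level = "class",
                       stringsAsFactors = FALSE)
  products <- data.frame(ref = vapply(outs, ref_of, ""),
                         coefficient = coefficients$products %||% 1L, level = "class",
                         stringsAsFactors = FALSE)
  mappings <- data.frame(source = character(), target = character(),
                         stringsAsFactors = FALSE)
  if (length(ins) == length(outs))
    mappings <- data.frame(source = inputs$ref, target = products$ref,
                           stringsAsFactors = FALSE)
  parts <- data.frame(parent = character(), child = character(),
                      element = character(), stringsAsFactors = FALSE)
  if (!is.null(atom_maps) && nrow(atom_maps)) {
    atom_ref <- function(groups, gi, canon_idx) {
      if (gi < 1L || gi > length(groups))
        stop_chess("mapping", "atom map references a group that does not exist")
      cls <- groups[[gi]]
      cg <- class_graph(cls$class_key)
      input_idx <- as.integer(names(cg$numbering$heavy_map))[
        match(canon_idx, cg$numbering$heavy_map)]
      if (is.na(input_idx))
        stop_chess("mapping", paste0("atom index ", canon_idx,
                                     " is not in class graph ", cls$class_key))
      list(ref = paste0(uri_local(cls$class_uri, base), "A", canon_idx,
                        cg$mol$atoms$element[input_idx]),
           parent = uri_local(cls$class_uri, base),
           element = cg$mol$atoms$element[input_idx])
    }
    for (k in seq_len(nrow(atom_maps))) {
      fr <- atom_ref(ins, atom_maps$from_group[k], atom_maps$from_atom[k])
      to <- atom_ref(outs, atom_maps$to_group[k], atom_maps$to_atom[k])
      parts <- rbind(parts,
                     data.frame(parent = c(fr$parent, to$parent),
                                child = c(fr$ref, to$ref),
                                element = c(fr$element, to$element),
                                stringsAsFactors = FALSE))
      mappings <- rbind(mappings, data.frame(source = fr$ref, target = to$ref,
                                             stringsAsFactors = FALSE))
      # mapped class atoms participate in their own right (has input /
      # has product on the atom types, alongside the groups)
      inputs <- rbind(inputs, data.frame(ref = fr$ref, coefficient = 1L,
                                         level = "class", stringsAsFactors = FALSE))
      products <- rbind(products, data.frame(ref = to$ref, coefficient = 1L,
                                             level = "class", stringsAsFactors = FALSE))
    }
    parts <- unique(parts)
    inputs <- unique(inputs); products <- unique(products)
  }
  rxn <- reaction_spec(inputs, products, agents, mappings, parts, base)
  keys <- c(stats::setNames(vapply(ins, function(x) x$class_key, ""),
                            vapply(ins, ref_of, "")),
            stats::setNames(vapply(outs, function(x) x$class_key, ""),
                            vapply(outs, ref_of, "")))
  attr(rxn, "class_keys") <- as.list(keys[!duplicated(names(keys))])
  rxn
}

#' Trace an atom through reactive transformations
#'
#' Follows transforms-into edges reachable from the class-level bindings of
#' an atom instance, recording each step with the reaction that carries it.
#' @param kb A `chess_graph` with encoded molecules (class-atom typing on)
#'   and reactions.
#' @param atom Atom URI ([chess_uri] or string).
#' @param base Base IRI.
#' @return data.frame with columns `step`, `reaction`, `from`, `to` (empty
#'   when the atom has no reaction bindings).
#' @export
trace_atom <- function(kb, atom, base = chess_base()) {
  a <- uri_str(atom)
  rdf_type <- chess_term("rdf_type")
  ti <- chess_term("transforms_into")
  tmap <- tg_match(kb, p = ti)
  out <- data.frame(step = integer(), reaction = character(),
                    from = character(), to = character(), stringsAsFactors = FALSE)
  frontier <- tg_match(kb, s = a, p = rdf_type)$o
  frontier <- frontier[startsWith(frontier, base)]
  seen <- character(); step <- 0L
  while (length(frontier)) {
    step <- step + 1L
    hits <- tmap[tmap$s %in% frontier, , drop = FALSE]
    hits <- hits[!paste(hits$s, hits$o) %in% seen, , drop = FALSE]
    if (!nrow(hits)) break
    seen <- c(seen, paste(hits$s, hits$o))
    for (k in seq_len(nrow(hits))) {
      rxn <- reaction_for_edge(kb, hits$s[k], hits$o[k])
      out <- rbind(out, data.frame(step = step, reaction = rxn,
                                   from = hits$s[k], to = hits$o[k],
                                   stringsAsFactors = FALSE))
    }
    frontier <- unique(hits$o)
  }
  out
}

# reaction node whose inputs cover `from` (directly or as part) and whose
# products cover `to`
reaction_for_edge <- function(kb, from, to) {
  hpp <- chess_term("has_proper_part")
  covers <- function(role, x) {
    df <- tg_match(kb, p = chess_term(role))
    direct <- df$s[df$o == x]
    via_part <- df$s[df$o %in% tg_match(kb, p = hpp, o = x)$s]
    unique(c(direct, via_part))
  }
  r <- intersect(covers("has_input", from), covers("has_product", to))
  if (length(r)) sort(r)[1] else NA_character_
}

#' Check conservation of matter over a generic reaction's atom maps
#'
#' Generic class-level reactions cannot always be balanced; imbalance is
#' reported as a warning, never an error.
#' @param rxn A [reaction_spec()] built from class keys.
#' @return Logical (balanced or not), invisibly.
#' @export
check_mass_balance <- function(rxn) {
  count_side <- function(df) {
    tab <- integer()
    for (k in seq_len(nrow(df))) {
      if (df$level[k] != "class") next
      cg <- tryCatch(class_graph_by_ref(rxn, df$ref[k]), error = function(e) NULL)
      if (is.null(cg)) next
      els <- table(cg$mol$atoms$element[heavy_indices(cg$mol)]) * df$coefficient[k]
      for (e in names(els)) tab[e] <- (tab[e] %||% 0L) + els[[e]]
    }
    tab[sort(names(tab))]
  }
  bal <- identical(count_side(rxn$inputs), count_side(rxn$products))
  if (!bal) warning("reaction is not balanced at the heavy-atom level ",
                    "(expected for generic functional-group transformations)")
  invisible(bal)
}

# resolve a class participant ref back to its class graph via the stored key
class_graph_by_ref <- function(rxn, ref) {
  key <- attr(rxn, "class_keys")[[ref]]
  if (is.null(key)) stop("no class key recorded for ", ref)
  class_graph(key)
}
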