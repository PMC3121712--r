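#' @title Triple graphs and RDF serialization
#' @description The emitted knowledge graph is a set of
#'   subject-predicate-object triples with a prefix map, held in-process.
#'   Serialization is deterministic (sorted statements) so output files are
#'   diffable; Turtle and N-Triples dialects are supported. Identical URIs
#'   from different sources merge on load, which is what makes independently
#'   encoded graphs for one compound collapse into a single node.
#' @name rdfio
NULL

#' Create an empty triple graph
#' @param namespaces Named character vector, prefix -> namespace IRI.
#' @return Object of class `chess_graph`.
#' @export
triple_graph <- function(namespaces = chess_namespaces()) {
  structure(list(
    triples = data.frame(s = character(), p = character(), o = character(),
                         lit = logical(), stringsAsFactors = FALSE),
    namespaces = namespaces), class = "chess_graph")
}

#' @export
print.chess_graph <- function(x, ...) {
  cat("<chess_graph> ", nrow(x$triples), " triples, ",
      length(x$namespaces), " namespaces\n", sep = "")
  invisible(x)
}

tg_add <- function(g, s, p, o, lit = FALSE) {
  if (!length(s)) return(g)
  add <- data.frame(s = as.character(s), p = as.character(p),
                    o = as.character(o),
                    lit = rep_len(lit, max(length(s), length(o))),
                    stringsAsFactors = FALSE)
  g$triples <- rbind(g$triples, add)
  g
}

tg_finalize <- function(g) {
  key <- paste(g$triples$s, g$triples$p, g$triples$o, g$triples$lit, sep = "\r")
  g$triples <- g$triples[!duplicated(key), , drop = FALSE]
  g$triples <- g$triples[order(g$triples$s, g$triples$p, g$triples$o), , drop = FALSE]
  rownames(g$triples) <- NULL
  g
}

# subset triples; NULL matches anything
tg_match <- function(g, s = NULL, p = NULL, o = NULL) {
  df <- g$triples
  if (!is.null(s)) df <- df[df$s %in% s, , drop = FALSE]
  if (!is.null(p)) df <- df[df$p %in% p, , drop = FALSE]
  if (!is.null(o)) df <- df[df$o %in% o, , drop = FALSE]
  df
}

#' Union of triple graphs
#'
#' Set semantics: loading or merging the same statements twice leaves the
#' graph unchanged, and shared entity URIs collapse.
#' @param ... `chess_graph` objects.
#' @return A `chess_graph`.
#' @export
graph_union <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "chess_graph"))
    gs <- gs[[1]]
  out <- triple_graph(do.call(c, c(lapply(gs, function(g) g$namespaces), list(character()))))
  out$namespaces <- out$namespaces[!duplicated(names(out$namespaces))]
  out$triples <- do.call(rbind, lapply(gs, function(g) g$triples))
  tg_finalize(out)
}

#' Encoding options
#'
#' @param emit_bond_entities Emit bond individuals (descriptors attach to
#'   them). At least one of the two bond flags must be set.
#' @param emit_direct_bond_predicates Also link bonded atoms directly with
#'   bidirectional order-specific predicates (the representation that makes
#'   pattern queries fast).
#' @param depths Fragment depths to emit.
#' @param include_hydrogens Materialize and encode explicit hydrogens (needed
#'   to annotate O-H bonds); default off, matching heavy-atom fragments.
#' @param type_fragment_classes Type each fragment instance to its structural
#'   class URI (required for similarity ranking and reaction matching).
#' @param type_class_atoms Additionally type member atoms to class-level atom
#'   nodes (required for atom-level reaction matching and atom tracing).
#' @return List of class `chess_encoding_options`.
#' @export
encoding_options <- function(emit_bond_entities = TRUE,
                             emit_direct_bond_predicates = TRUE,
                             depths = 1:3,
                             include_hydrogens = FALSE,
                             type_fragment_classes = TRUE,
                             type_class_atoms = FALSE) {
  if (!emit_bond_entities && !emit_direct_bond_predicates)
    stop("at least one bond representation must be emitted")
  structure(list(emit_bond_entities = emit_bond_entities,
                 emit_direct_bond_predicates = emit_direct_bond_predicates,
                 depths = depths, include_hydrogens = include_hydrogens,
                 type_fragment_classes = type_fragment_classes,
                 type_class_atoms = type_class_atoms),
            class = "chess_encoding_options")
}

direct_bond_predicate <- function(order) {
  chess_term(c(single = "has_single_bond_with", double = "has_double_bond_with",
               triple = "has_triple_bond_with", aromatic = "has_aromatic_bond_with")[order])
}

bond_class_term <- function(order) {
  chess_term(c(single = "bond_single", double = "bond_double",
               triple = "bond_triple", aromatic = "bond_aromatic")[order])
}

#' Encode a molecule as a triple graph
#'
#' Emits: molecule typing (molecular entity and molecule classes), element
#' typing for every atom, bond individuals typed by order, direct
#' bidirectional bond-type predicates, atom-centered fragments with class
#' typing, and `has proper part` parthood from the molecule to atoms, bonds
#' and fragments, from bonds to their two atoms and from fragments to member
#' atoms (with the inverse `is part of` from atoms).
#'
#' @param mol A [chess_mol].
#' @param numbering Its [canonical_numbering()]; recomputed when `NULL` or
#'   when hydrogens are materialized.
#' @param opts [encoding_options()].
#' @param base Base IRI.
#' @return A `chess_graph`.
#' @export
encode_molecule <- function(mol, numbering = NULL, opts = encoding_options(),
                            base = chess_base()) {
  if (opts$include_hydrogens && !any(mol$atoms$element == "H")) {
    mol <- add_hydrogens(mol)
    numbering <- NULL
  }
  if (is.null(numbering)) numbering <- canonical_numbering(mol)
  frags <- atom_centered_fragments(mol, numbering, opts$depths, base)
  encode_molecule_prepared(mol, numbering, frags, opts, base)
}

# Worker shared by encode_molecule and the batched knowledgebase encoder.
encode_molecule_prepared <- function(mol, numbering, frags, opts, base) {
  g <- triple_graph(chess_namespaces())
  rdf_type <- chess_term("rdf_type")
  hpp <- chess_term("has_proper_part")
  ipo <- chess_term("is_part_of")
  m <- format(molecule_uri(numbering, base))
  g <- tg_add(g, m, rdf_type, chess_term("molecular_entity"))
  g <- tg_add(g, m, rdf_type, chess_term("molecule"))
  g <- tg_add(g, m, paste0(base, "inchi"), numbering$inchi, lit = TRUE)
  g <- tg_add(g, m, paste0(base, "inchiVersion"), numbering$version, lit = TRUE)

  hv <- heavy_indices(mol)
  atom_idx <- if (opts$include_hydrogens) seq_len(nrow(mol$atoms)) else hv
  auri <- vapply(atom_idx, function(i) format(atom_uri(numbering, i, base)), "")
  names(auri) <- atom_idx
  g <- tg_add(g, auri, rdf_type, element_term(mol$atoms$element[atom_idx]))
  g <- tg_add(g, auri, rdf_type, chess_term("atom"))
  g <- tg_add(g, rep(m, length(auri)), hpp, auri)
  g <- tg_add(g, auri, ipo, rep(m, length(auri)))

  b <- mol$bonds
  keep <- b$a %in% atom_idx & b$b %in% atom_idx
  b <- b[keep, , drop = FALSE]
  if (nrow(b)) {
    if (opts$emit_bond_entities) {
      buri <- vapply(seq_len(nrow(b)), function(k)
        format(bond_uri(numbering, b$a[k], b$b[k], base)), "")
      g <- tg_add(g, buri, rdf_type, bond_class_term(b$order))
      g <- tg_add(g, buri, rdf_type, chess_term("covalent_bond"))
      g <- tg_add(g, rep(m, length(buri)), hpp, buri)
      g <- tg_add(g, buri, hpp, auri[as.character(b$a)])
      g <- tg_add(g, buri, hpp, auri[as.character(b$b)])
    }
    if (opts$emit_direct_bond_predicates) {
      pred <- direct_bond_predicate(b$order)
      g <- tg_add(g, auri[as.character(b$a)], pred, auri[as.character(b$b)])
      g <- tg_add(g, auri[as.character(b$b)], pred, auri[as.character(b$a)])
    }
  }

  for (f in frags) {
    furi <- format(f$uri)
    g <- tg_add(g, furi, rdf_type, chess_term("organic_group"))
    g <- tg_add(g, m, hpp, furi)
    g <- tg_add(g, furi, ipo, m)
    member_uris <- auri[as.character(f$members_input)]
    g <- tg_add(g, rep(furi, length(member_uris)), hpp, member_uris)
    if (opts$type_fragment_classes) {
      curi <- format(f$class_uri)
      g <- tg_add(g, furi, rdf_type, curi)
      g <- tg_add(g, curi, rdf_type, chess_term("group"))
      g <- tg_add(g, curi, paste0(base, "classKey"), f$class_key, lit = TRUE)
      if (opts$type_class_atoms && is.na(f$depth) == FALSE) {
        camap <- fragment_class_atom_map(mol, f, numbering)
        if (!is.null(camap)) {
          suffixes <- class_atom_suffix(f$class_key)
          cg <- class_graph(f$class_key)
          for (ci in as.integer(names(camap))) {
            can <- unname(cg$numbering$heavy_map[as.character(ci)])
            sfx <- paste0("A", can, cg$mol$atoms$element[ci])
            ca_uri <- paste0(base, uri_local(curi, base), sfx)
            g <- tg_add(g, ca_uri, rdf_type, element_term(cg$mol$atoms$element[ci]))
            g <- tg_add(g, ca_uri, rdf_type, chess_term("atom"))
            g <- tg_add(g, curi, hpp, ca_uri)
            g <- tg_add(g, auri[as.character(camap[[as.character(ci)]])],
                        rdf_type, ca_uri)
          }
        }
      }
    }
  }
  tg_finalize(g)
}

#' Encode a set of molecules as one knowledgebase
#'
#' Batched (single InChI process call for all structures), then merged with
#' set semantics.
#' @param smiles Character vector of SMILES.
#' @param opts [encoding_options()].
#' @param base Base IRI.
#' @param names Optional molecule labels kept in the returned index.
#' @return A `chess_graph`; attribute `"index"` is a data.frame with columns
#'   `name`, `smiles`, `inchikey`, `uri`.
#' @export
encode_knowledgebase <- function(smiles, opts = encoding_options(),
                                 base = chess_base(), names = NULL) {
  mols <- parse_smiles_batch(smiles)
  if (opts$include_hydrogens) mols <- lapply(mols, add_hydrogens)
  nums <- canonical_numberings(mols)
  gs <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    frags <- atom_centered_fragments(mols[[i]], nums[[i]], opts$depths, base)
    gs[[i]] <- encode_molecule_prepared(mols[[i]], nums[[i]], frags, opts, base)
  }
  g <- graph_union(gs)
  attr(g, "index") <- data.frame(
    name = names %||% smiles, smiles = smiles,
    inchikey = vapply(nums, function(n) n$inchikey, ""),
    uri = vapply(nums, function(n) format(molecule_uri(n, base)), ""),
    stringsAsFactors = FALSE)
  g
}

#' Molecules present in a knowledgebase
#' @param kb A `chess_graph`.
#' @return Sorted character vector of molecule URIs.
#' @export
kb_molecules <- function(kb) {
  sort(unique(tg_match(kb, p = chess_term("rdf_type"),
                       o = chess_term("molecular_entity"))$s))
}

# ---- descriptors ------------------------------------------------------------

#' Attach a descriptor subgraph to an entity
#'
#' Emits the full CHEMINF-style pattern: descriptor typing, value /
#' uncertainty / unit, composite components via `has direct part`, the
#' chemical configuration node with its annotations, and computational
#' provenance (method individual, parameterized execution with parameters,
#' software and version). Variable descriptors are additionally marked with a
#' package-level class so that a configuration-less variable descriptor is
#' detectable by [validate_graph()].
#'
#' @param g A `chess_graph`.
#' @param owner [chess_uri] (or IRI string) of the annotated entity.
#' @param desc A [descriptor()].
#' @param base Base IRI.
#' @return The augmented graph; the minted descriptor URI is attached as
#'   attribute `"descriptor_uri"`.
#' @export
attach_descriptor <- function(g, owner, desc, base = chess_base()) {
  owner_uri <- if (inherits(owner, "chess_uri")) owner
               else chess_uri(uri_local(owner, base), base)
  duri <- descriptor_uri(desc, owner_uri, base)
  g <- encode_descriptor_node(g, format(owner_uri), duri, desc, base)
  g <- tg_finalize(g)
  attr(g, "descriptor_uri") <- duri
  g
}

encode_descriptor_node <- function(g, owner_str, duri, desc, base, attach = TRUE) {
  rdf_type <- chess_term("rdf_type")
  d <- format(duri)
  if (attach) g <- tg_add(g, owner_str, chess_term("has_attribute"), d)
  g <- tg_add(g, d, rdf_type, desc$type_term)
  if (desc$kind == "variable")
    g <- tg_add(g, d, rdf_type, paste0(base, "VariableChemicalDescriptor"))
  if (!is.null(desc$value))
    g <- tg_add(g, d, chess_term("has_value"), desc$value, lit = TRUE)
  if (!is.null(desc$uncertainty))
    g <- tg_add(g, d, chess_term("has_uncertainty"), desc$uncertainty, lit = TRUE)
  if (!is.null(desc$unit)) {
    u <- unit_token(desc$unit)
    g <- tg_add(g, d, chess_term("has_unit"), u, lit = !grepl("^https?://", u))
  }
  if (!is.null(desc$components)) {
    owner_uri <- chess_uri(uri_local(owner_str, base), base)
    for (cmp in desc$components) {
      curi <- descriptor_uri(cmp, owner_uri, base)
      # components hang off the composite via has-direct-part, not the owner
      g <- tg_add(g, d, chess_term("has_direct_part"), format(curi))
      g <- encode_descriptor_node(g, owner_str, curi, cmp, base, attach = FALSE)
    }
  }
  if (!is.null(desc$configuration)) {
    cc <- format(configuration_uri(desc$configuration, base))
    g <- tg_add(g, d, chess_term("has_attribute"), cc)
    g <- tg_add(g, cc, rdf_type, chess_term("chemical_configuration"))
    ann <- desc$configuration$annotations
    for (k in names(ann)) {
      pred <- if (k == "provider") chess_term("has_provider")
              else paste0(base, "annotation_", k)
      g <- tg_add(g, cc, pred, ann[[k]], lit = TRUE)
    }
  }
  if (!is.null(desc$provenance))
    g <- encode_provenance(g, d, desc$provenance, base)
  g
}

encode_provenance <- function(g, d, prov, base) {
  rdf_type <- chess_term("rdf_type")
  if (!is.null(prov$algorithm_term)) {
    alg <- prov$algorithm_term
    alg_uri <- if (grepl("^https?://", alg)) alg else paste0(base, alg)
    g <- tg_add(g, d, chess_term("is_specified_output_of"), alg_uri)
    g <- tg_add(g, alg_uri, rdf_type, chess_term("algorithm"))
  }
  if (!is.null(prov$software) || length(prov$parameters)) {
    ex <- paste0(base, uri_local(d, base), "-EX")
    g <- tg_add(g, d, chess_term("is_output_of"), ex)
    g <- tg_add(g, ex, rdf_type, chess_term("parameterized_execution"))
    for (k in seq_along(prov$parameters)) {
      pp <- prov$parameters[[k]]
      puri <- paste0(base, uri_local(d, base), "-P", k)
      g <- tg_add(g, ex, chess_term("has_attribute"), puri)
      if (!is.null(pp$term)) g <- tg_add(g, puri, rdf_type, uri_str(pp$term))
      g <- tg_add(g, puri, chess_term("has_value"), as.character(pp$value), lit = TRUE)
      if (!is.null(pp$unit)) {
        u <- unit_token(pp$unit)
        g <- tg_add(g, puri, chess_term("has_unit"), u, lit = !grepl("^https?://", u))
      }
    }
    if (!is.null(prov$software)) {
      sw <- paste0(base, gsub("[^A-Za-z0-9]", "", prov$software[1]))
      g <- tg_add(g, ex, chess_term("has_participant"), sw)
      g <- tg_add(g, sw, rdf_type, chess_term("software_application"))
      if (length(prov$software) > 1L) {
        v <- paste0(sw, "-V")
        g <- tg_add(g, sw, chess_term("has_attribute"), v)
        g <- tg_add(g, v, rdf_type, chess_term("software_version"))
        g <- tg_add(g, v, chess_term("has_value"), prov$software[2], lit = TRUE)
      }
    }
  }
  g
}

# ---- reactions --------------------------------------------------------------

#' Encode a reaction specification
#'
#' The reaction node is typed as a chemical reaction; participants attach via
#' `has input` / `has product` / `has agent`; transforms-into statements pair
#' each reacting group or atom with its product counterpart; class-level
#' groups get their atom nodes and parthood emitted so atom mappings are
#' resolvable. Stoichiometric coefficients other than 1 are carried on
#' reified participation statements.
#' @param rxn A [reaction_spec()].
#' @param base Base IRI.
#' @return A `chess_graph`.
#' @export
encode_reaction <- function(rxn, base = chess_base()) {
  stopifnot(inherits(rxn, "chess_reaction"))
  g <- triple_graph(chess_namespaces())
  rdf_type <- chess_term("rdf_type")
  hpp <- chess_term("has_proper_part")
  r <- format(reaction_uri(rxn, base))
  g <- tg_add(g, r, rdf_type, chess_term("chemical_reaction"))
  roles <- c(inputs = "has_input", products = "has_product", agents = "has_agent")
  for (role in names(roles)) {
    df <- rxn[[role]]
    if (!nrow(df)) next
    refs <- paste0(base, df$ref)
    g <- tg_add(g, rep(r, nrow(df)), chess_term(roles[[role]]), refs)
    for (k in seq_len(nrow(df))) {
      if (df$level[k] == "class" && grepl("^FG", df$ref[k]))
        g <- tg_add(g, refs[k], rdf_type, chess_term("organic_group"))
      if (df$coefficient[k] != 1L) {
        st <- paste0(base, uri_local(r, base), "-ST",
                     chess_hash(c(role, df$ref[k])))
        rdfns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
        g <- tg_add(g, st, paste0(rdfns, "subject"), r)
        g <- tg_add(g, st, paste0(rdfns, "predicate"), chess_term(roles[[role]]))
        g <- tg_add(g, st, paste0(rdfns, "object"), refs[k])
        g <- tg_add(g, st, chess_term("has_coefficient"),
                    as.character(df$coefficient[k]), lit = TRUE)
      }
    }
  }
  if (nrow(rxn$parts)) {
    g <- tg_add(g, paste0(base, rxn$parts$parent), hpp, paste0(base, rxn$parts$child))
    has_el <- nzchar(rxn$parts$element)
    if (any(has_el)) {
      g <- tg_add(g, paste0(base, rxn$parts$child[has_el]), rdf_type,
                  element_term(rxn$parts$element[has_el]))
      g <- tg_add(g, paste0(base, rxn$parts$child[has_el]), rdf_type,
                  chess_term("atom"))
    }
  }
  if (nrow(rxn$mappings))
    g <- tg_add(g, paste0(base, rxn$mappings$source),
                chess_term("transforms_into"), paste0(base, rxn$mappings$target))
  tg_finalize(g)
}

# ---- serialization ----------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

compact_iri <- function(iri, ns) {
  for (px in names(ns)) {
    if (startsWith(iri, ns[[px]])) {
      local <- sub(ns[[px]], "", iri, fixed = TRUE)
      # only compact when the local name is a safe Turtle PN_LOCAL
      if (grepl("^[A-Za-z][A-Za-z0-9_-]*$", local)) return(paste0(px, ":", local))
    }
  }
  paste0("<", iri, ">")
}

term_to_text <- function(o, lit, ns) {
  ifelse(lit, paste0("\"", escape_literal(o), "\""),
         vapply(o, compact_iri, "", ns = ns))
}

#' Serialize a triple graph
#'
#' Statements are sorted so repeated runs produce byte-identical files. The
#' file round-trips: [read_graph()] on the output returns a graph set-equal
#' to the input.
#' @param g A `chess_graph`.
#' @param path Output file.
#' @param dialect `"turtle"` or `"ntriples"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, dialect = c("turtle", "ntriples")) {
  dialect <- match.arg(dialect)
  g <- tg_finalize(g)
  df <- g$triples
  if (dialect == "turtle") {
    ns <- g$namespaces
    header <- sprintf("@prefix %s: <%s> .", names(ns), unname(ns))
    body <- sprintf("%s %s %s .",
                    vapply(df$s, compact_iri, "", ns = ns),
                    vapply(df$p, compact_iri, "", ns = ns),
                    term_to_text(df$o, df$lit, ns))
    writeLines(c(header, "", body), path)
  } else {
    body <- sprintf("<%s> <%s> %s .", df$s, df$p,
                    ifelse(df$lit, paste0("\"", escape_literal(df$o), "\""),
                           paste0("<", df$o, ">")))
    writeLines(body, path)
  }
  invisible(path)
}

#' Read a Turtle or N-Triples file
#'
#' Parses the line-oriented subset this package emits (prefix declarations
#' and one statement per line).
#' @param path Input file.
#' @return A `chess_graph`.
#' @export
read_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ns <- character()
  s <- p <- o <- character(); lit <- logical()
  expand <- function(tok, lineno) {
    if (startsWith(tok, "<")) return(sub("^<(.*)>$", "\\1", tok))
    m <- regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", tok)[[1]]
    if (m[1] == -1) stop("parse failure in ", path, " line ", lineno,
                         ": unrecognized term ", tok)
    px <- substr(tok, m[2], m[2] + attr(m, "match.length")[2] - 1L)
    local <- substr(tok, m[3], nchar(tok))
    if (!px %in% names(ns)) stop("parse failure in ", path, " line ", lineno,
                                 ": undeclared prefix ", px)
    paste0(ns[[px]], local)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^@prefix", ln)) {
      m <- regmatches(ln, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s*<([^>]*)>\\s*\\.$", ln))[[1]]
      if (length(m) != 3) stop("parse failure in ", path, " line ", i,
                               ": malformed @prefix")
      ns[m[2]] <- m[3]
      next
    }
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)\\s+(.+?)\\s*\\.$", ln))[[1]]
    if (length(m) != 4) stop("parse failure in ", path, " line ", i, ": ", ln)
    s <- c(s, expand(m[2], i)); p <- c(p, expand(m[3], i))
    obj <- m[4]
    if (startsWith(obj, "\"")) {
      if (!grepl("^\".*\"$", obj)) stop("parse failure in ", path, " line ", i,
                                        ": unterminated literal")
      o <- c(o, unescape_literal(sub("^\"(.*)\"$", "\\1", obj)))
      lit <- c(lit, TRUE)
    } else {
      o <- c(o, expand(obj, i)); lit <- c(lit, FALSE)
    }
  }
  g <- triple_graph(if (length(ns)) ns else chess_namespaces())
  g$triples <- data.frame(s = s, p = p, o = o, lit = lit, stringsAsFactors = FALSE)
  tg_finalize(g)
}

#' Load and merge knowledgebase files
#'
#' @param paths Turtle / N-Triples files. Identical URIs from different files
#'   merge into single nodes (set semantics).
#' @return A `chess_graph`.
#' @export
load_knowledgebase <- function(paths) {
  graph_union(lapply(paths, read_graph))
}

# ---- validation -------------------------------------------------------------

#' Validate a knowledge graph
#'
#' Reports (as data.frame rows, not errors): variable descriptors lacking a
#' chemical configuration, descriptors without a unit, conflicting literal
#' values on one descriptor node, bond parts referencing atoms that are not
#' part of the parent molecule, and minted subjects missing a type statement.
#' @param kb A `chess_graph`.
#' @param base Base IRI.
#' @return data.frame with columns `level` (`"warning"`/`"error"`), `entity`,
#'   `message`; zero rows when the graph is clean.
#' @export
validate_graph <- function(kb, base = chess_base()) {
  rep_rows <- list()
  note <- function(level, entity, message)
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      level = level, entity = entity, message = message, stringsAsFactors = FALSE)
  rdf_type <- chess_term("rdf_type")
  hatt <- chess_term("has_attribute")
  types <- tg_match(kb, p = rdf_type)

  vdesc <- types$s[types$o == paste0(base, "VariableChemicalDescriptor")]
  cc_nodes <- types$s[types$o == chess_term("chemical_configuration")]
  for (d in vdesc) {
    linked <- tg_match(kb, s = d, p = hatt)$o
    if (!any(linked %in% cc_nodes))
      note("error", d, "variable descriptor lacks a chemical configuration")
  }

  desc_nodes <- unique(grep("-D[0-9a-f]{40}", types$s, value = TRUE))
  for (d in desc_nodes) {
    vals <- tg_match(kb, s = d, p = chess_term("has_value"))
    if (nrow(vals) > 1L)
      note("warning", d, paste0("conflicting values: ",
                                paste(sort(vals$o), collapse = " vs ")))
    if (nrow(vals) == 1L && !nrow(tg_match(kb, s = d, p = chess_term("has_unit"))))
      note("warning", d, "descriptor has a value but no unit")
  }

  hpp <- chess_term("has_proper_part")
  mols <- kb_molecules(kb)
  for (m in mols) {
    parts <- tg_match(kb, s = m, p = hpp)$o
    bonds <- grep("-B[A-Za-z]+[0-9]+", parts, value = TRUE)
    atoms <- grep("-A[A-Za-z]+[0-9]+$", parts, value = TRUE)
    for (bn in bonds) {
      ends <- tg_match(kb, s = bn, p = hpp)$o
      orphan <- setdiff(ends, atoms)
      if (length(orphan))
        note("error", bn, paste0("bond references atoms outside the molecule: ",
                                 paste(orphan, collapse = ", ")))
    }
  }

  minted <- unique(kb$triples$s[startsWith(kb$triples$s, base)])
  untyped <- setdiff(minted, types$s)
  untyped <- untyped[!grepl("-(EX|P[0-9]+|ST)", untyped)]
  for (u in untyped) note("warning", u, "minted subject has no type statement")

  if (!length(rep_rows))
    return(data.frame(level = character(), entity = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, rep_rows)
}

# ---- reconstitution ---------------------------------------------------------

#' Reconstitute a molecular graph from its triples
#'
#' Inverts [encode_molecule()]: reads atom typing, bond typing and parthood
#' statements back into a [chess_mol] whose atoms are ordered by canonical
#' index. The result is element- and bond-order-isomorphic to the encoded
#' graph (heavy-atom skeleton when hydrogens were suppressed).
#' @param kb A `chess_graph`.
#' @param molecule Molecule URI ([chess_uri] or string).
#' @param base Base IRI.
#' @return A [chess_mol].
#' @export
reconstitute_graph <- function(kb, molecule, base = chess_base()) {
  m <- uri_str(molecule)
  hpp <- chess_term("has_proper_part")
  parts <- tg_match(kb, s = m, p = hpp)$o
  key <- uri_local(m, base)
  atom_parts <- grep(paste0("^", key, "-A[A-Za-z][a-z]?[0-9]+$"),
                     vapply(parts, uri_local, "", base = base), value = TRUE)
  if (!length(atom_parts))
    stop_chess("incomplete_graph", paste0("no atom parthood triples for ", m))
  suffix <- sub(paste0("^", key, "-A"), "", atom_parts)
  element <- sub("[0-9]+$", "", suffix)
  canon <- as.integer(sub("^[A-Za-z]+", "", suffix))
  ord <- order(canon)
  atom_uris <- paste0(base, atom_parts)[ord]
  atoms <- data.frame(element = element[ord], stringsAsFactors = FALSE)
  idx_of <- stats::setNames(seq_along(atom_uris), atom_uris)

  bond_parts <- grep(paste0("^", key, "-B"), vapply(parts, uri_local, "", base = base),
                     value = TRUE)
  rdf_type <- chess_term("rdf_type")
  rev_order <- c(stats::setNames("single", chess_term("bond_single")),
                 stats::setNames("double", chess_term("bond_double")),
                 stats::setNames("triple", chess_term("bond_triple")),
                 stats::setNames("aromatic", chess_term("bond_aromatic")))
  a <- b <- integer(); ords <- character()
  for (bp in bond_parts) {
    buri <- paste0(base, bp)
    ends <- tg_match(kb, s = buri, p = hpp)$o
    if (length(ends) != 2L)
      stop_chess("incomplete_graph",
                 paste0("bond ", buri, " does not have two atom parts"))
    if (!all(ends %in% names(idx_of)))
      stop_chess("incomplete_graph",
                 paste0("bond ", buri, " references non-member atoms: ",
                        paste(setdiff(ends, names(idx_of)), collapse = ", ")))
    ty <- tg_match(kb, s = buri, p = rdf_type)$o
    o <- rev_order[ty[ty %in% names(rev_order)]]
    if (!length(o))
      stop_chess("incomplete_graph", paste0("bond ", buri, " has no order typing"))
    a <- c(a, idx_of[[ends[1]]]); b <- c(b, idx_of[[ends[2]]]); ords <- c(ords, o[[1]])
  }
  chess_mol(atoms, if (length(a)) data.frame(a = a, b = b, order = ords) else NULL,
            source_format = "constructed")
}
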