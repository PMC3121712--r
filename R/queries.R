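#' @title Query toolkit
#' @description Implements the query repertoire over an encoded
#'   knowledgebase: substructure search by graph pattern (executed as a
#'   basic-graph-pattern join over the triple store, with SPARQL 1.1 text
#'   generation for external endpoints), fragment-class similarity ranking,
#'   provenance-filtered descriptor retrieval, a Rule-of-Five filter, bond
#'   dissociation enthalpy window queries, reaction-candidate matching, and
#'   DL-safe rule emission.
#' @name queries
NULL

#' Build a query graph pattern
#'
#' @param nodes data.frame with columns `var` (variable names like `"a0"`)
#'   and `element` (symbols).
#' @param edges Optional data.frame with columns `a`, `b` (variable names)
#'   and `order` (bond order).
#' @param distinct `"all"` (default: every pair of variables must bind
#'   distinct atoms — monomorphism with inequality filters) or a data.frame
#'   of variable pairs.
#' @return Object of class `chess_query`.
#' @export
query_graph <- function(nodes, edges = NULL, distinct = "all") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("var", "element") %in% names(nodes)), nrow(nodes) >= 1L,
            !anyDuplicated(nodes$var))
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- data.frame(a = character(), b = character(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b", "order") %in% names(edges)))
    undeclared <- setdiff(c(edges$a, edges$b), nodes$var)
    if (length(undeclared))
      stop_chess("pattern", paste0("edge endpoint(s) not declared as nodes: ",
                                   paste(undeclared, collapse = ", ")))
    stopifnot(all(edges$order %in% BOND_ORDERS))
  }
  if (identical(distinct, "all")) {
    distinct <- if (nrow(nodes) > 1L) {
      cmb <- utils::combn(nodes$var, 2L)
      data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
    } else data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, distinct = distinct),
            class = "chess_query")
}

#' Chain query of n carbons (ethyl, propyl, ...)
#' @param n Chain length (>= 1).
#' @param element Element symbol, default carbon.
#' @return A [query_graph()].
#' @export
chain_query <- function(n, element = "C") {
  nodes <- data.frame(var = paste0("a", seq_len(n) - 1L), element = element,
                      stringsAsFactors = FALSE)
  edges <- if (n > 1L)
    data.frame(a = paste0("a", 0:(n - 2L)), b = paste0("a", 1:(n - 1L)),
               order = "single", stringsAsFactors = FALSE)
  query_graph(nodes, edges)
}

check_query_connected <- function(q) {
  if (nrow(q$nodes) == 1L) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(q$edges[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = q$nodes$var))
  if (igraph::components(g)$no > 1L)
    stop_chess("pattern", "query pattern is disconnected")
  invisible(TRUE)
}

#' Generate the SPARQL text of a substructure query
#'
#' One atom-typing and one parthood pattern per query node, one direct
#' bond-type pattern per edge, and pairwise inequality filters; valid SPARQL
#' 1.1 for any standard endpoint holding a CHESS-encoded graph.
#' @param q A [query_graph()].
#' @param base Base IRI.
#' @return Query text (character scalar).
#' @export
substructure_query <- function(q, base = chess_base()) {
  check_query_connected(q)
  ns <- chess_namespaces()
  # SPARQL PN_LOCAL (unlike Turtle's) may start with a digit, so numbered
  # SIO locals compact to the short "sio:000053" form
  sparql_iri <- function(iri) {
    for (px in names(ns)) {
      if (startsWith(iri, ns[[px]])) {
        local <- sub(ns[[px]], "", iri, fixed = TRUE)
        if (grepl("^[A-Za-z0-9_][A-Za-z0-9_-]*$", local))
          return(paste0(px, ":", local))
      }
    }
    paste0("<", iri, ">")
  }
  pre <- sprintf("PREFIX %s: <%s>", names(ns), unname(ns))
  pat <- c(sprintf("?m rdf:type %s . #molecule", sparql_iri(chess_term("molecule"))),
           sprintf("?%s rdf:type %s . #%s atom", q$nodes$var,
                   vapply(element_term(q$nodes$element), sparql_iri, ""),
                   q$nodes$element),
           sprintf("?m %s ?%s . #has proper part",
                   sparql_iri(chess_term("has_proper_part")), q$nodes$var))
  if (nrow(q$edges))
    pat <- c(pat, sprintf("?%s %s ?%s .", q$edges$a,
                          vapply(direct_bond_predicate(q$edges$order),
                                 sparql_iri, ""),
                          q$edges$b))
  if (nrow(q$distinct))
    pat <- c(pat, sprintf("FILTER(?%s != ?%s) .", q$distinct$a, q$distinct$b))
  paste(c(pre, "SELECT DISTINCT ?m", "WHERE {", paste0("  ", pat), "}"),
        collapse = "\n")
}

#' Execute a substructure search against a knowledgebase
#'
#' Evaluates the same basic graph pattern the generated SPARQL describes —
#' molecule typing, parthood, direct bond-type predicates, pairwise
#' inequality — by successive joins over the triple store. Returns exactly
#' the molecules whose chemical graph admits a subgraph matching the pattern
#' (monomorphism with distinct-variable constraints).
#' @param kb A `chess_graph` encoded with direct bond predicates.
#' @param q A [query_graph()].
#' @return Sorted character vector of molecule URIs.
#' @export
run_substructure_search <- function(kb, q) {
  check_query_connected(q)
  rdf_type <- chess_term("rdf_type")
  types <- tg_match(kb, p = rdf_type)
  mols <- unique(types$s[types$o == chess_term("molecule")])
  if (!length(mols)) return(character())
  parts <- tg_match(kb, p = chess_term("has_proper_part"))

  cand <- lapply(seq_len(nrow(q$nodes)), function(i)
    unique(types$s[types$o == element_term(q$nodes$element[i])]))
  names(cand) <- q$nodes$var

  # join order: BFS over the pattern so each new variable is edge-constrained
  ord <- q$nodes$var[1]
  remaining <- setdiff(q$nodes$var, ord)
  while (length(remaining)) {
    nxt <- remaining[remaining %in% c(q$edges$b[q$edges$a %in% ord],
                                      q$edges$a[q$edges$b %in% ord])][1]
    if (is.na(nxt)) nxt <- remaining[1]
    ord <- c(ord, nxt); remaining <- setdiff(remaining, nxt)
  }

  v1 <- ord[1]
  b <- parts[parts$s %in% mols & parts$o %in% cand[[v1]], c("s", "o")]
  names(b) <- c("m", v1)
  if (!nrow(b)) return(character())
  bound_edges <- rep(FALSE, nrow(q$edges))
  for (v in ord[-1]) {
    ek <- which(!bound_edges &
                  ((q$edges$a %in% names(b) & q$edges$b == v) |
                     (q$edges$b %in% names(b) & q$edges$a == v)))
    if (length(ek)) {
      k <- ek[1]
      u <- if (q$edges$b[k] == v) q$edges$a[k] else q$edges$b[k]
      eb <- tg_match(kb, p = direct_bond_predicate(q$edges$order[k]))[, c("s", "o")]
      eb <- eb[eb$o %in% cand[[v]], , drop = FALSE]
      names(eb) <- c(u, v)
      b <- merge(b, eb, by = u)
      bound_edges[k] <- TRUE
    } else {
      nb <- parts[parts$o %in% cand[[v]], c("s", "o")]
      names(nb) <- c("m", v)
      b <- merge(b, nb, by = "m")
    }
    # molecule membership of the newly bound atom
    keep <- paste(b$m, b[[v]]) %in% paste(parts$s, parts$o)
    b <- b[keep, , drop = FALSE]
    if (!nrow(b)) return(character())
    # remaining edges among bound variables become filters
    for (k in which(!bound_edges)) {
      if (q$edges$a[k] %in% names(b) && q$edges$b[k] %in% names(b)) {
        eb <- tg_match(kb, p = direct_bond_predicate(q$edges$order[k]))
        keep <- paste(b[[q$edges$a[k]]], b[[q$edges$b[k]]]) %in% paste(eb$s, eb$o)
        b <- b[keep, , drop = FALSE]
        bound_edges[k] <- TRUE
      }
    }
    if (!nrow(b)) return(character())
  }
  for (k in seq_len(nrow(q$distinct))) {
    b <- b[b[[q$distinct$a[k]]] != b[[q$distinct$b[k]]], , drop = FALSE]
    if (!nrow(b)) return(character())
  }
  sort(unique(b$m))
}

#' Fragment-class similarity ranking
#'
#' Scores each knowledgebase molecule by the number of distinct fragment
#' classes it shares with the query molecule (the fingerprint-style device:
#' rank by count of substructures belonging to the same class), descending;
#' ties broken by URI order; truncated to `limit`.
#' @param kb A `chess_graph` whose molecules were encoded with fragment class
#'   typing at the same depths as used for the query.
#' @param query_mol A [chess_mol] (or SMILES string).
#' @param limit Maximum rows returned (default 100).
#' @param depths Fragment depths for the query side.
#' @param base Base IRI.
#' @return Object of class `chess_similarity`: data.frame with columns
#'   `molecule`, `shared`.
#' @export
similarity_rank <- function(kb, query_mol, limit = 100L, depths = 1:3,
                            base = chess_base()) {
  if (is.character(query_mol)) query_mol <- parse_molecule(query_mol, "smiles")
  qclasses <- character()
  if (any(query_mol$atoms$element != "H")) {
    qnum <- canonical_numbering(query_mol)
    qfrags <- atom_centered_fragments(query_mol, qnum, depths, base)
    qclasses <- unique(vapply(qfrags, function(f) format(f$class_uri), ""))
  }
  if (!length(qclasses)) {
    warning("query molecule yields no fragments; empty ranking")
    return(structure(data.frame(molecule = character(), shared = integer()),
                     class = c("chess_similarity", "data.frame"), limit = limit))
  }
  types <- tg_match(kb, p = chess_term("rdf_type"))
  parts <- tg_match(kb, p = chess_term("has_proper_part"))
  frag_nodes <- grepl("-FG[0-9a-f]{40}$", parts$o)
  fparts <- parts[frag_nodes, , drop = FALSE]
  ftypes <- types[types$s %in% fparts$o & types$o %in% qclasses, , drop = FALSE]
  mol_of <- stats::setNames(fparts$s, fparts$o)
  shared_df <- unique(data.frame(m = mol_of[ftypes$s], cls = ftypes$o,
                                 stringsAsFactors = FALSE))
  counts <- table(shared_df$m)
  mols <- kb_molecules(kb)
  shared <- stats::setNames(integer(length(mols)), mols)
  shared[names(counts)] <- as.integer(counts)
  ordr <- order(-shared, names(shared))
  out <- data.frame(molecule = names(shared)[ordr], shared = unname(shared[ordr]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- utils::head(out, limit)
  structure(out, class = c("chess_similarity", "data.frame"), limit = limit)
}

#' Retrieve descriptors with provenance and configuration filters
#'
#' @param kb A `chess_graph`.
#' @param molecule Restrict to descriptors on this molecule or any of its
#'   parts (atoms, bonds, fragments). `NULL` for no restriction.
#' @param type_term Descriptor type: vocabulary concept name or IRI.
#' @param provider Filter on the configuration's provider annotation.
#' @param method Filter on provenance: method individual local name (e.g.
#'   `"AM1"`) or IRI.
#' @param unit Filter on the unit annotation (literal or IRI).
#' @param configuration Named list/vector of configuration annotations that
#'   must all match.
#' @param base Base IRI.
#' @return data.frame with one row per matching descriptor: `owner`,
#'   `descriptor`, `value`, `unit`, plus `x`, `y`, `z` columns when composite
#'   coordinate descriptors match (components of one composite are never
#'   mixed across configurations).
#' @export
retrieve_descriptors <- function(kb, molecule = NULL, type_term = NULL,
                                 provider = NULL, method = NULL, unit = NULL,
                                 configuration = NULL, base = chess_base()) {
  rdf_type <- chess_term("rdf_type")
  hatt <- chess_term("has_attribute")
  types <- tg_match(kb, p = rdf_type)
  atts <- tg_match(kb, p = hatt)
  dnodes <- unique(grep("-D[0-9a-f]{40}$", types$s, value = TRUE))
  if (!is.null(type_term)) {
    iri <- if (grepl("^https?://", type_term)) type_term else chess_term(type_term)
    dnodes <- intersect(dnodes, types$s[types$o == iri])
  }
  owner_of <- atts[atts$o %in% dnodes, c("s", "o"), drop = FALSE]
  owner_of <- owner_of[!grepl("-D[0-9a-f]{40}$", owner_of$s), , drop = FALSE]
  if (!is.null(molecule)) {
    m <- uri_str(molecule)
    scope <- c(m, tg_match(kb, s = m, p = chess_term("has_proper_part"))$o)
    owner_of <- owner_of[owner_of$s %in% scope, , drop = FALSE]
  }
  dnodes <- intersect(dnodes, owner_of$o)

  cc_nodes <- types$s[types$o == chess_term("chemical_configuration")]
  config_of <- atts[atts$s %in% dnodes & atts$o %in% cc_nodes, , drop = FALSE]
  keep_config <- function(d) {
    ccs <- config_of$o[config_of$s == d]
    want <- c(if (!is.null(provider)) stats::setNames(provider, "provider"),
              unlist(configuration))
    if (!length(want)) return(TRUE)
    if (!length(ccs)) return(FALSE)
    any(vapply(ccs, function(cc) {
      all(vapply(names(want), function(k) {
        pred <- if (k == "provider") chess_term("has_provider")
                else paste0(base, "annotation_", k)
        want[[k]] %in% tg_match(kb, s = cc, p = pred)$o
      }, logical(1)))
    }, logical(1)))
  }
  keep_method <- function(d) {
    if (is.null(method)) return(TRUE)
    iri <- if (grepl("^https?://", method)) method else paste0(base, method)
    iri %in% tg_match(kb, s = d, p = chess_term("is_specified_output_of"))$o
  }
  keep_unit <- function(d) {
    if (is.null(unit)) return(TRUE)
    u <- unit_token(unit)
    u %in% tg_match(kb, s = d, p = chess_term("has_unit"))$o
  }
  dnodes <- dnodes[vapply(dnodes, function(d)
    keep_config(d) && keep_method(d) && keep_unit(d), logical(1))]
  if (!length(dnodes))
    return(data.frame(owner = character(), descriptor = character(),
                      value = character(), unit = character(),
                      stringsAsFactors = FALSE))

  hdp <- chess_term("has_direct_part")
  val_of <- function(d) {
    v <- tg_match(kb, s = d, p = chess_term("has_value"))$o
    if (length(v)) v[1] else NA_character_
  }
  unit_of <- function(d) {
    u <- tg_match(kb, s = d, p = chess_term("has_unit"))$o
    if (length(u)) u[1] else NA_character_
  }
  axis_terms <- c(x = chess_term("coordinate_x"), y = chess_term("coordinate_y"),
                  z = chess_term("coordinate_z"))
  rows <- lapply(sort(dnodes), function(d) {
    owner <- sort(owner_of$s[owner_of$o == d])[1]
    row <- data.frame(owner = owner, descriptor = d, value = val_of(d),
                      unit = unit_of(d), stringsAsFactors = FALSE)
    comps <- tg_match(kb, s = d, p = hdp)$o
    if (length(comps)) {
      for (ax in names(axis_terms)) {
        cx <- comps[comps %in% types$s[types$o == axis_terms[[ax]]]]
        row[[ax]] <- if (length(cx)) val_of(cx[1]) else NA_character_
      }
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Rule-of-Five criteria
#'
#' Boundary semantics follow the axiomatic class definition: molecular mass
#' strictly below 500, hydrogen-bond acceptor count at most 10, donor count
#' at most 5, logP strictly between -5 and 5.
#' @param mass_max,hba_max,hbd_max,logp_min,logp_max Threshold overrides.
#' @return Object of class `chess_lipinski`.
#' @export
lipinski_criteria <- function(mass_max = 500.0, hba_max = 10L, hbd_max = 5L,
                              logp_min = -5.0, logp_max = 5.0) {
  structure(list(mass_max = mass_max, hba_max = hba_max, hbd_max = hbd_max,
                 logp_min = logp_min, logp_max = logp_max),
            class = "chess_lipinski")
}

#' Rule-of-Five filter over a knowledgebase
#'
#' A molecule passes when it carries at least one witness descriptor
#' satisfying each of the four constraints; molecules missing any required
#' descriptor are excluded (closed-world evaluation over loaded descriptors).
#' @param kb A `chess_graph`.
#' @param criteria A [lipinski_criteria()].
#' @param base Base IRI.
#' @return Sorted character vector of passing molecule URIs.
#' @export
lipinski_pass <- function(kb, criteria = lipinski_criteria(), base = chess_base()) {
  mols <- kb_molecules(kb)
  vals <- function(m, term) {
    df <- retrieve_descriptors(kb, molecule = m, type_term = term, base = base)
    suppressWarnings(as.numeric(df$value))
  }
  ok <- vapply(mols, function(m) {
    mass <- vals(m, "mass_descriptor"); hba <- vals(m, "hba_count")
    hbd <- vals(m, "hbd_count"); logp <- vals(m, "logp_descriptor")
    any(mass < criteria$mass_max) && any(hba <= criteria$hba_max) &&
      any(hbd <= criteria$hbd_max) &&
      any(logp > criteria$logp_min & logp < criteria$logp_max)
  }, logical(1))
  sort(mols[ok])
}

#' Bond-dissociation-enthalpy window search
#'
#' Retrieves molecules that carry a phenol-class fragment and an O-H single
#' bond whose BDE descriptor was computed with the given method, in the given
#' unit, with a value strictly inside `(low, high)` — the biologically
#' promising window for phenolic antioxidants (above ascorbate's weakest O-H
#' at 67 kcal/mol, below alpha-tocopherol's at 78).
#' @param kb A `chess_graph`.
#' @param low,high Window bounds (strict).
#' @param method Method filter (local name like `"AM1"` or IRI).
#' @param unit Unit filter.
#' @param phenol_class IRI of the phenol group class.
#' @param base Base IRI.
#' @return data.frame with columns `molecule`, `value` (numeric), sorted by
#'   molecule URI.
#' @export
bde_window_search <- function(kb, low = 67, high = 78, method = "AM1",
                              unit = "kcal/mol",
                              phenol_class = paste0(chess_base(), "FGPhenol"),
                              base = chess_base()) {
  rdf_type <- chess_term("rdf_type")
  types <- tg_match(kb, p = rdf_type)
  parts <- tg_match(kb, p = chess_term("has_proper_part"))
  phenolic <- unique(parts$s[parts$o %in% types$s[types$o == uri_str(phenol_class)]])
  phenolic <- intersect(phenolic, kb_molecules(kb))
  out <- data.frame(molecule = character(), value = numeric(),
                    stringsAsFactors = FALSE)
  single_bonds <- types$s[types$o == chess_term("bond_single")]
  o_atoms <- types$s[types$o == element_term("O")]
  h_atoms <- types$s[types$o == element_term("H")]
  bde <- retrieve_descriptors(kb, type_term = "bde_descriptor",
                              method = method, unit = unit, base = base)
  for (m in sort(phenolic)) {
    bonds <- intersect(tg_match(kb, s = m, p = chess_term("has_proper_part"))$o,
                       single_bonds)
    for (bn in bonds) {
      ends <- tg_match(kb, s = bn, p = chess_term("has_proper_part"))$o
      if (!(any(ends %in% o_atoms) && any(ends %in% h_atoms))) next
      df <- bde[bde$owner == bn, , drop = FALSE]
      v <- suppressWarnings(as.numeric(df$value))
      v <- v[!is.na(v) & v > low & v < high]
      if (length(v))
        out <- rbind(out, data.frame(molecule = m, value = v[1],
                                     stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

#' Candidate reactions for a molecule
#'
#' A reaction is a candidate when every one of its class-level inputs
#' (functional-group classes and class-level atom types) is instantiated by
#' a fragment or atom of the molecule; instance-level inputs must be the
#' molecule itself. Instance bindings are reported.
#' @param kb A `chess_graph` containing encoded molecules (with fragment
#'   class and class-atom typing) and reactions.
#' @param molecule Molecule URI.
#' @param base Base IRI.
#' @return data.frame with columns `reaction`, `input`, `instance`; zero rows
#'   when nothing matches.
#' @export
reaction_candidates <- function(kb, molecule, base = chess_base()) {
  m <- uri_str(molecule)
  rdf_type <- chess_term("rdf_type")
  types <- tg_match(kb, p = rdf_type)
  parts <- tg_match(kb, s = m, p = chess_term("has_proper_part"))$o
  reactions <- sort(unique(types$s[types$o == chess_term("chemical_reaction")]))
  empty <- data.frame(reaction = character(), input = character(),
                      instance = character(), stringsAsFactors = FALSE)
  out <- empty
  for (r in reactions) {
    inputs <- sort(tg_match(kb, s = r, p = chess_term("has_input"))$o)
    rows <- empty
    ok <- TRUE
    for (inp in inputs) {
      instances <- types$s[types$o == inp]              # ?x rdf:type <input>
      instances <- instances[instances %in% c(parts, m)]
      if (!length(instances) && inp == m) instances <- m
      if (!length(instances)) { ok <- FALSE; break }
      rows <- rbind(rows, data.frame(reaction = r, input = inp,
                                     instance = sort(instances)[1],
                                     stringsAsFactors = FALSE))
    }
    if (ok && length(inputs)) out <- rbind(out, rows)
  }
  out
}

#' Emit a DL-safe classification rule
#'
#' Textual rule with one atom-typing literal per query node, parthood and
#' bond literals, `different from` literals for the distinct pairs, and the
#' target class in the head. Emission only; no reasoner is invoked.
#' @param q A [query_graph()].
#' @param class_name Head class label, e.g. `"ethyl containing molecule"`.
#' @return Rule text.
#' @export
emit_dl_safe_rule <- function(q, class_name) {
  elem_label <- function(sym) {
    v <- chess_vocabulary()
    i <- match(paste0("atom_", sym), v$concept)
    ifelse(is.na(i), paste0(sym, " atom"), v$label[i])
  }
  body <- c("'molecule'(?m1)",
            sprintf("'%s'(?%s)", elem_label(q$nodes$element), q$nodes$var),
            sprintf("'is part of'(?%s, ?m1)", q$nodes$var))
  if (nrow(q$edges))
    body <- c(body, sprintf("'%s bond'(?%s, ?%s)", q$edges$order, q$edges$a, q$edges$b))
  if (nrow(q$distinct))
    body <- c(body, sprintf("'different from'(?%s, ?%s)", q$distinct$a, q$distinct$b))
  paste0(paste(body, collapse = ", "), "\n-> '", class_name, "'(?m1)")
}
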