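#' @title Atom-centered fragmentation
#' @description The fragment vocabulary is built from atom-centric heavy-atom
#'   subgraphs: for each heavy atom and each depth d, the subgraph induced by
#'   all heavy atoms within d bonds of the center. For n-propanol's oxygen the
#'   depth-1/2/3 fragments are the hydrogen-suppressed graphs CO, CCO and
#'   CCCO. Fragments with the same member set are collapsed to one; fragments
#'   with isomorphic structure share a class (the fingerprint-style vocabulary
#'   used for similarity ranking and reaction matching). Bond orders are kept
#'   inside class keys, so an aldehyde CC=O class differs from an alcohol CCO.
#' @name fragments
NULL

# Canonical class key of a heavy-atom induced subgraph: its canonical SMILES.
# `submols` is a list of chess_mol; one batched conversion call.
class_keys_for <- function(submols) {
  if (!length(submols)) return(character())
  ob_canonical_smiles(vapply(submols, as_molblock, ""))
}

# Induced heavy-atom subgraph. When a numbering is supplied, member atoms are
# listed in canonical-index order and bonds sorted, so the emitted mol block
# is a pure function of canonical structure (input atom order never leaks
# into class keys via e.g. kekulization choices).
induced_heavy_submol <- function(mol, members_input, numbering = NULL) {
  members_input <- if (is.null(numbering)) sort(members_input)
  else members_input[order(numbering$heavy_map[as.character(members_input)])]
  remap <- stats::setNames(seq_along(members_input), members_input)
  atoms <- mol$atoms[members_input, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  keep <- b$a %in% members_input & b$b %in% members_input
  bonds <- b[keep, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$a <- unname(remap[as.character(bonds$a)])
    bonds$b <- unname(remap[as.character(bonds$b)])
    swap <- bonds$a > bonds$b
    tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
    bonds <- bonds[order(bonds$a, bonds$b), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  out <- chess_mol(atoms, bonds, "constructed")
  attr(out, "member_order") <- members_input
  out
}

new_fragment <- function(center, depth, members, members_input, class_key,
                         uri, class_uri) {
  structure(list(center = center, depth = depth, members = members,
                 members_input = members_input, class_key = class_key,
                 uri = uri, class_uri = class_uri),
            class = "chess_fragment")
}

#' @export
print.chess_fragment <- function(x, ...) {
  cat("<chess_fragment> class ", x$class_key, ", center ", x$center,
      ", members {", paste(x$members, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Generate atom-centered fragments
#'
#' @param mol A [chess_mol].
#' @param numbering Its [canonical_numbering()].
#' @param depths Bond radii to fragment at; subset of `1:3` by default
#'   (larger radii are accepted).
#' @param base Base IRI.
#' @return List of `chess_fragment` objects: `center` and `members` are
#'   canonical heavy-atom indices, `class_key` the canonical SMILES of the
#'   hydrogen-suppressed induced subgraph, `uri` the minted fragment instance
#'   URI and `class_uri` the fragment-class URI. Duplicate member sets are
#'   collapsed (the smallest depth is kept).
#' @export
atom_centered_fragments <- function(mol, numbering, depths = 1:3,
                                    base = chess_base()) {
  stopifnot(all(depths >= 1L))
  hv <- heavy_indices(mol)
  if (!length(hv)) return(list())
  hb <- mol$bonds[mol$bonds$a %in% hv & mol$bonds$b %in% hv, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(a = as.character(hb$a), b = as.character(hb$b)),
    directed = FALSE, vertices = data.frame(name = as.character(hv)))
  dmat <- igraph::distances(g)
  seen <- character()
  centers <- integer(); depth_of <- integer(); member_sets <- list()
  for (d in sort(depths)) for (h in hv[order(numbering$heavy_map[as.character(hv)])]) {
    members <- hv[dmat[as.character(h), as.character(hv)] <= d]
    key <- paste(sort(members), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    centers <- c(centers, h); depth_of <- c(depth_of, d)
    member_sets <- c(member_sets, list(sort(members)))
  }
  submols <- lapply(member_sets, induced_heavy_submol, mol = mol,
                    numbering = numbering)
  keys <- class_keys_for(submols)
  out <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    members_canon <- sort(unname(numbering$heavy_map[as.character(member_sets[[i]])]))
    frag <- list(class_key = keys[i], members = members_canon)
    out[[i]] <- new_fragment(
      center = unname(numbering$heavy_map[as.character(centers[i])]),
      depth = depth_of[i], members = members_canon,
      members_input = member_sets[[i]], class_key = keys[i],
      uri = fragment_uri(numbering, frag, base),
      class_uri = fragment_class_uri(keys[i], base))
  }
  out
}

fragment_class_uri <- function(class_key, base = chess_base()) {
  chess_uri(paste0("FG", chess_hash(class_key)), base)
}

#' Fragment class of a fragment
#'
#' Two fragments with isomorphic hydrogen-suppressed graphs share one class:
#' the class key is the canonical SMILES of the induced subgraph and the class
#' URI is a deterministic digest of that key.
#' @param frag A `chess_fragment`.
#' @param base Base IRI.
#' @return List with `class_key` and `class_uri` (class `chess_fragment_class`).
#' @export
fragment_class <- function(frag, base = chess_base()) {
  structure(list(class_key = frag$class_key,
                 class_uri = fragment_class_uri(frag$class_key, base)),
            class = "chess_fragment_class")
}

#' Register a user-defined functional group
#'
#' Custom fragment/functional-group annotations may be added at any time; the
#' fragment instance is minted with the standard fragment-URI rule but typed
#' to the caller's class (e.g. a phenol class used by window queries).
#' @param mol A [chess_mol].
#' @param numbering Its [canonical_numbering()].
#' @param members Input indices of the member heavy atoms; they must induce a
#'   connected subgraph.
#' @param class_uri IRI (string or [chess_uri]) of the group class.
#' @param base Base IRI.
#' @return A `chess_fragment` carrying the custom class.
#' @export
register_custom_group <- function(mol, numbering, members, class_uri,
                                  base = chess_base()) {
  members <- sort(unique(as.integer(members)))
  stopifnot(length(members) >= 1L,
            all(members >= 1L & members <= nrow(mol$atoms)))
  if (any(mol$atoms$element[members] == "H"))
    stop_chess("connectivity", "custom groups are heavy-atom subgraphs")
  sub <- induced_heavy_submol(mol, members, numbering)
  g <- igraph::graph_from_data_frame(
    if (nrow(sub$bonds)) sub$bonds[, c("a", "b")] else data.frame(a = integer(), b = integer()),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(sub$atoms))))
  if (igraph::components(g)$no > 1L)
    stop_chess("connectivity", "member atoms do not induce a connected subgraph")
  key <- class_keys_for(list(sub))
  members_canon <- sort(unname(numbering$heavy_map[as.character(members)]))
  frag <- list(class_key = key, members = members_canon)
  new_fragment(center = members_canon[1], depth = NA_integer_,
               members = members_canon, members_input = members,
               class_key = key, uri = fragment_uri(numbering, frag, base),
               class_uri = if (inherits(class_uri, "chess_uri")) class_uri
                           else chess_uri(uri_local(class_uri, base), base))
}

#' Fragment class vocabulary table
#'
#' @param fragments List of `chess_fragment`s.
#' @return data.frame with columns `class_key`, `class_uri` (unique rows).
#' @export
fragment_class_table <- function(fragments) {
  df <- data.frame(
    class_key = vapply(fragments, function(f) f$class_key, ""),
    class_uri = vapply(fragments, function(f) format(f$class_uri), ""),
    stringsAsFactors = FALSE)
  unique(df[order(df$class_key), , drop = FALSE])
}

# ---- class graphs (for atom-level typing in reaction matching) -------------

# Parse a class key back into a molecular graph with canonical numbering.
# Cached: class keys recur constantly across a knowledgebase.
class_graph <- function(class_key) {
  cache <- .chess_env$class_graphs
  if (is.null(cache)) cache <- .chess_env$class_graphs <- new.env(parent = emptyenv())
  hit <- cache[[class_key]]
  if (!is.null(hit)) return(hit)
  mol <- parse_molecule(class_key, "smiles")
  num <- canonical_numbering(mol)
  val <- list(mol = mol, numbering = num)
  cache[[class_key]] <- val
  val
}

# Class-level atom node local suffix: "A" + index + symbol
# (class atoms follow the printed FGXXXA3O form; molecule atom instances use
# the normalized -A<sym><idx> grammar).
class_atom_suffix <- function(class_key) {
  cg <- class_graph(class_key)
  hv <- heavy_indices(cg$mol)
  idx <- unname(cg$numbering$heavy_map[as.character(hv)])
  stats::setNames(paste0("A", idx, cg$mol$atoms$element[hv]), hv)[order(idx)]
}

# Map a fragment's member input atoms (in `mol`) to class-graph atom indices.
# Deterministic: first embedding found by the backtracking matcher.
fragment_class_atom_map <- function(mol, frag, numbering = NULL) {
  cg <- class_graph(frag$class_key)
  sub <- induced_heavy_submol(mol, frag$members_input, numbering)
  m <- match_graph(cg$mol, sub, heavy_only = FALSE)
  if (!length(m)) return(NULL)   # should not happen: same graph by construction
  map <- m[[1]]
  # class atom i (input index in cg$mol) -> member input atom in mol
  member_order <- attr(sub, "member_order")
  stats::setNames(member_order[map], seq_along(map))
}
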