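# Shared fixtures and the independent subgraph-matching oracle.
#
# The oracle is deliberately a different algorithm on a different substrate
# from the package's triple-store search: bond orders are folded into vertex
# labels (each bond becomes a labeled midpoint vertex) and matching is done
# by igraph's LAD solver with element-constrained domains.

expand_labeled_graph <- function(mol) {
  hv <- which(mol$atoms$element != "H")
  remap <- stats::setNames(seq_along(hv), hv)
  lab <- mol$atoms$element[hv]
  edges <- integer(); n <- length(hv)
  b <- mol$bonds[mol$bonds$a %in% hv & mol$bonds$b %in% hv, , drop = FALSE]
  for (k in seq_len(nrow(b))) {
    n <- n + 1L
    lab <- c(lab, paste0("bond:", b$order[k]))
    edges <- c(edges, remap[[as.character(b$a[k])]], n,
               n, remap[[as.character(b$b[k])]])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::V(g)$label <- lab
  g
}

oracle_has_substructure <- function(pattern_mol, target_mol) {
  gp <- expand_labeled_graph(pattern_mol)
  gt <- expand_labeled_graph(target_mol)
  doms <- lapply(igraph::V(gp)$label,
                 function(l) which(igraph::V(gt)$label == l))
  if (any(lengths(doms) == 0)) return(FALSE)
  igraph::subgraph_isomorphic(gp, gt, method = "lad", induced = FALSE,
                              domains = doms)
}

# query_graph from the heavy skeleton of a molecule
query_from_mol <- function(mol) {
  hv <- which(mol$atoms$element != "H")
  nodes <- data.frame(var = paste0("a", seq_along(hv) - 1L),
                      element = mol$atoms$element[hv],
                      stringsAsFactors = FALSE)
  b <- mol$bonds[mol$bonds$a %in% hv & mol$bonds$b %in% hv, , drop = FALSE]
  edges <- if (nrow(b))
    data.frame(a = paste0("a", match(b$a, hv) - 1L),
               b = paste0("a", match(b$b, hv) - 1L),
               order = b$order, stringsAsFactors = FALSE)
  query_graph(nodes, edges)
}

# the eight standard search patterns: ethyl..pentyl chains, a five-membered
# ring with one double bond, hydroxyl (C-O), carbonyl (C=O), lone oxygen
standard_patterns <- function() {
  ring5 <- query_graph(
    data.frame(var = paste0("a", 0:4), element = "C"),
    data.frame(a = paste0("a", 0:4), b = paste0("a", c(1:4, 0)),
               order = c("double", rep("single", 4))))
  list(ethyl = chain_query(2), propyl = chain_query(3),
       butyl = chain_query(4), pentyl = chain_query(5),
       ring5_ene = ring5,
       hydroxyl = query_graph(data.frame(var = c("a0", "a1"),
                                         element = c("C", "O")),
                              data.frame(a = "a0", b = "a1", order = "single")),
       carbonyl = query_graph(data.frame(var = c("a0", "a1"),
                                         element = c("C", "O")),
                              data.frame(a = "a0", b = "a1", order = "double")),
       oxygen = query_graph(data.frame(var = "a0", element = "O")))
}

pattern_mol_of <- function(q) {
  vars <- q$nodes$var
  chess_mol(data.frame(element = q$nodes$element),
            if (nrow(q$edges)) data.frame(a = match(q$edges$a, vars),
                                          b = match(q$edges$b, vars),
                                          order = q$edges$order))
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  invisible(old)
}
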