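# Backtracking subgraph matcher on molecular graphs (adjacency lists, not the
# triple store). Semantics: subgraph monomorphism with all pattern variables
# pairwise distinct, element labels equal, and bond orders equal; matched
# bonds must exist in the target but the target may have extra bonds between
# matched atoms (non-induced matching, mirroring the generated SPARQL
# patterns). Serves as the independent oracle for the triple-store search and
# to align fragment instances with their class graphs.

# Returns a list of integer vectors (pattern index -> target index); empty
# list if no embedding exists. `heavy_only` restricts the target to heavy atoms.
match_graph <- function(pattern, target, find_all = FALSE, heavy_only = TRUE) {
  pa <- pattern$atoms; ta <- target$atoms
  t_ok <- if (heavy_only) ta$element != "H" else rep(TRUE, nrow(ta))
  np <- nrow(pa)
  # pattern adjacency: list of (neighbour, order)
  padj <- rep(list(integer()), np); pord <- rep(list(character()), np)
  if (nrow(pattern$bonds)) for (k in seq_len(nrow(pattern$bonds))) {
    a <- pattern$bonds$a[k]; b <- pattern$bonds$b[k]; o <- pattern$bonds$order[k]
    padj[[a]] <- c(padj[[a]], b); pord[[a]] <- c(pord[[a]], o)
    padj[[b]] <- c(padj[[b]], a); pord[[b]] <- c(pord[[b]], o)
  }
  tadj <- new.env(parent = emptyenv())
  if (nrow(target$bonds)) for (k in seq_len(nrow(target$bonds))) {
    a <- target$bonds$a[k]; b <- target$bonds$b[k]; o <- target$bonds$order[k]
    assign(paste(a, b), o, envir = tadj); assign(paste(b, a), o, envir = tadj)
  }
  # order pattern vertices connectedly (first vertex, then neighbours first)
  order_p <- integer(0); seen <- logical(np)
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (seen[v]) next
    seen[v] <- TRUE; order_p <- c(order_p, v)
    queue <- c(queue, padj[[v]][!seen[padj[[v]]]])
  }
  if (!all(seen)) order_p <- c(order_p, which(!seen))  # disconnected pattern

  results <- list()
  assign_map <- integer(np)
  used <- logical(nrow(ta))
  recurse <- function(pos) {
    if (pos > np) {
      results[[length(results) + 1L]] <<- assign_map
      return(!find_all)                      # TRUE stops the search
    }
    pv <- order_p[pos]
    for (tv in which(t_ok & !used & ta$element == pa$element[pv])) {
      ok <- TRUE
      for (j in seq_along(padj[[pv]])) {
        u <- padj[[pv]][j]
        if (assign_map[u] > 0L) {
          o <- mget(paste(assign_map[u], tv), envir = tadj,
                    ifnotfound = NA_character_)[[1]]
          if (is.na(o) || o != pord[[pv]][j]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_map[pv] <<- tv; used[tv] <<- TRUE
      if (recurse(pos + 1L)) return(TRUE)
      assign_map[pv] <<- 0L; used[tv] <<- FALSE
    }
    FALSE
  }
  recurse(1L)
  results
}

has_embedding <- function(pattern, target) length(match_graph(pattern, target)) > 0
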