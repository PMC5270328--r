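# internal helpers: scoped RNG and small graph primitives

# set the RNG to a reproducible state, returning the previous state so the
# caller can restore it (keeps library calls from disturbing user RNG)
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# adjacency list (child lists) from an edge data frame over `nodes`
adj_from_edges <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (nrow(edges)) {
    sp <- split(as.character(edges$to), factor(edges$from, levels = nodes))
    for (v in names(sp)) if (length(sp[[v]])) adj[[v]] <- sp[[v]]
  }
  adj
}

# TRUE if `to` can already reach `from` (so adding from -> to closes a cycle)
reaches <- function(adj, start, goal) {
  if (start == goal) return(TRUE)
  seen <- character(0)
  stack <- start
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == goal) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    nxt <- adj[[v]]
    if (length(nxt)) stack <- c(stack, setdiff(nxt, seen))
  }
  FALSE
}

# Kahn topological sort; NULL when the graph is cyclic
topo_sort <- function(edges, nodes) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- adj_from_edges(edges, nodes)
  if (nrow(edges)) {
    tab <- table(factor(as.character(edges$to), levels = nodes))
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  queue <- sort(nodes[indeg == 0])
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

is_acyclic <- function(edges, nodes) !is.null(topo_sort(edges, nodes))

empty_edges <- function() {
  data.frame(from = character(0), to = character(0),
             stringsAsFactors = FALSE)
}

# canonical directed-pair keys for fast set membership
edge_key <- function(from, to) paste(from, to, sep = "\r")
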