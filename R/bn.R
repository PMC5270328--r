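#' Learning configuration for network structure search
#'
#' @param max_iters Maximum hill-climbing moves per search.
#' @param restarts Number of move-order permutations explored; the best
#'   final structure is returned.
#' @param seed Integer seed controlling permutations and sampling.
#' @param tol Minimum score improvement for a move to be applied.
#' @param expansion_rounds Sampling/learning rounds in
#'   [expand_network()].
#' @param max_genes Cap on the number of nodes during expansion.
#' @return A `LearnConfig` list.
#' @export
learn_config <- function(max_iters = 200L, restarts = 1L, seed = 1L,
                         tol = 1e-6, expansion_rounds = 3L,
                         max_genes = Inf) {
  stopifnot(max_iters >= 1, restarts >= 1, tol >= 0,
            expansion_rounds >= 0, max_genes >= 1)
  structure(list(max_iters = as.integer(max_iters),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed), tol = tol,
                 expansion_rounds = as.integer(expansion_rounds),
                 max_genes = max_genes),
            class = "LearnConfig")
}

#' Convert an expression matrix to a modelling data matrix
#'
#' Transposes a genes-by-conditions `ExpressionMatrix` into the
#' observations-by-variables orientation used for Gaussian network
#' scoring, optionally applying the log2(CPM + 1) transform.
#'
#' @param matrix An `ExpressionMatrix` or plain numeric matrix already in
#'   observations-by-variables orientation (returned unchanged).
#' @param transform `"log_cpm"` (default for CPM input) or `"identity"`.
#' @return Numeric matrix, conditions in rows, genes in columns.
#' @export
bn_data <- function(matrix, transform = c("log_cpm", "identity")) {
  transform <- match.arg(transform)
  if (inherits(matrix, "ExpressionMatrix")) {
    vals <- if (transform == "log_cpm") log_cpm(matrix) else unclass(matrix)
    t(vals)
  } else {
    as.matrix(matrix)
  }
}

#' Gaussian BIC score of one node given a parent set
#'
#' Regresses the node on its parents by ordinary least squares and
#' returns the maximized Gaussian log-likelihood minus the BIC penalty
#' (p/2) log N, with p = number of parents + 2 (regression coefficients,
#' intercept and residual variance). Higher is better. A rank-deficient
#' parent design falls back to a ridge solve (lambda = 1e-8) with a
#' warning.
#'
#' @param data Numeric matrix, observations in rows, genes in columns
#'   (see [bn_data()]).
#' @param node Gene (column) name to score.
#' @param parents Character vector of parent gene names (possibly empty).
#' @return The node's BIC contribution (numeric scalar).
#' @export
node_bic <- function(data, node, parents = character(0)) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < length(parents) + 2) {
    stop("need at least #parents + 2 observations to score a node")
  }
  y <- data[, node]
  if (length(parents) == 0) {
    mu <- mean(y)
    rss <- sum((y - mu)^2)
  } else {
    X <- cbind(1, data[, parents, drop = FALSE])
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      warning("rank-deficient parent design; ridge fallback applied")
      beta <- solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, y))
      rss <- sum((y - X %*% beta)^2)
    } else {
      rss <- sum(qr.resid(qrx, y)^2)
    }
  }
  sigma2 <- max(rss / n, 1e-12)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  p <- length(parents) + 2
  loglik - p / 2 * log(n)
}

#' Construct a Bayesian-network structure
#'
#' @param nodes Character vector of gene identifiers.
#' @param edges Data frame with columns `from`, `to` (defaults to no
#'   edges). Must be acyclic.
#' @return A `BNStructure`: list with `nodes`, `parents` (named list of
#'   parent sets), and, after [score_structure()], `per_node_scores` and
#'   `total_score`.
#' @export
bn_structure <- function(nodes, edges = empty_edges()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  edges <- as.data.frame(edges)[, c("from", "to")]
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(missing)) stop("edge endpoints not in nodes: ",
                              paste(missing, collapse = ", "))
    if (any(edges$from == edges$to)) stop("self-loops are not permitted")
    edges <- unique(edges)
  }
  if (!is_acyclic(edges, nodes)) stop("edge set contains a directed cycle")
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) parents[[v]] <- character(0)
  if (nrow(edges)) {
    sp <- split(edges$from, factor(edges$to, levels = nodes))
    for (v in names(sp)) parents[[v]] <- sort(as.character(sp[[v]]))
  }
  structure(list(nodes = nodes, parents = parents,
                 per_node_scores = NULL, total_score = NA_real_),
            class = "BNStructure")
}

#' Extract the directed edges of a structure
#' @param structure A `BNStructure`.
#' @return Data frame with columns `from` and `to`.
#' @export
bn_edges <- function(structure) {
  out <- list()
  for (v in structure$nodes) {
    ps <- structure$parents[[v]]
    if (length(ps)) out[[v]] <- data.frame(from = ps, to = v,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_edges())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$from, res$to, method = "radix"), , drop = FALSE]
}

#' Score every node of a structure
#'
#' Fills `per_node_scores` and `total_score` (their sum) using
#' [node_bic()].
#'
#' @param data Observations-by-genes matrix.
#' @param structure A `BNStructure`.
#' @return The structure with scores attached.
#' @export
score_structure <- function(data, structure) {
  sc <- vapply(structure$nodes,
               function(v) node_bic(data, v, structure$parents[[v]]),
               numeric(1))
  structure$per_node_scores <- sc
  structure$total_score <- sum(sc)
  structure
}

#' @export
print.BNStructure <- function(x, ...) {
  cat(sprintf("BNStructure: %d nodes, %d edges, score %s\n",
              length(x$nodes), nrow(bn_edges(x)),
              if (is.na(x$total_score)) "unscored"
              else sprintf("%.4f", x$total_score)))
  invisible(x)
}

# internal move table for the hill climber: all legal (type, from, to)
# respecting constraints is computed fresh each iteration (graphs are small)
hc_moves <- function(struct, allowed_keys, wl_keys, adj) {
  nodes <- struct$nodes
  edges <- bn_edges(struct)
  cur_keys <- edge_key(edges$from, edges$to)
  moves <- list()
  # additions
  if (length(allowed_keys)) {
    cand <- allowed_keys[!(allowed_keys %in% cur_keys)]
    if (length(cand)) {
      parts <- strsplit(cand, "\r", fixed = TRUE)
      for (pr in parts) {
        u <- pr[1]; v <- pr[2]
        if (!(u %in% nodes) || !(v %in% nodes)) next
        if (reaches(adj, v, u)) next
        moves[[length(moves) + 1L]] <- c("add", u, v)
      }
    }
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      u <- edges$from[i]; v <- edges$to[i]
      k <- edge_key(u, v)
      if (k %in% wl_keys) next                      # whitelist is inviolable
      moves[[length(moves) + 1L]] <- c("delete", u, v)
      if (edge_key(v, u) %in% allowed_keys) {
        # reversal legal if v -/-> ... --> u without the edge u -> v
        adj2 <- adj
        adj2[[u]] <- setdiff(adj2[[u]], v)
        if (!reaches(adj2, u, v)) {
          moves[[length(moves) + 1L]] <- c("reverse", u, v)
        }
      }
    }
  }
  if (!length(moves)) {
    return(data.frame(type = character(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, moves)
  data.frame(type = m[, 1], from = m[, 2], to = m[, 3],
             stringsAsFactors = FALSE)
}

#' Constrained greedy hill-climbing structure search
#'
#' Starting from a seed graph that must contain every whitelist edge,
#' repeatedly evaluates all legal single-edge moves — additions of
#' allowed pairs, deletions of non-whitelist edges, and reversals of
#' non-whitelist edges whose reverse is allowed — applying the best
#' strictly improving move until no move improves the BIC score by more
#' than `config$tol`. With `config$restarts > 1` the search is repeated
#' under random permutations of the move-evaluation order (which breaks
#' score ties differently) and the best-scoring result is returned.
#'
#' @param data Observations-by-genes matrix (see [bn_data()]), or an
#'   `ExpressionMatrix` (log-CPM transform applied).
#' @param seed_graph A `BNStructure`, or `NULL` for an empty graph over
#'   all columns of `data`.
#' @param constraints A `ConstraintSet`, or `NULL` for an unconstrained
#'   search (all pairs allowed, empty whitelist).
#' @param config A `LearnConfig`.
#' @return The learned `BNStructure`, scored, with attribute
#'   `score_trace` (per applied move) for the best restart.
#' @export
hill_climb <- function(data, seed_graph = NULL, constraints = NULL,
                       config = learn_config()) {
  data <- bn_data(data)
  if (is.null(seed_graph)) seed_graph <- bn_structure(colnames(data))
  nodes <- seed_graph$nodes
  missing <- setdiff(nodes, colnames(data))
  if (length(missing)) stop("nodes absent from data: ",
                            paste(missing, collapse = ", "))

  if (is.null(constraints)) {
    grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, , drop = FALSE]
    allowed_keys <- edge_key(grid$from, grid$to)
    wl_keys <- character(0)
  } else {
    al <- constraints$allowed
    al <- al[al$from %in% nodes & al$to %in% nodes, , drop = FALSE]
    wl <- constraints$whitelist
    wl <- wl[wl$from %in% nodes & wl$to %in% nodes, , drop = FALSE]
    wl_keys <- edge_key(wl$from, wl$to)
    allowed_keys <- unique(c(edge_key(al$from, al$to), wl_keys))
    seed_keys <- with(bn_edges(seed_graph), edge_key(from, to))
    if (!all(wl_keys %in% seed_keys)) {
      stop("seed graph must contain every whitelist edge over its nodes")
    }
  }
  seed_keys <- with(bn_edges(seed_graph), edge_key(from, to))
  if (!all(seed_keys %in% allowed_keys)) {
    # seed edges outside the allowed set are tolerated but protected from
    # re-addition after deletion; treat them as allowed for consistency
    allowed_keys <- unique(c(allowed_keys, seed_keys))
  }

  cache <- new.env(parent = emptyenv())
  scored_bic <- function(v, ps) {
    key <- paste(v, paste(sort(ps), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- node_bic(data, v, ps)
      cache[[key]] <- got
    }
    got
  }

  run_once <- function(perm_seed) {
    struct <- seed_graph
    if (!is.null(perm_seed)) {
      # random-restart perturbation: a handful of random legal additions
      # moves the search into a different basin; unhelpful edges are
      # deletable later since they are not whitelisted
      old <- local_rng(perm_seed)
      for (t in seq_len(4L)) {
        edges <- bn_edges(struct)
        adj <- adj_from_edges(edges, struct$nodes)
        cur <- edge_key(edges$from, edges$to)
        cand <- setdiff(allowed_keys, cur)
        if (!length(cand)) break
        pick <- strsplit(sample(cand, 1), "\r", fixed = TRUE)[[1]]
        if (!(pick[1] %in% struct$nodes) || !(pick[2] %in% struct$nodes))
          next
        if (reaches(adj, pick[2], pick[1])) next
        struct$parents[[pick[2]]] <- sort(c(struct$parents[[pick[2]]],
                                            pick[1]))
      }
      restore_rng(old)
    }
    struct <- score_structure_cached(struct, scored_bic)
    trace <- struct$total_score
    for (iter in seq_len(config$max_iters)) {
      edges <- bn_edges(struct)
      adj <- adj_from_edges(edges, struct$nodes)
      moves <- hc_moves(struct, allowed_keys, wl_keys, adj)
      if (!nrow(moves)) break
      ord <- order(moves$type, moves$from, moves$to, method = "radix")
      moves <- moves[ord, , drop = FALSE]
      if (!is.null(perm_seed)) {
        old <- local_rng(perm_seed + iter)
        moves <- moves[sample.int(nrow(moves)), , drop = FALSE]
        restore_rng(old)
      }
      deltas <- numeric(nrow(moves))
      for (i in seq_len(nrow(moves))) {
        u <- moves$from[i]; v <- moves$to[i]
        pv <- struct$parents[[v]]
        deltas[i] <- switch(
          moves$type[i],
          add = scored_bic(v, c(pv, u)) - struct$per_node_scores[[v]],
          delete = scored_bic(v, setdiff(pv, u)) -
            struct$per_node_scores[[v]],
          reverse = (scored_bic(v, setdiff(pv, u)) -
                       struct$per_node_scores[[v]]) +
            (scored_bic(u, c(struct$parents[[u]], v)) -
               struct$per_node_scores[[u]]))
      }
      best <- which.max(deltas)
      if (deltas[best] <= config$tol) break
      u <- moves$from[best]; v <- moves$to[best]
      struct$parents[[v]] <- switch(
        moves$type[best],
        add = sort(c(struct$parents[[v]], u)),
        delete = setdiff(struct$parents[[v]], u),
        reverse = setdiff(struct$parents[[v]], u))
      if (moves$type[best] == "reverse") {
        struct$parents[[u]] <- sort(c(struct$parents[[u]], v))
        struct$per_node_scores[[u]] <- scored_bic(u, struct$parents[[u]])
      }
      struct$per_node_scores[[v]] <- scored_bic(v, struct$parents[[v]])
      struct$total_score <- sum(struct$per_node_scores)
      trace <- c(trace, struct$total_score)
    }
    attr(struct, "score_trace") <- trace
    struct
  }

  best <- run_once(NULL)
  if (config$restarts > 1) {
    for (r in seq_len(config$restarts - 1L)) {
      cand <- run_once(config$seed + 7919L * r)
      if (cand$total_score > best$total_score) best <- cand
    }
  }
  best
}

score_structure_cached <- function(structure, scorer) {
  sc <- vapply(structure$nodes,
               function(v) scorer(v, structure$parents[[v]]),
               numeric(1))
  structure$per_node_scores <- sc
  structure$total_score <- sum(sc)
  structure
}

#' Iterative pathway expansion by sampling and relearning
#'
#' Alternates cluster-guided gene sampling with constrained hill
#' climbing. Each round draws a batch of genes (excluding those already
#' in the network), adds them as isolated nodes, relearns the structure,
#' and freezes every edge of the local optimum that touches a
#' previously-present node by promoting it to the working whitelist, so
#' that later rounds build on the accepted local structure.
#'
#' @param data Observations-by-genes matrix or `ExpressionMatrix`.
#' @param initial Seed `BNStructure` (the initial pathway mapping).
#' @param constraints A `ConstraintSet`.
#' @param plan A `SamplingPlan`.
#' @param model The `ClusterModel` used for sampling.
#' @param config A `LearnConfig`; `expansion_rounds` and `max_genes`
#'   control the loop, `seed` drives the sampling draws.
#' @return The final scored `BNStructure`.
#' @export
expand_network <- function(data, initial, constraints, plan, model,
                           config = learn_config()) {
  data <- bn_data(data)
  work_cs <- constraints
  current <- hill_climb(data, initial, work_cs, config)
  rounds <- config$expansion_rounds
  for (round in seq_len(rounds)) {
    if (length(current$nodes) >= config$max_genes) break
    n_new <- min(plan$batch_size,
                 max(0, config$max_genes - length(current$nodes)))
    batch <- suppressWarnings(
      sample_genes(plan, model, exclude = current$nodes, n = n_new,
                   seed = config$seed + 101L * round))
    batch <- intersect(batch, colnames(data))
    if (!length(batch)) break
    prev_nodes <- current$nodes
    # freeze the accepted local structure
    frozen <- bn_edges(current)
    wl <- unique(rbind(work_cs$whitelist, frozen))
    work_cs$whitelist <- wl
    struct <- bn_structure(c(prev_nodes, batch), bn_edges(current))
    current <- hill_climb(data, struct, work_cs, config)
    # freeze only edges incident to previously-present nodes
    new_edges <- bn_edges(current)
    inc <- new_edges$from %in% prev_nodes | new_edges$to %in% prev_nodes
    work_cs$whitelist <- unique(rbind(constraints$whitelist,
                                      new_edges[inc, , drop = FALSE]))
  }
  current
}

#' Enumerate all labeled DAGs over a small node set
#'
#' Generates every subset of ordered node pairs and keeps the acyclic
#' ones. Feasible up to 4-5 nodes (543 labeled DAGs on 4 nodes).
#'
#' @param nodes Character vector (length <= 5).
#' @return List of edge data frames, one per DAG.
#' @export
enumerate_dags <- function(nodes) {
  n <- length(nodes)
  if (n > 5) stop("exhaustive enumeration is limited to 5 nodes")
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    edges <- pairs[sel, , drop = FALSE]
    if (is_acyclic(edges, nodes)) out[[length(out) + 1L]] <- edges
  }
  out
}

#' Exhaustive best-scoring DAG
#'
#' Scores every labeled DAG over `nodes` by summed node-wise BIC and
#' returns the global optimum. Used as a reference for the local search
#' on small instances.
#'
#' @param data Observations-by-genes matrix.
#' @param nodes Character vector of columns to search over (<= 5).
#' @param dags Optional pre-enumerated DAG list from
#'   [enumerate_dags()] (reused across repeated calls on the same node
#'   set).
#' @return A scored `BNStructure` attaining the global maximum.
#' @export
exhaustive_best <- function(data, nodes = colnames(data), dags = NULL) {
  data <- as.matrix(data)
  cache <- new.env(parent = emptyenv())
  scorer <- function(v, ps) {
    key <- paste(v, paste(sort(ps), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (is.null(got)) { got <- node_bic(data, v, ps); cache[[key]] <- got }
    got
  }
  if (is.null(dags)) dags <- enumerate_dags(nodes)
  best <- NULL
  for (edges in dags) {
    s <- bn_structure(nodes, edges)
    s <- score_structure_cached(s, scorer)
    if (is.null(best) || s$total_score > best$total_score) best <- s
  }
  best
}
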