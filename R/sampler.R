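#' Build a cluster sampling plan for a pathway
#'
#' The pivot cluster is the one containing the most genes of the initial
#' pathway (ties go to the smaller cluster index). Each cluster c receives
#' raw weight 1 / (1 + d_c), where d_c is the Euclidean distance between
#' the mean profile of c and that of the pivot; the pivot (d = 0) thus
#' automatically takes the maximum weight. Weights are normalized to sum
#' to one.
#'
#' @param model A `ClusterModel`.
#' @param initial_genes Gene identifiers of the initially mapped pathway;
#'   at least one must be assigned in `model`.
#' @param batch_size Number of genes drawn per sampling round.
#' @param kernel Distance-to-weight kernel: `"inverse"` (1/(1+d),
#'   default) or `"softmax"` (exp(-d)).
#' @return A `SamplingPlan`: list with `pivot_cluster`, `cluster_weights`,
#'   `batch_size`.
#' @export
make_plan <- function(model, initial_genes, batch_size = 10L,
                      kernel = c("inverse", "softmax")) {
  kernel <- match.arg(kernel)
  present <- intersect(initial_genes, names(model$assignments))
  if (length(present) == 0) {
    stop("no initial pathway gene is assigned in the cluster model")
  }
  counts <- tabulate(model$assignments[present], nbins = model$k)
  pivot <- which.max(counts)   # first maximum = smallest index on ties
  d <- sqrt(rowSums(sweep(model$means, 2, model$means[pivot, ], "-")^2))
  raw <- switch(kernel, inverse = 1 / (1 + d), softmax = exp(-d))
  weights <- raw / sum(raw)
  structure(list(pivot_cluster = pivot, cluster_weights = weights,
                 batch_size = as.integer(batch_size)),
            class = "SamplingPlan")
}

#' @export
print.SamplingPlan <- function(x, ...) {
  cat(sprintf("SamplingPlan: pivot cluster %d, weights (%s), batch %d\n",
              x$pivot_cluster,
              paste(sprintf("%.3f", x$cluster_weights), collapse = ", "),
              x$batch_size))
  invisible(x)
}

#' Sample candidate genes from clusters
#'
#' Two-stage draw: a cluster is chosen by the plan's weights, then a gene
#' uniformly from that cluster's unused members. Sampled genes are
#' distinct and disjoint from `exclude`; fewer than `n` genes are
#' returned (with a warning for an empty pool) when the pool is
#' exhausted.
#'
#' @param plan A `SamplingPlan`.
#' @param model The `ClusterModel` the plan was built from.
#' @param exclude Gene identifiers that must not be drawn.
#' @param n Number of genes to draw; defaults to the plan's batch size.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return Character vector of sampled gene identifiers.
#' @export
sample_genes <- function(plan, model, exclude = character(0),
                         n = plan$batch_size, seed = 1L) {
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)

  pool <- split(names(model$assignments), model$assignments)
  pool <- lapply(pool, setdiff, y = exclude)
  # index pools by cluster number 1..k (clusters can be empty)
  full <- stats::setNames(vector("list", model$k), as.character(seq_len(model$k)))
  for (nm in names(pool)) full[[nm]] <- pool[[nm]]
  pool <- full

  out <- character(0)
  w <- plan$cluster_weights
  while (length(out) < n) {
    avail <- vapply(pool, length, integer(1)) > 0
    if (!any(avail)) {
      if (length(out) == 0) warning("gene pool exhausted: nothing to sample")
      break
    }
    wa <- w * avail
    cl <- sample.int(model$k, 1, prob = wa / sum(wa))
    g <- pool[[cl]][sample.int(length(pool[[cl]]), 1)]
    pool[[cl]] <- setdiff(pool[[cl]], g)
    out <- c(out, g)
  }
  out
}
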