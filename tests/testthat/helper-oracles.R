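# Independent oracles and small fixture builders shared across tests.
# These deliberately use different code paths from the package internals.

# Gaussian BIC by explicit normal equations + pointwise log-density sum
# (package path uses a QR decomposition and a closed-form log-likelihood)
oracle_bic <- function(data, node, parents = character(0)) {
  y <- data[, node]
  n <- length(y)
  if (length(parents) == 0) {
    fit <- rep(mean(y), n)
  } else {
    X <- cbind(1, data[, parents, drop = FALSE])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    fit <- as.vector(X %*% beta)
  }
  sigma2 <- max(sum((y - fit)^2) / n, 1e-12)
  loglik <- sum(dnorm(y, mean = fit, sd = sqrt(sigma2), log = TRUE))
  loglik - (length(parents) + 2) / 2 * log(n)
}

# one-sided hypergeometric upper-tail sum via binomial coefficients
# (package path uses stats::phyper)
oracle_fisher_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# random DAG over `nodes` with `n_edges` edges, consistent with a random
# topological order; returns edge data frame with beta coefficients
random_dag <- function(nodes, n_edges, beta_range = c(0.8, 1.2),
                       seed = 1L) {
  set.seed(seed)
  ord <- sample(nodes)
  pairs <- t(combn(length(ord), 2))
  sel <- sample(nrow(pairs), n_edges)
  data.frame(from = ord[pairs[sel, 1]], to = ord[pairs[sel, 2]],
             beta = sample(c(-1, 1), n_edges, replace = TRUE) *
               runif(n_edges, beta_range[1], beta_range[2]),
             stringsAsFactors = FALSE)
}

undirected_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  unique(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to)))
}

# single-term GO annotation table for a set of carrier genes
ann_for <- function(carriers, term = "GO:T1",
                    category = "biological_process") {
  data.frame(gene_id = carriers, go_term = term, category = category,
             stringsAsFactors = FALSE)
}

# one-cluster ClusterModel over the given genes, for sampler-driven tests
# that do not care about expression profiles
toy_model_bn <- function(genes) {
  structure(list(k = 1L, means = matrix(0, 1, 2),
                 variances = matrix(1, 1, 2), weights = 1,
                 assignments = setNames(rep(1L, length(genes)), genes),
                 posterior = NULL, loglik = NA_real_,
                 loglik_trace = NA_real_, seed = 1L, converged = TRUE),
            class = "ClusterModel")
}

# hand-built two-node KGML document used across knowledgebase tests
tiny_kgml <- function() {
  paste(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00001" org="ref" number="1" title="tiny">',
    '  <entry id="1" name="ko:K00001 ko:K00002" type="ortholog" reaction="rn:R00001"/>',
    '  <entry id="2" name="ko:K00003" type="ortholog"/>',
    '  <entry id="3" name="cpd:C00010" type="compound"/>',
    '  <relation entry1="1" entry2="2" type="ECrel"/>',
    '  <reaction id="R00001" name="rn:R00001" type="irreversible">',
    '    <substrate id="C00010" name="cpd:C00010"/>',
    '    <product id="C00020" name="cpd:C00020"/>',
    '  </reaction>',
    '</pathway>', sep = "\n")
}

# pathway with single-gene KO nodes wired as given; used to drive
# build_constraints with hand-chosen candidate edges
chain_pathway <- function(kos, edges_idx, pathway_id = "path:tst00009",
                          org = "ref") {
  nodes <- setNames(lapply(kos, function(k) list(kos = k,
                                                 genes = character(0))),
                    as.character(seq_along(kos)))
  edges <- data.frame(from = as.character(edges_idx[, 1]),
                      to = as.character(edges_idx[, 2]),
                      rel_type = "ECrel", directed = TRUE,
                      stringsAsFactors = FALSE)
  structure(list(pathway_id = pathway_id, org = org, nodes = nodes,
                 edges = edges,
                 reactions = data.frame(ko = character(0),
                                        reaction_id = character(0),
                                        substrate = character(0),
                                        product = character(0),
                                        stringsAsFactors = FALSE),
                 compounds = character(0)),
            class = "Pathway")
}
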