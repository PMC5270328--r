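#' Generate ground-truth pathway structure
#'
#' Builds `n_pathways` random DAG-structured pathways over KO groups.
#' Each pathway draws `genes_per_pathway` genes (consecutive pathways
#' share `n_overlap` genes, so pathways are disjoint-plus-overlap),
#' groups them into KO groups (a group holds two genes with probability
#' `multi_ko_prob`, exercising multi-molecule nodes), and wires the
#' groups with `edges_per_pathway` random edges drawn consistently with
#' a topological order. A fraction of pathway genes is marked withheld:
#' present in the expression data and KO table but excluded from the
#' initial mapping, emulating incomplete ortholog assignment.
#'
#' @param n_genes Total genes, including noise genes outside pathways.
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Genes drawn per pathway.
#' @param edges_per_pathway KO-group edges per pathway; must not exceed
#'   g(g-1)/2 for g groups.
#' @param n_withheld Genes withheld from the initial mapping (drawn from
#'   pathway genes that carry true edges).
#' @param n_overlap Genes shared between consecutive pathways.
#' @param multi_ko_prob Probability that a KO group holds two genes.
#' @param seed Integer seed; generation is deterministic.
#' @return A `SyntheticSuite` skeleton: list with `gene_ids`,
#'   `pathways` (list of `Pathway` objects carrying the true KO-level
#'   structure), `gene_to_ko`, `truth_edges` (gene-level from/to/pathway),
#'   `withheld`, `params`, `seed`.
#' @export
gen_truth <- function(n_genes = 300L, n_pathways = 3L,
                      genes_per_pathway = 20L, edges_per_pathway = 25L,
                      n_withheld = 10L, n_overlap = 2L,
                      multi_ko_prob = 0.2, seed = 1L) {
  stopifnot(n_genes >= 1, n_pathways >= 1, genes_per_pathway >= 1,
            edges_per_pathway >= 0)
  if (n_genes < n_pathways * genes_per_pathway) {
    stop("n_genes too small for the requested pathways")
  }
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  shuffled <- sample(gene_ids)

  pathways <- list()
  gene_to_ko <- data.frame(gene_id = character(0), ko = character(0),
                           stringsAsFactors = FALSE)
  truth <- list()
  ko_counter <- 0L
  rxn_counter <- 0L
  prev_block <- character(0)
  pos <- 1L
  for (p in seq_len(n_pathways)) {
    n_fresh <- genes_per_pathway - if (p > 1) n_overlap else 0L
    block <- shuffled[pos:(pos + n_fresh - 1L)]
    pos <- pos + n_fresh
    if (p > 1 && n_overlap > 0) {
      block <- c(prev_block[seq_len(n_overlap)], block)
    }
    prev_block <- block

    # partition the block into KO groups; shared genes keep their KO
    known <- gene_to_ko$ko[match(block, gene_to_ko$gene_id)]
    groups <- list()
    i <- 1L
    todo <- block[is.na(known)]
    for (ko in unique(known[!is.na(known)])) {
      groups[[ko]] <- block[!is.na(known) & known == ko]
    }
    while (i <= length(todo)) {
      ko_counter <- ko_counter + 1L
      ko <- sprintf("K%05d", ko_counter)
      size <- if (i < length(todo) && stats::runif(1) < multi_ko_prob) 2L
              else 1L
      groups[[ko]] <- todo[i:(i + size - 1L)]
      gene_to_ko <- rbind(gene_to_ko,
                          data.frame(gene_id = groups[[ko]], ko = ko,
                                     stringsAsFactors = FALSE))
      i <- i + size
    }
    g <- length(groups)
    max_edges <- g * (g - 1) / 2
    if (edges_per_pathway > max_edges) {
      stop(sprintf(
        "edges_per_pathway = %d infeasible for %d KO groups (max %d)",
        edges_per_pathway, g, max_edges))
    }
    ord <- sample(names(groups))          # topological order of KO groups
    pairs <- if (g >= 2) t(utils::combn(g, 2)) else matrix(0L, 0, 2)
    sel <- if (nrow(pairs)) sample(nrow(pairs), edges_per_pathway)
           else integer(0)
    nodes <- stats::setNames(lapply(ord, function(ko) {
      list(kos = ko, genes = character(0))
    }), as.character(seq_along(ord)))
    edges <- if (length(sel)) {
      data.frame(from = as.character(pairs[sel, 1]),
                 to = as.character(pairs[sel, 2]),
                 rel_type = sample(c("ECrel", "PPrel"), length(sel),
                                   replace = TRUE),
                 directed = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(0), to = character(0),
                 rel_type = character(0), directed = logical(0),
                 stringsAsFactors = FALSE)
    }
    # attach a reaction with compounds to roughly a third of the nodes
    reactions <- data.frame(ko = character(0), reaction_id = character(0),
                            substrate = character(0), product = character(0),
                            stringsAsFactors = FALSE)
    compounds <- character(0)
    for (id in names(nodes)) {
      if (stats::runif(1) < 1 / 3) {
        rxn_counter <- rxn_counter + 1L
        rid <- sprintf("R%05d", rxn_counter)
        cs <- sprintf("C%05d", sample.int(99999, 2))
        reactions <- rbind(reactions, data.frame(
          ko = nodes[[id]]$kos, reaction_id = rid,
          substrate = cs[1], product = cs[2], stringsAsFactors = FALSE))
        compounds <- union(compounds, cs)
      }
    }
    pw <- structure(list(pathway_id = sprintf("path:syn%05d", p),
                         org = "ref", nodes = nodes, edges = edges,
                         reactions = reactions,
                         compounds = sort(compounds)),
                    class = "Pathway")
    pathways[[p]] <- pw

    # gene-level truth: each child-group gene depends on every
    # parent-group gene
    if (nrow(edges)) {
      for (j in seq_len(nrow(edges))) {
        pa <- ord[as.integer(edges$from[j])]
        ch <- ord[as.integer(edges$to[j])]
        grid <- expand.grid(from = groups[[pa]], to = groups[[ch]],
                            stringsAsFactors = FALSE)
        grid$pathway <- pw$pathway_id
        truth[[length(truth) + 1L]] <- grid
      }
    }
  }
  truth_edges <- if (length(truth)) {
    te <- unique(do.call(rbind, truth))
    rownames(te) <- NULL
    te
  } else {
    data.frame(from = character(0), to = character(0),
               pathway = character(0), stringsAsFactors = FALSE)
  }

  connected <- unique(c(truth_edges$from, truth_edges$to))
  n_withheld <- min(n_withheld, length(connected))
  withheld <- if (n_withheld > 0) sort(sample(connected, n_withheld))
              else character(0)

  structure(list(gene_ids = gene_ids, pathways = pathways,
                 gene_to_ko = gene_to_ko, truth_edges = truth_edges,
                 withheld = withheld,
                 params = list(n_genes = n_genes, n_pathways = n_pathways,
                               genes_per_pathway = genes_per_pathway,
                               edges_per_pathway = edges_per_pathway,
                               n_overlap = n_overlap,
                               multi_ko_prob = multi_ko_prob),
                 seed = seed),
            class = "SyntheticSuite")
}

#' Simulate observations from a linear-Gaussian structural model
#'
#' Each node equals the weighted sum of its parents plus Gaussian noise,
#' evaluated in topological order. Exported because it also serves as a
#' plain benchmark generator for structure-recovery experiments.
#'
#' @param edges Edge data frame with columns `from`, `to` and `beta`.
#' @param nodes Character vector of all variables (isolated nodes
#'   allowed).
#' @param n Number of observations.
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return Numeric matrix, n rows by `length(nodes)` columns.
#' @export
sim_linear_gaussian <- function(edges, nodes, n, sigma = 1, seed = 1L) {
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  ord <- topo_sort(edges[, c("from", "to")], nodes)
  if (is.null(ord)) stop("edge set contains a directed cycle")
  x <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in ord) {
    sel <- edges$to == v
    x[, v] <- stats::rnorm(n, 0, sigma)
    if (any(sel)) {
      x[, v] <- x[, v] +
        x[, edges$from[sel], drop = FALSE] %*% edges$beta[sel]
    }
  }
  x
}

#' Generate a synthetic count matrix faithful to the truth network
#'
#' Latent log2 expression follows the gene-level truth DAG: each
#' pathway's root genes receive a pathway-specific condition signature
#' (so pathway members co-cluster) plus noise, and child genes are the
#' beta-weighted sum of their parents' deviations plus noise. Counts are
#' Poisson draws around depth-scaled powers of two of the latent values,
#' so the CPM > 1 filter and the log transform are both exercised; a
#' small fraction of noise genes is essentially silent and is removed by
#' the default filter.
#'
#' @param suite A `SyntheticSuite` from [gen_truth()].
#' @param n_conditions Number of conditions (columns).
#' @param beta_range Absolute edge-coefficient range; signs are positive
#'   so count data stay on scale.
#' @param sigma Structural noise standard deviation (log2 scale).
#' @param signature_sd Standard deviation of the per-pathway condition
#'   signature (log2 scale); 0 removes co-regulation entirely, leaving
#'   pure structural-equation signal.
#' @param depth Library-depth multiplier for the Poisson means.
#' @param silent_frac Fraction of noise genes made effectively silent.
#' @param seed Integer seed.
#' @return An `ExpressionMatrix` of raw counts, with attribute `betas`
#'   (the truth edges with their sampled coefficients) and `latent` (the
#'   latent log2 matrix).
#' @export
gen_expression <- function(suite, n_conditions = 14L,
                           beta_range = c(0.8, 1.2), sigma = 0.5,
                           signature_sd = 1, depth = 5,
                           silent_frac = 0.06, seed = 1L) {
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  genes <- suite$gene_ids
  n <- length(genes)
  edges <- suite$truth_edges
  edges$beta <- if (diff(range(beta_range)) == 0) {
    rep(beta_range[1], nrow(edges))
  } else {
    stats::runif(nrow(edges), beta_range[1], beta_range[2])
  }

  pathway_genes <- unique(c(edges$from, edges$to,
                            suite$gene_to_ko$gene_id))
  noise_genes <- setdiff(genes, pathway_genes)
  silent <- sample(noise_genes,
                   round(silent_frac * length(noise_genes)))

  baseline <- stats::setNames(stats::rnorm(n, mean = 6, sd = 1.2), genes)
  baseline[silent] <- stats::rnorm(length(silent), mean = -8, sd = 1)

  # pathway-specific condition signatures drive co-clustering
  sig <- matrix(0, n, n_conditions, dimnames = list(genes, NULL))
  for (p in seq_along(suite$pathways)) {
    pw <- suite$pathways[[p]]
    kos <- unlist(lapply(pw$nodes, `[[`, "kos"))
    members <- suite$gene_to_ko$gene_id[suite$gene_to_ko$ko %in% kos]
    s <- stats::rnorm(n_conditions, 0, signature_sd)
    sig[members, ] <- sig[members, , drop = FALSE] +
      matrix(s, length(members), n_conditions, byrow = TRUE)
  }

  ord <- topo_sort(edges[, c("from", "to")], genes)
  dev <- matrix(0, n, n_conditions, dimnames = list(genes, NULL))
  has_parent <- genes %in% edges$to
  for (v in ord) {
    eps <- stats::rnorm(n_conditions, 0, sigma)
    if (has_parent[match(v, genes)]) {
      sel <- edges$to == v
      dev[v, ] <- colSums(dev[edges$from[sel], , drop = FALSE] *
                            edges$beta[sel]) + eps
    } else {
      dev[v, ] <- sig[v, ] + eps
    }
  }
  latent <- baseline[genes] + dev
  mu <- depth * 2^latent
  counts <- matrix(stats::rpois(length(mu), lambda = pmin(mu, 1e7)),
                   n, n_conditions,
                   dimnames = list(genes,
                                   sprintf("cond%02d", seq_len(n_conditions))))
  out <- expression_matrix(counts, normalized = FALSE)
  attr(out, "betas") <- edges
  attr(out, "latent") <- latent
  out
}

#' Serialize a suite's pathways to KGML text
#'
#' @param suite A `SyntheticSuite`.
#' @return Named character vector of KGML documents, one per pathway.
#' @export
emit_kgml <- function(suite) {
  texts <- vapply(suite$pathways, write_kgml, character(1))
  names(texts) <- vapply(suite$pathways, function(p) p$pathway_id,
                         character(1))
  texts
}

#' Plant GO annotations with known pathway enrichment
#'
#' Each pathway gets a dedicated biological-process "pathway term"
#' annotated to each member gene with probability `p_share`, so edges
#' within a pathway share a term at a known expected rate; every gene
#' additionally receives one to three background terms drawn from a
#' common pool across the three categories.
#'
#' @param suite A `SyntheticSuite`.
#' @param p_share Probability a member gene carries its pathway term.
#' @param n_background_terms Size of the background term pool.
#' @param seed Integer seed.
#' @return Annotation data frame (`gene_id`, `go_term`, `category`).
#' @export
gen_annotations <- function(suite, p_share = 0.6,
                            n_background_terms = 30L, seed = 1L) {
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  rows <- list()
  for (p in seq_along(suite$pathways)) {
    pw <- suite$pathways[[p]]
    kos <- unlist(lapply(pw$nodes, `[[`, "kos"))
    members <- unique(
      suite$gene_to_ko$gene_id[suite$gene_to_ko$ko %in% kos])
    term <- sprintf("GO:P%04d", p)
    carry <- members[stats::runif(length(members)) < p_share]
    if (length(carry)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = carry, go_term = term, category = "biological_process",
        stringsAsFactors = FALSE)
    }
  }
  pool <- data.frame(
    go_term = sprintf("GO:B%04d", seq_len(n_background_terms)),
    category = sample(go_categories, n_background_terms, replace = TRUE),
    stringsAsFactors = FALSE)
  for (g in suite$gene_ids) {
    k <- sample.int(3, 1)
    sel <- sample.int(n_background_terms, k)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, go_term = pool$go_term[sel],
      category = pool$category[sel], stringsAsFactors = FALSE)
  }
  ann <- unique(do.call(rbind, rows))
  rownames(ann) <- NULL
  ann
}

#' Generate a complete synthetic benchmark suite
#'
#' Convenience wrapper producing structure, expression counts, KGML
#' documents and GO annotations from a single seed (stage seeds are
#' fixed offsets, so regeneration is byte-identical).
#'
#' @inheritParams gen_truth
#' @inheritParams gen_expression
#' @param p_share Pathway-term annotation probability, see
#'   [gen_annotations()].
#' @return A `SyntheticSuite` with all fields populated: `counts`,
#'   `kgml`, `annotations`, `betas` in addition to the skeleton fields.
#' @export
gen_suite <- function(n_genes = 300L, n_pathways = 3L,
                      genes_per_pathway = 20L, edges_per_pathway = 25L,
                      n_withheld = 10L, n_conditions = 14L,
                      beta_range = c(0.8, 1.2), sigma = 0.5,
                      signature_sd = 1, depth = 5, p_share = 0.6,
                      seed = 1L) {
  suite <- gen_truth(n_genes = n_genes, n_pathways = n_pathways,
                     genes_per_pathway = genes_per_pathway,
                     edges_per_pathway = edges_per_pathway,
                     n_withheld = n_withheld, seed = seed)
  counts <- gen_expression(suite, n_conditions = n_conditions,
                           beta_range = beta_range, sigma = sigma,
                           signature_sd = signature_sd, depth = depth,
                           seed = seed + 1L)
  suite$counts <- counts
  suite$betas <- attr(counts, "betas")
  suite$kgml <- emit_kgml(suite)
  suite$annotations <- gen_annotations(suite, p_share = p_share,
                                       seed = seed + 2L)
  suite
}

#' @export
print.SyntheticSuite <- function(x, ...) {
  cat(sprintf(
    "SyntheticSuite (seed %d): %d genes, %d pathway(s), %d truth edge(s), %d withheld\n",
    x$seed, length(x$gene_ids), length(x$pathways), nrow(x$truth_edges),
    length(x$withheld)))
  invisible(x)
}

#' KO-level target edges of a pathway
#'
#' Expands a pathway's node-pair edges to KO-pair edges, the reference
#' edge set used for recall/precision evaluation.
#'
#' @param pathway A `Pathway`.
#' @return Edge data frame with columns `from`, `to` (KO identifiers).
#' @export
target_ko_edges <- function(pathway) {
  out <- list()
  if (nrow(pathway$edges)) {
    for (i in seq_len(nrow(pathway$edges))) {
      e <- pathway$edges[i, ]
      grid <- expand.grid(from = pathway$nodes[[e$from]]$kos,
                          to = pathway$nodes[[e$to]]$kos,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$from != grid$to, , drop = FALSE]
      if (nrow(grid)) out[[length(out) + 1L]] <- grid
    }
  }
  if (!length(out)) return(empty_edges())
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Write a synthetic suite to disk
#'
#' Writes `counts.tsv`, `gene2ko.tsv`, `go.tsv`, `truth_edges.tsv` and
#' one `pathway_<i>.kgml` per pathway into `dir`.
#'
#' @param suite A complete `SyntheticSuite` (see [gen_suite()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "counts.tsv")
  utils::write.table(
    data.frame(gene_id = rownames(suite$counts),
               unclass(suite$counts), check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "gene2ko.tsv")
  utils::write.table(suite$gene_to_ko, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "go.tsv")
  utils::write.table(suite$annotations, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth_edges.tsv")
  utils::write.table(suite$truth_edges, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  for (i in seq_along(suite$kgml)) {
    f <- file.path(dir, sprintf("pathway_%d.kgml", i))
    writeLines(suite$kgml[[i]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "withheld.tsv")
  utils::write.table(data.frame(gene_id = suite$withheld), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
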