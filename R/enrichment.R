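#' Read a GO annotation table
#'
#' @param file TSV with columns gene id, GO term, category. Categories
#'   must be one of `biological_process`, `molecular_function`,
#'   `cellular_component`.
#' @return Data frame with columns `gene_id`, `go_term`, `category`.
#' @export
read_annotations <- function(file) {
  df <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(gene_id = as.character(df[[1]]),
                    go_term = as.character(df[[2]]),
                    category = as.character(df[[3]]),
                    stringsAsFactors = FALSE)
  validate_annotations(out)
}

go_categories <- c("biological_process", "molecular_function",
                   "cellular_component")

validate_annotations <- function(annotations) {
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("gene_id", "go_term", "category") %in% names(annotations)))
  bad <- !(annotations$category %in% go_categories)
  if (any(bad)) {
    stop("unknown GO category: ",
         paste(unique(annotations$category[bad]), collapse = ", "))
  }
  unique(annotations)
}

#' GO-term over-representation by the one-sided Fisher exact test
#'
#' For every GO term annotated to at least one pathway gene, tests
#' over-representation of the term in the pathway against the background
#' with a one-sided (greater) Fisher exact test on the 2x2 table
#' (k, n - k; K - k, N - n - K + k), where k pathway genes of n carry the
#' term and K background genes of N do. The p-value is the hypergeometric
#' upper tail P(X >= k). Raw p-values are reported (flagged at
#' `p < alpha`); Benjamini-Hochberg adjustment is available via
#' `adjust = "BH"`.
#'
#' @param pathway_genes Character vector, a subset of `background`.
#' @param background Character vector of all genes under consideration.
#' @param annotations Annotation data frame (`gene_id`, `go_term`,
#'   `category`).
#' @param alpha Significance level for the `significant` flag.
#' @param adjust `"none"` (default, raw p-values) or `"BH"`.
#' @return Data frame of class `EnrichmentResult` with columns `go_term`,
#'   `category`, `k`, `K`, `n`, `N`, `p_value`, `significant`, sorted by
#'   ascending p-value.
#' @export
fisher_enrichment <- function(pathway_genes, background, annotations,
                              alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pathway_genes <- unique(as.character(pathway_genes))
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background must be nonempty")
  if (!all(pathway_genes %in% background)) {
    stop("pathway genes must be a subset of the background")
  }
  annotations <- validate_annotations(annotations)
  annotations <- annotations[annotations$gene_id %in% background, ,
                             drop = FALSE]
  n <- length(pathway_genes)
  N <- length(background)

  terms <- unique(annotations[annotations$gene_id %in% pathway_genes,
                              c("go_term", "category")])
  if (!nrow(terms)) {
    out <- data.frame(go_term = character(0), category = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("EnrichmentResult", class(out))
    return(out)
  }
  carriers <- split(annotations$gene_id,
                    paste(annotations$go_term, annotations$category,
                          sep = "\r"))
  key <- paste(terms$go_term, terms$category, sep = "\r")
  k <- integer(nrow(terms)); K <- integer(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    carr <- unique(carriers[[key[i]]])
    K[i] <- length(carr)
    k[i] <- sum(pathway_genes %in% carr)
  }
  # upper tail P(X >= k) of Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- pmin(p, 1)
  p_use <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  out <- data.frame(go_term = terms$go_term, category = terms$category,
                    k = k, K = K, n = n, N = N, p_value = p,
                    significant = p_use < alpha, stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adjusted <- p_use
  out <- out[order(out$p_value, out$go_term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' GO-sharing statistics over network edges
#'
#' Measures how often connected gene pairs share functional annotation:
#' the fraction of edges whose endpoint genes share at least one
#' identical GO term, and per GO category the fraction of edges whose
#' endpoints share at least one term of that category. Edges with an
#' unannotated endpoint count as non-sharing.
#'
#' @param edges Gene-pair edge data frame (`from`, `to`).
#' @param annotations Annotation data frame (`gene_id`, `go_term`,
#'   `category`).
#' @return List with `n_edges`, `share_identical` (overall fraction) and
#'   `share_by_category` (named numeric over the three GO categories).
#' @export
edge_go_stats <- function(edges, annotations) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) stop("edge set must be nonempty")
  annotations <- validate_annotations(annotations)
  terms_of <- split(paste(annotations$go_term, annotations$category,
                          sep = "\r"),
                    annotations$gene_id)
  share_any <- logical(nrow(edges))
  share_cat <- matrix(FALSE, nrow(edges), length(go_categories),
                      dimnames = list(NULL, go_categories))
  for (i in seq_len(nrow(edges))) {
    ta <- terms_of[[as.character(edges$from[i])]]
    tb <- terms_of[[as.character(edges$to[i])]]
    if (is.null(ta) || is.null(tb)) next
    shared <- intersect(ta, tb)
    if (!length(shared)) next
    share_any[i] <- TRUE
    cats <- vapply(strsplit(shared, "\r", fixed = TRUE), `[`, "", 2)
    share_cat[i, unique(cats)] <- TRUE
  }
  list(n_edges = nrow(edges),
       share_identical = mean(share_any),
       share_by_category = colMeans(share_cat))
}
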