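#' Re-introduce cycle-breaking edges into a learned network
#'
#' Bayesian-network learning requires an acyclic whitelist, so
#' cycle-closing (and species-excluded) edges of the initial mapping are
#' withheld during constraint construction. This step amends them back
#' into the learned gene network to restore feedback reactions; the
#' result may legitimately contain cycles.
#'
#' @param learned A `BNStructure` or an edge data frame (`from`, `to`),
#'   optionally with a `provenance` column.
#' @param dropped_edges Data frame of directed gene pairs (`from`, `to`)
#'   withheld during whitelist construction (see
#'   `build_constraints()$dropped`).
#' @return Edge data frame with columns `from`, `to`, `provenance`
#'   (existing tags preserved; re-introduced edges tagged `"amended"`),
#'   without duplicates.
#' @export
amend_cycles <- function(learned, dropped_edges = empty_edges()) {
  edges <- if (inherits(learned, "BNStructure")) bn_edges(learned)
           else as.data.frame(learned)
  if (is.null(edges$provenance)) edges$provenance <- "learned"
  edges <- edges[, c("from", "to", "provenance")]
  dropped_edges <- as.data.frame(dropped_edges)
  if (nrow(dropped_edges)) {
    add <- data.frame(from = as.character(dropped_edges$from),
                      to = as.character(dropped_edges$to),
                      provenance = "amended", stringsAsFactors = FALSE)
    add <- add[!(edge_key(add$from, add$to) %in%
                   edge_key(edges$from, edges$to)), , drop = FALSE]
    edges <- rbind(edges, add)
  }
  edges <- edges[!duplicated(edge_key(edges$from, edges$to)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Collapse a gene-level network to KO-group nodes
#'
#' Genes sharing a KO number are grouped into a single node; parallel
#' gene edges between the same KO pair merge into one KO-level edge that
#' retains all contributing gene pairs and the strongest provenance
#' (whitelist over learned over amended). Genes without a KO assignment
#' become singleton pseudo-KO nodes (prefix `gene:`) with a warning.
#'
#' @param graph Gene-level edge data frame (`from`, `to`, optional
#'   `provenance`), e.g. from [amend_cycles()].
#' @param gene_to_ko Data frame with columns `gene_id`, `ko`.
#' @return An `AssembledPathway`: list with `ko_nodes` (named list,
#'   KO -> member genes), `edges` (data frame from_ko/to_ko/provenance/
#'   gene_pairs) and `compounds` (empty until [attach_compounds()]).
#' @export
group_by_ko <- function(graph, gene_to_ko) {
  graph <- as.data.frame(graph)
  if (is.null(graph$provenance)) graph$provenance <- "learned"
  gene_to_ko <- normalize_gene_to_ko(gene_to_ko)
  # first KO wins for genes assigned to several (stable, documented)
  ko_of <- gene_to_ko$ko[!duplicated(gene_to_ko$gene_id)]
  names(ko_of) <- gene_to_ko$gene_id[!duplicated(gene_to_ko$gene_id)]

  genes <- unique(c(graph$from, graph$to))
  unassigned <- genes[!(genes %in% names(ko_of))]
  if (length(unassigned)) {
    warning(sprintf("%d gene(s) without KO kept as singleton nodes",
                    length(unassigned)))
    pseudo <- paste0("gene:", unassigned)
    names(pseudo) <- unassigned
    ko_of <- c(ko_of, pseudo)
  }

  ko_nodes <- lapply(split(names(ko_of), ko_of), sort)
  ko_nodes <- ko_nodes[vapply(ko_nodes,
                              function(g) any(g %in% genes), logical(1))]

  rank <- c(whitelist = 1L, learned = 2L, amended = 3L)
  agg <- list()
  if (nrow(graph)) {
    for (i in seq_len(nrow(graph))) {
      ka <- ko_of[[graph$from[i]]]
      kb <- ko_of[[graph$to[i]]]
      if (ka == kb) next            # intra-group edges collapse away
      key <- paste(ka, kb, sep = "|")
      pair <- paste(graph$from[i], graph$to[i], sep = "->")
      cur <- agg[[key]]
      if (is.null(cur)) {
        agg[[key]] <- list(from_ko = ka, to_ko = kb,
                           provenance = graph$provenance[i],
                           gene_pairs = pair)
      } else {
        cur$gene_pairs <- union(cur$gene_pairs, pair)
        if (rank[[graph$provenance[i]]] < rank[[cur$provenance]]) {
          cur$provenance <- graph$provenance[i]
        }
        agg[[key]] <- cur
      }
    }
  }
  edges <- if (length(agg)) {
    do.call(rbind, lapply(agg, function(a) data.frame(
      from_ko = a$from_ko, to_ko = a$to_ko, provenance = a$provenance,
      gene_pairs = paste(sort(a$gene_pairs), collapse = ";"),
      stringsAsFactors = FALSE)))
  } else {
    data.frame(from_ko = character(0), to_ko = character(0),
               provenance = character(0), gene_pairs = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(ko_nodes = ko_nodes, edges = edges,
                 compounds = data.frame(ko = character(0),
                                        compound = character(0),
                                        role = character(0),
                                        stringsAsFactors = FALSE)),
            class = "AssembledPathway")
}

#' @export
print.AssembledPathway <- function(x, ...) {
  cat(sprintf(
    "AssembledPathway: %d KO nodes, %d edges, %d compound link(s)\n",
    length(x$ko_nodes), nrow(x$edges), nrow(x$compounds)))
  invisible(x)
}

#' Attach reaction compounds to an assembled pathway
#'
#' For each KO node with a reaction record in the knowledgebase, links
#' its substrate and product compounds as compound nodes. Compounds are
#' presentation-layer only: they never participate in scoring. The
#' operation is idempotent.
#'
#' @param pathway An `AssembledPathway`.
#' @param kb A `Knowledgebase` whose `reactions` carry substrate/product
#'   compound identifiers.
#' @return The pathway with its `compounds` table populated.
#' @export
attach_compounds <- function(pathway, kb) {
  rx <- kb$reactions
  rx <- rx[rx$ko %in% names(pathway$ko_nodes), , drop = FALSE]
  links <- pathway$compounds
  if (nrow(rx)) {
    subs <- rx[!is.na(rx$substrate), c("ko", "substrate")]
    prods <- rx[!is.na(rx$product), c("ko", "product")]
    links <- rbind(
      links,
      if (nrow(subs)) data.frame(ko = subs$ko, compound = subs$substrate,
                                 role = "substrate",
                                 stringsAsFactors = FALSE),
      if (nrow(prods)) data.frame(ko = prods$ko, compound = prods$product,
                                  role = "product",
                                  stringsAsFactors = FALSE))
  }
  links <- unique(links)
  links <- links[order(links$ko, links$compound, links$role), , drop = FALSE]
  rownames(links) <- NULL
  pathway$compounds <- links
  pathway
}

#' Export an assembled pathway as an igraph object
#'
#' KO nodes and compound nodes are typed; edge provenance follows the
#' green/red colour convention (whitelist = green, learned = red,
#' amended = orange) with compounds in yellow.
#'
#' @param pathway An `AssembledPathway`.
#' @return An `igraph` graph, suitable for
#'   `igraph::write_graph(..., format = "graphml")` or plotting.
#' @export
as_igraph <- function(pathway) {
  kos <- names(pathway$ko_nodes)
  cpds <- unique(pathway$compounds$compound)
  verts <- data.frame(
    name = c(kos, cpds),
    type = c(rep("ko", length(kos)), rep("compound", length(cpds))),
    color = c(rep("lightblue", length(kos)), rep("yellow", length(cpds))),
    stringsAsFactors = FALSE)
  ecol <- c(whitelist = "green", learned = "red", amended = "orange")
  e1 <- if (nrow(pathway$edges)) {
    data.frame(from = pathway$edges$from_ko, to = pathway$edges$to_ko,
               provenance = pathway$edges$provenance,
               color = unname(ecol[pathway$edges$provenance]),
               stringsAsFactors = FALSE)
  } else NULL
  e2 <- if (nrow(pathway$compounds)) {
    cp <- pathway$compounds
    data.frame(from = ifelse(cp$role == "substrate", cp$compound, cp$ko),
               to = ifelse(cp$role == "substrate", cp$ko, cp$compound),
               provenance = "compound", color = "yellow",
               stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind(e1, e2)
  if (is.null(edges)) edges <- data.frame(from = character(0),
                                          to = character(0),
                                          provenance = character(0),
                                          color = character(0))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Write a network as a SIF (simple interaction format) file
#'
#' @param edges Edge data frame (`from`, `to`, optional `provenance` used
#'   as the interaction type) or an `AssembledPathway`.
#' @param file Output path.
#' @return Invisibly, the lines written.
#' @export
write_sif <- function(edges, file) {
  if (inherits(edges, "AssembledPathway")) {
    edges <- data.frame(from = edges$edges$from_ko,
                        to = edges$edges$to_ko,
                        provenance = edges$edges$provenance,
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)
  type <- if (is.null(edges$provenance)) rep("edge", nrow(edges))
          else edges$provenance
  lines <- sprintf("%s\t%s\t%s", edges$from, type, edges$to)
  writeLines(lines, file)
  invisible(lines)
}
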