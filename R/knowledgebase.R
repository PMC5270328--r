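#' Parse a KGML pathway document
#'
#' Reads a KEGG Markup Language (KGML) file into a `Pathway` object.
#' Ortholog entries become KO-group nodes (one node may carry several KO
#' numbers), compound entries are collected, relation elements become
#' typed directed edges between nodes, and reaction elements attach
#' substrate/product compound identifiers to the KO nodes that carry the
#' reaction.
#'
#' @param document Path to a KGML file, or a single character string of
#'   KGML XML.
#' @return A `Pathway`: list with `pathway_id`, `org` (organism code),
#'   `nodes` (named list, node id -> list(kos, genes)), `edges`
#'   (data frame from/to/rel_type/directed), `reactions` (data frame
#'   ko/reaction_id/substrate/product) and `compounds` (character set).
#' @export
parse_kgml <- function(document) {
  doc <- if (is.character(document) && length(document) == 1 &&
             !grepl("<", document, fixed = TRUE)) {
    xml2::read_xml(document)
  } else {
    xml2::read_xml(paste(document, collapse = "\n"))
  }
  root <- doc
  pathway_id <- xml2::xml_attr(root, "name")
  org <- xml2::xml_attr(root, "org")
  if (is.na(org)) org <- "ko"

  nodes <- list()
  compounds <- character(0)
  entry_kind <- character(0)
  for (entry in xml2::xml_find_all(root, ".//entry")) {
    id <- xml2::xml_attr(entry, "id")
    type <- xml2::xml_attr(entry, "type")
    name <- xml2::xml_attr(entry, "name")
    ids <- sub("^[a-z]+:", "", strsplit(name, "\\s+")[[1]])
    if (identical(type, "compound")) {
      compounds <- union(compounds, ids)
      entry_kind[id] <- "compound"
    } else if (type %in% c("ortholog", "gene", "enzyme")) {
      nodes[[id]] <- list(kos = ids, genes = character(0))
      entry_kind[id] <- "node"
    } else {
      entry_kind[id] <- "other"
    }
  }

  edges <- data.frame(from = character(0), to = character(0),
                      rel_type = character(0), directed = logical(0),
                      stringsAsFactors = FALSE)
  known_types <- c("ECrel", "PPrel", "GErel")
  for (rel in xml2::xml_find_all(root, ".//relation")) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    type <- xml2::xml_attr(rel, "type")
    if (!(type %in% known_types)) {
      warning(sprintf("relation type '%s' not recognised; stored as 'other'",
                      type))
      type <- "other"
    }
    if (is.null(nodes[[e1]]) || is.null(nodes[[e2]])) next
    edges <- rbind(edges, data.frame(from = e1, to = e2, rel_type = type,
                                     directed = TRUE,
                                     stringsAsFactors = FALSE))
  }

  reactions <- data.frame(ko = character(0), reaction_id = character(0),
                          substrate = character(0), product = character(0),
                          stringsAsFactors = FALSE)
  # map reaction name -> KOs of the entries declaring it
  entry_rxn <- list()
  for (entry in xml2::xml_find_all(root, ".//entry")) {
    rxn <- xml2::xml_attr(entry, "reaction")
    id <- xml2::xml_attr(entry, "id")
    if (!is.na(rxn) && !is.null(nodes[[id]])) {
      for (r in strsplit(rxn, "\\s+")[[1]]) {
        r <- sub("^rn:", "", r)
        entry_rxn[[r]] <- union(entry_rxn[[r]], nodes[[id]]$kos)
      }
    }
  }
  for (rxn in xml2::xml_find_all(root, ".//reaction")) {
    rid <- sub("^rn:", "", xml2::xml_attr(rxn, "name"))
    subs <- sub("^[a-z]+:", "",
                xml2::xml_attr(xml2::xml_find_all(rxn, "./substrate"), "name"))
    prods <- sub("^[a-z]+:", "",
                 xml2::xml_attr(xml2::xml_find_all(rxn, "./product"), "name"))
    kos <- entry_rxn[[rid]]
    if (is.null(kos)) next
    for (ko in kos) {
      grid <- expand.grid(substrate = if (length(subs)) subs else NA_character_,
                          product = if (length(prods)) prods else NA_character_,
                          stringsAsFactors = FALSE)
      reactions <- rbind(reactions,
                         data.frame(ko = ko, reaction_id = rid,
                                    substrate = grid$substrate,
                                    product = grid$product,
                                    stringsAsFactors = FALSE))
    }
    compounds <- union(compounds, c(subs, prods))
  }

  structure(list(pathway_id = pathway_id, org = org, nodes = nodes,
                 edges = edges, reactions = reactions,
                 compounds = sort(compounds)),
            class = "Pathway")
}

#' @export
print.Pathway <- function(x, ...) {
  cat(sprintf("Pathway %s [%s]: %d KO-group nodes, %d edges, %d compounds\n",
              x$pathway_id, x$org, length(x$nodes), nrow(x$edges),
              length(x$compounds)))
  invisible(x)
}

#' Write a Pathway to KGML
#'
#' Serializes a `Pathway` back to KGML XML, the inverse of [parse_kgml()]
#' for the fields this package uses (nodes, typed relations, reactions and
#' compounds).
#'
#' @param pathway A `Pathway`.
#' @param file Optional path; when `NULL` the XML text is returned.
#' @return The KGML text, invisibly when written to `file`.
#' @export
write_kgml <- function(pathway, file = NULL) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    "<?xml version=\"1.0\"?>",
    sprintf("<pathway name=\"%s\" org=\"%s\" number=\"0\" title=\"%s\">",
            esc(pathway$pathway_id), esc(pathway$org),
            esc(pathway$pathway_id)))
  rxn_by_ko <- split(pathway$reactions, pathway$reactions$ko)
  next_id <- length(pathway$nodes) + 1L
  for (id in names(pathway$nodes)) {
    kos <- pathway$nodes[[id]]$kos
    rids <- unique(unlist(lapply(kos, function(k) {
      r <- rxn_by_ko[[k]]; if (is.null(r)) character(0) else r$reaction_id
    })))
    rattr <- if (length(rids)) {
      sprintf(" reaction=\"%s\"", paste0("rn:", rids, collapse = " "))
    } else ""
    lines <- c(lines, sprintf(
      "  <entry id=\"%s\" name=\"%s\" type=\"ortholog\"%s/>",
      id, paste0("ko:", kos, collapse = " "), rattr))
  }
  for (cpd in pathway$compounds) {
    lines <- c(lines, sprintf(
      "  <entry id=\"%d\" name=\"cpd:%s\" type=\"compound\"/>",
      next_id, cpd))
    next_id <- next_id + 1L
  }
  if (nrow(pathway$edges)) {
    for (i in seq_len(nrow(pathway$edges))) {
      e <- pathway$edges[i, ]
      lines <- c(lines, sprintf(
        "  <relation entry1=\"%s\" entry2=\"%s\" type=\"%s\"/>",
        e$from, e$to, e$rel_type))
    }
  }
  if (nrow(pathway$reactions)) {
    for (rid in unique(pathway$reactions$reaction_id)) {
      rx <- pathway$reactions[pathway$reactions$reaction_id == rid, ]
      subs <- unique(rx$substrate[!is.na(rx$substrate)])
      prods <- unique(rx$product[!is.na(rx$product)])
      lines <- c(lines, sprintf(
        "  <reaction id=\"%s\" name=\"rn:%s\" type=\"irreversible\">",
        rid, rid))
      for (s in subs) lines <- c(lines, sprintf(
        "    <substrate id=\"%s\" name=\"cpd:%s\"/>", s, s))
      for (p in prods) lines <- c(lines, sprintf(
        "    <product id=\"%s\" name=\"cpd:%s\"/>", p, p))
      lines <- c(lines, "  </reaction>")
    }
  }
  lines <- c(lines, "</pathway>")
  text <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

#' Pool KO-KO relations across pathways into a knowledgebase
#'
#' Every node-pair edge is expanded to all KO-number pairs between the two
#' nodes (multi-molecule nodes contribute one relation per KO pair).
#' Self-relations are dropped with a warning; duplicate relations from
#' different pathways are merged, pooling their organism codes and
#' pathway provenance. Reaction records (KO, reaction, substrate,
#' product) are pooled alongside for compound attachment.
#'
#' @param pathways A list of `Pathway` objects.
#' @return A `Knowledgebase`: list with `relations` (data frame
#'   source_ko/target_ko/rel_type/directed/species/pathways) and
#'   `reactions` (pooled reaction data frame).
#' @export
build_knowledgebase <- function(pathways) {
  if (inherits(pathways, "Pathway")) pathways <- list(pathways)
  if (length(pathways) == 0) stop("at least one pathway is required")
  recs <- list()
  self_dropped <- 0L
  for (pw in pathways) {
    if (!nrow(pw$edges)) next
    for (i in seq_len(nrow(pw$edges))) {
      e <- pw$edges[i, ]
      kos_a <- pw$nodes[[e$from]]$kos
      kos_b <- pw$nodes[[e$to]]$kos
      for (a in kos_a) for (b in kos_b) {
        if (a == b) { self_dropped <- self_dropped + 1L; next }
        key <- paste(a, b, e$rel_type, sep = "|")
        cur <- recs[[key]]
        if (is.null(cur)) {
          recs[[key]] <- list(source_ko = a, target_ko = b,
                              rel_type = e$rel_type, directed = e$directed,
                              species = pw$org, pathways = pw$pathway_id)
        } else {
          cur$species <- union(cur$species, pw$org)
          cur$pathways <- union(cur$pathways, pw$pathway_id)
          recs[[key]] <- cur
        }
      }
    }
  }
  if (self_dropped > 0) {
    warning(sprintf("%d self-relation(s) dropped", self_dropped))
  }
  if (length(recs) == 0) {
    warning("knowledgebase is empty: no relations found in input pathways")
    relations <- data.frame(source_ko = character(0), target_ko = character(0),
                            rel_type = character(0), directed = logical(0),
                            species = character(0), pathways = character(0),
                            stringsAsFactors = FALSE)
  } else {
    relations <- do.call(rbind, lapply(recs, function(r) {
      data.frame(source_ko = r$source_ko, target_ko = r$target_ko,
                 rel_type = r$rel_type, directed = r$directed,
                 species = paste(sort(r$species), collapse = ","),
                 pathways = paste(sort(r$pathways), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    relations <- relations[order(relations$source_ko, relations$target_ko,
                                 relations$rel_type), , drop = FALSE]
    rownames(relations) <- NULL
  }
  reactions <- do.call(rbind, c(list(data.frame(
    ko = character(0), reaction_id = character(0),
    substrate = character(0), product = character(0),
    stringsAsFactors = FALSE)),
    lapply(pathways, function(p) p$reactions)))
  reactions <- unique(reactions)
  rownames(reactions) <- NULL
  structure(list(relations = relations, reactions = reactions),
            class = "Knowledgebase")
}

#' @export
print.Knowledgebase <- function(x, ...) {
  cat(sprintf("Knowledgebase: %d KO-KO relations, %d reaction records\n",
              nrow(x$relations), nrow(x$reactions)))
  invisible(x)
}

#' Read a gene-to-KO assignment table
#'
#' @param file TSV with gene identifiers in the first column and K numbers
#'   in the second.
#' @return Data frame with columns `gene_id`, `ko`.
#' @export
read_gene_to_ko <- function(file) {
  df <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(df[[1]]), ko = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Populate a pathway's nodes with member genes
#'
#' Assigns genes to the KO-group nodes of a pathway by matching their KO
#' numbers (the initial mapping step). Nodes that receive no gene are
#' retained and reported in the `empty_nodes` attribute.
#'
#' @param pathway A `Pathway`.
#' @param gene_to_ko Data frame with columns `gene_id` and `ko`.
#' @return The `Pathway` with member-gene sets filled in.
#' @export
initial_mapping <- function(pathway, gene_to_ko) {
  gene_to_ko <- normalize_gene_to_ko(gene_to_ko)
  bad <- !grepl("^K\\d+", gene_to_ko$ko)
  if (any(bad)) {
    warning(sprintf("%d assignment(s) to malformed KO identifiers ignored",
                    sum(bad)))
    gene_to_ko <- gene_to_ko[!bad, , drop = FALSE]
  }
  by_ko <- split(gene_to_ko$gene_id, gene_to_ko$ko)
  for (id in names(pathway$nodes)) {
    genes <- unique(unlist(by_ko[pathway$nodes[[id]]$kos], use.names = FALSE))
    pathway$nodes[[id]]$genes <- sort(if (is.null(genes)) character(0)
                                      else genes)
  }
  empty <- names(pathway$nodes)[vapply(pathway$nodes,
                                       function(n) length(n$genes) == 0,
                                       logical(1))]
  attr(pathway, "empty_nodes") <- empty
  pathway
}

normalize_gene_to_ko <- function(gene_to_ko) {
  df <- as.data.frame(gene_to_ko)
  out <- data.frame(gene_id = as.character(df[[1]]),
                    ko = as.character(df[[2]]), stringsAsFactors = FALSE)
  unique(out)
}

#' Gene-level edges induced by a mapped pathway
#'
#' Expands each node-pair edge of a pathway into all ordered pairs of
#' member genes (self-pairs excluded), annotated with the KO pair that
#' licenses them.
#'
#' @param pathway A `Pathway` whose nodes carry member genes
#'   (see [initial_mapping()]).
#' @return Data frame with columns `from`, `to`, `source_ko`, `target_ko`,
#'   `rel_type`.
#' @export
gene_level_edges <- function(pathway) {
  out <- list()
  if (nrow(pathway$edges)) {
    for (i in seq_len(nrow(pathway$edges))) {
      e <- pathway$edges[i, ]
      nu <- pathway$nodes[[e$from]]
      nv <- pathway$nodes[[e$to]]
      if (!length(nu$genes) || !length(nv$genes)) next
      grid <- expand.grid(from = nu$genes, to = nv$genes,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$from != grid$to, , drop = FALSE]
      if (!nrow(grid)) next
      # license each gene pair with the KO pair(s) of its parent nodes
      kg <- expand.grid(source_ko = nu$kos, target_ko = nv$kos,
                        stringsAsFactors = FALSE)
      kg <- kg[kg$source_ko != kg$target_ko, , drop = FALSE]
      if (!nrow(kg)) next
      for (j in seq_len(nrow(kg))) {
        out[[length(out) + 1L]] <- data.frame(
          from = grid$from, to = grid$to,
          source_ko = kg$source_ko[j], target_ko = kg$target_ko[j],
          rel_type = e$rel_type, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(0), to = character(0),
                      source_ko = character(0), target_ko = character(0),
                      rel_type = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Derive whitelist/blacklist constraints for network learning
#'
#' The allowed-edge set contains every directed gene pair whose KO pair
#' carries a relation in the knowledgebase (undirected relations license
#' both orientations); its complement is the implicit blacklist. Whitelist
#' candidates are the gene-level edges of the initially mapped pathway
#' whose KO-pair relation exists in the knowledgebase; candidates
#' supported only by relations observed in `exclude_species` are skipped,
#' and the remainder are inserted in lexicographic (from, to) order, each
#' insertion rejected if it would close a directed cycle. Rejected and
#' skipped candidates are retained with their reason for later cycle
#' amendment.
#'
#' @param initial A mapped `Pathway` (member genes populated).
#' @param kb A `Knowledgebase`.
#' @param gene_to_ko Gene-to-KO table used to expand KO relations to gene
#'   pairs for the allowed set (may be broader than the table used for the
#'   initial mapping).
#' @param exclude_species Organism code whose exclusive relations are kept
#'   out of the whitelist, or `NULL`.
#' @return A `ConstraintSet`: list with `whitelist`, `allowed` and
#'   `dropped` (from/to/reason) edge data frames.
#' @export
build_constraints <- function(initial, kb, gene_to_ko,
                              exclude_species = NULL) {
  gene_to_ko <- normalize_gene_to_ko(gene_to_ko)
  by_ko <- split(gene_to_ko$gene_id, gene_to_ko$ko)
  rel <- kb$relations

  allowed <- list()
  if (nrow(rel)) {
    for (i in seq_len(nrow(rel))) {
      ga <- by_ko[[rel$source_ko[i]]]
      gb <- by_ko[[rel$target_ko[i]]]
      if (is.null(ga) || is.null(gb)) next
      grid <- expand.grid(from = ga, to = gb, stringsAsFactors = FALSE)
      grid <- grid[grid$from != grid$to, , drop = FALSE]
      if (nrow(grid)) allowed[[length(allowed) + 1L]] <- grid
      if (!rel$directed[i]) {
        rev <- data.frame(from = grid$to, to = grid$from,
                          stringsAsFactors = FALSE)
        if (nrow(rev)) allowed[[length(allowed) + 1L]] <- rev
      }
    }
  }
  allowed <- if (length(allowed)) unique(do.call(rbind, allowed))
             else empty_edges()
  rownames(allowed) <- NULL

  # candidate whitelist edges from the initial mapping, annotated with the
  # species scope of their supporting relations
  cand <- gene_level_edges(initial)
  rel_key <- paste(rel$source_ko, rel$target_ko, sep = "|")
  keep <- logical(nrow(cand))
  species_only_excluded <- logical(nrow(cand))
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      hits <- which(rel_key == paste(cand$source_ko[i], cand$target_ko[i],
                                     sep = "|"))
      if (!length(hits)) next
      keep[i] <- TRUE
      if (!is.null(exclude_species)) {
        scopes <- unique(unlist(strsplit(rel$species[hits], ",")))
        species_only_excluded[i] <- identical(scopes, exclude_species)
      }
    }
  }
  cand <- cand[keep, c("from", "to"), drop = FALSE]
  excl <- species_only_excluded[keep]
  dup <- duplicated(cand)
  cand <- cand[!dup, , drop = FALSE]
  excl <- excl[!dup]

  dropped <- data.frame(from = character(0), to = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (any(excl)) {
    dropped <- rbind(dropped, data.frame(from = cand$from[excl],
                                         to = cand$to[excl],
                                         reason = "species",
                                         stringsAsFactors = FALSE))
  }
  cand <- cand[!excl, , drop = FALSE]
  ord <- order(cand$from, cand$to, method = "radix")
  cand <- cand[ord, , drop = FALSE]

  nodes <- unique(c(cand$from, cand$to, allowed$from, allowed$to))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  wl <- list()
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      u <- cand$from[i]; v <- cand$to[i]
      if (reaches(adj, v, u)) {
        dropped <- rbind(dropped, data.frame(from = u, to = v,
                                             reason = "cycle",
                                             stringsAsFactors = FALSE))
      } else {
        adj[[u]] <- c(adj[[u]], v)
        wl[[length(wl) + 1L]] <- c(u, v)
      }
    }
  }
  whitelist <- if (length(wl)) {
    m <- do.call(rbind, wl)
    data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
  } else empty_edges()
  rownames(whitelist) <- NULL
  rownames(dropped) <- NULL

  # the whitelist must be licensed: union in its own pairs defensively
  structure(list(whitelist = whitelist, allowed = allowed, dropped = dropped),
            class = "ConstraintSet")
}

#' @export
print.ConstraintSet <- function(x, ...) {
  cat(sprintf(
    "ConstraintSet: %d whitelist edge(s), %d allowed pair(s), %d dropped\n",
    nrow(x$whitelist), nrow(x$allowed), nrow(x$dropped)))
  invisible(x)
}

#' Test directed gene pairs against the allowed set
#'
#' A pair is allowed (not blacklisted) when its KO pair carries a
#' knowledgebase relation, i.e. when it is present in the constraint
#' set's `allowed` edges or its whitelist.
#'
#' @param constraints A `ConstraintSet`.
#' @param from,to Character vectors of gene identifiers (recycled).
#' @return Logical vector.
#' @export
is_allowed <- function(constraints, from, to) {
  keys <- edge_key(from, to)
  ok <- c(edge_key(constraints$allowed$from, constraints$allowed$to),
          edge_key(constraints$whitelist$from, constraints$whitelist$to))
  keys %in% ok
}
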