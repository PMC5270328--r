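#' Pipeline run configuration
#'
#' Collects every file path and tuning parameter of the end-to-end
#' workflow. Unknown keys are rejected (any misspelled argument raises
#' the usual unused-argument error). A single global seed fans out to
#' per-stage seeds by fixed offsets so each stage is independently
#' reproducible.
#'
#' @param counts Path to the counts TSV (header = condition labels,
#'   first column = gene id).
#' @param gene2ko Path to the gene-to-KO TSV used for the initial
#'   mapping.
#' @param gene2ko_allowed Optional broader gene-to-KO TSV used to expand
#'   knowledgebase relations into the allowed-edge set (defaults to
#'   `gene2ko`).
#' @param kgml Character vector of KGML file paths (the pathways to
#'   reconstruct; also the evaluation targets).
#' @param go Optional path to the GO annotation TSV.
#' @param out_dir Output directory.
#' @param threshold CPM expression cutoff.
#' @param k Number of expression clusters, or `NULL` to select by
#'   cross-validation over `k_range`.
#' @param k_range Candidate cluster counts for cross-validation.
#' @param folds Cross-validation folds.
#' @param batch_size Genes sampled per expansion round.
#' @param expansion_rounds Sampling/learning rounds per pathway.
#' @param restarts Hill-climbing restarts.
#' @param max_iters Hill-climbing move cap.
#' @param repeats Stochastic repeats for evaluation averaging.
#' @param eval_mode `"directed"` or `"undirected"` edge matching.
#' @param exclude_species Organism code excluded from whitelist support.
#' @param alpha Enrichment significance level.
#' @param seed Global integer seed.
#' @return A `RunConfig` list.
#' @export
run_config <- function(counts, gene2ko, kgml, go = NULL,
                       gene2ko_allowed = NULL, out_dir = tempfile("kbn"),
                       threshold = 1.0, k = NULL, k_range = 2:8,
                       folds = 5L, batch_size = 10L,
                       expansion_rounds = 3L, restarts = 1L,
                       max_iters = 200L, repeats = 1L,
                       eval_mode = c("directed", "undirected"),
                       exclude_species = NULL, alpha = 0.05, seed = 1L) {
  structure(list(counts = counts, gene2ko = gene2ko,
                 gene2ko_allowed = gene2ko_allowed, kgml = kgml, go = go,
                 out_dir = out_dir, threshold = threshold, k = k,
                 k_range = k_range, folds = folds,
                 batch_size = as.integer(batch_size),
                 expansion_rounds = as.integer(expansion_rounds),
                 restarts = as.integer(restarts),
                 max_iters = as.integer(max_iters),
                 repeats = as.integer(repeats),
                 eval_mode = match.arg(eval_mode),
                 exclude_species = exclude_species, alpha = alpha,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full pathway-reconstruction workflow
#'
#' Executes normalize, filter, cluster, KGML parsing, initial mapping,
#' constraint construction, cluster-guided sampling with constrained
#' hill-climbing expansion, cycle amendment, KO grouping, compound
#' attachment, recall/precision evaluation and GO enrichment, writing
#' per-stage outputs plus a summary table under `config$out_dir`. Any
#' stage failure aborts with the stage name and cause; a `MANIFEST`
#' of completed stages is always written.
#'
#' @param config A `RunConfig` (see [run_config()]).
#' @return Invisibly, a list with `summary` (per-pathway data frame),
#'   `networks` (per-pathway `AssembledPathway`), `enrichment`
#'   (per-pathway data frames) and `model` (the `ClusterModel`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note_stage <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(config$out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- expression ----------------------------------------------------------
  mat <- stage("expression", {
    if (!file.exists(config$counts)) stop("counts file not found: ",
                                          config$counts)
    m <- read_counts(config$counts)
    m <- cpm_normalize(m)
    filter_expressed(m, threshold = config$threshold)
  })
  note_stage("expression")

  # -- clustering ----------------------------------------------------------
  lc <- log_cpm(mat)
  model <- stage("clustering", {
    k <- config$k
    if (is.null(k)) {
      k <- select_k(lc, config$k_range, folds = config$folds,
                    seed = config$seed + 10L)
    }
    fit_gmm(lc, k, seed = config$seed + 11L)
  })
  note_stage("clustering")

  # -- knowledgebase -------------------------------------------------------
  kb_parts <- stage("knowledgebase", {
    if (is.null(config$gene2ko) || !file.exists(config$gene2ko)) {
      stop("gene-to-KO file not found: ", config$gene2ko)
    }
    missing <- config$kgml[!file.exists(config$kgml)]
    if (length(missing)) stop("KGML file(s) not found: ",
                              paste(missing, collapse = ", "))
    pathways <- lapply(config$kgml, parse_kgml)
    g2k <- read_gene_to_ko(config$gene2ko)
    g2k_allowed <- if (is.null(config$gene2ko_allowed)) g2k
                   else read_gene_to_ko(config$gene2ko_allowed)
    kb <- suppressWarnings(build_knowledgebase(pathways))
    list(pathways = pathways, g2k = g2k, g2k_allowed = g2k_allowed,
         kb = kb)
  })
  note_stage("knowledgebase")

  data <- bn_data(mat, transform = "log_cpm")
  background <- rownames(mat)
  annotations <- if (!is.null(config$go)) {
    stage("annotations", read_annotations(config$go))
  } else NULL

  summary_rows <- list()
  networks <- list()
  enrich_out <- list()
  for (i in seq_along(kb_parts$pathways)) {
    pw <- kb_parts$pathways[[i]]
    pid <- pw$pathway_id
    res <- stage(paste0("learn:", pid), {
      reconstruct_pathway(pw, kb_parts$kb, kb_parts$g2k,
                          kb_parts$g2k_allowed, data, model, config,
                          seed = config$seed + 100L * i)
    })
    networks[[pid]] <- res$assembled
    summary_rows[[pid]] <- res$summary
    if (!is.null(annotations)) {
      enr <- stage(paste0("enrichment:", pid), {
        genes <- intersect(unique(unlist(res$assembled$ko_nodes)),
                           background)
        fisher_enrichment(genes, background, annotations,
                          alpha = config$alpha)
      })
      enrich_out[[pid]] <- enr
      utils::write.table(
        enr, file.path(config$out_dir,
                       sprintf("enrichment_%d.tsv", i)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_sif(res$assembled,
              file.path(config$out_dir, sprintf("network_%d.sif", i)))
    igraph::write_graph(as_igraph(res$assembled),
                        file.path(config$out_dir,
                                  sprintf("network_%d.graphml", i)),
                        format = "graphml")
  }
  note_stage("learning")

  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note_stage("summary")

  invisible(list(summary = summary, networks = networks,
                 enrichment = enrich_out, model = model))
}

# learn, assemble and evaluate one pathway; the initial mapping's KO-level
# edge recovery is reported as the baseline alongside the learned network
reconstruct_pathway <- function(pw, kb, g2k, g2k_allowed, data, model,
                                config, seed) {
  mapped <- suppressWarnings(initial_mapping(pw, g2k))
  cs <- build_constraints(mapped, kb, g2k_allowed,
                          exclude_species = config$exclude_species)
  present <- colnames(data)
  initial_genes <- unique(unlist(lapply(mapped$nodes, `[[`, "genes")))
  initial_genes <- intersect(initial_genes, present)

  wl <- cs$whitelist
  wl <- wl[wl$from %in% present & wl$to %in% present, , drop = FALSE]
  cs$whitelist <- wl
  cs$allowed <- cs$allowed[cs$allowed$from %in% present &
                             cs$allowed$to %in% present, , drop = FALSE]

  nodes <- unique(c(initial_genes, wl$from, wl$to))
  target <- target_ko_edges(pw)

  # baseline: KO-level edges recovered by the initial mapping alone
  init_gene_edges <- gene_level_edges(mapped)
  init_gene_edges <- init_gene_edges[
    init_gene_edges$from %in% present & init_gene_edges$to %in% present, ,
    drop = FALSE]
  init_ko <- if (nrow(init_gene_edges)) {
    unique(data.frame(from = init_gene_edges$source_ko,
                      to = init_gene_edges$target_ko,
                      stringsAsFactors = FALSE))
  } else empty_edges()
  ev_init <- edge_recall_precision(init_ko, target,
                                   mode = config$eval_mode,
                                   pathway_id = pw$pathway_id)

  lconf <- learn_config(max_iters = config$max_iters,
                        restarts = config$restarts, seed = seed,
                        tol = 1e-6,
                        expansion_rounds = config$expansion_rounds)
  run_once <- function(s) {
    lc <- lconf; lc$seed <- as.integer(s)
    learned <- if (length(nodes) == 0) {
      bn_structure(character(0))
    } else {
      plan <- make_plan(model, initial_genes,
                        batch_size = config$batch_size)
      init_struct <- bn_structure(nodes, wl)
      expand_network(data, init_struct, cs, plan, model, lc)
    }
    amended <- amend_cycles(learned, cs$dropped)
    assembled <- suppressWarnings(group_by_ko(amended, g2k_allowed))
    assembled <- attach_compounds(assembled, kb)
    assembled
  }
  assembled <- run_once(seed)
  pred_ko <- assembled$edges[, c("from_ko", "to_ko")]
  names(pred_ko) <- c("from", "to")
  # drop pseudo-KO singleton nodes from the evaluation edge set
  pred_ko <- pred_ko[!grepl("^gene:", pred_ko$from) &
                       !grepl("^gene:", pred_ko$to), , drop = FALSE]
  ev_bn <- if (config$repeats > 1) {
    repeat_evaluate(function(s) {
      a <- run_once(s)
      e <- a$edges[, c("from_ko", "to_ko")]
      names(e) <- c("from", "to")
      e[!grepl("^gene:", e$from) & !grepl("^gene:", e$to), , drop = FALSE]
    }, target, repeats = config$repeats, base_seed = seed,
    mode = config$eval_mode, pathway_id = pw$pathway_id)
  } else {
    edge_recall_precision(pred_ko, target, mode = config$eval_mode,
                          pathway_id = pw$pathway_id)
  }

  summary <- data.frame(
    pathway_id = pw$pathway_id,
    n_target_edges = ev_bn$n_target_edges,
    recall_initial = ev_init$recall,
    precision_initial = ev_init$precision,
    recall_bn = ev_bn$recall,
    precision_bn = ev_bn$precision,
    n_predicted_edges = ev_bn$n_predicted_edges,
    repeats = ev_bn$repeats,
    stringsAsFactors = FALSE)
  list(assembled = assembled, summary = summary, constraints = cs,
       eval_initial = ev_init, eval_bn = ev_bn)
}
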