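#' Edge-level recall and precision against a target pathway
#'
#' Recall is the fraction of target edges present in the prediction;
#' precision the fraction of predicted edges present in the target.
#' In undirected mode an edge matches regardless of orientation.
#' Convention for empty sets: both empty gives recall = precision = 1
#' (nothing to recover, nothing wrong); an empty prediction against a
#' non-empty target gives recall 0 and precision `NA` (undefined).
#'
#' @param predicted,target Edge data frames with columns `from`, `to`
#'   (KO-level identifiers after [group_by_ko()], or gene ids).
#' @param mode `"directed"` (default) or `"undirected"`.
#' @param pathway_id Optional label carried into the result.
#' @return An `EvalResult`: list with `pathway_id`, `recall`,
#'   `precision`, `n_target_edges`, `n_predicted_edges`, `n_matched`,
#'   `repeats` (1).
#' @export
edge_recall_precision <- function(predicted, target,
                                  mode = c("directed", "undirected"),
                                  pathway_id = NA_character_) {
  mode <- match.arg(mode)
  canon <- function(e) {
    e <- as.data.frame(e)
    if (!nrow(e)) return(character(0))
    f <- as.character(e$from); t <- as.character(e$to)
    if (mode == "undirected") {
      unique(edge_key(pmin(f, t), pmax(f, t)))
    } else unique(edge_key(f, t))
  }
  p <- canon(predicted); t <- canon(target)
  matched <- length(intersect(p, t))
  recall <- if (length(t) == 0) 1 else matched / length(t)
  precision <- if (length(p) == 0) {
    if (length(t) == 0) 1 else NA_real_
  } else matched / length(p)
  structure(list(pathway_id = pathway_id, recall = recall,
                 precision = precision, n_target_edges = length(t),
                 n_predicted_edges = length(p), n_matched = matched,
                 repeats = 1L),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf(
    "EvalResult%s: recall %.3f, precision %s (%d/%d target, %d predicted, %d repeat(s))\n",
    if (is.na(x$pathway_id)) "" else paste0(" [", x$pathway_id, "]"),
    x$recall,
    if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision),
    x$n_matched, x$n_target_edges, x$n_predicted_edges, x$repeats))
  invisible(x)
}

#' Average recall/precision over repeated stochastic runs
#'
#' Runs a prediction procedure `repeats` times with seeds
#' `base_seed, base_seed + 1, ...`, evaluates each prediction against the
#' target edge set, and averages. Failed repeats are recorded and
#' excluded from the mean.
#'
#' @param run Function of one argument (the seed) returning a predicted
#'   edge data frame (`from`, `to`).
#' @param target Target edge data frame.
#' @param repeats Number of repetitions (>= 1).
#' @param base_seed First seed.
#' @param mode Match orientation, as in [edge_recall_precision()].
#' @param pathway_id Optional label.
#' @return An `EvalResult` with mean `recall`/`precision`, plus
#'   `per_repeat` (data frame seed/recall/precision) and `n_failed`.
#' @export
repeat_evaluate <- function(run, target, repeats = 50L, base_seed = 1L,
                            mode = c("directed", "undirected"),
                            pathway_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(repeats >= 1)
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(repeats)) {
    seed <- base_seed + i - 1L
    res <- tryCatch({
      pred <- run(seed)
      edge_recall_precision(pred, target, mode = mode,
                            pathway_id = pathway_id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed, recall = res$recall, precision = res$precision,
      n_matched = res$n_matched,
      n_predicted_edges = res$n_predicted_edges,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("every repeat failed")
  tab <- do.call(rbind, rows)
  out <- structure(list(
    pathway_id = pathway_id,
    recall = mean(tab$recall),
    precision = mean(tab$precision, na.rm = TRUE),
    n_target_edges = edge_recall_precision(empty_edges(), target,
                                           mode = mode)$n_target_edges,
    n_predicted_edges = mean(tab$n_predicted_edges),
    n_matched = mean(tab$n_matched),
    repeats = nrow(tab)), class = "EvalResult")
  out$per_repeat <- tab
  out$n_failed <- n_failed
  out
}
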