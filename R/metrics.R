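ranked_ids <- function(ranked) {
  if (is.data.frame(ranked)) ranked$episode_id else as.character(ranked)
}

#' Information-retrieval metrics
#'
#' Standard rank-based metrics over a ranked list and a set of relevant
#' episode ids:
#'
#' * `average_precision` — mean of the precision values obtained at each
#'   rank holding a relevant episode, divided by the total number of
#'   relevant episodes (unretrieved relevant items contribute 0).
#' * `precision_at_k` — fraction of the top `k` ranks holding a relevant
#'   episode; ranks beyond the list length count as non-relevant.
#' * `r_precision` — precision at rank `R`, where `R` is the number of
#'   relevant episodes.
#'
#' @param ranked A `ranked_list` or character vector of episode ids in rank
#'   order.
#' @param relevant Character vector (or set) of relevant episode ids;
#'   must be non-empty for `average_precision` and `r_precision`.
#' @param k Cutoff for `precision_at_k`.
#' @return A score in `[0, 1]`.
#' @export
average_precision <- function(ranked, relevant) {
  relevant <- unique(as.character(relevant))
  if (!length(relevant)) stop("empty relevance set")
  ids <- ranked_ids(ranked)
  hit <- ids %in% relevant
  if (!any(hit)) return(0)
  ranks <- which(hit)
  sum(seq_along(ranks) / ranks) / length(relevant)
}

#' @rdname average_precision
#' @export
precision_at_k <- function(ranked, relevant, k = 10L) {
  ids <- utils::head(ranked_ids(ranked), k)
  sum(ids %in% as.character(relevant)) / k
}

#' @rdname average_precision
#' @export
r_precision <- function(ranked, relevant) {
  relevant <- unique(as.character(relevant))
  if (!length(relevant)) stop("empty relevance set")
  ids <- utils::head(ranked_ids(ranked), length(relevant))
  sum(ids %in% relevant) / length(relevant)
}

query_metrics <- function(ranked, relevant, k = 10L) {
  ids <- ranked_ids(ranked)
  c(ap = average_precision(ids, relevant),
    p_at_k = precision_at_k(ids, relevant, k),
    rprec = r_precision(ids, relevant),
    retrieved_relevant = sum(ids %in% as.character(relevant)))
}

new_eval_report <- function(per_query, config = list(), label = "") {
  structure(list(per_query = per_query,
                 means = c(map = mean(per_query$ap),
                           p_at_k = mean(per_query$p_at_k),
                           rprec = mean(per_query$rprec),
                           retrieved_relevant_total =
                             sum(per_query$retrieved_relevant),
                           retrieved_relevant_mean =
                             mean(per_query$retrieved_relevant)),
                 config = config, label = label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$label, " (", nrow(x$per_query), " queries)\n",
      sep = "")
  cat(sprintf("  MAP = %.4f   P@k = %.4f   Rprec = %.4f   rel.retrieved = %d\n",
              x$means["map"], x$means["p_at_k"], x$means["rprec"],
              as.integer(x$means["retrieved_relevant_total"])))
  invisible(x)
}
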