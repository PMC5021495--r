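# Over-representation of a query gene list (typically the significant DGE
# genes) in user-supplied gene-set collections, with Bonferroni control.
# One-sided upper-tail hypergeometric test: under the null the query is an
# unordered draw of n genes from the universe of N, K of which belong to the
# set; p = P(X >= k) for the observed overlap k.

#' Hypergeometric gene-set over-representation
#'
#' @param query Character vector of query gene ids; must be non-empty and a
#'   subset of `universe`.
#' @param sets A [module_set()] of gene sets to test; each set is
#'   intersected with the universe before testing.
#' @param universe Character vector of background gene ids (non-empty;
#'   duplicates dropped).
#' @return data.frame of class `enrichment_table`, one row per set, sorted
#'   by `p_value` ascending (ties by `set_id`), with columns `set_id`,
#'   `set_name`, `p_value`, `q_bonferroni` (`min(1, m p)` over the m tested
#'   sets), `q_bh`, `hit_count_query` (overlap with the query) and
#'   `hit_count_genome` (set size within the universe).
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  stopifnot(inherits(sets, "module_set"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query list")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) " ...")
  N <- length(universe)
  n <- length(query)
  m <- length(sets)
  K <- vapply(sets$genes, function(g) sum(unique(g) %in% universe), integer(1))
  k <- vapply(sets$genes, function(g) sum(unique(g) %in% query), integer(1))
  # P(X >= k); k = 0 gives exactly 1
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(set_id = sets$module_id, set_name = sets$label,
                    p_value = p,
                    q_bonferroni = pmin(1, m * p),
                    q_bh = bh_adjust(p),
                    hit_count_query = k, hit_count_genome = K,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_size") <- N
  attr(out, "query_size") <- n
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#' @param tab An `enrichment_table`.
#' @param path Output path.
#' @export
write_enrichment <- function(tab, path) {
  out <- tab
  out$p_value <- num_full(out$p_value)
  out$q_bonferroni <- num_full(out$q_bonferroni)
  out$q_bh <- num_full(out$q_bh)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
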