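#' Hypergeometric upper-tail probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated members when sampling `n` features from a universe of
#' `N` features of which `K` carry the annotation.
#'
#' @param k observed hits in the foreground.
#' @param K annotated features in the universe (term size).
#' @param n foreground size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || K > N || n > N)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K) <= N)")
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against gene sets
#'
#' Hypergeometric test of each gene set's overlap with a foreground list
#' relative to a universe (all quantified features), with
#' Benjamini-Hochberg adjustment over all tested terms. Gene-set members
#' are intersected with the universe before testing; terms with no
#' foreground overlap are omitted.
#'
#' @param foreground character vector, subset of `universe`.
#' @param universe character vector of all quantified features.
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param alpha_adjusted significance cutoff on the adjusted p value.
#' @return data.frame of class `ora_result`, sorted by p: term, k (hits),
#'   n (foreground size), K (term size in universe), N (universe size),
#'   p_value, p_adjust, significant, members (comma-separated hits).
#' @export
ora <- function(foreground, universe, gene_sets, alpha_adjusted = 0.05) {
  universe <- unique(universe)
  foreground <- unique(foreground)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(foreground %in% universe))
    stop("foreground must be a subset of the universe")
  N <- length(universe)
  n <- length(foreground)
  rows <- list()
  for (term in names(gene_sets)) {
    members <- intersect(gene_sets[[term]], universe)
    K <- length(members)
    hits <- intersect(foreground, members)
    k <- length(hits)
    if (k == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, k = k, n = n, K = K, N = N,
      p_value = hypergeom_upper_tail(k, K, n, N),
      members = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      p_adjust = numeric(), significant = logical(),
                      members = character(), stringsAsFactors = FALSE)
    class(out) <- c("ora_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- bh_adjust(out$p_value)
  out$significant <- out$p_adjust < alpha_adjusted
  out <- out[order(out$p_value), c("term", "k", "n", "K", "N", "p_value",
                                   "p_adjust", "significant", "members")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Map differential sites to a deduplicated parent-protein foreground
#'
#' Site-level enrichment tests operate on parent proteins: a protein with
#' several regulated sites counts once, avoiding pseudo-replication.
#'
#' @param site_ids character vector of site ids.
#' @param parent_map named vector site id -> accession.
#' @return unique accessions.
#' @export
sites_to_proteins <- function(site_ids, parent_map) {
  miss <- setdiff(site_ids, names(parent_map))
  if (length(miss)) stop("site(s) absent from parent map: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  unique(unname(parent_map[site_ids]))
}
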