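# Hypergeometric over-representation of a query target set against an
# annotation universe (diseases or pathways). The association statistic is
# the upper tail P(X >= k) for the overlap k between the query set (size
# n) and an annotated set (size K) in a universe of N genes:
#   P = 1 - sum_{i=0}^{k-1} C(K,i) C(N-K,n-i) / C(N,n)

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' random size-`n` draw from a universe of `N` genes, `K` of which carry
#' the annotation, overlaps the annotation in at least `k` genes. Computed
#' by summing log-gamma binomial terms in log space (numerically stable
#' for large universes) and clamped to `[0, 1]`.
#'
#' @param N universe size (> 0).
#' @param K annotated-set size, `K <= N`.
#' @param n query-set size, `n <= N`.
#' @param k observed overlap, `0 <= k <= min(n, K)`.
#' @return The tail probability (1 when `k = 0`).
#' @examples
#' hypergeom_upper_tail(10, 4, 3, 2)   # 1/3
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (N <= 0) stop("universe size N must be positive", call. = FALSE)
  if (K < 0 || K > N) stop("K must lie in [0, N]", call. = FALSE)
  if (n < 0 || n > N) stop("n must lie in [0, N]", call. = FALSE)
  if (k < 0 || k > min(n, K))
    stop("k must lie in [0, min(n, K)]", call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(n, K)
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logterms)
  p <- exp(m) * sum(exp(logterms - m))
  min(max(p, 0), 1)
}

#' Rank annotations by over-representation in a query set
#'
#' Tests every annotation (disease or pathway gene set) for
#' over-representation in a query gene set with the hypergeometric upper
#' tail, and ranks by p ascending (ties broken by annotation id). Raw p is
#' primary; a Benjamini-Hochberg adjusted column is included for users who
#' want multiplicity control.
#'
#' @param query_set character vector of query gene ids (non-empty).
#' @param universe named list of character vectors: one gene set per
#'   annotation (as from [read_annotations()]).
#' @param alpha significance level on the raw p (default 0.05).
#' @param universe_size the universe size `N`; defaults to the number of
#'   distinct genes in `universe` and `query_set` combined. Pass the
#'   annotation database's own total when it is known.
#' @return A data.frame sorted by rank with columns `annotation`, `N`,
#'   `K`, `n`, `k`, `p`, `bh_p`, `significant` (`p < alpha`), `rank`.
#' @examples
#' u <- list(d1 = c("g1", "g2", "g3"), d2 = c("g4", "g5"))
#' rank_annotations(c("g1", "g2"), u)
#' @export
rank_annotations <- function(query_set, universe, alpha = 0.05,
                             universe_size = NULL) {
  if (!length(query_set)) stop("query set is empty", call. = FALSE)
  if (!length(universe) || is.null(names(universe)))
    stop("`universe` must be a non-empty named list of gene sets",
         call. = FALSE)
  query_set <- unique(as.character(query_set))
  all_genes <- unique(c(unlist(universe, use.names = FALSE), query_set))
  N <- if (is.null(universe_size)) length(all_genes) else universe_size
  if (N < length(all_genes))
    stop("`universe_size` smaller than the number of distinct genes seen",
         call. = FALSE)
  n <- length(query_set)
  res <- data.frame(
    annotation = names(universe),
    N = N,
    K = vapply(universe, function(g) length(unique(g)), integer(1)),
    n = n,
    k = vapply(universe,
               function(g) length(intersect(unique(g), query_set)),
               integer(1)),
    stringsAsFactors = FALSE)
  res$p <- mapply(hypergeom_upper_tail, N = res$N, K = res$K,
                  n = res$n, k = res$k)
  res$bh_p <- p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  ord <- order(res$p, res$annotation)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
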