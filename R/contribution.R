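# Contribution score for components of a two-herb formula in a merged
# component-target network:
#   omega_i = C_i / T_edge                       (edge-weight fraction)
#   A_i     = omega_i + |(C_Ai + C_Bi) / (C_Ai - C_Bi)|   (affinity index)
#   CS(i)   = C_i * A_i * sum_{j in targets(i)} P_j
# with C_i the component's degree in the merged network, C_Ai / C_Bi its
# degrees in the two herb subnetworks, P_j the target degrees in the
# merged network, and T_edge the merged edge count. Because each component
# belongs to exactly one herb, one of C_Ai, C_Bi is zero and A_i reduces
# to omega_i + 1; the degenerate equal-degree denominator can only arise
# for data where a component is shared between herbs, and its handling is
# configurable.

#' Edge-weight fraction of a component
#'
#' The fraction `omega = c_edges / t_edges` of the merged network's edges
#' that are incident to one component.
#'
#' @param c_edges edges incident to the component (its degree).
#' @param t_edges total edges of the merged network (> 0).
#' @return A number in `[0, 1]`.
#' @examples
#' edge_weight(38, 650)
#' @export
edge_weight <- function(c_edges, t_edges) {
  if (t_edges <= 0) stop("total edge count must be positive", call. = FALSE)
  if (c_edges < 0 || c_edges > t_edges)
    stop("`c_edges` must lie in [0, t_edges]", call. = FALSE)
  c_edges / t_edges
}

#' Affinity index of a component
#'
#' `A = omega + |(c_a + c_b) / (c_a - c_b)|`, where `c_a` and `c_b` are
#' the component's degrees in the two herb subnetworks. When exactly one
#' of them is zero the ratio term is 1. When `c_a == c_b > 0` the
#' denominator vanishes; the `policy` decides what happens:
#' `"floor"` (default) floors the denominator at 1 so the ratio term is
#' `c_a + c_b`, `"skip"` drops the ratio term, `"error"` aborts.
#'
#' @param omega the component's edge-weight fraction ([edge_weight()]).
#' @param c_a,c_b non-negative integer degrees in the two herb
#'   subnetworks, not both zero.
#' @param policy handling of the `c_a == c_b > 0` degenerate denominator.
#' @return The affinity index, a single number.
#' @examples
#' affinity_index(0.05, 5, 0)   # 1.05
#' affinity_index(0,    3, 1)   # 2
#' @export
affinity_index <- function(omega, c_a, c_b,
                           policy = c("floor", "error", "skip")) {
  policy <- match.arg(policy)
  if (c_a < 0 || c_b < 0) stop("degrees must be non-negative", call. = FALSE)
  if (c_a + c_b == 0)
    stop("component has no edges in either herb subnetwork", call. = FALSE)
  if (c_a == c_b) {
    ratio <- switch(policy,
      floor = (c_a + c_b) / 1,
      skip = 0,
      error = stop("degenerate affinity denominator: c_a == c_b = ", c_a,
                   call. = FALSE))
  } else {
    ratio <- abs((c_a + c_b) / (c_a - c_b))
  }
  omega + ratio
}

#' Contribution scores for every component of a merged network
#'
#' Computes, for each component of a herb-labelled component-target
#' network, its merged-network degree, per-herb subnetwork degrees,
#' edge-weight fraction, affinity index, the sum of its targets' degrees,
#' the contribution score `CS = C * A * sum(P_j)`, the percentage of the
#' total CS, and the cumulative percentage down the ranking (CS
#' descending, ties broken by id ascending).
#'
#' @param net a [build_bipartite()] network whose `herb_of` assigns every
#'   component (left node with at least one edge) to exactly one of at
#'   most two herbs.
#' @param policy degenerate-denominator policy, see [affinity_index()].
#' @param sum_over `"incident"` (default) sums target degrees over the
#'   component's own targets; `"all"` sums over every target of the
#'   network (which makes the sum a global constant and is provided only
#'   for sensitivity checks).
#' @return A data.frame sorted by rank with columns `component_id`,
#'   `herb`, `degree`, `degree_a`, `degree_b`, `omega`, `affinity`,
#'   `target_degree_sum`, `cs`, `cs_pct`, `cum_pct`, `rank`.
#'   `cs_pct` sums to 100.
#' @examples
#' net <- gen_bipartite_edges(c(ZHISHI = 4, BAIZHU = 2), 6, 12, seed = 1)
#' cs <- contribution_scores(build_bipartite(net$edges, herb_of = net$herb_of))
#' cs[, c("component_id", "degree", "cs", "cs_pct", "cum_pct")]
#' @export
contribution_scores <- function(net, policy = c("floor", "error", "skip"),
                                sum_over = c("incident", "all")) {
  stopifnot(inherits(net, "bipartite_net"))
  policy <- match.arg(policy)
  sum_over <- match.arg(sum_over)
  if (!nrow(net$edges)) stop("network has no edges", call. = FALSE)
  if (is.null(net$herb_of))
    stop("network has no herb labels", call. = FALSE)
  comps <- sort(unique(net$edges$from))
  unlabelled <- setdiff(comps, names(net$herb_of))
  if (length(unlabelled))
    stop("component(s) without a herb label: ",
         paste(head(unlabelled, 3L), collapse = ", "), call. = FALSE)
  herbs <- sort(unique(unname(net$herb_of[comps])))
  if (length(herbs) > 2L)
    stop("contribution scores are defined for at most two herbs, got: ",
         paste(herbs, collapse = ", "), call. = FALSE)
  t_edges <- nrow(net$edges)
  res <- lapply(comps, function(ci) {
    deg <- unname(net$degree[[ci]])
    herb <- unname(net$herb_of[[ci]])
    c_a <- if (herb == herbs[1L]) deg else 0L
    c_b <- deg - c_a
    omega <- edge_weight(deg, t_edges)
    aff <- affinity_index(omega, c_a, c_b, policy = policy)
    targets <- if (sum_over == "incident")
      net$edges$to[net$edges$from == ci]
    else
      unique(net$edges$to)
    p_sum <- sum(net$degree[targets])
    data.frame(component_id = ci, herb = herb, degree = deg,
               degree_a = c_a, degree_b = c_b, omega = omega,
               affinity = aff, target_degree_sum = p_sum,
               cs = deg * aff * p_sum, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  total <- sum(res$cs)
  if (total == 0) stop("total contribution score is zero", call. = FALSE)
  res$cs_pct <- 100 * res$cs / total
  ord <- order(-res$cs, res$component_id)
  res <- res[ord, , drop = FALSE]
  res$cum_pct <- cumsum(res$cs_pct)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Components needed to reach a cumulative contribution cutoff
#'
#' The smallest number of top-ranked components whose cumulative CS
#' percentage reaches a cutoff — e.g. "how many components carry 90% of
#' the formula's total contribution?".
#'
#' @param results a [contribution_scores()] table (already ranked).
#' @param cutoff_pct cutoff in percent, in `(0, 100]`.
#' @return A list with `k` (number of components) and `achieved_pct` (the
#'   cumulative percentage at `k`).
#' @examples
#' net <- gen_bipartite_edges(c(ZHISHI = 44, BAIZHU = 17), 133, 650, seed = 7)
#' cs <- contribution_scores(build_bipartite(net$edges, herb_of = net$herb_of))
#' cumulative_report(cs, 90)
#' @export
cumulative_report <- function(results, cutoff_pct = 90) {
  if (!nrow(results)) stop("empty contribution table", call. = FALSE)
  if (cutoff_pct <= 0 || cutoff_pct > 100)
    stop("`cutoff_pct` must lie in (0, 100]", call. = FALSE)
  k <- which(results$cum_pct >= cutoff_pct - 1e-9)[1L]
  if (is.na(k)) k <- nrow(results)  # numerical guard; cum_pct ends at 100
  list(k = k, achieved_pct = results$cum_pct[k])
}
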