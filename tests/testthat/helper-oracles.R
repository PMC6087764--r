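# Independent oracles used across the suite. Each re-derives a quantity
# by direct enumeration or a textbook closed form, without touching the
# implementation under test.

fixture <- function(name) herbnet_example(name)

# Pooled-variance two-sample t, closed form.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2), df = na + nb - 2)
}

# Hypergeometric upper tail by direct summation of binomial products.
# choose() on integers this small (N <= 30) is exact in double precision,
# so the sum is an exact-arithmetic reference.
hyper_tail_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Binary Tanimoto of one pair, written out naively.
tanimoto_pair_oracle <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) 0 else inter / union
}

# Contribution scores by literal edge enumeration, independent of the
# bipartite_net degree bookkeeping. Returns cs named by component id.
cs_oracle <- function(edges, herb_of) {
  comps <- sort(unique(edges$from))
  t_edge <- nrow(edges)
  herbs <- sort(unique(unname(herb_of[comps])))
  vapply(comps, function(ci) {
    mine <- edges[edges$from == ci, , drop = FALSE]
    C <- nrow(mine)
    ca <- if (unname(herb_of[[ci]]) == herbs[1]) C else 0
    cb <- C - ca
    omega <- C / t_edge
    denom <- abs(ca - cb)
    if (denom == 0) denom <- 1
    A <- omega + (ca + cb) / denom
    psum <- sum(vapply(mine$to, function(tj) sum(edges$to == tj), numeric(1)))
    C * A * psum
  }, numeric(1))
}

# Deterministic two-herb network reproducing given per-herb target
# coverage: herb A components cover targets 1..cov_a, herb B components
# cover the last cov_b targets of 1..n_targets.
coverage_network <- function(cov_a, cov_b, n_targets,
                             n_comp_a = 4, n_comp_b = 2) {
  targ <- sprintf("T%03d", seq_len(n_targets))
  span <- function(ids, comps, prefix) {
    # round-robin the targets over the herb's components
    data.frame(from = paste0(prefix, ((seq_along(ids) - 1) %% comps) + 1),
               to = ids, stringsAsFactors = FALSE)
  }
  edges <- rbind(span(targ[seq_len(cov_a)], n_comp_a, "A"),
                 span(targ[seq(n_targets - cov_b + 1, n_targets)],
                      n_comp_b, "B"))
  herb_of <- c(setNames(rep("HERBA", n_comp_a), paste0("A", 1:n_comp_a)),
               setNames(rep("HERBB", n_comp_b), paste0("B", 1:n_comp_b)))
  list(edges = edges, herb_of = herb_of)
}
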