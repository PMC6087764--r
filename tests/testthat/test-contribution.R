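test_that("edge-weight fraction is a plain ratio with guarded domain", {
  expect_equal(edge_weight(38, 650), 38 / 650)
  expect_equal(edge_weight(0, 10), 0)
  expect_equal(edge_weight(10, 10), 1)
  expect_error(edge_weight(1, 0), "positive")
  expect_error(edge_weight(11, 10), "\\[0, t_edges\\]")
})

test_that("affinity index follows the formula and the degenerate policy", {
  expect_equal(affinity_index(0.05, 5, 0), 1.05)
  expect_equal(affinity_index(0, 3, 1), 2)
  expect_equal(affinity_index(0.1, 2, 2), 4.1)  # floored denominator
  expect_equal(affinity_index(0.1, 2, 2, policy = "skip"), 0.1)
  expect_error(affinity_index(0.1, 2, 2, policy = "error"), "degenerate")
  expect_error(affinity_index(0, 0, 0), "no edges")
})

test_that("hand-evaluated single and symmetric cases come out exactly", {
  one <- build_bipartite(data.frame(from = "c", to = "t"),
                         herb_of = c(c = "HERBA"))
  cs <- contribution_scores(one)
  expect_equal(cs$omega, 1)
  expect_equal(cs$affinity, 2)       # omega 1 + ratio 1
  expect_equal(cs$cs, 2)             # 1 * 2 * 1
  expect_equal(cs$cs_pct, 100)

  sym <- build_bipartite(
    data.frame(from = c("c1", "c1", "c2", "c2"),
               to = c("t1", "t2", "t3", "t4")),
    herb_of = c(c1 = "HERBA", c2 = "HERBA"))
  cs2 <- contribution_scores(sym)
  expect_equal(cs2$cs_pct, c(50, 50))
  expect_equal(cs2$component_id, c("c1", "c2"))  # tie broken by id
})

test_that("contribution scores equal the edge-enumeration oracle", {
  # exhaustive sweep over every 3x3 bipartite adjacency pattern
  combos <- expand.grid(rep(list(0:1), 9))
  comp <- paste0("c", 1:3)
  targ <- paste0("t", 1:3)
  herb_of <- c(c1 = "HERBA", c2 = "HERBA", c3 = "HERBB")
  for (r in seq_len(nrow(combos))) {
    mask <- as.integer(combos[r, ])
    if (sum(mask) == 0) next
    idx <- which(matrix(mask, 3, 3) == 1, arr.ind = TRUE)
    edges <- data.frame(from = comp[idx[, 1]], to = targ[idx[, 2]],
                        stringsAsFactors = FALSE)
    net <- build_bipartite(edges, herb_of = herb_of)
    cs <- contribution_scores(net)
    oracle <- cs_oracle(edges, herb_of)
    expect_equal(setNames(cs$cs, cs$component_id)[names(oracle)], oracle,
                 tolerance = 1e-12)
  }

  # seeded 5x5 networks with both herbs
  set.seed(123)
  for (seed in 1:40) {
    spec <- gen_bipartite_edges(c(HERBA = 3, HERBB = 2), 5,
                                sample(5:25, 1), seed = seed)
    net <- build_bipartite(spec$edges, herb_of = spec$herb_of)
    cs <- contribution_scores(net)
    oracle <- cs_oracle(spec$edges, spec$herb_of)
    expect_equal(setNames(cs$cs, cs$component_id)[names(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("cs_pct sums to 100 and cum_pct is a ranking curve", {
  for (seed in 1:20) {
    spec <- gen_bipartite_edges(c(ZHISHI = 12, BAIZHU = 6), 30,
                                60 + seed, seed = seed)
    net <- build_bipartite(spec$edges, herb_of = spec$herb_of)
    cs <- contribution_scores(net)
    expect_equal(sum(cs$cs_pct), 100, tolerance = 1e-9)
    expect_false(is.unsorted(cs$cum_pct))
    expect_false(is.unsorted(rev(cs$cs)))
    expect_equal(cs$cum_pct[nrow(cs)], 100, tolerance = 1e-9)
    expect_equal(cs$rank, seq_len(nrow(cs)))
  }
})

test_that("with disjoint herb component sets the affinity is omega + 1", {
  for (seed in 1:10) {
    spec <- gen_bipartite_edges(c(ZHISHI = 8, BAIZHU = 5), 20, 40,
                                seed = seed)
    net <- build_bipartite(spec$edges, herb_of = spec$herb_of)
    cs <- contribution_scores(net)
    expect_equal(cs$affinity, cs$omega + 1, tolerance = 1e-12)
  }
})

test_that("CS increases with component degree, target degrees held fixed", {
  # c_big hits three targets, c_small one; all targets also hit by a
  # common partner so the target degree profile is flat
  edges <- data.frame(
    from = c("cbig", "cbig", "cbig", "csmall", "z", "z", "z", "z"),
    to = c("t1", "t2", "t3", "t4", "t1", "t2", "t3", "t4"))
  herb_of <- c(cbig = "HERBA", csmall = "HERBA", z = "HERBB")
  cs <- contribution_scores(build_bipartite(edges, herb_of = herb_of))
  expect_gt(cs$cs[cs$component_id == "cbig"],
            cs$cs[cs$component_id == "csmall"])
})

test_that("a planted hub with high-degree targets attains rank 1", {
  for (seed in 1:5) {
    spec <- gen_bipartite_edges(c(ZHISHI = 19, BAIZHU = 10), 40, 120,
                                seed = seed)
    # plant a hub wired to every target
    hub_edges <- data.frame(from = "ZH-hub", to = paste0("T", 1:40))
    edges <- rbind(spec$edges, hub_edges)
    herb_of <- c(spec$herb_of, `ZH-hub` = "ZHISHI")
    cs <- contribution_scores(build_bipartite(edges, herb_of = herb_of))
    expect_equal(cs$component_id[1], "ZH-hub")
  }
})

test_that("cumulative report finds the smallest k reaching the cutoff", {
  equal4 <- build_bipartite(
    data.frame(from = rep(paste0("c", 1:4), each = 1),
               to = paste0("t", 1:4)),
    herb_of = setNames(rep("HERBA", 4), paste0("c", 1:4)))
  cs <- contribution_scores(equal4)
  rep50 <- cumulative_report(cs, 50)
  expect_equal(rep50$k, 2L)
  expect_equal(rep50$achieved_pct, 50)
  expect_error(cumulative_report(cs, 0), "\\(0, 100\\]")
  expect_error(cumulative_report(cs, 101), "\\(0, 100\\]")

  spec <- gen_bipartite_edges(c(ZHISHI = 30, BAIZHU = 15), 60, 300, seed = 2)
  csr <- contribution_scores(build_bipartite(spec$edges,
                                             herb_of = spec$herb_of))
  brute_k <- which(cumsum(sort(csr$cs_pct, decreasing = TRUE)) >= 90)[1]
  expect_equal(cumulative_report(csr, 90)$k, brute_k)
})

test_that("degenerate inputs are rejected", {
  net <- build_bipartite(data.frame(from = "c", to = "t"))
  expect_error(contribution_scores(net), "no herb labels")
  part <- build_bipartite(data.frame(from = c("c1", "c2"), to = c("t", "u")),
                          herb_of = c(c1 = "HERBA"))
  expect_error(contribution_scores(part), "without a herb label")
  three <- build_bipartite(
    data.frame(from = c("a", "b", "c"), to = c("t1", "t2", "t3")),
    herb_of = c(a = "H1", b = "H2", c = "H3"))
  expect_error(contribution_scores(three), "at most two herbs")
})
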