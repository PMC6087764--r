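test_that("descriptor-vector Tanimoto matches the closed form and its edge cases", {
  expect_equal(tanimoto_similarity(c(1, 2), c(2, 2)), 6 / 7)
  expect_equal(tanimoto_similarity(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(tanimoto_similarity(c(1, 0), c(0, 2)), 0)
  expect_error(tanimoto_similarity(1:2, 1:3), "equal length")
  expect_error(tanimoto_similarity(c(0, 0), c(0, 0)), "zero vectors")
})

test_that("Tanimoto is symmetric, bounded on [0,1] and 1 iff identical (binary)", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(8) * sample(0:1, 8, replace = TRUE)
    b <- runif(8) * sample(0:1, 8, replace = TRUE)
    if (all(a == 0) && all(b == 0)) next
    s <- tanimoto_similarity(a, b)
    expect_equal(s, tanimoto_similarity(b, a))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  for (i in 1:50) {
    a <- sample(0:1, 10, replace = TRUE)
    b <- sample(0:1, 10, replace = TRUE)
    if (all(a == 0) && all(b == 0)) next
    expect_equal(tanimoto_similarity(a, b) == 1, all(a == b))
  }
})

test_that("single components are judged with the printed thresholds", {
  crit <- screening_criteria()
  bz27 <- list(id = "BZ27", herb = "BAIZHU", ob = 56.48, caco2 = 1.23,
               dl = 0.15, gi = "high")
  d <- evaluate_component(bz27, crit)
  expect_true(d$passed)   # 0.15 >= the Baizhu DL floor of 0.14
  expect_length(d$failed_criteria, 0)

  # same DL under the default threshold fails
  zs_like <- modifyList(bz27, list(id = "X1", herb = "ZHISHI"))
  expect_equal(evaluate_component(zs_like, crit)$failed_criteria, "DL")

  hesperidin <- list(id = "ZS130", herb = "ZHISHI", ob = 13.33,
                     caco2 = -2.03, dl = 0.67, gi = "low")
  expect_equal(evaluate_component(hesperidin, crit)$failed_criteria,
               c("OB", "CACO2", "GI"))

  # boundary semantics: OB inclusive, Caco-2 strict
  boundary <- list(id = "B", herb = "ZHISHI", ob = 30, caco2 = 0.5,
                   dl = 0.18, gi = "high")
  expect_true(evaluate_component(boundary, crit)$passed)
  at_caco2 <- modifyList(boundary, list(caco2 = -0.4))
  expect_equal(evaluate_component(at_caco2, crit)$failed_criteria, "CACO2")

  # no herb label -> default DL threshold applies
  unlabelled <- list(id = "U", ob = 50, caco2 = 1, dl = 0.15, gi = "high")
  expect_equal(evaluate_component(unlabelled, crit)$failed_criteria, "DL")
})

test_that("the packaged table fails exactly the six manually retained components", {
  comps <- read_component_table(fixture("zzw_components.tsv"))
  scr <- apply_screen(comps)
  failed <- sort(scr$decisions$id[!scr$decisions$passed])
  expect_equal(failed,
               c("BZ107", "ZS104", "ZS130", "ZS143", "ZS144", "ZS150"))
  expect_equal(nrow(scr$active), 56L)

  # whitelisting the six manual retentions recovers the full printed set
  wl <- apply_screen(comps, screening_criteria(whitelist = failed))
  expect_equal(nrow(wl$active), 62L)
  expect_true(all(wl$decisions$retained_by_whitelist[
    wl$decisions$id %in% failed]))

  expect_warning(apply_screen(comps,
                              screening_criteria(whitelist = "NOPE1")),
                 "whitelist id")
})

test_that("screening is idempotent and handles empty input", {
  comps <- read_component_table(fixture("zzw_components.tsv"))
  active <- apply_screen(comps)$active
  again <- apply_screen(active)$active
  expect_identical(again, active)
  empty <- apply_screen(comps[0, ])
  expect_equal(nrow(empty$active), 0L)
  expect_equal(nrow(empty$decisions), 0L)
})

test_that("pairwise similarity summary matches brute-force enumeration", {
  fps <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0),
               c = c(1, 1, 1, 1), d = c(0, 0, 0, 1))
  s <- pairwise_similarity_summary(fps, threshold = 0.4)
  expect_equal(s$n_pairs, 6L)
  pairs <- combn(rownames(fps), 2)
  expected <- apply(pairs, 2, function(p)
    tanimoto_pair_oracle(fps[p[1], ], fps[p[2], ]))
  expect_equal(sort(s$similarities), sort(expected))
  expect_equal(s$n_below_or_equal, sum(expected <= 0.4))
  expect_equal(s$fraction, sum(expected <= 0.4) / 6)
})

test_that("similarity summary edge cases behave as documented", {
  ident <- matrix(1, nrow = 5, ncol = 8)
  s <- pairwise_similarity_summary(ident, threshold = 0.2)
  expect_equal(s$n_below_or_equal, 0L)
  expect_equal(s$fraction, 0)

  empty <- matrix(0, nrow = 3, ncol = 8)
  expect_warning(s0 <- pairwise_similarity_summary(empty), "empty fingerprints")
  expect_true(all(s0$similarities == 0))

  expect_error(pairwise_similarity_summary(matrix(1, 1, 4)), "at least 2")
})

test_that("62 fingerprints give the full 1891 comparison pairs", {
  fps <- gen_fingerprints(62, n_bits = 61, density = 0.3, seed = 1)
  expect_equal(pairwise_similarity_summary(fps)$n_pairs, 1891L)
})

test_that("pooled t-test agrees with the closed form and handles degeneracy", {
  res <- compare_property(c(1, 2, 3), c(1, 2, 3, 4, 5))
  orc <- pooled_t_oracle(c(1, 2, 3), c(1, 2, 3, 4, 5))
  expect_equal(res$t_stat, orc$t, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  expect_equal(res$df, 6)

  set.seed(99)
  for (i in 1:25) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    res <- compare_property(a, b)
    orc <- pooled_t_oracle(a, b)
    expect_equal(res$t_stat, orc$t, tolerance = 1e-12)
    expect_equal(res$p_value, orc$p, tolerance = 1e-12)
    expect_equal(sign(res$t_stat), sign(res$mean_a - res$mean_b))
  }

  ident <- compare_property(c(2, 2, 2), c(2, 2))
  expect_equal(ident$t_stat, 0)
  expect_equal(ident$p_value, 1)
  expect_error(compare_property(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_property(1, c(1, 2)), "at least 2")
})

test_that("Welch option reproduces t.test(var.equal = FALSE)", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(10, 11, 15, 9, 12, 14)
  res <- compare_property(a, b, welch = TRUE)
  ref <- t.test(a, b)
  expect_equal(res$t_stat, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})
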