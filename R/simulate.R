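# Seeded generators for every input the pipeline consumes: two-herb
# component property tables, bipartite component-target edge lists,
# annotation universes with one planted enriched set, and binary
# fingerprints. All are pure functions of their arguments plus the seed.

#' Describe one herb's component property distributions
#'
#' A generator profile: per-property means and dispersions plus the
#' probability of the high-GI-absorption class. Continuous properties are
#' drawn from normals (clamped to their natural ranges: `mw`, `ob`,
#' `tpsa` non-negative, `dl` in `[0, 1]`), the H-bond counts from Poisson
#' distributions.
#'
#' @param herb herb label (e.g. `"ZHISHI"`).
#' @param n_components number of components to draw (>= 1).
#' @param means named numeric vector of property means; names must be
#'   `mw`, `ob`, `caco2`, `dl`, `mlogp`, `nhacc`, `nhdon`, `tpsa`.
#' @param sds named numeric vector of positive dispersions for the
#'   normal-distributed properties (`nhacc`/`nhdon` are Poisson and take
#'   their dispersion from the mean).
#' @param gi_high_prob probability that a component is in the high-GI
#'   class.
#' @param id_prefix prefix for generated component ids (default: first
#'   two letters of `herb`).
#' @return An object of class `herb_profile`.
#' @seealso [zhishi_profile()], [baizhu_profile()], [gen_component_table()]
#' @export
herb_profile <- function(herb, n_components,
                         means = c(mw = 300, ob = 40, caco2 = 0.5, dl = 0.3,
                                   mlogp = 1, nhacc = 5, nhdon = 2,
                                   tpsa = 80),
                         sds = c(mw = 120, ob = 20, caco2 = 0.8, dl = 0.18,
                                 mlogp = 1.5, tpsa = 45),
                         gi_high_prob = 0.9,
                         id_prefix = toupper(substr(herb, 1, 2))) {
  props <- c("mw", "ob", "caco2", "dl", "mlogp", "nhacc", "nhdon", "tpsa")
  if (!all(props %in% names(means)))
    stop("`means` must name all of: ", paste(props, collapse = ", "),
         call. = FALSE)
  if (!all(c("mw", "ob", "caco2", "dl", "mlogp", "tpsa") %in% names(sds)))
    stop("`sds` must name the normal-distributed properties", call. = FALSE)
  if (any(sds <= 0)) stop("dispersions must be positive", call. = FALSE)
  if (gi_high_prob < 0 || gi_high_prob > 1)
    stop("`gi_high_prob` must lie in [0, 1]", call. = FALSE)
  if (n_components < 1) stop("`n_components` must be >= 1", call. = FALSE)
  structure(list(herb = herb, n_components = as.integer(n_components),
                 means = means[props],
                 sds = sds[c("mw", "ob", "caco2", "dl", "mlogp", "tpsa")],
                 gi_high_prob = gi_high_prob, id_prefix = id_prefix),
            class = "herb_profile")
}

#' Zhishi-like and Baizhu-like generator profiles
#'
#' Profiles whose property means reproduce the reported per-herb averages
#' of the Zhi-zhu Wan component survey: Zhishi (the flavonoid-rich Citrus
#' herb) has higher MW (393.39 vs 252.67), DL (0.41 vs 0.20), nHAcc
#' (7.67 vs 2.95), nHDon (3.50 vs 1.54) and lower OB (28.94 vs 37.76),
#' Caco-2 (-0.20 vs 0.69) and MLogP (0.15 vs 2.10) than Baizhu (the
#' lactone-rich Atractylodes herb); the remaining TPSA means (51.65 vs
#' 120.45) are taken at face value. Dispersions are not part of the
#' published summary; the defaults are sized so the between-herb
#' differences are detectable at the surveyed sample sizes (150 and 128).
#'
#' @param n_components number of components (defaults: 150 Zhishi, 128
#'   Baizhu, the surveyed set sizes).
#' @return A [herb_profile()].
#' @examples
#' comps <- gen_component_table(list(zhishi_profile(), baizhu_profile()),
#'                              seed = 1)
#' compare_herb_properties(comps, "ZHISHI", "BAIZHU")[1, ]
#' @export
zhishi_profile <- function(n_components = 150) {
  herb_profile("ZHISHI", n_components,
               means = c(mw = 393.39, ob = 28.94, caco2 = -0.20, dl = 0.41,
                         mlogp = 0.15, nhacc = 7.67, nhdon = 3.50,
                         tpsa = 51.65),
               id_prefix = "ZS")
}

#' @rdname zhishi_profile
#' @export
baizhu_profile <- function(n_components = 128) {
  herb_profile("BAIZHU", n_components,
               means = c(mw = 252.67, ob = 37.76, caco2 = 0.69, dl = 0.20,
                         mlogp = 2.10, nhacc = 2.95, nhdon = 1.54,
                         tpsa = 120.45),
               id_prefix = "BZ")
}

#' Generate a synthetic component property table
#'
#' Draws a component table from one or more [herb_profile()]s,
#' reproducibly for a fixed seed. The output satisfies the component-table
#' schema (see [read_component_table()]) and can be written with
#' [write_component_table()].
#'
#' @param profiles a list of [herb_profile()] objects (a single profile
#'   may be passed unwrapped).
#' @param seed RNG seed (mandatory; the generator is a pure function of
#'   profiles + seed).
#' @return A component data.frame with a `herb` column.
#' @export
gen_component_table <- function(profiles, seed) {
  if (inherits(profiles, "herb_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "herb_profile")))
  with_seed(seed, {
    tabs <- lapply(profiles, function(p) {
      n <- p$n_components
      m <- p$means
      s <- p$sds
      data.frame(
        id = paste0(p$id_prefix, seq_len(n)),
        name = paste0("synthetic-", tolower(p$herb), "-", seq_len(n)),
        mw = pmax(rnorm(n, m[["mw"]], s[["mw"]]), 50),
        ob = pmax(rnorm(n, m[["ob"]], s[["ob"]]), 0),
        caco2 = rnorm(n, m[["caco2"]], s[["caco2"]]),
        dl = pmin(pmax(rnorm(n, m[["dl"]], s[["dl"]]), 0), 1),
        mlogp = rnorm(n, m[["mlogp"]], s[["mlogp"]]),
        nhacc = rpois(n, m[["nhacc"]]),
        nhdon = rpois(n, m[["nhdon"]]),
        tpsa = pmax(rnorm(n, m[["tpsa"]], s[["tpsa"]]), 0),
        gi = ifelse(runif(n) < p$gi_high_prob, "high", "low"),
        herb = p$herb,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
}

#' Generate a seeded bipartite component-target edge list
#'
#' Draws a simple bipartite network with an exact edge count in which
#' every component has degree at least 1: each component first receives
#' one uniformly chosen target, then the remaining edges are sampled
#' uniformly without replacement from the unused component-target pairs.
#' Identical arguments and seed give an identical edge list.
#'
#' @param n_components named integer vector giving the number of
#'   components per herb (e.g. `c(ZHISHI = 44, BAIZHU = 17)`); an unnamed
#'   single count generates one unlabelled herb `"HERB"`.
#' @param n_targets number of targets.
#' @param n_edges total edges; must lie in
#'   `[sum(n_components), sum(n_components) * n_targets]`.
#' @param seed RNG seed (mandatory).
#' @param target_prefix prefix for target ids.
#' @param cover_right also guarantee that every target has degree at
#'   least 1 (requires `n_edges >= sum(n_components) + n_targets`);
#'   use for networks whose reported node counts include every target.
#' @return A list with `edges` (data.frame `from`/`to`) and `herb_of`
#'   (named character vector mapping component ids to herbs).
#' @examples
#' net <- gen_bipartite_edges(c(ZHISHI = 44, BAIZHU = 17), 133, 650, seed = 7)
#' nrow(net$edges)   # 650
#' @export
gen_bipartite_edges <- function(n_components, n_targets, n_edges, seed,
                                target_prefix = "T", cover_right = FALSE) {
  if (is.null(names(n_components))) {
    if (length(n_components) != 1L)
      stop("`n_components` must be named when giving several herbs",
           call. = FALSE)
    names(n_components) <- "HERB"
  }
  n_comp <- sum(n_components)
  if (n_comp < 1L || n_targets < 1L)
    stop("need at least one component and one target", call. = FALSE)
  if (n_edges < n_comp || n_edges > n_comp * n_targets)
    stop("`n_edges` must lie in [", n_comp, ", ", n_comp * n_targets, "]",
         call. = FALSE)
  if (cover_right && n_edges < n_comp + n_targets)
    stop("covering every target needs n_edges >= ", n_comp + n_targets,
         call. = FALSE)
  pre <- toupper(substr(names(n_components), 1, 2))
  if (anyDuplicated(pre)) pre <- names(n_components)  # keep ids unique
  herbs <- rep(names(n_components), n_components)
  prefixes <- rep(pre, n_components)
  comp_ids <- paste0(prefixes, "-", unlist(lapply(n_components, seq_len)))
  targ_ids <- paste0(target_prefix, seq_len(n_targets))
  with_seed(seed, {
    # one guaranteed edge per component
    first <- sample.int(n_targets, n_comp, replace = TRUE)
    used <- (seq_len(n_comp) - 1L) * n_targets + first
    if (cover_right) {
      uncovered <- setdiff(seq_len(n_targets), unique(first))
      if (length(uncovered)) {
        owner <- sample.int(n_comp, length(uncovered), replace = TRUE)
        used <- c(used, (owner - 1L) * n_targets + uncovered)
      }
    }
    extra <- n_edges - length(used)
    if (extra > 0L) {
      pool <- setdiff(seq_len(n_comp * n_targets), used)
      used <- c(used, sample(pool, extra))
    }
    ci <- (used - 1L) %/% n_targets + 1L
    ti <- (used - 1L) %% n_targets + 1L
    ord <- order(ci, ti)
    list(edges = data.frame(from = comp_ids[ci[ord]], to = targ_ids[ti[ord]],
                            stringsAsFactors = FALSE),
         herb_of = stats::setNames(herbs, comp_ids))
  })
}

#' Generate an annotation universe with one planted enriched set
#'
#' Builds a gene universe containing the query set, plants one annotation
#' that overlaps the query in exactly `k` genes, and adds uniformly drawn
#' decoy annotations — a ground-truth fixture for over-representation
#' analysis ([rank_annotations()]).
#'
#' @param query_set character vector of query gene ids.
#' @param universe_size universe size `N` (>= `length(query_set)`).
#' @param planted_size size `K` of the planted annotation.
#' @param planted_overlap overlap `k` with the query set,
#'   `k <= min(K, length(query_set))`.
#' @param n_decoys number of decoy annotations.
#' @param decoy_size size of each decoy (default `planted_size`).
#' @param seed RNG seed (mandatory).
#' @return A list with `annotations` (named list of gene sets; the planted
#'   one is called `"PLANTED"`), `genes` (the universe id vector) and
#'   `planted` (its name).
#' @examples
#' q <- paste0("g", 1:100)
#' u <- gen_annotation_universe(q, universe_size = 1000, planted_size = 40,
#'                              planted_overlap = 15, n_decoys = 50, seed = 3)
#' rank_annotations(q, u$annotations, universe_size = 1000)[1, ]
#' @export
gen_annotation_universe <- function(query_set, universe_size, planted_size,
                                    planted_overlap, n_decoys,
                                    decoy_size = planted_size, seed) {
  query_set <- unique(as.character(query_set))
  if (universe_size < length(query_set))
    stop("universe smaller than the query set", call. = FALSE)
  if (planted_size > universe_size)
    stop("planted annotation larger than the universe", call. = FALSE)
  if (planted_overlap > min(planted_size, length(query_set)))
    stop("`planted_overlap` cannot exceed min(planted_size, |query|)",
         call. = FALSE)
  n_extra <- universe_size - length(query_set)
  genes <- c(query_set, if (n_extra) paste0("decoygene", seq_len(n_extra)))
  background <- setdiff(genes, query_set)
  with_seed(seed, {
    planted <- c(sample(query_set, planted_overlap),
                 sample(background, planted_size - planted_overlap))
    decoys <- lapply(seq_len(n_decoys), function(i) sample(genes, decoy_size))
    names(decoys) <- sprintf("DECOY%03d", seq_len(n_decoys))
    list(annotations = c(list(PLANTED = planted), decoys),
         genes = genes, planted = "PLANTED")
  })
}

#' Generate random binary fingerprints
#'
#' Independent Bernoulli bits, reproducible per seed; a stand-in for
#' substructure profiles when real fingerprints are unavailable.
#'
#' @param n number of fingerprints.
#' @param n_bits fingerprint length (default 61, the substructure count
#'   used for the packaged formula's profiles).
#' @param density probability that a bit is set, in `[0, 1]`.
#' @param seed RNG seed (mandatory).
#' @param ids optional component ids for the rownames.
#' @return An integer 0/1 matrix, one fingerprint per row.
#' @export
gen_fingerprints <- function(n, n_bits = 61, density = 0.3, seed,
                             ids = NULL) {
  if (n_bits < 1) stop("`n_bits` must be >= 1", call. = FALSE)
  if (density < 0 || density > 1)
    stop("`density` must lie in [0, 1]", call. = FALSE)
  if (!is.null(ids) && length(ids) != n)
    stop("`ids` must have length n", call. = FALSE)
  with_seed(seed, {
    mat <- matrix(rbinom(n * n_bits, 1L, density), nrow = n)
    rownames(mat) <- if (is.null(ids)) paste0("FP", seq_len(n)) else ids
    mat
  })
}
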