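# Four-criterion ADME screen (OB / Caco-2 / DL / GI), Tanimoto similarity
# for descriptor vectors and binary fingerprints, and per-herb property
# comparison by two-sample t-test.

#' Screening criteria for the ADME filter
#'
#' Bundles the four thresholds of the standard TCM active-component screen:
#' oral bioavailability `ob >= ob_min` (inclusive), Caco-2 permeability
#' `caco2 > caco2_min` (strict: components at or below the threshold are
#' considered non-permeable), drug-likeness `dl >= dl_min` (inclusive,
#' with optional per-herb overrides such as a relaxed threshold for the
#' lactone-rich Baizhu), and a required GI absorption class. A whitelist
#' of component ids is always retained regardless of the criteria,
#' mirroring the common practice of keeping high-abundance, high-activity
#' marker components that fail the automatic screen.
#'
#' @param ob_min minimum oral bioavailability, percent (default 30).
#' @param caco2_min exclusive lower bound on Caco-2 permeability
#'   (default -0.4).
#' @param dl_min default minimum drug-likeness (default 0.18).
#' @param dl_min_by_herb named numeric vector of per-herb drug-likeness
#'   thresholds overriding `dl_min` (default `c(BAIZHU = 0.14)`).
#' @param gi_required required GI absorption class, `"high"` or `"low"`.
#' @param whitelist character vector of component ids retained
#'   unconditionally.
#' @return An object of class `screening_criteria`.
#' @examples
#' screening_criteria()                      # the standard thresholds
#' screening_criteria(whitelist = c("ZS104", "ZS130"))
#' @export
screening_criteria <- function(ob_min = 30, caco2_min = -0.4,
                               dl_min = 0.18,
                               dl_min_by_herb = c(BAIZHU = 0.14),
                               gi_required = c("high", "low"),
                               whitelist = character()) {
  gi_required <- match.arg(gi_required)
  stopifnot(is.finite(ob_min), is.finite(caco2_min), is.finite(dl_min))
  if (length(dl_min_by_herb) &&
      (is.null(names(dl_min_by_herb)) || any(!nzchar(names(dl_min_by_herb)))))
    stop("`dl_min_by_herb` must be a named numeric vector", call. = FALSE)
  structure(list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min,
                 dl_min_by_herb = dl_min_by_herb, gi_required = gi_required,
                 whitelist = unique(as.character(whitelist))),
            class = "screening_criteria")
}

#' @export
print.screening_criteria <- function(x, ...) {
  cat("ADME screening criteria\n")
  cat(sprintf("  OB     >= %g %%\n", x$ob_min))
  cat(sprintf("  Caco-2 >  %g\n", x$caco2_min))
  cat(sprintf("  DL     >= %g", x$dl_min))
  if (length(x$dl_min_by_herb))
    cat(" (", paste(names(x$dl_min_by_herb), ">=", x$dl_min_by_herb,
                    collapse = "; "), ")", sep = "")
  cat(sprintf("\n  GI     == %s\n", x$gi_required))
  if (length(x$whitelist))
    cat("  whitelist:", paste(x$whitelist, collapse = ", "), "\n")
  invisible(x)
}

.dl_threshold <- function(herb, criteria) {
  if (!is.null(herb) && !is.na(herb) && herb %in% names(criteria$dl_min_by_herb))
    unname(criteria$dl_min_by_herb[[herb]])
  else
    criteria$dl_min
}

#' Evaluate one component against the screening criteria
#'
#' Applies the four tests in the fixed order OB, CACO2, DL, GI and records
#' which fail. The drug-likeness threshold is resolved through the
#' component's herb (components without a herb label use the default
#' threshold).
#'
#' @param component a one-row data.frame or named list with fields `id`,
#'   `ob`, `caco2`, `dl`, `gi` and optionally `herb`.
#' @param criteria a [screening_criteria()] object.
#' @return A list with `component_id`, `passed`, `failed_criteria`
#'   (character vector, subset of `c("OB","CACO2","DL","GI")` in that
#'   order) and `retained_by_whitelist`.
#' @examples
#' crit <- screening_criteria()
#' hesperidin <- list(id = "ZS130", herb = "ZHISHI",
#'                    ob = 13.33, caco2 = -2.03, dl = 0.67, gi = "low")
#' evaluate_component(hesperidin, crit)$failed_criteria  # OB CACO2 GI
#' @export
evaluate_component <- function(component, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  herb <- if ("herb" %in% names(component)) component[["herb"]] else NA
  failed <- character()
  if (component[["ob"]] < criteria$ob_min) failed <- c(failed, "OB")
  if (component[["caco2"]] <= criteria$caco2_min) failed <- c(failed, "CACO2")
  if (component[["dl"]] < .dl_threshold(herb, criteria)) failed <- c(failed, "DL")
  if (tolower(component[["gi"]]) != criteria$gi_required) failed <- c(failed, "GI")
  list(component_id = as.character(component[["id"]]),
       passed = length(failed) == 0L,
       failed_criteria = failed,
       retained_by_whitelist = component[["id"]] %in% criteria$whitelist &&
         length(failed) > 0L)
}

#' Apply the ADME screen to a component table
#'
#' Screens every component, keeping those that pass all four criteria plus
#' any whitelisted ids present in the input. Input order is preserved.
#'
#' @param components data.frame as from [read_component_table()].
#' @param criteria a [screening_criteria()] object.
#' @return A list with `active` (the retained subset of `components`) and
#'   `decisions`, a data.frame with one row per input component: `id`,
#'   `passed`, `failed_criteria` (comma-joined), `retained_by_whitelist`
#'   and `active`. Whitelist ids absent from the input raise a warning.
#' @examples
#' comps <- read_component_table(herbnet_example("zzw_components.tsv"))
#' scr <- apply_screen(comps)
#' subset(scr$decisions, !passed)$id   # the six automatic failures
#' @export
apply_screen <- function(components, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  missing_wl <- setdiff(criteria$whitelist, components$id)
  if (length(missing_wl))
    warning("whitelist id(s) not in component table: ",
            paste(missing_wl, collapse = ", "), call. = FALSE)
  n <- nrow(components)
  decisions <- data.frame(
    id = character(n), passed = logical(n), failed_criteria = character(n),
    retained_by_whitelist = logical(n), active = logical(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- evaluate_component(components[i, ], criteria)
    decisions$id[i] <- d$component_id
    decisions$passed[i] <- d$passed
    decisions$failed_criteria[i] <- paste(d$failed_criteria, collapse = ",")
    decisions$retained_by_whitelist[i] <- d$retained_by_whitelist
    decisions$active[i] <- d$passed || d$retained_by_whitelist
  }
  list(active = components[decisions$active, , drop = FALSE],
       decisions = decisions)
}

#' Tanimoto score for continuous descriptor vectors
#'
#' The descriptor-vector form of the Tanimoto coefficient,
#' `T(A, B) = (A.B) / (|A|^2 + |B|^2 - A.B)`, used e.g. to define
#' drug-likeness as the similarity between a component's molecular
#' descriptors and an average reference-drug descriptor vector. For
#' non-negative vectors the score lies in `[0, 1]` and equals 1 iff
#' `A == B`.
#'
#' @param a,b equal-length finite numeric vectors, not both all-zero.
#' @return The Tanimoto score, a single number.
#' @examples
#' tanimoto_similarity(c(1, 2), c(2, 2))   # 6/7
#' @export
tanimoto_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("descriptor vectors must have equal length", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("descriptor vectors must be finite", call. = FALSE)
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) {
    if (all(a == 0) && all(b == 0))
      stop("Tanimoto score undefined for two zero vectors", call. = FALSE)
    return(1)  # a == b, nonzero
  }
  ab / denom
}

# Binary (bit-set) Tanimoto: |a AND b| / |a OR b|.
tanimoto_binary <- function(a, b) {
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) return(NA_real_)
  inter / union
}

#' Pairwise fingerprint similarity summary
#'
#' Computes the binary Tanimoto similarity `|a AND b| / |a OR b|` over all
#' unordered distinct pairs of fingerprints and counts how many pairs fall
#' at or below a similarity threshold — the standard check that a
#' component set is structurally diverse (low mutual similarity implies a
#' low drug-drug interaction risk). Pairs of two all-zero fingerprints are
#' counted as similarity 0 with a warning.
#'
#' @param fps integer 0/1 matrix, one fingerprint per row (as from
#'   [read_fingerprints()] or [gen_fingerprints()]); at least 2 rows.
#' @param threshold similarity cut-off (default 0.2).
#' @return A list with `n_pairs` (`n(n-1)/2`), `n_below_or_equal`,
#'   `fraction` and the full `similarities` vector.
#' @examples
#' fps <- gen_fingerprints(62, seed = 1)
#' pairwise_similarity_summary(fps)$n_pairs   # 1891
#' @export
pairwise_similarity_summary <- function(fps, threshold = 0.2) {
  fps <- as.matrix(fps)
  n <- nrow(fps)
  if (n < 2L)
    stop("need at least 2 fingerprints", call. = FALSE)
  if (any(!fps %in% c(0L, 1L)))
    stop("fingerprints must be binary", call. = FALSE)
  storage.mode(fps) <- "integer"
  inter <- tcrossprod(fps)
  ones <- rowSums(fps)
  union <- outer(ones, ones, "+") - inter
  sim <- ifelse(union > 0, inter / union, NA_real_)
  sims <- sim[lower.tri(sim)]
  if (anyNA(sims)) {
    warning(sum(is.na(sims)),
            " pair(s) of empty fingerprints scored as similarity 0",
            call. = FALSE)
    sims[is.na(sims)] <- 0
  }
  list(n_pairs = length(sims),
       n_below_or_equal = sum(sims <= threshold),
       fraction = sum(sims <= threshold) / length(sims),
       similarities = sims)
}

#' Compare a property between two groups by two-sample t-test
#'
#' Two-sided two-sample t-test with pooled variance (Student's test;
#' `welch = TRUE` switches to the unequal-variance form), used to compare
#' a physicochemical property between the component sets of two herbs.
#' Degenerate inputs with zero pooled variance return `t = 0, p = 1` when
#' the group means are equal and are an error otherwise.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2, finite).
#' @param property optional property name carried into the result.
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   form.
#' @return A one-row data.frame with `property`, `mean_a`, `mean_b`,
#'   `t_stat` (sign matches `mean_a - mean_b`), `p_value`, `df`, `n_a`,
#'   `n_b`.
#' @examples
#' compare_property(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
compare_property <- function(values_a, values_b, property = NA_character_,
                             welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("values must be finite", call. = FALSE)
  if (var(values_a) == 0 && var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      t_stat <- 0
      p <- 1
      df <- length(values_a) + length(values_b) - 2L
    } else {
      stop("zero variance in both groups with unequal means: ",
           "t statistic undefined", call. = FALSE)
    }
  } else {
    fit <- t.test(values_a, values_b, var.equal = !welch,
                  alternative = "two.sided")
    t_stat <- unname(fit$statistic)
    p <- fit$p.value
    df <- unname(fit$parameter)
  }
  data.frame(property = property,
             mean_a = mean(values_a), mean_b = mean(values_b),
             t_stat = t_stat, p_value = p, df = df,
             n_a = length(values_a), n_b = length(values_b),
             stringsAsFactors = FALSE)
}

#' Compare all properties between two herbs
#'
#' Convenience wrapper running [compare_property()] for each numeric
#' property column of a component table, split by herb.
#'
#' @param components data.frame as from [read_component_table()].
#' @param herb_a,herb_b the two herb labels to compare.
#' @param properties property columns to test.
#' @param welch passed to [compare_property()].
#' @return A data.frame with one row per property.
#' @export
compare_herb_properties <- function(components, herb_a, herb_b,
                                    properties = c("mw", "ob", "caco2", "dl",
                                                   "mlogp", "nhacc", "nhdon",
                                                   "tpsa"),
                                    welch = FALSE) {
  a <- components[components$herb %in% herb_a, , drop = FALSE]
  b <- components[components$herb %in% herb_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("no components found for one of the herbs", call. = FALSE)
  out <- lapply(properties, function(p)
    compare_property(a[[p]], b[[p]], property = p, welch = welch))
  do.call(rbind, out)
}
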