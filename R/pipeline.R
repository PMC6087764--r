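# End-to-end orchestration: read inputs -> ADME screen -> component-target
# network (+ per-herb subnetworks, shared targets) -> contribution scores
# -> optional target-pathway network, enrichment and similarity profiling
# -> TSV outputs and a JSON run report.

#' Pipeline configuration
#'
#' Collects input paths and analysis settings for [run_pipeline()]. Only
#' `components` and `ct_edges` are mandatory; the other analyses run when
#' their inputs are given.
#'
#' @param components path to a component property table (TSV).
#' @param ct_edges path to the component-target edge list (TSV).
#' @param targets optional path to a target table (TSV).
#' @param tp_edges optional path to a target-pathway edge list (TSV).
#' @param annotations optional path to a disease/pathway annotation map.
#' @param fingerprints optional path to a fingerprint table.
#' @param criteria a [screening_criteria()] object.
#' @param cs_policy degenerate-denominator policy for
#'   [contribution_scores()].
#' @param alpha significance level for enrichment.
#' @param similarity_threshold cut-off for the similarity summary.
#' @param universe_size optional explicit enrichment universe size.
#' @param out_dir output directory (created if needed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(components, ct_edges, targets = NULL,
                            tp_edges = NULL, annotations = NULL,
                            fingerprints = NULL,
                            criteria = screening_criteria(),
                            cs_policy = "floor", alpha = 0.05,
                            similarity_threshold = 0.2,
                            universe_size = NULL,
                            out_dir = tempfile("herbnet_run")) {
  stopifnot(inherits(criteria, "screening_criteria"))
  paths <- list(components = components, ct_edges = ct_edges,
                targets = targets, tp_edges = tp_edges,
                annotations = annotations, fingerprints = fingerprints)
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop("input file for ", sQuote(nm), " does not exist: ", paths[[nm]],
           call. = FALSE)
  structure(c(paths, list(criteria = criteria, cs_policy = cs_policy,
                          alpha = alpha,
                          similarity_threshold = similarity_threshold,
                          universe_size = universe_size,
                          out_dir = out_dir)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()]; the `criteria` key may hold a mapping with
#' `ob_min`, `caco2_min`, `dl_min`, `dl_min_by_herb`, `gi_required` and
#' `whitelist`. Relative input paths are resolved against the YAML file's
#' directory.
#'
#' @param path path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  crit <- screening_criteria()
  if (!is.null(raw$criteria)) {
    cc <- raw$criteria
    crit <- screening_criteria(
      ob_min = cc$ob_min %||% 30,
      caco2_min = cc$caco2_min %||% -0.4,
      dl_min = cc$dl_min %||% 0.18,
      dl_min_by_herb = if (is.null(cc$dl_min_by_herb)) c(BAIZHU = 0.14)
                       else unlist(cc$dl_min_by_herb),
      gi_required = cc$gi_required %||% "high",
      whitelist = cc$whitelist %||% character())
  }
  pipeline_config(
    components = resolve(raw$components),
    ct_edges = resolve(raw$ct_edges),
    targets = resolve(raw$targets),
    tp_edges = resolve(raw$tp_edges),
    annotations = resolve(raw$annotations),
    fingerprints = resolve(raw$fingerprints),
    criteria = crit,
    cs_policy = raw$cs_policy %||% "floor",
    alpha = raw$alpha %||% 0.05,
    similarity_threshold = raw$similarity_threshold %||% 0.2,
    universe_size = raw$universe_size,
    out_dir = raw$out_dir %||% tempfile("herbnet_run"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.criteria_as_list <- function(crit) {
  list(ob_min = crit$ob_min, caco2_min = crit$caco2_min,
       dl_min = crit$dl_min, dl_min_by_herb = as.list(crit$dl_min_by_herb),
       gi_required = crit$gi_required, whitelist = crit$whitelist)
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage, writes TSV/SIF/GraphML outputs and a
#' JSON run report into `config$out_dir`, and returns the report as a
#' list. Stages: ADME screen (decisions.tsv), component-target network
#' (ct.sif, ct.graphml) with per-herb subnetwork summaries and shared
#' targets, contribution scores (cs.tsv), and — when inputs are given —
#' target-pathway network summary, annotation enrichment
#' (enrichment.tsv) and fingerprint similarity. A stage failure aborts
#' with an error naming the stage, and partial outputs are removed.
#'
#' The report is deterministic for identical inputs apart from the single
#' `timestamp` field.
#'
#' @param config a [pipeline_config()].
#' @return The run report, invisibly (also written to `report.json`).
#' @examples
#' \donttest{
#' net <- gen_bipartite_edges(c(ZHISHI = 44, BAIZHU = 17), 133, 650, seed = 7)
#' td <- tempfile(); dir.create(td)
#' write_edge_list(net$edges, file.path(td, "ct.tsv"))
#' cfg <- pipeline_config(herbnet_example("zzw_components.tsv"),
#'                        file.path(td, "ct.tsv"), out_dir = td)
#' rep <- run_pipeline(cfg)
#' rep$screen$n_active
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(writer, path) {
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "init"
  report <- tryCatch({
    stage <- "screen"
    comps <- read_component_table(config$components)
    scr <- apply_screen(comps, config$criteria)
    emit(function(p) write.table(scr$decisions, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE),
         file.path(config$out_dir, "decisions.tsv"))

    stage <- "network"
    edges <- read_edge_list(config$ct_edges)
    herb_of <- stats::setNames(comps$herb, comps$id)
    herb_of <- herb_of[!is.na(herb_of)]
    active_ids <- scr$active$id
    edges <- edges[edges$from %in% active_ids, , drop = FALSE]
    if (!nrow(edges))
      stop("no component-target edges for active components")
    net <- build_bipartite(edges, herb_of = herb_of)
    emit(function(p) export_sif(net, p),
         file.path(config$out_dir, "ct.sif"))
    emit(function(p) export_graphml(net, p),
         file.path(config$out_dir, "ct.graphml"))
    herbs <- sort(unique(unname(net$herb_of[unique(net$edges$from)])))
    subnets <- lapply(herbs, function(h) herb_subnetwork(net, h))
    names(subnets) <- herbs
    shared <- if (length(subnets) == 2L)
      shared_targets(subnets[[1L]], subnets[[2L]]) else character()

    stage <- "contribution"
    cs <- contribution_scores(net, policy = config$cs_policy)
    emit(function(p) write.table(cs, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE),
         file.path(config$out_dir, "cs.tsv"))

    tp_summary <- NULL
    if (!is.null(config$tp_edges)) {
      stage <- "pathway_network"
      tp <- build_bipartite(read_edge_list(config$tp_edges))
      tp_summary <- unclass(summary(tp))
    }

    enr_head <- NULL
    if (!is.null(config$annotations)) {
      stage <- "enrichment"
      ann <- read_annotations(config$annotations)
      enr <- rank_annotations(unique(net$edges$to), ann,
                              alpha = config$alpha,
                              universe_size = config$universe_size)
      emit(function(p) write.table(enr, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE),
           file.path(config$out_dir, "enrichment.tsv"))
      enr_head <- head(enr, 10L)
    }

    sim <- NULL
    if (!is.null(config$fingerprints)) {
      stage <- "similarity"
      fps <- read_fingerprints(config$fingerprints)
      s <- pairwise_similarity_summary(fps, config$similarity_threshold)
      sim <- s[c("n_pairs", "n_below_or_equal", "fraction")]
    }

    stage <- "report"
    inputs <- Filter(Negate(is.null),
                     config[c("components", "ct_edges", "targets", "tp_edges",
                              "annotations", "fingerprints")])
    report <- list(
      tool = "herbnet",
      version = as.character(utils::packageVersion("herbnet")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = list(criteria = .criteria_as_list(config$criteria),
                    cs_policy = config$cs_policy, alpha = config$alpha,
                    similarity_threshold = config$similarity_threshold),
      input_checksums = as.list(tools::md5sum(unlist(inputs))),
      screen = list(n_components = nrow(comps),
                    n_active = nrow(scr$active),
                    n_failed = sum(!scr$decisions$passed),
                    failed_ids = scr$decisions$id[!scr$decisions$passed]),
      ct_network = unclass(summary(net)),
      herb_networks = lapply(subnets, function(s) unclass(summary(s))),
      shared_targets = shared,
      contribution = list(
        n_components = nrow(cs),
        cs_pct_total = sum(cs$cs_pct),
        top = head(cs[c("component_id", "degree", "cs", "cs_pct",
                        "cum_pct")], 10L),
        k_for_90pct = cumulative_report(cs, 90)$k),
      tp_network = tp_summary,
      enrichment_top = enr_head,
      similarity = sim)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    report
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage ", sQuote(stage), ": ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(report)
}
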