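# Bipartite component-target / target-pathway networks: construction,
# degree statistics, per-herb subnetworks, shared targets, rankings, and
# Cytoscape-readable exports (SIF, GraphML via igraph).

#' Build a bipartite network
#'
#' Constructs a simple (duplicate edges collapse to one) bipartite network
#' from an edge list, with optional explicit node sets — isolated declared
#' nodes are retained with degree 0 — and an optional herb label for each
#' left node. An id appearing on both sides is an error.
#'
#' @param edges data.frame with character columns `from` (left side, e.g.
#'   components) and `to` (right side, e.g. targets), as from
#'   [read_edge_list()].
#' @param left_ids,right_ids optional character vectors declaring the node
#'   sets; defaults to the ids observed in `edges`.
#' @param herb_of optional named character vector mapping left-node ids to
#'   herb labels.
#' @return An object of class `bipartite_net`: a list with `left`, `right`
#'   (sorted id vectors), `edges` (deduplicated data.frame), `degree`
#'   (named integer vector over all nodes) and `herb_of`.
#' @examples
#' net <- build_bipartite(data.frame(from = c("c1", "c1", "c2"),
#'                                   to   = c("t1", "t2", "t1")))
#' net$degree[["c1"]]   # 2
#' summary(net)
#' @export
build_bipartite <- function(edges, left_ids = NULL, right_ids = NULL,
                            herb_of = NULL) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                 drop = FALSE]
  left <- sort(unique(c(edges$from, as.character(left_ids))))
  right <- sort(unique(c(edges$to, as.character(right_ids))))
  both <- intersect(left, right)
  if (length(both))
    stop("id(s) appear on both sides of the bipartite network: ",
         paste(head(both, 3L), collapse = ", "), call. = FALSE)
  deg <- c(table(factor(edges$from, levels = left)),
           table(factor(edges$to, levels = right)))
  deg <- stats::setNames(as.integer(deg), c(left, right))
  if (!is.null(herb_of)) {
    herb_of <- herb_of[names(herb_of) %in% left]
    if (anyNA(herb_of))
      stop("herb labels must not be NA", call. = FALSE)
  }
  structure(list(left = left, right = right, edges = edges,
                 degree = deg, herb_of = herb_of),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("bipartite network: %d left x %d right nodes, %d edges\n",
              length(x$left), length(x$right), nrow(x$edges)))
  if (!is.null(x$herb_of))
    cat("  herbs:", paste(sort(unique(x$herb_of)), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a bipartite network
#'
#' Node and edge counts plus the two mean degrees: edges per left node
#' (e.g. targets per component) and edges per right node (components per
#' target). Means are kept at full precision; round only for reporting.
#'
#' @param object a [build_bipartite()] network with both sides non-empty.
#' @param ... unused.
#' @return A list of class `bipartite_summary` with `n_left`, `n_right`,
#'   `n_nodes`, `n_edges`, `mean_left_degree`, `mean_right_degree`.
#' @examples
#' net <- gen_bipartite_edges(c(ZHISHI = 44, BAIZHU = 17), 133, 650, seed = 7)
#' s <- summary(build_bipartite(net$edges, herb_of = net$herb_of))
#' round(s$mean_right_degree, 1)   # 650/133 -> 4.9
#' @export
summary.bipartite_net <- function(object, ...) {
  if (!length(object$left) || !length(object$right))
    stop("cannot summarize a network with an empty side", call. = FALSE)
  n_edges <- nrow(object$edges)
  structure(list(n_left = length(object$left),
                 n_right = length(object$right),
                 n_nodes = length(object$left) + length(object$right),
                 n_edges = n_edges,
                 mean_left_degree = n_edges / length(object$left),
                 mean_right_degree = n_edges / length(object$right)),
            class = "bipartite_summary")
}

#' @export
print.bipartite_summary <- function(x, ...) {
  cat(sprintf("%d nodes (%d left + %d right), %d edges\n",
              x$n_nodes, x$n_left, x$n_right, x$n_edges))
  cat(sprintf("mean degree: left %.1f, right %.1f\n",
              x$mean_left_degree, x$mean_right_degree))
  invisible(x)
}

#' Restrict a network to one herb's components
#'
#' Keeps the edges whose left node belongs to the given herb; right nodes
#' are those with at least one retained edge, left nodes are all of the
#' herb's components (isolated ones keep degree 0).
#'
#' @param net a [build_bipartite()] network with `herb_of` populated.
#' @param herb a herb label present in `net$herb_of`.
#' @return A `bipartite_net`.
#' @export
herb_subnetwork <- function(net, herb) {
  stopifnot(inherits(net, "bipartite_net"))
  if (is.null(net$herb_of))
    stop("network has no herb labels", call. = FALSE)
  if (!herb %in% net$herb_of)
    stop("unknown herb label: ", sQuote(herb), call. = FALSE)
  comps <- names(net$herb_of)[net$herb_of == herb]
  edges <- net$edges[net$edges$from %in% comps, , drop = FALSE]
  build_bipartite(edges, left_ids = comps,
                  herb_of = net$herb_of[comps])
}

#' Targets shared by two networks
#'
#' Right-side nodes carrying at least one edge in each network — e.g. the
#' targets hit by both herbs' components.
#'
#' @param net_a,net_b two networks over a shared right-node namespace.
#' @return A sorted character vector of shared right-node ids.
#' @export
shared_targets <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "bipartite_net"), inherits(net_b, "bipartite_net"))
  hit_a <- unique(net_a$edges$to)
  hit_b <- unique(net_b$edges$to)
  sort(intersect(hit_a, hit_b))
}

#' Top nodes by degree
#'
#' Ranks one side of the network by degree, descending, with ties broken
#' by node id ascending so output is deterministic.
#'
#' @param net a `bipartite_net`.
#' @param side `"left"` or `"right"`.
#' @param k number of nodes to return (`k` larger than the side returns
#'   the full ranking with a warning).
#' @return A data.frame with columns `node` and `degree`.
#' @export
top_degree_nodes <- function(net, side = c("left", "right"), k = 10L) {
  stopifnot(inherits(net, "bipartite_net"))
  side <- match.arg(side)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  ids <- if (side == "left") net$left else net$right
  deg <- net$degree[ids]
  ord <- order(-deg, ids)
  if (k > length(ids)) {
    warning("k exceeds the number of ", side, " nodes; returning all",
            call. = FALSE)
    k <- length(ids)
  }
  data.frame(node = ids[ord][seq_len(k)],
             degree = unname(deg[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Export a network as SIF
#'
#' Writes the Cytoscape simple-interaction format,
#' `source<TAB>interaction<TAB>target`, one edge per line.
#'
#' @param net a `bipartite_net`.
#' @param path output path.
#' @param interaction interaction type written in the middle column.
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path, interaction = "targets") {
  stopifnot(inherits(net, "bipartite_net"))
  lines <- paste(net$edges$from, interaction, net$edges$to, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a SIF edge list
#'
#' @param path path to a SIF file.
#' @return A data.frame with columns `from` and `to` (the interaction
#'   column is dropped).
#' @export
read_sif <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
  if (ncol(raw) != 3L)
    stop("SIF lines must have three tab-separated fields", call. = FALSE)
  data.frame(from = raw[[1]], to = raw[[3]], stringsAsFactors = FALSE)
}

.as_igraph <- function(net) {
  nodes <- data.frame(
    name = c(net$left, net$right),
    side = c(rep("left", length(net$left)), rep("right", length(net$right))),
    stringsAsFactors = FALSE)
  herb <- rep(NA_character_, nrow(nodes))
  if (!is.null(net$herb_of)) {
    idx <- match(names(net$herb_of), nodes$name)
    herb[idx] <- unname(net$herb_of)
  }
  nodes$herb <- ifelse(is.na(herb), "", herb)
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = nodes)
}

#' Export a network as GraphML
#'
#' Writes a GraphML file (readable by Cytoscape) with `side` and `herb`
#' node attributes.
#'
#' @param net a `bipartite_net`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "bipartite_net"))
  igraph::write_graph(.as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back into a `bipartite_net`
#'
#' Inverse of [export_graphml()]; node and edge sets round-trip exactly.
#'
#' @param path path to a GraphML file written by [export_graphml()].
#' @return A `bipartite_net`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  side <- igraph::vertex_attr(g, "side")
  name <- igraph::vertex_attr(g, "name")
  herb <- igraph::vertex_attr(g, "herb")
  el <- igraph::as_edgelist(g)
  # orient each edge left -> right
  flip <- side[match(el[, 1], name)] == "right"
  edges <- data.frame(from = ifelse(flip, el[, 2], el[, 1]),
                      to = ifelse(flip, el[, 1], el[, 2]),
                      stringsAsFactors = FALSE)
  left <- name[side == "left"]
  herb_of <- NULL
  if (!is.null(herb) && any(nzchar(herb[side == "left"]))) {
    herb_of <- stats::setNames(herb[side == "left"], left)
    herb_of <- herb_of[nzchar(herb_of)]
  }
  build_bipartite(edges, left_ids = left, right_ids = name[side == "right"],
                  herb_of = herb_of)
}
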