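# Readers and writers for the tabular formats the pipeline consumes:
# component property tables, target tables, edge lists, annotation maps
# and binary fingerprints. All files are UTF-8, tab-separated, header row.

.component_cols <- c("id", "name", "mw", "ob", "caco2", "dl", "mlogp",
                     "nhacc", "nhdon", "tpsa", "gi")
.numeric_component_cols <- c("mw", "ob", "caco2", "dl", "mlogp",
                             "nhacc", "nhdon", "tpsa")

# Published tables print U+2212 for negative values; normalise before
# as.numeric so fixtures can stay verbatim.
.parse_numeric <- function(x, column) {
  x <- gsub("−", "-", trimws(x))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("unparseable numeric in column ", sQuote(column), " at row ",
         bad[1L], ": ", sQuote(x[bad[1L]]), call. = FALSE)
  out
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
             check.names = FALSE, quote = "", comment.char = "",
             fileEncoding = "UTF-8", na.strings = NULL,
             stringsAsFactors = FALSE)
}

#' Read a component property table
#'
#' Reads a tab-separated table of herbal components with the eight
#' physicochemical/ADME properties and the gastrointestinal absorption
#' class. Required columns: `id`, `name`, `mw` (molecular weight, g/mol),
#' `ob` (oral bioavailability, %), `caco2` (Caco-2 permeability, log scale),
#' `dl` (drug-likeness, 0-1), `mlogp` (Moriguchi logP), `nhacc`/`nhdon`
#' (H-bond acceptor/donor counts), `tpsa` (topological polar surface area,
#' A^2) and `gi` (`high`/`low`, case-insensitive). An optional `herb`
#' column labels the source herb; when absent, the herb is inferred from
#' the conventional `ZS`/`BZ` id prefixes (Zhishi/Baizhu) and is `NA` for
#' other prefixes.
#'
#' @param path path to a TSV file.
#' @return A `data.frame` with one row per component, columns as above plus
#'   `herb`, with numeric properties parsed (the Unicode minus sign of
#'   published tables is accepted) and `gi` normalised to `"high"`/`"low"`.
#' @examples
#' comps <- read_component_table(herbnet_example("zzw_components.tsv"))
#' nrow(comps)          # 62
#' table(comps$herb)    # 17 BAIZHU, 45 ZHISHI
#' @seealso [write_component_table()], [apply_screen()]
#' @export
read_component_table <- function(path) {
  raw <- .read_tsv(path)
  names(raw) <- tolower(names(raw))
  # tolerate the published header spellings
  alias <- c("molecule_name" = "name", "mlogp" = "mlogp",
             "gi absorption" = "gi", "mlog" = "mlogp")
  hit <- names(raw) %in% names(alias)
  names(raw)[hit] <- alias[names(raw)[hit]]
  missing <- setdiff(.component_cols, names(raw))
  if (length(missing))
    stop("component table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- raw[.component_cols]
  if (anyDuplicated(out$id))
    stop("duplicate component id: ",
         out$id[duplicated(out$id)][1L], call. = FALSE)
  for (col in .numeric_component_cols)
    out[[col]] <- .parse_numeric(out[[col]], col)
  for (col in c("nhacc", "nhdon")) {
    if (any(out[[col]] < 0 | out[[col]] != round(out[[col]])))
      stop(sQuote(col), " must contain non-negative integers", call. = FALSE)
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("mw", "ob", "dl", "tpsa"))
    if (any(out[[col]] < 0))
      stop(sQuote(col), " must be non-negative", call. = FALSE)
  gi <- tolower(trimws(out$gi))
  bad <- !gi %in% c("high", "low")
  if (any(bad))
    stop("unrecognised GI absorption class ", sQuote(out$gi[bad][1L]),
         " (expected high/low)", call. = FALSE)
  out$gi <- gi
  if ("herb" %in% names(raw)) {
    out$herb <- toupper(trimws(raw$herb))
  } else {
    prefix <- substr(out$id, 1L, 2L)
    out$herb <- ifelse(prefix == "ZS", "ZHISHI",
                       ifelse(prefix == "BZ", "BAIZHU", NA_character_))
  }
  rownames(out) <- NULL
  out
}

#' Write a component property table
#'
#' Inverse of [read_component_table()]: values round-trip exactly.
#' The `gi` class is written capitalised (`High`/`Low`) as in published
#' tables; the inferred `herb` column is included.
#'
#' @param components data.frame as returned by [read_component_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(components, path) {
  out <- components
  out$gi <- ifelse(out$gi == "high", "High", "Low")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a target protein table
#'
#' Reads a tab-separated table of target proteins with columns `gene`
#' (HGNC-style symbol), `protein_name` and `uniprot` (accession).
#' Gene symbols are preserved verbatim and must be unique.
#'
#' @param path path to a TSV file.
#' @return A `data.frame` with columns `gene`, `protein_name`, `uniprot`.
#' @examples
#' targets <- read_target_table(herbnet_example("zzw_targets.tsv"))
#' nrow(targets)   # 133
#' @export
read_target_table <- function(path) {
  raw <- .read_tsv(path)
  names(raw) <- tolower(gsub("[ .]", "_", names(raw)))
  alias <- c("protein name" = "protein_name", "uniprot_id" = "uniprot")
  hit <- names(raw) %in% names(alias)
  names(raw)[hit] <- alias[names(raw)[hit]]
  missing <- setdiff(c("gene", "protein_name", "uniprot"), names(raw))
  if (length(missing))
    stop("target table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- raw[c("gene", "protein_name", "uniprot")]
  if (anyDuplicated(out$gene))
    stop("duplicate gene symbol: ",
         out$gene[duplicated(out$gene)][1L], call. = FALSE)
  if (nrow(out) && any(!nzchar(trimws(out$uniprot))))
    stop("empty UniProt accession", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a two-column edge list
#'
#' Reads component-target (or target-pathway) associations, one pair per
#' line, tab-separated, with an optional header line. Duplicate pairs are
#' collapsed with a warning counting the removed rows (merged predictions
#' from several sources commonly repeat pairs); a pair whose two ids are
#' equal violates bipartiteness and is an error.
#'
#' @param path path to a TSV file with two columns.
#' @return A `data.frame` with character columns `from` and `to`, in file
#'   order after deduplication.
#' @export
read_edge_list <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("edge list must have two tab-separated columns", call. = FALSE)
  raw <- raw[, 1:2]
  names(raw) <- c("from", "to")
  # drop a header line such as "from<TAB>to" or "source<TAB>target"
  if (nrow(raw) &&
      tolower(raw$from[1L]) %in% c("from", "source", "component", "left") &&
      tolower(raw$to[1L]) %in% c("to", "target", "right"))
    raw <- raw[-1L, , drop = FALSE]
  if (any(raw$from == raw$to))
    stop("self-loop in edge list: ",
         sQuote(raw$from[raw$from == raw$to][1L]),
         " appears on both sides of an edge", call. = FALSE)
  dup <- duplicated(paste(raw$from, raw$to, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) removed", call. = FALSE)
    raw <- raw[!dup, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Write an edge list
#'
#' @param edges data.frame with columns `from` and `to`.
#' @param path output path.
#' @param header write a `from`/`to` header line?
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, header = TRUE) {
  write.table(edges[c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = header, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read binary substructure fingerprints
#'
#' Reads a TSV with columns `component_id` and `bits`, where `bits` is a
#' fixed-length string over `{0,1}` (one substructure per position).
#'
#' @param path path to a TSV file.
#' @return An integer 0/1 matrix, one row per component (rownames are the
#'   component ids), one column per bit.
#' @seealso [pairwise_similarity_summary()], [gen_fingerprints()]
#' @export
read_fingerprints <- function(path) {
  raw <- .read_tsv(path)
  names(raw) <- tolower(names(raw))
  missing <- setdiff(c("component_id", "bits"), names(raw))
  if (length(missing))
    stop("fingerprint table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(raw$component_id))
    stop("duplicate component id in fingerprint table", call. = FALSE)
  bits <- trimws(raw$bits)
  if (!nrow(raw))
    return(matrix(integer(), 0L, 0L))
  if (length(unique(nchar(bits))) != 1L)
    stop("fingerprints must all have the same length", call. = FALSE)
  if (any(grepl("[^01]", bits)))
    stop("fingerprint bits must be 0 or 1", call. = FALSE)
  mat <- do.call(rbind, lapply(strsplit(bits, ""), as.integer))
  rownames(mat) <- raw$component_id
  mat
}

#' Write binary substructure fingerprints
#'
#' @param fps integer 0/1 matrix with component ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  bits <- apply(fps, 1L, paste, collapse = "")
  write.table(data.frame(component_id = rownames(fps), bits = bits),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an annotation map
#'
#' Reads disease->gene or pathway->gene annotations from a two-column TSV
#' (`annotation_id<TAB>gene`, optional header) into the named-list form
#' [rank_annotations()] consumes.
#'
#' @param path path to a TSV file.
#' @return A named list of character vectors, one gene set per annotation.
#' @export
read_annotations <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("annotation map must have two tab-separated columns", call. = FALSE)
  raw <- raw[, 1:2]
  names(raw) <- c("annotation", "gene")
  if (nrow(raw) && tolower(raw$annotation[1L]) %in%
      c("annotation", "annotation_id", "disease", "pathway"))
    raw <- raw[-1L, , drop = FALSE]
  lapply(split(raw$gene, raw$annotation), unique)
}

#' Write an annotation map
#'
#' @param annotations named list of character vectors (gene sets).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    annotation_id = rep(names(annotations), lengths(annotations)),
    gene = unlist(annotations, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
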