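#' Read an expression matrix and sample design from TSV files
#'
#' The matrix file is tab-separated with a `gene_id` header for the first
#' column and one column per sample; the design file has exactly the
#' columns `sample_id`, `individual_id`, `group`, `time`. Validation and
#' sample ordering are delegated to [expr_dataset()].
#'
#' @param matrix_path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @return An [expr_dataset].
#' @export
read_expression <- function(matrix_path, design_path) {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  if (names(mat_df)[1] != "gene_id") {
    abort_("expression matrix must have 'gene_id' as its first column header")
  }
  genes <- as.character(mat_df$gene_id)
  values <- as.matrix(mat_df[-1])
  if (!is.numeric(values)) abort_("expression matrix contains non-numeric cells")
  rownames(values) <- genes
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  expr_dataset(values, design)
}

#' Write an expression dataset to TSV files
#'
#' @param ds An [expr_dataset].
#' @param matrix_path,design_path Output paths.
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, design_path) {
  stopifnot(inherits(ds, "expr_dataset"))
  mat_df <- tibble::as_tibble(ds$values, rownames = "gene_id")
  readr::write_tsv(mat_df, matrix_path, progress = FALSE)
  readr::write_tsv(ds$design, design_path, progress = FALSE)
  invisible(ds)
}

#' Write a ranked gene list to TSV
#'
#' Columns: gene_id, score, rank, p_value (NA when absent).
#'
#' @param ranking Tibble from [ranked_gene_list()] or compatible.
#' @param path Output path.
#' @return `ranking`, invisibly.
#' @export
write_ranked_list <- function(ranking, path) {
  out <- ranking
  if (!"p_value" %in% names(out)) out$p_value <- NA_real_
  readr::write_tsv(out[c("gene_id", "score", "rank", "p_value")], path, progress = FALSE)
  invisible(ranking)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

validate_edges_ <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (nrow(edges) > 0) {
    if (any(edges$gene_a == edges$gene_b)) {
      abort_(sprintf("self-loop on gene '%s'", edges$gene_a[edges$gene_a == edges$gene_b][1]))
    }
    key <- paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b))
    if (anyDuplicated(key)) {
      abort_(sprintf("duplicate edge: %s", key[duplicated(key)][1]))
    }
  }
  edges
}

#' Export a co-expression network in a standard text format
#'
#' Writes an undirected weighted gene network in a format standard graph
#' tools (including Cytoscape) can read: simple interaction format (SIF,
#' with interaction type "coexp"), GraphML, or a TSV edge list with a
#' header. Self-loops and duplicate unordered pairs are rejected.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`.
#' @param path Output path.
#' @param format One of "tsv", "sif", "graphml".
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- validate_edges_(edges)
  if (format == "tsv") {
    out <- edges
    out$weight <- formatC(out$weight, digits = 8, format = "g")
    readr::write_tsv(out, path, progress = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(edges) == 0) character(0) else {
      paste(edges$gene_a, "coexp", edges$gene_b, sep = "\t")
    }
    writeLines(lines, path)
  } else {
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$gene_a, to = edges$gene_b, weight = edges$weight),
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(gene_a = "c", gene_b = "c", weight = "d"))
}
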