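filter_report_ <- function(n_input, n_output, rule, removed) {
  structure(list(n_input = n_input, n_output = n_output,
                 rule = rule, removed = removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d -> %d genes (%d removed)\n",
              x$rule, x$n_input, x$n_output, length(x$removed)))
  invisible(x)
}

#' Collapse duplicate probe identifiers to one row per gene
#'
#' When several array probes map to the same gene identifier, keeps the
#' probe with the highest overall intensity (mean over all samples); ties
#' are broken by lexicographically smallest probe id. Probes with no
#' mapping are dropped. Retained rows are renamed to their gene ids.
#'
#' @param ds An [expr_dataset] whose rownames are probe ids.
#' @param id_map Data frame with columns `probe_id`, `gene_id` (NA gene_id
#'   means unmapped), or a named character vector probe -> gene.
#' @return List with elements `dataset` (the collapsed [expr_dataset]) and
#'   `report` (a `filter_report`).
#' @export
collapse_duplicate_ids <- function(ds, id_map) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.data.frame(id_map)) {
    id_map <- tibble::tibble(probe_id = names(id_map), gene_id = unname(id_map))
  }
  if (nrow(id_map) == 0) abort_("empty probe-to-gene map")
  stopifnot(all(c("probe_id", "gene_id") %in% names(id_map)))

  probes <- rownames(ds$values)
  map <- stats::setNames(as.character(id_map$gene_id), as.character(id_map$probe_id))
  target <- unname(map[probes])
  overall <- rowMeans(ds$values)

  keep_df <- data.frame(probe = probes, gene = target, mean = overall,
                        stringsAsFactors = FALSE)
  keep_df <- keep_df[!is.na(keep_df$gene), ]
  # best probe per gene: max overall mean, then lexicographic probe id
  keep_df <- keep_df[order(keep_df$gene, -keep_df$mean, keep_df$probe, method = "radix"), ]
  best <- keep_df[!duplicated(keep_df$gene), ]

  removed <- setdiff(probes, best$probe)
  values <- ds$values[best$probe, , drop = FALSE]
  rownames(values) <- best$gene
  values <- values[order(rownames(values), method = "radix"), , drop = FALSE]

  list(dataset = expr_dataset(values, ds$design),
       report = filter_report_(length(probes), nrow(values),
                               "collapse duplicate ids (highest overall intensity)",
                               removed))
}

#' Keep the most variable genes
#'
#' Retains the `ceiling(keep_fraction * n)` genes with the highest overall
#' variance, computed per gene over all samples pooled across both groups
#' (population variance, denominator n). Ties are broken by gene id.
#'
#' @param ds An [expr_dataset].
#' @param keep_fraction Fraction of genes to keep, in (0, 1]; default 0.20.
#' @return List with `dataset` and `report`, as in [collapse_duplicate_ids()].
#' @export
variance_filter <- function(ds, keep_fraction = 0.20) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    abort_("`keep_fraction` must be in (0, 1]")
  }
  n <- nrow(ds$values)
  v <- rowMeans(ds$values^2) - rowMeans(ds$values)^2
  if (all(v == 0)) warning("all genes have zero variance; retaining by gene id order")
  k <- ceiling(keep_fraction * n)
  ord <- order(-v, rownames(ds$values), method = "radix")
  keep <- sort(rownames(ds$values)[ord[seq_len(k)]])
  removed <- setdiff(rownames(ds$values), keep)
  list(dataset = expr_dataset(ds$values[keep, , drop = FALSE], ds$design),
       report = filter_report_(n, k, sprintf("variance filter (top %g)", keep_fraction),
                               removed))
}

#' Center each gene within each individual
#'
#' Subtracts, for every gene and every individual, that individual's mean
#' over its own time points. Within-individual Pearson correlations are
#' unchanged (correlation is location-invariant); what changes is the
#' behaviour of methods that pool samples across individuals, where
#' per-individual baseline offsets otherwise dominate.
#'
#' @param ds An [expr_dataset].
#' @return The centered [expr_dataset].
#' @export
center_individuals <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  values <- ds$values
  for (ind in unique(ds$design$individual_id)) {
    cols <- ds$design$sample_id[ds$design$individual_id == ind]
    values[, cols] <- values[, cols, drop = FALSE] -
      rowMeans(values[, cols, drop = FALSE])
  }
  expr_dataset(values, ds$design)
}
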