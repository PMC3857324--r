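#' Construct a grouped time-series expression dataset
#'
#' Bundles a gene-by-sample expression matrix with its sample design
#' (which individual each sample belongs to, which of the two groups that
#' individual is in, and the time of measurement) and validates the
#' structure the per-individual correlation machinery relies on: every
#' individual belongs to exactly one group, has at least three time points
#' (needed for the correlation test with `m - 2` degrees of freedom), and
#' has no duplicated measurement times.
#'
#' Samples are reordered by (group, individual, time) so that all
#' downstream computations are invariant to the input column order. The
#' lexicographically smaller group label plays the role of group X in
#' reports; the DCeN score itself is symmetric in the two groups.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene identifiers) and colnames (sample identifiers). Values are
#'   log-scale intensities or log-ratios; missing or non-numeric cells are
#'   rejected rather than imputed.
#' @param design Data frame with exactly the columns `sample_id`,
#'   `individual_id`, `group`, `time`; one row per matrix column.
#' @return An object of class `expr_dataset`: a list with elements
#'   `values` (the reordered matrix) and `design` (a tibble).
#' @examples
#' ds <- simulate_cohort(synthetic_config(n_genes = 20, module_sizes = 10,
#'                                        n_decoupled = 2, seed = 1))$dataset
#' ds
#' @export
expr_dataset <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_("`values` must be a numeric matrix (genes x samples)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort_(sprintf("non-finite expression value at gene '%s', sample '%s'; missing values are not supported",
                   rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  genes <- rownames(values)
  if (is.null(genes) || anyDuplicated(genes)) {
    dup <- if (is.null(genes)) "<missing rownames>" else genes[duplicated(genes)][1]
    abort_(sprintf("gene identifiers must be unique rownames (offending: '%s')", dup))
  }
  if (is.null(colnames(values))) abort_("`values` must have sample ids as colnames")

  design <- tibble::as_tibble(design)
  need <- c("sample_id", "individual_id", "group", "time")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    abort_(sprintf("design is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  design <- design[need]
  design$sample_id <- as.character(design$sample_id)
  design$individual_id <- as.character(design$individual_id)
  design$group <- as.character(design$group)
  design$time <- as.numeric(design$time)
  if (anyNA(design)) abort_("design contains missing values")

  absent <- setdiff(colnames(values), design$sample_id)
  if (length(absent) > 0) {
    abort_(sprintf("sample '%s' in the expression matrix has no design row", absent[1]))
  }
  extra <- setdiff(design$sample_id, colnames(values))
  if (length(extra) > 0) {
    abort_(sprintf("design sample '%s' is absent from the expression matrix", extra[1]))
  }
  if (anyDuplicated(design$sample_id)) {
    abort_(sprintf("duplicated design row for sample '%s'",
                   design$sample_id[duplicated(design$sample_id)][1]))
  }

  grp_per_ind <- tapply(design$group, design$individual_id, function(g) length(unique(g)))
  if (any(grp_per_ind > 1)) {
    abort_(sprintf("individual '%s' appears in more than one group",
                   names(grp_per_ind)[grp_per_ind > 1][1]))
  }
  groups <- sort(unique(design$group))
  if (length(groups) != 2) {
    abort_(sprintf("exactly two groups are required, found %d (%s)",
                   length(groups), paste(groups, collapse = ", ")))
  }
  m_per_ind <- table(design$individual_id)
  if (any(m_per_ind < 3)) {
    abort_(sprintf("individual '%s' has fewer than 3 time points",
                   names(m_per_ind)[m_per_ind < 3][1]))
  }
  dup_time <- duplicated(design[c("individual_id", "time")])
  if (any(dup_time)) {
    abort_(sprintf("duplicated time %g for individual '%s'",
                   design$time[dup_time][1], design$individual_id[dup_time][1]))
  }

  ord <- order(design$group, design$individual_id, design$time, method = "radix")
  design <- design[ord, ]
  values <- values[, design$sample_id, drop = FALSE]

  structure(list(values = values, design = design), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  ind <- individual_groups(x)
  cat(sprintf("<expr_dataset> %d genes x %d samples\n", nrow(x$values), ncol(x$values)))
  for (g in sort(unique(ind))) {
    cat(sprintf("  group %s: %d individuals\n", g, sum(ind == g)))
  }
  invisible(x)
}

#' Map individuals to their group labels
#'
#' @param ds An [expr_dataset].
#' @return Named character vector: names are individual ids, values group labels.
#' @export
individual_groups <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  d <- ds$design[!duplicated(ds$design$individual_id), ]
  stats::setNames(d$group, d$individual_id)
}

#' Extract one individual's time-ordered expression submatrix
#'
#' @param ds An [expr_dataset].
#' @param individual_id Individual identifier present in the design.
#' @return Numeric matrix genes x m, columns in time order.
#' @export
individual_values <- function(ds, individual_id) {
  stopifnot(inherits(ds, "expr_dataset"))
  sel <- ds$design$individual_id == individual_id
  if (!any(sel)) abort_(sprintf("unknown individual '%s'", individual_id))
  d <- ds$design[sel, ]
  ds$values[, d$sample_id[order(d$time)], drop = FALSE]
}

#' Restrict a dataset to a subset of individuals
#'
#' @param ds An [expr_dataset].
#' @param individuals Character vector of individual ids to keep.
#' @return An [expr_dataset] with only those individuals' samples.
#' @export
subset_individuals <- function(ds, individuals) {
  stopifnot(inherits(ds, "expr_dataset"))
  unknown <- setdiff(individuals, ds$design$individual_id)
  if (length(unknown) > 0) abort_(sprintf("unknown individual '%s'", unknown[1]))
  keep <- ds$design$individual_id %in% individuals
  expr_dataset(ds$values[, ds$design$sample_id[keep], drop = FALSE],
               ds$design[keep, ])
}

#' Turn per-gene scores into a ranked gene list
#'
#' Orders genes by decreasing score, breaking ties by lexicographic gene
#' id so that output is deterministic across runs and platforms, and
#' assigns dense ranks 1..N.
#'
#' @param scores Named numeric vector (names are gene ids) or a data frame
#'   with columns `gene_id` and `score`.
#' @param p_value Optional named numeric vector of p-values per gene.
#' @return Tibble with columns `gene_id`, `score`, `rank` and, when
#'   supplied, `p_value`; rows in rank order.
#' @export
ranked_gene_list <- function(scores, p_value = NULL) {
  if (is.data.frame(scores)) {
    gene_id <- as.character(scores$gene_id)
    score <- as.numeric(scores$score)
  } else {
    gene_id <- names(scores)
    score <- as.numeric(scores)
  }
  if (is.null(gene_id) || anyDuplicated(gene_id)) {
    abort_("scores must be named by unique gene ids")
  }
  ord <- order_ranked_(gene_id, score)
  out <- tibble::tibble(gene_id = gene_id[ord],
                        score = score[ord],
                        rank = seq_along(gene_id))
  if (!is.null(p_value)) out$p_value <- as.numeric(p_value[out$gene_id])
  out
}
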