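#' Baseline group co-expression networks
#'
#' Three clearly-labelled analogs of the strategies the DCeN method is
#' compared against. Each produces one gene-pair association matrix per
#' group; rank genes from it with [connectivity_rank()].
#'
#' * `average_profile_network()`: averages the individuals' expression
#'   profiles point-wise within each group (requiring a common time grid)
#'   and correlates the mean profiles — the classical "group average"
#'   route. Timing heterogeneity between individuals flattens the mean
#'   profile and destroys correlation this route would otherwise see.
#' * `concat_network()`: concatenates the individuals' time-ordered
#'   series end-to-end within each group (in fixed individual order) and
#'   correlates the concatenated vectors; optionally centers each
#'   individual first ([center_individuals()]) so baseline offsets do not
#'   dominate.
#' * `indcorr_network()`: averages each pair's within-individual raw
#'   correlations over the group's individuals — the individual-
#'   correlation route, aggregating correlations rather than signed
#'   significance weights.
#'
#' @param ds An [expr_dataset].
#' @param center For `concat_network()`: center each individual first.
#' @param nets,groups For `indcorr_network()`: per-individual networks
#'   and the individual-to-group map.
#' @return Object of class `group_cornet`: list with `method` tag, the
#'   per-group association matrices `s_X`, `s_Y` (symmetric, zero
#'   diagonal), and `group_labels`.
#' @name baselines
NULL

new_group_cornet <- function(method, s_X, s_Y, group_labels) {
  diag(s_X) <- 0
  diag(s_Y) <- 0
  s_X[!is.finite(s_X)] <- 0
  s_Y[!is.finite(s_Y)] <- 0
  structure(list(method = method, s_X = s_X, s_Y = s_Y, group_labels = group_labels),
            class = "group_cornet")
}

group_split_ <- function(ds) {
  groups <- individual_groups(ds)
  glabs <- sort(unique(unname(groups)))
  lapply(stats::setNames(glabs, c("X", "Y")), function(g) names(groups)[groups == g])
}

#' @rdname baselines
#' @export
average_profile_network <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  members <- group_split_(ds)
  glabs <- vapply(members, function(x) unname(individual_groups(ds)[x[1]]), character(1))
  s <- lapply(members, function(inds) {
    mats <- lapply(inds, function(i) individual_values(ds, i))
    times <- lapply(inds, function(i) {
      sort(ds$design$time[ds$design$individual_id == i])
    })
    if (length(unique(lapply(times, as.numeric))) > 1 ||
        length(unique(vapply(mats, ncol, integer(1)))) > 1) {
      abort_("individuals within a group do not share a common time grid; resample before averaging (not supported)")
    }
    mean_profile <- Reduce(`+`, mats) / length(mats)
    r <- suppressWarnings(stats::cor(t(mean_profile)))
    r[!is.finite(r)] <- 0
    r
  })
  new_group_cornet("average", s$X, s$Y, c(X = glabs[["X"]], Y = glabs[["Y"]]))
}

#' @rdname baselines
#' @export
concat_network <- function(ds, center = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (center) ds <- center_individuals(ds)
  members <- group_split_(ds)
  glabs <- vapply(members, function(x) unname(individual_groups(ds)[x[1]]), character(1))
  s <- lapply(members, function(inds) {
    cat_mat <- do.call(cbind, lapply(sort(inds), function(i) individual_values(ds, i)))
    r <- suppressWarnings(stats::cor(t(cat_mat)))
    r[!is.finite(r)] <- 0
    r
  })
  new_group_cornet(if (center) "concat_centered" else "concat",
                   s$X, s$Y, c(X = glabs[["X"]], Y = glabs[["Y"]]))
}

#' @rdname baselines
#' @export
indcorr_network <- function(nets, groups) {
  stopifnot(length(nets) > 0)
  ids <- vapply(nets, function(x) x$individual_id, character(1))
  glabs <- sort(unique(unname(groups[ids])))
  if (length(glabs) != 2) abort_("exactly two groups with members are required")
  s <- lapply(glabs, function(g) {
    members <- which(groups[ids] == g)
    if (length(members) == 0) abort_(sprintf("group '%s' is empty", g))
    Reduce(`+`, lapply(nets[members], function(x) x$r)) / length(members)
  })
  new_group_cornet("indcorr", s[[1]], s[[2]], c(X = glabs[1], Y = glabs[2]))
}

#' Rank genes by differential soft-thresholded connectivity
#'
#' WGCNA-style aggregation of a gene's pairwise association changes:
#' each association is soft-thresholded as `|s|^beta` and the per-gene
#' score is the summed absolute between-group difference,
#' `score(g) = sum_h | |s_X(g,h)|^beta - |s_Y(g,h)|^beta |`.
#'
#' @param net A `group_cornet` from one of the [baselines].
#' @param beta Soft-threshold power (>= 1); default 6, the conventional
#'   choice for signed-magnitude adjacencies.
#' @return A ranked tibble, see [ranked_gene_list()].
#' @export
connectivity_rank <- function(net, beta = 6) {
  stopifnot(inherits(net, "group_cornet"))
  if (!is.numeric(beta) || beta < 1) abort_("`beta` must be >= 1")
  d <- rowSums(abs(abs(net$s_X)^beta - abs(net$s_Y)^beta))
  ranked_gene_list(d)
}

#' @export
print.group_cornet <- function(x, ...) {
  cat(sprintf("<group_cornet> method '%s', %d genes (groups %s vs %s)\n",
              x$method, nrow(x$s_X), x$group_labels["X"], x$group_labels["Y"]))
  invisible(x)
}
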