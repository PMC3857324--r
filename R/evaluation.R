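#' Relative overlap of two top-k gene lists
#'
#' @param list_a,list_b Ranked tibbles over the same gene universe
#'   (columns `gene_id`, `rank`).
#' @param k Top list size, 1 <= k <= universe size.
#' @return `|top_k(a) intersect top_k(b)| / k`, in \[0, 1\].
#' @export
top_overlap <- function(list_a, list_b, k) {
  if (!is.numeric(k) || k <= 0) abort_("`k` must be a positive integer")
  if (!setequal(list_a$gene_id, list_b$gene_id)) {
    abort_("the two rankings cover different gene universes")
  }
  if (k > nrow(list_a)) abort_("`k` exceeds the gene universe size")
  ta <- list_a$gene_id[list_a$rank <= k]
  tb <- list_b$gene_id[list_b$rank <= k]
  length(intersect(ta, tb)) / k
}

# resolve a ranking method (tag or function) to function(expr_dataset) -> ranked tibble
resolve_method_ <- function(method, beta = 6) {
  if (is.function(method)) return(method)
  switch(method,
    dcen = function(ds) dcen(ds)$scores,
    average = function(ds) connectivity_rank(average_profile_network(ds), beta),
    concat = function(ds) connectivity_rank(concat_network(ds), beta),
    concat_centered = function(ds) connectivity_rank(concat_network(ds, center = TRUE), beta),
    indcorr = function(ds) {
      connectivity_rank(indcorr_network(build_individual_networks(ds),
                                        individual_groups(ds)), beta)
    },
    random = function(ds) {
      g <- rownames(ds$values)
      ranked_gene_list(stats::setNames(sample(length(g)), g))
    },
    abort_(sprintf("unknown ranking method '%s'", method))
  )
}

#' Reproducibility of top-ranked genes across disjoint subsamples
#'
#' Repeatedly draws `2 * n_per_group` individuals per group without
#' replacement, splits them into two disjoint sub-cohorts of
#' `n_per_group` individuals per group, ranks each sub-cohort with the
#' chosen method, and records the relative top-k overlap of the two
#' rankings at each requested top list size. A method that responds to
#' real, shared signal overlaps far above the chance level `k / G`; a
#' method dominated by sampling noise does not.
#'
#' @param ds An [expr_dataset] with at least `2 * n_per_group`
#'   individuals in each group.
#' @param method Ranking method: one of "dcen", "average", "concat",
#'   "concat_centered", "indcorr", "random", or a function
#'   `expr_dataset -> ranked tibble`.
#' @param n_per_group Individuals per group per sub-cohort.
#' @param n_pairs Number of independent sub-cohort pairs; default 100.
#' @param top_sizes Integer vector of top list sizes; default 200.
#' @param seed Integer seed; required.
#' @param beta Soft-threshold power for the baseline methods.
#' @return Object of class `repro_result`: list with `overlaps` (tibble:
#'   pair, top_size, overlap), `summary` (tibble: top_size, mean_overlap,
#'   se), `method`, `n_per_group`, `n_pairs`.
#' @export
subsample_reproducibility <- function(ds, method, n_per_group, n_pairs = 100,
                                      top_sizes = 200, seed = NULL, beta = 6) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (is.null(seed)) abort_("subsampling requires an explicit `seed`")
  groups <- individual_groups(ds)
  if (any(table(groups) < 2 * n_per_group)) {
    abort_(sprintf("each group needs at least %d individuals for disjoint sub-cohorts of %d",
                   2 * n_per_group, n_per_group))
  }
  if (any(top_sizes > nrow(ds$values))) abort_("top size exceeds the number of genes")
  rank_fun <- resolve_method_(method, beta)
  method_tag <- if (is.function(method)) "custom" else method
  glabs <- sort(unique(unname(groups)))

  overlaps <- with_seed_(seed, {
    purrr::map_dfr(seq_len(n_pairs), function(b) {
      halves <- lapply(glabs, function(g) {
        drawn <- sample(names(groups)[groups == g], 2 * n_per_group)
        list(a = drawn[seq_len(n_per_group)], b = drawn[-seq_len(n_per_group)])
      })
      sub_a <- subset_individuals(ds, unlist(lapply(halves, `[[`, "a")))
      sub_b <- subset_individuals(ds, unlist(lapply(halves, `[[`, "b")))
      ra <- rank_fun(sub_a)
      rb <- rank_fun(sub_b)
      tibble::tibble(pair = b, top_size = as.integer(top_sizes),
                     overlap = vapply(top_sizes, function(k) top_overlap(ra, rb, k),
                                      numeric(1)))
    })
  })
  summary <- dplyr::summarise(dplyr::group_by(overlaps, .data$top_size),
                              mean_overlap = mean(.data$overlap),
                              se = stats::sd(.data$overlap) / sqrt(dplyr::n()),
                              .groups = "drop")
  structure(list(overlaps = overlaps, summary = summary, method = method_tag,
                 n_per_group = n_per_group, n_pairs = n_pairs, seed = seed),
            class = "repro_result")
}

#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf("<repro_result> method '%s', n=%d per group, %d pairs\n",
              x$method, x$n_per_group, x$n_pairs))
  print(x$summary)
  invisible(x)
}

#' @rdname subsample_reproducibility
#' @param x A `repro_result`.
#' @param ... Unused.
#' @method tidy repro_result
#' @export
tidy.repro_result <- function(x, ...) {
  dplyr::mutate(x$summary, method = x$method, n_per_group = x$n_per_group,
                n_pairs = x$n_pairs, .before = 1)
}

#' @rdname subsample_reproducibility
#' @param object A `repro_result`.
#' @method autoplot repro_result
#' @export
autoplot.repro_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$top_size, y = .data$mean_overlap)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_overlap - .data$se,
                                          ymax = .data$mean_overlap + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "top list size", y = "mean relative overlap",
                  title = sprintf("Top-list reproducibility (%s, n=%d per group)",
                                  object$method, object$n_per_group)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' Gene-label permutation enrichment of a ranking's top candidates
#'
#' Tests whether the genes at the top of a ranking carry more of an
#' external gene-level property (e.g. a validated regulatory effect, or a
#' binary genetic-interaction flag) than chance. The observed statistic
#' at each top list size k is the mean property over the top-k genes; the
#' null redistributes the property values over the ranked genes at random
#' (`n_perm` times), and
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` (one-sided, excess
#' effect).
#'
#' Genes without a property value must be excluded from the ranking
#' before calling (rank only the annotated universe).
#'
#' @param ranking Ranked tibble (`gene_id`, `rank`).
#' @param property Named numeric vector covering every ranked gene.
#' @param top_sizes Integer vector of top list sizes.
#' @param n_perm Number of gene-label permutations; default 10000.
#' @param seed Integer seed; required.
#' @return Object of class `enrichment_result`: list with `table`
#'   (tibble: top_size, observed, p_value) and `n_perm`.
#' @export
enrichment_permutation <- function(ranking, property, top_sizes,
                                   n_perm = 10000, seed = NULL) {
  if (is.null(seed)) abort_("permutation requires an explicit `seed`")
  missing_prop <- setdiff(ranking$gene_id, names(property))
  if (length(missing_prop) > 0) {
    abort_(sprintf("gene '%s' has no property value; restrict the ranking to annotated genes",
                   missing_prop[1]))
  }
  if (any(top_sizes <= 0 | top_sizes > nrow(ranking))) {
    abort_("top sizes must lie in 1..number of ranked genes")
  }
  prop <- unname(property[ranking$gene_id[order(ranking$rank)]])
  if (stats::sd(prop) == 0) {
    warning("property is constant over genes; enrichment p-values are 1")
  }
  cums <- cumsum(prop)
  observed <- cums[top_sizes] / top_sizes
  null_stats <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b) {
      cs <- cumsum(sample(prop))
      cs[top_sizes] / top_sizes
    }, numeric(length(top_sizes)))
  })
  null_stats <- matrix(null_stats, nrow = length(top_sizes))
  pv <- vapply(seq_along(top_sizes), function(j) {
    (1 + sum(null_stats[j, ] >= observed[j])) / (1 + n_perm)
  }, numeric(1))
  structure(list(table = tibble::tibble(top_size = as.integer(top_sizes),
                                        observed = observed, p_value = pv),
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d permutations\n", x$n_perm))
  print(x$table)
  invisible(x)
}

#' @rdname enrichment_permutation
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) x$table

#' @rdname enrichment_permutation
#' @param object An `enrichment_result`.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$top_size, y = .data$observed)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < 0.05)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                                 name = "p < 0.05") +
    ggplot2::labs(x = "top list size", y = "mean property over top candidates",
                  title = "Permutation enrichment of top-ranked genes") +
    ggplot2::theme_minimal()
}
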