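#' Group-averaged co-expression weights
#'
#' Averages the per-individual signed weights `w` arithmetically within
#' each of the two groups, giving one genes-x-genes weight matrix per
#' group. Averaging the signed weights (rather than correlations) rewards
#' pairs whose correlation is both strong and consistent in sign across a
#' group's individuals; sign-inconsistent pairs cancel towards 0.
#'
#' @param nets List of `indiv_network` objects.
#' @param groups Named character vector individual id -> group label; the
#'   lexicographically smaller label is reported as group X.
#' @return Object of class `group_weights`: list with `wbar_X`, `wbar_Y`
#'   (symmetric matrices in \[-1, 1\], zero diagonal), group sizes `n_X`,
#'   `n_Y`, and `group_labels` (named c(X = ..., Y = ...)).
#' @export
average_weights <- function(nets, groups) {
  stopifnot(length(nets) > 0)
  ids <- vapply(nets, function(x) x$individual_id, character(1))
  unknown <- setdiff(ids, names(groups))
  if (length(unknown) > 0) abort_(sprintf("individual '%s' has no group label", unknown[1]))
  glabs <- sort(unique(unname(groups[ids])))
  if (length(glabs) != 2) {
    abort_(sprintf("exactly two groups with members are required, found %d", length(glabs)))
  }
  avg <- lapply(glabs, function(g) {
    members <- which(groups[ids] == g)
    Reduce(`+`, lapply(nets[members], function(x) x$w)) / length(members)
  })
  structure(list(wbar_X = avg[[1]], wbar_Y = avg[[2]],
                 n_X = sum(groups[ids] == glabs[1]),
                 n_Y = sum(groups[ids] == glabs[2]),
                 group_labels = c(X = glabs[1], Y = glabs[2])),
            class = "group_weights")
}

#' The DCeN differential co-expression score
#'
#' For each gene g, over its retained neighbors h (mask entries
#' `a_gh = 1`), computes
#' \deqn{d_g = \frac{\sum_h a_{gh}\,|\bar w_X(g,h) - \bar w_Y(g,h)|}
#'                  {\sum_h a_{gh}\,(|\bar w_X(g,h)| + |\bar w_Y(g,h)|)},}
#' the proportion of the gene's total neighborhood connectivity (summed
#' over both groups) that changes between the groups. If both averaged
#' neighborhoods are equal, `d_g = 0`; the maximum of 1 is attained
#' exactly when, for every retained neighbor, the weaker averaged weight
#' is zero or of opposite sign to the stronger one. A gene whose retained
#' neighborhood is empty, or whose denominator is zero, gets `d_g = 0`.
#'
#' @param avw A `group_weights` object from [average_weights()].
#' @param mask A `consistency_mask` over the same gene universe.
#' @return Object of class `dcen_result`; see [dcen()].
#' @export
dcen_score <- function(avw, mask) {
  stopifnot(inherits(avw, "group_weights"), inherits(mask, "consistency_mask"))
  genes <- rownames(avw$wbar_X)
  if (!identical(genes, rownames(mask$a))) abort_("gene universes of weights and mask differ")
  num <- rowSums(mask$a * abs(avw$wbar_X - avw$wbar_Y))
  den <- rowSums(mask$a * (abs(avw$wbar_X) + abs(avw$wbar_Y)))
  d <- ifelse(den > 0, num / den, 0)
  names(d) <- genes
  new_dcen_result(ranked_gene_list(d),
                  params = list(p_cut = mask$p_cut, frac = mask$frac,
                                min_count = mask$min_count,
                                n_X = avw$n_X, n_Y = avw$n_Y,
                                group_labels = avw$group_labels,
                                n_retained_pairs = sum(mask$a[upper.tri(mask$a)]),
                                n_perm = NULL, seed = NULL))
}

new_dcen_result <- function(scores, params) {
  structure(list(scores = scores, params = params), class = "dcen_result")
}

#' Rank genes by differential co-expression across individuals (DCeN)
#'
#' End-to-end pipeline: builds one signed co-expression network per
#' individual from that individual's own time series
#' ([build_individual_network()]), retains gene pairs with
#' sign-consistent significant correlation in enough individuals of at
#' least one group ([consistency_mask()]), averages the weights within
#' groups ([average_weights()]), and scores every gene with
#' [dcen_score()]. Optionally attaches permutation p-values
#' ([permutation_pvalues()]).
#'
#' Because correlations are computed within each individual before any
#' cross-individual aggregation, the score is robust to individuals
#' traversing a shared expression program at different speeds or offsets —
#' the regime in which group-average profiles destroy co-expression
#' signal.
#'
#' @param ds An [expr_dataset].
#' @param p_cut,frac,min_count Prefilter thresholds, see
#'   [consistency_mask()]; defaults 0.05, 0.25, 2.
#' @param n_perm Number of group-label permutations for empirical
#'   p-values (NULL to skip); the published procedure uses 100.
#' @param seed Seed for the permutations (required when `n_perm` is set).
#' @return Object of class `dcen_result` with elements `scores` (tibble:
#'   gene_id, score, rank, and p_value when permutations were run) and
#'   `params`. Use [tidy()] / [glance()] / `autoplot()` on it.
#' @examples
#' sim <- simulate_cohort(synthetic_config(n_genes = 40, module_sizes = 20,
#'                                         n_decoupled = 4, seed = 7))
#' res <- dcen(sim$dataset)
#' tidy(res)
#' @export
dcen <- function(ds, p_cut = 0.05, frac = 0.25, min_count = 2,
                 n_perm = NULL, seed = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.null(n_perm)) {
    return(permutation_pvalues(ds, p_cut = p_cut, frac = frac,
                               min_count = min_count, n_perm = n_perm, seed = seed))
  }
  groups <- individual_groups(ds)
  nets <- build_individual_networks(ds)
  mask <- consistency_mask(nets, groups, p_cut = p_cut, frac = frac, min_count = min_count)
  dcen_score(average_weights(nets, groups), mask)
}

#' Empirical significance of DCeN scores by group-label permutation
#'
#' Forms an empirical null by randomly permuting the group labels of
#' whole individuals (an individual's time series keeps its identity;
#' only its label moves), preserving the group sizes, and recomputing the
#' prefilter, the group averages, and every gene's score for each
#' permutation. The per-individual networks themselves do not depend on
#' the labels and are computed once. Null scores are pooled across genes
#' and permutations — with 100 permutations a per-gene null could not
#' resolve p below 0.01 — and
#' `p(g) = (1 + #\{null >= d_g\}) / (1 + n_perm * n_genes)`.
#'
#' @inheritParams dcen
#' @param n_perm Number of permutations; default 100.
#' @param seed Integer seed; required.
#' @return A `dcen_result` whose `scores` tibble carries `p_value`.
#' @export
permutation_pvalues <- function(ds, p_cut = 0.05, frac = 0.25, min_count = 2,
                                n_perm = 100, seed = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.numeric(n_perm) || n_perm < 1) abort_("`n_perm` must be >= 1")
  if (is.null(seed)) abort_("permutation p-values require an explicit `seed`")
  groups <- individual_groups(ds)
  if (any(table(groups) < 2)) {
    abort_("permutation requires at least 2 individuals per group")
  }
  nets <- build_individual_networks(ds)
  score_for <- function(grp) {
    mask <- consistency_mask(nets, grp, p_cut = p_cut, frac = frac, min_count = min_count)
    res <- dcen_score(average_weights(nets, grp), mask)
    stats::setNames(res$scores$score, res$scores$gene_id)[rownames(ds$values)]
  }
  observed <- score_for(groups)
  ind_ids <- names(groups)
  null_scores <- with_seed_(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      score_for(stats::setNames(sample(unname(groups)), ind_ids))
    }), use.names = FALSE)
  })
  n_null <- length(null_scores)
  pv <- vapply(observed, function(d) (1 + sum(null_scores >= d)) / (1 + n_null),
               numeric(1))
  res <- new_dcen_result(
    ranked_gene_list(observed, p_value = pv),
    params = list(p_cut = p_cut, frac = frac, min_count = min_count,
                  n_X = sum(groups == sort(unique(groups))[1]),
                  n_Y = sum(groups == sort(unique(groups))[2]),
                  group_labels = c(X = sort(unique(groups))[1],
                                   Y = sort(unique(groups))[2]),
                  n_retained_pairs = NA_integer_,
                  n_perm = n_perm, seed = seed))
  res
}

#' Switching neighborhood of a focal gene
#'
#' Selects the `ceiling(diff_fraction * n_genes)` genes whose
#' group-averaged co-expression with the focal gene differs most between
#' the two conditions (ties broken by gene id), then returns, for each
#' condition, the strong edges (`|wbar| > edge_cut`) among the focal gene
#' plus its selected neighbors. With the default weight, `|w| > 0.95`
#' corresponds to correlation significance p < 0.05 within individuals.
#' Feed the edge tibbles to [write_network()] for Cytoscape-ready output.
#'
#' @param avw A `group_weights` object.
#' @param focal_gene Gene id present in the weight matrices.
#' @param diff_fraction Fraction of genes to select; default 0.005
#'   (the "top 0.5%").
#' @param edge_cut Minimum absolute averaged weight for an edge;
#'   default 0.95.
#' @return List with `neighbors` (character vector), `edges_X` and
#'   `edges_Y` (tibbles gene_a, gene_b, weight).
#' @export
switching_neighborhood <- function(avw, focal_gene, diff_fraction = 0.005,
                                   edge_cut = 0.95) {
  stopifnot(inherits(avw, "group_weights"))
  genes <- rownames(avw$wbar_X)
  if (!focal_gene %in% genes) abort_(sprintf("unknown focal gene '%s'", focal_gene))
  if (!is.numeric(diff_fraction) || diff_fraction <= 0 || diff_fraction > 1) {
    abort_("`diff_fraction` must be in (0, 1]")
  }
  diffs <- abs(avw$wbar_X[focal_gene, ] - avw$wbar_Y[focal_gene, ])
  diffs <- diffs[names(diffs) != focal_gene]
  k <- ceiling(diff_fraction * length(genes))
  ord <- order(-diffs, names(diffs), method = "radix")
  neighbors <- names(diffs)[ord[seq_len(min(k, length(diffs)))]]
  sub <- sort(c(focal_gene, neighbors))
  edges_in <- function(wbar) {
    ww <- wbar[sub, sub, drop = FALSE]
    idx <- upper_pairs_(length(sub))
    keep <- abs(ww[idx]) > edge_cut
    tibble::tibble(gene_a = sub[idx[keep, 1]],
                   gene_b = sub[idx[keep, 2]],
                   weight = ww[idx][keep])
  }
  list(neighbors = neighbors,
       edges_X = edges_in(avw$wbar_X),
       edges_Y = edges_in(avw$wbar_Y))
}

#' @export
print.dcen_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("<dcen_result> %d genes (groups %s: n=%d, %s: n=%d)\n",
              nrow(x$scores), p$group_labels["X"], p$n_X, p$group_labels["Y"], p$n_Y))
  if (!is.null(p$n_perm)) {
    cat(sprintf("  permutation p-values from %d group-label permutations (seed %s)\n",
                p$n_perm, p$seed))
  }
  print(utils::head(x$scores, 5))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DCeN result into one row per gene
#'
#' @param x A `dcen_result`.
#' @param ... Unused.
#' @return Tibble with gene_id, score, rank (and p_value when computed).
#' @method tidy dcen_result
#' @export
tidy.dcen_result <- function(x, ...) x$scores

#' One-row summary of a DCeN analysis
#'
#' @param x A `dcen_result`.
#' @param ... Unused.
#' @return One-row tibble: gene and group counts, thresholds, number of
#'   retained pairs, permutation settings.
#' @method glance dcen_result
#' @export
glance.dcen_result <- function(x, ...) {
  p <- x$params
  tibble::tibble(n_genes = nrow(x$scores), n_X = p$n_X, n_Y = p$n_Y,
                 p_cut = p$p_cut, frac = p$frac, min_count = p$min_count,
                 n_retained_pairs = p$n_retained_pairs,
                 n_perm = ifelse(is.null(p$n_perm), NA_integer_, p$n_perm),
                 n_significant = if ("p_value" %in% names(x$scores)) {
                   sum(x$scores$p_value < 0.05)
                 } else NA_integer_)
}

#' Plot a ranked DCeN score profile
#'
#' @param object A `dcen_result`.
#' @param ... Unused.
#' @return A ggplot: score against rank, coloured by significance when
#'   permutation p-values are available.
#' @method autoplot dcen_result
#' @export
autoplot.dcen_result <- function(object, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::labs(x = "rank", y = expression(d[g]),
                  title = "DCeN differential co-expression scores")
  if ("p_value" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < 0.05), size = 0.8) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
                                   name = "p < 0.05")
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, colour = "grey20")
  }
  p + ggplot2::theme_minimal()
}
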