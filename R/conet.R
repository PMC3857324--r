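#' Two-sided significance of a Pearson correlation from a short series
#'
#' For a correlation `r` computed from `m` paired observations, the
#' statistic `t = r * sqrt((m - 2) / (1 - r^2))` follows a Student's t
#' distribution with `m - 2` degrees of freedom under the null hypothesis
#' of no correlation. Returns the two-sided tail probability, which is
#' symmetric in the sign of `r` and monotonically decreasing in `|r|`.
#' `|r| = 1` maps to `p = 0` (limit convention).
#'
#' @param r Correlation value(s) in \[-1, 1\] (vectorized).
#' @param m Number of time points; must be >= 3 so the test has at least
#'   one degree of freedom.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @examples
#' correlation_pvalue(0, 6)        # 1
#' correlation_pvalue(0.9, 6)      # ~0.0145
#' correlation_pvalue(1, 5)        # 0
#' @export
correlation_pvalue <- function(r, m) {
  if (length(m) != 1 || !is.finite(m) || m < 3) abort_("`m` must be a single integer >= 3")
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) abort_("`r` must lie in [-1, 1]")
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact1 <- abs(r) >= 1
  p[exact1] <- 0
  tt <- r[!exact1] * sqrt((m - 2) / (1 - r[!exact1]^2))
  p[!exact1] <- 2 * stats::pt(-abs(tt), df = m - 2)
  p
}

#' Build one individual's signed co-expression network
#'
#' Computes all pairwise Pearson correlations `r` across the individual's
#' time-ordered expression values, their two-sided significance `p` (via
#' [correlation_pvalue()] with that individual's number of time points
#' `m`), and the signed significance weight
#' `w = sgn(r) * (1 - p)`.
#'
#' The weight lies in \[-1, 1\], is monotone in `|r|` for fixed `m`, and
#' makes the consistency prefilter (`p < 0.05`) equivalent to
#' `|w| > 0.95` — the same cut used to draw "strong correlation" edges in
#' switching-neighborhood networks. The weight function can be replaced
#' through `weight_fun` (e.g. `function(r, p) r` for raw correlations).
#'
#' A gene that is constant within the individual has no defined
#' correlation with anything; such pairs are assigned `r = 0`, `p = 1`,
#' `w = 0` rather than propagating NaN.
#'
#' @param ds An [expr_dataset].
#' @param individual_id Individual to build the network for.
#' @param weight_fun Function of (r, p) returning the edge weight;
#'   default `sgn(r) * (1 - p)`.
#' @return Object of class `indiv_network`: list with `individual_id`,
#'   symmetric matrices `r` (diagonal 1), `p` (diagonal 0), `w`
#'   (diagonal 0), and `m`.
#' @export
build_individual_network <- function(ds, individual_id,
                                     weight_fun = function(r, p) sign(r) * (1 - p)) {
  vals <- individual_values(ds, individual_id)
  m <- ncol(vals)
  r <- suppressWarnings(stats::cor(t(vals)))  # constant rows give NA
  r[!is.finite(r)] <- 0
  r[] <- pmin(1, pmax(-1, r))  # guard rounding past +/-1; keep dim
  p <- matrix(correlation_pvalue(as.vector(r), m),
              nrow(r), ncol(r), dimnames = dimnames(r))
  p[r == 0] <- 1
  diag(r) <- 1
  diag(p) <- 0
  w <- weight_fun(r, p)
  diag(w) <- 0
  structure(list(individual_id = individual_id, r = r, p = p, w = w, m = m),
            class = "indiv_network")
}

#' Build the co-expression network of every individual
#'
#' @param ds An [expr_dataset].
#' @param weight_fun Passed to [build_individual_network()].
#' @return Named list of `indiv_network` objects, one per individual.
#' @export
build_individual_networks <- function(ds, weight_fun = function(r, p) sign(r) * (1 - p)) {
  ids <- unique(ds$design$individual_id)
  stats::setNames(
    lapply(ids, function(i) build_individual_network(ds, i, weight_fun)),
    ids)
}

#' Cross-individual consistency prefilter on gene pairs
#'
#' Retains a gene pair when its correlation is significant
#' (`p < p_cut`) *with a consistent sign* in enough individuals of at
#' least one group. "Enough" is, per group G with `n_G` individuals,
#' `T_G = max(ceiling(frac * n_G), min(min_count, n_G), 1)`: at least a
#' fraction `frac` of the group, with a floor of `min_count` individuals
#' where the group is large enough to provide them. The positive-sign and
#' negative-sign counts are tested separately, so evidence split across
#' signs does not accumulate.
#'
#' @param nets List of `indiv_network` objects (see
#'   [build_individual_networks()]).
#' @param groups Named character vector mapping individual id to group
#'   label (see [individual_groups()]).
#' @param p_cut Significance threshold; default 0.05.
#' @param frac Minimum fraction of a group's individuals; default 0.25.
#' @param min_count Minimum number of individuals where available;
#'   default 2.
#' @return Object of class `consistency_mask`: list with the binary
#'   symmetric matrix `a` (zero diagonal), the thresholds used, and the
#'   per-group counts `n_G`.
#' @export
consistency_mask <- function(nets, groups, p_cut = 0.05, frac = 0.25, min_count = 2) {
  stopifnot(length(nets) > 0)
  ids <- vapply(nets, function(x) x$individual_id, character(1))
  unknown <- setdiff(ids, names(groups))
  if (length(unknown) > 0) abort_(sprintf("individual '%s' has no group label", unknown[1]))
  glabs <- sort(unique(groups[ids]))
  if (any(!glabs %in% groups[ids]) || length(glabs) < 1) abort_("no group members found")

  genes <- rownames(nets[[1]]$r)
  n <- length(genes)
  a <- matrix(0L, n, n, dimnames = list(genes, genes))
  n_G <- integer(0)
  for (g in glabs) {
    members <- which(groups[ids] == g)
    if (length(members) == 0) abort_(sprintf("group '%s' is empty", g))
    n_G[g] <- length(members)
    t_g <- max(ceiling(frac * length(members)),
               min(min_count, length(members)), 1)
    kpos <- matrix(0L, n, n)
    kneg <- matrix(0L, n, n)
    for (j in members) {
      sig <- nets[[j]]$p < p_cut
      kpos <- kpos + (sig & nets[[j]]$r > 0)
      kneg <- kneg + (sig & nets[[j]]$r < 0)
    }
    a <- a | (kpos >= t_g) | (kneg >= t_g)
  }
  a <- matrix(as.integer(a), n, n, dimnames = list(genes, genes))
  diag(a) <- 0L
  structure(list(a = a, p_cut = p_cut, frac = frac, min_count = min_count, n_G = n_G),
            class = "consistency_mask")
}

#' @export
print.consistency_mask <- function(x, ...) {
  cat(sprintf("<consistency_mask> %d genes, %d retained pairs (p_cut=%g, frac=%g, min_count=%d)\n",
              nrow(x$a), sum(x$a[upper.tri(x$a)]), x$p_cut, x$frac, x$min_count))
  invisible(x)
}
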