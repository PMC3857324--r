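# Brute-force scalar recomputation of the whole scoring pipeline
# (r -> p -> w -> a -> wbar -> d) with explicit nested loops and hand-written
# sums. Deliberately shares no code with the package internals beyond the
# t-distribution tail function.

oracle_pearson <- function(x, y) {
  m <- length(x)
  mx <- sum(x) / m
  my <- sum(y) / m
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

oracle_dcen <- function(ds, p_cut = 0.05, frac = 0.25, min_count = 2) {
  genes <- rownames(ds$values)
  n <- length(genes)
  groups <- individual_groups(ds)
  inds <- names(groups)

  w_list <- list()
  r_list <- list()
  p_list <- list()
  for (ind in inds) {
    vals <- individual_values(ds, ind)
    m <- ncol(vals)
    r <- matrix(0, n, n, dimnames = list(genes, genes))
    p <- matrix(1, n, n, dimnames = list(genes, genes))
    w <- matrix(0, n, n, dimnames = list(genes, genes))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
        rij <- oracle_pearson(vals[i, ], vals[j, ])
        if (is.na(rij)) { r[i, j] <- 0; p[i, j] <- 1; w[i, j] <- 0; next }
        rij <- max(-1, min(1, rij))
        pij <- if (abs(rij) >= 1) 0 else {
          tij <- rij * sqrt((m - 2) / (1 - rij^2))
          2 * stats::pt(-abs(tij), df = m - 2)
        }
        r[i, j] <- rij
        p[i, j] <- pij
        w[i, j] <- sign(rij) * (1 - pij)
      }
    }
    r_list[[ind]] <- r; p_list[[ind]] <- p; w_list[[ind]] <- w
  }

  glabs <- sort(unique(unname(groups)))
  a <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      for (g in glabs) {
        members <- inds[groups[inds] == g]
        t_g <- max(ceiling(frac * length(members)),
                   min(min_count, length(members)), 1)
        kpos <- 0; kneg <- 0
        for (ind in members) {
          if (p_list[[ind]][i, j] < p_cut) {
            if (r_list[[ind]][i, j] > 0) kpos <- kpos + 1
            if (r_list[[ind]][i, j] < 0) kneg <- kneg + 1
          }
        }
        if (kpos >= t_g || kneg >= t_g) a[i, j] <- 1L
      }
    }
  }

  wbar <- lapply(glabs, function(g) {
    members <- inds[groups[inds] == g]
    acc <- matrix(0, n, n, dimnames = list(genes, genes))
    for (ind in members) acc <- acc + w_list[[ind]]
    acc / length(members)
  })

  d <- numeric(n)
  names(d) <- genes
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (a[i, j] == 1L) {
        num <- num + abs(wbar[[1]][i, j] - wbar[[2]][i, j])
        den <- den + abs(wbar[[1]][i, j]) + abs(wbar[[2]][i, j])
      }
    }
    d[i] <- if (den > 0) num / den else 0
  }
  list(d = d, a = a, wbar_X = wbar[[1]], wbar_Y = wbar[[2]])
}

# hand-written Student t density; used to check tail probabilities by
# numeric integration, independently of stats::pt
oracle_t_tail <- function(t0, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t0), Inf, rel.tol = 1e-10)$value
}
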