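# fixture builders used across the suite; everything is generated in code

# small deterministic dataset: 4 genes, 2 individuals per group, 3 time points
toy_dataset <- function() {
  design <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    individual_id = rep(c("i1", "i2", "j1", "j2"), each = 3),
    group = rep(c("A", "A", "B", "B"), each = 3),
    time = rep(0:2, 4))
  set.seed(42)
  values <- matrix(rnorm(48), 4, 12,
                   dimnames = list(paste0("g", 1:4), design$sample_id))
  expr_dataset(values, design)
}

# random Gaussian dataset with no group structure
random_dataset <- function(n_genes, n_per_group, m, seed) {
  ind <- c(sprintf("a%02d", seq_len(n_per_group)), sprintf("b%02d", seq_len(n_per_group)))
  design <- tibble::tibble(
    sample_id = paste0(rep(ind, each = m), "_t", rep(seq_len(m), 2 * n_per_group)),
    individual_id = rep(ind, each = m),
    group = rep(c("ctrl", "trt"), each = n_per_group * m),
    time = rep(seq_len(m), 2 * n_per_group))
  set.seed(seed)
  values <- matrix(rnorm(n_genes * nrow(design)), n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)), design$sample_id))
  expr_dataset(values, design)
}

# group_weights object with explicit matrices (for analytic score cases)
make_avw <- function(wbar_X, wbar_Y, n_X = 3, n_Y = 3) {
  structure(list(wbar_X = wbar_X, wbar_Y = wbar_Y, n_X = n_X, n_Y = n_Y,
                 group_labels = c(X = "X", Y = "Y")),
            class = "group_weights")
}

# consistency_mask object with an explicit binary matrix
make_mask <- function(a, p_cut = 0.05, frac = 0.25, min_count = 2) {
  structure(list(a = a, p_cut = p_cut, frac = frac, min_count = min_count,
                 n_G = c(X = 3, Y = 3)),
            class = "consistency_mask")
}

# group_cornet with explicit association matrices
new_cornet_for_test <- function(s_X, s_Y, method = "test") {
  structure(list(method = method, s_X = s_X, s_Y = s_Y,
                 group_labels = c(X = "X", Y = "Y")),
            class = "group_cornet")
}

# symmetric matrix from upper-triangle entries given as (i, j, value) rows
sym_matrix <- function(genes, entries = NULL, diag_value = 0) {
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  if (!is.null(entries)) {
    for (k in seq_len(nrow(entries))) {
      i <- entries[k, 1]; j <- entries[k, 2]
      m[i, j] <- m[j, i] <- entries[k, 3]
    }
  }
  diag(m) <- diag_value
  m
}
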