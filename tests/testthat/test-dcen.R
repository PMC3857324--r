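test_that("group weight averaging is the arithmetic mean per group", {
  genes <- c("g1", "g2")
  fake <- function(id, w12) {
    structure(list(individual_id = id,
                   r = sym_matrix(genes, diag_value = 1),
                   p = sym_matrix(genes),
                   w = sym_matrix(genes, cbind(1, 2, w12)),
                   m = 5), class = "indiv_network")
  }
  groups <- c(a = "X", b = "X", c = "Y")
  avw <- average_weights(list(fake("a", 0.9), fake("b", 0.7), fake("c", 0.5)), groups)
  expect_equal(avw$wbar_X["g1", "g2"], 0.8)
  expect_equal(avw$wbar_Y["g1", "g2"], 0.5)   # single-individual group
  expect_equal(avw$n_X, 2)
  # cancellation of opposite weights
  avw2 <- average_weights(list(fake("a", 0.8), fake("b", -0.8), fake("c", 0)), groups)
  expect_equal(avw2$wbar_X["g1", "g2"], 0)
})

test_that("the score attains its documented bounds and values", {
  genes <- c("focal", "nb")
  mask <- make_mask(sym_matrix(genes, cbind(1, 2, 1)))
  score_of <- function(wx, wy) {
    avw <- make_avw(sym_matrix(genes, cbind(1, 2, wx)),
                    sym_matrix(genes, cbind(1, 2, wy)))
    res <- dcen_score(avw, mask)
    res$scores$score[res$scores$gene_id == "focal"]
  }
  expect_equal(score_of(0.8, 0.8), 0)          # equal neighborhoods
  expect_equal(score_of(0.8, -0.3), 1)         # opposite signs -> maximum
  expect_equal(score_of(0.8, 0), 1)            # weaker weight zero -> maximum
  expect_equal(score_of(0.6, 0.2), 0.5)        # hand evaluation: 0.4 / 0.8
  # empty retained neighborhood: d = 0
  empty_mask <- make_mask(sym_matrix(genes))
  avw <- make_avw(sym_matrix(genes, cbind(1, 2, 0.9)), sym_matrix(genes, cbind(1, 2, 0.1)))
  expect_equal(dcen_score(avw, empty_mask)$scores$score, c(0, 0))
})

test_that("scores are bounded in [0,1] and symmetric in the group labels", {
  for (s in 1:5) {
    ds <- random_dataset(8, 3, 5, seed = 100 + s)
    res <- dcen(ds)
    expect_true(all(res$scores$score >= 0 & res$scores$score <= 1))
    # swap group labels
    design2 <- ds$design
    design2$group <- ifelse(design2$group == "ctrl", "trt", "ctrl")
    res2 <- dcen(expr_dataset(ds$values, design2))
    expect_equal(tidy(res2)$score, tidy(res)$score, tolerance = 1e-12)
  }
})

test_that("production pipeline matches the brute-force oracle", {
  # a handful here; the full 100-instance sweep runs in the acceptance suite
  for (s in 1:10) {
    n_genes <- sample(4:8, 1)
    ds <- random_dataset(n_genes, sample(2:4, 1), 5, seed = 9000 + s)
    orc <- oracle_dcen(ds)
    res <- dcen(ds)
    got <- stats::setNames(res$scores$score, res$scores$gene_id)[names(orc$d)]
    expect_equal(got, orc$d, tolerance = 1e-10)
  }
})

test_that("permutation p-values use pooled nulls with add-one correction", {
  ds <- random_dataset(6, 3, 5, seed = 17)
  res <- permutation_pvalues(ds, n_perm = 5, seed = 1)
  expect_true(all(res$scores$p_value > 0 & res$scores$p_value <= 1))
  # add-one structure: smallest possible p is 1/(1 + n_perm * n_genes)
  expect_true(all(res$scores$p_value >= 1 / (1 + 5 * 6)))
  # a zero score can never beat null values >= 0, so its p is 1
  zero_genes <- res$scores$gene_id[res$scores$score == 0]
  if (length(zero_genes) > 0) {
    expect_true(all(res$scores$p_value[res$scores$gene_id %in% zero_genes] == 1))
  }
  # determinism under the same seed
  res2 <- permutation_pvalues(ds, n_perm = 5, seed = 1)
  expect_equal(tidy(res), tidy(res2))
  expect_error(permutation_pvalues(ds, n_perm = 5), "seed")
  one_per_group <- subset_individuals(ds, c("a01", "b01"))
  expect_error(permutation_pvalues(one_per_group, n_perm = 5, seed = 1),
               "2 individuals")
})

test_that("a rigged observed score above every null value gets the add-one minimum", {
  # identical groups except one decoupled gene -> that gene tops the ranking
  sim <- simulate_cohort(synthetic_config(n_genes = 20, module_sizes = c(10, 10),
                                          n_decoupled = 1, n_individuals = 3,
                                          noise_sd = 0.05, seed = 2))
  res <- permutation_pvalues(sim$dataset, n_perm = 20, seed = 3)
  top_gene <- res$scores$gene_id[1]
  expect_equal(top_gene, sim$truth$genes$gene_id[sim$truth$genes$decoupled])
  expect_equal(min(res$scores$p_value), res$scores$p_value[1])
})

test_that("switching neighborhoods select top-difference genes and strong edges", {
  set.seed(4)
  genes <- sprintf("g%04d", 1:1000)
  n <- length(genes)
  base <- matrix(stats::runif(n * n, -0.2, 0.2), n, n, dimnames = list(genes, genes))
  wx <- (base + t(base)) / 2
  diag(wx) <- 0
  wy <- wx
  # plant 5 strong switches on the focal gene plus strong in-condition edges
  focal <- "g0001"
  planted <- c("g0100", "g0200", "g0300", "g0400", "g0500")
  wx[focal, planted] <- wx[planted, focal] <- 0.97
  wy[focal, planted] <- wy[planted, focal] <- -0.97
  wx["g0100", "g0200"] <- wx["g0200", "g0100"] <- 0.96
  avw <- make_avw(wx, wy)
  sw <- switching_neighborhood(avw, focal, diff_fraction = 0.005, edge_cut = 0.95)
  expect_length(sw$neighbors, 5)  # ceil(0.005 * 1000)
  expect_setequal(sw$neighbors, planted)
  expect_true(all(abs(sw$edges_X$weight) > 0.95))
  expect_true(all(abs(sw$edges_Y$weight) > 0.95))
  # the 0.97 edge appears in X, not in Y (where it is -0.97, still > cut in |.|)
  key_x <- paste(sw$edges_X$gene_a, sw$edges_X$gene_b)
  expect_true(paste(focal, "g0100") %in% key_x)
  expect_true(paste("g0100", "g0200") %in% key_x)

  # degenerate: identical weights -> zero differences, lexicographic ties,
  # identical edge sets
  same <- make_avw(wx, wx)
  sw2 <- switching_neighborhood(same, focal, 0.005)
  expect_equal(sw2$neighbors, setdiff(genes, focal)[1:5])
  expect_equal(sw2$edges_X, sw2$edges_Y)
  expect_error(switching_neighborhood(avw, focal, diff_fraction = 0), "diff_fraction")
  expect_error(switching_neighborhood(avw, "nope"), "unknown focal gene")
})

test_that("tidy, glance, and autoplot expose the result", {
  ds <- random_dataset(6, 2, 5, seed = 31)
  res <- dcen(ds)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("gene_id", "score", "rank"))
  gl <- glance(res)
  expect_equal(gl$n_genes, 6L)
  expect_s3_class(autoplot(res), "ggplot")
})
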