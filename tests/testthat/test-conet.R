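test_that("correlation p-values match the t-distribution tail", {
  expect_equal(correlation_pvalue(0, 6), 1)
  expect_equal(correlation_pvalue(1, 5), 0)
  expect_equal(correlation_pvalue(-1, 5), 0)
  # frozen value checked against numeric integration of the t density (4 df)
  expect_equal(correlation_pvalue(0.9, 6), 0.0145, tolerance = 1e-3)
  expect_equal(correlation_pvalue(0.9, 6), oracle_t_tail(0.9 * sqrt(4 / 0.19), 4),
               tolerance = 1e-10)
  # symmetry and monotonicity in |r|
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(correlation_pvalue(rs, 7), correlation_pvalue(-rs, 7))
  expect_true(all(diff(correlation_pvalue(rs, 7)) < 0))
  expect_error(correlation_pvalue(0.5, 2), "m")
  expect_error(correlation_pvalue(1.5, 6), "-1, 1")
})

test_that("p-value is calibrated for independent Gaussian series", {
  set.seed(99)
  n_pairs <- 4000
  m <- 6
  p <- replicate(n_pairs, {
    correlation_pvalue(cor(rnorm(m), rnorm(m)), m)
  })
  frac <- mean(p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(frac - 0.05), tol)
})

test_that("individual networks have the documented structure", {
  ds <- toy_dataset()
  vals <- ds$values
  vals["g2", 1:3] <- vals["g1", 1:3]          # identical pair for i1
  vals["g3", 1:3] <- 5                         # constant gene for i1
  vals["g4", 1:3] <- -2 * vals["g1", 1:3] + 1  # anti-correlated, affine
  ds <- expr_dataset(vals, ds$design)
  net <- build_individual_network(ds, "i1")
  expect_equal(net$m, 3)
  expect_equal(net$r["g1", "g2"], 1)
  expect_equal(net$p["g1", "g2"], 0)
  expect_equal(net$w["g1", "g2"], 1)
  # constant gene: w = 0 against everything
  expect_equal(unname(net$w["g3", ]), rep(0, 4))
  expect_equal(unname(net$p["g3", c("g1", "g2", "g4")]), rep(1, 3))
  # anti-correlation gives negative weight of matching magnitude
  expect_equal(net$r["g1", "g4"], -1)
  expect_equal(net$w["g1", "g4"], -1)
  expect_true(isSymmetric(net$w))
  expect_equal(unname(diag(net$w)), rep(0, 4))
  expect_error(build_individual_network(ds, "nope"), "unknown individual")
})

test_that("weights are invariant to positive affine transforms and flip with sign", {
  ds <- random_dataset(5, 2, 6, seed = 3)
  net0 <- build_individual_network(ds, "a01")
  vals <- ds$values
  cols <- ds$design$sample_id[ds$design$individual_id == "a01"]
  vals["g001", cols] <- 3.7 * vals["g001", cols] + 11
  net1 <- build_individual_network(expr_dataset(vals, ds$design), "a01")
  expect_equal(net1$w, net0$w, tolerance = 1e-12)
  vals["g001", cols] <- -vals["g001", cols]
  net2 <- build_individual_network(expr_dataset(vals, ds$design), "a01")
  expect_equal(net2$w["g001", "g002"], -net0$w["g001", "g002"], tolerance = 1e-12)
})

test_that("consistency threshold arithmetic follows the 25%/min-2 rule", {
  # build synthetic networks with controllable significance patterns:
  # helper producing an indiv_network with given significant pairs
  genes <- c("g1", "g2", "g3")
  fake_net <- function(id, sig_sign) {
    r <- sym_matrix(genes, diag_value = 1)
    p <- sym_matrix(genes, diag_value = 0) + 1
    diag(p) <- 0
    w <- sym_matrix(genes)
    if (!is.na(sig_sign)) {
      r["g1", "g2"] <- r["g2", "g1"] <- sig_sign * 0.99
      p["g1", "g2"] <- p["g2", "g1"] <- 0.001
      w["g1", "g2"] <- w["g2", "g1"] <- sig_sign * 0.999
    }
    structure(list(individual_id = id, r = r, p = p, w = w, m = 5),
              class = "indiv_network")
  }

  # n = 17 in one group: T = max(ceil(4.25), 2) = 5
  ids17 <- sprintf("r%02d", 1:17)
  groups <- stats::setNames(c(rep("X", 17), rep("Y", 3)), c(ids17, c("y1", "y2", "y3")))
  nets <- c(lapply(1:17, function(i) fake_net(ids17[i], if (i <= 5) 1 else NA)),
            lapply(c("y1", "y2", "y3"), function(i) fake_net(i, NA)))
  expect_equal(consistency_mask(nets, groups)$a["g1", "g2"], 1L)
  # only 4 significant: below T = 5
  nets4 <- c(lapply(1:17, function(i) fake_net(ids17[i], if (i <= 4) 1 else NA)),
             lapply(c("y1", "y2", "y3"), function(i) fake_net(i, NA)))
  expect_equal(consistency_mask(nets4, groups)$a["g1", "g2"], 0L)

  # n = 3 per group: T = max(1, 2) = 2, one significant individual is not enough
  groups3 <- stats::setNames(rep(c("X", "Y"), each = 3),
                             c("x1", "x2", "x3", "y1", "y2", "y3"))
  nets1 <- lapply(names(groups3), function(i) fake_net(i, if (i == "x1") 1 else NA))
  expect_equal(consistency_mask(nets1, groups3)$a["g1", "g2"], 0L)
  nets2 <- lapply(names(groups3), function(i) fake_net(i, if (i %in% c("x1", "x2")) 1 else NA))
  expect_equal(consistency_mask(nets2, groups3)$a["g1", "g2"], 1L)

  # sign-split: 3 positive + 3 negative in a 17-member group does not reach T = 5
  netsplit <- c(lapply(1:17, function(i) {
    fake_net(ids17[i], if (i <= 3) 1 else if (i <= 6) -1 else NA)
  }), lapply(c("y1", "y2", "y3"), function(i) fake_net(i, NA)))
  expect_equal(consistency_mask(netsplit, groups)$a["g1", "g2"], 0L)
})

test_that("prefilter limit settings behave as documented", {
  ds <- random_dataset(8, 3, 5, seed = 7)
  nets <- build_individual_networks(ds)
  groups <- individual_groups(ds)
  # p_cut = 1: every pair passes
  m1 <- consistency_mask(nets, groups, p_cut = 1, frac = 0.25, min_count = 2)
  off_diag <- upper.tri(m1$a)
  expect_true(all(m1$a[off_diag] == 1L))
  # frac = 0, min_count = 0: any pair significant in >= 1 individual passes
  m0 <- consistency_mask(nets, groups, p_cut = 0.05, frac = 0, min_count = 0)
  any_sig <- Reduce(`|`, lapply(nets, function(x) x$p < 0.05))
  diag(any_sig) <- FALSE
  expect_equal(m0$a[off_diag], as.integer(any_sig[off_diag]))
})
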