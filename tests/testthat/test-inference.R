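test_that("weight-permutation null conserves the weight multiset exactly", {
  set.seed(30)
  W <- random_weight_matrix(10, density = 0.6)
  net <- as_scn_network(W)
  fit <- optimize_partition(net, n_restarts = 10, seed = 1)
  null <- random_modularity_null(net, fit$partition, n_reps = 100, seed = 2)
  expect_length(null$null_q, 100L)
  expect_equal(null$observed_q, fit$Q)
  # rebuild one replicate by hand to confirm the multiset is preserved
  seeds <- derive_seeds(2, 2)
  ut <- upper.tri(W)
  with_seed(seeds[2], {
    Wp <- matrix(0, 10, 10)
    Wp[ut] <- sample(W[ut])
    Wp <- Wp + t(Wp)
  })
  expect_identical(sort(Wp[ut]), sort(W[ut]))
  expect_equal(sum(Wp), sum(W))
})

test_that("uniform-weight networks give a degenerate, non-significant null", {
  W <- matrix(0.4, 6, 6)
  diag(W) <- 0
  colnames(W) <- rownames(W) <- letters[1:6]
  net <- as_scn_network(W)
  p <- partition(rep(1:2, each = 3), letters[1:6])
  null <- random_modularity_null(net, p, n_reps = 100, seed = 1)
  expect_equal(stats::sd(null$null_q), 0)
  expect_equal(null$p, 1)
  expect_equal(null$p_greater, 1)
})

test_that("planted modular networks beat every weight-permuted null", {
  spec <- cohort_spec(n_control = 100, seed = 31)
  cohort <- generate_cohort(spec)
  net <- normalize_by_total_weight(apply_weight_policy(
    build_correlation_network(residualize(cohort)$control)))
  fit <- optimize_partition(net, n_restarts = 20, seed = 4)
  null <- random_modularity_null(net, fit$partition, n_reps = 1000, seed = 5)
  expect_true(all(null$null_q < null$observed_q))
  expect_lt(null$p, 0.001)
  expect_lt(null$p_greater, 0.001)
})

test_that("constant statistics give permutation p = 1 under add-one", {
  pair <- toy_pair(n = 10, seed = 32)
  const <- function(cohort) c(stat = 1)
  perm <- permutation_group_test(pair$case, pair$control, const,
                                 n_perm = 50, seed = 1)
  expect_equal(unname(perm$observed_diff), 0)
  expect_equal(unname(perm$p_value), 1)
  # u / n_perm convention is recoverable
  perm2 <- permutation_group_test(pair$case, pair$control, const,
                                  n_perm = 50, seed = 1,
                                  include_observed = FALSE)
  expect_equal(unname(perm2$p_value), 1)
})

test_that("permutation tests are reproducible and reject non-finite statistics", {
  pair <- toy_pair(n = 12, seed = 33)
  stat <- network_statistic(attr(pair$case, "planted_partition"),
                            measures = "modularity")
  # tiny permuted subsets can be single-sex, which legitimately warns
  p1 <- suppressWarnings(permutation_group_test(pair$case, pair$control, stat,
                                                n_perm = 30, seed = 7))
  p2 <- suppressWarnings(permutation_group_test(pair$case, pair$control, stat,
                                                n_perm = 30, seed = 7))
  expect_identical(p1$null_diffs, p2$null_diffs)
  bad <- local({
    count <- 0
    function(cohort) {
      count <<- count + 1
      if (count >= 4) NaN else 0.5
    }
  })
  expect_error(
    permutation_group_test(pair$case, pair$control, bad, n_perm = 30,
                           seed = 1),
    "replicate 1")
})

test_that("an injected module difference is detected by the permutation test", {
  spec <- cohort_spec(n_autism = 100, n_control = 100, seed = 34,
                      group_effects = list(
                        list(group = "autism", module = 1, delta = -0.3)))
  pair <- make_autism_like_pair(spec)
  baseline <- optimize_partition(
    normalize_by_total_weight(apply_weight_policy(
      build_correlation_network(residualize(pair$control)$control))),
    n_restarts = 20, seed = 1)$partition
  stat <- network_statistic(baseline, measures = "module_connectivity")
  perm <- permutation_group_test(pair$case, pair$control, stat,
                                 n_perm = 300, seed = 8)
  # module 1 is canonical module 1 here because recovery is exact at n = 100
  expect_lt(unname(perm$observed_diff["MC.1"]), 0)
  expect_lt(unname(perm$p_value["MC.1"]), 0.01)
})

test_that("Fisher edge comparison matches hand arithmetic and is antisymmetric", {
  make_net <- function(r_ab, n) {
    W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    W["a", "b"] <- r_ab
    net <- as_scn_network(W + t(W))
    net$n_subjects <- n
    net
  }
  cmp <- fisher_edge_comparison(make_net(-0.45, 49), make_net(0.43, 51))
  row <- cmp[cmp$roi_a == "a" & cmp$roi_b == "b", ]
  se <- sqrt(1 / 46 + 1 / 48)
  expect_equal(row$Z, (atanh(0.43) - atanh(-0.45)) / se, tolerance = 1e-12)
  expect_equal(row$p, 2 * stats::pnorm(-abs(row$Z)), tolerance = 1e-12)
  expect_equal(row$z_case, atanh(-0.45))
  # equal correlations give Z = 0
  cmp0 <- fisher_edge_comparison(make_net(0.3, 20), make_net(0.3, 25))
  expect_equal(cmp0$Z[cmp0$roi_a == "a" & cmp0$roi_b == "b"], 0)
  # swapping the groups flips every Z exactly
  swapped <- fisher_edge_comparison(make_net(0.43, 51), make_net(-0.45, 49))
  expect_equal(swapped$Z, -cmp$Z, tolerance = 1e-12)
})

test_that("perfect correlations are flagged and excluded from the FDR family", {
  W1 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W1["a", "b"] <- 1
  W1["a", "c"] <- 0.2
  net1 <- as_scn_network(W1 + t(W1))
  net1$n_subjects <- 30
  W2 <- W1 * 0.5
  net2 <- as_scn_network(W2 + t(W2))
  net2$n_subjects <- 30
  expect_warning(cmp <- fisher_edge_comparison(net1, net2), "excluded")
  bad <- cmp$roi_a == "a" & cmp$roi_b == "b"
  expect_true(cmp$degenerate[bad])
  expect_true(is.na(cmp$fdr_significant[bad]))
  expect_false(any(is.na(cmp$fdr_significant[!bad])))
})

test_that("mismatched node sets are rejected by name", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  net1 <- as_scn_network(W)
  W2 <- W
  dimnames(W2) <- list(c("a", "b", "x"), c("a", "b", "x"))
  net2 <- as_scn_network(W2)
  net1$n_subjects <- net2$n_subjects <- 10
  expect_error(fisher_edge_comparison(net1, net2), "x")
})

test_that("BH step-up matches its definition and handles edge cases", {
  expect_identical(bh_fdr(rep(0.001, 10), q = 0.01), rep(TRUE, 10))
  p <- c(0.001, 0.008, 0.039, 0.041)
  expect_identical(bh_fdr(p, q = 0.05), rep(TRUE, 4))  # i* = 4
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
  expect_error(bh_fdr(c(0.1, 1.2), 0.05), "\\[0, 1\\]")
  set.seed(35)
  for (i in 1:20) {
    p <- stats::runif(200)^sample(c(1, 2, 3), 1)
    expect_identical(bh_fdr(p, 0.05), bh_stepup_direct(p, 0.05))
  }
})
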