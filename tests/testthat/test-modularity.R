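test_that("modularity reproduces closed-form values", {
  # single module: l/L - (2L/2L)^2 = 0
  net <- two_cliques_network(size = 4, w = 0.5)
  nodes <- net$nodes
  expect_equal(modularity_q(net, partition(rep(1, 8), nodes)), 0)
  # two disconnected equal cliques: 2 * (1/2 - 1/4)
  expect_equal(modularity_q(net, clique_partition(4)), 0.5)
  # 4-node hand example {a-b, c-d, a-c}, split {ab|cd}: 2*(1/3 - (3/6)^2)
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["c", "d"] <- W["a", "c"] <- 1
  net4 <- as_scn_network(W + t(W))
  expect_equal(modularity_q(net4, partition(c(1, 1, 2, 2), letters[1:4])),
               1 / 6)
})

test_that("modularity agrees with the pairwise-definition oracle and igraph", {
  set.seed(20)
  for (i in 1:10) {
    W <- random_weight_matrix(9, density = 0.6)
    memb <- sample(1:3, 9, replace = TRUE)
    net <- as_scn_network(W)
    p <- partition(memb, nodes = colnames(W))
    q <- modularity_q(net, p)
    expect_equal(q, q_direct(W, unclass(p)), tolerance = 1e-12)
    if (requireNamespace("igraph", quietly = TRUE)) {
      g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                               weighted = TRUE)
      expect_equal(q, igraph::modularity(g, unclass(p),
                                         weights = igraph::E(g)$weight),
                   tolerance = 1e-12)
    }
  }
})

test_that("Q, MD and PC are invariant under global weight rescaling", {
  set.seed(21)
  W <- random_weight_matrix(12, density = 0.5)
  p <- partition(rep(1:3, each = 4), nodes = colnames(W))
  net1 <- as_scn_network(W)
  net2 <- as_scn_network(W * 37.5)
  expect_equal(modularity_q(net1, p), modularity_q(net2, p),
               tolerance = 1e-12)
  r1 <- node_roles(net1, p)
  r2 <- node_roles(net2, p)
  expect_equal(r1$PC, r2$PC, tolerance = 1e-12)
  expect_equal(r1$MD, r2$MD, tolerance = 1e-12)
})

test_that("optimizer recovers the two-clique partition at Q = 0.5", {
  net <- two_cliques_network(size = 4, w = 0.5)
  fit <- optimize_partition(net, n_restarts = 10, seed = 1)
  expect_equal(fit$Q, 0.5, tolerance = 1e-12)
  expect_identical(unclass(fit$partition), unclass(clique_partition(4)))
  expect_equal(fit$n_modules, 2L)
  # deterministic given the seed
  fit2 <- optimize_partition(net, n_restarts = 10, seed = 1)
  expect_identical(fit$partition, fit2$partition)
})

test_that("optimizer Q satisfies the l_s/d_s decomposition identity", {
  set.seed(22)
  W <- random_weight_matrix(15, density = 0.4)
  fit <- optimize_partition(as_scn_network(W), n_restarts = 20, seed = 2)
  expect_equal(fit$Q,
               sum(fit$l_s / fit$L - (fit$d_s / (2 * fit$L))^2),
               tolerance = 1e-12)
  expect_equal(fit$Q, max(fit$trace), tolerance = 1e-12)
})

test_that("optimizer matches exhaustive search on small networks", {
  # a light version of the acceptance sweep: 10 networks of 6-7 nodes
  set.seed(23)
  for (i in 1:10) {
    n <- sample(6:7, 1)
    W <- random_weight_matrix(n, density = 0.5)
    if (sum(W) == 0) next
    best <- max(vapply(all_partitions(n),
                       function(m) q_direct(W, m), 0))
    fit <- optimize_partition(as_scn_network(W), n_restarts = 50, seed = i)
    expect_equal(fit$Q, best, tolerance = 1e-10)
  }
})

test_that("module connectivities implement their definitions and conserve L", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["c", "d"] <- W["a", "c"] <- 1
  net <- as_scn_network(W + t(W))
  p <- partition(c(1, 1, 2, 2), letters[1:4])
  expect_equal(intra_module_connectivity(net, p, 1), 1)
  expect_equal(intra_module_connectivity(net, p, 2), 1)
  expect_equal(inter_module_connectivity(net, p, 1, 2), 1)
  expect_error(intra_module_connectivity(net, p, 5), "unknown module")
  expect_error(inter_module_connectivity(net, p, 1, 1), "distinct")
  # single-module partition: MC = L
  p1 <- partition(rep(1, 4), letters[1:4])
  expect_equal(intra_module_connectivity(net, p1, 1), 3)

  set.seed(24)
  for (i in 1:5) {
    W <- random_weight_matrix(10, density = 0.7)
    net <- as_scn_network(W)
    p <- partition(sample(1:3, 10, replace = TRUE), nodes = colnames(W))
    mc <- module_connectivity(net, p)
    expect_equal(sum(mc$MC) + sum(mc$IMC[upper.tri(mc$IMC)]), mc$L,
                 tolerance = 1e-12)
  }
})

test_that("node roles reproduce hand-computed MD and PC", {
  # node a: strength 4 split kappa = (2, 1, 1) over three modules
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- 2
  A["a", "c"] <- 1
  A["a", "d"] <- 1
  net <- as_scn_network(A + t(A))
  roles <- node_roles(net, partition(c(1, 1, 2, 3), letters[1:4]))
  expect_equal(roles$PC[roles$roi == "a"], 1 - 6 / 16)
  # all weight intra-modular -> PC = 0
  net2 <- two_cliques_network(4, 0.5)
  roles2 <- node_roles(net2, clique_partition(4))
  expect_equal(roles2$PC, rep(0, 8))
  expect_equal(roles2$MD, rep(0, 8))  # identical nodes: sigma = 0 convention
  # equal weight to each of 3 modules -> PC = 2/3 (the 1 - 1/N_m ceiling)
  B <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  B["a", "b"] <- B["a", "d"] <- B["a", "f"] <- 1
  B["b", "c"] <- B["d", "e"] <- B["f", "g"] <- 1
  netb <- as_scn_network(B + t(B))
  pb <- partition(c(1, 1, 1, 2, 2, 3, 3), letters[1:7])
  rolesb <- node_roles(netb, pb)
  expect_equal(rolesb$PC[rolesb$roi == "a"], 2 / 3)
  # module intra-strengths (1, 2, 3) -> population z-scores -/+ sqrt(3/2)
  C <- matrix(0, 4, 4,
              dimnames = list(c("x", "y", "z", "o"), c("x", "y", "z", "o")))
  C["x", "z"] <- 1
  C["y", "z"] <- 2
  netc <- as_scn_network(C + t(C))
  pc <- partition(c(1, 1, 1, 2), c("x", "y", "z", "o"))
  rolesc <- node_roles(netc, pc)
  # intra strengths (1, 2, 3): mean 2, population sd sqrt(2/3)
  expect_equal(rolesc$MD[1:3], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(mean(rolesc$MD[1:3]), 0, tolerance = 1e-10)
})

test_that("PC stays within [0, 1 - 1/N_m] and module MD means vanish", {
  set.seed(25)
  for (i in 1:10) {
    W <- random_weight_matrix(12, density = 0.6)
    p <- partition(sample(1:4, 12, replace = TRUE), nodes = colnames(W))
    roles <- suppressMessages(node_roles(as_scn_network(W), p))
    nm <- n_modules(p)
    expect_true(all(roles$PC >= -1e-12))
    expect_true(all(roles$PC <= 1 - 1 / nm + 1e-12))
    for (s in seq_len(nm)) {
      md <- roles$MD[roles$module == s]
      if (length(md) > 1 && stats::sd(md) > 0)
        expect_equal(mean(md), 0, tolerance = 1e-10)
    }
  }
})

test_that("isolated nodes get PC 0 by convention", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 1
  net <- as_scn_network(W + t(W))
  expect_message(roles <- node_roles(net, partition(c(1, 1, 2), letters[1:3])),
                 "isolated")
  expect_equal(roles$PC[roles$roi == "c"], 0)
})

test_that("planted three-block networks are recovered exactly and match igraph", {
  skip_if_not_installed("igraph")
  spec <- cohort_spec(n_control = 100, seed = 26)
  cohort <- generate_cohort(spec)
  net <- normalize_by_total_weight(apply_weight_policy(
    build_correlation_network(residualize(cohort)$control)))
  fit <- optimize_partition(net, n_restarts = 20, seed = 3)
  pp <- unclass(attr(cohort, "planted_partition"))
  expect_equal(fit$n_modules, 3L)
  expect_equal(adjusted_rand_index(unclass(fit$partition), pp), 1)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE)
  set.seed(1)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  expect_equal(adjusted_rand_index(igraph::membership(cl),
                                   unclass(fit$partition)), 1)
})
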