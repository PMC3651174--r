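# Independent oracles and small fixtures shared across tests.

# Modularity straight from the pairwise definition,
# Q = (1/2L) sum_ij [W_ij - k_i k_j / 2L] delta(c_i, c_j),
# written independently of the package's per-module accumulation.
q_direct <- function(W, memb) {
  m2 <- sum(W)
  k <- rowSums(W)
  same <- outer(memb, memb, "==")
  sum((W - outer(k, k) / m2)[same]) / m2
}

# All set partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(assign, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# Random sparse symmetric weight matrix with named nodes.
random_weight_matrix <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- stats::runif(sum(ut)) * stats::rbinom(sum(ut), 1, density)
  W[ut] <- w
  W <- W + t(W)
  colnames(W) <- rownames(W) <- sprintf("n%02d", seq_len(n))
  W
}

# Two disconnected equal-weight cliques (weight w on every internal edge).
two_cliques_network <- function(size = 4, w = 0.5) {
  n <- 2L * size
  W <- matrix(0, n, n)
  W[seq_len(size), seq_len(size)] <- w
  W[(size + 1):n, (size + 1):n] <- w
  diag(W) <- 0
  colnames(W) <- rownames(W) <- sprintf("n%02d", seq_len(n))
  as_scn_network(W)
}

clique_partition <- function(size = 4) {
  partition(rep(1:2, each = size), nodes = sprintf("n%02d", seq_len(2L * size)))
}

# Benjamini-Hochberg step-up straight from its definition.
bh_stepup_direct <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# Small two-group cohort for io / pipeline smoke tests.
toy_pair <- function(n = 20, seed = 101, ...) {
  make_autism_like_pair(cohort_spec(n_autism = n, n_control = n,
                                    seed = seed, ...))
}
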