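# Internal fast modularity for a membership vector on a weight matrix with
# zero diagonal: Q = sum_s [ l_s/L - (d_s/2L)^2 ], where l_s is the summed
# edge weight inside module s, d_s the summed node strength of module s, and
# L the total edge weight.
modularity_membership <- function(W, memb) {
  L <- sum(W) / 2
  if (L <= 0) stop("total network weight must be positive")
  k <- rowSums(W)
  nm <- max(memb)
  l_s <- numeric(nm)
  for (s in seq_len(nm)) {
    ids <- which(memb == s)
    l_s[s] <- sum(W[ids, ids]) / 2
  }
  d_s <- as.vector(rowsum(k, memb))
  sum(l_s / L - (d_s / (2 * L))^2)
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_s [ l_s / L - (d_s / 2L)^2 ]` over modules s, where `l_s` is the
#' sum of edge weights inside module s, `d_s` the sum of node strengths
#' (a node's strength is the sum of its incident edge weights) over the
#' module, and `L` the total edge weight. Q is invariant under global weight
#' rescaling, so normalized and unnormalized networks give identical values.
#'
#' @param network an `scn_network` with non-negative weights (a policy
#'   applied; `keep_signed` networks with negative entries are rejected).
#' @param partition an `scn_partition` covering the network's nodes.
#' @return the modularity Q (a single number).
#' @examples
#' W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' W[1, 2] <- W[3, 4] <- W[1, 3] <- 1
#' net <- as_scn_network(W + t(W))
#' modularity_q(net, partition(c(1, 1, 2, 2), nodes = letters[1:4]))  # 1/6
#' @export
modularity_q <- function(network, partition) {
  W <- policy_weights(network)
  p <- match_partition(partition, network$nodes)
  modularity_membership(W, unclass(p))
}

# ---------------------------------------------------------------------------
# Louvain-style optimizer: greedy local moving + community aggregation on a
# dense symmetric matrix. Convention for aggregated graphs: the diagonal
# A[c, c] holds *twice* the internal weight of super-node c, so that
# sum(A) = 2L and rowSums(A) are node strengths throughout.

# One sweep of greedy local moving from an initial assignment; returns
# canonical community labels and whether any node moved.
local_move <- function(A, init = seq_len(nrow(A))) {
  n <- nrow(A)
  m2 <- sum(A)                     # 2L
  k <- rowSums(A)
  comm <- init
  # summed strength per community, indexable by community label
  sigma_tot <- numeric(max(comm))
  agg <- rowsum(k, comm)
  sigma_tot[as.integer(rownames(agg))] <- agg
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      wi <- A[i, ]
      wi[i] <- 0                   # self-loop moves with the node
      w_to <- rowsum(wi, comm)     # weight from i to each community
      labs <- as.integer(rownames(w_to))
      w_to <- w_to[, 1]
      sig <- sigma_tot[labs]
      sig[labs == ci] <- sig[labs == ci] - k[i]
      # gain (x 1/L) of placing i in each candidate community
      score <- w_to - k[i] * sig / m2
      cur <- score[labs == ci]
      best <- which(score > cur + 1e-12)
      if (length(best)) {
        best <- best[which.max(score[best])]
        cb <- labs[best]
        sigma_tot[ci] <- sigma_tot[ci] - k[i]
        sigma_tot[cb] <- sigma_tot[cb] + k[i]
        comm[i] <- cb
        moved <- TRUE
      }
    }
    if (!moved) break
    moved_any <- TRUE
  }
  list(comm = match(comm, unique(comm)), moved = moved_any)
}

# Collapse communities into super-nodes, keeping the 2x-internal-weight
# diagonal convention.
aggregate_graph <- function(A, comm) {
  B <- rowsum(t(rowsum(A, comm)), comm)
  dimnames(B) <- NULL
  B
}

# Full multi-level pass; returns membership of the original nodes. Half of
# the restarts (on average) start from singletons, the rest from a random
# coarse partition -- greedy local moving cannot split communities, so varied
# starting points are needed to escape merge-order traps on small graphs.
louvain_once <- function(W) {
  n <- nrow(W)
  init <- if (n > 2 && stats::runif(1) < 0.5) {
    sample.int(sample(2:max(2, n - 1), 1), n, replace = TRUE)
  } else {
    seq_len(n)
  }
  A <- W
  membership <- seq_len(n)
  first <- TRUE
  repeat {
    step <- local_move(A, init = if (first) init else seq_len(nrow(A)))
    first <- FALSE
    if (!step$moved) {
      # keep the initial grouping if it was already a local optimum
      membership <- step$comm[membership]
      break
    }
    membership <- step$comm[membership]
    A <- aggregate_graph(A, step$comm)
    if (nrow(A) == 1L) break
  }
  membership
}

#' Find the maximum-modularity partition
#'
#' Greedy Louvain-style agglomeration (local moving + community aggregation)
#' restarted `n_restarts` times from random node orders; the partition with
#' the highest Q is returned, with module labels canonicalized by lowest node
#' index. The number and sizes of modules are not specified in advance.
#' Deterministic given `seed`.
#'
#' @param network an `scn_network` with non-negative weights.
#' @param n_restarts number of seeded restarts (default 100).
#' @param seed RNG seed.
#' @return an `scn_modules` object: `partition`, `Q`, `l_s` (per-module
#'   internal weight), `d_s` (per-module strength sum), `L` (total weight),
#'   `n_modules`, and `trace` (best-Q audit across restarts).
#' @export
optimize_partition <- function(network, n_restarts = 100, seed = 1L) {
  W <- policy_weights(network)
  if (sum(W) <= 0) stop("total network weight must be positive")
  trace <- numeric(n_restarts)
  best_q <- -Inf
  best_memb <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      memb <- louvain_once(W)
      q <- modularity_membership(W, memb)
      trace[r] <- q
      if (q > best_q + 1e-12) {
        best_q <- q
        best_memb <- memb
      }
    }
  })
  p <- partition(best_memb, nodes = network$nodes)
  L <- sum(W) / 2
  k <- rowSums(W)
  nm <- n_modules(p)
  l_s <- vapply(seq_len(nm), function(s) {
    ids <- which(unclass(p) == s); sum(W[ids, ids]) / 2
  }, 0)
  d_s <- as.vector(rowsum(k, unclass(p)))
  structure(list(partition = p, Q = best_q, l_s = l_s, d_s = d_s, L = L,
                 n_modules = nm, n_restarts = n_restarts, seed = seed,
                 trace = trace),
            class = "scn_modules")
}

#' @export
print.scn_modules <- function(x, ...) {
  cat(sprintf("Optimal modular organization: %d modules, Q = %.4f\n",
              x$n_modules, x$Q))
  sizes <- tabulate(unclass(x$partition), x$n_modules)
  cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  cat(sprintf("  best of %d restarts (reached at restart %d)\n",
              x$n_restarts, which.max(x$trace)))
  invisible(x)
}

#' Intra- and inter-module connectivity
#'
#' `intra_module_connectivity()` returns MC_s, the sum of edge weights with
#' both endpoints in module s; `inter_module_connectivity()` returns IMC_st,
#' the sum of edge weights with one endpoint in each of modules s and t.
#' Together they conserve weight: sum_s MC_s + sum_{s<t} IMC_st = L.
#' `module_connectivity()` computes all of them at once.
#'
#' @param network an `scn_network` with non-negative weights.
#' @param partition an `scn_partition`.
#' @param s,t module ids.
#' @return a single weight sum; for `module_connectivity()`, a list with
#'   `MC` (named vector), `IMC` (N_m x N_m matrix, diagonal `NA`), and `L`.
#' @export
intra_module_connectivity <- function(network, partition, s) {
  W <- policy_weights(network)
  p <- match_partition(partition, network$nodes)
  if (!s %in% seq_len(n_modules(p))) stop("unknown module id: ", s)
  ids <- which(unclass(p) == s)
  sum(W[ids, ids]) / 2
}

#' @rdname intra_module_connectivity
#' @export
inter_module_connectivity <- function(network, partition, s, t) {
  W <- policy_weights(network)
  p <- match_partition(partition, network$nodes)
  nm <- n_modules(p)
  if (!s %in% seq_len(nm)) stop("unknown module id: ", s)
  if (!t %in% seq_len(nm)) stop("unknown module id: ", t)
  if (s == t) stop("inter-module connectivity needs two distinct modules")
  sum(W[unclass(p) == s, unclass(p) == t])
}

#' @rdname intra_module_connectivity
#' @export
module_connectivity <- function(network, partition) {
  W <- policy_weights(network)
  p <- match_partition(partition, network$nodes)
  nm <- n_modules(p)
  memb <- unclass(p)
  block <- rowsum(t(rowsum(W, memb)), memb)  # summed weights between modules
  MC <- diag(block) / 2
  IMC <- block
  diag(IMC) <- NA_real_
  names(MC) <- paste0("M", seq_len(nm))
  dimnames(IMC) <- list(names(MC), names(MC))
  list(MC = MC, IMC = IMC, L = sum(W) / 2)
}

#' Node-level module roles: intra-module degree and participation coefficient
#'
#' For node i in module s(i), with `kappa_is` the summed weight from i to
#' module s and `k_i` its total strength:
#' * intra-module degree `MD_i = (kappa_{i,s(i)} - mean) / sd`, the z-score
#'   of its within-module strength over the nodes of its module (population
#'   standard deviation; if the module's sd is 0, including singleton
#'   modules, MD is 0 by convention);
#' * participation coefficient `PC_i = 1 - sum_s (kappa_is / k_i)^2`, 0 when
#'   all weight is intra-modular, approaching `1 - 1/N_m` when spread evenly.
#'   Isolated nodes (`k_i = 0`) get PC 0 by convention (with a message).
#'
#' @param network an `scn_network` with non-negative weights.
#' @param partition an `scn_partition`.
#' @return an `scn_node_roles` data.frame: `roi`, `module`, `strength`,
#'   `MD`, `PC`, with the node-to-module weight matrix in attribute `kappa`.
#' @export
node_roles <- function(network, partition) {
  W <- policy_weights(network)
  p <- match_partition(partition, network$nodes)
  memb <- unclass(p)
  nm <- n_modules(p)
  kappa <- t(rowsum(W, memb))            # nodes x modules
  colnames(kappa) <- paste0("M", seq_len(nm))
  k <- rowSums(kappa)
  kappa_own <- kappa[cbind(seq_along(memb), memb)]

  MD <- numeric(length(memb))
  for (s in seq_len(nm)) {
    ids <- which(memb == s)
    x <- kappa_own[ids]
    mu <- mean(x)
    sd_pop <- sqrt(mean((x - mu)^2))
    MD[ids] <- if (sd_pop > 1e-14 * max(abs(x), 1)) (x - mu) / sd_pop else 0
  }

  PC <- numeric(length(memb))
  pos <- k > 0
  if (any(!pos))
    message(sum(!pos), " isolated node(s); PC set to 0 by convention")
  PC[pos] <- 1 - rowSums((kappa[pos, , drop = FALSE] / k[pos])^2)

  out <- data.frame(roi = network$nodes, module = memb, strength = k,
                    MD = MD, PC = PC, stringsAsFactors = FALSE)
  attr(out, "kappa") <- kappa
  class(out) <- c("scn_node_roles", "data.frame")
  out
}
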