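#' Build a group-level correlation network
#'
#' Pairwise Pearson correlation of residualized thickness across subjects for
#' every region pair gives a fully weighted, symmetric network with N nodes
#' and K = N(N-1)/2 edges. The raw signed correlation matrix is always kept
#' (it is what the Fisher r-to-z edge comparison uses); modularity-facing
#' weights are derived from it by [apply_weight_policy()].
#'
#' @param residuals an `scn_residuals` (or a plain subjects x ROI numeric
#'   matrix with column names).
#' @param group group label recorded on the network (default: taken from
#'   `residuals`).
#' @return an `scn_network`: list with `weights` (modularity-facing matrix,
#'   initially the signed correlations with a zeroed diagonal), `signed_r`,
#'   `nodes`, `n_nodes`, `n_edges`, `n_subjects`, `group`, `policy`
#'   (`"none"` until a policy is applied), `normalized`, `total_weight`.
#' @export
build_correlation_network <- function(residuals, group = NULL) {
  if (inherits(residuals, "scn_residuals")) {
    if (is.null(group)) group <- residuals$group
    Y <- residuals$values
  } else {
    Y <- as.matrix(residuals)
    if (is.null(group)) group <- "group"
  }
  if (nrow(Y) < 4)
    stop("need at least 4 subjects to correlate (Fisher SE undefined for ",
         "n <= 3); got ", nrow(Y))
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI column(s), correlation undefined: ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  R <- stats::cor(Y)
  diag(R) <- 0
  n <- ncol(R)
  structure(list(weights = R, signed_r = R, nodes = colnames(Y),
                 n_nodes = n, n_edges = n * (n - 1L) / 2L,
                 n_subjects = nrow(Y), group = group,
                 policy = "none", normalized = FALSE,
                 total_weight = sum(R[upper.tri(R)])),
            class = "scn_network")
}

#' Derive modularity-facing edge weights from signed correlations
#'
#' Newman's weighted modularity assumes non-negative weights, but thickness
#' correlations can be negative. Three readings are exposed:
#' `"truncate_negative"` (default) zeroes negative correlations,
#' `"absolute"` takes magnitudes, and `"keep_signed"` passes the signed
#' matrix through unchanged -- such a network is flagged and rejected by the
#' modularity computations. The signed matrix is preserved in all cases.
#'
#' @param network an `scn_network`.
#' @param policy one of `"truncate_negative"`, `"absolute"`, `"keep_signed"`.
#' @return the network with `weights` replaced and `policy` recorded.
#' @export
apply_weight_policy <- function(network,
                                policy = c("truncate_negative", "absolute",
                                           "keep_signed")) {
  stopifnot(inherits(network, "scn_network"))
  policy <- match.arg(policy)
  W <- network$signed_r
  W <- switch(policy,
              truncate_negative = pmax(W, 0),
              absolute = abs(W),
              keep_signed = W)
  diag(W) <- 0
  network$weights <- W
  network$policy <- policy
  network$normalized <- FALSE
  network$total_weight <- sum(W[upper.tri(W)])
  network
}

#' Normalize edge weights by total network weight
#'
#' Divides every policy weight by L, the sum over the K distinct edges, so
#' that networks from different groups carry the same total weight (L = 1)
#' and module-level weight sums are comparable across groups. Modularity is
#' invariant under this rescaling; intra-/inter-module connectivity is not,
#' which is the point.
#'
#' @param network an `scn_network` with a weight policy applied.
#' @return the network with normalized `weights`, `normalized = TRUE` and
#'   `total_weight = 1`.
#' @export
normalize_by_total_weight <- function(network) {
  stopifnot(inherits(network, "scn_network"))
  if (network$policy == "none")
    stop("apply a weight policy before normalizing")
  L <- sum(network$weights[upper.tri(network$weights)])
  if (L <= 0) stop("total network weight is ", L, "; degenerate network")
  network$weights <- network$weights / L
  network$normalized <- TRUE
  network$total_weight <- 1
  network
}

#' Wrap a weight matrix as a network
#'
#' Builds an `scn_network` directly from a symmetric weight matrix, for toy
#' examples and externally computed networks. The matrix is treated as both
#' the signed correlation matrix and the modularity-facing weights (policy
#' `"as_given"`); the diagonal is zeroed.
#'
#' @param weights symmetric numeric matrix; column names become node names.
#' @param group group label.
#' @param n_subjects subject count behind the weights (needed only for
#'   Fisher edge comparisons).
#' @return an `scn_network`.
#' @examples
#' W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' W["a", "b"] <- W["c", "d"] <- W["a", "c"] <- 1
#' net <- as_scn_network(W + t(W))
#' modularity_q(net, partition(c(1, 1, 2, 2), nodes = letters[1:4]))  # 1/6
#' @export
as_scn_network <- function(weights, group = "network", n_subjects = NA) {
  W <- as.matrix(weights)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-12)
    stop("'weights' must be a symmetric square matrix")
  if (is.null(colnames(W)))
    colnames(W) <- rownames(W) <- sprintf("node%02d", seq_len(ncol(W)))
  diag(W) <- 0
  n <- ncol(W)
  structure(list(weights = W, signed_r = W, nodes = colnames(W),
                 n_nodes = n, n_edges = n * (n - 1L) / 2L,
                 n_subjects = n_subjects, group = group,
                 policy = "as_given", normalized = FALSE,
                 total_weight = sum(W[upper.tri(W)])),
            class = "scn_network")
}

# Internal: modularity-facing weights, checked for Q-safety.
policy_weights <- function(network, require_nonnegative = TRUE) {
  stopifnot(inherits(network, "scn_network"))
  W <- network$weights
  if (require_nonnegative && any(W < 0)) {
    stop("network has negative weights (policy '", network$policy,
         "'); Newman modularity needs a non-negative weight policy")
  }
  W
}

#' Edge table of a network
#'
#' @param network an `scn_network`.
#' @return data.frame with one row per distinct edge (upper triangle in atlas
#'   order): `roi_a`, `roi_b`, `r_signed`, `weight`.
#' @export
network_edge_table <- function(network) {
  stopifnot(inherits(network, "scn_network"))
  ut <- upper.tri(network$signed_r)
  idx <- which(ut, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  data.frame(roi_a = network$nodes[idx[, 1]],
             roi_b = network$nodes[idx[, 2]],
             r_signed = network$signed_r[idx],
             weight = network$weights[idx],
             stringsAsFactors = FALSE)
}

#' Export a network as GraphML
#'
#' Writes the current modularity-facing weights (attribute `weight`) and the
#' signed correlations (attribute `r`) for use in external graph viewers.
#' Requires the igraph package.
#'
#' @param network an `scn_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export needs the 'igraph' package")
  g <- igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  edges <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$r <- network$signed_r[cbind(edges[, 1], edges[, 2])]
  igraph::V(g)$name <- network$nodes
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.scn_network <- function(x, ...) {
  cat("Structural covariance network (group '", x$group, "')\n", sep = "")
  cat("  ", x$n_nodes, " nodes, ", x$n_edges, " weighted edges, n = ",
      x$n_subjects, " subjects\n", sep = "")
  cat("  weight policy: ", x$policy,
      if (x$normalized) " (normalized, L = 1)" else "", "\n", sep = "")
  invisible(x)
}
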