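#' Random-network null for modularity
#'
#' Generates null networks by uniformly permuting the multiset of
#' upper-triangle edge weights over the node pairs (same nodes, same number
#' of edges, same weight multiset -- total weight is conserved exactly; node
#' strengths are not). Each replicate is scored with the supplied partition
#' (the baseline strategy) or re-optimized from scratch, and the observed Q
#' is compared against the null sample with a one-sample t-test.
#'
#' @param network an `scn_network` with non-negative weights.
#' @param partition reference `scn_partition`; if `NULL` the network's own
#'   optimum is found first (with `n_restarts` restarts).
#' @param n_reps null replicates (>= 100; published practice is 10,000).
#' @param seed RNG seed.
#' @param reoptimize re-run the partition optimizer inside every replicate
#'   (`TRUE`) or re-score the fixed partition (default, much cheaper).
#' @param n_restarts optimizer restarts when optimizing.
#' @return an `scn_random_null`: `observed_q`, `null_q` (vector), `statistic`
#'   (t), `p` (two-sided), `p_greater` (one-sided, observed exceeding the
#'   null mean), `n_reps`, `seed`, `reoptimize`.
#' @export
random_modularity_null <- function(network, partition = NULL,
                                   n_reps = 10000, seed = 1L,
                                   reoptimize = FALSE, n_restarts = 20) {
  W <- policy_weights(network)
  if (n_reps < 100) stop("n_reps must be at least 100")
  seeds <- derive_seeds(seed, 2)
  if (is.null(partition)) {
    partition <- optimize_partition(network, n_restarts = n_restarts,
                                    seed = seeds[1])$partition
  }
  p <- match_partition(partition, network$nodes)
  observed <- modularity_membership(W, unclass(p))

  ut <- upper.tri(W)
  w_edges <- W[ut]
  n <- nrow(W)
  null_q <- numeric(n_reps)
  with_seed(seeds[2], {
    for (r in seq_len(n_reps)) {
      Wp <- matrix(0, n, n)
      Wp[ut] <- sample(w_edges)
      Wp <- Wp + t(Wp)
      null_q[r] <- if (reoptimize) {
        net_r <- network
        net_r$weights <- Wp
        optimize_partition(net_r, n_restarts = n_restarts,
                           seed = sample.int(.Machine$integer.max, 1))$Q
      } else {
        modularity_membership(Wp, unclass(p))
      }
    }
  })

  if (stats::sd(null_q) == 0) {
    same <- isTRUE(all.equal(mean(null_q), observed))
    tstat <- if (same) 0 else Inf
    p_two <- if (same) 1 else 0
    p_greater <- if (same) 1 else as.numeric(mean(null_q) < observed)
  } else {
    tt <- stats::t.test(null_q, mu = observed)
    tstat <- unname(tt$statistic)
    p_two <- tt$p.value
    # one-sided: observed larger than the null mean
    p_greater <- stats::pt(tstat, df = n_reps - 1)
  }
  structure(list(observed_q = observed, null_q = null_q, statistic = tstat,
                 p = p_two, p_greater = p_greater, n_reps = n_reps,
                 seed = seed, reoptimize = reoptimize),
            class = "scn_random_null")
}

#' @export
print.scn_random_null <- function(x, ...) {
  cat(sprintf("Random-network modularity null (%d weight permutations)\n",
              x$n_reps))
  cat(sprintf("  observed Q = %.4f, null Q = %.4f +- %.4f\n", x$observed_q,
              mean(x$null_q), stats::sd(x$null_q)))
  cat(sprintf("  one-sample t-test: p = %.3g (two-sided), p = %.3g ",
              x$p, x$p_greater))
  cat("(one-sided, observed > null)\n")
  invisible(x)
}

#' Build a cohort-to-measures network statistic
#'
#' Returns a deterministic function `cohort -> named numeric vector` that
#' runs the full network construction (residualize as a single population,
#' correlate, weight policy, normalization) and evaluates network measures
#' under a fixed reference partition. Such statistics are what
#' [permutation_group_test()] permutes.
#'
#' @param partition fixed reference `scn_partition`.
#' @param measures any of `"modularity"` (component `Q`),
#'   `"module_connectivity"` (components `MC.<s>` and `IMC.<s>.<t>`),
#'   `"node_roles"` (components `MD.<roi>` and `PC.<roi>`).
#' @param policy weight policy (see [apply_weight_policy()]).
#' @param covariates covariates for [residualize()].
#' @param normalize normalize by total weight before measuring (default TRUE).
#' @return a function of one `scn_cohort` argument.
#' @export
network_statistic <- function(partition,
                              measures = c("modularity",
                                           "module_connectivity"),
                              policy = "truncate_negative",
                              covariates = c("global_mean", "age", "sex",
                                             "age_sex"),
                              normalize = TRUE) {
  measures <- match.arg(measures, c("modularity", "module_connectivity",
                                    "node_roles"), several.ok = TRUE)
  force(partition); force(policy); force(covariates); force(normalize)
  function(cohort) {
    res <- residualize_group(thickness_matrix(cohort), cohort$age,
                             as.integer(cohort$sex == "M"), "subset",
                             covariates)
    net <- build_correlation_network(res)
    net <- apply_weight_policy(net, policy)
    if (normalize) net <- normalize_by_total_weight(net)
    p <- match_partition(partition, net$nodes)
    out <- numeric(0)
    if ("modularity" %in% measures)
      out <- c(out, Q = modularity_membership(net$weights, unclass(p)))
    if ("module_connectivity" %in% measures) {
      mc <- module_connectivity(net, p)
      v <- mc$MC
      names(v) <- paste0("MC.", seq_along(v))
      out <- c(out, v)
      nm <- length(mc$MC)
      for (s in seq_len(nm - 1)) {
        for (t in seq(s + 1, nm)) {
          out <- c(out, stats::setNames(mc$IMC[s, t],
                                        paste0("IMC.", s, ".", t)))
        }
      }
    }
    if ("node_roles" %in% measures) {
      nr <- node_roles(net, p)
      out <- c(out, stats::setNames(nr$MD, paste0("MD.", nr$roi)),
               stats::setNames(nr$PC, paste0("PC.", nr$roi)))
    }
    out
  }
}

#' Subject-relabeling permutation test for network measures
#'
#' Tests group differences in any network-level statistic by randomly
#' reassigning subjects to the two groups (preserving the original group
#' sizes), recomputing the statistic for each permuted group, and comparing
#' the observed difference to the permutation distribution. The statistic may
#' be vector-valued (e.g. Q plus all module connectivities at once); p-values
#' are per component, two-tailed.
#'
#' The default p-value uses the add-one convention
#' `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`, which is never zero;
#' `include_observed = FALSE` gives the plain proportion `u / n_perm`.
#'
#' @param cohort_a,cohort_b `scn_cohort`s for the two groups.
#' @param statistic function of one cohort returning a (named) numeric
#'   vector; see [network_statistic()]. Must be finite on every permutation.
#' @param n_perm number of permutations (published practice is 10,000).
#' @param seed RNG seed.
#' @param include_observed use the add-one convention (default TRUE).
#' @return an `scn_permutation`: `observed_diff` (a - b), `null_diffs`
#'   (n_perm x components matrix), `p_value` (per component), `n_perm`,
#'   `seed`.
#' @export
permutation_group_test <- function(cohort_a, cohort_b, statistic,
                                   n_perm = 10000, seed = 1L,
                                   include_observed = TRUE) {
  stat_a <- statistic(cohort_a)
  stat_b <- statistic(cohort_b)
  observed <- stat_a - stat_b
  if (anyNA(observed) || any(!is.finite(observed)))
    stop("statistic is non-finite on the observed groups")

  combined <- combine_cohorts(cohort_a, cohort_b)
  n_a <- nrow(cohort_a)
  n_tot <- nrow(combined)
  null_diffs <- matrix(NA_real_, n_perm, length(observed),
                       dimnames = list(NULL, names(observed)))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      idx <- sample.int(n_tot, n_a)
      d <- statistic(cohort_rows(combined, idx)) -
        statistic(cohort_rows(combined, -idx))
      if (anyNA(d) || any(!is.finite(d)))
        stop("statistic returned a non-finite value at permutation ",
             "replicate ", r)
      null_diffs[r, ] <- d
    }
  })
  exceed <- colSums(abs(null_diffs) >=
                    matrix(abs(observed), n_perm, length(observed),
                           byrow = TRUE))
  p <- if (include_observed) (1 + exceed) / (n_perm + 1) else exceed / n_perm
  structure(list(observed_diff = observed, null_diffs = null_diffs,
                 p_value = p, n_perm = n_perm, seed = seed,
                 include_observed = include_observed),
            class = "scn_permutation")
}

#' @export
print.scn_permutation <- function(x, ...) {
  cat(sprintf("Subject-relabeling permutation test (%d permutations)\n",
              x$n_perm))
  k <- min(length(x$observed_diff), 12L)
  df <- data.frame(diff = round(x$observed_diff[seq_len(k)], 4),
                   p = signif(x$p_value[seq_len(k)], 3))
  print(df)
  if (length(x$observed_diff) > k)
    cat("  ... and", length(x$observed_diff) - k, "more components\n")
  invisible(x)
}

#' Edge-wise Fisher r-to-z comparison of two correlation networks
#'
#' For every region pair, the two groups' Pearson correlations are
#' variance-stabilized with Fisher's transform `z = atanh(r)` and compared
#' with the normal statistic
#' `Z = (z_control - z_case) / sqrt(1/(n_case - 3) + 1/(n_control - 3))`,
#' so that edges whose correlation is *reduced* in the case group get
#' positive Z. Two-tailed normal p-values are corrected across all K edges
#' with Benjamini-Hochberg FDR at level `q`. Edges with |r| = 1 in either
#' group have infinite z; they are flagged `degenerate`, excluded from the
#' FDR family, and reported with a warning.
#'
#' @param net_case,net_control `scn_network`s carrying signed correlations
#'   and subject counts (> 3).
#' @param q FDR level (default 0.01).
#' @param partition optional reference `scn_partition`; adds the module of
#'   each endpoint to the table.
#' @return an `scn_edge_comparison` data.frame with one row per distinct
#'   edge: `roi_a`, `roi_b`, `r_case`, `r_control`, `z_case`, `z_control`,
#'   `Z`, `p`, `fdr_significant`, `degenerate` (and `module_a`/`module_b`).
#' @export
fisher_edge_comparison <- function(net_case, net_control, q = 0.01,
                                   partition = NULL) {
  stopifnot(inherits(net_case, "scn_network"),
            inherits(net_control, "scn_network"))
  if (!identical(net_case$nodes, net_control$nodes))
    stop("networks are over different node sets: ",
         paste(utils::head(c(setdiff(net_case$nodes, net_control$nodes),
                             setdiff(net_control$nodes, net_case$nodes)), 5),
               collapse = ", "))
  n1 <- net_case$n_subjects
  n2 <- net_control$n_subjects
  if (is.na(n1) || is.na(n2) || n1 <= 3 || n2 <= 3)
    stop("both networks need n_subjects > 3 for the Fisher standard error")

  ut <- upper.tri(net_case$signed_r)
  idx <- which(ut, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  r1 <- net_case$signed_r[idx]
  r2 <- net_control$signed_r[idx]
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  Z <- (z2 - z1) / se
  p <- 2 * stats::pnorm(-abs(Z))
  degenerate <- !is.finite(z1) | !is.finite(z2)
  if (any(degenerate))
    warning(sum(degenerate), " edge(s) with |r| = 1 excluded from the FDR ",
            "family (infinite Fisher z)")
  fdr <- rep(NA, length(p))
  fdr[!degenerate] <- bh_fdr(p[!degenerate], q)

  out <- data.frame(roi_a = net_case$nodes[idx[, 1]],
                    roi_b = net_case$nodes[idx[, 2]],
                    r_case = r1, r_control = r2,
                    z_case = z1, z_control = z2,
                    Z = Z, p = p, fdr_significant = fdr,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    pp <- match_partition(partition, net_case$nodes)
    out$module_a <- unclass(pp)[idx[, 1]]
    out$module_b <- unclass(pp)[idx[, 2]]
  }
  attr(out, "q") <- q
  attr(out, "n_subjects") <- c(case = n1, control = n2)
  class(out) <- c("scn_edge_comparison", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR rejections
#'
#' Rejects all hypotheses with `p <= p_(i*)` where
#' `i* = max{ i : p_(i) <= i q / m }`, controlling the expected proportion of
#' false rejections among the rejections at level `q`.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical vector of rejection flags (empty input gives an empty
#'   vector).
#' @export
bh_fdr <- function(p_values, q = 0.01) {
  if (!length(p_values)) return(logical(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH") <= q
}
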