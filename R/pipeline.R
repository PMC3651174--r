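#' Fit the full two-group modular-organization comparison
#'
#' The end-to-end analysis: per-group residualization, correlation networks,
#' weight policy and total-weight normalization, modularity optimization on
#' the control network (whose partition is taken as the baseline modular
#' organization), imposition of that partition on the case network, and the
#' three inferential procedures -- a weight-permutation null for each group's
#' modularity, a subject-relabeling permutation test for Q, module
#' connectivities (MC/IMC) and node roles (MD/PC) under the baseline
#' partition, and the edge-wise Fisher r-to-z comparison with BH-FDR.
#' All group differences are oriented case minus control.
#'
#' @param cohort an `scn_cohort` containing both groups.
#' @param case,control group labels in `cohort$group`.
#' @param policy weight policy for modularity-facing weights.
#' @param covariates covariates removed by [residualize()].
#' @param n_restarts optimizer restarts.
#' @param n_perm subject-relabeling permutations.
#' @param n_random weight-permutation null replicates.
#' @param reoptimize_null re-optimize the partition inside each null
#'   replicate instead of re-scoring the fixed partition (default FALSE).
#' @param q FDR level for the edge comparison.
#' @param seed master seed; all stages draw reproducible sub-seeds from it.
#' @param include_node_roles also permutation-test per-node MD and PC
#'   (default TRUE).
#' @return an `scn_compare` object; see [summary.scn_compare()].
#' @export
scn_compare <- function(cohort, case = "autism", control = "control",
                        policy = c("truncate_negative", "absolute"),
                        covariates = c("global_mean", "age", "sex",
                                       "age_sex"),
                        n_restarts = 100, n_perm = 10000, n_random = 10000,
                        reoptimize_null = FALSE, q = 0.01, seed = 1L,
                        include_node_roles = TRUE) {
  stopifnot(inherits(cohort, "scn_cohort"))
  policy <- match.arg(policy)
  for (g in c(case, control)) {
    if (!any(cohort$group == g)) stop("no subjects with group label '", g, "'")
  }
  seeds <- derive_seeds(seed, 4)
  cohort_case <- cohort_rows(cohort, cohort$group == case)
  cohort_control <- cohort_rows(cohort, cohort$group == control)

  res <- run_stage("residualize",
                   residualize(combine_cohorts(cohort_case, cohort_control),
                               covariates = covariates))
  nets <- run_stage("network", lapply(res[c(case, control)], function(r) {
    normalize_by_total_weight(
      apply_weight_policy(build_correlation_network(r), policy))
  }))
  net_case <- nets[[case]]
  net_control <- nets[[control]]

  fit_control <- run_stage("optimize",
                           optimize_partition(net_control,
                                              n_restarts = n_restarts,
                                              seed = seeds[1]))
  fit_case <- run_stage("optimize",
                        optimize_partition(net_case,
                                           n_restarts = n_restarts,
                                           seed = seeds[1]))
  baseline <- fit_control$partition

  measures <- c("modularity", "module_connectivity",
                if (include_node_roles) "node_roles")
  statistic <- network_statistic(baseline, measures = measures,
                                 policy = policy, covariates = covariates)
  observed_case <- statistic(cohort_case)
  observed_control <- statistic(cohort_control)

  permutation <- run_stage("permutation",
                           permutation_group_test(cohort_case, cohort_control,
                                                  statistic,
                                                  n_perm = n_perm,
                                                  seed = seeds[2]))
  random_null <- run_stage("random_null", list(
    case = random_modularity_null(net_case, fit_case$partition,
                                  n_reps = n_random, seed = seeds[3],
                                  reoptimize = reoptimize_null,
                                  n_restarts = n_restarts),
    control = random_modularity_null(net_control, baseline,
                                     n_reps = n_random, seed = seeds[4],
                                     reoptimize = reoptimize_null,
                                     n_restarts = n_restarts)
  ))
  edges <- run_stage("edge_comparison",
                     fisher_edge_comparison(net_case, net_control, q = q,
                                            partition = baseline))

  structure(list(
    networks = stats::setNames(list(net_case, net_control),
                               c("case", "control")),
    baseline_partition = baseline,
    case_partition = fit_case$partition,
    Q_optimal = c(case = fit_case$Q, control = fit_control$Q),
    n_modules = c(case = fit_case$n_modules, control = fit_control$n_modules),
    observed = list(case = observed_case, control = observed_control,
                    diff = observed_case - observed_control),
    permutation = permutation,
    random_null = random_null,
    edges = edges,
    settings = list(case = case, control = control, policy = policy,
                    covariates = covariates, n_restarts = n_restarts,
                    n_perm = n_perm, n_random = n_random,
                    reoptimize_null = reoptimize_null, q = q, seed = seed,
                    include_node_roles = include_node_roles,
                    n_subjects = c(case = nrow(cohort_case),
                                   control = nrow(cohort_control)))),
    class = "scn_compare")
}

#' @export
print.scn_compare <- function(x, ...) {
  s <- x$settings
  cat("Structural covariance network comparison (case - control)\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d); policy %s\n",
              s$case, s$n_subjects["case"], s$control,
              s$n_subjects["control"], s$policy))
  cat(sprintf("  modules: %d (case), %d (control); baseline = control\n",
              x$n_modules["case"], x$n_modules["control"]))
  dQ <- x$observed$diff["Q"]
  cat(sprintf("  Q under baseline partition: case %.4f, control %.4f (diff %+.4f, perm p = %.3g)\n",
              x$observed$case["Q"], x$observed$control["Q"], dQ,
              x$permutation$p_value["Q"]))
  nsig <- sum(x$edges$fdr_significant, na.rm = TRUE)
  cat(sprintf("  edges altered at FDR q = %g: %d of %d (%d decreased, %d increased in case)\n",
              s$q, nsig, nrow(x$edges),
              sum(x$edges$fdr_significant & x$edges$Z > 0, na.rm = TRUE),
              sum(x$edges$fdr_significant & x$edges$Z < 0, na.rm = TRUE)))
  invisible(x)
}

#' Summarize a network comparison
#'
#' @param object an `scn_compare`.
#' @param ... unused.
#' @return a list of data.frames: `modularity` (Q per group, permutation and
#'   random-null p-values), `modules` (per-module MC difference and p),
#'   `module_pairs` (IMC difference and p), `nodes` (per-node MD/PC
#'   differences and p, if computed), `edges` (FDR-significant edges).
#' @export
summary.scn_compare <- function(object, ...) {
  x <- object
  p <- x$permutation$p_value
  d <- x$observed$diff
  nm <- n_modules(x$baseline_partition)

  modularity <- data.frame(
    measure = "Q",
    case = unname(x$observed$case["Q"]),
    control = unname(x$observed$control["Q"]),
    diff = unname(d["Q"]),
    p_perm = unname(p["Q"]),
    p_random_null_case = x$random_null$case$p,
    p_random_null_control = x$random_null$control$p
  )
  mods <- paste0("MC.", seq_len(nm))
  modules <- data.frame(
    module = seq_len(nm),
    size = tabulate(unclass(x$baseline_partition), nm),
    MC_case = unname(x$observed$case[mods]),
    MC_control = unname(x$observed$control[mods]),
    diff = unname(d[mods]),
    p_perm = unname(p[mods])
  )
  pairs <- t(utils::combn(nm, 2))
  imc <- paste0("IMC.", pairs[, 1], ".", pairs[, 2])
  module_pairs <- data.frame(
    module_s = pairs[, 1], module_t = pairs[, 2],
    IMC_case = unname(x$observed$case[imc]),
    IMC_control = unname(x$observed$control[imc]),
    diff = unname(d[imc]),
    p_perm = unname(p[imc])
  )
  nodes <- NULL
  if (x$settings$include_node_roles) {
    rois <- names(x$baseline_partition)
    md <- paste0("MD.", rois)
    pc <- paste0("PC.", rois)
    nodes <- data.frame(
      roi = rois, module = unclass(x$baseline_partition),
      MD_diff = unname(d[md]), MD_p = unname(p[md]),
      PC_diff = unname(d[pc]), PC_p = unname(p[pc]),
      stringsAsFactors = FALSE
    )
    nodes$MD_fdr <- bh_fdr(nodes$MD_p, x$settings$q)
    nodes$PC_fdr <- bh_fdr(nodes$PC_p, x$settings$q)
  }
  edges <- x$edges[which(x$edges$fdr_significant), , drop = FALSE]
  out <- list(modularity = modularity, modules = modules,
              module_pairs = module_pairs, nodes = nodes, edges = edges,
              settings = x$settings)
  class(out) <- "summary.scn_compare"
  out
}

#' @export
print.summary.scn_compare <- function(x, ...) {
  cat("== Modularity (baseline = control partition) ==\n")
  print(x$modularity, row.names = FALSE, digits = 4)
  cat("\n== Intra-module connectivity (case - control) ==\n")
  print(x$modules, row.names = FALSE, digits = 4)
  cat("\n== Inter-module connectivity (case - control) ==\n")
  print(x$module_pairs, row.names = FALSE, digits = 4)
  if (!is.null(x$nodes)) {
    sig <- x$nodes[x$nodes$MD_fdr | x$nodes$PC_fdr, , drop = FALSE]
    cat("\n== Node roles altered at FDR q =", x$settings$q, "==\n")
    if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
    else cat("  none\n")
  }
  cat("\n== Edges altered at FDR q =", x$settings$q, "==\n")
  if (nrow(x$edges)) {
    print(x$edges[c("roi_a", "roi_b", "r_case", "r_control", "Z",
                    "module_a", "module_b")],
          row.names = FALSE, digits = 3)
  } else cat("  none\n")
  invisible(x)
}

#' Plot module connectivity differences
#'
#' Bar chart of case-minus-control differences in intra-module (MC) and
#' inter-module (IMC) connectivity under the baseline partition, with
#' permutation p-values printed above the bars.
#'
#' @param x an `scn_compare`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.scn_compare <- function(x, ...) {
  s <- summary(x)
  vals <- c(s$modules$diff, s$module_pairs$diff)
  labs <- c(paste0("MC ", s$modules$module),
            paste0("IMC ", s$module_pairs$module_s, "-",
                   s$module_pairs$module_t))
  pv <- c(s$modules$p_perm, s$module_pairs$p_perm)
  bp <- graphics::barplot(vals, names.arg = labs,
                          ylab = "case - control connectivity",
                          col = ifelse(vals > 0, "firebrick", "steelblue"),
                          ...)
  graphics::text(bp, vals, labels = sprintf("p=%.3g", pv),
                 pos = ifelse(vals >= 0, 3, 1), cex = 0.8, xpd = NA)
  invisible(x)
}

#' Published altered inter-regional correlations (worked-example inputs)
#'
#' Region pairs with significantly altered cortical-thickness correlations
#' reported in a published study of 49 autistic and 51 typically developing
#' children, with each group's Pearson r and the published Fisher-comparison
#' Z score (sign: positive = reduced correlation in autism). Useful as exact
#' desk-scale inputs for [fisher_edge_comparison()] arithmetic.
#'
#' @return data.frame: `roi_a`, `roi_b`, `r_autism`, `r_control`,
#'   `z_published`, `n_autism`, `n_control`.
#' @export
published_edge_correlations <- function() {
  path <- system.file("extdata", "published_edge_correlations.csv",
                      package = "scnmod", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$n_autism <- 49L
  out$n_control <- 51L
  out
}
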