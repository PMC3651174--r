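#' Remove covariate effects from regional thickness
#'
#' Before correlating regions across subjects, each region's thickness is
#' replaced by the residuals of an ordinary least squares regression on an
#' intercept, the subject's global mean thickness (mean over all regions),
#' age, sex (M = 1, F = 0) and the age-by-sex interaction. Fitting is done
#' separately within each group by default, because the covariance networks
#' are built per group; `per_group = FALSE` pools all subjects in one design.
#'
#' If the design is rank-deficient (e.g. a single-sex group makes the
#' interaction collinear with age), the offending column(s) are dropped with
#' a warning rather than failing.
#'
#' @param cohort an `scn_cohort` (may contain several groups).
#' @param per_group fit one regression per group (default) or one pooled fit.
#' @param covariates which covariates enter the design (besides the
#'   intercept): any subset of `"global_mean"`, `"age"`, `"sex"`,
#'   `"age_sex"`. Note that the global-mean covariate deliberately removes
#'   shared signal and therefore alters the inter-regional correlation
#'   structure, in the manner of global signal regression.
#' @return a named list (one element per group, or `"pooled"`) of
#'   `scn_residuals` objects: each has `values` (subjects x ROI residual
#'   matrix, mm), `group`, `coefficients` (covariates x ROI), and `dropped`
#'   (names of any covariates removed for collinearity).
#' @examples
#' spec <- cohort_spec(n_control = 30, seed = 7)
#' res <- residualize(generate_cohort(spec))
#' round(max(abs(colMeans(res$control$values))), 12)  # columns are centered
#' @export
residualize <- function(cohort, per_group = TRUE,
                        covariates = c("global_mean", "age", "sex",
                                       "age_sex")) {
  stopifnot(inherits(cohort, "scn_cohort"))
  covariates <- match.arg(covariates, several.ok = TRUE)
  if (per_group) {
    groups <- unique(cohort$group)
    out <- lapply(groups, function(g) {
      sub <- cohort_rows(cohort, cohort$group == g)
      residualize_group(thickness_matrix(sub), sub$age,
                        as.integer(sub$sex == "M"), g, covariates)
    })
    names(out) <- groups
  } else {
    out <- list(pooled = residualize_group(
      thickness_matrix(cohort), cohort$age,
      as.integer(cohort$sex == "M"), "pooled", covariates))
  }
  out
}

# Internal: OLS residuals of Y (subjects x ROI) on the covariate design.
residualize_group <- function(Y, age, sex01, group, covariates) {
  n <- nrow(Y)
  X <- cbind(intercept = rep(1, n))
  if ("global_mean" %in% covariates) X <- cbind(X, global_mean = rowMeans(Y))
  if ("age" %in% covariates) X <- cbind(X, age = age)
  if ("sex" %in% covariates) X <- cbind(X, sex = sex01)
  if ("age_sex" %in% covariates) X <- cbind(X, age_sex = age * sex01)
  if (n < ncol(X) + 2)
    stop("group '", group, "' has ", n, " subjects; need at least ",
         ncol(X) + 2, " to fit ", ncol(X), " covariates")

  dropped <- character(0)
  # base qr's rank test is column-relative, so an (almost) all-zero column
  # (e.g. the global mean of already-residualized data) slips through and the
  # fit would project onto numerical noise; drop such columns explicitly
  norms <- sqrt(colSums(X^2))
  tiny <- norms < 1e-10 * sqrt(n)
  if (any(tiny)) {
    dropped <- colnames(X)[tiny]
    warning("group '", group, "': dropping collinear covariate(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !tiny, drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    newly <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    dropped <- c(dropped, newly)
    warning("group '", group, "': dropping collinear covariate(s): ",
            paste(newly, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    qx <- qr(X)
  }
  values <- qr.resid(qx, Y)
  coefs <- qr.coef(qx, Y)
  rownames(coefs) <- colnames(X)
  structure(list(values = values, group = group, n_subjects = n,
                 coefficients = coefs, covariates = colnames(X),
                 dropped = dropped),
            class = "scn_residuals")
}

#' @export
print.scn_residuals <- function(x, ...) {
  cat("Residualized thickness (group '", x$group, "'): ", nrow(x$values),
      " subjects x ", ncol(x$values), " ROIs\n", sep = "")
  cat("  design:", paste(x$covariates, collapse = " + "), "\n")
  if (length(x$dropped))
    cat("  dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Export residuals as CSV
#'
#' @param residuals an `scn_residuals`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_residuals <- function(residuals, path) {
  stopifnot(inherits(residuals, "scn_residuals"))
  df <- data.frame(subject_id = rownames(residuals$values),
                   residuals$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
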