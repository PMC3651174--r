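#' Specify a synthetic thickness cohort
#'
#' Defines a generative model for cortical-thickness cohorts with the
#' statistical structure the downstream analysis assumes: a planted modular
#' (block) inter-regional correlation structure, linear age and sex effects,
#' and optional group-specific block perturbations. Defaults emulate a
#' two-group pediatric study: 49 cases + 51 controls, 68 regions, mean
#' thickness 2.5 mm, ages 6-15 years with a negative linear thickness-age
#' slope, and a roughly 4:1 male:female ratio.
#'
#' The stochastic part of each region's thickness has total standard
#' deviation `noise_sd / sqrt(1 - r_within)` mm, of which `noise_sd` is the
#' idiosyncratic (region-specific) component; the remainder is shared block
#' variance, so the generated inter-regional correlations equal `r_within`
#' within planted modules and `r_between` elsewhere. The defaults give a
#' total regional SD of about 0.5 mm.
#'
#' @param n_autism,n_control subjects per group (each must be >= 4; Fisher
#'   z-based edge comparisons need n > 3).
#' @param n_rois number of regions (default 68, the built-in atlas).
#' @param planted_partition ground-truth module assignment
#'   ([partition()] or plain label vector of length `n_rois`). Default: three
#'   blocks of 13, 28 and 27 regions when `n_rois` is 68, near-equal thirds
#'   otherwise.
#' @param r_within,r_between target Pearson correlations within and between
#'   planted modules; requires `0 <= |r_between| < r_within <= 1`.
#' @param age_range,age_mean,age_sd age distribution in years: normal with
#'   `age_mean`/`age_sd`, truncated to `age_range` by rejection.
#' @param age_slope thickness-age effect in mm/year (negative by default:
#'   cortical thinning over childhood).
#' @param sex_effect additive male-minus-female thickness offset in mm.
#' @param p_male probability a subject is male (default 0.8, matching the
#'   male-skewed composition typical of autism cohorts).
#' @param group_effects list of block perturbations, each a list with
#'   `group` (label it applies to), `delta` (added to the target correlation)
#'   and either `module = s` (within-block) or `modules = c(s, t)`
#'   (between-block). The implied correlation matrix must remain positive
#'   semi-definite; the generator verifies this and rejects otherwise.
#' @param noise_sd idiosyncratic per-region noise SD in mm. `noise_sd = 0`
#'   with `r_within = 1` gives perfectly collinear regions within modules.
#' @param base_thickness mean thickness in mm at the mean age.
#' @param clip_range thickness values are clipped to this range (mm) after
#'   all effects; the realized clipping rate is recorded and should stay
#'   below 1% under default parameters.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return an object of class `scn_cohort_spec` (a validated list).
#' @seealso [generate_cohort()], [make_autism_like_pair()]
#' @export
cohort_spec <- function(n_autism = 49, n_control = 51, n_rois = 68,
                        planted_partition = NULL,
                        r_within = 0.5, r_between = 0.1,
                        age_range = c(6, 15), age_mean = 9.65, age_sd = 2.15,
                        age_slope = -0.03, sex_effect = 0.02, p_male = 0.8,
                        group_effects = list(),
                        noise_sd = 0.35, base_thickness = 2.5,
                        clip_range = c(0, 5), seed = 1L) {
  if (n_autism < 4 || n_control < 4)
    stop("n_subjects must be at least 4 per group (Fisher SE needs n > 3)")
  if (is.null(planted_partition)) {
    sizes <- if (n_rois == 68) c(13L, 28L, 27L) else {
      base <- n_rois %/% 3L
      c(base, base, n_rois - 2L * base)
    }
    planted_partition <- rep(seq_along(sizes), times = sizes)
  }
  nodes <- if (n_rois == 68) dk_atlas()$abbreviation
           else sprintf("ROI%02d", seq_len(n_rois))
  planted_partition <- partition(planted_partition, nodes = nodes)
  if (length(planted_partition) != n_rois)
    stop("planted_partition must assign all ", n_rois, " regions")
  if (r_within <= 0 || r_within > 1) stop("r_within must be in (0, 1]")
  if (abs(r_between) >= r_within)
    stop("|r_between| must be smaller than r_within")
  if (r_within == 1 && noise_sd != 0)
    stop("r_within = 1 (collinear modules) requires noise_sd = 0")
  for (ge in group_effects) {
    if (is.null(ge$group) || is.null(ge$delta) ||
        (is.null(ge$module) && is.null(ge$modules)))
      stop("each group effect needs 'group', 'delta' and 'module'/'modules'")
  }
  spec <- list(n_autism = n_autism, n_control = n_control, n_rois = n_rois,
               planted_partition = planted_partition,
               r_within = r_within, r_between = r_between,
               age_range = age_range, age_mean = age_mean, age_sd = age_sd,
               age_slope = age_slope, sex_effect = sex_effect,
               p_male = p_male, group_effects = group_effects,
               noise_sd = noise_sd, base_thickness = base_thickness,
               clip_range = clip_range, seed = as.integer(seed))
  class(spec) <- "scn_cohort_spec"
  # fail fast if any group's implied correlation matrix is not PSD
  for (g in unique(c("control", vapply(group_effects, `[[`, "", "group"))))
    target_correlation(spec, g)
  spec
}

#' @export
print.scn_cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_autism, "+", x$n_control, "subjects,",
      x$n_rois, "ROIs in", n_modules(x$planted_partition),
      "planted modules\n")
  cat(sprintf("  r_within = %.2f, r_between = %.2f, noise_sd = %.2f mm\n",
              x$r_within, x$r_between, x$noise_sd))
  if (length(x$group_effects))
    cat("  group effects:", length(x$group_effects), "block perturbation(s)\n")
  invisible(x)
}

# Internal: block target correlation matrix for one group; verifies PSD.
target_correlation <- function(spec, group) {
  m <- unclass(spec$planted_partition)
  n <- spec$n_rois
  C <- matrix(spec$r_between, n, n)
  for (s in seq_len(attr(spec$planted_partition, "n_modules"))) {
    ids <- which(m == s)
    C[ids, ids] <- spec$r_within
  }
  for (ge in spec$group_effects) {
    if (!identical(as.character(ge$group), as.character(group))) next
    if (!is.null(ge$module)) {
      ids <- which(m == ge$module)
      if (!length(ids)) stop("group effect names unknown module ", ge$module)
      C[ids, ids] <- C[ids, ids] + ge$delta
    } else {
      i <- which(m == ge$modules[1]); j <- which(m == ge$modules[2])
      if (!length(i) || !length(j))
        stop("group effect names unknown module pair")
      C[i, j] <- C[i, j] + ge$delta
      C[j, i] <- C[j, i] + ge$delta
    }
  }
  diag(C) <- 1
  if (any(abs(C) > 1))
    stop("perturbed target correlations leave [-1, 1]; not a valid ",
         "correlation matrix")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied correlation matrix is not positive semi-definite ",
         sprintf("(min eigenvalue %.3g); ", min(ev)),
         "reduce |r_between| or the group-effect deltas")
  dimnames(C) <- list(names(spec$planted_partition),
                      names(spec$planted_partition))
  C
}

# Internal atlas stand-in for non-68-region synthetic cohorts.
synthetic_atlas <- function(nodes) {
  data.frame(index = seq_along(nodes), abbreviation = nodes,
             name = nodes, hemisphere = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic thickness cohort
#'
#' Draws one cohort from a [cohort_spec()]: ages from a truncated normal,
#' sex from a Bernoulli(`p_male`), and regional thickness as
#' `base_thickness + age_slope * (age - age_mean) + sex_effect * male +`
#' a zero-mean Gaussian vector with the block correlation structure implied
#' by the spec (and any `group_effects` matching `group`), scaled to the
#' spec's total SD and clipped to `clip_range`. Identical `spec` + `seed`
#' give a bit-identical cohort.
#'
#' @param spec an `scn_cohort_spec`.
#' @param group group label for the generated subjects; group effects whose
#'   `group` matches are applied. `"autism"` uses `n_autism` subjects,
#'   anything else `n_control`, unless `n` overrides.
#' @param n optional subject count override.
#' @param seed RNG seed (default `spec$seed`).
#' @return an `scn_cohort` with attributes `planted_partition` and
#'   `clip_rate`.
#' @examples
#' spec <- cohort_spec(n_control = 20, seed = 42)
#' cohort <- generate_cohort(spec, group = "control")
#' @export
generate_cohort <- function(spec, group = "control", n = NULL,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "scn_cohort_spec"))
  if (is.null(n))
    n <- if (identical(group, "autism")) spec$n_autism else spec$n_control
  if (n < 4) stop("n_subjects must be at least 4 (Fisher SE needs n > 3)")

  C <- target_correlation(spec, group)
  eig <- eigen(C, symmetric = TRUE)
  A <- sqrt(pmax(eig$values, 0)) * t(eig$vectors)  # A'A = C
  sigma <- if (spec$r_within < 1) spec$noise_sd / sqrt(1 - spec$r_within)
           else 0.5

  with_seed(seed, {
    age <- numeric(0)
    while (length(age) < n) {
      draw <- stats::rnorm(n, spec$age_mean, spec$age_sd)
      age <- c(age, draw[draw >= spec$age_range[1] &
                         draw <= spec$age_range[2]])
    }
    age <- age[seq_len(n)]
    male <- stats::rbinom(n, 1L, spec$p_male)
    Z <- matrix(stats::rnorm(n * spec$n_rois), n, spec$n_rois)
  })
  X <- Z %*% A
  thick <- spec$base_thickness +
    spec$age_slope * (age - spec$age_mean) +
    spec$sex_effect * male +
    sigma * X

  lo <- spec$clip_range[1]; hi <- spec$clip_range[2]
  clipped <- sum(thick < lo | thick > hi)
  clip_rate <- clipped / length(thick)
  if (clip_rate > 0.01)
    warning(sprintf("%.1f%% of thickness values clipped to [%g, %g] mm",
                    100 * clip_rate, lo, hi))
  thick <- pmin(pmax(thick, lo), hi)
  colnames(thick) <- names(spec$planted_partition)

  df <- data.frame(subject_id = sprintf("%s_%04d", group, seq_len(n)),
                   group = group, age = age,
                   sex = ifelse(male == 1L, "M", "F"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(thick))
  atlas <- if (spec$n_rois == 68) dk_atlas()
           else synthetic_atlas(names(spec$planted_partition))
  cohort <- as_scn_cohort(df, atlas = atlas)
  attr(cohort, "planted_partition") <- spec$planted_partition
  attr(cohort, "clip_rate") <- clip_rate
  cohort
}

#' @rdname generate_cohort
#' @param object an `scn_cohort_spec`.
#' @param nsim number of cohorts to simulate.
#' @param ... unused.
#' @return for `simulate()`: a list of `nsim` cohorts drawn with
#'   independent derived seeds.
#' @export
simulate.scn_cohort_spec <- function(object, nsim = 1, seed = object$seed,
                                     group = "control", n = NULL, ...) {
  seeds <- derive_seeds(seed, nsim)
  lapply(seeds, function(s) generate_cohort(object, group = group,
                                            n = n, seed = s))
}

#' Generate a matched case/control cohort pair with altered modules
#'
#' Convenience fixture mirroring the headline group-difference pattern:
#' relative to controls, the case group's within-module correlation is
#' lowered in modules 1 and 2 and raised in module 3 (deltas -0.3/-0.3/+0.3
#' by default, supplied via `spec$group_effects` if present). The two cohorts
#' are drawn with independent sub-seeds and matched covariate distributions.
#'
#' @param spec an `scn_cohort_spec`. If it carries no `group_effects`, the
#'   default three-module perturbation above is applied to group `"autism"`.
#' @param seed master seed (default `spec$seed`).
#' @return list with elements `case` and `control` (both `scn_cohort`).
#' @export
make_autism_like_pair <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scn_cohort_spec"))
  if (!length(spec$group_effects)) {
    if (n_modules(spec$planted_partition) < 3)
      stop("default perturbations need at least 3 planted modules")
    spec$group_effects <- list(
      list(group = "autism", module = 1, delta = -0.3),
      list(group = "autism", module = 2, delta = -0.3),
      list(group = "autism", module = 3, delta = +0.3)
    )
    target_correlation(spec, "autism")  # re-verify PSD with the defaults
  }
  seeds <- derive_seeds(seed, 2)
  list(case = generate_cohort(spec, group = "autism", seed = seeds[1]),
       control = generate_cohort(spec, group = "control", seed = seeds[2]))
}

#' Stack cohorts into one table
#'
#' @param ... `scn_cohort` objects sharing the same ROI set.
#' @return a single `scn_cohort`.
#' @export
combine_cohorts <- function(...) {
  parts <- list(...)
  rois <- attr(parts[[1]], "roi")
  for (p in parts) {
    if (!identical(attr(p, "roi"), rois))
      stop("cohorts have different ROI sets")
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "roi") <- rois
  class(out) <- c("scn_cohort", "data.frame")
  out
}

#' Serialize / restore a cohort spec
#'
#' Writes the full generative specification (including the planted partition
#' and group effects) as YAML or JSON, and reads it back so that a simulation
#' is reproducible from the file plus a seed alone.
#'
#' @param spec an `scn_cohort_spec`.
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `write_cohort_spec()` returns the path invisibly;
#'   `read_cohort_spec()` returns the restored `scn_cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scn_cohort_spec"))
  x <- unclass(spec)
  x$planted_partition <- list(
    nodes = names(spec$planted_partition),
    module = as.integer(unclass(spec$planted_partition))
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- partition(x$planted_partition$module,
                  nodes = x$planted_partition$nodes)
  ge <- x$group_effects
  if (is.data.frame(ge)) {  # jsonlite simplification
    ge <- lapply(seq_len(nrow(ge)), function(i) as.list(ge[i, ]))
  }
  ge <- lapply(ge, function(e) e[!vapply(e, function(v)
    all(is.na(unlist(v))), TRUE)])
  cohort_spec(
    n_autism = x$n_autism, n_control = x$n_control, n_rois = x$n_rois,
    planted_partition = pp, r_within = x$r_within, r_between = x$r_between,
    age_range = unlist(x$age_range), age_mean = x$age_mean, age_sd = x$age_sd,
    age_slope = x$age_slope, sex_effect = x$sex_effect, p_male = x$p_male,
    group_effects = if (length(ge)) ge else list(),
    noise_sd = x$noise_sd, base_thickness = x$base_thickness,
    clip_range = unlist(x$clip_range), seed = x$seed
  )
}
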