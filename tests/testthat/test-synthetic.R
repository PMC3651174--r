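test_that("identical spec and seed give a bit-identical cohort", {
  spec <- cohort_spec(n_control = 12, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(spec, seed = 100)))
})

test_that("noiseless collinear spec makes modules perfectly correlated", {
  spec <- cohort_spec(n_control = 10, r_within = 1, r_between = 0.2,
                      noise_sd = 0, age_slope = 0, sex_effect = 0, seed = 3)
  cohort <- generate_cohort(spec)
  Y <- as.matrix(as.data.frame(cohort)[attr(cohort, "roi")])
  pp <- unclass(attr(cohort, "planted_partition"))
  ids <- which(pp == 1)
  R <- stats::cor(Y[, ids])
  expect_equal(max(abs(R - 1)), 0, tolerance = 1e-10)
})

test_that("empirical correlations match the planted targets at n = 200", {
  spec <- cohort_spec(n_control = 200, r_within = 0.6, r_between = 0,
                      age_slope = 0, sex_effect = 0, seed = 21)
  cohort <- generate_cohort(spec)
  Y <- as.matrix(as.data.frame(cohort)[attr(cohort, "roi")])
  pp <- unclass(attr(cohort, "planted_partition"))
  R <- stats::cor(Y)
  same <- outer(pp, pp, "==") & upper.tri(R)
  diff <- outer(pp, pp, "!=") & upper.tri(R)
  expect_gt(mean(R[same]), 0.55)
  expect_lt(mean(R[same]), 0.65)
  expect_gt(mean(R[diff]), -0.05)
  expect_lt(mean(R[diff]), 0.05)
})

test_that("planted correlations converge to the targets at n = 2000", {
  spec <- cohort_spec(n_control = 2000, r_within = 0.5, r_between = 0.1,
                      age_slope = 0, sex_effect = 0, seed = 8)
  cohort <- generate_cohort(spec)
  Y <- as.matrix(as.data.frame(cohort)[attr(cohort, "roi")])
  pp <- unclass(attr(cohort, "planted_partition"))
  R <- stats::cor(Y)
  expect_equal(mean(R[outer(pp, pp, "==") & upper.tri(R)]), 0.5,
               tolerance = 0.02 / 0.5)
  expect_equal(mean(R[outer(pp, pp, "!=") & upper.tri(R)]), 0.1,
               tolerance = 0.02 / 0.1)
})

test_that("invalid parameterizations are rejected", {
  expect_error(cohort_spec(r_within = 0.3, r_between = 0.4), "r_between")
  expect_error(cohort_spec(n_control = 3), "at least 4")
  expect_error(cohort_spec(r_within = 1, noise_sd = 0.2), "noise_sd = 0")
  # a large negative between-block correlation is not positive semi-definite
  expect_error(cohort_spec(r_within = 0.9, r_between = -0.5),
               "positive semi-definite")
  # a perturbation pushing a block past r = 1 is rejected
  expect_error(
    cohort_spec(group_effects = list(
      list(group = "autism", module = 1, delta = 0.6))),
    "\\[-1, 1\\]")
})

test_that("group effects perturb only the named group's blocks", {
  spec <- cohort_spec(n_autism = 400, n_control = 400, r_within = 0.5,
                      r_between = 0.1, age_slope = 0, sex_effect = 0,
                      group_effects = list(
                        list(group = "autism", module = 1, delta = -0.3)),
                      seed = 13)
  case <- generate_cohort(spec, group = "autism")
  ctrl <- generate_cohort(spec, group = "control", seed = 14)
  pp <- unclass(spec$planted_partition)
  block1 <- function(cohort) {
    Y <- as.matrix(as.data.frame(cohort)[attr(cohort, "roi")])
    R <- stats::cor(Y[, pp == 1])
    mean(R[upper.tri(R)])
  }
  # mean within-block r over 78 dependent edges: ~3 sampling SDs at n = 400
  expect_lt(abs(block1(case) - 0.2), 0.06)
  expect_lt(abs(block1(ctrl) - 0.5), 0.06)
})

test_that("zero-magnitude group effects give distributionally identical cohorts", {
  spec <- cohort_spec(n_autism = 30, n_control = 30,
                      group_effects = list(
                        list(group = "autism", module = 1, delta = 0),
                        list(group = "autism", module = 2, delta = 0),
                        list(group = "autism", module = 3, delta = 0)),
                      seed = 5)
  pair <- make_autism_like_pair(spec)
  # identical target correlation matrices -> same generator inputs
  expect_equal(target_correlation(spec, "autism"),
               target_correlation(spec, "control"))
  expect_equal(nrow(pair$case), 30L)
  expect_equal(nrow(pair$control), 30L)
})

test_that("clipping to the thickness range is logged", {
  spec <- cohort_spec(n_control = 50, seed = 6)
  cohort <- generate_cohort(spec)
  expect_lt(attr(cohort, "clip_rate"), 0.01)
  expect_true(all(as.matrix(as.data.frame(cohort)[attr(cohort, "roi")]) >= 0))
  # absurd noise clips heavily and warns
  loud <- cohort_spec(n_control = 30, noise_sd = 3, seed = 6)
  expect_warning(generate_cohort(loud), "clipped")
})

test_that("cohort specs serialize to YAML and JSON and back", {
  spec <- cohort_spec(n_autism = 10, n_control = 12, r_within = 0.45,
                      group_effects = list(
                        list(group = "autism", module = 2, delta = -0.2)),
                      seed = 77)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cohort_spec(spec, path)
    back <- read_cohort_spec(path)
    expect_identical(generate_cohort(back), generate_cohort(spec))
  }
})

test_that("simulate() draws independent reproducible cohorts", {
  spec <- cohort_spec(n_control = 8, seed = 31)
  sims <- simulate(spec, nsim = 3)
  expect_length(sims, 3L)
  expect_false(identical(sims[[1]], sims[[2]]))
  expect_identical(sims, simulate(spec, nsim = 3))
})
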