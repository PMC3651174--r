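# Internal: evaluate `code` under a private RNG stream seeded with `seed`,
# restoring the caller's .Random.seed afterwards. seed = NULL leaves the
# global stream untouched (and un-restored).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
  }
  force(code)
}

# Internal: draw n sub-seeds (31-bit positive integers) from a master seed,
# so independent stages get independent, reproducible streams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index measuring agreement between two
#' clusterings of the same nodes, corrected for chance. 1 means identical
#' partitions (up to label permutation), 0 is the expected value for
#' independent random partitions.
#'
#' @param x,y cluster label vectors of equal length (any atomic type).
#' @return a single number in (-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must cover the same nodes")
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(sum(tab))
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Internal: stage-labelled error propagation for pipeline orchestration.
run_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      message("stage '", stage, "' warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
}
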