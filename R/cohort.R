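# Internal: read a delimited text table, auto-detecting comma vs tab from the
# header line. Decimal point only; strings kept as character.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Assemble and validate a thickness cohort
#'
#' A cohort is a data.frame with one row per subject: `subject_id`, `group`,
#' `age` (years), `sex` (`"M"`/`"F"`), followed by one mean-thickness column
#' (mm) per atlas region. ROI columns are reordered to canonical atlas order;
#' thickness values must be finite and non-negative.
#'
#' @param df data.frame with the columns above.
#' @param atlas atlas data.frame (default [dk_atlas()]); its `abbreviation`
#'   column defines the required ROI columns and their order.
#' @return an `scn_cohort` (a data.frame with attribute `roi`).
#' @export
as_scn_cohort <- function(df, atlas = dk_atlas()) {
  required <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  rois <- atlas$abbreviation
  miss_roi <- setdiff(rois, names(df))
  if (length(miss_roi))
    stop("cohort is missing ROI column(s): ", paste(miss_roi, collapse = ", "))

  sex <- as.character(df$sex)
  sex[sex %in% c("1", "male")] <- "M"
  sex[sex %in% c("0", "female")] <- "F"
  if (!all(sex %in% c("M", "F")))
    stop("sex must be coded M/F (or 0/1)")
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age)) stop("non-numeric age value(s)")

  thick <- df[rois]
  for (j in seq_along(thick)) {
    v <- suppressWarnings(as.numeric(thick[[j]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop("missing or invalid thickness in column ", rois[j],
           " at row(s): ", paste(bad, collapse = ", "))
    }
    thick[[j]] <- v
  }

  out <- data.frame(subject_id = as.character(df$subject_id),
                    group = as.character(df$group),
                    age = age, sex = sex,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, thick)
  attr(out, "roi") <- rois
  class(out) <- c("scn_cohort", "data.frame")
  out
}

#' Read a cohort table from CSV/TSV
#'
#' The file must have a header `subject_id,group,age,sex` followed by one
#' column per atlas region, named by the atlas abbreviations (any column
#' order; reordered on read). The delimiter is auto-detected (comma or tab).
#'
#' @inheritParams as_scn_cohort
#' @param path file path.
#' @return an `scn_cohort`.
#' @export
read_cohort <- function(path, atlas = dk_atlas()) {
  df <- read_delim_auto(path)
  cohort <- as_scn_cohort(df, atlas = atlas)
  counts <- table(cohort$group)
  message("read ", nrow(cohort), " subjects (",
          paste(names(counts), counts, sep = ": ", collapse = ", "), ")")
  cohort
}

#' Write a cohort table
#'
#' Numeric values are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces them bit-exactly.
#'
#' @param cohort an `scn_cohort`.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "scn_cohort"))
  out <- as.data.frame(cohort)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: thickness block as a subjects x ROI matrix.
thickness_matrix <- function(cohort) {
  rois <- attr(cohort, "roi")
  m <- as.matrix(as.data.frame(cohort)[rois])
  rownames(m) <- cohort$subject_id
  m
}

# Internal: subset rows of a cohort, keeping class and roi attribute.
cohort_rows <- function(cohort, idx) {
  out <- as.data.frame(cohort)[idx, , drop = FALSE]
  attr(out, "roi") <- attr(cohort, "roi")
  class(out) <- c("scn_cohort", "data.frame")
  out
}

#' @export
print.scn_cohort <- function(x, ...) {
  counts <- table(x$group)
  cat("Thickness cohort:", nrow(x), "subjects,",
      length(attr(x, "roi")), "ROIs\n")
  cat("  groups:", paste(names(counts), counts, sep = " = ",
                         collapse = ", "), "\n")
  cat("  age:", sprintf("%.1f-%.1f years", min(x$age), max(x$age)),
      " sex:", sum(x$sex == "M"), "M /", sum(x$sex == "F"), "F\n")
  invisible(x)
}
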