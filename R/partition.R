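#' Construct a node partition
#'
#' A partition assigns every network node to exactly one module. Module
#' labels are canonicalized to contiguous integers 1..N_m in order of first
#' appearance along the node index, so equal partitions always compare
#' identical and module "1" is the module containing the lowest-index node.
#'
#' @param assignment vector of module labels, one per node (any atomic type;
#'   relabelled canonically).
#' @param nodes character vector of node names; defaults to
#'   `names(assignment)`.
#' @return an object of class `scn_partition`: a named integer vector with
#'   attribute `n_modules`.
#' @examples
#' p <- partition(c(2, 2, 7, 7, 2), nodes = letters[1:5])
#' n_modules(p)  # 2; labels canonicalized to 1, 1, 2, 2, 1
#' @export
partition <- function(assignment, nodes = names(assignment)) {
  if (is.null(nodes)) nodes <- as.character(seq_along(assignment))
  if (length(nodes) != length(assignment))
    stop("'nodes' and 'assignment' lengths differ")
  if (anyNA(assignment)) stop("every node must be assigned to a module")
  if (anyDuplicated(nodes)) {
    stop("duplicated node name(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  labels <- match(assignment, unique(assignment))
  out <- as.integer(labels)
  names(out) <- nodes
  attr(out, "n_modules") <- max(out)
  class(out) <- "scn_partition"
  out
}

#' Number of modules in a partition
#' @param x an `scn_partition`.
#' @return integer module count N_m.
#' @export
n_modules <- function(x) {
  stopifnot(inherits(x, "scn_partition"))
  attr(x, "n_modules")
}

#' @export
print.scn_partition <- function(x, ...) {
  sizes <- tabulate(unclass(x), attr(x, "n_modules"))
  cat("Node partition:", length(x), "nodes in", attr(x, "n_modules"),
      "modules (sizes:", paste(sizes, collapse = ", "), ")\n")
  invisible(x)
}

# Internal: align a partition to a node ordering, validating coverage.
match_partition <- function(p, nodes) {
  if (!inherits(p, "scn_partition")) p <- partition(p, nodes = names(p))
  if (!is.null(names(p)) && !is.null(nodes)) {
    idx <- match(nodes, names(p))
    if (anyNA(idx)) {
      stop("partition is missing node(s): ",
           paste(nodes[is.na(idx)], collapse = ", "))
    }
    p <- partition(unclass(p)[idx], nodes = nodes)
  } else if (length(p) != length(nodes)) {
    stop("partition covers ", length(p), " nodes but the network has ",
         length(nodes))
  }
  p
}

#' Read a partition from a two-column table
#'
#' Expects a header `roi,module` (comma- or tab-separated): one row per node
#' with its module id. Module ids must be contiguous integers 1..N_m with no
#' empty module; every node in `nodes` must appear exactly once.
#'
#' @param path file path.
#' @param nodes node names the partition must cover, in canonical order
#'   (default: the built-in 68-region atlas).
#' @return an `scn_partition`.
#' @export
read_partition <- function(path, nodes = dk_atlas()$abbreviation) {
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2L)
    stop("partition file needs two columns (roi, module): ", path)
  roi <- as.character(tab[[1L]])
  mod <- tab[[2L]]
  if (anyDuplicated(roi)) {
    stop("node(s) listed twice: ",
         paste(unique(roi[duplicated(roi)]), collapse = ", "))
  }
  missing <- setdiff(nodes, roi)
  if (length(missing))
    stop("partition file missing node(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(roi, nodes)
  if (length(extra))
    stop("unknown node(s) in partition file: ", paste(extra, collapse = ", "))
  mod <- suppressWarnings(as.integer(mod))
  if (anyNA(mod)) stop("non-integer module id in partition file")
  ids <- sort(unique(mod))
  if (!identical(ids, seq_len(max(mod))))
    stop("module ids must be contiguous 1..N_m with no empty module")
  partition(mod[match(nodes, roi)], nodes = nodes)
}

#' Write a partition to CSV
#'
#' @param p an `scn_partition`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "scn_partition"))
  utils::write.csv(
    data.frame(roi = names(p), module = unclass(p)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
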