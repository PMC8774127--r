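#' Construct a validated structural connectome
#'
#' A connectome is a weighted, undirected brain network: nodes are cortical
#' areas of a parcellation and the edge weight between two areas summarizes
#' the white-matter tracts connecting them (e.g. streamline count normalized
#' by median fiber length).  The object stores the weight matrix together
#' with the assignment of each area to an intrinsic connectivity network.
#'
#' Validation enforces: square matrix, symmetry within `tol` (small
#' asymmetries are averaged away), zero diagonal (nonzero diagonals are
#' zeroed with a warning), non-negative weights, unique node ids, and a
#' network label for every node.
#'
#' @param weights square numeric matrix of non-negative edge weights.
#' @param network_of named character vector mapping node id -> network name.
#'   Names must cover the row names of `weights` (or, if `weights` has no
#'   dimnames, have length `nrow(weights)` and supply the node ids).
#' @param tol symmetry tolerance; asymmetry beyond this is an error.
#' @return an object of class `"connectome"`: a list with elements
#'   `node_ids`, `weights` (with dimnames), and `network_of`.
#' @examples
#' w <- matrix(c(0, 3.5, 3.5, 0), 2, 2)
#' cn <- connectome(w, c(a = "visual", b = "default"))
#' cn$node_ids
#' @export
connectome <- function(weights, network_of, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop("non-square connectome matrix: ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("connectome weights must be finite and non-missing", call. = FALSE)

  ids <- rownames(weights)
  if (is.null(ids)) {
    if (is.null(names(network_of)) || length(network_of) != nrow(weights))
      stop("unnamed weight matrix requires `network_of` named for every node",
           call. = FALSE)
    ids <- names(network_of)
    dimnames(weights) <- list(ids, ids)
  }
  if (anyDuplicated(ids))
    stop("duplicate node ids in connectome", call. = FALSE)
  if (!all(ids %in% names(network_of)))
    stop("network_of does not cover node ids: ",
         paste(utils::head(setdiff(ids, names(network_of)), 5),
               collapse = ", "), call. = FALSE)

  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop("connectome asymmetry ", format(asym), " exceeds tolerance ",
         format(tol), call. = FALSE)
  weights <- (weights + t(weights)) / 2

  d <- diag(weights)
  if (any(d != 0)) {
    warning("nonzero diagonal (max ", format(max(abs(d))),
            ") forced to zero", call. = FALSE)
    diag(weights) <- 0
  }
  if (any(weights < 0))
    stop("negative connectome weights", call. = FALSE)

  structure(
    list(node_ids = ids,
         weights = weights,
         network_of = network_of[ids]),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("connectome: ", length(x$node_ids), " nodes, ", nz, " edges, ",
      length(unique(x$network_of)), " networks\n", sep = "")
  invisible(x)
}

#' Construct validated parcellated BOLD timeseries
#'
#' One resting-state run after parcellation: the mean BOLD signal of each
#' cortical area at each repetition time (TR).  Rows are areas, columns TRs.
#'
#' @param data numeric matrix, nodes x TRs, no missing values, at least 2
#'   TRs.  Row names are the node ids (required).
#' @param tr_seconds repetition time in seconds (positive scalar).
#' @return object of class `"parcellated_bold"`: list with `node_ids`,
#'   `data`, `tr_seconds`.
#' @export
parcellated_bold <- function(data, tr_seconds = 3) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(data)))
    stop("timeseries rows must be named by node id", call. = FALSE)
  if (anyDuplicated(rownames(data)))
    stop("duplicate node ids in timeseries", call. = FALSE)
  if (ncol(data) < 2)
    stop("TRs >= 2 required (got ", ncol(data), ")", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop("missing value at (", rownames(data)[bad[1]], ", TR ", bad[2], ")",
         call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar", call. = FALSE)
  structure(
    list(node_ids = rownames(data), data = data, tr_seconds = tr_seconds),
    class = "parcellated_bold")
}

#' @export
print.parcellated_bold <- function(x, ...) {
  cat("parcellated_bold: ", nrow(x$data), " nodes x ", ncol(x$data),
      " TRs (TR = ", x$tr_seconds, " s)\n", sep = "")
  invisible(x)
}

# Align a bold object to a connectome's node order; error on mismatch.
align_bold <- function(bold, cn) {
  if (!setequal(bold$node_ids, cn$node_ids))
    stop("node ids of timeseries and connectome differ", call. = FALSE)
  if (!identical(bold$node_ids, cn$node_ids)) {
    bold$data <- bold$data[cn$node_ids, , drop = FALSE]
    bold$node_ids <- cn$node_ids
  }
  bold
}
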