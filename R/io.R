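# Delimited-text interchange for connectomes, timeseries, labels, subjects
# and results.  TSV is the default; .csv switches the delimiter.

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_table_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = delim_for(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

#' Read a node -> network label table
#'
#' @param path two-column delimited file (`node_id`, `network`); a header
#'   row is required.
#' @return named character vector mapping node id to network, in file order.
#'   The file order is the canonical node order for all other readers.
#' @export
read_labels <- function(path) {
  tab <- read_table_checked(path)
  if (ncol(tab) < 2)
    stop("labels file must have two columns (node_id, network)", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate node ids in labels file", call. = FALSE)
  stats::setNames(as.character(tab[[2]]), ids)
}

#' Read a structural connectome from delimited text
#'
#' Expects a square numeric table whose header row (and first column, if
#' present as row names) gives the node ids, plus a separate two-column
#' label table.  The matrix is re-ordered to the label-file node order, so
#' that every subject in a cohort is aligned identically.
#'
#' @param path square matrix file (TSV/CSV, header = node ids; optional
#'   first column of row ids).
#' @param labels_path label table, see [read_labels()].
#' @return validated [connectome()].
#' @export
read_connectome <- function(path, labels_path) {
  network_of <- read_labels(labels_path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  # first column may carry row ids
  rn <- NULL
  if (!is.numeric(tab[[1]])) {
    rn <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric entries in connectome", call. = FALSE)
  if (nrow(m) != ncol(m))
    stop("non-square connectome table: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  rownames(m) <- if (is.null(rn)) colnames(m) else rn
  ids <- names(network_of)
  if (!setequal(colnames(m), ids))
    stop("node id mismatch between matrix and labels", call. = FALSE)
  m <- m[ids, ids, drop = FALSE]
  connectome(m, network_of)
}

#' Read parcellated BOLD timeseries from delimited text
#'
#' Rows are nodes (first column = node id), remaining columns TRs.  By
#' default the temporal mean of each node is removed on read, since the
#' graph-filtering analysis operates on fluctuations, not baseline.
#'
#' @param path delimited file, first column node ids.
#' @param demean remove each node's temporal mean (default `TRUE`).
#' @param tr_seconds repetition time in seconds.
#' @return validated [parcellated_bold()].
#' @export
read_timeseries <- function(path, demean = TRUE, tr_seconds = 3) {
  tab <- read_table_checked(path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate node ids in timeseries", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value at (", ids[bad[1]], ", TR ", bad[2], ")",
         call. = FALSE)
  }
  if (ncol(m) < 2) stop("TRs >= 2 required", call. = FALSE)
  if (demean) m <- m - rowMeans(m)
  parcellated_bold(m, tr_seconds = tr_seconds)
}

#' Read subject metadata
#'
#' @param path delimited file with columns `subject_id`, `age_years`,
#'   `group`, `mean_fd_mm`.
#' @param groups allowed group labels.
#' @return data.frame of subjects in file order.
#' @export
read_subjects <- function(path, groups = c("athlete", "control")) {
  tab <- read_table_checked(path)
  need <- c("subject_id", "age_years", "group", "mean_fd_mm")
  if (!all(need %in% names(tab)))
    stop("subjects file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0) stop("no subjects in ", path, call. = FALSE)
  tab$subject_id <- as.character(tab$subject_id)
  tab$group <- as.character(tab$group)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject ids", call. = FALSE)
  unknown <- setdiff(unique(tab$group), groups)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tab$age_years) || !is.numeric(tab$mean_fd_mm))
    stop("age_years and mean_fd_mm must be numeric", call. = FALSE)
  if (any(!is.finite(tab$age_years)) || any(!is.finite(tab$mean_fd_mm)))
    stop("non-finite age or FD", call. = FALSE)
  if (any(tab$age_years <= 0 | tab$age_years >= 150))
    stop("age_years outside (0, 150)", call. = FALSE)
  if (any(tab$mean_fd_mm < 0))
    stop("negative mean_fd_mm", call. = FALSE)
  tab[, need]
}

#' The study cohort demographic table
#'
#' Ages and mean framewise displacement of the 19 female roller-derby
#' athletes and 14 controls analyzed in the source study, as printed in its
#' demographic table.  Used by the cohort-statistics checks and available
#' via `--ages-from-table` style reproduction runs.
#'
#' @return data.frame with columns `subject_id`, `age_years`, `group`,
#'   `mean_fd_mm` (33 rows).
#' @export
study_subjects <- function() {
  read_subjects(system.file("extdata", "cohort_subjects.tsv",
                            package = "neurocouple", mustWork = TRUE))
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(node_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a connectome, timeseries, labels or subjects table
#'
#' Round-trip counterparts of the readers; values survive write/read to
#' better than 1e-12 (full double precision is printed).
#'
#' @param x object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  op <- options(digits = 17); on.exit(options(op))
  write_matrix_tsv(x$weights, path)
  invisible(path)
}

#' @rdname write_connectome
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "parcellated_bold"))
  op <- options(digits = 17); on.exit(options(op))
  m <- x$data
  colnames(m) <- paste0("tr", seq_len(ncol(m)))
  write_matrix_tsv(m, path)
  invisible(path)
}

#' @rdname write_connectome
#' @export
write_labels <- function(x, path) {
  utils::write.table(
    data.frame(node_id = names(x), network = unname(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
write_subjects <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write PLS and regression results to a directory
#'
#' Writes, as TSV: one per-latent-variable table (salience, bootstrap
#' ratio, CI bounds per area), the network summary, the permutation p
#' table, and (if given) the mass-univariate regression table with raw and
#' adjusted p.  A JSON manifest records configuration, seeds and package
#' version.
#'
#' @param pls a `pls_result` from [pls_brain_age()], or `NULL`.
#' @param regression regression table from [run_mass_univariate()], or
#'   `NULL`.
#' @param path output directory (created if absent).
#' @param manifest named list of run metadata merged into the manifest.
#' @return character vector of files written (the manifest last).
#' @export
write_results <- function(pls = NULL, regression = NULL, path,
                          manifest = list()) {
  if (is.null(pls) && is.null(regression))
    stop("nothing to write", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (file.access(path, 2) != 0)
    stop("unwritable output directory: ", path, call. = FALSE)
  written <- character()
  put <- function(df, file) {
    fp <- file.path(path, file)
    utils::write.table(df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, fp)
  }
  if (!is.null(pls)) {
    K <- length(pls$singular_values)
    for (k in seq_len(K)) {
      put(data.frame(node_id = rownames(pls$brain_saliences),
                     network = pls$network_of[rownames(pls$brain_saliences)],
                     salience = pls$brain_saliences[, k],
                     bsr = pls$bsr[, k],
                     ci_low = pls$ci_low[, k],
                     ci_high = pls$ci_high[, k]),
          sprintf("lv%d_areas.tsv", k))
    }
    put(pls$network_summary, "network_summary.tsv")
    put(data.frame(lv = seq_len(K),
                   singular_value = pls$singular_values,
                   perm_p = pls$perm_p,
                   perm_p_label = ifelse(pls$perm_p == 0,
                                         paste0("<", format(1 / pls$n_perm)),
                                         format(pls$perm_p))),
        "latent_variables.tsv")
  }
  if (!is.null(regression)) put(regression, "age_regression.tsv")
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(
    c(list(package = "neurocouple",
           version = as.character(utils::packageVersion("neurocouple")),
           written = basename(written)),
      manifest),
    mf, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  c(written, mf)
}
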