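# Count-table input, validation, filtering and result output.

#' Construct a validated count matrix
#'
#' The entry point of every analysis is a feature-by-sample table of
#' non-negative integer sequencing counts together with a two-level condition
#' assignment. Counts are kept as integers; proportions and log abundances
#' are always derived downstream, never stored.
#'
#' @param counts numeric matrix, features in rows and samples in columns.
#'   Row names are feature IDs, column names sample IDs; both must be unique.
#'   All cells must be non-negative integers.
#' @param conditions optional vector or factor of length `ncol(counts)` with
#'   exactly two levels, each represented by at least two samples.
#' @param ref optional name of the reference condition level (the x = 0
#'   group). Defaults to the lexicographically first level. Between-group
#'   differences downstream are reported as non-reference minus reference.
#' @return an object of class `ssda_counts`: a list with elements `counts`
#'   (integer matrix) and `conditions` (two-level factor or `NULL`).
#' @examples
#' y <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- ssda_counts(y, conditions = c("A", "A", "B", "B"))
#' cm
#' @export
ssda_counts <- function(counts, conditions = NULL, ref = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("F", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (nrow(counts) < 1L) stop("need at least one feature", call. = FALSE)
  if (ncol(counts) < 2L) stop("need at least two samples", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid count (negative, non-integer or missing) at feature '%s', sample '%s'",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]
    ), call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature ID: '",
         rownames(counts)[duplicated(rownames(counts))][1L], "'", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ID: '",
         colnames(counts)[duplicated(colnames(counts))][1L], "'", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.null(conditions)) conditions <- encode_conditions(conditions, ref)
  structure(list(counts = counts, conditions = conditions),
            class = "ssda_counts")
}

#' @noRd
encode_conditions <- function(conditions, ref = NULL) {
  if (is.factor(conditions) && nlevels(conditions) == 2L && is.null(ref)) {
    if (any(table(conditions) < 2L))
      stop("each condition level needs at least two samples", call. = FALSE)
    return(conditions)        # already encoded; keep the reference level
  }
  conditions <- as.character(conditions)
  lev <- sort(unique(conditions))
  if (length(lev) != 2L)
    stop("two-group only: found ", length(lev), " condition level(s)",
         call. = FALSE)
  if (!is.null(ref)) {
    if (!ref %in% lev)
      stop("reference level '", ref, "' not among conditions", call. = FALSE)
    lev <- c(ref, setdiff(lev, ref))
  }
  f <- factor(conditions, levels = lev)
  if (any(table(f) < 2L))
    stop("each condition level needs at least two samples", call. = FALSE)
  f
}

#' @export
print.ssda_counts <- function(x, ...) {
  cat(sprintf("ssda_counts: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$conditions)) {
    tb <- table(x$conditions)
    cat(sprintf("conditions: %s (n=%d, reference) vs %s (n=%d)\n",
                names(tb)[1L], tb[1L], names(tb)[2L], tb[2L]))
  } else {
    cat("conditions: none attached\n")
  }
  invisible(x)
}

#' Read a count table from TSV/CSV
#'
#' Expects feature IDs in the first column, a header row of sample IDs, and
#' non-negative integer counts in the remaining cells.
#'
#' @param path file path.
#' @param delimiter field separator; defaults to `","` for files ending in
#'   `.csv` and tab otherwise.
#' @return an `ssda_counts` object without conditions (attach via
#'   [read_conditions()] or the `conditions` argument of [ssda_counts()]).
#' @export
read_counts <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 3L)
    stop("count table needs a feature-ID column and >= 2 sample columns",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at feature '%s', sample '%s'",
                 ids[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  rownames(m) <- ids
  ssda_counts(m)
}

#' Read a sample-to-condition assignment
#'
#' Two-column table (sample ID, condition label) in any order; reordered to
#' match `sample_ids`. Exactly two condition levels are allowed.
#'
#' @param path file path to a TSV/CSV without or with header; the first two
#'   columns are used.
#' @param sample_ids character vector of sample IDs the labels must cover.
#' @param ref optional reference level; defaults to lexicographically first.
#' @return two-level factor ordered like `sample_ids`.
#' @export
read_conditions <- function(path, sample_ids, ref = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = FALSE, sep = delimiter,
                          stringsAsFactors = FALSE, comment.char = "")
  # tolerate a header row naming the columns
  if (nrow(df) > 0L && df[1L, 1L] %in% c("sample", "sample_id", "id"))
    df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("conditions file needs two columns", call. = FALSE)
  lab <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  missing <- setdiff(sample_ids, names(lab))
  if (length(missing) > 0L)
    stop("no condition for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  encode_conditions(lab[sample_ids], ref)
}

#' Pre-filter low-count features
#'
#' Removes features whose total count across samples is below
#' `max(min_total, 1)`; by default only all-zero rows are dropped, since the
#' Dirichlet prior downstream handles sparse features. Removed IDs are kept
#' in the `removed_features` attribute of the result.
#'
#' @param cm an `ssda_counts` object.
#' @param min_total non-negative integer total-count threshold.
#' @return filtered `ssda_counts` with attribute `removed_features`.
#' @export
filter_features <- function(cm, min_total = 0L) {
  stopifnot(inherits(cm, "ssda_counts"), min_total >= 0)
  keep <- rowSums(cm$counts) >= max(min_total, 1)
  if (!any(keep)) stop("all features removed by filter", call. = FALSE)
  removed <- rownames(cm$counts)[!keep]
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  attr(out, "removed_features") <- removed
  out
}

#' Write a result table to TSV
#'
#' Columns are written in a stable order so output files are diffable:
#' feature_id, diff_btw, diff_win, effect, ep_t, eq_t, ep_w, eq_w,
#' mean_log2_abundance. Values round-trip at better than ten significant
#' digits.
#'
#' @param rt an `ssda_result` data frame from [run_da()].
#' @param path output file path.
#' @export
write_results <- function(rt, path) {
  cols <- c("feature_id", "diff_btw", "diff_win", "effect",
            "ep_t", "eq_t", "ep_w", "eq_w", "mean_log2_abundance")
  stopifnot(all(cols %in% names(rt)))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("directory does not exist: ", dirname(path), call. = FALSE)
  df <- as.data.frame(rt)[, cols]
  for (cl in cols[-1L]) df[[cl]] <- formatC(df[[cl]], digits = 12, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path.
#' @return `ssda_result` data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("ssda_result", "data.frame")
  df
}
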