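#' Default assessment task names
#'
#' The four span tasks of the automated working memory assessment battery,
#' in the canonical order used throughout the package: verbal short-term
#' (forward digit recall), visuospatial short-term (dot matrix), verbal
#' working memory (backward digit recall) and visuospatial working memory
#' (Mr. X).
#'
#' @return a character vector of four task names.
#' @export
default_tasks <- function() c("forward_digit", "dot_matrix", "backward_digit", "mr_x")

#' Construct a score table
#'
#' A score table holds one age-standardized assessment profile per
#' participant (nominal scale mean 100, SD 15), the input vectors for SOM
#' training. Rows with missing scores are rejected, never imputed.
#'
#' @param scores numeric matrix, participants x tasks; no missing values.
#' @param participant_id character vector of unique participant identifiers.
#' @param task_names ordered task names; order is significant and preserved.
#' @param timepoint optional single label for the whole table
#'   (e.g. `"pre"`, `"post"`, `"baseline"`).
#' @param covariates optional data.frame of named numeric columns
#'   (e.g. `gf_score`, `age_years`), one row per participant.
#' @return an object of class `score_table`.
#' @export
score_table <- function(scores, participant_id, task_names = colnames(scores),
                        timepoint = NULL, covariates = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(task_names)) stop("`task_names` required when `scores` has no colnames", call. = FALSE)
  if (length(task_names) != ncol(scores)) {
    stop("`task_names` length must equal the number of score columns", call. = FALSE)
  }
  participant_id <- as.character(participant_id)
  if (length(participant_id) != nrow(scores)) {
    stop("one participant_id per score row required", call. = FALSE)
  }
  if (anyDuplicated(participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(participant_id[duplicated(participant_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(scores) || !all(is.finite(scores))) {
    bad <- which(!stats::complete.cases(scores) | rowSums(!is.finite(scores)) > 0)
    stop("missing or non-finite scores in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(timepoint)) {
    stopifnot(is.character(timepoint), length(timepoint) == 1L)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(scores)) {
      stop("covariates must have one row per participant", call. = FALSE)
    }
    if (!all(vapply(covariates, is.numeric, TRUE))) {
      stop("covariate columns must be numeric", call. = FALSE)
    }
  }
  dimnames(scores) <- list(participant_id, task_names)
  structure(
    list(scores = scores, participant_id = participant_id,
         task_names = as.character(task_names), timepoint = timepoint,
         covariates = covariates),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d participants x %d tasks (%s)%s\n",
              nrow(x$scores), length(x$task_names),
              paste(x$task_names, collapse = ", "),
              if (is.null(x$timepoint)) "" else paste0(" [", x$timepoint, "]")))
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.score_table <- function(x) dim(x$scores)

#' @export
as.data.frame.score_table <- function(x, ...) {
  df <- data.frame(participant_id = x$participant_id, x$scores,
                   row.names = NULL, check.names = FALSE)
  if (!is.null(x$timepoint)) df$timepoint <- x$timepoint
  if (!is.null(x$covariates)) df <- cbind(df, x$covariates)
  df
}

#' Read a score table from delimited text
#'
#' Expects a comma-separated UTF-8 file with a header row, a
#' `participant_id` column and one numeric column per task. Optional
#' `timepoint` (single repeated label) and covariate columns are picked up
#' when present. Rows with missing or non-numeric scores are rejected with
#' the offending row number.
#'
#' @param path file path.
#' @param task_names required task columns, in order (default
#'   [default_tasks()]).
#' @param covariate_names covariate columns to attach when present; by
#'   default any of `gf_score`, `age_years` found in the file.
#' @return a [score_table()].
#' @export
read_score_table <- function(path, task_names = default_tasks(),
                             covariate_names = c("gf_score", "age_years")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("participant_id", task_names), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (tk in task_names) {
    v <- df[[tk]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop(sprintf("non-numeric or missing score in column '%s', row(s): %s",
                   tk, paste(which(is.na(v)), collapse = ", ")), call. = FALSE)
    }
    df[[tk]] <- v
  }
  timepoint <- NULL
  if ("timepoint" %in% names(df)) {
    tp <- unique(df$timepoint)
    if (length(tp) != 1L) stop("a score table holds a single timepoint", call. = FALSE)
    timepoint <- as.character(tp)
  }
  covs <- intersect(covariate_names, names(df))
  score_table(
    scores = as.matrix(df[task_names]),
    participant_id = df$participant_id,
    task_names = task_names,
    timepoint = timepoint,
    covariates = if (length(covs)) df[covs] else NULL
  )
}

#' Write a score table as CSV
#'
#' Inverse of [read_score_table()]: full numeric precision is preserved so a
#' write/read roundtrip reproduces the table exactly.
#'
#' @param table a [score_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  df <- as.data.frame(table)
  # format() would truncate; write doubles at round-trip precision
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: check two tables share tasks (and optionally participants).
check_same_tasks <- function(a_tasks, b_tasks) {
  if (!identical(as.character(a_tasks), as.character(b_tasks))) {
    stop("task names do not match: [", paste(a_tasks, collapse = ", "), "] vs [",
         paste(b_tasks, collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}
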