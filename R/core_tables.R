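#' Construct and validate a study object
#'
#' A `study_data` object bundles the session metadata, the wide IDP matrix,
#' an optional IQM matrix and the IDP category map. Every downstream
#' statistic indexes into this object. Validation enforces the referential
#' invariants: unique session ids, gap-free repeat indices per
#' (subject, scanner), one IDP row per session, and a category entry for
#' every IDP column.
#'
#' @param sessions data.frame with columns `session_id`, `subject_id`,
#'   `scanner_id`, `site`, `vendor`, `repeat_index`, `age`, `sex`.
#' @param idps numeric matrix, one row per session (rownames = session ids),
#'   one column per IDP. `NA` marks missing values.
#' @param categories data.frame with columns `idp_name`, `category`,
#'   `group`, `modality`; every IDP column must appear.
#' @param iqms optional numeric matrix, same row convention as `idps`.
#' @return An object of class `study_data`.
#' @export
study_data <- function(sessions, idps, categories, iqms = NULL) {
  obj <- structure(
    list(sessions = sessions, idps = idps, iqms = iqms,
         categories = categories),
    class = "study_data")
  validate_study(obj)
}

SESSION_COLUMNS <- c("session_id", "subject_id", "scanner_id", "site",
                     "vendor", "repeat_index", "age", "sex")

#' Validate a study object
#'
#' @param study a `study_data` object.
#' @return The study, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "study_data"))
  ses <- study$sessions
  missing_cols <- setdiff(SESSION_COLUMNS, names(ses))
  if (length(missing_cols) > 0L)
    stop("sessions table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ses$session_id))
    stop("duplicate session_id in sessions table", call. = FALSE)
  key <- paste(ses$subject_id, ses$scanner_id, ses$repeat_index)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, scanner_id, repeat_index)", call. = FALSE)
  # repeat_index must run 0..k with no gaps within each (subject, scanner)
  by_pair <- split(ses$repeat_index, paste(ses$subject_id, ses$scanner_id))
  bad <- vapply(by_pair, function(r) !identical(sort(as.integer(r)),
                                                seq.int(0L, length(r) - 1L)),
                logical(1))
  if (any(bad))
    stop("repeat_index not a gap-free 0..k sequence for: ",
         paste(names(by_pair)[bad], collapse = "; "), call. = FALSE)

  idps <- study$idps
  if (!is.matrix(idps)) stop("idps must be a matrix", call. = FALSE)
  unknown <- setdiff(rownames(idps), ses$session_id)
  if (length(unknown) > 0L)
    stop("idps rows reference unknown session_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!setequal(rownames(idps), ses$session_id) ||
      anyDuplicated(rownames(idps)))
    stop("idps must have exactly one row per session_id", call. = FALSE)

  cats <- study$categories
  needed <- c("idp_name", "category", "group", "modality")
  if (!all(needed %in% names(cats)))
    stop("categories table needs columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  uncat <- setdiff(colnames(idps), cats$idp_name)
  if (length(uncat) > 0L)
    stop("IDP column(s) absent from categories: ",
         paste(head(uncat, 5L), collapse = ", "), call. = FALSE)
  n_per_cat <- table(cats$category[cats$idp_name %in% colnames(idps)])
  if (any(n_per_cat < 2L))
    stop("every IDP category needs >= 2 IDPs (rank correlation undefined ",
         "on a single point); offending: ",
         paste(names(n_per_cat)[n_per_cat < 2L], collapse = ", "),
         call. = FALSE)

  if (!is.null(study$iqms)) {
    if (!is.matrix(study$iqms)) stop("iqms must be a matrix", call. = FALSE)
    unknown <- setdiff(rownames(study$iqms), ses$session_id)
    if (length(unknown) > 0L)
      stop("iqms rows reference unknown session_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  # canonical row order: idps (and iqms) follow the sessions table
  study$idps <- idps[match(ses$session_id, rownames(idps)), , drop = FALSE]
  if (!is.null(study$iqms))
    study$iqms <- study$iqms[match(ses$session_id, rownames(study$iqms)), ,
                             drop = FALSE]
  study
}

#' @export
print.study_data <- function(x, ...) {
  cat("study_data:", nrow(x$sessions), "sessions,",
      ncol(x$idps), "IDPs in",
      length(unique(x$categories$category[
        x$categories$idp_name %in% colnames(x$idps)])), "categories",
      if (!is.null(x$iqms)) sprintf(", %d IQMs", ncol(x$iqms)) else "",
      "\n", sep = " ")
  cat("  subjects:", length(unique(x$sessions$subject_id)),
      " scanners:", length(unique(x$sessions$scanner_id)),
      " within-scanner repeats:", sum(x$sessions$repeat_index > 0L), "\n")
  invisible(x)
}

#' Load a study from TSV files
#'
#' Reads the session table, wide IDP table, category map and (optionally)
#' IQM table from tab-separated files and returns a validated
#' [study_data()] object. The dialect is fixed: tab separator, header row,
#' `NA` for missing, `.` decimal point.
#'
#' @param sessions_path,idps_path,categories_path paths to the TSV files.
#' @param iqms_path optional path to an IQM TSV.
#' @return A validated `study_data` object with IDP rows reordered to match
#'   the session table.
#' @export
load_study <- function(sessions_path, idps_path, categories_path,
                       iqms_path = NULL) {
  sessions <- read_tsv_file(sessions_path)
  missing_cols <- setdiff(SESSION_COLUMNS, names(sessions))
  if (length(missing_cols) > 0L)
    stop("sessions file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sessions$repeat_index <- as.integer(sessions$repeat_index)
  idps <- read_matrix_tsv(idps_path, key = "session_id")
  categories <- read_tsv_file(categories_path)
  iqms <- if (!is.null(iqms_path)) read_matrix_tsv(iqms_path, "session_id")
  study_data(sessions, idps, categories, iqms = iqms)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
             check.names = FALSE, stringsAsFactors = FALSE)
}

read_matrix_tsv <- function(path, key) {
  df <- read_tsv_file(path)
  if (!key %in% names(df))
    stop("file ", path, " missing key column '", key, "'", call. = FALSE)
  keys <- as.character(df[[key]])
  m <- as.matrix(df[setdiff(names(df), key)])
  storage.mode(m) <- "double"
  rownames(m) <- keys
  m
}

#' Write a rectangular result as TSV
#'
#' Writes matrices or data frames in the package's fixed TSV dialect: tab
#' separator, header row, `NA` for missing, full `%.17g` precision for
#' numeric cells so that read-back reproduces the written doubles exactly.
#' Row names (when present) go into a leading label column.
#'
#' @param table a matrix or data.frame.
#' @param path output file path.
#' @param rowname_col name for the leading label column when `table` has
#'   row names (default `"row"`); ignored otherwise.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, rowname_col = "row") {
  df <- as.data.frame(table, stringsAsFactors = FALSE,
                      check.names = FALSE, optional = TRUE)
  has_rn <- !is.null(rownames(table)) &&
    !identical(rownames(table), as.character(seq_len(nrow(df))))
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      out <- as.character(col)
      out[is.na(col)] <- "NA"
      out
    }
  })
  header <- names(df)
  if (has_rn) {
    cols <- c(list(rownames(table)), cols)
    header <- c(rowname_col, header)
  }
  lines <- if (nrow(df) == 0L) character(0) else
    do.call(paste, c(cols, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), lines), con, sep = "\n")
  invisible(path)
}

#' Spearman rank correlation with pairwise-complete pairs
#'
#' The shared rank-correlation primitive behind the between-session
#' similarity matrix and the subject-ranking consistency statistic. Pairs
#' with a missing value in either input are dropped before ranking
#' (pairwise-complete); ties receive average ranks. When fewer than two
#' complete pairs remain, or either input is constant after dropping, the
#' correlation is undefined and `NA` is returned (never 0: a degenerate
#' input must not masquerade as "no association").
#'
#' @param x,y numeric vectors of equal length.
#' @return A correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(x, y, method = "spearman")
}
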