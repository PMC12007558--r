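#' Per-category between-session correlation matrices
#'
#' For every IDP category, computes the Spearman rank correlation between
#' every pair of sessions over that category's IDP vector, giving one
#' session-by-session matrix per category. Missing values are handled
#' pairwise-complete; undefined correlations (fewer than two complete
#' pairs, or a constant vector) are `NA`. Diagonals are set to exactly 1.
#'
#' For a functional-connectivity edge category, pass the retained edge
#' names from [select_top_edges()] via `keep_idps` so only the strongest
#' edges enter the similarity computation.
#'
#' @param study a [study_data()] object.
#' @param keep_idps optional named list: `category -> character vector` of
#'   IDP names to restrict that category to.
#' @return named list of symmetric session-by-session matrices, one per
#'   category, class `category_correlations`.
#' @export
category_correlation_matrices <- function(study, keep_idps = NULL) {
  validate_study(study)
  cats <- study$categories
  cat_names <- unique(cats$category[cats$idp_name %in% colnames(study$idps)])
  out <- lapply(setNames(cat_names, cat_names), function(cm) {
    members <- cats$idp_name[cats$category == cm]
    members <- intersect(members, colnames(study$idps))
    if (!is.null(keep_idps[[cm]]))
      members <- intersect(members, keep_idps[[cm]])
    if (length(members) < 2L)
      stop("category '", cm, "' has < 2 IDPs after restriction",
           call. = FALSE)
    x <- study$idps[, members, drop = FALSE]
    r <- suppressWarnings(
      cor(t(x), method = "spearman", use = "pairwise.complete.obs"))
    # too-few complete pairs: cor() still reports a value for 2+ points;
    # enforce the >= 2 complete-pairs rule pair by pair via NA propagation
    diag(r) <- 1
    dimnames(r) <- list(rownames(x), rownames(x))
    r
  })
  structure(out, class = "category_correlations")
}

#' Median between-session similarity matrix
#'
#' Collapses the per-category correlation matrices into the single
#' between-session similarity matrix: the entrywise median across
#' categories, ignoring categories whose correlation is undefined for a
#' pair. A pair is `NA` only if every category is undefined for it. Each
#' category carries equal weight regardless of its IDP count.
#'
#' @param cc a `category_correlations` list.
#' @return list with `P` (session x session matrix), `n_categories`
#'   (matrix counting the categories contributing to each entry) and
#'   `session_ids`; class `similarity_matrix`.
#' @export
similarity_matrix <- function(cc) {
  stopifnot(inherits(cc, "category_correlations"), length(cc) >= 1L)
  arr <- simplify2array(cc)            # n_ses x n_ses x n_cat
  P <- apply(arr, c(1, 2), median, na.rm = TRUE)
  P[!is.finite(P)] <- NA_real_
  n_contrib <- apply(!is.na(arr), c(1, 2), sum)
  structure(list(P = P, n_categories = n_contrib,
                 session_ids = rownames(P)),
            class = "similarity_matrix")
}

#' Classify unordered session pairs
#'
#' Partitions all `choose(n, 2)` unordered session pairs into the four
#' classes defined by equality of subject and scanner:
#' `within_scanner_within_subject`, `between_scanner_within_subject`,
#' `within_scanner_between_subject`, `between_scanner_between_subject`.
#'
#' @param sessions session table (data.frame).
#' @return data.frame with columns `session_a`, `session_b`, `pair_class`.
#' @export
classify_pairs <- function(sessions) {
  n <- nrow(sessions)
  idx <- combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  same_subj <- sessions$subject_id[i] == sessions$subject_id[j]
  same_scan <- sessions$scanner_id[i] == sessions$scanner_id[j]
  cls <- ifelse(same_subj & same_scan, "within_scanner_within_subject",
         ifelse(same_subj, "between_scanner_within_subject",
         ifelse(same_scan, "within_scanner_between_subject",
                "between_scanner_between_subject")))
  data.frame(session_a = sessions$session_id[i],
             session_b = sessions$session_id[j],
             pair_class = cls, stringsAsFactors = FALSE)
}

PAIR_CLASSES <- c("within_scanner_within_subject",
                  "between_scanner_within_subject",
                  "within_scanner_between_subject",
                  "between_scanner_between_subject")

#' Per-class similarity distributions
#'
#' Collects the similarity-matrix entries belonging to each session-pair
#' class and summarises them (count, missing count, median, quartiles).
#' An empty class yields an empty summary, not an error.
#'
#' @param sim a [similarity_matrix()] result.
#' @param pairs output of [classify_pairs()] for the same sessions.
#' @return list with `values` (named list of numeric vectors per class)
#'   and `summary` (data.frame: class, n, n_missing, q25, median, q75).
#' @export
pair_class_distributions <- function(sim, pairs) {
  stopifnot(inherits(sim, "similarity_matrix"))
  ia <- match(pairs$session_a, sim$session_ids)
  ib <- match(pairs$session_b, sim$session_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("pair table references sessions absent from the similarity matrix",
         call. = FALSE)
  vals <- sim$P[cbind(ia, ib)]
  values <- lapply(setNames(PAIR_CLASSES, PAIR_CLASSES), function(cl) {
    v <- vals[pairs$pair_class == cl]
    v[!is.na(v)]
  })
  n_missing <- vapply(PAIR_CLASSES, function(cl)
    sum(is.na(vals[pairs$pair_class == cl])), integer(1))
  summ <- data.frame(
    pair_class = PAIR_CLASSES,
    n = vapply(values, length, integer(1)),
    n_missing = n_missing,
    q25 = vapply(values, function(v)
      if (length(v)) unname(quantile(v, 0.25)) else NA_real_, double(1)),
    median = vapply(values, function(v)
      if (length(v)) median(v) else NA_real_, double(1)),
    q75 = vapply(values, function(v)
      if (length(v)) unname(quantile(v, 0.75)) else NA_real_, double(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(values = values, summary = summ)
}
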