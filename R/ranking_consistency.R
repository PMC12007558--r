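#' Per-scanner subject vectors
#'
#' Extracts, for one scanner, the vector of IDP values over subjects —
#' one value per subject, taken from the subject's primary
#' (`repeat_index` 0) session on that scanner; missing sessions propagate
#' as `NA` without changing the vector length.
#'
#' @param study a [study_data()] object.
#' @param scanner scanner id.
#' @param policy `"first"` (primary session, default) or
#'   `"mean-of-repeats"` (mean over all the subject's sessions on that
#'   scanner).
#' @return numeric matrix, subjects x IDPs.
#' @export
subject_vectors <- function(study, scanner,
                            policy = c("first", "mean-of-repeats")) {
  validate_study(study)
  policy <- match.arg(policy)
  ses <- study$sessions
  if (!scanner %in% ses$scanner_id)
    stop("unknown scanner: ", scanner, call. = FALSE)
  subjects <- unique(ses$subject_id)
  out <- matrix(NA_real_, nrow = length(subjects), ncol = ncol(study$idps),
                dimnames = list(subjects, colnames(study$idps)))
  for (s in subjects) {
    rows <- ses$subject_id == s & ses$scanner_id == scanner
    if (!any(rows)) next
    out[s, ] <- if (policy == "first") {
      ix <- which(rows & ses$repeat_index == 0L)
      if (length(ix) == 1L) study$idps[ix, ] else NA_real_
    } else {
      colMeans(study$idps[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Between-scanner consistency of subject ranking
#'
#' For every IDP and every unordered pair of scanners in the subset,
#' computes the Spearman rank correlation between the two scanners'
#' subject vectors: 1 means the two scanners order the subjects
#' identically on that IDP. Pairs with fewer than `min_complete` complete
#' subjects are reported missing.
#'
#' @param study a [study_data()] object.
#' @param scanner_subset character vector of scanner ids (>= 2); defaults
#'   to all scanners.
#' @param policy session-selection policy, see [subject_vectors()].
#' @param min_complete minimum complete subject pairs per correlation
#'   (default 3).
#' @return list with `Q` (matrix: scanner pairs x IDPs), `pairs`
#'   (data.frame of the scanner pairs), `per_idp` (data.frame: idp_name,
#'   median_Q over pairs) and `subset_label`; class `ranking_report`.
#' @export
ranking_consistency <- function(study, scanner_subset = NULL,
                                policy = c("first", "mean-of-repeats"),
                                min_complete = 3L) {
  validate_study(study)
  policy <- match.arg(policy)
  scanners <- unique(study$sessions$scanner_id)
  if (is.null(scanner_subset)) scanner_subset <- scanners
  if (!all(scanner_subset %in% scanners))
    stop("unknown scanner(s): ",
         paste(setdiff(scanner_subset, scanners), collapse = ", "),
         call. = FALSE)
  if (length(scanner_subset) < 2L)
    stop("scanner_subset needs >= 2 scanners", call. = FALSE)

  vecs <- lapply(setNames(scanner_subset, scanner_subset),
                 function(b) subject_vectors(study, b, policy = policy))
  pr <- combn(scanner_subset, 2)
  pair_names <- paste(pr[1, ], pr[2, ], sep = "|")
  Q <- matrix(NA_real_, nrow = ncol(pr), ncol = ncol(study$idps),
              dimnames = list(pair_names, colnames(study$idps)))
  for (p in seq_len(ncol(pr))) {
    vl <- vecs[[pr[1, p]]]
    vk <- vecs[[pr[2, p]]]
    for (d in seq_len(ncol(Q))) {
      x <- vl[, d]; y <- vk[, d]
      if (sum(!is.na(x) & !is.na(y)) < min_complete) next
      Q[p, d] <- rank_correlation(x, y)
    }
  }
  per_idp <- data.frame(
    idp_name = colnames(Q),
    median_Q = apply(Q, 2, function(q) {
      q <- q[!is.na(q)]
      if (length(q) == 0L) NA_real_ else median(q)
    }),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(Q = Q,
                 pairs = data.frame(scanner_l = pr[1, ],
                                    scanner_k = pr[2, ],
                                    stringsAsFactors = FALSE),
                 per_idp = per_idp,
                 subset_label = if (setequal(scanner_subset, scanners))
                   "all" else paste(sort(scanner_subset), collapse = ",")),
            class = "ranking_report")
}

# all permutations of 1..n (n <= 8), in lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Null distribution of ranking consistency under random rankings
#'
#' The indicative baseline against which observed ranking consistency is
#' judged: the distribution of Spearman correlations between random
#' subject rankings. `mode = "exact"` enumerates all `n!` permutations
#' against a fixed reference ranking (valid by exchangeability; `n <= 8`);
#' `mode = "montecarlo"` draws `n_draws` independent random permutation
#' pairs.
#'
#' @param n_subjects number of subjects ranked (>= 2).
#' @param n_draws Monte-Carlo draws (default 10000).
#' @param seed integer seed (Monte-Carlo mode).
#' @param mode `"montecarlo"` (default) or `"exact"`.
#' @return list with `q25`, `q50`, `q75`, `values` (the correlation
#'   draws), `n_subjects`, `n_draws`, `mode`, `seed`; class
#'   `null_baseline`.
#' @export
null_baseline <- function(n_subjects, n_draws = 10000L, seed = 1L,
                          mode = c("montecarlo", "exact")) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 2L)
  if (mode == "exact") {
    if (n_subjects > 8L)
      stop("exact enumeration limited to n_subjects <= 8", call. = FALSE)
    ref <- seq_len(n_subjects)
    perms <- all_permutations(n_subjects)
    vals <- apply(perms, 1, function(p) cor(ref, p, method = "spearman"))
    n_draws <- nrow(perms)
  } else {
    vals <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
      cor(sample.int(n_subjects), sample.int(n_subjects),
          method = "spearman")
    }, double(1)))
  }
  q <- unname(quantile(vals, c(0.25, 0.5, 0.75)))
  structure(list(q25 = q[1], q50 = q[2], q75 = q[3], values = vals,
                 n_subjects = as.integer(n_subjects),
                 n_draws = as.integer(n_draws), mode = mode,
                 seed = as.integer(seed)),
            class = "null_baseline")
}
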