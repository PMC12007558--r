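#' Coefficient of variation
#'
#' Sample standard deviation divided by the absolute mean of a set of
#' repeated measurements; the package's scale-free variability measure.
#' Returns `NA` when fewer than two non-missing values remain or when the
#' mean is too close to zero for the ratio to be meaningful (threshold
#' `eps` times the value scale), rather than an exploding ratio.
#'
#' @param values numeric vector of repeated measurements.
#' @param ddof degrees-of-freedom correction for the sd: 1 (default,
#'   sample sd) or 0 (population sd).
#' @param eps relative near-zero-mean guard.
#' @return non-negative CoV, or `NA_real_`.
#' @export
coefficient_of_variation <- function(values, ddof = 1, eps = 1e-12) {
  stopifnot(ddof %in% c(0, 1))
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2L) return(NA_real_)
  m <- mean(v)
  scale <- max(abs(v), 1)
  if (abs(m) < eps * scale) return(NA_real_)
  s <- sd(v)
  if (ddof == 0) s <- s * sqrt((n - 1) / n)
  s / abs(m)
}

# mean over a list of per-unit CoVs, NA-aware; NA if nothing defined
mean_cov <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

#' The three-baseline CoV profile
#'
#' For every IDP, computes the three coefficients of variation that frame
#' the harmonisation problem:
#'
#' * `cov_within_scanner` — CoV across each qualifying (subject, scanner)
#'   within-scanner repeat set (all sessions of that subject on that
#'   scanner, at least two), averaged over qualifying subjects: the
#'   test-retest noise floor.
#' * `cov_between_scanner` — CoV across each subject's primary
#'   (`repeat_index` 0) sessions, one per scanner, averaged over subjects:
#'   the scanner effect under study. With `between_policy =
#'   "mean-of-repeats"` a repeated scanner is represented by the mean of
#'   its repeats instead of the primary session.
#' * `cov_biological` — CoV across subjects' primary sessions within each
#'   scanner, averaged over scanners: between-subject (biological)
#'   variability.
#'
#' plus the relative difference `100 * (between - within) / within`.
#'
#' @param study a [study_data()] object.
#' @param ddof sd divisor policy, passed to [coefficient_of_variation()].
#' @param between_policy `"first"` (primary sessions only, default) or
#'   `"mean-of-repeats"`.
#' @return data.frame (one row per IDP): `idp_name`, `cov_within_scanner`,
#'   `cov_between_scanner`, `cov_biological`, `relative_difference_pct`;
#'   class `reliability_report`. Warns (not errors) when a repeat class is
#'   empty.
#' @export
class_cov_profile <- function(study, ddof = 1,
                              between_policy = c("first",
                                                 "mean-of-repeats")) {
  validate_study(study)
  between_policy <- match.arg(between_policy)
  ses <- study$sessions
  idps <- study$idps
  idp_names <- colnames(idps)

  # within-scanner: (subject, scanner) sets with >= 2 sessions
  pair_key <- paste(ses$subject_id, ses$scanner_id, sep = "\r")
  sets <- split(seq_len(nrow(ses)), pair_key)
  sets <- sets[vapply(sets, length, integer(1)) >= 2L]
  if (length(sets) == 0L) {
    warning("no (subject, scanner) pair has >= 2 sessions; ",
            "within-scanner CoV undefined", call. = FALSE)
    cov_within <- rep(NA_real_, length(idp_names))
  } else {
    per_set <- vapply(sets, function(ix)
      apply(idps[ix, , drop = FALSE], 2, coefficient_of_variation,
            ddof = ddof), double(length(idp_names)))
    cov_within <- apply(matrix(per_set, nrow = length(idp_names)), 1,
                        mean_cov)
  }

  # between-scanner: per subject, one value per scanner
  subjects <- unique(ses$subject_id)
  per_subj <- vapply(subjects, function(s) {
    rows <- ses$subject_id == s
    if (between_policy == "first") {
      ix <- which(rows & ses$repeat_index == 0L)
      vals <- idps[ix, , drop = FALSE]
    } else {
      scs <- unique(ses$scanner_id[rows])
      vals <- t(vapply(scs, function(b)
        colMeans(idps[rows & ses$scanner_id == b, , drop = FALSE],
                 na.rm = TRUE), double(length(idp_names))))
      vals[!is.finite(vals)] <- NA_real_
    }
    apply(vals, 2, coefficient_of_variation, ddof = ddof)
  }, double(length(idp_names)))
  cov_between <- apply(matrix(per_subj, nrow = length(idp_names)), 1,
                       mean_cov)

  # biological: per scanner, across subjects' primary sessions
  scanners <- unique(ses$scanner_id)
  per_scan <- vapply(scanners, function(b) {
    ix <- which(ses$scanner_id == b & ses$repeat_index == 0L)
    apply(idps[ix, , drop = FALSE], 2, coefficient_of_variation,
          ddof = ddof)
  }, double(length(idp_names)))
  cov_bio <- apply(matrix(per_scan, nrow = length(idp_names)), 1, mean_cov)

  rel <- mapply(relative_difference, cov_between, cov_within)
  structure(data.frame(idp_name = idp_names,
                       cov_within_scanner = cov_within,
                       cov_between_scanner = cov_between,
                       cov_biological = cov_bio,
                       relative_difference_pct = rel,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("reliability_report", "data.frame"))
}

#' Relative difference between two CoVs, in percent
#'
#' @param between,within non-negative CoVs.
#' @return `100 * (between - within) / within`, or `NA_real_` when
#'   `within` is missing or not positive.
#' @export
relative_difference <- function(between, within) {
  if (is.na(between) || is.na(within) || within <= 0) return(NA_real_)
  100 * (between - within) / within
}

#' Scanner bias of between- versus within-scanner means
#'
#' For every subject with within-scanner repeats, compares the mean of the
#' subject's primary sessions across scanners (the between-scanner mean)
#' with the mean over the subject's within-scanner repeat set, IDP-wise:
#' `100 * (between_mean - within_mean) / within_mean`. Also returns the
#' group-level mean across qualifying subjects and a variant with the
#' between-scanner mean restricted to scanners of one vendor.
#'
#' @param study a [study_data()] object.
#' @param vendor optional vendor label for the restricted variant.
#' @param eps near-zero-mean guard on the within-scanner mean.
#' @return list with `per_subject` (data.frame: subject_id, idp_name,
#'   bias_pct), `group` (data.frame: idp_name, bias_pct) and, when
#'   `vendor` is given, `vendor_group` (same shape, with the
#'   between-scanner mean taken over that vendor's scanners only).
#' @export
scanner_bias <- function(study, vendor = NULL, eps = 1e-12) {
  validate_study(study)
  ses <- study$sessions
  idps <- study$idps
  rep_key <- paste(ses$subject_id, ses$scanner_id, sep = "\r")
  rep_sizes <- table(rep_key)
  qual_keys <- names(rep_sizes)[rep_sizes >= 2L]
  subjects <- unique(ses$subject_id[rep_key %in% qual_keys])
  if (length(subjects) == 0L)
    stop("no subject has within-scanner repeats", call. = FALSE)

  bias_one <- function(s, scanner_filter = NULL) {
    rows <- ses$subject_id == s
    rep_scanner <- ses$scanner_id[rows & rep_key %in% qual_keys][1]
    within_ix <- which(rows & ses$scanner_id == rep_scanner)
    between_ix <- which(rows & ses$repeat_index == 0L)
    if (!is.null(scanner_filter))
      between_ix <- between_ix[ses$vendor[between_ix] == scanner_filter]
    wm <- colMeans(idps[within_ix, , drop = FALSE], na.rm = TRUE)
    bm <- colMeans(idps[between_ix, , drop = FALSE], na.rm = TRUE)
    scale <- pmax(abs(wm), 1)
    out <- 100 * (bm - wm) / wm
    out[!is.finite(out) | abs(wm) < eps * scale] <- NA_real_
    out
  }

  per_subj <- vapply(subjects, bias_one, double(ncol(idps)))
  per_subject <- data.frame(
    subject_id = rep(subjects, each = ncol(idps)),
    idp_name = rep(colnames(idps), times = length(subjects)),
    bias_pct = as.vector(per_subj),
    stringsAsFactors = FALSE)
  group <- data.frame(
    idp_name = colnames(idps),
    bias_pct = apply(matrix(per_subj, nrow = ncol(idps)), 1, mean_cov),
    stringsAsFactors = FALSE)
  out <- list(per_subject = per_subject, group = group)
  if (!is.null(vendor)) {
    pv <- vapply(subjects, bias_one, double(ncol(idps)),
                 scanner_filter = vendor)
    out$vendor_group <- data.frame(
      idp_name = colnames(idps),
      bias_pct = apply(matrix(pv, nrow = ncol(idps)), 1, mean_cov),
      stringsAsFactors = FALSE)
  }
  out
}

#' Aggregate a reliability report by IDP group
#'
#' @param report a [class_cov_profile()] result.
#' @param categories the category map (data.frame with `idp_name`,
#'   `group`).
#' @param statistic `"mean"` or `"median"`.
#' @return data.frame, one row per group, with the group-level statistic
#'   of each CoV column and of the relative difference, missing-aware.
#' @export
aggregate_by_group <- function(report, categories,
                               statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  grp <- categories$group[match(report$idp_name, categories$idp_name)]
  if (anyNA(grp))
    stop("IDP(s) missing from the category map: ",
         paste(head(report$idp_name[is.na(grp)], 5), collapse = ", "),
         call. = FALSE)
  fun <- if (statistic == "mean") mean else median
  num_cols <- c("cov_within_scanner", "cov_between_scanner",
                "cov_biological", "relative_difference_pct")
  agg <- aggregate(report[num_cols], by = list(group = grp),
                   FUN = function(x) {
                     x <- x[!is.na(x)]
                     if (length(x) == 0L) NA_real_ else fun(x)
                   })
  agg[order(agg$group), , drop = FALSE]
}

#' Z-scored image quality metric heatmap
#'
#' Produces the scanner-by-IQM (or subject-by-IQM) quality heatmap: each
#' IQM is z-scored for each subject across scanners (sample sd), then
#' averaged across subjects — or the transpose construction for the
#' subject-level view. Within-scanner repeat sessions are excluded before
#' z-scoring so no scanner is over-represented. IQMs constant along the
#' z-axis yield missing entries.
#'
#' @param study a [study_data()] with an `iqms` table.
#' @param axis `"across_scanners"` (scanner x IQM, default) or
#'   `"across_subjects"` (subject x IQM).
#' @return numeric matrix of averaged z-scores.
#' @export
zscore_iqms <- function(study, axis = c("across_scanners",
                                        "across_subjects")) {
  validate_study(study)
  axis <- match.arg(axis)
  if (is.null(study$iqms)) stop("study has no IQM table", call. = FALSE)
  keep <- study$sessions$repeat_index == 0L
  ses <- study$sessions[keep, , drop = FALSE]
  iqms <- study$iqms[keep, , drop = FALSE]
  if (axis == "across_scanners") {
    z_within <- "subject_id"; z_across <- "scanner_id"
  } else {
    z_within <- "scanner_id"; z_across <- "subject_id"
  }
  units <- unique(ses[[z_across]])
  blocks <- split(seq_len(nrow(ses)), ses[[z_within]])
  zsum <- matrix(0, nrow = length(units), ncol = ncol(iqms),
                 dimnames = list(units, colnames(iqms)))
  zcnt <- zsum
  for (ix in blocks) {
    x <- iqms[ix, , drop = FALSE]
    mu <- colMeans(x, na.rm = TRUE)
    sdev <- apply(x, 2, sd, na.rm = TRUE)
    sdev[sdev == 0] <- NA_real_
    z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
    u <- match(ses[[z_across]][ix], units)
    ok <- !is.na(z)
    z[!ok] <- 0
    zsum[u, ] <- zsum[u, ] + z
    zcnt[u, ] <- zcnt[u, ] + ok
  }
  out <- zsum / zcnt
  out[zcnt == 0] <- NA_real_
  out
}

#' Select the strongest connectivity edges
#'
#' Ranks the edges of a connectivity category by the absolute mean edge
#' weight over all within-scanner repeat sessions of the subjects that
#' have such repeats, and keeps the top `k = k_override` edges if given,
#' else `round(fraction * n_edges)`. Ties are broken by edge name
#' (lexicographic) so selection is deterministic.
#'
#' @param study a [study_data()] object.
#' @param edge_category category label holding the edge IDPs.
#' @param fraction fraction of edges to keep, in (0, 1].
#' @param k_override optional explicit edge count (overrides `fraction`).
#' @return character vector of retained edge names.
#' @export
select_top_edges <- function(study, edge_category, fraction = 0.05,
                             k_override = NULL) {
  validate_study(study)
  stopifnot(fraction > 0, fraction <= 1)
  cats <- study$categories
  edges <- intersect(cats$idp_name[cats$category == edge_category],
                     colnames(study$idps))
  if (length(edges) == 0L)
    stop("no IDPs in category '", edge_category, "'", call. = FALSE)
  ses <- study$sessions
  rep_key <- paste(ses$subject_id, ses$scanner_id, sep = "\r")
  rep_sizes <- table(rep_key)
  qual <- rep_key %in% names(rep_sizes)[rep_sizes >= 2L]
  if (!any(qual))
    stop("no subject has within-scanner repeats", call. = FALSE)
  means <- colMeans(study$idps[qual, edges, drop = FALSE], na.rm = TRUE)
  k <- if (!is.null(k_override)) as.integer(k_override)
       else max(1L, round(fraction * length(edges)))
  if (k > length(edges))
    stop("requested ", k, " edges but only ", length(edges), " exist",
         call. = FALSE)
  ord <- order(-abs(means), names(means))
  sort(names(means)[ord][seq_len(k)])
}
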