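# Covariate design matrix for ComBat: age centred (numerical
# conditioning), sex as a 0/1 dummy against the stored reference level.
covariate_matrix <- function(sessions, covariates, age_center,
                             sex_levels) {
  if (length(covariates) == 0L)
    return(matrix(0, nrow = nrow(sessions), ncol = 0))
  cols <- list()
  if ("age" %in% covariates)
    cols$age <- sessions$age - age_center
  if ("sex" %in% covariates) {
    bad <- setdiff(unique(sessions$sex), sex_levels)
    if (length(bad) > 0L)
      stop("unseen sex level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cols$sex <- as.numeric(sessions$sex == sex_levels[2])
  }
  do.call(cbind, cols)
}

#' Fit a parametric empirical-Bayes ComBat model
#'
#' Estimates and shrinks per-batch location and scale effects on a
#' feature table while preserving covariate-associated signal:
#'
#' 1. least-squares fit of batch offsets plus covariates, with the
#'    sample-size-weighted batch offsets constrained to sum to zero so the
#'    grand mean is preserved;
#' 2. pooled per-feature variance (divisor N) of the full-model residuals;
#' 3. standardisation `z = (y - alpha - x beta) / sigma`;
#' 4. per-batch sample mean `gamma_hat` and variance `delta2_hat` of `z`;
#' 5. hyperpriors by method of moments across features: normal prior
#'    `(gamma_bar, tau2_bar)` for locations, inverse-gamma `(a, b)` for
#'    variances with `a = (2 s2 + m^2)/s2`, `b = (m s2 + m^3)/s2` from the
#'    mean `m` and variance `s2` of the `delta2_hat`;
#' 6. alternating conditional posterior means
#'    `gamma* = (n tau2 gamma_hat + delta2* gamma_bar)/(n tau2 + delta2*)`
#'    and `delta2* = (b + 0.5 sum (z - gamma*)^2)/(n/2 + a - 1)` until the
#'    maximum relative change drops below `tol`.
#'
#' When the across-feature variance of `delta2_hat` is numerically zero
#' the inverse-gamma moments are undefined; shrinkage is then skipped for
#' that batch (`gamma* = gamma_hat`, `delta* = delta_hat`) and recorded.
#' With a single batch the model is a no-op by construction
#' (`gamma* = 0`, `delta* = 1`): there is no second batch to harmonise
#' toward.
#'
#' @param study a [study_data()] object.
#' @param batch_key session column holding the batch label (default
#'   `"scanner_id"`).
#' @param covariates subset of `c("age", "sex")` to preserve.
#' @param fit_sessions `"all"` (default) fits on every session;
#'   `"primary"` fits on `repeat_index` 0 sessions only.
#' @param eb set `FALSE` to disable empirical-Bayes shrinkage entirely
#'   (batch effects used as estimated).
#' @param scale_divisor divisor convention for the per-batch scale
#'   estimate `delta2_hat`: `"population"` (default, divisor `n_b`,
#'   consistent with the divisor-N pooled variance — makes the non-EB
#'   adjustment exactly idempotent and the single-batch fit an exact
#'   identity) or `"sample"` (divisor `n_b - 1`, the convention of the
#'   reference neuroimaging ComBat implementations).
#' @param tol,max_iter convergence control for the EB iterations.
#' @return A `combat_model` list (estimates, hyperpriors, iteration
#'   counts, covariate encoding).
#' @export
fit_combat <- function(study, batch_key = "scanner_id",
                       covariates = c("age", "sex"),
                       fit_sessions = c("all", "primary"),
                       eb = TRUE,
                       scale_divisor = c("population", "sample"),
                       tol = 1e-4, max_iter = 100L) {
  validate_study(study)
  fit_sessions <- match.arg(fit_sessions)
  scale_divisor <- match.arg(scale_divisor)
  if (length(covariates) > 0L) {
    bad <- setdiff(covariates, c("age", "sex"))
    if (length(bad) > 0L)
      stop("unsupported covariate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    covariates <- unique(covariates)
  } else covariates <- character(0)
  ses <- study$sessions
  keep <- if (fit_sessions == "primary") ses$repeat_index == 0L else
    rep(TRUE, nrow(ses))
  ses <- ses[keep, , drop = FALSE]
  y <- study$idps[keep, , drop = FALSE]
  if (anyNA(y))
    stop("ComBat requires a complete feature table (no NA)", call. = FALSE)
  batch <- as.character(ses[[batch_key]])
  batches <- unique(batch)
  n_per <- table(factor(batch, levels = batches))
  if (any(n_per < 2L))
    stop("every batch needs >= 2 sessions; offending: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "), call. = FALSE)
  n <- nrow(y); V <- ncol(y); B <- length(batches)

  age_center <- mean(ses$age)
  sex_levels <- sort(unique(ses$sex))
  Xc <- covariate_matrix(ses, covariates, age_center, sex_levels)
  Xb <- vapply(batches, function(b) as.numeric(batch == b), double(n))
  colnames(Xb) <- batches
  X <- cbind(Xb, Xc)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (confounded covariates?)",
         call. = FALSE)
  coefs <- solve(crossprod(X), crossprod(X, y))     # (B + p) x V
  batch_int <- coefs[seq_len(B), , drop = FALSE]
  beta_hat <- coefs[-seq_len(B), , drop = FALSE]
  w <- as.numeric(n_per) / n
  alpha_hat <- as.numeric(w %*% batch_int)          # weighted grand mean
  if (any(apply(y, 2, sd) == 0))
    stop("constant feature(s) present; remove before fitting",
         call. = FALSE)

  fitted_full <- X %*% coefs
  var_pooled <- colSums((y - fitted_full)^2) / n    # divisor N
  stand_mean <- matrix(alpha_hat, n, V, byrow = TRUE) +
    (if (ncol(Xc) > 0) Xc %*% beta_hat else 0)
  z <- (y - stand_mean) / matrix(sqrt(var_pooled), n, V, byrow = TRUE)

  gamma_hat <- matrix(NA_real_, B, V, dimnames = list(batches, colnames(y)))
  delta2_hat <- gamma_hat
  for (b in seq_len(B)) {
    zb <- z[batch == batches[b], , drop = FALSE]
    gamma_hat[b, ] <- colMeans(zb)
    d2 <- apply(zb, 2, var)
    if (scale_divisor == "population")
      d2 <- d2 * (nrow(zb) - 1) / nrow(zb)
    delta2_hat[b, ] <- d2
  }

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  priors <- data.frame(batch = batches, gamma_bar = NA_real_,
                       tau2_bar = NA_real_, a = NA_real_, b = NA_real_,
                       eb = FALSE, iterations = 0L,
                       stringsAsFactors = FALSE)
  if (B == 1L) {
    gamma_star[1, ] <- 0
    delta2_star[1, ] <- 1
  } else if (eb) {
    for (b in seq_len(B)) {
      g_hat <- gamma_hat[b, ]; d2_hat <- delta2_hat[b, ]
      m <- mean(d2_hat); s2 <- var(d2_hat)
      if (!is.finite(s2) || s2 < 1e-12 * max(m^2, 1)) next  # EB skipped
      g_bar <- mean(g_hat); t2 <- var(g_hat)
      a_b <- (2 * s2 + m^2) / s2
      b_b <- (m * s2 + m^3) / s2
      nb <- as.numeric(n_per[b])
      zb <- z[batch == batches[b], , drop = FALSE]
      g_old <- g_hat; d_old <- d2_hat
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (nb * t2 * g_hat + d_old * g_bar) / (nb * t2 + d_old)
        sum2 <- colSums((zb - matrix(g_new, nb, V, byrow = TRUE))^2)
        d_new <- (b_b + 0.5 * sum2) / (nb / 2 + a_b - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
        g_old <- g_new; d_old <- d_new
        if (change < tol || it >= max_iter) break
      }
      gamma_star[b, ] <- g_old
      delta2_star[b, ] <- d_old
      priors[b, c("gamma_bar", "tau2_bar", "a", "b")] <-
        c(g_bar, t2, a_b, b_b)
      priors$eb[b] <- TRUE
      priors$iterations[b] <- it
    }
  }
  if (any(delta2_star <= 0))
    stop("non-positive posterior scale; data degenerate", call. = FALSE)

  structure(list(features = colnames(y), batches = batches,
                 batch_key = batch_key, n_per_batch = n_per,
                 covariates = covariates, age_center = age_center,
                 sex_levels = sex_levels, scale_divisor = scale_divisor,
                 alpha_hat = setNames(alpha_hat, colnames(y)),
                 beta_hat = beta_hat, var_pooled = var_pooled,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 priors = priors),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("combat_model:", length(x$features), "features,",
      length(x$batches), "batch(es); covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "none", "\n")
  cat("  EB shrinkage applied in", sum(x$priors$eb), "of",
      length(x$batches), "batches\n")
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Removes the estimated batch location/scale effects:
#' `y* = sigma * (z - gamma*_b) / delta*_b + alpha + x beta`, re-adding
#' the fitted covariate signal. The adjustment is a strictly increasing
#' affine map per (feature, batch), so within-batch subject orderings are
#' preserved exactly.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param study a [study_data()] whose features match the model; sessions
#'   may be any subset/superset rows with known batch labels.
#' @return A harmonised copy of `study` (metadata untouched).
#' @export
apply_combat <- function(model, study) {
  stopifnot(inherits(model, "combat_model"))
  validate_study(study)
  y <- study$idps
  if (!identical(colnames(y), model$features))
    stop("feature columns do not match the fitted model", call. = FALSE)
  batch <- as.character(study$sessions[[model$batch_key]])
  unseen <- setdiff(batch, model$batches)
  if (length(unseen) > 0L)
    stop("unseen batch label(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  n <- nrow(y); V <- ncol(y)
  Xc <- covariate_matrix(study$sessions, model$covariates,
                         model$age_center, model$sex_levels)
  stand_mean <- matrix(model$alpha_hat, n, V, byrow = TRUE) +
    (if (ncol(Xc) > 0) Xc %*% model$beta_hat else 0)
  sig <- matrix(sqrt(model$var_pooled), n, V, byrow = TRUE)
  z <- (y - stand_mean) / sig
  bi <- match(batch, model$batches)
  z_adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star[bi, , drop = FALSE])
  out <- study
  out$idps <- z_adj * sig + stand_mean
  dimnames(out$idps) <- dimnames(y)
  out
}

#' Fit and apply CovBat
#'
#' CovBat extends ComBat to batch effects in the covariance structure:
#' after the ComBat location/scale adjustment, the covariate-adjusted
#' residuals are decomposed into principal components across features,
#' and each retained component's score series is given a plain per-batch
#' location/scale standardisation (no shrinkage — each score is a single
#' "feature"), before reconstruction and re-adding the fitted mean
#' structure.
#'
#' @inheritParams fit_combat
#' @param variance_fraction retain the smallest number of components
#'   whose cumulative explained variance reaches this fraction, in
#'   (0, 1] (default 0.95).
#' @return list with `model` (class `covbat_model`: the inner
#'   `combat_model`, rotation, centre, retained `K`, explained variance)
#'   and `study` (the harmonised copy).
#' @export
fit_apply_covbat <- function(study, batch_key = "scanner_id",
                             covariates = c("age", "sex"),
                             variance_fraction = 0.95,
                             fit_sessions = c("all", "primary"),
                             eb = TRUE, tol = 1e-4, max_iter = 100L) {
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]", call. = FALSE)
  cb <- fit_combat(study, batch_key = batch_key, covariates = covariates,
                   fit_sessions = fit_sessions, eb = eb, tol = tol,
                   max_iter = max_iter)
  harmonised <- apply_combat(cb, study)
  y <- harmonised$idps
  n <- nrow(y); V <- ncol(y)
  Xc <- covariate_matrix(study$sessions, cb$covariates, cb$age_center,
                         cb$sex_levels)
  stand_mean <- matrix(cb$alpha_hat, n, V, byrow = TRUE) +
    (if (ncol(Xc) > 0) Xc %*% cb$beta_hat else 0)
  resid <- y - stand_mean

  pc <- prcomp(resid, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  K <- which(cum >= variance_fraction - 1e-9)[1]
  if (is.na(K)) K <- length(ev)
  K <- min(K, sum(ev > 1e-12 * ev[1]))   # never keep null components
  scores <- pc$x
  batch <- as.character(study$sessions[[batch_key]])
  batches <- unique(batch)
  n_per <- table(factor(batch, levels = batches))

  adj <- data.frame()
  for (j in seq_len(K)) {
    s <- scores[, j]
    m_b <- tapply(s, factor(batch, levels = batches), mean)
    grand <- sum(as.numeric(n_per) / n * m_b)
    pooled <- sqrt(sum((s - m_b[batch])^2) / n)
    zj <- (s - grand) / pooled
    g_b <- tapply(zj, factor(batch, levels = batches), mean)
    d_b <- sqrt(tapply(zj, factor(batch, levels = batches), var))
    scores[, j] <- pooled * (zj - g_b[batch]) / d_b[batch] + grand
    adj <- rbind(adj, data.frame(component = j, batch = batches,
                                 location = as.numeric(g_b),
                                 scale = as.numeric(d_b),
                                 stringsAsFactors = FALSE))
  }
  resid_adj <- scores %*% t(pc$rotation) +
    matrix(pc$center, n, V, byrow = TRUE)
  out <- harmonised
  out$idps <- resid_adj + stand_mean
  dimnames(out$idps) <- dimnames(y)
  model <- structure(list(combat = cb, rotation = pc$rotation,
                          center = pc$center, K = K,
                          variance_fraction = variance_fraction,
                          explained = cum, score_adjust = adj),
                     class = "covbat_model")
  list(model = model, study = out)
}

#' Paired pre/post harmonisation evaluation
#'
#' Runs the three-baseline CoV profile and the subject-ranking
#' consistency on a study before and after harmonisation and pairs the
#' results per IDP: the harmonisation question is whether the
#' between-scanner CoV moves down to the within-scanner baseline while
#' subject ranking is left intact.
#'
#' @param before,after `study_data` objects over identical sessions.
#' @param vendor optional vendor label for a single-vendor ranking
#'   subset (defaults to the vendor with the most scanners, when it has
#'   at least two).
#' @return list with `cov_before`, `cov_after` (reliability reports),
#'   `delta` (per-IDP changes), `ranking_before`, `ranking_after` (and
#'   `_vendor` variants), and a one-row `summary` data.frame with the
#'   median between/within CoV ratios and median ranking consistencies
#'   pre/post.
#' @export
evaluate_harmonisation <- function(before, after, vendor = NULL) {
  validate_study(before); validate_study(after)
  if (!identical(before$sessions$session_id, after$sessions$session_id) ||
      !identical(dim(before$idps), dim(after$idps)))
    stop("before/after studies must cover identical sessions and features",
         call. = FALSE)
  cov_b <- class_cov_profile(before)
  cov_a <- class_cov_profile(after)
  delta <- data.frame(
    idp_name = cov_b$idp_name,
    d_cov_between = cov_a$cov_between_scanner - cov_b$cov_between_scanner,
    d_cov_within = cov_a$cov_within_scanner - cov_b$cov_within_scanner,
    ratio_before = cov_b$cov_between_scanner / cov_b$cov_within_scanner,
    ratio_after = cov_a$cov_between_scanner / cov_a$cov_within_scanner,
    stringsAsFactors = FALSE)
  rank_b <- ranking_consistency(before)
  rank_a <- ranking_consistency(after)

  ses <- before$sessions
  if (is.null(vendor)) {
    per_vendor <- tapply(ses$scanner_id, ses$vendor,
                         function(x) length(unique(x)))
    if (max(per_vendor) >= 2L) vendor <- names(which.max(per_vendor))
  }
  rank_bv <- rank_av <- NULL
  if (!is.null(vendor)) {
    subset <- unique(ses$scanner_id[ses$vendor == vendor])
    if (length(subset) >= 2L) {
      rank_bv <- ranking_consistency(before, subset)
      rank_av <- ranking_consistency(after, subset)
    }
  }
  med <- function(x) median(x[!is.na(x)])
  summary <- data.frame(
    median_ratio_before = med(delta$ratio_before),
    median_ratio_after = med(delta$ratio_after),
    median_cov_between_before = med(cov_b$cov_between_scanner),
    median_cov_between_after = med(cov_a$cov_between_scanner),
    median_cov_within_before = med(cov_b$cov_within_scanner),
    median_rank_before = med(rank_b$per_idp$median_Q),
    median_rank_after = med(rank_a$per_idp$median_Q),
    median_rank_vendor_before =
      if (is.null(rank_bv)) NA_real_ else med(rank_bv$per_idp$median_Q),
    median_rank_vendor_after =
      if (is.null(rank_av)) NA_real_ else med(rank_av$per_idp$median_Q))
  list(cov_before = cov_b, cov_after = cov_a, delta = delta,
       ranking_before = rank_b, ranking_after = rank_a,
       ranking_vendor_before = rank_bv, ranking_vendor_after = rank_av,
       summary = summary)
}
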