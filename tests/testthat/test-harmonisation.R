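test_that("a single-batch fit is an identity map", {
  study <- shift_study(shift = 0)
  keep <- study$sessions$scanner_id == "A"
  one <- study_data(study$sessions[keep, ], study$idps[keep, ],
                    study$categories)
  m <- fit_combat(one, covariates = character(0))
  expect_equal(unname(m$gamma_star[1, ]), rep(0, ncol(one$idps)))
  expect_equal(unname(m$delta2_star[1, ]), rep(1, ncol(one$idps)))
  out <- apply_combat(m, one)
  expect_equal(out$idps, one$idps, tolerance = 1e-8)
})

test_that("a pure location shift is estimated and removed", {
  shift <- 4
  study <- shift_study(shift = shift)
  m <- fit_combat(study, covariates = character(0))
  # estimated location offsets differ by ~ shift in standardised units
  diff_gamma <- (m$gamma_star["B", ] - m$gamma_star["A", ]) *
    sqrt(m$var_pooled)
  expect_equal(unname(diff_gamma), rep(shift, ncol(study$idps)),
               tolerance = 0.05)
  out <- apply_combat(m, study)
  a <- out$idps[study$sessions$scanner_id == "A", ]
  b <- out$idps[study$sessions$scanner_id == "B", ]
  gap <- abs(colMeans(b) - colMeans(a))
  expect_true(all(gap < 1e-6 * apply(study$idps, 2, sd)))
})

test_that("the whole-cohort feature means are preserved", {
  study <- shift_study()
  m <- fit_combat(study, covariates = c("age", "sex"))
  out <- apply_combat(m, study)
  expect_equal(colMeans(out$idps), colMeans(study$idps), tolerance = 1e-6)
})

test_that("harmonisation is idempotent and preserves within-batch ranking", {
  sim <- small_simulation(seed = 6)
  study <- sim$study
  # the location/scale adjustment map itself is exactly idempotent
  m0 <- fit_combat(study, covariates = character(0), eb = FALSE)
  once0 <- apply_combat(m0, study)
  twice0 <- apply_combat(fit_combat(once0, covariates = character(0),
                                    eb = FALSE), once0)
  expect_lt(max(abs(twice0$idps - once0$idps)) / max(abs(once0$idps)),
            1e-6)
  # with empirical-Bayes shrinkage, re-harmonisation only nudges values:
  # each pass shrinks the remaining (already small) batch deviations
  m <- fit_combat(study, covariates = character(0))
  once <- apply_combat(m, study)
  m2 <- fit_combat(once, covariates = character(0))
  twice <- apply_combat(m2, once)
  scale <- max(abs(once$idps))
  expect_lt(max(abs(twice$idps - once$idps)) / scale, 0.05)
  expect_lt(max(abs(twice$idps - once$idps)),
            0.5 * max(abs(once$idps - study$idps)))
  # affine per (batch, feature): within-batch orderings bit-identical
  for (b in unique(study$sessions$scanner_id)) {
    rows <- study$sessions$scanner_id == b
    pre <- apply(study$idps[rows, ], 2, rank)
    post <- apply(once$idps[rows, ], 2, rank)
    expect_identical(pre, post)
  }
})

test_that("contract violations are rejected", {
  study <- shift_study()
  ses1 <- study$sessions[c(1:12, 13), ]
  ses1$scanner_id[13] <- "C"   # a batch of size 1
  s1 <- study_data(ses1, study$idps[ses1$session_id, ], study$categories)
  expect_error(fit_combat(s1), "batch")
  idps <- study$idps; idps[, 1] <- 3
  s2 <- study_data(study$sessions, idps, study$categories)
  expect_error(fit_combat(s2), "constant")
  m <- fit_combat(study)
  other <- study
  other$sessions$scanner_id[1] <- "Z"
  other$sessions$session_id[1] <- "z_Z_rep0"
  rownames(other$idps)[1] <- "z_Z_rep0"
  expect_error(apply_combat(m, other), "unseen batch")
  idps_na <- study$idps; idps_na[1, 1] <- NA
  s3 <- study_data(study$sessions, idps_na, study$categories)
  expect_error(fit_combat(s3), "complete")
})

test_that("our ComBat agrees with the sva reference implementation", {
  sim <- small_simulation(seed = 12)
  study <- sim$study
  # sample-divisor mode reproduces the reference algorithm exactly
  m <- fit_combat(study, covariates = c("age", "sex"),
                  scale_divisor = "sample")
  ours <- apply_combat(m, study)
  mod <- stats::model.matrix(~ age + factor(sex, levels = c("M", "F")),
                             data = study$sessions)
  theirs <- t(sva::ComBat(dat = t(study$idps),
                          batch = study$sessions$scanner_id,
                          mod = mod, par.prior = TRUE))
  expect_equal(unname(ours$idps), unname(theirs), tolerance = 1e-6)
  # the population-divisor default differs from the reference only by a
  # per-batch rescale of the standardised residuals
  mp <- fit_combat(study, covariates = c("age", "sex"))
  ours_pop <- apply_combat(mp, study)
  expect_equal(unname(ours_pop$idps), unname(theirs), tolerance = 0.05)
  for (v in seq_len(ncol(study$idps)))
    expect_gt(cor(ours_pop$idps[, v], theirs[, v]), 0.999)
})

test_that("estimated scanner offsets recover the generative truth", {
  sim <- preset_cache(1)
  study <- sim$study
  m <- fit_combat(study, fit_sessions = "primary")
  est <- m$gamma_star * matrix(sqrt(m$var_pooled), nrow(m$gamma_star),
                               ncol(m$gamma_star), byrow = TRUE)
  n_primary <- table(study$sessions$scanner_id[
    study$sessions$repeat_index == 0L])
  truth <- batch_centred_effects(sim$truth$gamma, n_primary)
  expect_gte(cor(as.vector(est[rownames(truth), ]), as.vector(truth)),
             0.9)
})

test_that("covariate-preserving ComBat leaves age and sex effects intact", {
  # age effects sized to dominate the (small) residual subject variance,
  # so per-feature slope estimates are informative
  spec <- small_simulation(seed = 1)$spec
  config <- simulation_config(
    n_idps_per_category = c(ca = 20L, cb = 20L),
    beta_age_range = c(-2, 2), tau_range = c(1, 2), seed = 15)
  sim <- simulate_idps(build_design(spec), config)
  study <- sim$study
  m <- fit_combat(study, covariates = c("age", "sex"))
  out <- apply_combat(m, study)
  # the fitted age slope should track the generative one
  expect_gt(cor(m$beta_hat["age", ], config$beta_age), 0.9)
  # and the harmonised data should retain it: refit per feature
  age_c <- study$sessions$age - mean(study$sessions$age)
  slopes <- apply(out$idps, 2, function(y) coef(lm(y ~ age_c))[2])
  expect_gt(cor(slopes, config$beta_age), 0.9)
})

test_that("CovBat is a near no-op when batches do not differ", {
  study <- shift_study(shift = 0)
  res <- fit_apply_covbat(study, covariates = character(0))
  scale <- max(abs(study$idps))
  expect_lt(max(abs(res$study$idps - study$idps)) / scale, 0.02)
  expect_error(fit_apply_covbat(study, variance_fraction = 0),
               "variance_fraction")
  expect_error(fit_apply_covbat(study, variance_fraction = 1.2),
               "variance_fraction")
})

test_that("q = 1 retains every non-degenerate component", {
  sim <- small_simulation(seed = 11, n_idps = 40L)
  res <- fit_apply_covbat(sim$study, covariates = character(0),
                          variance_fraction = 1)
  # n sessions < n features: centred residuals have rank n - 1
  expect_equal(res$model$K, nrow(sim$study$idps) - 1L)
})

test_that("CovBat equalises a constructed batch covariance difference", {
  n <- 24L; V <- 30L
  subjects <- sprintf("r%02d", seq_len(n))
  ses <- data.frame(
    session_id = c(paste0(subjects, "_A_rep0"),
                   paste0(subjects, "_B_rep0")),
    subject_id = rep(subjects, 2),
    scanner_id = rep(c("A", "B"), each = n),
    site = "x", vendor = "v", repeat_index = 0L,
    age = 30, sex = "M", stringsAsFactors = FALSE)
  dirn <- rep(1 / sqrt(V), V)
  noise <- withr::with_seed(31, matrix(rnorm(2 * n * V, sd = 0.5),
                                       2 * n, V))
  scoresA <- withr::with_seed(32, rnorm(n, sd = 6))   # strong first PC
  scoresB <- withr::with_seed(33, rnorm(n, sd = 2))   # variance ratio 9:1
  idps <- 100 + outer(c(scoresA, scoresB), dirn) + noise
  dimnames(idps) <- list(ses$session_id, sprintf("f%02d", seq_len(V)))
  cats <- data.frame(idp_name = colnames(idps), category = "c1",
                     group = "g", modality = "T1w",
                     stringsAsFactors = FALSE)
  study <- study_data(ses, idps, cats)
  res <- fit_apply_covbat(study, covariates = character(0),
                          variance_fraction = 0.5)
  proj_post <- res$study$idps %*% dirn
  vA <- var(proj_post[ses$scanner_id == "A"])
  vB <- var(proj_post[ses$scanner_id == "B"])
  expect_lt(abs(vA / vB - 1), 0.1)
  # before harmonisation the ratio was ~ (16 + noise) / (4 + noise)
  proj_pre <- study$idps %*% dirn
  expect_gt(var(proj_pre[ses$scanner_id == "A"]) /
              var(proj_pre[ses$scanner_id == "B"]), 2.5)
})

test_that("evaluate_harmonisation pairs reports and zeroes out on identity", {
  sim <- small_simulation(seed = 18)
  study <- sim$study
  ev <- evaluate_harmonisation(study, study)
  expect_true(all(ev$delta$d_cov_between == 0, na.rm = TRUE))
  expect_true(all(ev$delta$d_cov_within == 0, na.rm = TRUE))
  expect_equal(ev$summary$median_rank_before, ev$summary$median_rank_after)
  m <- fit_combat(study, covariates = character(0),
                  fit_sessions = "primary")
  out <- apply_combat(m, study)
  ev2 <- evaluate_harmonisation(study, out)
  # between-scanner CoV drops for the vast majority of IDPs
  expect_gte(mean(ev2$delta$d_cov_between < 0, na.rm = TRUE), 0.9)
  drop <- nrow(study$sessions)   # a primary session without repeats
  bad <- study_data(study$sessions[-drop, ], study$idps[-drop, ],
                    study$categories, iqms = study$iqms[-drop, ])
  expect_error(evaluate_harmonisation(study, bad), "identical sessions")
})
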