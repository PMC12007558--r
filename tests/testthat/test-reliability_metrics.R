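test_that("coefficient_of_variation handles the canonical cases", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)  # sd 1, mean 2
  expect_true(is.na(coefficient_of_variation(c(1, -1))))   # mean ~ 0
  expect_true(is.na(coefficient_of_variation(c(3, NA))))   # < 2 values
  expect_equal(coefficient_of_variation(c(1, 2, 3), ddof = 0),
               sqrt(2 / 3) / 2)
  expect_equal(coefficient_of_variation(c(-9, -11)),
               coefficient_of_variation(c(9, 11)))  # absolute mean
})

test_that("class_cov_profile reproduces hand-computed toy values", {
  study <- toy_study()
  # force a clean hand computation on i1:
  #   s1 on A: repeats 9, 11 -> within CoV = sd(9,11)/10 = sqrt(2)/10
  #   s1 primaries: A 9, B 10; s2: 30, 31; s3: 50, 51
  idps <- study$idps
  idps[, "i1"] <- c(9, 11, 10, 30, 31, 50, 51)
  study <- study_data(study$sessions, idps, study$categories)
  rep <- class_cov_profile(study)
  r1 <- rep[rep$idp_name == "i1", ]
  expect_equal(r1$cov_within_scanner, sqrt(2) / 10)
  expect_equal(r1$cov_between_scanner,
               mean(c(sd(c(9, 10)) / mean(c(9, 10)),
                      sd(c(30, 31)) / mean(c(30, 31)),
                      sd(c(50, 51)) / mean(c(50, 51)))))
  expect_equal(r1$cov_biological,
               mean(c(sd(c(9, 30, 50)) / mean(c(9, 30, 50)),
                      sd(c(10, 31, 51)) / mean(c(10, 31, 51)))))
  expect_equal(r1$relative_difference_pct,
               100 * (r1$cov_between_scanner - r1$cov_within_scanner) /
                 r1$cov_within_scanner)
})

test_that("identical values across scanners give zero between-scanner CoV", {
  study <- toy_study()
  idps <- study$idps
  idps[, ] <- rep(c(10, 10, 10, 20, 20, 30, 30), 4)  # constant per subject
  study <- study_data(study$sessions, idps, study$categories)
  rep <- class_cov_profile(study)
  expect_true(all(rep$cov_between_scanner == 0))
  expect_true(all(rep$cov_within_scanner == 0))
  expect_true(all(rep$cov_biological > 0))
})

test_that("a design without repeats warns and leaves within CoV missing", {
  study <- toy_study()
  keep <- study$sessions$repeat_index == 0L
  ses <- study$sessions[keep, ]
  study2 <- study_data(ses, study$idps[keep, ], study$categories)
  expect_warning(rep <- class_cov_profile(study2), "within-scanner")
  expect_true(all(is.na(rep$cov_within_scanner)))
  expect_false(all(is.na(rep$cov_between_scanner)))
})

test_that("relative_difference follows its definition", {
  expect_equal(relative_difference(0.02, 0.02), 0)
  expect_equal(relative_difference(0.06, 0.02), 200)
  expect_equal(relative_difference(0.01, 0.02), -50)
  expect_true(is.na(relative_difference(0.01, 0)))
  expect_true(is.na(relative_difference(NA, 0.02)))
})

test_that("scanner bias matches a spreadsheet-style hand computation", {
  study <- toy_study()
  idps <- study$idps
  # s1 within-scanner set on A: 100, 100 -> mean 100
  # s1 primaries: A 100, B 120 -> between mean 110 -> bias +10%
  idps[, "i1"] <- c(100, 100, 120, 1, 1, 1, 1)
  idps[, "i2"] <- c(50, 70, 90, 2, 2, 2, 2)   # within 60, between 70
  study <- study_data(study$sessions, idps, study$categories)
  bias <- scanner_bias(study)
  expect_equal(bias$per_subject$bias_pct[
    bias$per_subject$idp_name == "i1"], 10)
  expect_equal(bias$per_subject$bias_pct[
    bias$per_subject$idp_name == "i2"],
    100 * (mean(c(50, 90)) - 60) / 60)
  # identical data everywhere -> zero bias
  idps[, ] <- 7
  expect_error(study_data(study$sessions, idps, study$categories), NA)
  b0 <- scanner_bias(study_data(study$sessions, idps, study$categories))
  expect_true(all(b0$group$bias_pct == 0))
  # vendor restriction: only scanner B is V2, so between mean = B's value
  bV2 <- scanner_bias(study, vendor = "V2")
  expect_equal(bV2$vendor_group$bias_pct[
    bV2$vendor_group$idp_name == "i1"], 100 * (120 - 100) / 100)
})

test_that("group aggregation matches hand results and singleton identity", {
  study <- toy_study()
  rep <- class_cov_profile(study)
  agg_mean <- aggregate_by_group(rep, study$categories, "mean")
  g1 <- rep$cov_within_scanner[rep$idp_name %in% c("i1", "i2")]
  expect_equal(agg_mean$cov_within_scanner[agg_mean$group == "g1"],
               mean(g1))
  agg_med <- aggregate_by_group(rep, study$categories, "median")
  expect_equal(agg_med$cov_within_scanner[agg_med$group == "g1"],
               median(g1))
  # singleton groups reproduce the per-IDP report
  cats <- study$categories
  cats$group <- cats$idp_name
  agg_single <- aggregate_by_group(rep, cats, "mean")
  expect_equal(agg_single$cov_between_scanner[
    match(rep$idp_name, agg_single$group)], rep$cov_between_scanner)
  # all-missing group stays missing
  rep2 <- rep
  rep2$cov_within_scanner[rep2$idp_name %in% c("i3", "i4")] <- NA
  agg2 <- aggregate_by_group(rep2, study$categories, "mean")
  expect_true(is.na(agg2$cov_within_scanner[agg2$group == "g2"]))
  expect_error(aggregate_by_group(rep, study$categories[1:3, ], "mean"),
               "missing from the category map")
})

test_that("CoV-based reports are invariant under positive scaling", {
  sim <- small_simulation(seed = 8, n_idps = 6L)
  study <- sim$study
  r1 <- class_cov_profile(study)
  study2 <- study
  study2$idps <- sweep(study2$idps, 2, c(2, 5, 0.1, 40, 7, 1), "*")
  r2 <- class_cov_profile(study2)
  expect_equal(r2$cov_within_scanner, r1$cov_within_scanner)
  expect_equal(r2$cov_between_scanner, r1$cov_between_scanner)
  expect_equal(r2$relative_difference_pct, r1$relative_difference_pct)
})

test_that("IQM z-scores average to zero and flag constructed outliers", {
  sim <- small_simulation(seed = 4)
  study <- sim$study
  z <- zscore_iqms(study, "across_scanners")
  # each (IQM, subject) z-scores to mean 0 across scanners, so the
  # subject-averaged columns must also average to ~0 across scanners
  expect_true(all(abs(colMeans(z)) < 1e-10))
  zt <- zscore_iqms(study, "across_subjects")
  expect_true(all(abs(colMeans(zt)) < 1e-10))
  expect_equal(dim(zt), c(length(unique(study$sessions$subject_id)),
                          ncol(study$iqms)))
  # affine rescaling of an IQM column changes nothing
  study2 <- study
  study2$iqms[, 2] <- 100 - 3 * study2$iqms[, 2]
  z2 <- zscore_iqms(study2, "across_scanners")
  expect_equal(abs(z2[, 2]), abs(z[, 2]))
  expect_equal(z2[, -2], z[, -2])
  # constant IQM -> missing, not zero
  study3 <- study
  study3$iqms[, 1] <- 5
  z3 <- zscore_iqms(study3, "across_scanners")
  expect_true(all(is.na(z3[, 1])))
})

test_that("within-scanner repeats are excluded from IQM z-scoring", {
  sim <- small_simulation(seed = 4)
  study <- sim$study
  z_before <- zscore_iqms(study, "across_scanners")
  study2 <- study
  study2$iqms[study2$sessions$repeat_index > 0L, ] <- 1e6
  expect_equal(zscore_iqms(study2, "across_scanners"), z_before)
})

test_that("edge selection ranks by absolute mean over repeat sessions", {
  ses <- toy_sessions()
  edges <- sprintf("fc_edge_%02d", 1:10)
  idps <- matrix(0.01, nrow = 7, ncol = 10,
                 dimnames = list(ses$session_id, edges))
  # repeat sessions of s1 on A are rows 1-2: set the selection means there
  means <- c(0.9, -0.8, 0.1, 0.05, -0.02, 0.3, -0.4, 0.2, 0.15, -0.25)
  idps[1, ] <- means; idps[2, ] <- means
  cats <- data.frame(idp_name = edges, category = "fc_edges",
                     group = "fc", modality = "rfMRI",
                     stringsAsFactors = FALSE)
  study <- study_data(ses, idps, cats)
  expect_equal(select_top_edges(study, "fc_edges", fraction = 0.2),
               sort(edges[c(1, 2)]))   # |0.9| and |-0.8| win
  expect_equal(length(select_top_edges(study, "fc_edges", 0.05)), 1)
  expect_equal(select_top_edges(study, "fc_edges", k_override = 10),
               sort(edges))
  expect_error(select_top_edges(study, "fc_edges", k_override = 11),
               "only 10")
  # deterministic tie-break by name
  idps[1:2, ] <- rep(c(0.5, 0.5, 0.1), length.out = 10)
  study2 <- study_data(ses, idps, cats)
  expect_equal(select_top_edges(study2, "fc_edges", k_override = 1),
               "fc_edge_01")
})
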