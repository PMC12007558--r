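# Shared fixtures and independent oracles, all built in code.

# Brute-force Spearman oracle: average-rank transform, then the Pearson
# product-moment formula. Kept deliberately naive and separate from the
# package's primitive.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Minimal hand-built study: 3 subjects x 2 scanners (+1 repeat), 4 IDPs
# in 2 categories. Values chosen so hand computations stay tractable.
toy_sessions <- function() {
  data.frame(
    session_id = c("s1_A_rep0", "s1_A_rep1", "s1_B_rep0",
                   "s2_A_rep0", "s2_B_rep0", "s3_A_rep0", "s3_B_rep0"),
    subject_id = c("s1", "s1", "s1", "s2", "s2", "s3", "s3"),
    scanner_id = c("A", "A", "B", "A", "B", "A", "B"),
    site = c("x", "x", "y", "x", "y", "x", "y"),
    vendor = c("V1", "V1", "V2", "V1", "V2", "V1", "V2"),
    repeat_index = c(0L, 1L, 0L, 0L, 0L, 0L, 0L),
    age = c(30, 30, 30, 40, 40, 25, 25),
    sex = c("M", "M", "M", "F", "F", "M", "M"),
    stringsAsFactors = FALSE)
}

toy_categories <- function() {
  data.frame(idp_name = c("i1", "i2", "i3", "i4"),
             category = c("c1", "c1", "c2", "c2"),
             group = c("g1", "g1", "g2", "g2"),
             modality = c("T1w", "T1w", "dMRI", "dMRI"),
             stringsAsFactors = FALSE)
}

toy_study <- function(idps = NULL) {
  ses <- toy_sessions()
  if (is.null(idps)) {
    idps <- matrix(c(10, 20, 1.0, 0.5,
                     11, 21, 1.1, 0.6,
                     12, 22, 1.2, 0.7,
                     30, 40, 2.0, 1.5,
                     31, 41, 2.1, 1.6,
                     50, 60, 3.0, 2.5,
                     51, 61, 3.1, 2.6),
                   ncol = 4, byrow = TRUE,
                   dimnames = list(ses$session_id,
                                   c("i1", "i2", "i3", "i4")))
  }
  study_data(ses, idps, toy_categories())
}

# Write a study to TSVs in a temp dir; returns the file paths.
write_toy_tsvs <- function(study, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  paths <- list(sessions = file.path(dir, "sessions.tsv"),
                idps = file.path(dir, "idps.tsv"),
                categories = file.path(dir, "idp_categories.tsv"))
  write_table(study$sessions, paths$sessions)
  idps_df <- data.frame(session_id = rownames(study$idps), study$idps,
                        check.names = FALSE, stringsAsFactors = FALSE,
                        row.names = NULL)
  write_table(idps_df, paths$idps)
  write_table(study$categories, paths$categories)
  paths
}

# A small crossed design + simulation for harmonisation tests:
# ns subjects x nb scanners, optional repeats, complete IDP table.
small_simulation <- function(seed = 1, n_idps = 40L, repeats = TRUE) {
  subjects <- sprintf("p%02d", 1:8)
  scanners <- c("A", "B", "C")
  rp <- if (repeats) list(p01 = list(scanner = "A", n_extra = 3L),
                          p02 = list(scanner = "B", n_extra = 3L)) else list()
  spec <- design_spec(
    subjects, scanners, rp,
    vendor_of = c(A = "V1", B = "V1", C = "V2"),
    site_of = c(A = "sa", B = "sb", C = "sc"),
    ages = stats::setNames(seq(25, 46, by = 3), subjects),
    sexes = stats::setNames(rep(c("M", "F"), 4), subjects))
  config <- simulation_config(
    n_idps_per_category = c(ca = ceiling(n_idps / 2),
                            cb = floor(n_idps / 2)),
    seed = seed)
  sim <- simulate_idps(build_design(spec), config)
  sim$spec <- spec
  sim$config <- config
  sim
}

# A complete two-batch table with a known pure location shift on batch 2.
shift_study <- function(shift = 4, n_per_batch = 12L, n_idps = 20L,
                        seed = 2) {
  subjects <- sprintf("q%02d", seq_len(n_per_batch))
  ses <- data.frame(
    session_id = c(paste0(subjects, "_A_rep0"), paste0(subjects, "_B_rep0")),
    subject_id = rep(subjects, 2),
    scanner_id = rep(c("A", "B"), each = n_per_batch),
    site = "x", vendor = "v",
    repeat_index = 0L,
    age = rep(seq(25, 47, length.out = n_per_batch), 2),
    sex = rep(rep(c("M", "F"), length.out = n_per_batch), 2),
    stringsAsFactors = FALSE)
  base <- withr::with_seed(seed,
    matrix(rnorm(n_per_batch * n_idps, mean = 50, sd = 4),
           n_per_batch, n_idps))
  idps <- rbind(base, base + shift)
  dimnames(idps) <- list(ses$session_id, sprintf("f%02d", seq_len(n_idps)))
  cats <- data.frame(idp_name = colnames(idps),
                     category = rep(c("c1", "c2"), length.out = n_idps),
                     group = "g", modality = "T1w",
                     stringsAsFactors = FALSE)
  study_data(ses, idps, cats)
}

# One paper-scale preset simulation, computed once per test run and shared
# by the acceptance blocks (and any test needing paper-scale data).
preset_cache <- local({
  env <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) {
      pl <- preset_paper_like(seed = seed)
      sim <- simulate_idps(build_design(pl$spec), pl$config)
      sim$spec <- pl$spec
      sim$config <- pl$config
      env[[key]] <- sim
    }
    env[[key]]
  }
})
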