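#' Assemble a pipeline run configuration
#'
#' One configuration drives the whole simulate -> describe ->
#' harmonise -> evaluate pipeline. The configuration is serialised
#' verbatim into the output directory so every run is reproducible from
#' its artefacts.
#'
#' @param out_dir output directory (created if needed).
#' @param preset `"paper-like"` to simulate the built-in travelling-heads
#'   preset, or `NULL` when supplying `paths`.
#' @param paths named list of TSV paths (`sessions`, `idps`,
#'   `categories`, optionally `iqms`) for user-supplied tables.
#' @param seed integer seed for every stochastic stage.
#' @param cov_ddof sd divisor policy for CoVs (1 or 0).
#' @param between_policy `"first"` or `"mean-of-repeats"`.
#' @param edge_category connectivity-edge category name (set `NULL` to
#'   skip edge selection).
#' @param edge_fraction,edge_k edge-selection fraction and optional
#'   explicit count.
#' @param method harmonisation method: `"combat"`, `"covbat"` or
#'   `"none"`.
#' @param covariates covariates preserved by harmonisation.
#' @param fit_sessions sessions used to estimate batch effects:
#'   `"primary"` (default; the balanced one-session-per-scanner subset,
#'   so subject effects cancel exactly in batch contrasts) or `"all"`.
#'   Harmonisation is applied to every session either way.
#' @param variance_fraction CovBat retained-variance fraction.
#' @param null_draws Monte-Carlo draws for the ranking null.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, preset = "paper-like", paths = NULL,
                       seed = 1L, cov_ddof = 1,
                       between_policy = "first",
                       edge_category = "fc_edges", edge_fraction = 0.05,
                       edge_k = NULL, method = "combat",
                       covariates = c("age", "sex"),
                       fit_sessions = "primary",
                       variance_fraction = 0.95, null_draws = 10000L) {
  stopifnot(!is.null(preset) || !is.null(paths),
            method %in% c("combat", "covbat", "none"),
            fit_sessions %in% c("all", "primary"))
  structure(list(out_dir = out_dir, preset = preset, paths = paths,
                 seed = as.integer(seed), cov_ddof = cov_ddof,
                 between_policy = between_policy,
                 edge_category = edge_category,
                 edge_fraction = edge_fraction, edge_k = edge_k,
                 method = method, covariates = covariates,
                 fit_sessions = fit_sessions,
                 variance_fraction = variance_fraction,
                 null_draws = as.integer(null_draws)),
            class = "run_config")
}

write_study_tables <- function(study, dir) {
  write_table(study$sessions, file.path(dir, "sessions.tsv"))
  idps_df <- data.frame(session_id = rownames(study$idps),
                        study$idps, check.names = FALSE,
                        stringsAsFactors = FALSE, row.names = NULL)
  write_table(idps_df, file.path(dir, "idps.tsv"))
  write_table(study$categories, file.path(dir, "idp_categories.tsv"))
  if (!is.null(study$iqms)) {
    iqms_df <- data.frame(session_id = rownames(study$iqms),
                          study$iqms, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL)
    write_table(iqms_df, file.path(dir, "iqms.tsv"))
  }
}

#' Run the full evaluation pipeline
#'
#' Executes every stage against one configuration: simulate (or load)
#' the study, select connectivity edges, compute the between-session
#' similarity matrix and pair-class distributions, the three-baseline
#' CoV profile with group aggregation, scanner bias, IQM z-score
#' heatmaps, ranking consistency (all scanners and largest single-vendor
#' subset) with its simulated null, then harmonise and produce the
#' paired pre/post evaluation. Every artefact is written as TSV/JSON
#' under `config$out_dir` and listed, with an MD5 content hash, in
#' `manifest.tsv`. Identical configuration and seed give byte-identical
#' numeric artefacts.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `study`, ground `truth` (when
#'   simulated), the `evaluation` result and the `manifest` data.frame.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_out <- unclass(config)
  cfg_out$out_dir <- NULL   # implied by location; keeps runs comparable
  jsonlite::write_json(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  study <- stage("input", {
    if (!is.null(config$preset)) {
      pl <- preset_paper_like(seed = config$seed)
      sim <- simulate_idps(build_design(pl$spec), pl$config)
      truth <- sim$truth
      note("simulated preset '", config$preset, "' with seed ",
           config$seed, ": ", nrow(sim$study$sessions), " sessions x ",
           ncol(sim$study$idps), " IDPs")
      sim$study
    } else {
      p <- config$paths
      note("loaded user tables from ", p$sessions)
      load_study(p$sessions, p$idps, p$categories, iqms_path = p$iqms)
    }
  })
  write_study_tables(study, config$out_dir)
  if (!is.null(truth)) {
    write_table(truth$gamma, file.path(config$out_dir,
                                       "ground_truth_gamma.tsv"),
                rowname_col = "scanner_id")
    write_table(truth$delta, file.path(config$out_dir,
                                       "ground_truth_delta.tsv"),
                rowname_col = "scanner_id")
  }

  keep_idps <- NULL
  if (!is.null(config$edge_category) &&
      config$edge_category %in% study$categories$category) {
    edges <- stage("edge_selection",
      select_top_edges(study, config$edge_category,
                       fraction = config$edge_fraction,
                       k_override = config$edge_k))
    keep_idps <- setNames(list(edges), config$edge_category)
    writeLines(edges, file.path(config$out_dir, "retained_edges.txt"))
    note("edge selection: kept ", length(edges), " of ",
         sum(study$categories$category == config$edge_category),
         " edges in '", config$edge_category, "'")
  }

  stage("similarity", {
    cc <- category_correlation_matrices(study, keep_idps = keep_idps)
    sim <- similarity_matrix(cc)
    write_table(sim$P, file.path(config$out_dir, "P.tsv"),
                rowname_col = "session_id")
    for (cm in names(cc))
      write_table(cc[[cm]], file.path(config$out_dir,
                                      paste0("R_", cm, ".tsv")),
                  rowname_col = "session_id")
    pairs <- classify_pairs(study$sessions)
    write_table(pairs, file.path(config$out_dir, "pair_classes.tsv"))
    dist <- pair_class_distributions(sim, pairs)
    write_table(dist$summary,
                file.path(config$out_dir, "class_distributions.tsv"))
    note("similarity: ", nrow(pairs), " session pairs in ",
         length(cc), " categories")
  })

  stage("reliability", {
    rep <- class_cov_profile(study, ddof = config$cov_ddof,
                             between_policy = config$between_policy)
    write_table(rep, file.path(config$out_dir, "reliability_report.tsv"))
    write_table(aggregate_by_group(rep, study$categories, "mean"),
                file.path(config$out_dir, "reliability_groups_mean.tsv"))
    write_table(aggregate_by_group(rep, study$categories, "median"),
                file.path(config$out_dir, "reliability_groups_median.tsv"))
    bias <- scanner_bias(study)
    write_table(bias$group, file.path(config$out_dir, "bias_report.tsv"))
    note("reliability: ", sum(is.na(rep$cov_between_scanner)),
         " IDPs with undefined between-scanner CoV")
  })

  if (!is.null(study$iqms)) {
    stage("iqms", {
      write_table(zscore_iqms(study, "across_scanners"),
                  file.path(config$out_dir, "iqm_z_scanner.tsv"),
                  rowname_col = "scanner_id")
      write_table(zscore_iqms(study, "across_subjects"),
                  file.path(config$out_dir, "iqm_z_subject.tsv"),
                  rowname_col = "subject_id")
    })
  } else note("IQM stage skipped: no IQM table supplied")

  stage("ranking", {
    rk <- ranking_consistency(study)
    write_table(rk$per_idp, file.path(config$out_dir, "ranking_report.tsv"))
    per_vendor <- tapply(study$sessions$scanner_id, study$sessions$vendor,
                         function(x) length(unique(x)))
    if (max(per_vendor) >= 2L) {
      vend <- names(which.max(per_vendor))
      subset <- unique(study$sessions$scanner_id[
        study$sessions$vendor == vend])
      rkv <- ranking_consistency(study, subset)
      write_table(rkv$per_idp,
                  file.path(config$out_dir, "ranking_report_vendor.tsv"))
    }
    nb <- null_baseline(length(unique(study$sessions$subject_id)),
                        n_draws = config$null_draws, seed = config$seed)
    jsonlite::write_json(nb[c("q25", "q50", "q75", "n_subjects",
                              "n_draws", "mode", "seed")],
                         file.path(config$out_dir, "null_baseline.json"),
                         auto_unbox = TRUE, digits = NA)
    note("ranking null: IQR [", round(nb$q25, 3), ", ",
         round(nb$q75, 3), "] from ", nb$n_draws, " draws")
  })

  evaluation <- NULL
  if (config$method != "none") {
    evaluation <- stage("harmonise", {
      harmonised <- if (config$method == "combat") {
        model <- fit_combat(study, covariates = config$covariates,
                            fit_sessions = config$fit_sessions)
        jsonlite::write_json(
          list(method = "combat", batches = model$batches,
               covariates = model$covariates,
               eb_batches = sum(model$priors$eb),
               iterations = model$priors$iterations),
          file.path(config$out_dir, "model.json"),
          auto_unbox = TRUE, digits = NA)
        apply_combat(model, study)
      } else {
        cv <- fit_apply_covbat(study, covariates = config$covariates,
                               fit_sessions = config$fit_sessions,
                               variance_fraction = config$variance_fraction)
        jsonlite::write_json(
          list(method = "covbat", K = cv$model$K,
               variance_fraction = cv$model$variance_fraction),
          file.path(config$out_dir, "model.json"),
          auto_unbox = TRUE, digits = NA)
        cv$study
      }
      idps_df <- data.frame(session_id = rownames(harmonised$idps),
                            harmonised$idps, check.names = FALSE,
                            stringsAsFactors = FALSE, row.names = NULL)
      write_table(idps_df,
                  file.path(config$out_dir, "harmonised_idps.tsv"))
      ev <- evaluate_harmonisation(study, harmonised)
      write_table(ev$summary,
                  file.path(config$out_dir, "evaluation_summary.tsv"))
      write_table(ev$delta,
                  file.path(config$out_dir, "evaluation_delta.tsv"))
      note("harmonisation (", config$method, "): median between/within ",
           "CoV ratio ", round(ev$summary$median_ratio_before, 2),
           " -> ", round(ev$summary$median_ratio_after, 2))
      ev
    })
  } else note("harmonisation stage skipped (method = none)")

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  files <- setdiff(list.files(config$out_dir), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE)
  write_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(study = study, truth = truth, evaluation = evaluation,
                 manifest = manifest))
}

report_panel <- function(path, plot, width = 7, height = 4.5) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
  basename(path)
}

#' Render a figure report from a pipeline output directory
#'
#' Reads the artefacts written by [run_all()] and renders a Markdown
#' report with the package's standard panels: IQM z-score heatmaps,
#' between-session similarity distributions by pair class, scanner bias
#' by IDP group, the three-CoV log-scale panel with group means and
#' relative differences, ranking consistency against the null band, and
#' the pre/post harmonisation comparison. Panels whose artefacts are
#' missing are omitted with a notice.
#'
#' @param out_dir directory produced by [run_all()].
#' @return Path to the rendered `report.md`, invisibly.
#' @export
render_report <- function(out_dir) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  md <- c("# Harmonisation benchmark report", "")
  have <- function(f) file.exists(file.path(out_dir, f))
  rd <- function(f) read_tsv_file(file.path(out_dir, f))
  add_panel <- function(title, fig, notice_when_missing = NULL) {
    if (is.null(fig)) {
      md <<- c(md, paste0("## ", title), "",
               paste0("*Panel omitted: ", notice_when_missing, "*"), "")
    } else {
      md <<- c(md, paste0("## ", title), "",
               paste0("![", title, "](figures/", fig, ")"), "")
    }
  }

  # IQM heatmaps
  if (have("iqm_z_scanner.tsv")) {
    z <- rd("iqm_z_scanner.tsv")
    long <- data.frame(
      scanner = rep(z$scanner_id, times = ncol(z) - 1),
      iqm = rep(setdiff(names(z), "scanner_id"), each = nrow(z)),
      z = unlist(z[setdiff(names(z), "scanner_id")], use.names = FALSE))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$iqm, .data$scanner,
                                            fill = .data$z)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(limits = c(-2.5, 2.5),
                                    oob = scales_squish) +
      ggplot2::labs(x = NULL, y = NULL,
                    title = "Scanner-level IQM z-scores") +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 60, hjust = 1))
    add_panel("Image quality metrics",
              report_panel(file.path(fig_dir, "iqm_z.png"), p))
  } else add_panel("Image quality metrics", NULL, "no IQM artefacts")

  # similarity distributions
  if (have("class_distributions.tsv") && have("P.tsv") &&
      have("pair_classes.tsv")) {
    P <- rd("P.tsv")
    ids <- P$session_id
    Pm <- as.matrix(P[setdiff(names(P), "session_id")])
    rownames(Pm) <- ids
    pairs <- rd("pair_classes.tsv")
    pairs$value <- Pm[cbind(match(pairs$session_a, ids),
                            match(pairs$session_b, ids))]
    p <- ggplot2::ggplot(pairs[!is.na(pairs$value), ],
                         ggplot2::aes(.data$pair_class, .data$value)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "between-session similarity (median r)",
                    title = "Session-pair similarity by class") +
      ggplot2::theme_minimal(base_size = 9)
    add_panel("Between-session similarity",
              report_panel(file.path(fig_dir, "similarity.png"), p))
  } else add_panel("Between-session similarity", NULL,
                   "similarity artefacts missing")

  # bias
  if (have("bias_report.tsv")) {
    bias <- rd("bias_report.tsv")
    bias$index <- seq_len(nrow(bias))
    p <- ggplot2::ggplot(bias, ggplot2::aes(.data$index, .data$bias_pct)) +
      ggplot2::geom_point(size = 0.5) +
      ggplot2::geom_hline(yintercept = c(-10, 0, 10), linetype = 3) +
      ggplot2::labs(x = "IDP", y = "bias (%)",
                    title = "Between- vs within-scanner mean bias") +
      ggplot2::theme_minimal(base_size = 9)
    add_panel("Scanner bias",
              report_panel(file.path(fig_dir, "bias.png"), p))
  } else add_panel("Scanner bias", NULL, "bias artefacts missing")

  # three-CoV panel
  if (have("reliability_report.tsv") && have("reliability_groups_mean.tsv")) {
    rel <- rd("reliability_report.tsv")
    rel$index <- seq_len(nrow(rel))
    long <- rbind(
      data.frame(index = rel$index, cov = rel$cov_within_scanner,
                 baseline = "within-scanner"),
      data.frame(index = rel$index, cov = rel$cov_between_scanner,
                 baseline = "between-scanner"),
      data.frame(index = rel$index, cov = rel$cov_biological,
                 baseline = "biological"))
    p <- ggplot2::ggplot(long[!is.na(long$cov), ],
                         ggplot2::aes(.data$index, .data$cov,
                                      colour = .data$baseline)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.7) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "IDP", y = "CoV (log scale)",
                    title = "Three-baseline CoV profile") +
      ggplot2::theme_minimal(base_size = 9)
    add_panel("Coefficients of variation",
              report_panel(file.path(fig_dir, "cov.png"), p))
    gm <- rd("reliability_groups_mean.tsv")
    md <- c(md, "Group-wise mean CoVs:", "", "```",
            utils::capture.output(print(gm, digits = 3)), "```", "")
  } else add_panel("Coefficients of variation", NULL,
                   "reliability artefacts missing")

  # ranking vs null
  if (have("ranking_report.tsv") && have("null_baseline.json")) {
    rk <- rd("ranking_report.tsv")
    nb <- jsonlite::read_json(file.path(out_dir, "null_baseline.json"),
                              simplifyVector = TRUE)
    rk$index <- seq_len(nrow(rk))
    p <- ggplot2::ggplot(rk[!is.na(rk$median_Q), ],
                         ggplot2::aes(.data$index, .data$median_Q)) +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = nb$q25, ymax = nb$q75,
                        fill = "red", alpha = 0.2) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::labs(x = "IDP", y = "median ranking consistency",
                    title = "Subject-ranking consistency vs null IQR") +
      ggplot2::theme_minimal(base_size = 9)
    add_panel("Ranking consistency",
              report_panel(file.path(fig_dir, "ranking.png"), p))
  } else add_panel("Ranking consistency", NULL,
                   "ranking artefacts missing")

  # pre/post harmonisation
  if (have("evaluation_delta.tsv") && have("evaluation_summary.tsv")) {
    ev <- rd("evaluation_delta.tsv")
    long <- rbind(
      data.frame(ratio = ev$ratio_before, stage = "before"),
      data.frame(ratio = ev$ratio_after, stage = "after"))
    p <- ggplot2::ggplot(long[!is.na(long$ratio), ],
                         ggplot2::aes(.data$stage, .data$ratio)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::geom_hline(yintercept = 1, linetype = 3) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = NULL, y = "between/within CoV ratio",
                    title = "Harmonisation effect on CoV ratio") +
      ggplot2::theme_minimal(base_size = 9)
    add_panel("Harmonisation pre/post",
              report_panel(file.path(fig_dir, "harmonisation.png"), p))
    es <- rd("evaluation_summary.tsv")
    md <- c(md, "Evaluation summary:", "", "```",
            utils::capture.output(print(es, digits = 3)), "```", "")
  } else add_panel("Harmonisation pre/post", NULL,
                   "no harmonisation artefacts (method = none?)")

  report_path <- file.path(out_dir, "report.md")
  writeLines(md, report_path)
  invisible(report_path)
}

# clamp out-of-range fill values instead of dropping them (local stand-in
# for scales::squish, keeping the scales package out of Imports)
scales_squish <- function(x, range = c(-2.5, 2.5)) {
  pmin(pmax(x, range[1]), range[2])
}
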