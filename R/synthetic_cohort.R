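#' Describe a travelling-heads acquisition design
#'
#' @param subjects character vector of subject ids.
#' @param scanners character vector of scanner ids.
#' @param repeat_plan named list: `subject_id -> list(scanner, n_extra)`,
#'   giving the scanner on which that subject receives extra within-scanner
#'   repeat sessions. Every subject is scanned once on every scanner
#'   regardless.
#' @param vendor_of named character vector mapping scanner id to vendor.
#' @param site_of named character vector mapping scanner id to site.
#' @param ages named numeric vector of subject ages (years).
#' @param sexes named character vector of subject sexes (`"M"`/`"F"`).
#' @return A `design_spec` list.
#' @export
design_spec <- function(subjects, scanners, repeat_plan = list(),
                        vendor_of, site_of, ages, sexes) {
  stopifnot(!anyDuplicated(subjects), !anyDuplicated(scanners),
            all(scanners %in% names(vendor_of)),
            all(scanners %in% names(site_of)),
            all(subjects %in% names(ages)),
            all(subjects %in% names(sexes)))
  for (s in names(repeat_plan)) {
    if (!s %in% subjects)
      stop("repeat_plan references unknown subject: ", s, call. = FALSE)
    if (!repeat_plan[[s]]$scanner %in% scanners)
      stop("repeat_plan references unknown scanner: ",
           repeat_plan[[s]]$scanner, call. = FALSE)
  }
  structure(list(subjects = subjects, scanners = scanners,
                 repeat_plan = repeat_plan, vendor_of = vendor_of,
                 site_of = site_of, ages = ages, sexes = sexes),
            class = "design_spec")
}

#' Enumerate the sessions of a design
#'
#' Deterministically expands a [design_spec()] into the session table:
#' every subject gets a `repeat_index` 0 session on every scanner, and
#' subjects in the repeat plan get `repeat_index` 1..n extra sessions on
#' their designated scanner. Session ids follow
#' `"<subject>_<scanner>_rep<k>"`.
#'
#' @param spec a `design_spec`.
#' @return data.frame of sessions (one row per session).
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  rows <- list()
  for (subj in spec$subjects) {
    for (scan in spec$scanners) {
      n_extra <- 0L
      rp <- spec$repeat_plan[[subj]]
      if (!is.null(rp) && identical(rp$scanner, scan))
        n_extra <- as.integer(rp$n_extra)
      for (k in 0:n_extra) {
        rows[[length(rows) + 1L]] <- data.frame(
          session_id = sprintf("%s_%s_rep%d", subj, scan, k),
          subject_id = subj, scanner_id = scan,
          site = unname(spec$site_of[scan]),
          vendor = unname(spec$vendor_of[scan]),
          repeat_index = k,
          age = unname(spec$ages[subj]),
          sex = unname(spec$sexes[subj]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Deterministic per-quantity sub-seed so that each random component of the
# simulation has its own stream derived from the single user-facing seed.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 99991L
  as.integer((as.numeric(seed) * 100003 + h * 7919) %% 2147483399) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configure the synthetic IDP generator
#'
#' Draws per-IDP generative parameters (deterministically from `seed`) for
#' the location/scale scanner-effect model
#' \deqn{y_{sbrv} = \alpha_v + x_s^\top\beta_v + u_{sv} + \gamma_{bv}
#'       + \eta_{bsv} + \delta_{bv}\,\varepsilon_{sbrv},}
#' with subject effects \eqn{u_{sv} \sim N(0, \tau_v^2)}, additive scanner
#' effects \eqn{\gamma_{bv} \sim N(0, \sigma_\gamma^2)}, multiplicative
#' scanner effects \eqn{\delta_{bv}} log-uniform on `scanner_scale_range`,
#' a subject-by-scanner interaction \eqn{\eta_{bsv} \sim N(0,
#' \sigma_\eta^2)} and session noise \eqn{\varepsilon \sim N(0,
#' \sigma_v^2)}. The additive and interaction effects can be partially
#' shared within vendor (variance shares `gamma_vendor_share`,
#' `interaction_vendor_share`): the interaction sharing is what makes
#' subject rankings agree more between scanners of the same vendor, since
#' purely additive offsets never reorder subjects.
#'
#' @param n_idps_per_category named integer vector: IDP count per category.
#' @param modality_of named character vector mapping category to modality
#'   (defaults to `"mixed"` for unlisted categories).
#' @param alpha_range,beta_age_range,beta_sex_range,tau_range,noise_sd_range
#'   uniform draw ranges for the per-IDP baseline mean, age effect
#'   (units/year, applied to age centred at 36), sex effect (units, female
#'   vs male), biological between-subject sd, and within-session noise sd.
#' @param scanner_additive_sd sd of the additive scanner effect
#'   \eqn{\gamma_{bv}}.
#' @param scanner_scale_range range of the multiplicative scanner effect
#'   \eqn{\delta_{bv}} (log-uniform); must lie in (0, Inf).
#' @param interaction_sd sd of the subject-by-scanner interaction.
#' @param gamma_vendor_share,interaction_vendor_share fraction of the
#'   corresponding effect variance shared by scanners of the same vendor,
#'   in `[0, 1]`.
#' @param iqm_scanner_sd,iqm_noise_sd scanner-offset and session-noise sd
#'   of the synthetic image quality metrics.
#' @param n_iqms_per_modality IQMs generated per modality.
#' @param seed integer seed; all draws flow from it via named sub-streams.
#' @return A `simulation_config` list carrying the realised per-IDP
#'   parameter vectors (`alpha`, `beta_age`, `beta_sex`, `tau`, `sigma`)
#'   and the category table.
#' @export
simulation_config <- function(n_idps_per_category,
                              modality_of = NULL,
                              alpha_range = c(80, 120),
                              beta_age_range = c(-0.3, 0.3),
                              beta_sex_range = c(-5, 5),
                              tau_range = c(5, 15),
                              scanner_additive_sd = 7,
                              scanner_scale_range = c(0.9, 1.15),
                              noise_sd_range = c(1.5, 2.5),
                              interaction_sd = 1.5,
                              gamma_vendor_share = 0.5,
                              interaction_vendor_share = 0.9,
                              iqm_scanner_sd = 1,
                              iqm_noise_sd = 0.5,
                              n_iqms_per_modality = 3L,
                              seed = 1L) {
  stopifnot(length(n_idps_per_category) >= 1L,
            !is.null(names(n_idps_per_category)),
            all(n_idps_per_category >= 2L),
            all(scanner_scale_range > 0),
            scanner_additive_sd >= 0, interaction_sd >= 0,
            gamma_vendor_share >= 0, gamma_vendor_share <= 1,
            interaction_vendor_share >= 0, interaction_vendor_share <= 1)
  cats <- names(n_idps_per_category)
  idp_names <- unlist(lapply(cats, function(cm) {
    if (cm == "fc_edges") {
      # edge IDPs are named after node pairs; the count must equal
      # choose(n_nodes, 2) for some integer node count
      n_nodes <- (1 + sqrt(1 + 8 * n_idps_per_category[[cm]])) / 2
      if (abs(n_nodes - round(n_nodes)) > 1e-9)
        stop("fc_edges count must be choose(n, 2) for integer n",
             call. = FALSE)
      pairs <- combn(sprintf("n%02d", seq_len(round(n_nodes))), 2)
      sprintf("fc_edge_%s_%s", pairs[1, ], pairs[2, ])
    } else {
      sprintf("%s_%03d", cm, seq_len(n_idps_per_category[[cm]]))
    }
  }), use.names = FALSE)
  category <- rep(cats, times = n_idps_per_category)
  modality <- rep("mixed", length(cats))
  names(modality) <- cats
  if (!is.null(modality_of)) modality[names(modality_of)] <- modality_of
  categories <- data.frame(idp_name = idp_names, category = category,
                           group = category,
                           modality = unname(modality[category]),
                           stringsAsFactors = FALSE)
  v <- length(idp_names)
  params <- with_seed(substream_seed(seed, "idp_params"), list(
    alpha = runif(v, alpha_range[1], alpha_range[2]),
    beta_age = runif(v, beta_age_range[1], beta_age_range[2]),
    beta_sex = runif(v, beta_sex_range[1], beta_sex_range[2]),
    tau = runif(v, tau_range[1], tau_range[2]),
    sigma = runif(v, noise_sd_range[1], noise_sd_range[2])))
  structure(c(list(categories = categories, idp_names = idp_names,
                   scanner_additive_sd = scanner_additive_sd,
                   scanner_scale_range = scanner_scale_range,
                   interaction_sd = interaction_sd,
                   gamma_vendor_share = gamma_vendor_share,
                   interaction_vendor_share = interaction_vendor_share,
                   iqm_scanner_sd = iqm_scanner_sd,
                   iqm_noise_sd = iqm_noise_sd,
                   n_iqms_per_modality = as.integer(n_iqms_per_modality),
                   seed = as.integer(seed)),
              params),
            class = "simulation_config")
}

# draw a (unit x IDP) effect matrix where a fraction `share` of the variance
# is common to all units of the same vendor
vendor_clustered_normal <- function(units, vendor_of_unit, n_idp, sd, share) {
  vendors <- unique(vendor_of_unit)
  vend_part <- matrix(rnorm(length(vendors) * n_idp, 0, sd),
                      nrow = length(vendors), dimnames = list(vendors, NULL))
  unit_part <- matrix(rnorm(length(units) * n_idp, 0, sd),
                      nrow = length(units), dimnames = list(units, NULL))
  out <- sqrt(share) * vend_part[vendor_of_unit, , drop = FALSE] +
    sqrt(1 - share) * unit_part
  rownames(out) <- units
  out
}

#' Simulate an IDP table for a design
#'
#' Generates the wide session-by-IDP matrix under the model documented in
#' [simulation_config()], returning both the [study_data()] object and the
#' realised ground-truth effects, so that harmonisation can be scored by
#' parameter recovery. Identical `(design, config)` pairs produce
#' bit-identical output.
#'
#' @param design session table from [build_design()].
#' @param config a [simulation_config()].
#' @return list with elements `study` (a `study_data`) and `truth` (a list
#'   with `gamma`, `delta` (scanner x IDP), `eta` (scanner x subject x
#'   IDP), `subject_effects` (subject x IDP), `alpha`, `beta_age`,
#'   `beta_sex`).
#' @export
simulate_idps <- function(design, config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  subjects <- unique(design$subject_id)
  scanners <- unique(design$scanner_id)
  vendor_of <- design$vendor[match(scanners, design$scanner_id)]
  v <- length(config$idp_names)

  u <- with_seed(substream_seed(seed, "subject_effects"),
    matrix(rnorm(length(subjects) * v), nrow = length(subjects),
           dimnames = list(subjects, config$idp_names)) *
      rep(config$tau, each = length(subjects)))

  gamma <- with_seed(substream_seed(seed, "scanner_gamma"),
    vendor_clustered_normal(scanners, vendor_of, v,
                            config$scanner_additive_sd,
                            config$gamma_vendor_share))
  colnames(gamma) <- config$idp_names

  lr <- log(config$scanner_scale_range)
  mid <- mean(lr)
  delta <- with_seed(substream_seed(seed, "scanner_delta"), {
    vend <- matrix(runif(length(unique(vendor_of)) * v, lr[1], lr[2]),
                   nrow = length(unique(vendor_of)),
                   dimnames = list(unique(vendor_of), NULL))
    scan <- matrix(runif(length(scanners) * v, lr[1], lr[2]),
                   nrow = length(scanners), dimnames = list(scanners, NULL))
    w <- config$gamma_vendor_share
    out <- exp(mid + sqrt(w) * (vend[vendor_of, , drop = FALSE] - mid) +
                 sqrt(1 - w) * (scan - mid))
    rownames(out) <- scanners
    out
  })
  colnames(delta) <- config$idp_names

  eta <- with_seed(substream_seed(seed, "interaction"), {
    vendors <- unique(vendor_of)
    dims <- c(length(scanners), length(subjects), v)
    vend <- array(rnorm(length(vendors) * length(subjects) * v, 0,
                        config$interaction_sd),
                  dim = c(length(vendors), length(subjects), v))
    scan <- array(rnorm(prod(dims), 0, config$interaction_sd), dim = dims)
    wi <- config$interaction_vendor_share
    out <- sqrt(wi) * vend[match(vendor_of, vendors), , , drop = FALSE] +
      sqrt(1 - wi) * scan
    dimnames(out) <- list(scanners, subjects, config$idp_names)
    out
  })

  eps <- with_seed(substream_seed(seed, "noise"),
    matrix(rnorm(nrow(design) * v), nrow = nrow(design),
           dimnames = list(design$session_id, config$idp_names)) *
      rep(config$sigma, each = nrow(design)))

  si <- match(design$subject_id, subjects)
  bi <- match(design$scanner_id, scanners)
  sex01 <- as.numeric(design$sex == "F")
  age_c <- design$age - 36
  y <- matrix(rep(config$alpha, each = nrow(design)), nrow = nrow(design),
              dimnames = list(design$session_id, config$idp_names))
  y <- y + outer(age_c, config$beta_age) + outer(sex01, config$beta_sex)
  y <- y + u[si, , drop = FALSE] + gamma[bi, , drop = FALSE]
  y <- y + matrix(eta[cbind(rep(bi, v), rep(si, v),
                            rep(seq_len(v), each = nrow(design)))],
                  nrow = nrow(design))
  y <- y + delta[bi, , drop = FALSE] * eps
  rownames(y) <- design$session_id

  study <- study_data(design, y, config$categories,
                      iqms = simulate_iqms(design, config))
  truth <- list(gamma = gamma, delta = delta, eta = eta,
                subject_effects = u, alpha = config$alpha,
                beta_age = config$beta_age, beta_sex = config$beta_sex)
  list(study = study, truth = truth)
}

#' Simulate image quality metrics for a design
#'
#' Stand-in for per-session quality-control outputs (SNR, tSNR, motion
#' indices): each IQM has a per-scanner offset plus session noise, so
#' scanner-level quality differences are visible in the downstream z-score
#' heatmaps. Seeded and deterministic.
#'
#' @inheritParams simulate_idps
#' @return numeric matrix, sessions x IQMs.
#' @export
simulate_iqms <- function(design, config) {
  stopifnot(inherits(config, "simulation_config"))
  modalities <- unique(config$categories$modality)
  iqm_names <- as.vector(outer(c("snr", "tsnr", "motion")[
    seq_len(min(3L, config$n_iqms_per_modality))],
    modalities, function(a, b) paste0(b, "_", a)))
  if (config$n_iqms_per_modality > 3L)
    iqm_names <- c(iqm_names, as.vector(outer(
      paste0("qm", 4:config$n_iqms_per_modality), modalities,
      function(a, b) paste0(b, "_", a))))
  q <- length(iqm_names)
  scanners <- unique(design$scanner_id)
  offsets <- with_seed(substream_seed(config$seed, "iqm_scanner"),
    matrix(rnorm(length(scanners) * q, 0, config$iqm_scanner_sd),
           nrow = length(scanners), dimnames = list(scanners, iqm_names)))
  noise <- with_seed(substream_seed(config$seed, "iqm_noise"),
    matrix(rnorm(nrow(design) * q, 0, config$iqm_noise_sd),
           nrow = nrow(design),
           dimnames = list(design$session_id, iqm_names)))
  out <- 10 + offsets[match(design$scanner_id, scanners), , drop = FALSE] +
    noise
  rownames(out) <- design$session_id
  out
}

#' The default travelling-heads preset
#'
#' Returns the design and simulation configuration the package uses as its
#' reference study: 10 subjects scanned once on each of 6 scanners spanning
#' 3 vendors and 5 sites, with 4 subjects receiving 5 extra within-scanner
#' repeats each (80 sessions in total: 60 primary, 20 repeats); 8 IDP
#' categories (379 IDPs, including a 210-edge functional-connectivity block
#' from 21 network nodes) across 4 modalities.
#'
#' @param seed integer seed forwarded to [simulation_config()].
#' @return list with elements `spec` (a [design_spec()]) and `config`
#'   (a [simulation_config()]).
#' @export
preset_paper_like <- function(seed = 1L) {
  subjects <- sprintf("sub%02d", 1:10)
  scanners <- c("GE_MR750", "Philips_Achieva", "Philips_Ingenia",
                "Siemens_Prisma32", "Siemens_Prisma64", "Siemens_Trio")
  vendor_of <- c(GE_MR750 = "GE", Philips_Achieva = "Philips",
                 Philips_Ingenia = "Philips", Siemens_Prisma32 = "Siemens",
                 Siemens_Prisma64 = "Siemens", Siemens_Trio = "Siemens")
  site_of <- c(GE_MR750 = "siteA", Philips_Achieva = "siteB",
               Philips_Ingenia = "siteC", Siemens_Prisma32 = "siteD",
               Siemens_Prisma64 = "siteD", Siemens_Trio = "siteE")
  repeat_scanners <- c("Philips_Achieva", "Siemens_Prisma32",
                       "Siemens_Trio", "Siemens_Prisma64")
  repeat_plan <- setNames(lapply(seq_len(4), function(i)
    list(scanner = repeat_scanners[i], n_extra = 5L)), subjects[1:4])
  ages <- setNames(c(24, 27, 30, 32, 34, 36, 39, 41, 44, 48), subjects)
  sexes <- setNames(c("M", "M", "F", "M", "M", "M", "F", "M", "M", "M"),
                    subjects)
  spec <- design_spec(subjects, scanners, repeat_plan, vendor_of, site_of,
                      ages, sexes)
  config <- simulation_config(
    n_idps_per_category = c(subcortical_volumes = 14L, tissue_volumes = 6L,
                            cortical_parcel_volumes = 60L,
                            subcortical_t2star = 14L, dmri_tract_fa = 27L,
                            dmri_tract_md = 27L, fc_node_amplitudes = 21L,
                            fc_edges = 210L),
    modality_of = c(subcortical_volumes = "T1w", tissue_volumes = "T1w",
                    cortical_parcel_volumes = "T1w",
                    subcortical_t2star = "SWI", dmri_tract_fa = "dMRI",
                    dmri_tract_md = "dMRI", fc_node_amplitudes = "rfMRI",
                    fc_edges = "rfMRI"),
    seed = seed)
  list(spec = spec, config = config)
}

#' Batch-centred scanner effects
#'
#' Removes, per feature, the sample-size-weighted mean of an effect across
#' batches. Under a harmonisation model whose batch offsets are constrained
#' to a weighted zero sum, only these centred offsets are identifiable, so
#' parameter-recovery comparisons use them.
#'
#' @param effects scanner x feature matrix.
#' @param n_per_batch named count of sessions per scanner.
#' @return matrix of the same shape with weighted column means removed.
#' @export
batch_centred_effects <- function(effects, n_per_batch) {
  w <- n_per_batch[rownames(effects)] / sum(n_per_batch[rownames(effects)])
  sweep(effects, 2, colSums(effects * as.numeric(w)), "-")
}
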