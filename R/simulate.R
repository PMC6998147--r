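#' The default descriptive marker panel
#'
#' The 15-gene panel of smoke-response marker genes (8 upregulated, 7
#' downregulated) used as the default planted truth by the simulators and as
#' the gene set behind the packaged reference risk model.
#'
#' @param effect Planted per-gene effect magnitude in log2 units (recycled).
#' @return A marker-panel tibble with columns `gene_id`, `direction`
#'   (`"up"`/`"down"`) and `effect`.
#' @export
default_marker_panel <- function(effect = 1.0) {
  up <- c("AREG", "CYP1B1", "DUSP6", "PHLDA1", "SLC7A11", "TXNIP", "WNT5A", "ZBED2")
  down <- c("ADM", "CXCR4", "EFNA1", "EGLN3", "FBXO32", "HILPDA", "IGFBP3")
  tibble::tibble(
    gene_id = c(up, down),
    direction = c(rep("up", length(up)), rep("down", length(down))),
    effect = rep_len(abs(effect), length(up) + length(down))
  )
}

#' Configuration for the synthetic exposure study
#'
#' Describes an in vitro exposure design: an untreated control, six test
#' substances at two dose levels and two exposure times, and an aqueous
#' smoke extract (AqE) series at three doses and the same two times, with
#' `n_replicates` tissue cultures per condition. Marker-panel genes are
#' shifted by their `effect` (in their stated direction) in every treated
#' arm, dose- and time-consistently; substance-specific extras shift only in
#' their own substance.
#'
#' @param n_genes Number of genes in the simulated universe.
#' @param n_replicates Replicates per condition.
#' @param substances Character vector of test-substance names.
#' @param aqe_doses Numeric AqE doses (cigarettes/L).
#' @param times_h Exposure times in hours.
#' @param panel Planted marker panel (see [default_marker_panel()]).
#' @param substance_effects Named list: substance -> tibble(gene_id,
#'   direction, effect) of extra genes perturbed only by that substance.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param baseline_mean Mean baseline log2 intensity.
#' @param low_intensity_fraction Fraction of background genes drawn near the
#'   detection floor (baseline 2 log2 units lower), exercising the
#'   low-intensity filter.
#' @param dose_response `"flat"` (default; planted effects identical at
#'   every dose, as dose-independence selection demands) or `"linear"`
#'   (effect scales with dose rank, for testing that non-flat genes can
#'   still be selected only if they pass every dose).
#' @param seed Integer RNG seed.
#' @return A config list of class `exposure_sim_config`.
#' @export
exposure_sim_config <- function(n_genes = 2000L,
                                n_replicates = 3L,
                                substances = c("cisplatin", "bleomycin", "NaClO", "tBHQ", "TNFa", "IL1b"),
                                aqe_doses = c(0.5, 1.0, 2.0),
                                times_h = c(4, 24),
                                panel = default_marker_panel(),
                                substance_effects = list(),
                                noise_sd = 0.25,
                                baseline_mean = 7.0,
                                low_intensity_fraction = 0.15,
                                dose_response = c("flat", "linear"),
                                seed = 1L) {
  dose_response <- match.arg(dose_response)
  stopifnot(n_genes >= 1L, n_replicates >= 1L, noise_sd > 0,
            length(aqe_doses) >= 1L, length(substances) >= 1L,
            all(panel$effect >= 0))
  extra_genes <- unlist(lapply(substance_effects, function(x) x$gene_id), use.names = FALSE)
  if (nrow(panel) + length(unique(extra_genes)) > n_genes) {
    stop("planted panel larger than the gene universe", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    substances = substances, aqe_doses = aqe_doses, times_h = times_h,
    panel = panel, substance_effects = substance_effects,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    low_intensity_fraction = low_intensity_fraction,
    dose_response = dose_response, seed = as.integer(seed)
  ), class = "exposure_sim_config")
}

sim_gene_universe <- function(n_genes, planted_ids, baseline_mean, low_intensity_fraction) {
  n_bg <- n_genes - length(planted_ids)
  bg_ids <- sprintf("G%05d", seq_len(n_bg))
  gene_id <- c(planted_ids, bg_ids)
  baseline <- rep(baseline_mean, n_genes)
  # background genes only: a fraction sits 2 log2 units below the main
  # population, to be caught by the intensity-percentile filter
  n_low <- round(low_intensity_fraction * n_bg)
  if (n_low > 0L) {
    low_idx <- length(planted_ids) + sample.int(n_bg, n_low)
    baseline[low_idx] <- baseline_mean - 2
  }
  list(gene_id = gene_id, baseline = baseline)
}

#' Simulate an exposure study with planted truth
#'
#' Generates the expression matrix, exposure annotation and planted-truth
#' panel for the design in [exposure_sim_config()]. Noise is i.i.d.
#' Gaussian on the log2 scale; output is fully determined by the config
#' (including its seed).
#'
#' @param config An [exposure_sim_config()].
#' @return A list with elements `expression` (wide tibble), `annotation`
#'   (exposure annotation tibble) and `truth` (list: `panel`,
#'   `substance_effects`, `seed`).
#' @export
simulate_exposure_study <- function(config = exposure_sim_config()) {
  stopifnot(inherits(config, "exposure_sim_config"))
  set.seed(config$seed)

  conditions <- dplyr::bind_rows(
    tibble::tibble(arm = "control", substance = NA_character_, dose_level = NA_character_,
                   dose_rank = NA_real_, time_h = NA_real_),
    tidyr::expand_grid(substance = config$substances,
                       dose_level = c("low", "high"),
                       time_h = config$times_h) |>
      dplyr::mutate(arm = "substance",
                    dose_rank = ifelse(.data$dose_level == "low", 1, 2)) |>
      dplyr::select("arm", "substance", "dose_level", "dose_rank", "time_h"),
    tidyr::expand_grid(dose = config$aqe_doses, time_h = config$times_h) |>
      dplyr::mutate(arm = "aqe", substance = NA_character_,
                    dose_level = as.character(.data$dose),
                    dose_rank = match(.data$dose, sort(config$aqe_doses))) |>
      dplyr::select("arm", "substance", "dose_level", "dose_rank", "time_h")
  )
  annotation <- tidyr::expand_grid(conditions, replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(sample_id = paste0(
      ifelse(.data$arm == "control", "ctrl",
             ifelse(.data$arm == "aqe", paste0("aqe_", .data$dose_level, "_", .data$time_h, "h"),
                    paste0(.data$substance, "_", .data$dose_level, "_", .data$time_h, "h"))),
      "_r", .data$replicate)) |>
    dplyr::select("sample_id", "arm", "substance", "dose_level", "dose_rank", "time_h", "replicate")

  panel <- config$panel
  extra_ids <- unique(unlist(lapply(config$substance_effects, function(x) x$gene_id), use.names = FALSE))
  uni <- sim_gene_universe(config$n_genes, c(panel$gene_id, extra_ids),
                           config$baseline_mean, config$low_intensity_fraction)
  n_genes <- config$n_genes
  n_samples <- nrow(annotation)

  signal <- matrix(uni$baseline, nrow = n_genes, ncol = n_samples)
  rownames(signal) <- uni$gene_id
  colnames(signal) <- annotation$sample_id

  treated <- annotation$arm != "control"
  dose_scale <- if (config$dose_response == "linear") {
    ifelse(treated, annotation$dose_rank / max(annotation$dose_rank, na.rm = TRUE), 0)
  } else {
    as.numeric(treated)
  }
  sgn <- ifelse(panel$direction == "up", 1, -1)
  signal[panel$gene_id, ] <- signal[panel$gene_id, ] +
    outer(sgn * panel$effect, dose_scale)

  for (sub in names(config$substance_effects)) {
    eff <- config$substance_effects[[sub]]
    sel <- treated & !is.na(annotation$substance) & annotation$substance == sub
    s2 <- ifelse(panel_dir_sign(eff$direction) > 0, 1, -1)
    signal[eff$gene_id, sel] <- signal[eff$gene_id, sel] + outer(s2 * eff$effect, rep(1, sum(sel)))
  }

  values <- signal + matrix(stats::rnorm(n_genes * n_samples, sd = config$noise_sd),
                            nrow = n_genes)
  expression <- as_expression_tbl(values)
  annotation <- dplyr::select(annotation, -"dose_rank")
  validate_exposure_annotation(annotation)
  list(expression = expression,
       annotation = annotation,
       truth = list(panel = panel,
                    substance_effects = config$substance_effects,
                    seed = config$seed))
}

panel_dir_sign <- function(direction) ifelse(direction == "up", 1, -1)

#' Configuration for the synthetic cohort
#'
#' Describes a three-group case-control cohort (non-smokers, smokers, COPD)
#' with graded marker shifts and status-correlated covariates. The default
#' effect scale (total NS -> COPD shift of 0.4 log2 per marker against a
#' 0.7 log2 biological noise SD) keeps the three groups substantially
#' overlapping, as real airway cohorts are, so downstream logistic fits
#' remain well-conditioned. Marker genes
#' move monotonically across NS -> SMK -> COPD in the panel's direction;
#' pack-years are zero for non-smokers and drawn from a truncated normal
#' correlated with age in the smoking groups.
#'
#' @param n_per_group Named counts for `NS`, `SMK`, `COPD`.
#' @param panel Planted marker panel; `effect` is interpreted as the total
#'   NS -> COPD shift, with `smk_fraction` of it reached in smokers.
#' @param smk_fraction Fraction of the NS->COPD shift present in smokers.
#' @param baseline_mean Baseline log2 intensity for every gene in NS.
#' @param noise_sd Per-sample Gaussian noise SD (log2) for all genes.
#' @param n_genes Total genes simulated (panel + background).
#' @param age_mean,age_sd Named per-group parameters for age (years).
#' @param pack_years_mean,pack_years_sd Named per-group parameters for
#'   pack-years (NS fixed at 0).
#' @param age_py_cor Within-group correlation between age and pack-years.
#' @param seed Integer RNG seed.
#' @return A config list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_per_group = c(NS = 68L, SMK = 88L, COPD = 48L),
                              panel = default_marker_panel(effect = 0.4),
                              smk_fraction = 0.5,
                              baseline_mean = 7.0,
                              noise_sd = 0.7,
                              n_genes = 1000L,
                              age_mean = c(NS = 40, SMK = 45, COPD = 55),
                              age_sd = c(NS = 10, SMK = 10, COPD = 8),
                              pack_years_mean = c(NS = 0, SMK = 25, COPD = 40),
                              pack_years_sd = c(NS = 0, SMK = 10, COPD = 12),
                              age_py_cor = 0.4,
                              seed = 7L) {
  stopifnot(all(n_per_group > 0L), noise_sd > 0, abs(age_py_cor) <= 1,
            nrow(panel) <= n_genes, smk_fraction >= 0, smk_fraction <= 1)
  structure(list(
    n_per_group = n_per_group, panel = panel, smk_fraction = smk_fraction,
    baseline_mean = baseline_mean, noise_sd = noise_sd, n_genes = as.integer(n_genes),
    age_mean = age_mean, age_sd = age_sd,
    pack_years_mean = pack_years_mean, pack_years_sd = pack_years_sd,
    age_py_cor = age_py_cor, seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Simulate a three-group cohort with planted truth
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `expression`, `annotation` (cohort annotation) and
#'   `truth` (tibble of per-gene planted group means plus a `monotone`
#'   flag).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  groups <- c("NS", "SMK", "COPD")
  n <- config$n_per_group[groups]
  status <- rep(groups, times = n)
  n_total <- sum(n)
  sample_id <- sprintf("%s_%03d", status, stats::ave(seq_len(n_total), status, FUN = seq_along))

  # covariates: age ~ normal per group; pack-years truncated-normal per
  # group, correlated with age within group; non-smokers fixed at 0
  age <- stats::rnorm(n_total, config$age_mean[status], config$age_sd[status])
  z_age <- (age - config$age_mean[status]) / config$age_sd[status]
  r <- config$age_py_cor
  py_raw <- config$pack_years_mean[status] +
    config$pack_years_sd[status] * (r * z_age + sqrt(1 - r^2) * stats::rnorm(n_total))
  pack_years <- pmax(py_raw, 0)
  pack_years[status == "NS"] <- 0

  annotation <- tibble::tibble(sample_id = sample_id, status = status,
                               age = age, pack_years = pack_years,
                               study = "synthetic")

  panel <- config$panel
  sgn <- panel_dir_sign(panel$direction)
  truth <- tibble::tibble(
    gene_id = panel$gene_id,
    direction = panel$direction,
    mean_NS = config$baseline_mean,
    mean_SMK = config$baseline_mean + sgn * panel$effect * config$smk_fraction,
    mean_COPD = config$baseline_mean + sgn * panel$effect
  )
  truth$monotone <- (truth$mean_SMK - truth$mean_NS) * (truth$mean_COPD - truth$mean_SMK) >= 0 |
    panel$effect == 0
  if (any(!truth$monotone)) {
    warning("non-monotone marker effects planted; flagged in truth", call. = FALSE)
  }

  n_bg <- config$n_genes - nrow(panel)
  gene_id <- c(panel$gene_id, sprintf("G%05d", seq_len(n_bg)))
  means <- matrix(config$baseline_mean, nrow = config$n_genes, ncol = n_total,
                  dimnames = list(gene_id, sample_id))
  group_means <- cbind(NS = truth$mean_NS, SMK = truth$mean_SMK, COPD = truth$mean_COPD)
  means[panel$gene_id, ] <- group_means[, status, drop = FALSE]

  values <- means + matrix(stats::rnorm(config$n_genes * n_total, sd = config$noise_sd),
                           nrow = config$n_genes)
  expression <- as_expression_tbl(values)
  validate_cohort_annotation(annotation)
  list(expression = expression, annotation = annotation, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the expression TSV, annotation TSV and a truth JSON (planted panel,
#' effects, seed) so external harnesses can consume the same files the
#' pipeline reads.
#'
#' @param sim Result of [simulate_exposure_study()] or [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_expression_tsv(sim$expression, paths[["expression"]])
  readr::write_tsv(sim$annotation, paths[["annotation"]], progress = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
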