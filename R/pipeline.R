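#' Pipeline run configuration
#'
#' A single configuration driving the end-to-end synthetic run:
#' simulate -> differential expression -> marker cascade -> classification
#' -> PRF model -> scoring. Individual stages can be toggled off; the seed
#' propagates to every stochastic stage.
#'
#' @param seed Master seed (simulation seeds and the CV seed derive from
#'   it).
#' @param out_dir Output directory for artifacts and the manifest.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "deg", "select_markers", "classify", "fit_prf",
#'   "score")`.
#' @param exposure_config,cohort_config Simulator configs; `NULL` uses the
#'   defaults reseeded from `seed`.
#' @param fdr_cut,fc_cut DEG thresholds (fold-change cut applies to the AqE
#'   series).
#' @param cv CV settings as a [cv_config()]; `NULL` uses defaults reseeded
#'   from `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("prfpipe_run_"),
                            stages = c("simulate", "deg", "select_markers",
                                       "classify", "fit_prf", "score"),
                            exposure_config = NULL, cohort_config = NULL,
                            fdr_cut = 0.05, fc_cut = 1.5, cv = NULL) {
  known <- c("simulate", "deg", "select_markers", "classify", "fit_prf", "score")
  stopifnot(all(stages %in% known))
  seed <- as.integer(seed)
  structure(list(
    seed = seed, out_dir = out_dir, stages = stages,
    exposure_config = exposure_config %||% exposure_sim_config(seed = seed),
    cohort_config = cohort_config %||% cohort_sim_config(seed = seed + 1L),
    fdr_cut = fdr_cut, fc_cut = fc_cut,
    cv = cv %||% cv_config(seed = seed)
  ), class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order on synthetic data, writing every
#' intermediate artifact (TSV/JSON) under `config$out_dir` together with a
#' machine-readable manifest (inputs, md5 hashes, seeds, timings, package
#' version). Identical config and seed reproduce identical artifact
#' hashes. A stage failure aborts with the stage name; artifacts written so
#' far are retained.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "prfpipe",
                   version = as.character(utils::packageVersion("prfpipe")),
                   seed = config$seed, stages = config$stages,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   artifacts = list(), timings = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    message("[prfpipe] stage: ", name)
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  emit <- function(key, path) manifest$artifacts[[key]] <<- path

  run_stage("simulate", function() {
    state$exposure <- simulate_exposure_study(config$exposure_config)
    state$cohort <- simulate_cohort(config$cohort_config)
    emit("exposure", write_simulation(state$exposure, config$out_dir, "exposure"))
    emit("cohort", write_simulation(state$cohort, config$out_dir, "cohort"))
  })
  run_stage("deg", function() {
    ann <- state$exposure$annotation
    ctrl <- ann$sample_id[ann$arm == "control"]
    aqe <- ann[ann$arm == "aqe" & ann$time_h == 4, ]
    stats_by_dose <- purrr::map(sort(unique(aqe$dose_level)), function(d) {
      deg_stats(state$exposure$expression, ctrl, aqe$sample_id[aqe$dose_level == d],
                contrast = list(arm = "aqe", dose_level = d, time_h = 4))
    })
    state$aqe_stats <- stats_by_dose
    path <- file.path(config$out_dir, "aqe_deg_stats.tsv")
    purrr::map2(stats_by_dose, sort(unique(aqe$dose_level)),
                ~ dplyr::mutate(tibble::as_tibble(.x), dose = .y)) |>
      purrr::list_rbind() |>
      readr::write_tsv(path, progress = FALSE)
    emit("aqe_deg_stats", path)
  })
  run_stage("select_markers", function() {
    state$cascade <- run_marker_cascade(state$exposure$expression, state$exposure$annotation,
                                        fdr_cut = config$fdr_cut, fc_cut = config$fc_cut)
    path <- file.path(config$out_dir, "panel.json")
    panel <- state$cascade$final_panel
    jsonlite::write_json(
      purrr::map(seq_len(nrow(panel)), function(i) {
        list(gene_id = panel$gene_id[i], direction = panel$direction[i],
             provenance = state$cascade$provenance[[panel$gene_id[i]]])
      }), path, auto_unbox = TRUE, pretty = TRUE)
    emit("panel", path)
  })
  run_stage("classify", function() {
    panel <- if (!is.null(state$cascade)) state$cascade$final_panel else config$exposure_config$panel
    state$cv <- repeated_cv(state$cohort$expression, state$cohort$annotation,
                            panel, config$cv)
    path <- file.path(config$out_dir, "confusion.json")
    jsonlite::write_json(list(mean_counts = as.data.frame(state$cv$mean_counts),
                              true_rate = as.list(state$cv$true_rate),
                              overall_accuracy = state$cv$overall_accuracy,
                              macro_accuracy = state$cv$macro_accuracy),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("confusion", path)
  })
  run_stage("fit_prf", function() {
    panel <- if (!is.null(state$cascade)) state$cascade$final_panel else config$exposure_config$panel
    state$prf_model <- fit_prf_model(state$cohort$expression, state$cohort$annotation, panel)
    path <- file.path(config$out_dir, "prf_model.json")
    save_prf_model(state$prf_model, path)
    emit("prf_model", path)
  })
  run_stage("score", function() {
    state$scores <- score_samples(state$prf_model, state$cohort$expression,
                                  state$cohort$annotation)
    path <- file.path(config$out_dir, "prf_scores.tsv")
    readr::write_tsv(tibble::as_tibble(state$scores), path, progress = FALSE)
    emit("prf_scores", path)
    med_path <- file.path(config$out_dir, "prf_group_medians.tsv")
    readr::write_tsv(prf_group_medians(state$scores), med_path, progress = FALSE)
    emit("prf_group_medians", med_path)
  })

  files <- unlist(manifest$artifacts, use.names = FALSE)
  files <- files[file.exists(files)]
  manifest$hashes <- as.list(tools::md5sum(files))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- list(manifest = manifest, state = as.list(state))
  invisible(out)
}
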