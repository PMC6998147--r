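#' Direction-consistent intersection of DEG sets
#'
#' All panel-building intersections are per direction: a gene survives only
#' if it appears with the same direction in every set. Up- and
#' downregulated genes are intersected separately (one Venn per direction).
#'
#' @param deg_sets A list of DEG-set tibbles (`gene_id`, `direction`).
#' @return A tibble (`gene_id`, `direction`) with genes present, same
#'   direction, in every input set.
#' @keywords internal
intersect_directional <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 1L)
  out <- dplyr::distinct(tibble::as_tibble(deg_sets[[1L]])[, c("gene_id", "direction")])
  for (s in deg_sets[-1L]) {
    out <- dplyr::inner_join(out, dplyr::distinct(tibble::as_tibble(s)[, c("gene_id", "direction")]),
                             by = c("gene_id", "direction"))
  }
  dplyr::arrange(out, .data$direction, .data$gene_id)
}

#' Genes perturbed in common across an AqE dose series
#'
#' Step one of the panel cascade: the per-direction intersection of the DEG
#' sets from each aqueous-extract dose, yielding the smoke-inducible genes
#' that respond consistently at every concentration.
#'
#' @param deg_sets List (length >= 2) of DEG-set tibbles, one per dose.
#' @return A marker-panel tibble (`gene_id`, `direction`).
#' @export
common_across_doses <- function(deg_sets) {
  if (!is.list(deg_sets) || length(deg_sets) < 2L) {
    stop("need at least two dose DEG sets", call. = FALSE)
  }
  intersect_directional(deg_sets)
}

contrast_field <- function(set, field) {
  ct <- attr(set, "contrast")
  if (is.list(ct) && !is.null(ct[[field]])) ct[[field]] else NULL
}

check_same_contrast <- function(set_1, set_2, fields) {
  for (f in fields) {
    v1 <- contrast_field(set_1, f); v2 <- contrast_field(set_2, f)
    if (!is.null(v1) && !is.null(v2) && !identical(v1, v2)) {
      stop("contrast mismatch on '", f, "': ", v1, " vs ", v2, call. = FALSE)
    }
  }
}

#' Time-independently perturbed DEGs
#'
#' Direction-consistent intersection of the 4 h and 24 h DEG sets for one
#' substance at one dose: genes a substance perturbs regardless of exposure
#' time.
#'
#' @param set_4h,set_24h DEG-set tibbles for the two exposure times of the
#'   same substance and dose (checked via their `contrast` attributes when
#'   present).
#' @return A DEG-set tibble.
#' @export
time_independent_degs <- function(set_4h, set_24h) {
  check_same_contrast(set_4h, set_24h, c("substance", "dose_level"))
  out <- intersect_directional(list(set_4h, set_24h))
  ct <- attr(set_4h, "contrast")
  if (is.list(ct)) attr(out, "contrast") <- ct[setdiff(names(ct), "time_h")]
  out
}

#' Dose-independently perturbed DEGs
#'
#' Direction-consistent intersection of the low- and high-dose
#' time-independent sets of one substance.
#'
#' @param set_low,set_high Time-independent DEG-set tibbles for the two
#'   dose levels of the same substance.
#' @return A DEG-set tibble.
#' @export
dose_independent_degs <- function(set_low, set_high) {
  check_same_contrast(set_low, set_high, "substance")
  out <- intersect_directional(list(set_low, set_high))
  ct <- attr(set_low, "contrast")
  if (is.list(ct)) attr(out, "contrast") <- ct[setdiff(names(ct), "dose_level")]
  out
}

#' Merge the AqE panel with the substance DEG sets
#'
#' Final cascade step: unions the per-substance dose-independent DEG sets
#' (keeping directions) and intersects the union per direction with the
#' AqE-common panel. Provenance records, for every final gene, the AqE
#' doses and the substances that support it.
#'
#' @param aqe_common Marker-panel tibble from [common_across_doses()].
#' @param substance_sets Named list (substance -> dose-independent DEG-set
#'   tibble).
#' @param aqe_support Optional named list (dose label -> AqE DEG set) used
#'   only to enumerate supporting AqE contrasts in the provenance.
#' @return A `cascade_result` list: `aqe_common`, `substance_sets`,
#'   `substance_union`, `final_panel`, `provenance`.
#' @export
merge_with_aqe <- function(aqe_common, substance_sets, aqe_support = NULL) {
  stopifnot(is.list(substance_sets))
  union_tbl <- if (length(substance_sets) == 0L) {
    tibble::tibble(gene_id = character(), direction = character())
  } else {
    purrr::imap(substance_sets,
                ~ dplyr::mutate(tibble::as_tibble(.x)[, c("gene_id", "direction")], substance = .y)) |>
      purrr::list_rbind()
  }
  substance_union <- dplyr::distinct(union_tbl[, c("gene_id", "direction")]) |>
    dplyr::arrange(.data$direction, .data$gene_id)
  final_panel <- dplyr::inner_join(
    tibble::as_tibble(aqe_common)[, c("gene_id", "direction")],
    substance_union, by = c("gene_id", "direction")) |>
    dplyr::arrange(.data$direction, .data$gene_id)

  provenance <- purrr::map(seq_len(nrow(final_panel)), function(i) {
    g <- final_panel$gene_id[i]; d <- final_panel$direction[i]
    subs <- unique(union_tbl$substance[union_tbl$gene_id == g & union_tbl$direction == d])
    aqe <- if (is.null(aqe_support)) "aqe_common" else {
      names(aqe_support)[purrr::map_lgl(aqe_support, function(s) {
        any(s$gene_id == g & s$direction == d)
      })]
    }
    c(paste0("aqe:", aqe), paste0("substance:", subs))
  })
  names(provenance) <- final_panel$gene_id
  structure(list(aqe_common = aqe_common,
                 substance_sets = substance_sets,
                 substance_union = substance_union,
                 final_panel = final_panel,
                 provenance = provenance),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Marker-selection cascade\n")
  cat("  AqE dose-common genes: ", nrow(x$aqe_common), "\n", sep = "")
  cat("  substance union:       ", nrow(x$substance_union), "\n", sep = "")
  cat("  final panel:           ", nrow(x$final_panel),
      " (", sum(x$final_panel$direction == "up"), " up / ",
      sum(x$final_panel$direction == "down"), " down)\n", sep = "")
  invisible(x)
}

#' Run the full marker-selection cascade on an exposure study
#'
#' Orchestrates the panel derivation from a single exposure dataset:
#' filtering and testing run separately for the AqE batch (AqE arms +
#' controls) and the substance batch (substance arms + controls), honoring
#' the separate normalization of the two exposure series. Per contrast the
#' treated arm is tested against the untreated controls with the moderated
#' t-test and BH-FDR. AqE DEGs additionally require `|FC| > fc_cut`; the
#' AqE dose series is taken at `aqe_time_h` (default 4 h). Substance DEGs
#' use the FDR cut alone and are intersected across times, then doses, then
#' unioned and merged with the AqE panel.
#'
#' @param expression Wide expression tibble of the exposure study.
#' @param annotation Exposure annotation tibble.
#' @param fdr_cut FDR threshold for every contrast.
#' @param fc_cut Linear fold-change threshold applied to AqE contrasts.
#' @param aqe_time_h Exposure time whose AqE dose series defines the
#'   smoke-common panel.
#' @param filter Logical; apply [filter_genes()] per batch before testing.
#' @return A `cascade_result` (see [merge_with_aqe()]) with the per-contrast
#'   DEG sets attached as `aqe_sets` and `time_independent`.
#' @export
run_marker_cascade <- function(expression, annotation,
                               fdr_cut = 0.05, fc_cut = 1.5,
                               aqe_time_h = 4, filter = TRUE) {
  pair <- align_annotation(expression, annotation)
  expression <- pair$expression
  annotation <- validate_exposure_annotation(pair$annotation)
  ctrl <- annotation$sample_id[annotation$arm == "control"]
  if (length(ctrl) < 2L) stop("need at least two control samples", call. = FALSE)

  batch_expr <- function(arms) {
    ids <- annotation$sample_id[annotation$arm %in% c("control", arms)]
    ex <- expression[, c("gene_id", ids), drop = FALSE]
    if (filter) {
      keep <- filter_genes(ex)
      ex <- ex[ex$gene_id %in% keep, , drop = FALSE]
    }
    ex
  }

  # AqE batch: one contrast per dose at the panel time point
  aqe_ex <- batch_expr("aqe")
  aqe_ann <- annotation[annotation$arm == "aqe" & annotation$time_h == aqe_time_h, ]
  aqe_doses <- sort(unique(aqe_ann$dose_level))
  aqe_sets <- purrr::map(aqe_doses, function(d) {
    trt <- aqe_ann$sample_id[aqe_ann$dose_level == d]
    st <- deg_stats(aqe_ex, ctrl, trt, contrast = list(arm = "aqe", dose_level = d, time_h = aqe_time_h))
    call_degs(st, fdr_cut = fdr_cut, fc_cut = fc_cut)
  })
  names(aqe_sets) <- aqe_doses
  aqe_common <- common_across_doses(aqe_sets)

  # substance batch: per substance x dose x time, then the two intersections
  sub_ex <- batch_expr("substance")
  sub_ann <- annotation[annotation$arm == "substance", ]
  substances <- unique(sub_ann$substance)
  time_independent <- list()
  substance_sets <- purrr::map(substances, function(sub) {
    dose_sets <- purrr::map(c("low", "high"), function(d) {
      time_sets <- purrr::map(sort(unique(sub_ann$time_h)), function(tt) {
        trt <- sub_ann$sample_id[sub_ann$substance == sub &
                                   sub_ann$dose_level == d & sub_ann$time_h == tt]
        st <- deg_stats(sub_ex, ctrl, trt,
                        contrast = list(arm = "substance", substance = sub,
                                        dose_level = d, time_h = tt))
        call_degs(st, fdr_cut = fdr_cut, fc_cut = NULL)
      })
      ti <- time_independent_degs(time_sets[[1L]], time_sets[[2L]])
      time_independent[[paste(sub, d, sep = ":")]] <<- ti
      ti
    })
    dose_independent_degs(dose_sets[[1L]], dose_sets[[2L]])
  })
  names(substance_sets) <- substances

  res <- merge_with_aqe(aqe_common, substance_sets, aqe_support = aqe_sets)
  res$aqe_sets <- aqe_sets
  res$time_independent <- time_independent
  res
}

#' Spearman co-expression of a marker panel
#'
#' Rank correlation of every pair of panel genes across samples; used to
#' check that the selected markers move together (a shared-mechanism
#' signature). Constant genes have no defined rank correlation and are
#' reported as `NA` with a warning, never as 0.
#'
#' @param expression Wide expression tibble.
#' @param panel Marker-panel tibble (`gene_id`, `direction`) or character
#'   vector of gene ids.
#' @return A symmetric gene-by-gene correlation matrix with unit diagonal.
#' @export
spearman_panel_correlation <- function(expression, panel) {
  genes <- if (is.data.frame(panel)) panel$gene_id else panel
  m <- expression_matrix(expression)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0L) {
    stop("panel genes absent from matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(m) < 3L) stop("need at least three samples", call. = FALSE)
  sub <- t(m[genes, , drop = FALSE])
  const <- apply(sub, 2L, function(x) stats::sd(x) == 0)
  rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
  if (any(const)) {
    warning("constant gene(s): ", paste(genes[const], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- ifelse(const, NA_real_, 1)
  rho
}
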