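#' Expression tables
#'
#' `prfpipe` represents a gene-by-sample grid of normalized log2 intensities
#' as a wide tibble: a `gene_id` character column followed by one numeric
#' column per sample. All pipeline functions take this tibble as their first
#' argument, so stages chain with the pipe.
#'
#' @name expression-table
#' @keywords internal
NULL

#' Validate an expression table
#'
#' Checks the wide-tibble expression contract: a `gene_id` character column
#' first, at least one numeric sample column, unique gene and sample
#' identifiers, and finite values throughout. Missing values are rejected
#' rather than imputed.
#'
#' @param expression A wide expression tibble (`gene_id` + sample columns).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(expression) {
  if (!is.data.frame(expression) || ncol(expression) < 2L) {
    stop("expression must be a data frame with a gene_id column and at least one sample column", call. = FALSE)
  }
  if (names(expression)[1L] != "gene_id") {
    stop("first column of an expression table must be 'gene_id'", call. = FALSE)
  }
  gene_ids <- expression$gene_id
  if (!is.character(gene_ids)) {
    stop("gene_id must be a character column", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  sample_ids <- names(expression)[-1L]
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample identifiers: ", paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  for (s in sample_ids) {
    col <- expression[[s]]
    if (!is.numeric(col)) {
      stop("sample column '", s, "' is not numeric", call. = FALSE)
    }
    if (any(!is.finite(col))) {
      bad <- which(!is.finite(col))[1L]
      stop("non-finite value at gene '", gene_ids[bad], "', sample '", s, "'", call. = FALSE)
    }
  }
  invisible(expression)
}

#' Extract the numeric matrix from an expression table
#'
#' @param expression A validated expression tibble.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
expression_matrix <- function(expression) {
  validate_expression(expression)
  m <- as.matrix(expression[, -1L, drop = FALSE])
  rownames(m) <- expression$gene_id
  m
}

#' Build an expression table from a numeric matrix
#'
#' @param m Numeric matrix with rownames (genes) and colnames (samples).
#' @return A wide expression tibble.
#' @export
as_expression_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), out)
  validate_expression(out)
  out
}

#' Read an expression TSV
#'
#' Reads a tab-separated file whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns hold numeric normalized log2
#' intensities, one column per sample. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return A wide expression tibble.
#' @export
read_expression_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop("malformed expression TSV '", path, "': row ", probs$row[1L], " (", probs$expected[1L], ")", call. = FALSE)
  }
  if (ncol(raw) < 2L) {
    stop("expression TSV must have a gene id column and at least one sample column", call. = FALSE)
  }
  names(raw)[1L] <- "gene_id"
  gene_ids <- raw$gene_id
  for (s in names(raw)[-1L]) {
    num <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric value '", raw[[s]][bad[1L]], "' at gene '", gene_ids[bad[1L]],
           "', sample '", s, "' in ", path, call. = FALSE)
    }
    raw[[s]] <- num
  }
  validate_expression(raw)
  raw
}

#' Write an expression TSV
#'
#' Values are serialized with the shortest decimal representation that
#' round-trips exactly to the same double, so
#' `read_expression_tsv(write_expression_tsv(x))` reproduces `x` bit for
#' value.
#'
#' @param expression A wide expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  validate_expression(expression)
  if (nrow(expression) == 0L) {
    stop("refusing to write an expression table with no genes", call. = FALSE)
  }
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Align an expression table with a sample annotation
#'
#' Verifies that every sample column has exactly one annotation row and vice
#' versa, then reorders the expression columns to the annotation's row
#' order. Mismatches are reported by name.
#'
#' @param expression A wide expression tibble.
#' @param annotation A data frame with a `sample_id` column (exposure or
#'   cohort annotation).
#' @return A list with elements `expression` and `annotation`, sample order
#'   normalized to the annotation.
#' @export
align_annotation <- function(expression, annotation) {
  validate_expression(expression)
  if (!is.data.frame(annotation) || !"sample_id" %in% names(annotation)) {
    stop("annotation must be a data frame with a sample_id column", call. = FALSE)
  }
  ann_ids <- annotation$sample_id
  if (anyDuplicated(ann_ids)) {
    dup <- unique(ann_ids[duplicated(ann_ids)])
    stop("duplicate sample_id in annotation: ", paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  mat_ids <- names(expression)[-1L]
  missing_ann <- setdiff(mat_ids, ann_ids)
  missing_mat <- setdiff(ann_ids, mat_ids)
  if (length(missing_ann) > 0L || length(missing_mat) > 0L) {
    stop("expression/annotation mismatch",
         if (length(missing_ann) > 0L) paste0("; samples without annotation: ", paste(utils::head(missing_ann, 5L), collapse = ", ")),
         if (length(missing_mat) > 0L) paste0("; annotated samples absent from matrix: ", paste(utils::head(missing_mat, 5L), collapse = ", ")),
         call. = FALSE)
  }
  expression <- expression[, c("gene_id", ann_ids), drop = FALSE]
  list(expression = expression, annotation = tibble::as_tibble(annotation))
}

#' Validate an exposure-study sample annotation
#'
#' Exposure annotations describe the in vitro design: an untreated control
#' arm, test-substance arms (substance x dose level x exposure time) and a
#' whole-smoke aqueous-extract (AqE) dose series.
#'
#' @param annotation Data frame with columns `sample_id`, `arm`
#'   (`control`/`substance`/`aqe`), `substance`, `dose_level`, `time_h`,
#'   `replicate`.
#' @return The annotation as a tibble, invisibly returned after checks.
#' @export
validate_exposure_annotation <- function(annotation) {
  req <- c("sample_id", "arm", "substance", "dose_level", "time_h", "replicate")
  miss <- setdiff(req, names(annotation))
  if (length(miss) > 0L) stop("exposure annotation missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(annotation$arm %in% c("control", "substance", "aqe"))) {
    stop("arm must be one of control, substance, aqe", call. = FALSE)
  }
  ctrl <- annotation$arm == "control"
  if (any(!is.na(annotation$substance[ctrl]) & annotation$substance[ctrl] != "")) {
    stop("control rows must have empty substance", call. = FALSE)
  }
  if (any(!is.na(annotation$dose_level[ctrl]) & annotation$dose_level[ctrl] != "")) {
    stop("control rows must have no dose", call. = FALSE)
  }
  invisible(tibble::as_tibble(annotation))
}

#' Validate a cohort sample annotation
#'
#' Cohort annotations label each subject as non-smoker (`NS`), smoker
#' (`SMK`) or COPD patient (`COPD`), with optional age and pack-years
#' covariates and the contributing study.
#'
#' @param annotation Data frame with columns `sample_id`, `status`, and
#'   optionally `age`, `pack_years`, `study`.
#' @return The annotation as a tibble, invisibly returned after checks.
#' @export
validate_cohort_annotation <- function(annotation) {
  req <- c("sample_id", "status")
  miss <- setdiff(req, names(annotation))
  if (length(miss) > 0L) stop("cohort annotation missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(annotation$status)) || !all(annotation$status %in% c("NS", "SMK", "COPD"))) {
    stop("status must be NS, SMK or COPD and never missing", call. = FALSE)
  }
  if ("pack_years" %in% names(annotation)) {
    py <- annotation$pack_years
    if (any(py[!is.na(py)] < 0)) stop("pack_years must be non-negative", call. = FALSE)
  }
  invisible(tibble::as_tibble(annotation))
}
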