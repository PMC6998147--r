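#' Fit a logistic model on panel-gene expression
#'
#' Maximum-likelihood logistic regression of a binary outcome on the log2
#' expression of the given genes, fitted by iteratively reweighted least
#' squares. Convergence is declared when the largest absolute score
#' (gradient) component falls below 1e-8; after 50 iterations the fit
#' returns with `converged = FALSE` and a warning (as happens under perfect
#' separation, which is tolerated rather than penalized).
#'
#' @param expression Wide expression tibble.
#' @param labels Binary outcome per sample column: logical, 0/1 numeric, or
#'   a two-level factor (second level = positive).
#' @param genes Character vector of predictor gene ids (may be empty for an
#'   intercept-only model).
#' @param contrast Optional label (`"NS_vs_SMK"` or `"SMK_vs_COPD"`).
#' @return A `prf_logistic` object: `intercept`, `coefficients` (named),
#'   `contrast`, `n`, `log_lik`, `aic`, `converged`, `iterations`.
#' @export
fit_logistic <- function(expression, labels, genes, contrast = NULL) {
  m <- expression_matrix(expression)
  y <- to_binary(labels)
  if (length(y) != ncol(m)) {
    stop("labels length (", length(y), ") != sample count (", ncol(m), ")", call. = FALSE)
  }
  if (length(unique(y)) < 2L) stop("both outcome classes must be present", call. = FALSE)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0L) {
    stop("model genes absent from matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(m) <= length(genes) + 1L) {
    stop("need n > number of genes + 1", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, t(m[genes, , drop = FALSE]))
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)

  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  last_step <- Inf
  for (iter in seq_len(50L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    # under separation the score saturates to zero while the coefficients
    # keep drifting, so convergence also requires a vanishing Newton step
    if (max(abs(score)) < 1e-8 && last_step < 1e-6) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, score), error = function(e) {
      stop("singular information matrix during IRLS", call. = FALSE)
    })
    beta <- beta + step
    last_step <- max(abs(step))
  }
  if (!converged) {
    warning("IRLS did not converge in 50 iterations (possible separation)", call. = FALSE)
  }
  mu <- pmin(pmax(stats::plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
  log_lik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  coefs <- beta[-1L]
  names(coefs) <- genes
  structure(list(intercept = unname(beta[1L]),
                 coefficients = coefs,
                 contrast = contrast,
                 n = length(y),
                 log_lik = log_lik,
                 aic = 2 * (1 + length(coefs)) - 2 * log_lik,
                 converged = converged,
                 iterations = iter),
            class = "prf_logistic")
}

to_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("factor labels must have exactly two levels", call. = FALSE)
    return(as.integer(labels == levels(labels)[2L]))
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  stop("labels must be logical, 0/1, or a two-level factor", call. = FALSE)
}

#' @export
print.prf_logistic <- function(x, ...) {
  cat("Logistic model", if (!is.null(x$contrast)) paste0(" (", x$contrast, ")"),
      ": intercept ", signif(x$intercept, 5),
      ", ", length(x$coefficients), " gene(s), AIC ", round(x$aic, 2),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.cv_confusion
#' @method tidy prf_logistic
#' @export
tidy.prf_logistic <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname glance.cv_confusion
#' @method glance prf_logistic
#' @export
glance.prf_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, log_lik = x$log_lik, aic = x$aic,
                 df = length(x$coefficients) + 1L, converged = x$converged)
}

#' Bidirectional stepwise AIC gene selection
#'
#' Greedy stepwise search over logistic models: starting from the full
#' candidate model, every single-gene drop and add is evaluated and the
#' move with the lowest AIC taken, stopping when no move improves AIC.
#' Moves are enumerated in lexicographic gene order (drops before adds), so
#' ties resolve deterministically.
#'
#' @param expression Wide expression tibble.
#' @param labels Binary outcome (see [fit_logistic()]).
#' @param candidates Marker-panel tibble or character vector of candidate
#'   genes.
#' @param contrast Optional contrast label carried onto the fit.
#' @param tol Minimum AIC improvement to accept a move.
#' @return The selected `prf_logistic` fit, with the visited-model count in
#'   attribute `n_evaluated`.
#' @export
stepwise_select <- function(expression, labels, candidates, contrast = NULL, tol = 1e-8) {
  genes <- sort(unique(if (is.data.frame(candidates)) candidates$gene_id else candidates))
  if (length(genes) < 1L) stop("need at least one candidate gene", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  # candidate fits are allowed to hit the iteration cap silently (their
  # converged flag is kept); only the selected model warns, once, below
  fit_subset <- function(subset) {
    key <- paste(subset, collapse = "\r")
    if (is.null(cache[[key]])) {
      cache[[key]] <- withCallingHandlers(
        fit_logistic(expression, labels, subset, contrast = contrast),
        warning = function(w) {
          if (grepl("IRLS did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
    cache[[key]]
  }
  current <- sort(genes)
  best <- fit_subset(current)
  repeat {
    moves <- c(lapply(current, function(g) setdiff(current, g)),
               lapply(setdiff(genes, current), function(g) sort(c(current, g))))
    if (length(moves) == 0L) break
    fits <- lapply(moves, fit_subset)
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    j <- which.min(aics)
    if (aics[j] < best$aic - tol) {
      current <- moves[[j]]
      best <- fits[[j]]
    } else break
  }
  attr(best, "n_evaluated") <- length(ls(cache))
  if (!best$converged) {
    warning("selected stepwise model did not converge (possible separation)", call. = FALSE)
  }
  best
}

#' Predicted probability from a logistic model
#'
#' Evaluates `p = 1 / (1 + exp(-(C + sum(coef * expr))))` for every sample.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` so extreme linear
#' predictors never overflow to exactly 0 or 1.
#'
#' @param model A `prf_logistic`.
#' @param expression Wide expression tibble containing every model gene.
#' @return Named numeric vector of probabilities, one per sample.
#' @export
predict_probability <- function(model, expression) {
  stopifnot(inherits(model, "prf_logistic"))
  m <- expression_matrix(expression)
  genes <- names(model$coefficients)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0L) {
    stop("model gene(s) missing from expression: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept +
    if (length(genes) > 0L) drop(crossprod(m[genes, , drop = FALSE], model$coefficients))
    else rep(0, ncol(m))
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  stats::setNames(as.numeric(p), colnames(m))
}

#' The PRF index
#'
#' The potential-risk-factor index is the odds of the joint event "smoker
#' and progressed to COPD": `PRF = (p_smk * p_copd) / (1 - p_smk * p_copd)`.
#' It is strictly increasing in each probability.
#'
#' @param p_smk,p_copd Probabilities in [0, 1) with product < 1
#'   (vectorized).
#' @return Non-negative numeric vector of PRF values.
#' @export
prf_index <- function(p_smk, p_copd) {
  if (any(p_smk < 0 | p_smk >= 1) || any(p_copd < 0 | p_copd >= 1)) {
    stop("probabilities must lie in [0, 1)", call. = FALSE)
  }
  prod <- p_smk * p_copd
  if (any(prod >= 1)) stop("probability product must be < 1", call. = FALSE)
  prod / (1 - prod)
}

#' Fit the two-stage PRF risk model
#'
#' Fits the smoker model (non-smokers vs smokers) and the COPD model
#' (smokers vs COPD) on a marker panel, each by stepwise AIC selection from
#' the full candidate set (or by a plain full fit when `stepwise = FALSE`),
#' and packages them as a `prf_model`. Expression values enter the models
#' as-is (log2 normalized intensities); `scaling_note` records the
#' convention the coefficients expect.
#'
#' @param expression Wide expression tibble.
#' @param annotation Cohort annotation tibble.
#' @param panel Marker-panel tibble or character vector of candidate genes.
#' @param stepwise Perform stepwise AIC selection (default) or fit the full
#'   panel in both models.
#' @param scaling_note Free-text description of the expression convention.
#' @return A `prf_model`: `model_smk`, `model_copd`, `scaling_note`.
#' @export
fit_prf_model <- function(expression, annotation, panel, stepwise = TRUE,
                          scaling_note = "log2 normalized intensities, used as-is") {
  pair <- align_annotation(expression, annotation)
  expression <- pair$expression
  annotation <- validate_cohort_annotation(pair$annotation)
  genes <- if (is.data.frame(panel)) panel$gene_id else panel

  subset_fit <- function(statuses, positive, contrast) {
    keep <- annotation$status %in% statuses
    ex <- expression[, c("gene_id", annotation$sample_id[keep]), drop = FALSE]
    y <- as.integer(annotation$status[keep] == positive)
    if (stepwise) stepwise_select(ex, y, genes, contrast = contrast)
    else fit_logistic(ex, y, sort(genes), contrast = contrast)
  }
  structure(list(
    model_smk = subset_fit(c("NS", "SMK"), "SMK", "NS_vs_SMK"),
    model_copd = subset_fit(c("SMK", "COPD"), "COPD", "SMK_vs_COPD"),
    scaling_note = scaling_note
  ), class = "prf_model")
}

#' @export
print.prf_model <- function(x, ...) {
  cat("PRF risk model\n  smoker model:  ")
  print(x$model_smk)
  cat("  COPD model:    ")
  print(x$model_copd)
  cat("  scaling: ", x$scaling_note, "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.cv_confusion
#' @method tidy prf_model
#' @export
tidy.prf_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$model_smk), model = "NS_vs_SMK"),
    dplyr::mutate(tidy(x$model_copd), model = "SMK_vs_COPD")
  )
}

#' Score samples with a PRF model
#'
#' Computes, per sample, the smoker probability, the COPD probability and
#' their PRF composition. When an annotation is supplied its `status`
#' column is joined onto the result.
#'
#' @param model A `prf_model`.
#' @param expression Wide expression tibble with all model genes.
#' @param annotation Optional cohort annotation.
#' @return A `prf_scores` tibble: `sample_id`, `p_smk`, `p_copd`, `prf`
#'   (and `status` when annotated).
#' @export
score_samples <- function(model, expression, annotation = NULL) {
  stopifnot(inherits(model, "prf_model"))
  p_smk <- predict_probability(model$model_smk, expression)
  p_copd <- predict_probability(model$model_copd, expression)
  out <- tibble::tibble(sample_id = names(p_smk),
                        p_smk = unname(p_smk),
                        p_copd = unname(p_copd),
                        prf = prf_index(unname(p_smk), unname(p_copd)))
  if (!is.null(annotation)) {
    out <- dplyr::left_join(out, annotation[, intersect(c("sample_id", "status"), names(annotation))],
                            by = "sample_id")
  }
  class(out) <- c("prf_scores", class(out))
  out
}

#' Group medians of PRF scores
#'
#' @param scores A `prf_scores` tibble with a `status` column.
#' @return A tibble of per-status medians of `p_smk`, `p_copd`, `prf`.
#' @export
prf_group_medians <- function(scores) {
  stopifnot("status" %in% names(scores))
  scores |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(dplyr::across(c("p_smk", "p_copd", "prf"), stats::median),
                     n = dplyr::n(), .groups = "drop")
}

#' PRF ratio of a treated group versus control
#'
#' Mean treated PRF over mean control PRF, with the dispersion of the
#' treated replicates on the same scale (sd of treated PRFs divided by the
#' control mean).
#'
#' @param treated,control `prf_scores` tibbles (or any data frame with a
#'   `prf` column).
#' @return A one-row tibble: `ratio`, `sd`, `n_treated`, `n_control`.
#' @export
prf_ratio_vs_control <- function(treated, control) {
  if (nrow(treated) == 0L || nrow(control) == 0L) stop("empty input", call. = FALSE)
  mc <- mean(control$prf)
  if (mc == 0) stop("control mean PRF is zero", call. = FALSE)
  tibble::tibble(ratio = mean(treated$prf) / mc,
                 sd = stats::sd(treated$prf) / mc,
                 n_treated = nrow(treated), n_control = nrow(control))
}

#' Pearson correlation of PRF with a covariate
#'
#' Product-moment correlation between per-sample PRF and a covariate such
#' as age or pack-years; incomplete pairs are dropped. A constant input has
#' no defined correlation and returns `NA` with a warning.
#'
#' @param scores A `prf_scores` tibble.
#' @param covariate Numeric vector aligned with `scores` rows.
#' @return A single Pearson R (possibly `NA`).
#' @export
covariate_correlation <- function(scores, covariate) {
  stopifnot(nrow(scores) == length(covariate))
  ok <- is.finite(scores$prf) & is.finite(covariate)
  if (sum(ok) < 3L) stop("need at least three complete pairs", call. = FALSE)
  x <- scores$prf[ok]; y <- covariate[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

model_to_list <- function(m) {
  list(intercept = m$intercept,
       coefficients = as.list(m$coefficients),
       contrast = m$contrast,
       fit_metadata = list(n = m$n, log_lik = m$log_lik, aic = m$aic,
                           converged = m$converged))
}

list_to_model <- function(l, contrast_default) {
  if (is.null(l$intercept) || is.null(l$coefficients)) {
    stop("model JSON must contain 'intercept' and 'coefficients'", call. = FALSE)
  }
  md <- l$fit_metadata
  structure(list(intercept = as.numeric(l$intercept),
                 coefficients = unlist(l$coefficients),
                 contrast = l$contrast %||% contrast_default,
                 n = md$n %||% NA_integer_,
                 log_lik = md$log_lik %||% NA_real_,
                 aic = md$aic %||% NA_real_,
                 converged = md$converged %||% NA,
                 iterations = NA_integer_),
            class = "prf_logistic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a PRF model as JSON
#'
#' The JSON schema is `{"model_smk": {"intercept": ..., "coefficients":
#' {gene: value, ...}}, "model_copd": {...}, "scaling_note": "..."}`;
#' round-trips are value-exact (full-precision serialization).
#'
#' @param model A `prf_model`.
#' @param path File path.
#' @return `save_prf_model()`: `path` invisibly; `load_prf_model()`: a
#'   `prf_model`.
#' @export
save_prf_model <- function(model, path) {
  stopifnot(inherits(model, "prf_model"))
  jsonlite::write_json(list(model_smk = model_to_list(model$model_smk),
                            model_copd = model_to_list(model$model_copd),
                            scaling_note = model$scaling_note),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_prf_model
#' @export
load_prf_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(l$model_smk) || is.null(l$model_copd)) {
    stop("PRF model JSON must contain 'model_smk' and 'model_copd'", call. = FALSE)
  }
  structure(list(model_smk = list_to_model(l$model_smk, "NS_vs_SMK"),
                 model_copd = list_to_model(l$model_copd, "SMK_vs_COPD"),
                 scaling_note = l$scaling_note %||% ""),
            class = "prf_model")
}

#' The published reference PRF model
#'
#' Loads the packaged parameters of the published two-stage risk model for
#' the 15-gene smoke-response panel: an 11-gene non-smoker-vs-smoker logit
#' (intercept 1.6715) and a 4-gene smoker-vs-COPD logit (intercept
#' -0.8555), estimated by stepwise logistic regression on pooled public
#' airway cohorts. Note the expression scaling behind these published
#' coefficient magnitudes is tied to the original normalization; scoring
#' other data may require recalibration (see `scaling_note`).
#'
#' @return A `prf_model`.
#' @export
prf_reference_model <- function() {
  load_prf_model(system.file("extdata", "prf_reference_model.json",
                             package = "prfpipe", mustWork = TRUE))
}
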