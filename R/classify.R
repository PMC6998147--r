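#' Cross-validation configuration
#'
#' @param k Number of folds (stratified by class).
#' @param repeats Number of independent repeats of the whole k-fold split.
#' @param seed Master RNG seed; per-repeat seeds are drawn once from it
#'   (`sample.int(.Machine$integer.max, repeats)`), so runs with the same
#'   master seed share the same repeat-r split and fit for every prefix of
#'   repeats.
#' @param num_trees Trees in the random-forest ensemble.
#' @param mtry Features tried per split; `NULL` for the `floor(sqrt(p))`
#'   default.
#' @param classes Class labels, in display order.
#' @return A config list of class `cv_config`.
#' @export
cv_config <- function(k = 5L, repeats = 100L, seed = 1L,
                      num_trees = 500L, mtry = NULL,
                      classes = c("NS", "SMK", "COPD")) {
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), num_trees = as.integer(num_trees),
                 mtry = mtry, classes = classes),
            class = "cv_config")
}

#' Random-forest classifier behind the fit/predict contract
#'
#' The evaluator accepts any classifier expressed as a `fit(x, y)` /
#' `predict(model, x)` pair; this is the default, a standard random forest.
#'
#' @param num_trees Number of trees.
#' @param mtry Features per split (`NULL` = `floor(sqrt(p))`).
#' @return A list with elements `fit` and `predict`.
#' @export
rf_classifier <- function(num_trees = 500L, mtry = NULL) {
  list(
    fit = function(x, y) {
      m <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(x)))) else mtry
      randomForest::randomForest(x = x, y = y, ntree = num_trees, mtry = m)
    },
    predict = function(model, x) stats::predict(model, newdata = x)
  )
}

# Stratified fold assignment: per class, shuffle members and deal folds
# round-robin, so remainders spread evenly.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer members (", length(idx), ") than folds (", k, ")",
           call. = FALSE)
    }
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified cross-validated panel classification
#'
#' For each repeat: draw a stratified k-fold split, train the classifier on
#' the panel genes of the training folds, predict the held-out folds, and
#' accumulate the predicted-by-truth confusion counts. Counts are averaged
#' over repeats (hence fractional). Fully reproducible from the config
#' seed.
#'
#' @param expression Wide expression tibble.
#' @param annotation Cohort annotation tibble (`sample_id`, `status`).
#' @param panel Marker-panel tibble or character vector of gene ids.
#' @param config A [cv_config()].
#' @param classifier A fit/predict pair, default [rf_classifier()] with the
#'   config's tree count and mtry.
#' @return A `cv_confusion` object: `mean_counts` (predicted x truth
#'   matrix), `true_rate` (per-truth-class recall), `predicted_rate`
#'   (per-predicted-row precision), `overall_accuracy`, `macro_accuracy`,
#'   `repeat_accuracy` (per-repeat overall accuracies), `n_samples`,
#'   `config`.
#' @export
repeated_cv <- function(expression, annotation, panel,
                        config = cv_config(), classifier = NULL) {
  pair <- align_annotation(expression, annotation)
  expression <- pair$expression
  annotation <- pair$annotation
  genes <- if (is.data.frame(panel)) panel$gene_id else panel
  m <- expression_matrix(expression)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0L) {
    stop("panel genes absent from matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(classifier)) classifier <- rf_classifier(config$num_trees, config$mtry)
  x <- as.data.frame(t(m[genes, , drop = FALSE]))
  y <- factor(annotation$status, levels = config$classes)
  if (any(is.na(y))) stop("status labels outside configured classes", call. = FALSE)
  n <- length(y)

  set.seed(config$seed)
  repeat_seeds <- sample.int(.Machine$integer.max, config$repeats)

  counts <- matrix(0, length(config$classes), length(config$classes),
                   dimnames = list(predicted = config$classes, truth = config$classes))
  repeat_accuracy <- numeric(config$repeats)
  for (r in seq_len(config$repeats)) {
    set.seed(repeat_seeds[r])
    folds <- stratified_folds(y, config$k)
    pred <- factor(rep(NA_character_, n), levels = config$classes)
    for (f in seq_len(config$k)) {
      test <- folds == f
      fit <- classifier$fit(x[!test, , drop = FALSE], y[!test])
      pred[test] <- classifier$predict(fit, x[test, , drop = FALSE])
    }
    tab <- table(predicted = pred, truth = y)
    counts <- counts + unclass(tab)
    repeat_accuracy[r] <- sum(diag(tab)) / n
  }
  mean_counts <- counts / config$repeats

  structure(list(
    mean_counts = mean_counts,
    true_rate = diag(mean_counts) / colSums(mean_counts),
    predicted_rate = diag(mean_counts) / rowSums(mean_counts),
    overall_accuracy = sum(diag(mean_counts)) / n,
    macro_accuracy = mean(diag(mean_counts) / colSums(mean_counts)),
    repeat_accuracy = repeat_accuracy,
    n_samples = n,
    config = config
  ), class = "cv_confusion")
}

#' Per-class true rates from a confusion summary
#'
#' The true rate of a class is its diagonal mean count divided by the total
#' number of samples truly in that class (the column sum of the
#' predicted-by-truth grid), i.e. per-class recall. A class never observed
#' yields a missing rate.
#'
#' @param summary A `cv_confusion` object or a predicted-by-truth count
#'   matrix.
#' @return Named numeric vector of per-class rates (NA for empty classes).
#' @export
true_rates <- function(summary) {
  counts <- if (inherits(summary, "cv_confusion")) summary$mean_counts else summary
  totals <- colSums(counts)
  rate <- diag(counts) / totals
  rate[totals == 0] <- NA_real_
  rate
}

#' @export
print.cv_confusion <- function(x, digits = 3, ...) {
  cat("Repeated ", x$config$k, "-fold cross-validation (", x$config$repeats,
      " repeats, ", x$n_samples, " samples)\n", sep = "")
  grid <- cbind(round(x$mean_counts, 1), `true rate` = round(x$true_rate, 2))
  print(grid)
  cat("overall accuracy: ", round(x$overall_accuracy, digits),
      "   macro accuracy: ", round(x$macro_accuracy, digits), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation confusion summary
#'
#' @param x A `cv_confusion` object.
#' @param ... Unused.
#' @return A long tibble with `predicted`, `truth`, `mean_count`.
#' @method tidy cv_confusion
#' @export
tidy.cv_confusion <- function(x, ...) {
  as.data.frame(as.table(x$mean_counts), responseName = "mean_count") |>
    tibble::as_tibble() |>
    dplyr::mutate(predicted = as.character(.data$predicted),
                  truth = as.character(.data$truth))
}

#' One-row summary of a cross-validation run
#'
#' @param x A `cv_confusion` object.
#' @param ... Unused.
#' @return A one-row tibble: `overall_accuracy`, `macro_accuracy`, `k`,
#'   `repeats`, `n_samples`.
#' @method glance cv_confusion
#' @export
glance.cv_confusion <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 macro_accuracy = x$macro_accuracy,
                 k = x$config$k, repeats = x$config$repeats,
                 n_samples = x$n_samples)
}
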