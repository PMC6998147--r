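make_logit_data <- function(n, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  m <- matrix(stats::rnorm(n * p), nrow = p,
              dimnames = list(sprintf("gene%02d", seq_len(p)), sprintf("s%04d", seq_len(n))))
  eta <- intercept + drop(crossprod(m, beta))
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(expression = as_expression_tbl(m), y = y, m = m)
}

test_that("an intercept-only fit reproduces the log-odds closed form", {
  d <- make_logit_data(100, beta = 0.0, seed = 3)
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(d$expression, y, character(0))
  expect_equal(fit$intercept, log(30 / 70), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 - 2 * fit$log_lik)
})

test_that("IRLS recovers planted parameters and matches glm and a generic optimizer", {
  d <- make_logit_data(5000, beta = 1.5, intercept = 0, seed = 11)
  fit <- fit_logistic(d$expression, d$y, "gene01")
  gfit <- stats::glm(d$y ~ t(d$m), family = stats::binomial())
  se <- summary(gfit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$intercept - 0), 3 * se[1])
  expect_lt(abs(fit$coefficients[["gene01"]] - 1.5), 3 * se[2])
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(stats::coef(gfit)), tolerance = 1e-8)
  expect_equal(fit$aic, stats::AIC(gfit), tolerance = 1e-8)

  # generic-optimizer cross-check on small random datasets
  for (seed in 1:20) {
    d2 <- make_logit_data(200, beta = c(0.8, -0.5), intercept = 0.3, seed = seed)
    fit2 <- fit_logistic(d2$expression, d2$y, rownames(d2$m))
    X <- cbind(1, t(d2$m))
    obj <- logistic_nll(X, d2$y)
    opt <- stats::optim(rep(0, 3), obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    expect_lt(max(abs(c(fit2$intercept, fit2$coefficients) - opt$par)), 1e-5)
  }
})

test_that("logistic fitting rejects one-class labels and singular designs", {
  d <- make_logit_data(50, beta = 1, seed = 2)
  expect_error(fit_logistic(d$expression, rep(1, 50), "gene01"), "both outcome classes")
  dup <- dplyr::bind_rows(d$expression, dplyr::mutate(d$expression[1, ], gene_id = "copy"))
  expect_error(fit_logistic(dup, d$y, c("gene01", "copy")), "singular")
})

test_that("perfect separation is tolerated with a warning, not an error", {
  m <- matrix(c(1:10), nrow = 1, dimnames = list("g1", paste0("s", 1:10)))
  y <- as.integer(1:10 > 5)
  expect_warning(fit <- fit_logistic(as_expression_tbl(m), y, "g1"), "converge")
  expect_false(fit$converged)
  expect_true(is.finite(fit$aic))
})

test_that("stepwise selection keeps informative genes and never beats the subset oracle", {
  set.seed(77)
  beta <- c(1.5, -1.5, 0, 0, 0, 0)
  d <- make_logit_data(800, beta = beta, seed = 77)
  sel <- stepwise_select(d$expression, d$y, rownames(d$m))
  expect_true(all(c("gene01", "gene02") %in% names(sel$coefficients)))
  full <- fit_logistic(d$expression, d$y, sort(rownames(d$m)))
  null <- fit_logistic(d$expression, d$y, character(0))
  expect_lte(sel$aic, full$aic + 1e-8)
  expect_lte(sel$aic, null$aic + 1e-8)

  # exhaustive oracle on one dataset: greedy must match the best subset here
  genes <- rownames(d$m)
  subsets <- unlist(lapply(0:6, function(k) utils::combn(genes, k, simplify = FALSE)),
                    recursive = FALSE)
  aics <- vapply(subsets, function(s) fit_logistic(d$expression, d$y, s)$aic, numeric(1))
  expect_lte(sel$aic, min(aics) + 1e-6)
})

test_that("predicted probabilities follow the logistic closed form with guards", {
  ref <- prf_reference_model()
  zero <- as_expression_tbl(matrix(0, nrow = 15, ncol = 2, dimnames = list(
    default_marker_panel()$gene_id, c("a", "b"))))
  p <- predict_probability(ref$model_smk, zero)
  expect_equal(unname(p), rep(stats::plogis(1.6715), 2), tolerance = 1e-12)
  expect_equal(round(unname(p)[1], 4), 0.8418)

  lin0 <- structure(list(intercept = 0, coefficients = stats::setNames(numeric(0), character(0)),
                         contrast = NULL, n = 0L, log_lik = NA_real_, aic = NA_real_,
                         converged = TRUE, iterations = 0L), class = "prf_logistic")
  expect_equal(unname(predict_probability(lin0, zero)), c(0.5, 0.5))

  big <- structure(list(intercept = 800, coefficients = stats::setNames(numeric(0), character(0)),
                        contrast = NULL, n = 0L, log_lik = NA_real_, aic = NA_real_,
                        converged = TRUE, iterations = 0L), class = "prf_logistic")
  pbig <- unname(predict_probability(big, zero))
  expect_true(all(pbig < 1 & is.finite(pbig)))

  missing_gene <- zero[-1, ]
  expect_error(predict_probability(ref$model_smk, missing_gene),
               default_marker_panel()$gene_id[1])
})

test_that("the PRF index is the odds of the probability product", {
  expect_equal(prf_index(0, 0.7), 0)
  expect_equal(prf_index(0.5 / 0.9, 0.9), 1)   # product 0.5 -> odds 1
  expect_equal(prf_index(0.8, 0.5), 0.4 / 0.6)
  # strictly increasing in each argument
  expect_gt(prf_index(0.6, 0.5), prf_index(0.5, 0.5))
  expect_gt(prf_index(0.5, 0.6), prf_index(0.5, 0.5))
  expect_error(prf_index(1, 0.5), "\\[0, 1\\)")
  expect_error(prf_index(-0.1, 0.5), "\\[0, 1\\)")
})

test_that("scoring composes the two models and is deterministic per sample", {
  sim <- simulate_cohort(small_cohort_config(seed = 41))
  model <- fit_prf_model(sim$expression, sim$annotation, default_marker_panel(),
                         stepwise = FALSE)
  scores <- score_samples(model, sim$expression, sim$annotation)
  expect_equal(scores$prf / (1 + scores$prf), scores$p_smk * scores$p_copd,
               tolerance = 1e-12)
  # duplicating a sample column duplicates its score exactly
  dup <- sim$expression
  dup$dup_sample <- dup[[2]]
  s2 <- score_samples(model, dup)
  expect_equal(s2$prf[s2$sample_id == "dup_sample"],
               scores$prf[scores$sample_id == names(sim$expression)[2]])

  med <- prf_group_medians(scores)
  expect_setequal(med$status, c("NS", "SMK", "COPD"))
})

test_that("an intercept-only reference model scores every sample identically", {
  ref <- prf_reference_model()
  int_only <- ref
  int_only$model_smk$coefficients <- stats::setNames(numeric(0), character(0))
  int_only$model_copd$coefficients <- stats::setNames(numeric(0), character(0))
  ex <- tiny_expression()
  sc <- score_samples(int_only, ex)
  expected <- prf_index(stats::plogis(1.6715), stats::plogis(-0.8555))
  expect_equal(sc$prf, rep(expected, 3), tolerance = 1e-12)
  expect_equal(expected, 0.3354, tolerance = 5e-4)
})

test_that("PRF ratios versus control behave homogeneously", {
  treated <- tibble::tibble(prf = c(0.4, 0.5, 0.6))
  control <- tibble::tibble(prf = c(0.4, 0.5, 0.6))
  expect_equal(prf_ratio_vs_control(treated, control)$ratio, 1)
  doubled <- tibble::tibble(prf = treated$prf * 2)
  expect_equal(prf_ratio_vs_control(doubled, control)$ratio, 2)
  expect_equal(prf_ratio_vs_control(doubled, control)$sd,
               stats::sd(doubled$prf) / mean(control$prf))
  expect_error(prf_ratio_vs_control(treated, tibble::tibble(prf = c(0, 0))), "zero")
})

test_that("covariate correlation matches the product-moment definition", {
  sc <- tibble::tibble(prf = c(0.1, 0.2, 0.3, 0.5))
  expect_equal(covariate_correlation(sc, sc$prf), 1)
  expect_equal(covariate_correlation(sc, -sc$prf), -1)
  expect_warning(r <- covariate_correlation(sc, rep(2, 4)), "constant")
  expect_true(is.na(r))
  expect_error(covariate_correlation(sc[1:2, ], c(1, 2)), "three")

  # independence null: correlations concentrate near zero
  set.seed(100)
  rs <- replicate(100, {
    x <- tibble::tibble(prf = stats::rnorm(200))
    covariate_correlation(x, stats::rnorm(200))
  })
  expect_gte(mean(abs(rs) < 0.2), 0.95)
})

test_that("PRF models round-trip through JSON exactly", {
  sim <- simulate_cohort(small_cohort_config(seed = 51))
  model <- fit_prf_model(sim$expression, sim$annotation,
                         default_marker_panel()$gene_id[1:5], stepwise = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  save_prf_model(model, path)
  back <- load_prf_model(path)
  expect_identical(back$model_smk$intercept, model$model_smk$intercept)
  expect_identical(back$model_smk$coefficients, model$model_smk$coefficients)
  expect_identical(back$model_copd$coefficients, model$model_copd$coefficients)
  expect_identical(back$scaling_note, model$scaling_note)
  expect_error(load_prf_model(withr::local_tempfile(lines = "{}", fileext = ".json")),
               "model_smk")
})

test_that("the packaged reference model carries the published parameters", {
  ref <- prf_reference_model()
  expect_equal(ref$model_smk$intercept, 1.6715)
  expect_equal(ref$model_copd$intercept, -0.8555)
  expect_equal(ref$model_smk$coefficients[["HILPDA"]], 3.2193)
  expect_setequal(names(ref$model_copd$coefficients),
                  c("AREG", "DUSP6", "EFNA1", "TXNIP"))
  expect_length(ref$model_smk$coefficients, 11L)
})
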