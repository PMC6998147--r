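test_that("intensity filter keeps expressed genes and drops floor-dwellers", {
  # 10 genes: one sits below the pooled 20th percentile in every sample
  set.seed(1)
  vals <- matrix(stats::runif(27, 6, 8), nrow = 9)
  m <- rbind(vals, low = c(0.1, 0.2, 0.15))
  rownames(m) <- c(sprintf("g%02d", 1:9), "low")
  colnames(m) <- c("s1", "s2", "s3")
  ex <- as_expression_tbl(m)
  # brute-force oracle on the fixture
  lin <- 2^m
  floor_q <- stats::quantile(as.vector(lin), 0.2, names = FALSE)
  oracle <- rownames(m)[apply(lin, 1, max) >= floor_q &
                          apply(lin, 1, sd) / rowMeans(lin) < 0.5]
  expect_false("low" %in% oracle)
  expect_identical(filter_genes(ex), oracle)

  # a constant, well-expressed gene is always retained (CV = 0)
  ex2 <- as_expression_tbl(rbind(m, const = c(7, 7, 7)))
  expect_true("const" %in% filter_genes(ex2))
})

test_that("the CV filter removes a gene with linear values (1, 1, 4)", {
  m <- rbind(target = log2(c(1, 1, 4)),   # linear CV = sqrt(3)/2 ~ 0.866
             steady = log2(c(2, 2.1, 2)))
  colnames(m) <- c("s1", "s2", "s3")
  ex <- as_expression_tbl(m)
  kept <- filter_genes(ex, intensity_percentile = 0, cv_threshold = 0.5)
  expect_identical(kept, "steady")
  # at a laxer threshold just above its CV the gene survives
  expect_true("target" %in% filter_genes(ex, intensity_percentile = 0, cv_threshold = 0.87))
})

test_that("single-gene moderated t reduces to the ordinary pooled t", {
  ex <- as_expression_tbl(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                                 dimnames = list("g1", paste0("s", 1:6))))
  res <- moderated_t(ex, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$t_mod, 3.674235, tolerance = 1e-6)
  expect_equal(res$df_total, 4)
  tt <- stats::t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
})

test_that("identical group means give t = 0 and p = 1", {
  set.seed(5)
  m <- matrix(rnorm(60, 7, 0.3), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  m[1, 4:6] <- m[1, 1:3]  # exactly equal means and spread
  res <- moderated_t(as_expression_tbl(m), paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p_raw[1], 1)
})

test_that("prior-df limits recover the pooled t and the pure prior variance", {
  set.seed(8)
  m <- matrix(rnorm(600, 7, 0.5), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  ex <- as_expression_tbl(m)
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)

  plain <- moderated_t(ex, ga, gb, prior_df = 0)
  pooled_t <- apply(m, 1, function(x) {
    unname(stats::t.test(x[4:6], x[1:3], var.equal = TRUE)$statistic)
  })
  expect_lt(max(abs(plain$t_mod - pooled_t)), 1e-10)

  s02 <- 0.2
  inf <- moderated_t(ex, ga, gb, prior_df = Inf, prior_var = s02)
  delta <- rowMeans(m[, 4:6]) - rowMeans(m[, 1:3])
  expect_equal(inf$t_mod, unname(delta / sqrt(s02 * (2 / 3))), tolerance = 1e-12)
  expect_true(all(is.infinite(inf$df_total)))
})

test_that("moderated t agrees with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(42)
  m <- matrix(rnorm(300 * 6, 7, 0.4), nrow = 300,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
  m[1:20, 4:6] <- m[1:20, 4:6] + 1
  res <- moderated_t(as_expression_tbl(m), paste0("s", 1:3), paste0("s", 4:6))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, c(0, 0, 0, 1, 1, 1))))
  expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(res, "prior_var"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(res$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("degenerate and misused inputs are rejected", {
  ex <- tiny_expression()
  expect_error(moderated_t(ex, "s1", c("s2", "s3")), "at least two")
  expect_error(moderated_t(ex, c("s1", "s2"), c("s2", "s3")), "disjoint")
  flat <- as_expression_tbl(matrix(5, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6))))
  expect_error(moderated_t(flat, paste0("s", 1:3), paste0("s", 4:6)), "zero variance")
})

test_that("BH adjustment matches hand-derivable cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("BH adjustment equals the brute-force step-up oracle and is monotone", {
  set.seed(99)
  for (i in 1:200) {
    p <- stats::runif(sample(1:120, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # raising one p never lowers any adjusted value
  p <- stats::runif(40)
  base <- bh_adjust(p)
  for (j in c(1, 17, 40)) {
    p2 <- p
    p2[j] <- min(1, p2[j] + 0.3)
    expect_true(all(bh_adjust(p2) >= base - 1e-12))
  }
})

test_that("signed fold change follows the log2 difference and is antisymmetric", {
  m <- rbind(zero = c(5, 5, 5, 5), up = c(5, 5, 6, 6), down = c(6, 6, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  ex <- as_expression_tbl(m)
  fc <- fold_change(ex, c("s1", "s2"), c("s3", "s4"))
  expect_equal(fc$fold_change, c(1, 2, -2))
  rev <- fold_change(ex, c("s3", "s4"), c("s1", "s2"))
  expect_equal(rev$fold_change[2:3], -fc$fold_change[2:3])
  expect_true(all(abs(fc$fold_change) >= 1))
})

test_that("DEG calling applies FDR and fold-change thresholds per gene", {
  stats_tbl <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    fold_change = c(1.6, 1.4, -1.8, 2.5),
    p_fdr = c(0.04, 0.04, 0.01, 0.2),
    direction = c("up", "up", "down", "up")
  )
  set1 <- call_degs(stats_tbl, fdr_cut = 0.05, fc_cut = 1.5)
  expect_identical(set1$gene_id, c("a", "c"))
  expect_identical(set1$direction, c("up", "down"))
  set2 <- call_degs(stats_tbl, fdr_cut = 0.05, fc_cut = NULL)
  expect_identical(set2$gene_id, c("a", "b", "c"))
})

test_that("deg_stats assembles a coherent per-gene table", {
  set.seed(12)
  m <- matrix(rnorm(50 * 6, 7, 0.3), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  m[1, 4:6] <- m[1, 4:6] + 2
  st <- deg_stats(as_expression_tbl(m), paste0("s", 1:3), paste0("s", 4:6),
                  contrast = list(arm = "aqe", dose_level = "1"))
  expect_true(all(st$p_fdr >= st$p_raw - 1e-15))
  expect_true(all(abs(st$fold_change) >= 1))
  expect_true(all(sign(st$fold_change) == sign(st$log2_fc) | st$log2_fc == 0))
  expect_identical(attr(call_degs(st), "contrast"), list(arm = "aqe", dose_level = "1"))
})
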