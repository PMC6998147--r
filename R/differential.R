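#' Filter low-intensity and high-variability genes
#'
#' Mirrors the pre-test probe filter used on normalized microarray
#' intensities: a gene is dropped if its intensity lies below the pooled
#' 20th percentile in every sample (i.e. its maximum linear-scale value is
#' below the pooled quantile), or if its linear-scale coefficient of
#' variation (sd/mean across samples) is at or above `cv_threshold`. Both
#' statistics are computed on linear intensities (`2^x`), since the input
#' holds log2 values. Gene order is preserved.
#'
#' @param expression A wide expression tibble (log2 scale).
#' @param intensity_percentile Pooled-distribution percentile in [0, 100)
#'   defining the low-intensity floor.
#' @param cv_threshold Coefficient-of-variation cutoff (fraction); genes at
#'   or above it are removed.
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(expression, intensity_percentile = 20, cv_threshold = 0.50) {
  m <- 2^expression_matrix(expression)
  if (nrow(m) == 0L) stop("empty expression matrix", call. = FALSE)
  if (ncol(m) < 2L) stop("filtering needs at least two samples", call. = FALSE)
  stopifnot(intensity_percentile >= 0, intensity_percentile < 100, cv_threshold > 0)
  floor_q <- stats::quantile(as.vector(m), probs = intensity_percentile / 100, names = FALSE)
  max_ok <- apply(m, 1L, max) >= floor_q
  cv <- apply(m, 1L, stats::sd) / rowMeans(m)
  rownames(m)[max_ok & cv < cv_threshold]
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Method-of-moments fit of the scaled inverse chi-square prior on gene-wise
# variances: matches the mean and variance of log(s^2) against the
# theoretical log-F moments (digamma/trigamma). Returns prior df d0
# (possibly Inf) and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e)
  excess <- e_var - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread of log-variances at or below its sampling floor:
    # variances are exchangeable, the prior is degenerate (d0 = Inf)
    d0 <- Inf
    s02 <- exp(e_mean)
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-test for one two-group contrast
#'
#' Per gene, computes the log2 mean difference `group_b - group_a`, the
#' pooled variance on `n_a + n_b - 2` degrees of freedom, shrinks gene-wise
#' variances toward a prior fitted across genes by method-of-moments on the
#' log sample variances (with a degenerate `d0 = Inf` branch when the
#' spread of log-variances falls below its theoretical sampling floor), and
#' tests `t = delta / (s_tilde * sqrt(1/n_a + 1/n_b))` against a t
#' distribution on `d0 + df` degrees of freedom (two-sided).
#'
#' With a single gene no prior can be fitted and the statistic reduces to
#' the ordinary pooled two-sample t. Genes with zero residual variance
#' receive the prior variance `s0^2` as their shrunken variance.
#'
#' @param expression A wide expression tibble (log2 scale).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   length >= 2. `group_a` is the reference (e.g. control).
#' @param prior_df,prior_var Optional overrides of the fitted prior
#'   (`d0`, `s0^2`); `prior_df = 0` yields the ordinary pooled t,
#'   `prior_df = Inf` uses `prior_var` (or the fitted `s0^2`) exactly.
#' @return A tibble with columns `gene_id`, `mean_a`, `mean_b`, `log2_fc`,
#'   `t_mod`, `df_total`, `p_raw`; the fitted prior is attached as
#'   attributes `prior_df` and `prior_var`.
#' @export
moderated_t <- function(expression, group_a, group_b,
                        prior_df = NULL, prior_var = NULL) {
  m <- expression_matrix(expression)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0L) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  n_a <- length(group_a); n_b <- length(group_b)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  delta <- mean_b - mean_a
  df <- n_a + n_b - 2
  ss <- rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)
  s2 <- ss / df
  if (all(s2 == 0)) stop("degenerate input: zero variance at every gene", call. = FALSE)

  if (is.null(prior_df)) {
    if (nrow(m) < 2L) {
      prior <- list(d0 = 0, s02 = NA_real_)
    } else {
      prior <- fit_variance_prior(s2, df)
    }
  } else {
    prior <- list(d0 = prior_df,
                  s02 = if (!is.null(prior_var)) prior_var else fit_variance_prior(s2, df)$s02)
  }
  d0 <- prior$d0; s02 <- prior$s02

  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    s2_post[s2 == 0] <- s02  # zero residual variance: prior floor
  }
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  df_total <- d0 + df
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- tibble::tibble(gene_id = rownames(m), mean_a = unname(mean_a),
                        mean_b = unname(mean_b), log2_fc = unname(delta),
                        t_mod = unname(t_mod),
                        df_total = rep(df_total, length(delta)), p_raw = unname(p_raw))
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: `adj_(i) = min_{j >= i}
#' (m * p_(j) / j)` over the sorted p-values, capped at 1 and mapped back to
#' input order. Input validation plus delegation to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Signed linear fold change
#'
#' Converts the log2 mean difference `delta = mean_b - mean_a` into the
#' conventional signed linear fold change: `2^delta` for `delta >= 0`,
#' `-2^(-delta)` otherwise, so `|FC| >= 1` always and the sign gives the
#' direction of change in `group_b` relative to `group_a`.
#'
#' @inheritParams moderated_t
#' @return A tibble with `gene_id`, `log2_fc`, `fold_change`.
#' @export
fold_change <- function(expression, group_a, group_b) {
  m <- expression_matrix(expression)
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0L) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  delta <- unname(rowMeans(m[, group_b, drop = FALSE]) - rowMeans(m[, group_a, drop = FALSE]))
  tibble::tibble(gene_id = rownames(m), log2_fc = delta,
                 fold_change = ifelse(delta >= 0, 2^delta, -2^(-delta)))
}

#' Full differential statistics for one contrast
#'
#' Combines [moderated_t()], [fold_change()] and [bh_adjust()] into the
#' per-gene differential table for `group_b` versus `group_a`.
#'
#' @inheritParams moderated_t
#' @param contrast Optional label describing the contrast.
#' @return A `deg_results` tibble with columns `gene_id`, `log2_fc`,
#'   `fold_change`, `t_mod`, `df_total`, `p_raw`, `p_fdr`, `direction`
#'   (`up`/`down`/`none`; `none` only when `log2_fc` is exactly 0).
#' @export
deg_stats <- function(expression, group_a, group_b, contrast = NULL,
                      prior_df = NULL, prior_var = NULL) {
  tt <- moderated_t(expression, group_a, group_b, prior_df = prior_df, prior_var = prior_var)
  out <- tt |>
    dplyr::mutate(fold_change = ifelse(.data$log2_fc >= 0, 2^.data$log2_fc, -2^(-.data$log2_fc)),
                  p_fdr = bh_adjust(.data$p_raw),
                  direction = dplyr::case_when(.data$log2_fc > 0 ~ "up",
                                               .data$log2_fc < 0 ~ "down",
                                               TRUE ~ "none")) |>
    dplyr::select("gene_id", "log2_fc", "fold_change", "t_mod", "df_total",
                  "p_raw", "p_fdr", "direction")
  attr(out, "prior_df") <- attr(tt, "prior_df")
  attr(out, "prior_var") <- attr(tt, "prior_var")
  attr(out, "contrast") <- contrast
  class(out) <- c("deg_results", class(out))
  out
}

#' Threshold differential statistics into a DEG set
#'
#' A gene is called differentially expressed when `p_fdr < fdr_cut` and,
#' if a fold-change cutoff is given, `|fold_change| > fc_cut`. The returned
#' set is a tibble of `(gene_id, direction)` pairs with the contrast label
#' attached.
#'
#' @param stats A [deg_stats()] tibble.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param fc_cut Absolute linear fold-change threshold, or `NULL` for none.
#' @return A DEG-set tibble (`gene_id`, `direction`) with attribute
#'   `contrast`.
#' @export
call_degs <- function(stats, fdr_cut = 0.05, fc_cut = NULL) {
  stopifnot(all(c("gene_id", "p_fdr", "fold_change", "direction") %in% names(stats)))
  keep <- stats$p_fdr < fdr_cut
  if (!is.null(fc_cut)) keep <- keep & abs(stats$fold_change) > fc_cut
  out <- tibble::as_tibble(stats[keep & stats$direction != "none",
                                 c("gene_id", "direction")])
  attr(out, "contrast") <- attr(stats, "contrast")
  out
}
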