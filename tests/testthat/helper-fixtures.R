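# Shared fixtures and independent oracles, all built in code.

# tiny deterministic expression table
tiny_expression <- function() {
  as_expression_tbl(matrix(
    c(1.5, 2.25, 3.125,
      4.0, 5.5, 6.75,
      7.1, 8.2, 9.3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3"))
  ))
}

# DEG-set tibble from parallel vectors
deg_set <- function(genes, dirs, contrast = NULL) {
  out <- tibble::tibble(gene_id = genes, direction = dirs)
  attr(out, "contrast") <- contrast
  out
}

# independent brute-force BH step-up oracle: adj_(i) = min_{j>=i} m p_(j)/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# negative log-likelihood and gradient of the logistic model, for the
# generic-optimizer cross-check of the IRLS fit
logistic_nll <- function(X, y) {
  list(
    fn = function(beta) {
      eta <- drop(X %*% beta)
      sum(log1p(exp(-abs(eta)))) + sum(pmax(eta, 0)) - sum(y * eta)
    },
    gr = function(beta) {
      mu <- stats::plogis(drop(X %*% beta))
      drop(crossprod(X, mu - y))
    }
  )
}

# small exposure config for fast mechanism tests (strong, clean signal)
small_exposure_config <- function(seed = 11L, effect = 1.2, ...) {
  exposure_sim_config(n_genes = 300L, panel = default_marker_panel(effect = effect),
                      noise_sd = 0.2, seed = seed, ...)
}

small_cohort_config <- function(seed = 11L, ...) {
  cohort_sim_config(n_per_group = c(NS = 20L, SMK = 26L, COPD = 14L),
                    n_genes = 120L, seed = seed, ...)
}
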