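# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they share no code path with the implementation.

# hand-coded IRLS for logistic y ~ 1 + x, with observed-information SEs
irls_logistic <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- drop(solve(t(X) %*% (w * X), t(X) %*% (w * z)))
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  V <- solve(t(X) %*% (w * X))
  list(intercept = unname(b[1]), slope = unname(b[2]),
       se = unname(sqrt(diag(V))))
}

# two-sided Fisher's exact p by explicit hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# per-element pooled two-sample t computed the textbook way, one element
# at a time
pooled_t_oracle <- function(x_case, x_ctrl) {
  n1 <- length(x_case)
  n0 <- length(x_ctrl)
  sp2 <- ((n1 - 1) * stats::var(x_case) + (n0 - 1) * stats::var(x_ctrl)) /
    (n1 + n0 - 2)
  (mean(x_case) - mean(x_ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# diff_result built directly from chosen t-statistics
toy_diff <- function(t, df = 10L, platform = "gene",
                     ids = sprintf("e%02d", seq_along(t))) {
  t <- as.numeric(t)
  structure(list(platform = platform, element_ids = ids,
                 t_stat = stats::setNames(t, ids),
                 p_value = stats::setNames(
                   2 * stats::pt(abs(t), df, lower.tail = FALSE), ids),
                 df = as.integer(df)),
            class = "diff_result")
}

# logistic_fit built directly (for testing the 2-df combination in
# isolation from the fitting step)
toy_logistic_fit <- function(slope, se, converged = TRUE) {
  structure(list(intercept = 0, slope = slope, slope_se = se,
                 converged = converged, n_obs = 100L),
            class = "logistic_fit")
}

# tiny two-platform dataset with hand-set values
toy_matrices <- function(n_gene = 4, n_metab = 2, n_samples = 8, seed = 1) {
  set.seed(seed)
  g <- omics_matrix(matrix(rnorm(n_gene * n_samples), n_gene,
                           dimnames = list(sprintf("g%d", 1:n_gene),
                                           sprintf("s%d", 1:n_samples))),
                    "gene")
  m <- omics_matrix(matrix(rnorm(n_metab * n_samples), n_metab,
                           dimnames = list(sprintf("m%d", 1:n_metab),
                                           sprintf("s%d", 1:n_samples))),
                    "metabolite")
  ph <- phenotype_vector(colnames(g), rep(c(1, 0), each = n_samples / 2))
  list(gene = g, metabolite = m, phenotype = ph)
}
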