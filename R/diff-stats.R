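#' Per-element two-sample t-tests
#'
#' Computes, for every element (row) of an intensity matrix, the pooled-
#' variance two-sample t-statistic comparing cases to controls, oriented so
#' that a positive statistic means the case mean exceeds the control mean,
#' with the two-sided p-value from the t distribution on
#' \eqn{n_1 + n_0 - 2} degrees of freedom. The equal-variance (pooled) form
#' is used throughout: both simulation models draw equal variances in the
#' two groups, and a pooled test gives every element of a platform the same
#' degrees of freedom, which keeps concatenated statistic vectors comparable
#' when sample sizes match.
#'
#' Elements with zero pooled variance and equal group means are reported as
#' t = 0, p = 1 (no evidence either way); zero pooled variance with unequal
#' means has no defined statistic and raises an error.
#'
#' @param mat an [omics_matrix()].
#' @param labels a [phenotype_vector()] covering exactly the matrix samples.
#'
#' @return List of class `diff_result`: `platform`, `element_ids`, `t_stat`,
#'   `p_value`, `df`.
#' @export
two_sample_t <- function(mat, labels) {
  stopifnot(inherits(mat, "omics_matrix"))
  q <- align_phenotype(mat, labels)
  n1 <- sum(q == 1L)
  n0 <- sum(q == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("each group needs at least 2 samples (got ", n1, " cases, ",
         n0, " controls)", call. = FALSE)
  tt <- t_stats_by_groups(unclass(mat), matrix(q, ncol = 1L))
  tvec <- tt$t[, 1L]
  df <- n1 + n0 - 2L
  bad <- !is.finite(tvec)
  if (any(bad)) {
    # zero pooled variance: equal means -> no signal; unequal means -> undefined
    means_equal <- abs(tt$mean_diff[bad, 1L]) < .Machine$double.eps^0.5
    if (any(!means_equal))
      stop("zero pooled variance with unequal means for element(s): ",
           paste(rownames(mat)[bad][!means_equal], collapse = ", "),
           call. = FALSE)
    tvec[bad] <- 0
  }
  p <- 2 * stats::pt(abs(tvec), df = df, lower.tail = FALSE)
  structure(list(platform = attr(mat, "platform"),
                 element_ids = rownames(mat),
                 t_stat = stats::setNames(tvec, rownames(mat)),
                 p_value = stats::setNames(p, rownames(mat)),
                 df = df),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("diff_result [%s]: %d elements, df = %d\n",
              x$platform, length(x$t_stat), x$df))
  cat(sprintf("  |t| range %.3f..%.3f; %d elements with p < 0.05\n",
              min(abs(x$t_stat)), max(abs(x$t_stat)), sum(x$p_value < 0.05)))
  invisible(x)
}

# Vectorised pooled-t engine shared by two_sample_t and the permutation null.
# X: p x n data; case_mat: n x H matrix of 0/1 case indicators, each column a
# label assignment with the same group sizes. Returns list(t = p x H matrix,
# mean_diff = p x H). Non-finite t marks zero pooled variance.
t_stats_by_groups <- function(X, case_mat) {
  n <- ncol(X)
  n1 <- sum(case_mat[, 1L])
  n0 <- n - n1
  S1 <- X %*% case_mat            # per-element case sums, p x H
  tot <- rowSums(X)
  S0 <- tot - S1
  X2 <- X * X
  Q1 <- X2 %*% case_mat
  Q0 <- rowSums(X2) - Q1
  m1 <- S1 / n1
  m0 <- S0 / n0
  ss <- (Q1 - S1 * m1) + (Q0 - S0 * m0)
  ss[ss < 0] <- 0                 # guard against negative rounding residue
  sp2 <- ss / (n1 + n0 - 2)
  md <- m1 - m0
  list(t = md / sqrt(sp2 * (1 / n1 + 1 / n0)), mean_diff = md)
}

# H uniformly drawn case/control assignments preserving group sizes,
# returned as an n x H 0/1 indicator matrix. The identity arrangement is not
# excluded.
permute_labels <- function(q, H) {
  n <- length(q)
  n1 <- sum(q == 1L)
  vapply(seq_len(H), function(h) {
    v <- integer(n)
    v[sample.int(n, n1)] <- 1L
    v
  }, integer(n))
}
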