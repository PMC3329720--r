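#' Rank-sum metric for the truly associated sets
#'
#' Sets are ranked by ascending p-value (rank 1 = smallest, midranks for
#' ties) and R is the sum of the ranks of the associated sets. With 10
#' associated sets among 50, R = 55 is a perfect ranking, 455 the worst,
#' and E(R) = 255 under a uniformly random ranking. Permutation p-values of
#' exactly 0 (the "below 1/H" sentinel) rank before every p >= 1/H and are
#' ordered among themselves by observed statistic, descending (midranks
#' when statistics tie or are unavailable).
#'
#' R is invariant under any strictly monotone transformation of the
#' p-values.
#'
#' @param p named p-value vector over all sets.
#' @param associated names of the truly associated sets.
#' @param statistic optional named statistic vector used to order sentinel
#'   p-values.
#' @return Scalar rank sum.
#' @export
rank_sum_R <- function(p, associated, statistic = NULL) {
  if (is.null(names(p))) stop("p must be a named vector", call. = FALSE)
  if (anyNA(p))
    stop("missing p-values for set(s): ",
         paste(names(p)[is.na(p)], collapse = ", "), call. = FALSE)
  idx <- match(associated, names(p))
  if (anyNA(idx))
    stop("associated sets absent from p: ",
         paste(associated[is.na(idx)], collapse = ", "), call. = FALSE)
  r <- numeric(length(p))
  sent <- p == 0
  if (any(sent)) {
    key <- if (!is.null(statistic)) -as.numeric(statistic[names(p)[sent]])
           else rep(0, sum(sent))
    r[sent] <- rank(key, ties.method = "average")
    r[!sent] <- sum(sent) + rank(p[!sent], ties.method = "average")
  } else {
    r <- rank(p, ties.method = "average")
  }
  sum(r[idx])
}

#' Per-set rejection frequencies and Type-I error over replicates
#'
#' Given a sets x replicates matrix of p-values from one method, computes
#' the fraction of replicates in which each set is rejected (p strictly
#' below `alpha`) and the Type-I error: the mean rejection frequency over
#' the designated null sets. A Benjamini-Hochberg column (rejection after
#' per-replicate BH adjustment across sets) is included for reference but
#' plays no role in the headline metrics.
#'
#' @param p_matrix numeric matrix, sets in rows (named), replicates in
#'   columns; permutation sentinel 0 counts as a rejection.
#' @param alpha rejection level in (0, 1).
#' @param null_sets names of the sets that are null by design (may be
#'   empty, in which case the Type-I error is NA with a flag).
#' @param method optional method label carried through.
#' @return List of class `eval_report`: `method`, `alpha`, `n_replicates`,
#'   `per_set_rejection_freq`, `per_set_rejection_freq_bh`, `type1_error`,
#'   `type1_defined`.
#' @export
rejection_frequencies <- function(p_matrix, alpha = 0.05, null_sets = character(),
                                  method = NA_character_) {
  p_matrix <- as.matrix(p_matrix)
  if (is.null(rownames(p_matrix)))
    stop("p_matrix must have set names as rownames", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  freq <- rowMeans(p_matrix < alpha)
  p_bh <- apply(p_matrix, 2L, stats::p.adjust, method = "BH")
  freq_bh <- rowMeans(p_bh < alpha)
  missing_null <- setdiff(null_sets, rownames(p_matrix))
  if (length(missing_null))
    stop("null sets absent from p_matrix: ",
         paste(missing_null, collapse = ", "), call. = FALSE)
  type1_defined <- length(null_sets) > 0L
  structure(list(method = method, alpha = alpha,
                 n_replicates = ncol(p_matrix),
                 per_set_rejection_freq = freq,
                 per_set_rejection_freq_bh = freq_bh,
                 type1_error = if (type1_defined) mean(freq[null_sets])
                               else NA_real_,
                 type1_defined = type1_defined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report%s: %d sets x %d replicates, alpha = %g\n",
              if (is.na(x$method)) "" else paste0(" [", x$method, "]"),
              length(x$per_set_rejection_freq), x$n_replicates, x$alpha))
  if (x$type1_defined)
    cat(sprintf("  Type-I error over null sets: %.4f\n", x$type1_error))
  if (!is.null(x$rank_sum_mean))
    cat(sprintf("  rank sum R: mean %.1f, sd %.1f over %d replicates\n",
                x$rank_sum_mean, x$rank_sum_sd, length(x$rank_sums)))
  invisible(x)
}

#' Full replicate-level evaluation of one method
#'
#' Combines [rejection_frequencies()] with per-replicate rank sums
#' ([rank_sum_R()]) of the truly associated sets.
#'
#' @param p_matrix sets x replicates p-value matrix (named rows).
#' @param truth a `sim_truth` (from the simulators) supplying
#'   `associated_sets` and `null_sets`.
#' @param alpha rejection level.
#' @param method optional method label.
#' @param statistic_matrix optional sets x replicates statistic matrix used
#'   to order sentinel p-values in the ranking.
#' @return An `eval_report` with `rank_sums`, `rank_sum_mean`,
#'   `rank_sum_sd` added when associated sets are available.
#' @export
evaluate_method <- function(p_matrix, truth, alpha = 0.05,
                            method = NA_character_,
                            statistic_matrix = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  rep_ <- rejection_frequencies(p_matrix, alpha = alpha,
                                null_sets = truth$null_sets, method = method)
  if (length(truth$associated_sets)) {
    rs <- vapply(seq_len(ncol(p_matrix)), function(j) {
      st <- if (!is.null(statistic_matrix)) statistic_matrix[, j]
      rank_sum_R(p_matrix[, j], truth$associated_sets, statistic = st)
    }, numeric(1))
    rep_$rank_sums <- rs
    rep_$rank_sum_mean <- mean(rs)
    rep_$rank_sum_sd <- stats::sd(rs)
  }
  rep_
}

#' Detection-frequency plot for an evaluation report
#'
#' Base-graphics dot plot of the per-set rejection frequency by set index,
#' the style used to compare enrichment methods across a battery of
#' designed sets.
#'
#' @param x an `eval_report`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.eval_report <- function(x, ...) {
  f <- x$per_set_rejection_freq
  graphics::plot(seq_along(f), f, ylim = c(0, 1), pch = 19,
                 xlab = "set index", ylab = "rejection frequency",
                 main = if (is.na(x$method)) "detection frequency"
                        else x$method, ...)
  graphics::abline(h = x$alpha, lty = 2)
  invisible(x)
}

#' Tabular form of an evaluation report
#'
#' @param x an `eval_report`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per set: rejection frequencies (raw and
#'   BH-adjusted) plus the method label.
#' @export
as.data.frame.eval_report <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(set_name = names(x$per_set_rejection_freq),
             method = x$method,
             rejection_freq = unname(x$per_set_rejection_freq),
             rejection_freq_bh = unname(x$per_set_rejection_freq_bh),
             stringsAsFactors = FALSE)
}
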