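#' Single-set enrichment result
#'
#' Light container for one set x method test outcome. Permutation-based
#' p-values of exactly zero mean "below the resolution of H permutations"
#' and are displayed as `<1/H`.
#'
#' @param set_name set identifier.
#' @param method method tag, e.g. `"fisher-exact:gene"`.
#' @param statistic test statistic (NA when unavailable).
#' @param p_value p-value in \[0, 1\], NA when the test could not be
#'   computed, 0 for a permutation p below 1/H.
#' @param direction `"enriched"`, `"depleted"` or `"n/a"`.
#' @param H number of permutations behind a permutation p-value (NA for
#'   analytic tests).
#' @return List of class `enrichment_result`.
#' @export
enrichment_result <- function(set_name, method, statistic, p_value,
                              direction = "n/a", H = NA_integer_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]", call. = FALSE)
  if (!direction %in% c("enriched", "depleted", "n/a"))
    stop("invalid direction", call. = FALSE)
  structure(list(set_name = set_name, method = method,
                 statistic = statistic, p_value = p_value,
                 direction = direction, H = H),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s  %s: statistic = %s, p = %s (%s)\n",
              x$set_name, x$method,
              format(x$statistic, digits = 4),
              format_pvalue(x$p_value, x$H), x$direction))
  invisible(x)
}

#' Format a p-value, honouring the permutation resolution sentinel
#'
#' @param p numeric p-value (0 encodes "below 1/H").
#' @param H permutation count, or NA for analytic p-values.
#' @return Character scalar such as `"0.04"` or `"<0.001"`.
#' @export
format_pvalue <- function(p, H = NA_integer_) {
  if (is.na(p)) return("NA")
  if (!is.na(H) && p == 0) return(paste0("<", format(1 / H, digits = 3)))
  format(p, digits = 4)
}

#' Flag differential elements at a per-element significance cutoff
#'
#' Dichotomises a [two_sample_t()] result: an element is flagged
#' differential when its two-sided p-value is strictly below `alpha_elem`.
#' The default 0.05 is the conventional per-element screening level.
#'
#' @param diff a `diff_result`.
#' @param alpha_elem cutoff in (0, 1\].
#' @return Named integer 0/1 vector per element.
#' @export
dichotomize <- function(diff, alpha_elem = 0.05) {
  stopifnot(inherits(diff, "diff_result"))
  if (!is.numeric(alpha_elem) || alpha_elem <= 0 || alpha_elem > 1)
    stop("alpha_elem must lie in (0, 1]", call. = FALSE)
  stats::setNames(as.integer(diff$p_value < alpha_elem), diff$element_ids)
}

#' Cross-classify differential status against set membership
#'
#' Builds the 2x2 table counting elements by (differential?, in set?) that
#' feeds the competitive Fisher's exact test.
#'
#' @param flags 0/1 differential flags per element (see [dichotomize()]).
#' @param membership 0/1 set membership per element, same length.
#' @return Integer vector of class `contingency_table` with components
#'   `in_set_diff`, `in_set_nondiff`, `out_set_diff`, `out_set_nondiff`.
#' @export
contingency <- function(flags, membership) {
  if (length(flags) != length(membership))
    stop("flags and membership lengths differ", call. = FALSE)
  flags <- as.integer(flags)
  membership <- as.integer(membership)
  if (!sum(membership))
    stop("degenerate set: no members among tested elements", call. = FALSE)
  tab <- c(in_set_diff     = sum(flags == 1L & membership == 1L),
           in_set_nondiff  = sum(flags == 0L & membership == 1L),
           out_set_diff    = sum(flags == 1L & membership == 0L),
           out_set_nondiff = sum(flags == 0L & membership == 0L))
  structure(tab, class = "contingency_table")
}

#' Competitive enrichment by Fisher's exact test
#'
#' Two-sided Fisher's exact test of independence on the 2x2 table from
#' [contingency()]: the p-value sums all tables with the observed margins
#' whose hypergeometric probability does not exceed that of the observed
#' table. Direction is read off the sample odds ratio (enriched when the
#' in-set differential odds exceed the out-of-set odds). A table with a
#' zero margin carries no information: p = 1, direction `"n/a"`.
#'
#' @param tab a `contingency_table`.
#' @param set_name label carried into the result.
#' @param method method tag carried into the result.
#' @return An [enrichment_result()].
#' @export
fisher_exact_enrichment <- function(tab, set_name = NA_character_,
                                    method = "fisher-exact") {
  stopifnot(inherits(tab, "contingency_table"))
  m <- matrix(as.integer(tab), nrow = 2, byrow = TRUE)  # rows: in/out of set
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    return(enrichment_result(set_name, method, statistic = NA_real_,
                             p_value = 1, direction = "n/a"))
  ft <- stats::fisher.test(m, alternative = "two.sided")
  ft$p.value <- min(1, ft$p.value)   # guard against summation overshoot
  cross1 <- as.numeric(m[1, 1]) * m[2, 2]
  cross2 <- as.numeric(m[1, 2]) * m[2, 1]
  direction <- if (cross1 > cross2) "enriched"
               else if (cross1 < cross2) "depleted" else "n/a"
  enrichment_result(set_name, method,
                    statistic = unname(ft$estimate), p_value = ft$p.value,
                    direction = direction)
}

#' Competitive enrichment by logistic regression on |t|
#'
#' Fits the logistic model
#' \deqn{\mathrm{logit}\,\Pr(\text{element} \in S) = \gamma_0 + \gamma\,|t|}
#' by maximum likelihood, where |t| is the absolute per-element t-statistic,
#' and tests \eqn{\gamma = 0} with the 1-df Wald statistic
#' \eqn{(\hat\gamma/\hat\sigma_\gamma)^2} against the upper \eqn{\chi^2_1}
#' tail. Unlike Fisher's exact test this uses the full strength of evidence
#' per element rather than a dichotomised flag. A positive slope indicates
#' enrichment, a negative slope depletion.
#'
#' Complete separation of |t| between members and non-members (their |t|
#' ranges do not overlap) has no finite MLE; the fit is flagged
#' non-converged and the p-value reported missing. A set containing all or
#' none of the tested elements is degenerate and raises an error.
#'
#' @param diff a `diff_result`.
#' @param membership 0/1 membership per element, aligned with `diff`.
#' @param set_name,method labels carried into the result.
#' @return List with components `fit` (class `logistic_fit`: `intercept`,
#'   `slope`, `slope_se`, `converged`, `n_obs`) and `result`
#'   (an [enrichment_result()]).
#' @export
logistic_enrichment <- function(diff, membership, set_name = NA_character_,
                                method = "logistic") {
  stopifnot(inherits(diff, "diff_result"))
  y <- as.integer(membership)
  if (length(y) != length(diff$t_stat))
    stop("membership length does not match diff result", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("degenerate set: membership must be a proper non-empty subset",
         call. = FALSE)
  x <- abs(unname(diff$t_stat))
  fit <- logistic_wald_fit(x, y)
  res <- if (fit$converged)
    enrichment_result(set_name, method,
                      statistic = (fit$slope / fit$slope_se)^2,
                      p_value = stats::pchisq((fit$slope / fit$slope_se)^2,
                                              df = 1, lower.tail = FALSE),
                      direction = if (fit$slope > 0) "enriched"
                                  else if (fit$slope < 0) "depleted" else "n/a")
  else
    enrichment_result(set_name, method, statistic = NA_real_,
                      p_value = NA_real_, direction = "n/a")
  list(fit = fit, result = res)
}

# ML logistic fit of y on a single covariate via IRLS (stats::glm.fit),
# with Wald standard errors from the weighted QR decomposition.
logistic_wald_fit <- function(x, y) {
  n <- length(y)
  # one-covariate complete separation: member/non-member ranges disjoint
  separated <- min(x[y == 1L]) > max(x[y == 0L]) ||
               max(x[y == 1L]) < min(x[y == 0L])
  Xd <- cbind(1, x)
  g <- suppressWarnings(stats::glm.fit(
    Xd, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 200L)))
  se <- rep(NA_real_, 2L)
  if (g$rank == 2L) {
    p1 <- seq_len(g$rank)
    covmat <- chol2inv(g$qr$qr[p1, p1, drop = FALSE])
    se[g$qr$pivot[p1]] <- sqrt(diag(covmat))
  }
  converged <- isTRUE(g$converged) && !separated && g$rank == 2L &&
    all(is.finite(g$coefficients)) && all(is.finite(se)) && se[2L] > 0
  structure(list(intercept = unname(g$coefficients[1L]),
                 slope = unname(g$coefficients[2L]),
                 slope_se = se[2L], converged = converged, n_obs = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: slope = %.4g (se %.4g), intercept = %.4g, %s, n = %d\n",
              x$slope, x$slope_se, x$intercept,
              if (x$converged) "converged" else "NOT converged", x$n_obs))
  invisible(x)
}

#' Self-contained sum-of-squared-statistics for one set
#'
#' \eqn{W_S = \sum_{j \in S} t_j^2}: the total squared evidence of
#' differential behaviour among the set's members, ignoring the complement.
#' Significance is assessed against a subject-permutation null
#' ([subject_permutation_null()], [empirical_pvalue()]).
#'
#' @param diff a `diff_result`.
#' @param membership 0/1 membership per element, aligned with `diff`.
#' @return Non-negative scalar.
#' @export
sum_squared_stat <- function(diff, membership) {
  stopifnot(inherits(diff, "diff_result"))
  membership <- as.integer(membership)
  if (length(membership) != length(diff$t_stat))
    stop("membership length does not match diff result", call. = FALSE)
  if (!sum(membership))
    stop("set has no members on this platform", call. = FALSE)
  sum(diff$t_stat[membership == 1L]^2)
}

#' Observed sum-of-squares statistics for every set
#'
#' @param diff a `diff_result`.
#' @param sets a [set_collection()].
#' @return Named vector of \eqn{W_S} over the sets with at least one member
#'   measured on `diff`'s platform.
#' @export
sumsq_by_set <- function(diff, sets) {
  M <- membership_matrix(sets, diff$element_ids, diff$platform)
  keep <- rowSums(M) > 0
  drop((M[keep, , drop = FALSE] %*% (unname(diff$t_stat)^2))[, 1L])
}

#' Subject-label permutation null for the sum-of-squares test
#'
#' For each of `H` random case/control label assignments (group sizes
#' preserved, the identity arrangement not excluded) the per-element
#' t-statistics are recomputed from the raw data and summed by set, giving
#' the null distribution \eqn{\tilde W_S} per platform. When the two
#' platforms are matched (same subjects), the SAME label permutation is
#' applied to both in each round, preserving the between-platform
#' correlation that the joint 2-D test relies on; unmatched platforms are
#' permuted independently.
#'
#' @param gene,metabolite [omics_matrix()] objects (either may be `NULL`).
#' @param labels a [phenotype_vector()].
#' @param sets a [set_collection()].
#' @param H number of permutations (>= 1; fewer than 100 triggers a
#'   resolution warning).
#' @param matched logical: are the platforms measured on the same subjects?
#' @param seed optional integer seed for reproducibility.
#' @return List of class `perm_null`: `H`, `matched`, per-platform sets x H
#'   matrices of null statistics (`gene`, `metabolite`; rows are the sets
#'   with members on that platform), and `assignments` - the samples x H
#'   0/1 case-indicator matrices actually used (identical for matched
#'   platforms).
#' @export
subject_permutation_null <- function(gene = NULL, metabolite = NULL, labels,
                                     sets, H = 1000L, matched = TRUE,
                                     seed = NULL) {
  if (is.null(gene) && is.null(metabolite))
    stop("at least one platform matrix is required", call. = FALSE)
  H <- as.integer(H)
  if (H < 1L) stop("H must be >= 1", call. = FALSE)
  if (H < 100L)
    warning("H = ", H, " permutations: p-value resolution is only 1/", H)
  if (!is.null(seed)) set.seed(seed)
  both <- !is.null(gene) && !is.null(metabolite)
  if (both && matched &&
      !setequal(colnames(gene), colnames(metabolite)))
    stop("matched platforms must share the same sample ids", call. = FALSE)

  null_for <- function(mat, perm) {
    tt <- t_stats_by_groups(unclass(mat),
                            perm[colnames(mat), , drop = FALSE])$t
    M <- membership_matrix(sets, rownames(mat), attr(mat, "platform"))
    M <- M[rowSums(M) > 0, , drop = FALSE]
    M %*% (tt * tt)
  }
  draw_perm <- function(mat) {
    q <- align_phenotype(mat, labels)
    p <- permute_labels(q, H)
    rownames(p) <- colnames(mat)
    p
  }

  out <- list(H = H, matched = isTRUE(matched), gene = NULL, metabolite = NULL,
              assignments = list(gene = NULL, metabolite = NULL))
  if (both && matched) {
    perm <- draw_perm(gene)       # shared label assignments, by sample id
    out$gene <- null_for(gene, perm)
    out$metabolite <- null_for(metabolite, perm)
    out$assignments <- list(gene = perm, metabolite = perm)
  } else {
    if (!is.null(gene)) {
      perm <- draw_perm(gene)
      out$gene <- null_for(gene, perm)
      out$assignments$gene <- perm
    }
    if (!is.null(metabolite)) {
      perm <- draw_perm(metabolite)
      out$metabolite <- null_for(metabolite, perm)
      out$assignments$metabolite <- perm
    }
  }
  structure(out, class = "perm_null")
}

#' Empirical one-sided permutation p-value
#'
#' \eqn{p = H^{-1} \sum_h I(\tilde W_h \ge \hat W)}: the proportion of null
#' statistics at least as large as the observed one (inclusive), a
#' one-sided test that by construction cannot detect depletion. An observed
#' value exceeding every null statistic yields 0, the "below 1/H" sentinel
#' (see [format_pvalue()]); no +1 small-sample correction is applied, so
#' every value is an exact multiple of 1/H.
#'
#' @param observed scalar observed statistic.
#' @param null_values numeric vector of H null statistics.
#' @return p-value in \{0, 1/H, ..., 1\}.
#' @export
empirical_pvalue <- function(observed, null_values) {
  if (!length(null_values)) stop("no null values supplied", call. = FALSE)
  mean(null_values >= observed)
}
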