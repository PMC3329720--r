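#' Concatenate two platforms into one element list
#'
#' The simplest joint analysis: append the per-metabolite statistic vector
#' to the per-gene vector and treat the result as a single platform, with
#' each set's membership the union of its members on both platforms (a
#' concatenated set has \eqn{N^s_G + N^s_M} members). In `t_stat` mode the
#' raw t-statistics are joined, which is only comparable when both
#' platforms share the same degrees of freedom; with unequal df an error
#' directs the caller to `p_value` mode, where p-values (comparable by
#' design, but directionless) are joined instead.
#'
#' Element ids are namespaced by platform (`gene:...`, `metabolite:...`)
#' when the raw ids collide across platforms.
#'
#' @param diff_gene,diff_metabolite `diff_result` objects for the two
#'   platforms.
#' @param sets a [set_collection()].
#' @param mode `"t_stat"` or `"p_value"`.
#' @return List of class `concat_result`: a `diff_result`-like object
#'   (`platform = "concat"`) plus `membership` (sets x concatenated
#'   elements 0/1 matrix) and per-set member counts `n_gene`, `n_metabolite`.
#' @export
concatenate_platforms <- function(diff_gene, diff_metabolite, sets,
                                  mode = c("t_stat", "p_value")) {
  mode <- match.arg(mode)
  stopifnot(inherits(diff_gene, "diff_result"),
            inherits(diff_metabolite, "diff_result"))
  if (mode == "t_stat" && diff_gene$df != diff_metabolite$df)
    stop("platforms have unequal degrees of freedom (", diff_gene$df, " vs ",
         diff_metabolite$df, "); raw t-statistics are not comparable - ",
         "use mode = \"p_value\"", call. = FALSE)
  ids_g <- diff_gene$element_ids
  ids_m <- diff_metabolite$element_ids
  if (length(intersect(ids_g, ids_m))) {
    ids_g <- paste0("gene:", ids_g)
    ids_m <- paste0("metabolite:", ids_m)
  }
  Mg <- membership_matrix(sets, diff_gene$element_ids, "gene")
  Mm <- membership_matrix(sets, diff_metabolite$element_ids, "metabolite")
  membership <- cbind(Mg, Mm)
  colnames(membership) <- c(ids_g, ids_m)
  t_stat <- if (mode == "t_stat")
    stats::setNames(c(unname(diff_gene$t_stat), unname(diff_metabolite$t_stat)),
                    c(ids_g, ids_m))
  else stats::setNames(rep(NA_real_, ncol(membership)), c(ids_g, ids_m))
  diff <- structure(list(platform = "concat",
                         element_ids = c(ids_g, ids_m),
                         t_stat = t_stat,
                         p_value = stats::setNames(
                           c(unname(diff_gene$p_value),
                             unname(diff_metabolite$p_value)),
                           c(ids_g, ids_m)),
                         df = if (mode == "t_stat") diff_gene$df else NA_integer_),
                    class = "diff_result")
  structure(list(diff = diff, membership = membership,
                 n_gene = rowSums(Mg), n_metabolite = rowSums(Mm),
                 mode = mode),
            class = "concat_result")
}

#' Combine two platform p-values by Fisher's method
#'
#' \eqn{-2(\ln p^M + \ln p^G)} referred to the upper tail of \eqn{\chi^2_4}.
#' The chi-squared reference assumes the two tests are independent, which
#' is only approximate for matched platforms, but the method is in wide use
#' and serves as a baseline joint test. A permutation p-value of exactly 0
#' ("below 1/H") is substituted by \eqn{1/(2H)} - half a step below the
#' permutation resolution - before taking logs; a zero without a
#' permutation context is a domain error.
#'
#' @param p_gene,p_metabolite the two p-values in (0, 1\] (0 allowed only
#'   with `H`).
#' @param H permutation count behind the inputs, if any.
#' @param set_name,method labels carried into the result.
#' @return An [enrichment_result()].
#' @export
fisher_combine <- function(p_gene, p_metabolite, H = NULL,
                           set_name = NA_character_, method = "pcombine") {
  fix <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p > 1 || p < 0) stop("p-value outside [0, 1]", call. = FALSE)
    if (p == 0) {
      if (is.null(H)) stop("p-value of 0 without a permutation context",
                           call. = FALSE)
      return(1 / (2 * H))
    }
    p
  }
  pg <- fix(p_gene); pm <- fix(p_metabolite)
  if (is.na(pg) || is.na(pm))
    return(enrichment_result(set_name, method, NA_real_, NA_real_))
  stat <- -2 * (log(pg) + log(pm))
  enrichment_result(set_name, method, statistic = stat,
                    p_value = stats::pchisq(stat, df = 4, lower.tail = FALSE))
}

#' Joint 2-degree-of-freedom Wald test from two logistic fits
#'
#' Tests \eqn{\gamma = 0, \mu = 0} jointly, where \eqn{\gamma} and
#' \eqn{\mu} are the membership-on-|t| logistic slopes of the two
#' platforms. With the slope covariance taken as zero (row-resampling
#' bootstraps show near-zero correlation between the two slope estimates,
#' so the variance matrix is diagonal) the Wald statistic is the sum of
#' the two univariate 1-df statistics,
#' \deqn{U = (\hat\gamma/\hat\sigma_\gamma)^2 + (\hat\mu/\hat\sigma_\mu)^2,}
#' referred to the upper \eqn{\chi^2_2} tail, which equals
#' \eqn{\exp(-U/2)}. The off-diagonal covariance slot is retained in the
#' interface for future weighted variants but fixed at 0.
#'
#' @param fit_gene,fit_metabolite `logistic_fit` objects (see
#'   [logistic_enrichment()]). Either non-converged fit yields a missing
#'   joint p-value.
#' @param set_name,method labels carried into the result.
#' @param cov_slope reserved; must currently be 0.
#' @return An [enrichment_result()].
#' @export
wald_2df <- function(fit_gene, fit_metabolite, set_name = NA_character_,
                     method = "logistic:joint", cov_slope = 0) {
  stopifnot(inherits(fit_gene, "logistic_fit"),
            inherits(fit_metabolite, "logistic_fit"))
  if (cov_slope != 0)
    stop("non-zero slope covariance is not supported", call. = FALSE)
  if (!fit_gene$converged || !fit_metabolite$converged) {
    res <- enrichment_result(set_name, method, NA_real_, NA_real_)
    attr(res, "reason") <- "univariate logistic fit did not converge"
    return(res)
  }
  U <- (fit_gene$slope / fit_gene$slope_se)^2 +
       (fit_metabolite$slope / fit_metabolite$slope_se)^2
  enrichment_result(set_name, method, statistic = U,
                    p_value = stats::pchisq(U, df = 2, lower.tail = FALSE))
}

#' Cloud of permutation statistic pairs
#'
#' Container for the H null pairs \eqn{(\tilde W^G_S, \tilde W^M_S)} of one
#' set, with their centroid (column means) and 2x2 sample covariance. The
#' observed pair is never part of the cloud.
#'
#' @param pairs numeric H x 2 matrix of null statistic pairs (H >= 2).
#' @return List of class `null_cloud`: `H`, `pairs`, `centroid`,
#'   `covariance`.
#' @export
null_cloud <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 2L)
    stop("pairs must be an H x 2 matrix with H >= 2", call. = FALSE)
  storage.mode(pairs) <- "double"
  structure(list(H = nrow(pairs), pairs = pairs,
                 centroid = colMeans(pairs), covariance = stats::cov(pairs)),
            class = "null_cloud")
}

#' @export
print.null_cloud <- function(x, ...) {
  cat(sprintf("null_cloud: H = %d, centroid = (%.4g, %.4g)\n",
              x$H, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Mahalanobis distance of a statistic pair from a null cloud
#'
#' \deqn{D = \sqrt{(w - \psi)^\top V^{-1} (w - \psi)}}
#' with \eqn{\psi} the cloud centroid and \eqn{V} its sample covariance.
#' Unlike Euclidean distance this accounts for the shape and spread of the
#' null distribution, so a point can be extreme along a thin axis of the
#' cloud while lying close in raw units. A numerically singular covariance
#' (e.g. a constant column from a tiny set at small H) is regularised by
#' adding a ridge of \eqn{10^{-8} \cdot \mathrm{tr}(V)/2} to the diagonal,
#' with a warning; set `ridge = FALSE` to turn that fallback into an error.
#'
#' @param point numeric pair \eqn{(W^G, W^M)}.
#' @param cloud a [null_cloud()].
#' @param ridge allow the ridge fallback for singular covariances?
#' @return Non-negative scalar distance (0 iff `point` equals the centroid).
#' @export
mahalanobis_distance <- function(point, cloud, ridge = TRUE) {
  stopifnot(inherits(cloud, "null_cloud"), length(point) == 2L)
  V <- cloud_inverse(cloud, ridge)
  d <- as.numeric(point) - cloud$centroid
  sqrt(max(0, drop(d %*% V %*% d)))
}

# inverse of the cloud covariance with optional ridge regularisation
cloud_inverse <- function(cloud, ridge = TRUE) {
  V <- cloud$covariance
  tr <- V[1, 1] + V[2, 2]
  detV <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  if (!is.finite(detV) || detV <= .Machine$double.eps * (tr / 2)^2) {
    if (!ridge) stop("singular null-cloud covariance", call. = FALSE)
    warning("singular null-cloud covariance; adding diagonal ridge")
    V <- V + diag(1e-8 * tr / 2, 2L)
  }
  solve(V)
}

#' Joint permutation p-value via the 2-D Mahalanobis distance
#'
#' The joint self-contained test: the observed pair
#' \eqn{(\hat W^G_S, \hat W^M_S)} and all H null pairs are reduced to their
#' Mahalanobis distances from the null cloud's centroid, and
#' \deqn{P^{GM}_S = H^{-1} \sum_h I(D(\tilde W_h) \ge D(\hat W)).}
#' The inequality is inclusive; an observed pair strictly outside the null
#' hull yields 0, the "below 1/H" sentinel. The cloud must come from
#' permutations shared across matched platforms
#' (see [subject_permutation_null()]).
#'
#' @param observed numeric pair of observed statistics.
#' @param cloud a [null_cloud()].
#' @param set_name,method labels carried into the result.
#' @param ridge passed to [mahalanobis_distance()].
#' @return An [enrichment_result()] whose statistic is the observed
#'   distance.
#' @export
joint_permutation_pvalue <- function(observed, cloud,
                                     set_name = NA_character_,
                                     method = "sumsq:joint", ridge = TRUE) {
  stopifnot(inherits(cloud, "null_cloud"))
  Vinv <- cloud_inverse(cloud, ridge)
  ctr <- cloud$centroid
  d_obs <- {
    d <- as.numeric(observed) - ctr
    sqrt(max(0, drop(d %*% Vinv %*% d)))
  }
  Dc <- sweep(cloud$pairs, 2L, ctr)
  d_null <- sqrt(pmax(0, rowSums((Dc %*% Vinv) * Dc)))
  enrichment_result(set_name, method, statistic = d_obs,
                    p_value = mean(d_null >= d_obs), H = cloud$H)
}

#' Concatenation arm of the sum-of-squares test
#'
#' Applies the self-contained test to the concatenated element list: the
#' statistic is \eqn{W^G_S + W^M_S} and its null distribution is the
#' per-permutation sum \eqn{\tilde W^G_S + \tilde W^M_S} over the shared
#' (matched) permutations, assessed with [empirical_pvalue()]. With equal
#' degrees of freedom this is identical to running the univariate test on a
#' single pre-concatenated matrix.
#'
#' @param observed numeric pair of observed statistics.
#' @param cloud a [null_cloud()] of matched null pairs.
#' @param set_name,method labels carried into the result.
#' @return An [enrichment_result()].
#' @export
sumsq_concatenated <- function(observed, cloud, set_name = NA_character_,
                               method = "sumsq:concat") {
  stopifnot(inherits(cloud, "null_cloud"))
  stat <- sum(as.numeric(observed))
  enrichment_result(set_name, method, statistic = stat,
                    p_value = empirical_pvalue(stat, rowSums(cloud$pairs)),
                    H = cloud$H)
}
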