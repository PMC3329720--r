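#' Replicate study under the disjoint-set model
#'
#' Simulates `n_reps` independent datasets from one [disjoint_config()]
#' scenario, applies the requested enrichment methods to each, and collects
#' per-replicate p-value matrices and rank sums of the truly associated
#' sets. The rare set x replicate where a test cannot be computed (a
#' non-converged logistic fit) contributes p = 1 - no evidence - to the
#' ranking; the substitution count is reported.
#'
#' @param config a [disjoint_config()]; its `seed` field is ignored in
#'   favour of per-replicate seeds derived from `seed`.
#' @param methods method tags (see [integrative_enrichment()]).
#' @param n_reps number of replicate datasets.
#' @param H permutations per replicate for `sumsq` methods.
#' @param alpha rejection level used in the rejection-frequency summaries.
#' @param seed master seed; all per-replicate seeds derive from it.
#' @return List of class `enrich_study`: `rank_sums` (replicates x methods),
#'   `summary` (per-method mean/sd of R and Type-I error over the
#'   non-associated sets), `p` (per-method sets x replicates matrices),
#'   `statistic` (same shape), `truth`, `n_na_substituted`, `config`.
#' @export
disjoint_rank_study <- function(config, methods, n_reps = 100L, H = 1000L,
                                alpha = 0.05, seed = NULL) {
  stopifnot(inherits(config, "disjoint_config"))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  p <- stat <- NULL
  truth <- NULL
  n_na <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    sim <- simulate_disjoint(cfg)
    fit <- integrative_enrichment(sim$gene, sim$metabolite, sim$phenotype,
                                  sim$sets, methods = methods, H = H,
                                  matched = TRUE)
    if (is.null(p)) {
      truth <- sim$truth
      sets <- sim$sets$set_names
      p <- lapply(methods, function(m)
        matrix(NA_real_, length(sets), n_reps, dimnames = list(sets, NULL)))
      names(p) <- methods
      stat <- p
    }
    for (m in methods) {
      mp <- method_pvalues(fit, m)
      n_na <- n_na + sum(is.na(mp$p))
      mp$p[is.na(mp$p)] <- 1
      p[[m]][names(mp$p), r] <- mp$p
      stat[[m]][names(mp$statistic), r] <- mp$statistic
    }
  }
  rank_sums <- vapply(methods, function(m) {
    vapply(seq_len(n_reps), function(r)
      rank_sum_R(p[[m]][, r], truth$associated_sets),
      numeric(1))
  }, numeric(n_reps))
  rank_sums <- matrix(rank_sums, nrow = n_reps,
                      dimnames = list(NULL, methods))
  summary <- data.frame(
    method = methods,
    rank_sum_mean = colMeans(rank_sums),
    rank_sum_sd = apply(rank_sums, 2L, stats::sd),
    type1_error = vapply(methods, function(m)
      rejection_frequencies(p[[m]], alpha, truth$null_sets, m)$type1_error,
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(rank_sums = rank_sums, summary = summary, p = p,
                 statistic = stat, truth = truth,
                 n_na_substituted = n_na, alpha = alpha, config = config),
            class = "enrich_study")
}

#' Replicate study under the heterogeneous-set model
#'
#' Draws the 70-set membership once, then simulates `n_reps` datasets with
#' varying data seeds against that fixed membership, applies the requested
#' methods, and summarises per-set rejection frequencies and the Type-I
#' error over the null-partition sets.
#'
#' @param config a [hetero_config()]; its seed fields are ignored in favour
#'   of seeds derived from `seed`.
#' @inheritParams disjoint_rank_study
#' @param alpha_elem per-element cutoff for the `fisher-exact` family.
#' @return List of class `enrich_study`: `summary` (per-method Type-I
#'   error), `reports` (per-method `eval_report`), `p`, `truth`,
#'   `n_na_substituted`, `config`.
#' @export
hetero_type1_study <- function(config, methods, n_reps = 100L, H = 1000L,
                               alpha = 0.05, alpha_elem = 0.05, seed = NULL) {
  stopifnot(inherits(config, "hetero_config"))
  if (!is.null(seed)) set.seed(seed)
  config$seed_membership <- sample.int(.Machine$integer.max - 1L, 1L)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  membership <- hetero_membership(config)
  p <- NULL
  truth <- NULL
  n_na <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed_data <- rep_seeds[r]
    sim <- simulate_heterogeneous(cfg, membership)
    fit <- integrative_enrichment(sim$gene, sim$metabolite, sim$phenotype,
                                  sim$sets, methods = methods, H = H,
                                  matched = TRUE, alpha_elem = alpha_elem)
    if (is.null(p)) {
      truth <- sim$truth
      sets <- sim$sets$set_names
      p <- lapply(methods, function(m)
        matrix(NA_real_, length(sets), n_reps, dimnames = list(sets, NULL)))
      names(p) <- methods
    }
    for (m in methods) {
      mp <- method_pvalues(fit, m)
      n_na <- n_na + sum(is.na(mp$p))
      mp$p[is.na(mp$p)] <- 1
      p[[m]][names(mp$p), r] <- mp$p
    }
  }
  reports <- lapply(methods, function(m)
    rejection_frequencies(p[[m]], alpha, truth$null_sets, m))
  names(reports) <- methods
  summary <- data.frame(
    method = methods,
    type1_error = vapply(reports, `[[`, numeric(1), "type1_error"),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, reports = reports, p = p, truth = truth,
                 n_na_substituted = n_na, alpha = alpha, config = config),
            class = "enrich_study")
}

#' @export
print.enrich_study <- function(x, ...) {
  cat(sprintf("enrich_study: %d replicates\n",
              ncol(x$p[[1]])))
  print(x$summary, row.names = FALSE)
  if (x$n_na_substituted > 0L)
    cat(sprintf("  (%d non-computable set tests substituted with p = 1)\n",
                x$n_na_substituted))
  invisible(x)
}
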