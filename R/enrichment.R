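#' Joint and univariate set-enrichment testing
#'
#' The central fitting function: computes per-element two-sample
#' t-statistics on one or two platforms and applies the requested
#' enrichment tests to every set. Method tags are `"family:arm"` with
#' family in `fisher-exact` (competitive, dichotomised 2x2 exact test),
#' `logistic` (competitive, membership regressed on |t|) or `sumsq`
#' (self-contained sum of squared t-statistics, subject-permutation null),
#' and arm in:
#' \describe{
#'   \item{gene / metabolite}{univariate test on one platform.}
#'   \item{concat}{the platforms concatenated into one element list
#'     (union membership per set).}
#'   \item{pcombine}{Fisher's \eqn{\chi^2_4} combination of the two
#'     univariate p-values.}
#'   \item{joint}{the genuinely bivariate test: the 2-df Wald statistic for
#'     `logistic`, the 2-D Mahalanobis permutation p-value for `sumsq`
#'     (not defined for `fisher-exact`).}
#' }
#' Permutations are drawn only when a `sumsq` method is requested; matched
#' platforms share each label permutation.
#'
#' @param gene,metabolite [omics_matrix()] objects (one may be `NULL`).
#' @param labels a [phenotype_vector()].
#' @param sets a [set_collection()].
#' @param methods character vector of method tags.
#' @param alpha_elem per-element significance cutoff feeding
#'   [dichotomize()] for the `fisher-exact` family.
#' @param H permutation count for the `sumsq` family.
#' @param matched are the two platforms measured on the same subjects?
#' @param concat_mode `"t_stat"` (default; requires equal df) or
#'   `"p_value"` for the `concat` arm.
#' @param seed optional seed for the permutation draw.
#' @return Object of class `intenrich`; see [as.data.frame.intenrich()].
#' @examples
#' cfg <- disjoint_config(n_sets = 5, n_associated = 2, n_samples = 10,
#'                        seed = 1)
#' sim <- simulate_disjoint(cfg)
#' fit <- integrative_enrichment(sim$gene, sim$metabolite, sim$phenotype,
#'                               sim$sets, methods = c("logistic:gene",
#'                               "logistic:joint"), H = 50)
#' head(as.data.frame(fit))
#' @export
integrative_enrichment <- function(gene = NULL, metabolite = NULL, labels,
                                   sets, methods = c("fisher-exact:gene",
                                                     "logistic:gene",
                                                     "sumsq:gene"),
                                   alpha_elem = 0.05, H = 1000L,
                                   matched = TRUE,
                                   concat_mode = c("t_stat", "p_value"),
                                   seed = NULL) {
  concat_mode <- match.arg(concat_mode)
  methods <- validate_methods(methods, has_gene = !is.null(gene),
                              has_metab = !is.null(metabolite))
  stopifnot(inherits(sets, "set_collection"))
  arms <- vapply(strsplit(methods, ":", fixed = TRUE), `[`, "", 2L)
  fams <- vapply(strsplit(methods, ":", fixed = TRUE), `[`, "", 1L)

  diff_g <- if (!is.null(gene)) two_sample_t(gene, labels)
  diff_m <- if (!is.null(metabolite)) two_sample_t(metabolite, labels)
  set_names <- sets$set_names
  Mg <- if (!is.null(diff_g)) membership_matrix(sets, diff_g$element_ids, "gene")
  Mm <- if (!is.null(diff_m))
    membership_matrix(sets, diff_m$element_ids, "metabolite")
  n_g <- if (is.null(Mg)) rep(0L, length(set_names)) else rowSums(Mg)
  n_m <- if (is.null(Mm)) rep(0L, length(set_names)) else rowSums(Mm)

  need_perm <- any(fams == "sumsq")
  perm <- NULL
  if (need_perm)
    perm <- subject_permutation_null(gene = gene, metabolite = metabolite,
                                     labels = labels, sets = sets, H = H,
                                     matched = matched, seed = seed)
  conc <- NULL
  if (any(arms == "concat" & fams != "sumsq"))
    conc <- concatenate_platforms(diff_g, diff_m, sets, mode = concat_mode)

  flags <- list()
  get_flags <- function(key, diff) {
    if (is.null(flags[[key]])) flags[[key]] <<- dichotomize(diff, alpha_elem)
    flags[[key]]
  }
  W_g <- if (need_perm && !is.null(diff_g)) sumsq_by_set(diff_g, sets)
  W_m <- if (need_perm && !is.null(diff_m)) sumsq_by_set(diff_m, sets)
  logi_cache <- list()   # per-platform lists of logistic fits/results by set
  logistic_platform <- function(platform) {
    if (!is.null(logi_cache[[platform]])) return(logi_cache[[platform]])
    diff <- if (platform == "gene") diff_g else diff_m
    M <- if (platform == "gene") Mg else Mm
    out <- lapply(set_names, function(s) {
      if (sum(M[s, ]) == 0L || sum(M[s, ]) == ncol(M)) return(NULL)
      logistic_enrichment(diff, M[s, ], set_name = s,
                          method = paste0("logistic:", platform))
    })
    names(out) <- set_names
    logi_cache[[platform]] <<- out
    out
  }

  rows <- list()
  add_row <- function(res, ng, nm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      set_name = res$set_name, method = res$method,
      statistic = if (is.null(res$statistic)) NA_real_ else res$statistic,
      p_value = res$p_value, direction = res$direction,
      n_genes = ng, n_metabolites = nm, stringsAsFactors = FALSE)
  }
  na_result <- function(s, method)
    enrichment_result(s, method, NA_real_, NA_real_)

  for (mi in seq_along(methods)) {
    fam <- fams[mi]; arm <- arms[mi]; tag <- methods[mi]
    for (si in seq_along(set_names)) {
      s <- set_names[si]
      res <- switch(
        paste(fam, arm, sep = ":"),
        "fisher-exact:gene" = ,
        "fisher-exact:metabolite" = {
          M <- if (arm == "gene") Mg else Mm
          diff <- if (arm == "gene") diff_g else diff_m
          if (sum(M[s, ]) == 0L) na_result(s, tag)
          else fisher_exact_enrichment(
            contingency(get_flags(arm, diff), M[s, ]), s, tag)
        },
        "fisher-exact:concat" = {
          mem <- conc$membership[s, ]
          if (sum(mem) == 0L) na_result(s, tag)
          else fisher_exact_enrichment(
            contingency(get_flags("concat", conc$diff), mem), s, tag)
        },
        "fisher-exact:pcombine" = {
          pg <- fisher_row(Mg, diff_g, s, get_flags, "gene")
          pm <- fisher_row(Mm, diff_m, s, get_flags, "metabolite")
          fisher_combine(pg, pm, H = NULL, set_name = s, method = tag)
        },
        "logistic:gene" = ,
        "logistic:metabolite" = {
          fit <- logistic_platform(arm)[[s]]
          if (is.null(fit)) na_result(s, tag) else fit$result
        },
        "logistic:concat" = {
          mem <- conc$membership[s, ]
          if (conc$mode != "t_stat")
            stop("logistic:concat requires concat_mode = \"t_stat\"",
                 call. = FALSE)
          if (sum(mem) == 0L || sum(mem) == length(mem)) na_result(s, tag)
          else logistic_enrichment(conc$diff, mem, s, tag)$result
        },
        "logistic:pcombine" = {
          fg <- logistic_platform("gene")[[s]]
          fm <- logistic_platform("metabolite")[[s]]
          fisher_combine(if (is.null(fg)) NA else fg$result$p_value,
                         if (is.null(fm)) NA else fm$result$p_value,
                         H = NULL, set_name = s, method = tag)
        },
        "logistic:joint" = {
          fg <- logistic_platform("gene")[[s]]
          fm <- logistic_platform("metabolite")[[s]]
          if (is.null(fg) || is.null(fm)) na_result(s, tag)
          else wald_2df(fg$fit, fm$fit, set_name = s, method = tag)
        },
        "sumsq:gene" = ,
        "sumsq:metabolite" = {
          W <- if (arm == "gene") W_g else W_m
          nul <- perm[[arm]]
          if (!s %in% names(W)) na_result(s, tag)
          else enrichment_result(s, tag, statistic = W[[s]],
                                 p_value = empirical_pvalue(W[[s]], nul[s, ]),
                                 H = perm$H)
        },
        "sumsq:concat" = {
          if (!s %in% names(W_g) || !s %in% names(W_m)) na_result(s, tag)
          else sumsq_concatenated(
            c(W_g[[s]], W_m[[s]]),
            null_cloud(cbind(perm$gene[s, ], perm$metabolite[s, ])), s, tag)
        },
        "sumsq:pcombine" = {
          pg <- if (s %in% names(W_g))
            empirical_pvalue(W_g[[s]], perm$gene[s, ]) else NA_real_
          pm <- if (s %in% names(W_m))
            empirical_pvalue(W_m[[s]], perm$metabolite[s, ]) else NA_real_
          fisher_combine(pg, pm, H = perm$H, set_name = s, method = tag)
        },
        "sumsq:joint" = {
          if (!s %in% names(W_g) || !s %in% names(W_m)) na_result(s, tag)
          else joint_permutation_pvalue(
            c(W_g[[s]], W_m[[s]]),
            null_cloud(cbind(perm$gene[s, ], perm$metabolite[s, ])), s, tag)
        },
        stop("unhandled method: ", tag))
      add_row(res, n_g[[si]], n_m[[si]])
    }
  }
  structure(list(results = do.call(rbind, rows),
                 methods = methods, alpha_elem = alpha_elem,
                 H = if (need_perm) H else NA_integer_,
                 matched = matched, permutations_run = need_perm,
                 diff = list(gene = diff_g, metabolite = diff_m),
                 call = match.call()),
            class = "intenrich")
}

# univariate fisher-exact p for one set (helper for the pcombine arm)
fisher_row <- function(M, diff, s, get_flags, platform) {
  if (is.null(M) || sum(M[s, ]) == 0L) return(NA_real_)
  fisher_exact_enrichment(contingency(get_flags(platform, diff), M[s, ]))$p_value
}

# method tags must be family:arm from the supported grid
validate_methods <- function(methods, has_gene, has_metab) {
  methods <- unique(as.character(methods))
  if (!length(methods)) stop("no methods requested", call. = FALSE)
  parts <- strsplit(methods, ":", fixed = TRUE)
  ok_fam <- c("fisher-exact", "logistic", "sumsq")
  ok_arm <- c("gene", "metabolite", "concat", "pcombine", "joint")
  for (i in seq_along(methods)) {
    p <- parts[[i]]
    if (length(p) != 2L || !p[1] %in% ok_fam || !p[2] %in% ok_arm)
      stop("invalid method tag: ", methods[i], call. = FALSE)
    if (p[1] == "fisher-exact" && p[2] == "joint")
      stop("fisher-exact has no joint arm; use pcombine or concat",
           call. = FALSE)
    needs_g <- p[2] != "metabolite"
    needs_m <- p[2] != "gene"
    if ((needs_g && !has_gene) || (needs_m && !has_metab))
      stop("method ", methods[i], " requires platform data that was not supplied",
           call. = FALSE)
  }
  methods
}

#' @export
print.intenrich <- function(x, ...) {
  cat("Integrative set-enrichment fit\n")
  cat(sprintf("  %d sets x %d methods (%s)\n",
              length(unique(x$results$set_name)), length(x$methods),
              paste(x$methods, collapse = ", ")))
  if (x$permutations_run)
    cat(sprintf("  permutation null: H = %d, %s samples\n", x$H,
                if (x$matched) "matched" else "unmatched"))
  ok <- !is.na(x$results$p_value)
  cat(sprintf("  %d/%d tests computed; %d with p < 0.05\n",
              sum(ok), nrow(x$results), sum(x$results$p_value[ok] < 0.05)))
  invisible(x)
}

#' @export
summary.intenrich <- function(object, alpha = 0.05, ...) {
  df <- object$results
  by_method <- split(df, df$method)
  tab <- do.call(rbind, lapply(by_method, function(d) {
    data.frame(method = d$method[1], n_sets = nrow(d),
               n_significant = sum(!is.na(d$p_value) & d$p_value < alpha),
               n_enriched = sum(d$direction == "enriched", na.rm = TRUE),
               n_depleted = sum(d$direction == "depleted", na.rm = TRUE),
               n_missing = sum(is.na(d$p_value)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, H = object$H),
            class = "summary.intenrich")
}

#' @export
print.summary.intenrich <- function(x, ...) {
  cat(sprintf("Set-enrichment summary (alpha = %g)\n", x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Results table of an enrichment fit
#'
#' @param x an `intenrich` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per set x method: `set_name`, `method`,
#'   `statistic`, `p_value`, `direction`, `n_genes`, `n_metabolites`.
#' @export
as.data.frame.intenrich <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  x$results
}

#' Extract one method's p-values keyed by set
#'
#' @param fit an `intenrich` object.
#' @param method one method tag present in the fit.
#' @return List with named numeric vectors `p` and `statistic` over sets.
#' @export
method_pvalues <- function(fit, method) {
  stopifnot(inherits(fit, "intenrich"))
  d <- fit$results[fit$results$method == method, ]
  if (!nrow(d)) stop("method not present in fit: ", method, call. = FALSE)
  list(p = stats::setNames(d$p_value, d$set_name),
       statistic = stats::setNames(d$statistic, d$set_name))
}
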