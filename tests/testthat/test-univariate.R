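test_that("dichotomisation thresholds strictly and at the right rate", {
  d <- toy_diff(c(3, 1, 2))
  d$p_value[] <- c(0.01, 0.2, 0.049)
  expect_equal(unname(dichotomize(d, 0.05)), c(1L, 0L, 1L))
  expect_equal(unname(dichotomize(d, 1)), c(1L, 1L, 1L))
  expect_error(dichotomize(d, 0), "alpha_elem")

  set.seed(11)
  du <- toy_diff(rep(0, 10000))
  du$p_value[] <- runif(10000)
  rate <- mean(dichotomize(du, 0.05))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("contingency counts agree with a naive double loop", {
  expect_equal(unname(unclass(contingency(c(1, 1, 0, 0), c(1, 0, 1, 0)))),
               c(1L, 1L, 1L, 1L))
  expect_equal(unname(unclass(contingency(c(0, 0, 0), c(1, 1, 0)))[c(1, 3)]),
               c(0L, 0L))
  expect_error(contingency(c(1, 0), c(0, 0)), "degenerate")

  set.seed(21)
  flags <- rbinom(200, 1, 0.3)
  mem <- rbinom(200, 1, 0.2)
  mem[1] <- 1L   # guard against an empty set
  tab <- contingency(flags, mem)
  ref <- c(0L, 0L, 0L, 0L)
  for (i in 1:200) {
    slot <- if (mem[i] == 1 && flags[i] == 1) 1L
            else if (mem[i] == 1) 2L
            else if (flags[i] == 1) 3L else 4L
    ref[slot] <- ref[slot] + 1L
  }
  expect_equal(unname(unclass(tab)), ref)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  t1 <- fisher_exact_enrichment(contingency(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(t1$p_value, 1)
  tab <- structure(c(in_set_diff = 3L, in_set_nondiff = 1L,
                     out_set_diff = 2L, out_set_nondiff = 14L),
                   class = "contingency_table")
  r <- fisher_exact_enrichment(tab, "s", "fisher-exact")
  expect_equal(r$p_value, enum_fisher_p(3, 1, 2, 14), tolerance = 1e-12)
  expect_equal(r$direction, "enriched")
  # transposition symmetry of the exact test
  tab_t <- structure(c(in_set_diff = 3L, in_set_nondiff = 2L,
                       out_set_diff = 1L, out_set_nondiff = 14L),
                     class = "contingency_table")
  expect_equal(fisher_exact_enrichment(tab_t)$p_value, r$p_value,
               tolerance = 1e-12)
  # zero margin carries no information
  tab0 <- structure(c(in_set_diff = 0L, in_set_nondiff = 5L,
                      out_set_diff = 0L, out_set_nondiff = 15L),
                    class = "contingency_table")
  r0 <- fisher_exact_enrichment(tab0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$direction, "n/a")
  # random spot checks against the enumeration oracle
  set.seed(31)
  for (i in 1:50) {
    cc <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    tb <- structure(c(in_set_diff = cc[1], in_set_nondiff = cc[2],
                      out_set_diff = cc[3], out_set_nondiff = cc[4]),
                    class = "contingency_table")
    got <- fisher_exact_enrichment(tb)$p_value
    want <- if (any(c(cc[1] + cc[2], cc[3] + cc[4], cc[1] + cc[3],
                      cc[2] + cc[4]) == 0L)) 1
            else enum_fisher_p(cc[1], cc[2], cc[3], cc[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("logistic enrichment matches an independent IRLS oracle", {
  set.seed(41)
  d <- toy_diff(rnorm(10, sd = 2))
  mem <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0)
  fit <- logistic_enrichment(d, mem, "s")$fit
  ref <- irls_logistic(abs(unname(d$t_stat)), mem)
  expect_equal(fit$slope, ref$slope, tolerance = 1e-6)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-6)
  expect_equal(fit$slope_se, ref$se[2], tolerance = 1e-6)
  # Wald p from the chi-square(1) upper tail
  r <- logistic_enrichment(d, mem)$result
  expect_equal(r$p_value,
               pchisq((ref$slope / ref$se[2])^2, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("logistic enrichment honours balance, rescaling and separation", {
  # each distinct |t| once with membership 1 and once with 0: zero slope
  tt <- c(1, 1, 2, 2, 3, 3)
  d <- toy_diff(tt)
  mem <- c(1, 0, 1, 0, 1, 0)
  fit <- logistic_enrichment(d, mem)$fit
  expect_lt(abs(fit$slope), 1e-8)
  expect_equal(logistic_enrichment(d, mem)$result$p_value, 1,
               tolerance = 1e-6)
  # doubling |t| halves the slope, Wald statistic invariant
  set.seed(42)
  d1 <- toy_diff(rnorm(12, sd = 2))
  mem1 <- rep(c(1, 0), 6)
  d2 <- d1; d2$t_stat <- 2 * d1$t_stat
  f1 <- logistic_enrichment(d1, mem1)
  f2 <- logistic_enrichment(d2, mem1)
  expect_equal(f2$fit$slope, f1$fit$slope / 2, tolerance = 1e-6)
  expect_equal(f2$result$statistic, f1$result$statistic, tolerance = 1e-6)
  # complete separation: members hold all the largest |t|
  ds <- toy_diff(c(5, 6, 7, 1, 2, 3))
  fs <- logistic_enrichment(ds, c(1, 1, 1, 0, 0, 0))
  expect_false(fs$fit$converged)
  expect_true(is.na(fs$result$p_value))
  expect_error(logistic_enrichment(ds, rep(1, 6)), "degenerate")
})

test_that("sum of squared statistics behaves arithmetically", {
  expect_equal(sum_squared_stat(toy_diff(c(0, 0, 0)), c(1, 1, 1)), 0)
  expect_equal(sum_squared_stat(toy_diff(c(1, 2, 3)), c(1, 1, 1)), 14)
  expect_equal(sum_squared_stat(toy_diff(c(1, 2, 3, 0)), c(1, 1, 1, 1)), 14)
  expect_error(sum_squared_stat(toy_diff(c(1, 2)), c(0, 0)), "no members")
})

test_that("empirical p-values count inclusively on the right scale", {
  expect_equal(empirical_pvalue(10, 1:9), 0)
  expect_equal(empirical_pvalue(0.5, 1:9), 1)
  # 96 null values below, 4 at or above: p = 0.04
  nulls <- c(seq_len(96) / 100, 2, 3, 4, 5)
  expect_equal(empirical_pvalue(1.5, nulls), 0.04)
  expect_equal(format_pvalue(0, 100), "<0.01")
})

test_that("permutation null recomputes statistics from raw data, deterministically", {
  toy <- toy_matrices(n_gene = 3, n_metab = 2, n_samples = 6, seed = 5)
  sets <- set_collection(gene = list(sA = c("g1", "g2"), sB = "g3"),
                         metabolite = list(sA = c("m1", "m2")))
  pn1 <- suppressWarnings(subject_permutation_null(
    toy$gene, toy$metabolite, toy$phenotype, sets, H = 12, seed = 9))
  pn2 <- suppressWarnings(subject_permutation_null(
    toy$gene, toy$metabolite, toy$phenotype, sets, H = 12, seed = 9))
  expect_identical(pn1$gene, pn2$gene)
  expect_identical(pn1$metabolite, pn2$metabolite)
  # matched platforms share the label assignment
  expect_identical(pn1$assignments$gene, pn1$assignments$metabolite)
  # each null statistic equals the from-scratch sum of squared pooled t
  # under that permutation's labels
  for (h in c(1L, 7L)) {
    q <- pn1$assignments$gene[, h]
    W_ref <- sum(vapply(c("g1", "g2"), function(g)
      pooled_t_oracle(toy$gene[g, q == 1], toy$gene[g, q == 0])^2,
      numeric(1)))
    expect_equal(unname(pn1$gene["sA", h]), W_ref, tolerance = 1e-10)
  }
  expect_error(
    suppressWarnings(subject_permutation_null(toy$gene, toy$metabolite,
                             phenotype_vector(paste0("x", 1:6),
                                              rep(c(1, 0), 3)),
                             sets, H = 5, matched = TRUE)),
    "phenotype|share")
  expect_warning(subject_permutation_null(toy$gene, labels = toy$phenotype,
                                          sets = sets, H = 10),
                 "resolution")
})

test_that("observed null statistics sit uniformly within their permutation cloud", {
  # with H = 199, p < 0.05 iff at most 9 of 199 nulls reach the observed
  # value: exact rejection probability 10/200 under exchangeability
  set.seed(61)
  n_rep <- 300L
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(4 * 12), 4, dimnames = list(sprintf("g%d", 1:4),
                                                  sprintf("s%d", 1:12)))
    mat <- omics_matrix(X, "gene")
    ph <- phenotype_vector(colnames(X), rep(c(1, 0), each = 6))
    sets <- set_collection(gene = list(s1 = rownames(X)))
    d <- two_sample_t(mat, ph)
    W <- sum_squared_stat(d, rep(1, 4))
    pn <- subject_permutation_null(mat, labels = ph, sets = sets, H = 199)
    rej[r] <- empirical_pvalue(W, pn$gene["s1", ]) < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})
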