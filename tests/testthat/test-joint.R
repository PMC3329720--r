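test_that("concatenation joins statistics and unions memberships", {
  dg <- toy_diff(c(1.5, -0.5), df = 8, platform = "gene", ids = c("g1", "g2"))
  dm <- toy_diff(2.5, df = 8, platform = "metabolite", ids = "m1")
  sets <- set_collection(gene = list(sA = "g1", sB = "g2"),
                         metabolite = list(sA = "m1"))
  cc <- concatenate_platforms(dg, dm, sets)
  expect_length(cc$diff$t_stat, 3L)
  expect_equal(unname(cc$membership["sA", ]), c(1L, 0L, 1L))
  expect_equal(unname(cc$n_gene["sA"] + cc$n_metabolite["sA"]), 2)
  # unequal df: raw t concatenation refused, p-value mode allowed
  dm10 <- toy_diff(2.5, df = 10, platform = "metabolite", ids = "m1")
  expect_error(concatenate_platforms(dg, dm10, sets), "degrees of freedom")
  cc_p <- concatenate_platforms(dg, dm10, sets, mode = "p_value")
  expect_true(all(is.na(cc_p$diff$t_stat)))
  expect_length(cc_p$diff$p_value, 3L)
  # colliding ids get namespaced
  dm_c <- toy_diff(1, df = 8, platform = "metabolite", ids = "g1")
  sets_c <- set_collection(gene = list(sA = "g1"),
                           metabolite = list(sA = "g1"))
  cc_c <- concatenate_platforms(dg, dm_c, sets_c)
  expect_true(all(c("gene:g1", "metabolite:g1") %in% cc_c$diff$element_ids))
})

test_that("concatenated Fisher counts equal the by-hand platform sums", {
  # 8-element toy: flags chosen by p-value threshold, then counted by hand
  dg <- toy_diff(c(4, 3.5, 0.1, 0.2, 0.3), df = 8, platform = "gene")
  dm <- toy_diff(c(3.8, 0.2, 0.1), df = 8, platform = "metabolite",
                 ids = c("m1", "m2", "m3"))
  sets <- set_collection(gene = list(S = c("e01", "e03")),
                         metabolite = list(S = "m1"))
  cc <- concatenate_platforms(dg, dm, sets)
  tab <- contingency(dichotomize(cc$diff, 0.05), cc$membership["S", ])
  flags_g <- dichotomize(dg, 0.05)
  flags_m <- dichotomize(dm, 0.05)
  g_SD_hand <- sum(flags_g[c("e01", "e03")]) + sum(flags_m["m1"])
  expect_equal(unname(unclass(tab)["in_set_diff"]), g_SD_hand)
  expect_equal(sum(unclass(tab)), 8L)
})

test_that("Fisher's p-value combination follows the chi-square(4) tail", {
  expect_equal(fisher_combine(1, 1)$statistic, 0)
  expect_equal(fisher_combine(1, 1)$p_value, 1)
  r <- fisher_combine(0.05, 0.05)
  expect_equal(r$statistic, -4 * log(0.05), tolerance = 1e-12)
  # chi-square(4) survival has closed form exp(-x/2) (1 + x/2)
  expect_equal(r$p_value, 0.017478661368, tolerance = 1e-8)
  expect_equal(r$p_value, exp(-r$statistic / 2) * (1 + r$statistic / 2),
               tolerance = 1e-12)
  # monotone non-decreasing in each input
  grid <- seq(0.01, 1, by = 0.045)
  p_fix <- 0.2
  out <- vapply(grid, function(p) fisher_combine(p, p_fix)$p_value,
                numeric(1))
  expect_true(all(diff(out) >= 0))
  # permutation zeros substitute half the resolution step
  expect_equal(fisher_combine(0, 0.5, H = 100)$statistic,
               -2 * (log(1 / 200) + log(0.5)), tolerance = 1e-12)
  expect_error(fisher_combine(0, 0.5), "permutation context")
})

test_that("the 2-df Wald test sums squared z-scores with chi-square(2) tail", {
  f0 <- toy_logistic_fit(0, 1)
  expect_equal(wald_2df(f0, f0)$statistic, 0)
  expect_equal(wald_2df(f0, f0)$p_value, 1)
  r <- wald_2df(toy_logistic_fit(2, 1), toy_logistic_fit(0, 1))
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, exp(-2), tolerance = 1e-12)
  # chi-square(2) upper tail == exp(-U/2) identically
  set.seed(51)
  for (i in 1:20) {
    fa <- toy_logistic_fit(rnorm(1), runif(1, 0.5, 2))
    fb <- toy_logistic_fit(rnorm(1), runif(1, 0.5, 2))
    rr <- wald_2df(fa, fb)
    expect_equal(rr$p_value, exp(-rr$statistic / 2), tolerance = 1e-12)
  }
  # collapses to the other platform's squared z when one slope is 0
  rz <- wald_2df(toy_logistic_fit(1.7, 0.6), toy_logistic_fit(0, 1))
  expect_equal(rz$statistic, (1.7 / 0.6)^2, tolerance = 1e-12)
  # non-convergence propagates as missing
  rn <- wald_2df(toy_logistic_fit(1, 1, converged = FALSE),
                 toy_logistic_fit(1, 1))
  expect_true(is.na(rn$p_value))
})

test_that("Mahalanobis distance handles centroid, hand case and affine maps", {
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  cl <- null_cloud(pts)
  expect_equal(cl$centroid, c(1, 1))
  expect_equal(mahalanobis_distance(c(1, 1), cl), 0)
  # sample covariance is diag(4/3, 4/3): D((2,2)) = sqrt(2 * 3/4)
  expect_equal(mahalanobis_distance(c(2, 2), cl), sqrt(1.5),
               tolerance = 1e-12)
  # identity covariance reduces to Euclidean distance
  cl_id <- cl
  cl_id$covariance <- diag(2)
  expect_equal(mahalanobis_distance(c(4, 5), cl_id),
               sqrt(sum((c(4, 5) - c(1, 1))^2)), tolerance = 1e-12)
  # agrees with the base-R quadratic form on random clouds
  set.seed(71)
  P <- matrix(rnorm(60), 30, 2) %*% rbind(c(1, 0.6), c(0, 0.8))
  cl2 <- null_cloud(P)
  q <- c(1.3, -0.4)
  expect_equal(mahalanobis_distance(q, cl2)^2,
               unname(stats::mahalanobis(rbind(q), cl2$centroid,
                                         cl2$covariance)),
               tolerance = 1e-10)
  # invariance under a simultaneous invertible affine transformation
  A <- rbind(c(2, 1), c(-0.5, 1.5)); b <- c(3, -7)
  cl3 <- null_cloud(t(A %*% t(P)) + rep(b, each = nrow(P)))
  expect_equal(mahalanobis_distance(drop(A %*% q) + b, cl3),
               mahalanobis_distance(q, cl2), tolerance = 1e-9)
  # singular cloud: ridge fallback warns, or errors when disabled
  Pc <- cbind(rnorm(10), 1)
  clc <- null_cloud(Pc)
  expect_warning(mahalanobis_distance(c(0, 1), clc), "ridge")
  expect_error(mahalanobis_distance(c(0, 1), clc, ridge = FALSE), "singular")
})

test_that("joint permutation p-values count null distances inclusively", {
  set.seed(81)
  P <- matrix(rnorm(200), 100, 2)
  cl <- null_cloud(P)
  expect_equal(joint_permutation_pvalue(cl$centroid, cl)$p_value, 1)
  # place the observed point so exactly 4 null distances reach it
  d <- sqrt(stats::mahalanobis(P, cl$centroid, cl$covariance))
  target <- mean(sort(d, decreasing = TRUE)[4:5])  # between 4th and 5th
  dir <- c(1, 0)
  scale <- target / mahalanobis_distance(cl$centroid + dir, cl)
  obs <- cl$centroid + dir * scale
  r <- joint_permutation_pvalue(obs, cl)
  expect_equal(r$p_value, 0.04)
  # strictly outside the cloud: below-resolution sentinel
  far <- cl$centroid + dir * scale * 50
  expect_equal(joint_permutation_pvalue(far, cl)$p_value, 0)
  # monotone non-increasing in the observed distance
  ps <- vapply(seq(0, 3, by = 0.25), function(s)
    joint_permutation_pvalue(cl$centroid + dir * s, cl)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("the concatenated sum-of-squares arm equals a pre-concatenated run", {
  toy <- toy_matrices(n_gene = 4, n_metab = 3, n_samples = 10, seed = 13)
  sets <- set_collection(gene = list(S = c("g1", "g2"), T = c("g3", "g4")),
                         metabolite = list(S = c("m1", "m3"), T = "m2"))
  H <- 64L
  pn <- suppressWarnings(subject_permutation_null(
    toy$gene, toy$metabolite, toy$phenotype, sets, H = H, seed = 3))
  dg <- two_sample_t(toy$gene, toy$phenotype)
  dm <- two_sample_t(toy$metabolite, toy$phenotype)
  Wg <- sumsq_by_set(dg, sets)
  Wm <- sumsq_by_set(dm, sets)
  # the same permutations applied to one stacked matrix with merged sets
  stacked <- omics_matrix(rbind(unclass(toy$gene), unclass(toy$metabolite)),
                          "gene")
  sets_merged <- set_collection(gene = list(S = c("g1", "g2", "m1", "m3"),
                                            T = c("g3", "g4", "m2")))
  pn2 <- suppressWarnings(subject_permutation_null(
    stacked, labels = toy$phenotype, sets = sets_merged, H = H, seed = 3))
  for (s in c("S", "T")) {
    cl <- null_cloud(cbind(pn$gene[s, ], pn$metabolite[s, ]))
    r <- sumsq_concatenated(c(Wg[[s]], Wm[[s]]), cl, s)
    expect_equal(r$statistic, Wg[[s]] + Wm[[s]])
    d_all <- two_sample_t(stacked, toy$phenotype)
    W_all <- sumsq_by_set(d_all, sets_merged)
    expect_equal(r$statistic, W_all[[s]], tolerance = 1e-10)
    expect_equal(r$p_value,
                 empirical_pvalue(W_all[[s]], pn2$gene[s, ]),
                 tolerance = 1e-12)
  }
  # all-zero signal degenerates gracefully
  czero <- null_cloud(matrix(rep(c(1, 2), each = 5), 5))
  expect_equal(sumsq_concatenated(c(0, 0), czero)$p_value, 1)
})
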