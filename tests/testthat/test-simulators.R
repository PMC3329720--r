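test_that("disjoint simulation is reproducible and respects its design", {
  cfg <- disjoint_config(n_sets = 6, n_associated = 2, genes_per_set = 5,
                         metabolites_per_set = 3, n_samples = 12, seed = 99)
  s1 <- simulate_disjoint(cfg)
  s2 <- simulate_disjoint(cfg)
  expect_identical(unclass(s1$gene), unclass(s2$gene))
  expect_identical(unclass(s1$metabolite), unclass(s2$metabolite))
  expect_identical(s1$truth$diff_gene, s2$truth$diff_gene)

  expect_equal(dim(s1$gene), c(30L, 12L))
  expect_equal(dim(s1$metabolite), c(18L, 12L))
  expect_length(s1$sets$set_names, 6L)
  expect_equal(lengths(s1$sets$gene), rep(5L, 6), ignore_attr = TRUE)
  # disjoint: every element in exactly one set
  expect_equal(anyDuplicated(unlist(s1$sets$gene)), 0L)
  # effect magnitudes stay inside the configured ranges
  eg <- s1$truth$effect_gene[s1$truth$diff_gene == 1]
  em <- s1$truth$effect_metab[s1$truth$diff_metab == 1]
  expect_true(all(abs(eg) >= 0.5 & abs(eg) <= 2.5))
  expect_true(all(abs(em) >= 0.5 & abs(em) <= 1.5))
  # only associated sets can carry effects when d0 = c0 = 0
  hit_sets <- unique(c(
    names(which(vapply(s1$sets$gene, function(g)
      any(s1$truth$diff_gene[g] == 1), logical(1)))),
    names(which(vapply(s1$sets$metabolite, function(m)
      any(s1$truth$diff_metab[m] == 1), logical(1))))))
  expect_true(all(hit_sets %in% s1$truth$associated_sets))

  expect_error(disjoint_config(rho_gg = 0.1, rho_mg = 0.3), "rho")
  expect_error(disjoint_config(n_samples = 31), "even")
  expect_error(disjoint_config(d1 = 1.2), "probabilities")
})

test_that("disjoint differential fractions match their Bernoulli design", {
  # flag draws only: tiny sample dimension, many replicates
  cfg <- disjoint_config(n_samples = 4)
  set.seed(7)
  n_rep <- 300L
  frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg$seed <- r
    s <- simulate_disjoint(cfg)
    frac[r] <- mean(c(s$truth$diff_gene, s$truth$diff_metab))
  }
  # 10 of 50 sets at 25%: expected overall differential fraction 5%
  n_draws <- n_rep * 1200
  expect_lt(abs(mean(frac) - 0.05), 3 * sqrt(0.05 * 0.95 / n_draws))
})

test_that("simulated error correlations recover their configuration", {
  cfg <- disjoint_config(n_sets = 2, n_associated = 0, genes_per_set = 4,
                         metabolites_per_set = 3, d1 = 0, c1 = 0,
                         rho_gg = 0.6, rho_mm = 0.6, rho_mg = 0.25,
                         n_samples = 5000, seed = 55)
  s <- simulate_disjoint(cfg)
  g <- unclass(s$gene); m <- unclass(s$metabolite)
  mc3 <- 3 / sqrt(cfg$n_samples)
  expect_lt(abs(cor(g["g1", ], g["g2", ]) - 0.6), mc3)
  expect_lt(abs(cor(m["m1", ], m["m2", ]) - 0.6), mc3)
  expect_lt(abs(cor(g["g1", ], m["m1", ]) - 0.25), mc3)
  # no correlation across sets (g1 in set 1, g5 in set 2)
  expect_lt(abs(cor(g["g1", ], g["g5", ])), mc3)
})

test_that("heterogeneous design yields its printed sizes and 12% rates", {
  for (mpb in c(20L, 4L)) {
    cfg <- hetero_config(metabolites_per_block = mpb, n_samples = 8,
                         seed_membership = 1, seed_data = 2)
    s <- simulate_heterogeneous(cfg)
    expect_equal(nrow(s$gene), 1000L)
    expect_equal(nrow(s$metabolite), if (mpb == 20L) 1000L else 200L)
    expect_equal(mean(s$truth$diff_gene), 0.12)
    expect_equal(mean(s$truth$diff_metab), 0.12)
    expect_length(s$sets$set_names, 70L)
    # null partition (sets 30-70): null elements only, all covered
    null_sets <- s$truth$null_sets
    expect_length(null_sets, 41L)
    null_members_g <- unlist(s$sets$gene[null_sets])
    expect_true(all(s$truth$diff_gene[null_members_g] == 0))
    # blocks are laid out first: the null pool is everything after the
    # nine design blocks
    null_pool_g <- names(s$truth$diff_gene)[-seq_len(9L * 20L)]
    expect_setequal(null_members_g, null_pool_g)
    null_members_m <- unlist(s$sets$metabolite[null_sets])
    null_pool_m <- names(s$truth$diff_metab)[-seq_len(9L * mpb)]
    expect_setequal(null_members_m, null_pool_m)
  }
})

test_that("heterogeneous membership is fixed across data replicates", {
  cfg <- hetero_config(metabolites_per_block = 4, n_samples = 8,
                       seed_membership = 42, seed_data = 1)
  s1 <- simulate_heterogeneous(cfg)
  cfg$seed_data <- 2
  s2 <- simulate_heterogeneous(cfg)
  expect_identical(s1$sets$gene, s2$sets$gene)
  expect_identical(s1$sets$metabolite, s2$sets$metabolite)
  expect_false(identical(unclass(s1$gene), unclass(s2$gene)))
  # block-driven correlation: r1 within correlated blocks, none in h = 1
  cfg3 <- hetero_config(metabolites_per_block = 4, n_samples = 3000,
                        r1 = 0.35, r2 = 0.15, seed_membership = 3,
                        seed_data = 4)
  s3 <- simulate_heterogeneous(cfg3)
  g <- unclass(s3$gene)
  resid <- g[, s3$phenotype == 0]     # controls carry no effect shift
  mc3 <- 3 / sqrt(ncol(resid))
  i2 <- 21:22                         # block h = 2: correlated
  i1 <- 1:2                           # block h = 1: uncorrelated
  expect_lt(abs(cor(resid[i2[1], ], resid[i2[2], ]) - 0.35), mc3)
  expect_lt(abs(cor(resid[i1[1], ], resid[i1[2], ])), mc3)
})
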