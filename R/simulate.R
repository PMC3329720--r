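#' Configuration for the disjoint-set simulation
#'
#' Parameters of the additive two-platform model with disjoint,
#' equally-sized, internally homogeneous sets:
#' \deqn{Y_{ij} = \alpha + \beta_j + \omega_j D_j Q_i + e_{ij}, \qquad
#'       Z_{ik} = \theta + \phi_k + \eta_k C_k Q_i + e_{ik},}
#' where \eqn{Q_i} is the case indicator, \eqn{D_j}/\eqn{C_k} are Bernoulli
#' differential indicators with success probability `d1`/`c1` inside
#' associated sets and `d0`/`c0` elsewhere, and the errors are multivariate
#' normal with within-set correlations `rho_gg` (gene-gene), `rho_mm`
#' (metabolite-metabolite) and `rho_mg` (cross-platform, matched samples)
#' and no correlation across sets. Per-element variances are
#' \eqn{4\sigma^2} with \eqn{\sigma^2} an inverse-\eqn{\chi^2_4} draw
#' (\eqn{1/X}, \eqn{X \sim \chi^2_4}), baseline means
#' \eqn{\beta_j, \phi_k \sim N(0, 4\sigma^2)}, and effect sizes
#' \eqn{\omega_j \sim U(\pm[0.5, 2.5])},
#' \eqn{\eta_k \sim U(\pm[0.5, 1.5])} - the narrower metabolite range
#' yields the weaker intensity differences typical of that platform.
#'
#' Defaults give 50 sets of 20 genes and 4 metabolites, 10 associated sets,
#' 25% within-set differential probability, within-set correlation 0.20,
#' cross-platform 0.10, and 100 matched samples split 50/50 (the sample
#' size under which this design's reported ranking behaviour reproduces;
#' see the methods vignette).
#'
#' @param n_sets,n_associated number of sets and how many of them are
#'   associated with the phenotype (the first `n_associated`).
#' @param genes_per_set,metabolites_per_set set sizes per platform.
#' @param d1,d0,c1,c0 differential probabilities inside/outside associated
#'   sets, genes (`d`) and metabolites (`c`).
#' @param rho_gg,rho_mm,rho_mg within-set error correlations; requires
#'   `rho_gg == rho_mm >= rho_mg >= 0`.
#' @param n_samples total matched samples (even; split equally into
#'   cases/controls).
#' @param omega_range,eta_range magnitude ranges of the case effects; the
#'   sign is a fair coin.
#' @param grand_mean_gene,grand_mean_metabolite global means \eqn{\alpha},
#'   \eqn{\theta}.
#' @param seed optional RNG seed used by [simulate_disjoint()].
#' @return List of class `disjoint_config`.
#' @export
disjoint_config <- function(n_sets = 50L, n_associated = 10L,
                            genes_per_set = 20L, metabolites_per_set = 4L,
                            d1 = 0.25, d0 = 0, c1 = 0.25, c0 = 0,
                            rho_gg = 0.20, rho_mm = rho_gg, rho_mg = 0.10,
                            n_samples = 100L,
                            omega_range = c(0.5, 2.5),
                            eta_range = c(0.5, 1.5),
                            grand_mean_gene = 0, grand_mean_metabolite = 0,
                            seed = NULL) {
  probs <- c(d1 = d1, d0 = d0, c1 = c1, c0 = c0)
  if (any(probs < 0 | probs > 1))
    stop("differential probabilities must lie in [0, 1]", call. = FALSE)
  if (rho_gg != rho_mm)
    stop("model requires rho_gg == rho_mm", call. = FALSE)
  if (!(rho_gg >= rho_mg && rho_mg >= 0))
    stop("model requires rho_gg = rho_mm >= rho_mg >= 0", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples %% 2L != 0L || n_samples < 4L)
    stop("n_samples must be even and >= 4", call. = FALSE)
  if (n_associated > n_sets)
    stop("n_associated cannot exceed n_sets", call. = FALSE)
  stopifnot(length(omega_range) == 2L, omega_range[1] > 0,
            diff(omega_range) >= 0,
            length(eta_range) == 2L, eta_range[1] > 0, diff(eta_range) >= 0)
  cfg <- list(n_sets = as.integer(n_sets),
              n_associated = as.integer(n_associated),
              genes_per_set = as.integer(genes_per_set),
              metabolites_per_set = as.integer(metabolites_per_set),
              d1 = d1, d0 = d0, c1 = c1, c0 = c0,
              rho_gg = rho_gg, rho_mm = rho_mm, rho_mg = rho_mg,
              n_samples = n_samples,
              omega_range = as.numeric(omega_range),
              eta_range = as.numeric(eta_range),
              grand_mean_gene = grand_mean_gene,
              grand_mean_metabolite = grand_mean_metabolite,
              seed = seed)
  # the requested block correlation must be positive definite
  R <- block_correlation(cfg$genes_per_set, cfg$metabolites_per_set,
                         rho_gg, rho_mm, rho_mg)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch))
    stop("requested within-set correlation block is not positive definite",
         call. = FALSE)
  structure(cfg, class = "disjoint_config")
}

# within-set correlation block: genes first, then metabolites
block_correlation <- function(n_g, n_m, rho_gg, rho_mm, rho_mg) {
  k <- n_g + n_m
  R <- matrix(rho_mg, k, k)
  if (n_g) R[seq_len(n_g), seq_len(n_g)] <- rho_gg
  if (n_m) R[n_g + seq_len(n_m), n_g + seq_len(n_m)] <- rho_mm
  diag(R) <- 1
  R
}

# correlated MVN noise for one block: k x n, unit-diagonal correlation chol_R
# scaled to per-element standard deviations sdv
block_noise <- function(chol_R, sdv, n) {
  k <- length(sdv)
  e <- crossprod(chol_R, matrix(stats::rnorm(k * n), k, n))
  e * sdv
}

signed_uniform <- function(n, range) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, range[1], range[2])
}

#' Simulate a disjoint-set two-platform dataset
#'
#' Draws one dataset under the model described in [disjoint_config()]:
#' matched gene and metabolite matrices, the phenotype, the (disjoint) set
#' collection and the ground truth of differential flags and associated
#' sets.
#'
#' @param config a [disjoint_config()].
#' @return List of class `sim_data` with components `gene`, `metabolite`
#'   ([omics_matrix()]), `phenotype`, `sets`, `truth` (class `sim_truth`:
#'   `diff_gene`, `diff_metab`, `associated_sets`, `null_sets`, `set_info`)
#'   and `config`.
#' @export
simulate_disjoint <- function(config) {
  stopifnot(inherits(config, "disjoint_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$n_sets
  gps <- config$genes_per_set
  mps <- config$metabolites_per_set
  G <- s * gps
  M <- s * mps
  n <- config$n_samples
  wd <- nchar(as.character(s))
  set_names <- sprintf(paste0("set%0", wd, "d"), seq_len(s))
  gene_ids <- sprintf(paste0("g%0", nchar(G), "d"), seq_len(G))
  metab_ids <- sprintf(paste0("m%0", nchar(M), "d"), seq_len(M))
  sample_ids <- sprintf(paste0("s%0", nchar(n), "d"), seq_len(n))

  gene_set <- rep(seq_len(s), each = gps)
  metab_set <- rep(seq_len(s), each = mps)
  associated <- seq_len(s) <= config$n_associated

  v_g <- 4 / stats::rchisq(G, df = 4)
  v_m <- 4 / stats::rchisq(M, df = 4)
  beta <- stats::rnorm(G, 0, sqrt(v_g))
  phi <- stats::rnorm(M, 0, sqrt(v_m))
  D <- stats::rbinom(G, 1L, ifelse(associated[gene_set], config$d1, config$d0))
  C <- stats::rbinom(M, 1L, ifelse(associated[metab_set], config$c1, config$c0))
  omega <- signed_uniform(G, config$omega_range)
  eta <- signed_uniform(M, config$eta_range)

  q <- rep(c(1L, 0L), each = n %/% 2L)
  case_cols <- which(q == 1L)

  chol_R <- chol(block_correlation(gps, mps, config$rho_gg, config$rho_mm,
                                   config$rho_mg))
  Y <- matrix(0, G, n, dimnames = list(gene_ids, sample_ids))
  Z <- matrix(0, M, n, dimnames = list(metab_ids, sample_ids))
  for (si in seq_len(s)) {
    gi <- which(gene_set == si)
    mi <- which(metab_set == si)
    e <- block_noise(chol_R, sqrt(c(v_g[gi], v_m[mi])), n)
    Y[gi, ] <- config$grand_mean_gene + beta[gi] + e[seq_len(gps), ]
    Z[mi, ] <- config$grand_mean_metabolite + phi[mi] +
      e[gps + seq_len(mps), ]
  }
  Y[, case_cols] <- Y[, case_cols] + (omega * D)
  Z[, case_cols] <- Z[, case_cols] + (eta * C)

  sets <- set_collection(
    gene = split(gene_ids, set_names[gene_set]),
    metabolite = split(metab_ids, set_names[metab_set]))
  truth <- structure(list(
    diff_gene = stats::setNames(D, gene_ids),
    diff_metab = stats::setNames(C, metab_ids),
    effect_gene = stats::setNames(omega * D, gene_ids),
    effect_metab = stats::setNames(eta * C, metab_ids),
    associated_sets = set_names[associated],
    null_sets = set_names[!associated],
    set_info = data.frame(set_name = set_names, associated = associated,
                          null = !associated, stringsAsFactors = FALSE)),
    class = "sim_truth")
  structure(list(gene = omics_matrix(Y, "gene"),
                 metabolite = omics_matrix(Z, "metabolite"),
                 phenotype = phenotype_vector(sample_ids, q),
                 sets = sets, truth = truth, config = config),
            class = "sim_data")
}

#' Configuration for the heterogeneous-set simulation
#'
#' A fixed-design alternative to [disjoint_config()]: elements are drawn in
#' nine blocks with deterministic differential status and block-wise
#' correlation, a pool of null elements fills the matrices, and 70
#' overlapping sets of varying fidelity sample that pool. Block
#' distributions h = 1..9: genes are differential in h = 1..6, metabolites
#' in h = 1,2,3,7,8,9; within-platform correlation `r1` applies in
#' h = 2,3,5,6,8,9 and cross-platform correlation `r2` in h = 3,6,9; null
#' elements (h = 0) are uncorrelated and non-differential. The element-wise
#' variance/mean/effect model is that of the disjoint simulation. With the
#' default 20 genes per block and 1000 genes, 120/1000 genes (12%) are
#' differential by construction, and likewise 12% of metabolites.
#'
#' Set design: sets 1-9 are the full blocks (enrichment purity
#' \eqn{\pi = 1}); sets 10-18 take half of block h plus null fill
#' (\eqn{\pi = 0.5}); sets 19-24 take a quarter of blocks h = 1..6 plus
#' null fill (\eqn{\pi = 0.25}); sets 25-29 are random draws from all
#' elements; the remaining `n_null_sets` sets partition the null elements
#' into near-equal chunks so that every null element appears in at least
#' one set. Membership is drawn once per study (`seed_membership`) and held
#' fixed while replicate datasets vary `seed_data`.
#'
#' @param n_genes total genes (divisible by `genes_per_block`).
#' @param genes_per_block,metabolites_per_block block sizes; total
#'   metabolites is `n_genes / genes_per_block * metabolites_per_block`
#'   (1000 or 200 for the default gene pool with 20 or 4 metabolites).
#' @param r1,r2 within-platform and cross-platform correlation
#'   (`r1 >= r2 >= 0`).
#' @param n_samples total matched samples (even, equal split).
#' @param omega_range,eta_range,grand_mean_gene,grand_mean_metabolite as in
#'   [disjoint_config()].
#' @param n_null_sets,n_random_sets null-partition and random set counts.
#' @param seed_membership,seed_data the two RNG streams.
#' @return List of class `hetero_config`.
#' @export
hetero_config <- function(n_genes = 1000L, genes_per_block = 20L,
                          metabolites_per_block = 20L,
                          r1 = 0.20, r2 = 0.10, n_samples = 60L,
                          omega_range = c(0.5, 2.5), eta_range = c(0.5, 1.5),
                          grand_mean_gene = 0, grand_mean_metabolite = 0,
                          n_null_sets = 41L, n_random_sets = 5L,
                          seed_membership = NULL, seed_data = NULL) {
  if (!(r1 >= r2 && r2 >= 0))
    stop("requires r1 >= r2 >= 0", call. = FALSE)
  n_genes <- as.integer(n_genes)
  gpb <- as.integer(genes_per_block)
  mpb <- as.integer(metabolites_per_block)
  if (n_genes %% gpb != 0L)
    stop("n_genes must be divisible by genes_per_block", call. = FALSE)
  if (9L * gpb >= n_genes)
    stop("gene pool too small for 9 blocks plus null elements", call. = FALSE)
  n_metab <- (n_genes %/% gpb) * mpb
  n_samples <- as.integer(n_samples)
  if (n_samples %% 2L != 0L || n_samples < 4L)
    stop("n_samples must be even and >= 4", call. = FALSE)
  structure(list(n_genes = n_genes, genes_per_block = gpb,
                 metabolites_per_block = mpb, n_metabolites = n_metab,
                 r1 = r1, r2 = r2, n_samples = n_samples,
                 omega_range = as.numeric(omega_range),
                 eta_range = as.numeric(eta_range),
                 grand_mean_gene = grand_mean_gene,
                 grand_mean_metabolite = grand_mean_metabolite,
                 n_null_sets = as.integer(n_null_sets),
                 n_random_sets = as.integer(n_random_sets),
                 seed_membership = seed_membership, seed_data = seed_data),
            class = "hetero_config")
}

# near-equal consecutive chunking of a vector into k groups
chunk_near_equal <- function(x, k) {
  n <- length(x)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  split(x, rep(seq_len(k), sizes))
}

# the fixed block design: per-element block id (0 = null) and differential
# status, for one platform
hetero_blocks <- function(n_elem, per_block) {
  h <- integer(n_elem)
  h[seq_len(9L * per_block)] <- rep(1:9, each = per_block)
  h
}

#' Draw the fixed set memberships of the heterogeneous design
#'
#' Uses `config$seed_membership`. Normally called via
#' [simulate_heterogeneous()], but exposed so that one membership can be
#' shared across replicate datasets explicitly.
#'
#' @param config a [hetero_config()].
#' @return List with `sets` (a [set_collection()]) and `set_info`
#'   (data.frame: set_name, category, pi, h, null).
#' @export
hetero_membership <- function(config) {
  stopifnot(inherits(config, "hetero_config"))
  if (!is.null(config$seed_membership)) set.seed(config$seed_membership)
  gpb <- config$genes_per_block
  mpb <- config$metabolites_per_block
  G <- config$n_genes
  M <- config$n_metabolites
  gene_ids <- sprintf(paste0("g%0", nchar(G), "d"), seq_len(G))
  metab_ids <- sprintf(paste0("m%0", nchar(M), "d"), seq_len(M))
  gh <- hetero_blocks(G, gpb)
  mh <- hetero_blocks(M, mpb)
  null_genes <- gene_ids[gh == 0L]
  null_metabs <- metab_ids[mh == 0L]
  n_sets <- 24L + config$n_random_sets + config$n_null_sets
  wd <- nchar(as.character(n_sets))
  nm <- function(i) sprintf(paste0("set%0", wd, "d"), i)

  gsets <- list(); msets <- list()
  info <- list()
  add <- function(i, g, m, category, pi, h) {
    gsets[[nm(i)]] <<- g
    msets[[nm(i)]] <<- m
    info[[length(info) + 1L]] <<- data.frame(
      set_name = nm(i), category = category, pi = pi, h = h,
      null = category == "null", stringsAsFactors = FALSE)
  }
  take <- function(pool, frac, size) {
    k <- max(1L, round(frac * size))
    sample(pool, k)
  }
  for (h in 1:9)                              # full blocks, pi = 1
    add(h, gene_ids[gh == h], metab_ids[mh == h], "enriched", 1, h)
  for (h in 1:9) {                            # half blocks + null fill
    g <- take(gene_ids[gh == h], 0.5, gpb)
    m <- take(metab_ids[mh == h], 0.5, mpb)
    add(9L + h, c(g, sample(null_genes, gpb - length(g))),
        c(m, sample(null_metabs, mpb - length(m))), "enriched", 0.5, h)
  }
  for (h in 1:6) {                            # quarter blocks + null fill
    g <- take(gene_ids[gh == h], 0.25, gpb)
    m <- take(metab_ids[mh == h], 0.25, mpb)
    add(18L + h, c(g, sample(null_genes, gpb - length(g))),
        c(m, sample(null_metabs, mpb - length(m))), "enriched", 0.25, h)
  }
  for (i in seq_len(config$n_random_sets))    # random draws from everything
    add(24L + i, sample(gene_ids, gpb), sample(metab_ids, mpb),
        "random", NA_real_, NA_integer_)
  gchunk <- chunk_near_equal(sample(null_genes), config$n_null_sets)
  mchunk <- chunk_near_equal(sample(null_metabs), config$n_null_sets)
  for (i in seq_len(config$n_null_sets))      # partition of the null pool
    add(24L + config$n_random_sets + i, gchunk[[i]], mchunk[[i]],
        "null", NA_real_, 0L)
  list(sets = set_collection(gene = gsets, metabolite = msets),
       set_info = do.call(rbind, info))
}

#' Simulate a heterogeneous-set two-platform dataset
#'
#' Draws one dataset under the fixed 70-set design of [hetero_config()].
#' Pass a pre-drawn `membership` (from [hetero_membership()]) to hold the
#' set definitions fixed across replicate datasets; otherwise it is drawn
#' here from `config$seed_membership`.
#'
#' @param config a [hetero_config()].
#' @param membership optional result of [hetero_membership()].
#' @return A `sim_data` list as in [simulate_disjoint()]; the truth's
#'   `null_sets` are the null-partition sets and `associated_sets` the
#'   design sets 1-24.
#' @export
simulate_heterogeneous <- function(config, membership = NULL) {
  stopifnot(inherits(config, "hetero_config"))
  if (is.null(membership)) membership <- hetero_membership(config)
  if (!is.null(config$seed_data)) set.seed(config$seed_data)
  gpb <- config$genes_per_block
  mpb <- config$metabolites_per_block
  G <- config$n_genes
  M <- config$n_metabolites
  n <- config$n_samples
  gene_ids <- sprintf(paste0("g%0", nchar(G), "d"), seq_len(G))
  metab_ids <- sprintf(paste0("m%0", nchar(M), "d"), seq_len(M))
  sample_ids <- sprintf(paste0("s%0", nchar(n), "d"), seq_len(n))
  gh <- hetero_blocks(G, gpb)
  mh <- hetero_blocks(M, mpb)
  diff_gene <- as.integer(gh %in% 1:6)
  diff_metab <- as.integer(mh %in% c(1:3, 7:9))

  v_g <- 4 / stats::rchisq(G, df = 4)
  v_m <- 4 / stats::rchisq(M, df = 4)
  beta <- stats::rnorm(G, 0, sqrt(v_g))
  phi <- stats::rnorm(M, 0, sqrt(v_m))
  omega <- signed_uniform(G, config$omega_range)
  eta <- signed_uniform(M, config$eta_range)
  q <- rep(c(1L, 0L), each = n %/% 2L)
  case_cols <- which(q == 1L)

  rho_w <- function(h) if (h %in% c(2, 3, 5, 6, 8, 9)) config$r1 else 0
  rho_x <- function(h) if (h %in% c(3, 6, 9)) config$r2 else 0
  Y <- matrix(0, G, n, dimnames = list(gene_ids, sample_ids))
  Z <- matrix(0, M, n, dimnames = list(metab_ids, sample_ids))
  for (h in 1:9) {
    gi <- which(gh == h)
    mi <- which(mh == h)
    ch <- chol(block_correlation(gpb, mpb, rho_w(h), rho_w(h), rho_x(h)))
    e <- block_noise(ch, sqrt(c(v_g[gi], v_m[mi])), n)
    Y[gi, ] <- e[seq_len(gpb), ]
    Z[mi, ] <- e[gpb + seq_len(mpb), ]
  }
  gi0 <- which(gh == 0L)
  mi0 <- which(mh == 0L)
  Y[gi0, ] <- matrix(stats::rnorm(length(gi0) * n), length(gi0), n) *
    sqrt(v_g[gi0])
  Z[mi0, ] <- matrix(stats::rnorm(length(mi0) * n), length(mi0), n) *
    sqrt(v_m[mi0])
  Y <- Y + config$grand_mean_gene + beta
  Z <- Z + config$grand_mean_metabolite + phi
  Y[, case_cols] <- Y[, case_cols] + (omega * diff_gene)
  Z[, case_cols] <- Z[, case_cols] + (eta * diff_metab)

  info <- membership$set_info
  truth <- structure(list(
    diff_gene = stats::setNames(diff_gene, gene_ids),
    diff_metab = stats::setNames(diff_metab, metab_ids),
    effect_gene = stats::setNames(omega * diff_gene, gene_ids),
    effect_metab = stats::setNames(eta * diff_metab, metab_ids),
    associated_sets = info$set_name[info$category == "enriched"],
    null_sets = info$set_name[info$null],
    set_info = info),
    class = "sim_truth")
  structure(list(gene = omics_matrix(Y, "gene"),
                 metabolite = omics_matrix(Z, "metabolite"),
                 phenotype = phenotype_vector(sample_ids, q),
                 sets = membership$sets, truth = truth, config = config),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data: %d genes x %d samples, %d metabolites, %d sets\n",
              nrow(x$gene), ncol(x$gene), nrow(x$metabolite),
              length(x$sets$set_names)))
  invisible(x)
}
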