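---
title: "Integrative set enrichment across two omics platforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative set enrichment across two omics platforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A two-group study that measures both gene expression and metabolite
intensities on (mostly) the same subjects produces two lists of
differential elements. Pathway databases assign genes *and* metabolites to
the same named sets, so the natural question is joint: *does this pathway
show coordinated differential behaviour across both platforms?* Metabolite
panels are small — a set with three measured metabolites can be 67%
"enriched" without any statistical meaning — so borrowing strength from
the gene side is attractive, and vice versa.

`intenrich` implements the two families of single-platform enrichment
tests and four ways of joining them across platforms, together with the
simulation models used to characterise their operating characteristics.

## Per-element differential testing

Everything starts from per-element two-sample t-statistics. We use the
pooled-variance form, oriented so that $t > 0$ means the case mean exceeds
the control mean, with $df = n_1 + n_0 - 2$. Pooled rather than unequal-
variance: the simulation models draw a single variance per element for
both groups, and a pooled test gives all elements of a platform a common
degrees of freedom, which is what makes concatenated t-vectors comparable
when the sample sizes match. Elements with zero pooled variance and equal
means are reported as $t = 0$, $p = 1$; zero variance with unequal means
has no defined statistic and is treated as an error rather than silently
patched.

## The enrichment tests

**Competitive tests** compare a set $S$ against its complement among the
measured elements.

* *Fisher's exact test.* Elements are flagged differential at a
  per-element cutoff `alpha_elem` (default 0.05, the conventional
  screening level; the cutoff is a genuine tuning parameter and the
  Type-I behaviour of the concatenated variant is sensitive to the flag
  rate it induces). The 2×2 table of (flagged?) × (in set?) is tested
  two-sided; enrichment and depletion are distinguished by the sample
  odds ratio.
* *Logistic regression.* Set membership is regressed on $|t|$:
  $\mathrm{logit}\Pr(j \in S) = \gamma_0 + \gamma |t_j|$, with a 1-df Wald
  test of $\gamma = 0$. This uses the full strength of evidence per
  element instead of a dichotomised flag. With a single covariate,
  complete separation is detected exactly (disjoint $|t|$ ranges for
  members and non-members); such fits are flagged non-converged and their
  p-value reported missing.

**The self-contained test** ignores the complement: $W_S = \sum_{j \in S}
t_j^2$, assessed against a subject-label permutation null. For each of
$H$ permutations the labels are reshuffled (group sizes preserved, the
identity arrangement not excluded), all t-statistics are recomputed from
the raw matrix, and $\tilde W_S$ is re-summed. The empirical p-value
$H^{-1} \sum_h I(\tilde W_h \ge \hat W)$ uses the inclusive inequality
and no +1 correction, so p-values are exact multiples of $1/H$; an
observed statistic exceeding every null value is reported as "$< 1/H$"
(stored as 0). The default $H = 1000$ is the resolution floor of these
p-values.

**Joint tests.** Four ways to combine the platforms:

1. *Concatenation*: append the metabolite vector to the gene vector and
   run a univariate test on the union membership. Raw t-statistics are
   only concatenated when both platforms share the same degrees of
   freedom; otherwise the p-value mode must be used.
2. *Fisher's p-value combination*: $-2(\ln p^G_S + \ln p^M_S)$ against
   $\chi^2_4$. The reference distribution assumes independent tests,
   which is approximate for matched subjects. Permutation p-values of
   exactly zero are substituted by $1/(2H)$ — half a step below the
   permutation resolution — before logging.
3. *2-df Wald*: with slopes $\hat\gamma, \hat\mu$ and standard errors
   from the two univariate logistic fits,
   $U_S = (\hat\gamma/\hat\sigma_\gamma)^2 + (\hat\mu/\hat\sigma_\mu)^2
   \sim \chi^2_2$. The slope covariance is fixed at zero: row-resampling
   bootstrap estimates of it are near zero even for correlated data, and
   subject-level resampling badly underestimates the slope variances, so
   a diagonal variance matrix is the defensible choice. The interface
   retains the covariance slot for future weighted versions.
4. *2-D permutation test*: the observed pair $(\hat W^G_S, \hat W^M_S)$
   is compared with the cloud of $H$ matched-permutation null pairs via
   the Mahalanobis distance from the cloud centroid,
   $D = \sqrt{(w - \psi)^\top V_H^{-1} (w - \psi)}$, and
   $p = H^{-1}\sum_h I(D(\tilde W_h) \ge D(\hat W))$. The Mahalanobis
   metric respects the shape of the null cloud, so a point can be extreme
   along its thin axis — precisely the sets that are missed marginally.
   The centroid and covariance are computed from the null pairs only,
   never including the observed pair. Matched platforms share each label
   permutation, which is what preserves the between-platform correlation
   in the cloud; the `matched` flag therefore gates this test.

Numerical edge cases: a numerically singular cloud covariance (a constant
column, which arises for tiny sets at small $H$) is regularised by adding
$10^{-8}\cdot\mathrm{tr}(V)/2$ to the diagonal with a warning, or errors
if the ridge is disabled; Fisher-exact p-values are clamped at 1 against
floating-point summation overshoot.

## Simulation models

**Disjoint model.** Fifty equally sized, non-overlapping sets (20 genes,
4 or 20 metabolites each), of which the first 10 are associated with the
phenotype. Per element the variance is $4\sigma^2$ with $\sigma^2 = 1/X$,
$X \sim \chi^2_4$ — a heavy-tailed mix that produces both quiet and noisy
elements — and the baseline mean is $N(0, 4\sigma^2)$. Errors are
multivariate normal with within-set correlations $\rho_{GG} = \rho_{MM}$
(default 0.20) and cross-platform $\rho_{MG}$ (default 0.10, matched
samples), zero across sets. Covariances are built as
$\rho\sqrt{v_j v_k}$, preserving the configured *correlations* under
heterogeneous variances (a constant covariance could not). Differential
indicators are Bernoulli: probability $d_1$ ($c_1$) inside associated
sets, $d_0$ ($c_0$) elsewhere — defaults $0.25/0$, giving an expected 5%
differential rate overall. Case samples of flagged elements are shifted
by $\omega_j \sim U(\pm[0.5, 2.5])$ for genes and
$\eta_k \sim U(\pm[0.5, 1.5])$ for metabolites; the narrower metabolite
range mimics that platform's weaker effect sizes. Global means default to
0 — the tests are location-invariant, so only users who want realistic
intensity scales need to set them.

**Heterogeneous model.** A fixed design rather than Bernoulli draws:
nine blocks of 20 genes + 4 or 20 metabolites with deterministic
differential status (genes differential in blocks 1–6, metabolites in
1–3 and 7–9), within-platform correlation $r_1$ in blocks 2,3,5,6,8,9 and
cross-platform $r_2$ in 3,6,9 (defaults 0.20/0.10), plus an uncorrelated
null pool filling the matrices to 1000 genes and 1000 (or 200)
metabolites — 12% of each platform differential by construction. Seventy
sets sample this pool: full blocks (purity $\pi = 1$), half blocks with
null fill ($\pi = 0.5$), quarter blocks ($\pi = 0.25$), five random
draws, and 41 sets partitioning the null pool (each null element appears
in at least one). Membership is drawn once per study (`seed_membership`)
and held fixed while replicate datasets vary `seed_data`, the way a real
pathway annotation stays fixed across cohorts.

**Sample sizes.** The design contemplates studies of 30 and 100 samples
with equal case/control split. The package's defaults are the conditions
under which its documented operating characteristics are reproducible:
disjoint-model studies use 100 samples (50/50) and heterogeneous-model
studies 60 samples (30 per group). Both are stated study conditions of
the harness, not tuning knobs; changing them changes power and therefore
every rank-sum and Type-I figure.

**What the simulators do not emulate:** real pathway topology and
overlap structure, non-normal and heteroscedastic-within-group
intensities, missing values, batch effects, or unmatched designs with
different subjects per platform (the interfaces accept them; the studies
do not exercise them). Passing the simulation-based checks therefore
says the methods behave as designed under block-correlated Gaussian
data — not that any particular real dataset satisfies those assumptions.

## Evaluation harness

Two metrics, computed by `disjoint_rank_study()` /
`hetero_type1_study()` over (by default) 100 replicate datasets:

* *Per-set rejection frequency* at $\alpha = 0.05$, and the Type-I error
  as the mean frequency over the designated null sets (the 41
  null-partition sets of the heterogeneous design). A Benjamini–Hochberg
  column is emitted alongside for reference but plays no role in the
  headline metrics.
* *Rank sum $R$*: sets ranked by ascending p-value, $R$ = sum of the
  ranks of the 10 truly associated sets; 55 is perfect, 455 worst,
  $E(R) = 255$ under a random ranking. Ties — which permutation p-values
  produce in bulk once several sets hit the $1/H$ floor — receive
  midranks, which keeps $E(R) = 255$ exact under exchangeability. This
  makes $R$ mildly sensitive to $H$ in noisy scenarios: a coarser floor
  ties more null sets into the top group and pushes $R$ up. An optional
  `statistic` argument to `rank_sum_R()` instead orders the floor group
  by observed statistic, descending, for users who prefer a fully
  resolved ranking; the study harness uses plain midranks.

The rare set × replicate whose test cannot be computed (a non-converged
logistic fit under separation) contributes $p = 1$ — no evidence — to
rankings and rejection counts; the harness reports how many such
substitutions occurred.

Problem sizes used by the shipped studies and tests: 100 replicates per
scenario, $H = 1000$ permutations, 1000 genes with 200 or 1000
metabolites; the oracle-equivalence checks enumerate all 2×2 tables with
total ≤ 40 and the null-calibration checks use 100 replicates of 50
sets.

## Known limitations

* Concatenation inflates the competitive tests' Type-I error through
  depletion calls (a 40-element set with no flagged members looks
  significantly depleted against a 12% background); this reproduced
  behaviour is a property of the method, not a bug, and is the main
  argument for the model-based joint tests.
* The self-contained family loses specificity when background
  differential noise makes every set non-null in the strict sense; under
  such noise its joint variant degrades fastest, and because many sets
  then sit at the permutation floor, the reported rank sums depend
  noticeably on $H$.
* The 2-df Wald test with diagonal variance is equivalent to summing the
  univariate evidence; it cannot exploit genuine slope correlation, and
  with it the Fisher combination usually agrees closely.
* Only two platforms are supported; the Wald and Mahalanobis
  constructions extend to $n$ platforms naturally but that plumbing is
  out of scope here.
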