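---
title: "Methods: signed-P gene set enrichment for caste x age RNA-seq designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed-P gene set enrichment for caste x age RNA-seq designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casteGSEA)
```

This vignette documents the statistical machinery of `casteGSEA`: the model
each stage fits, the parameters that matter and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## The expression model

Counts for gene $g$ in sample $j$ are modelled as negative binomial,
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
$\mathrm{Var} = \mu + \phi\mu^2$, and a log-linear mean

$$\log \mu_{gj} = \log(\tilde L_j) + \beta_0 + \beta_C\,\mathrm{queen}_j +
\beta_A\,\mathrm{month2}_j + \beta_{CA}\,\mathrm{queen}_j\,\mathrm{month2}_j,$$

where $\tilde L_j$ is the *effective* library size (column sum times the
TMM factor). Caste and age are categorical fixed effects with day-1 worker
as the reference level. The model assumes counts are independent across
genes and samples given the design — there is no sample-level random
effect, which is adequate for pooled-individual replicates but would
understate uncertainty if replicates shared colonies.

**Aggregation.** Transcript (isoform) counts are summed within isogroups
before modelling; per-sample totals are conserved exactly, so aggregation
never changes library sizes.

**TMM normalisation** (`tmm_factors`). The reference sample is the one
whose upper-quartile count fraction is closest to the mean such fraction.
For each sample, per-gene log2 ratios of library-size-scaled proportions
against the reference (M-values) are trimmed — 30% of M-values and 5% of
A-values on each side, genes with a zero in either sample excluded — and
averaged with inverse delta-method binomial variances as weights; factors
are rescaled to geometric mean exactly 1. The trim fractions are the
established defaults for this estimator; they tolerate an asymmetric
differentially expressed minority of up to roughly the trim fraction, which
is why calibration simulations here keep one-sided DE fractions at a few
percent (an *all*-DE matrix is unidentifiable: a fold change shared by
every gene is indistinguishable from a library-size difference).

**Dispersion** (`estimate_dispersion`). Three steps:

1. per-gene method-of-moments estimates from pooled within-treatment-cell
   variances of normalised counts;
2. a *trend*: binned medians (20 abundance bins) of those estimates,
   linearly interpolated against log mean abundance;
3. a *tagwise* estimate: a per-gene Cox–Reid adjusted profile likelihood
   ($\ell(\phi) - \tfrac12 \log\det X^\top W X$, evaluated at closed-form
   group-mean fits on a 45-point log-spaced grid from $10^{-8}$ to
   $10^{0.7}$) shrunk toward the trend on the log scale with weights equal
   to the residual degrees of freedom and `prior_df` (default 10).

The Cox–Reid adjustment matters: the unadjusted profile MLE is biased low
(it ignores the degrees of freedom spent on the mean), and plugging a
low-biased $\phi$ into the likelihood-ratio test visibly inflates small
P-values under the null. `prior_df = 10` is a conventional amount of
shrinkage for designs with 16–20 residual degrees of freedom;
`prior_df = Inf` gives purely trended dispersion.

**GLM fitting and testing** (`fit_glm`). Each gene is fitted by iteratively
reweighted least squares with weights $\mu/(1+\phi\mu)$, vectorised across
genes (the weighted cross-products for all genes are formed with two matrix
multiplications per iteration; the per-gene $p \times p$ systems are solved
in closed form for $p \le 2$). Numerical choices: linear predictors clamped
to $[-30, 30]$; initial values from an unweighted least-squares fit to
$\log(\max(y, 0.5))$; at most 50 iterations; convergence when the relative
log-likelihood change is below $10^{-8}$; genes that fail to converge are
flagged and assigned $P = 1$ with a warning rather than dropped silently.
Contrast P-values are likelihood-ratio tests of the dropped term against
$\chi^2_1$. Genes with zero counts in every sample must be removed before
normalisation (their M-values are undefined).

**Per-stratum versus joint contrasts.** The caste effect *within* an age
(and the age effect within a caste) is fitted by default on the
corresponding sample subset, with the interaction tested in the joint
model. A joint-fit option exists (`joint = TRUE`) for the contrasts that
are single coefficients of the joint parameterisation. Per-stratum fitting
was chosen as the default because the scientific report is a per-age table
of caste tests, and a stratum fit makes no homogeneity-of-dispersion-use
assumption across the other factor's levels.

**Sign convention.** Every contrast record carries
$c = -1$ for queen-biased (or up-with-age) genes and $c = +1$ otherwise.
This makes the signed score $s = c(1-P)$ place queen-biased genes with
strong support near $-1$, i.e. at the *low* end of the ranked list.

## The gene set enrichment test

Given the ranked list (ascending $s$, ties broken deterministically by
gene identifier; a seeded random tie-break is available), the running sum
gains $+1$ at each of the $n$ set members and loses $n/(N-n)$ at each of
the other $N-n$ genes, so it returns to 0 after the last gene — exactly,
because the implementation accumulates the sums multiplied by $N-n$, which
are integers. The enrichment score is $\mathrm{ES} = \max |{\rm sum}|$ with
the first attaining position recorded; the direction is read off the sign
of the running sum at that position (positive = members cluster toward the
low/queen end). ES is bounded by $n$ and invariant under any relabelling
that preserves ranks and membership.

The null distribution is built by drawing $B$ random $n$-gene subsets of
the ranked list without replacement (default $B = 5000$) and recording each
ES — resampling over gene labels with the observed ranking held fixed, not
sample permutation. Random sets are scored with a closed-form ES from the
sorted member positions (between member positions the running sum falls
linearly, so extremes occur only at a member position or one before),
evaluated in the same integer-scaled space, which makes each null draw
$O(n)$ instead of $O(N)$ and exactly equal to the full-trace computation.
Sampling is over the whole list, with no exclusion of the observed set's
members — with a 20-gene set in a multi-thousand-gene transcriptome the
difference is negligible, and sampling from all $N$ is the simpler rule.

The empirical P-value is $(k+1)/(B+1)$ with $k$ the number of null scores
at least as large as the observed ES. The add-one convention never returns
0 and is a valid test at every $B$; when $k = 0$ the result is the
resolution floor $1/(B+1)$ and the print method renders it as
`P < 1/B`, the conventional way resampling floors are reported.

## GO-term enrichment

Annotations are first closed over the ontology: a gene annotated to a term
is annotated to all its ancestors along `is_a`/`part_of` edges (memoised
depth-first traversal; a cycle raises an error; the closure is idempotent
and can be disabled). Terms with fewer than `min_size = 5` members among
ranked genes are skipped — a Kolmogorov–Smirnov test on fewer than 5 ranks
is uninformative; the floor is configurable and deliberately conservative
since no floor is inherent to the method.

Each term is tested with the two-tailed two-sample KS statistic
$D = \sup_x |F_{\rm members}(x) - F_{\rm others}(x)|$ over the pooled
ranking. A two-tailed statistic is the right one here because the ranked
list is signed: a term can be displaced toward either extreme, and a
one-sided test would see only one. P-values are exact for member count
$\le 8$ and $N \le 30$ — computed by counting monotone lattice paths that
stay inside the band $|i/n_1 - j/n_2| < D$, which is arithmetic identical
to enumerating every possible member placement — and otherwise asymptotic,
using the Kolmogorov distribution at the two-sample effective size with the
Stephens small-sample argument correction
$(\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$. The correction was adopted
because the plain asymptotic argument is visibly inaccurate at GO-term
sizes (tens of members), while the corrected form tracks the exact
enumeration to within a few percent there.

Because the KS test is unsigned, the reported direction of a term is a
separate annotation: the sign of the mean signed score of its members
(negative = queen / up-with-age extreme). This is a documented choice — the
test itself carries no direction.

**Local false discovery rate** (`estimate_lfdr`). The P-value ensemble
across terms is modelled as the two-group mixture
$f(p) = \eta_0 + (1-\eta_0) f_1(p)$. $\eta_0$ is the Storey estimator at
$\lambda = 0.5$ (fraction of P-values above $\lambda$ divided by
$1-\lambda$, capped at 1) — $\lambda = 0.5$ is the standard
bias/variance compromise and the estimator is insensitive to it for the
ensembles sizes used here. The marginal density $f$ is the Grenander
estimator: the slope of the least concave majorant of the empirical CDF,
computed by weighted pool-adjacent-violators on the raw ECDF slopes. Then
$\mathrm{lfdr}(p) = \min(1, \eta_0/\hat f(p))$, clamped to $[0,1]$ and made
non-decreasing in $p$ by a final isotonic pass. At least 20 P-values are
required — below that the mixture fit is meaningless. A term is called
enriched when $\mathrm{lfdr} \le 0.05$ (inclusive), the posterior
probability of the null given the observed P-value being at most 5%.
Whether lfdr should be estimated jointly across ontology namespaces is not
determined by the method; the default here is jointly, which borrows
strength across more terms.

## The synthetic-data generator

`generate_design` reproduces the study layout: a full caste × age
factorial per tissue with 6 leg and 5 brain replicates per treatment.
`generate_truth` draws per-gene baselines log-normal
(meanlog $= \log 100$, sdlog $= 1.3$ — a realistic span of bulk RNA-seq
abundances) and dispersions gamma (shape 2, mean 0.1 — typical tagwise
magnitudes for insect bulk libraries); no reference library sizes or
dispersion estimates are available to calibrate against, so these defaults
are conventional rather than calibrated. The focal set receives its caste bias through the
interaction term only, so "no day-1 difference, queen-biased at 2 months"
is a single knob (`lfc_interaction`, log2 scale, positive = queen-up).
`simulate_counts` draws
$y \sim \mathrm{NB}(L_j\,b_g 2^{x_j^\top \beta_g}/10^6, \phi_g)$, with
$\phi = 0$ degenerating to Poisson, and library sizes log-uniform on
$[0.5, 2] \times 10^6$ by default — wide enough that skipping
normalisation visibly breaks calibration, which is what a test fixture
should enforce.

Every generator runs on its own RNG stream derived from the master seed
plus a fixed per-operation offset, and restores the caller's RNG state;
adding a new generator therefore never changes the draws of existing ones,
and identical seeds give bit-identical outputs.

What the generator does *not* emulate: read-level error, positional and GC
bias, isoform-switching within isogroups, correlated expression between
genes, batch or lane effects, and colony structure among replicates.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the stated model, not that the model captures every
feature of real libraries — in particular, inter-gene correlation would
widen the GSEA null beyond what label resampling sees, a caveat shared by
all label-resampling enrichment tests.

## Problem sizes used by the test-suite simulations

Calibration and power checks in the package's tests run at: 2000 genes for
P-value-uniformity and fold-change-recovery simulations (50 DE genes at
log2FC 1 among 1950 nulls); 500 random sets of size 20 at $B = 500$ for
GSEA type-I error; 50 seeded end-to-end runs for the age-dependent power
pattern (interaction log2FC 0.5, $\phi = 0.1$, 6 replicates); exhaustive
enumeration at $N = 10, n = 3$ (all 120 subsets) for the resampling-null
mean and $N = 20, n = 5$ (all 15504 subsets) for the KS oracle. These
sizes give the property checks enough resolution (binomial standard errors
of a few tenths of a percent on tail fractions) while keeping the suite
fast enough to run routinely.

## Known limitations

- The NB GLM uses plain likelihood-ratio tests; no quasi-likelihood
  F-tests or exact small-sample tests, so P-values at very low counts rely
  on the $\chi^2_1$ approximation.
- The dispersion trend is a binned-median interpolation, not a smooth
  curve fit; it is deliberately simple and is only a shrinkage target.
- GSEA increments are unweighted ($+1$), exactly as defined here; there is
  no correlation-weighted variant, no FDR across many sets (the design
  tests one focal set per tissue/age), and no leading-edge extraction.
- The GO machinery implements only `is_a`/`part_of` closure and a
  KS/lfdr pipeline; there are no elim/weight-style decorrelation
  algorithms and no Fisher's-exact mode.
- Similarity-search handling starts from tabular hit files; running the
  searches themselves, ORF prediction, and HSP-level filtering beyond the
  e-value cutoff are out of scope.
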