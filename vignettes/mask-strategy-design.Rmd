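---
title: "Designing variant masking strategies for burden tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing variant masking strategies for burden tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gene-level burden test collapses a gene's qualifying variants into a
per-sample dosage sum and regresses a quantitative trait on it. The set of
qualifying variants is defined by a *mask*: a boolean predicate over
functional annotations (consequence terms, LOFTEE loss-of-function
confidence, pathogenicity predictor calls and score thresholds) and
allele-frequency tokens. Because the causal architecture of a gene is
unknown, analysts test several masks — a *masking strategy* — and must pay
a Bonferroni price for it: with mask-level threshold
$\alpha_0 = 2.5\times10^{-6}$, a strategy of $m$ masks declares an
association significant at $p < \alpha_0/m$. A (gene, trait) pair detected
by several member masks counts once.

This package treats the choice of strategy as an optimization problem:
maximize the number of Bonferroni-corrected significant associations. The
interacting pieces are (i) a mask definition language with harmonization
rules, (ii) composite pathogenicity scores that summarize a redundant
predictor ensemble, (iii) a calibrated burden-testing engine, (iv)
redundancy-aware mask clustering, and (v) a greedy maximum-coverage
optimizer.

## The mask language

Masks are infix boolean expressions (`&` binds tighter than `|`) over a
fixed atom vocabulary; see `?parse_mask`. MAF tokens read `mafX` = MAF
$< X\%$ (`maf1` → < 1%, `maf0_1` → < 0.1%, `maf0_01` → < 0.01%), `maf_gt_X`
= MAF $> X\%$. Score atoms use $\geq$ on the native scale —
`REVEL_score_0_55` reads "REVEL at least 0.55". `normalize_mask()` applies
the harmonization rewrites used when reconciling definitions from
heterogeneous sources:

* `maf ≤ t` → `maf < t`;
* `nonsynonymous` → `missense`;
* bare `splice` → `splice_donor | splice_acceptor` (`splice_region` stays a
  distinct atom and is never treated as essential splice);
* unversioned `polyphen2` → both HDIV and HVAR variants;
* reference-panel MAF atoms (`gnomad_maf1`, ...) → cohort MAF atoms.

Canonical form is the flattened n-ary AND/OR with duplicate children removed
and children sorted lexicographically. It is cheap, deterministic, and
idempotent; canonical equality implies logical equivalence, which the test
suite verifies by exhaustive truth-table enumeration. No full boolean
minimization is attempted — equivalences beyond syntactic normalization are
intentionally out of scope for deduplication, mirroring how harmonized
definitions are compared in practice.

Two evaluation decisions matter. First, **missing predictor values never
satisfy an atom**: a variant unscored by REVEL cannot pass
`REVEL_score_0_55`. This is the conservative filter semantics of
annotation-based masking; callers who prefer imputation can attach imputed
scores first. Second, categorization resolves mixed compositions by a fixed
precedence (coding atoms dominate; then pLoF+missense, pLoF+damaging
missense, pLoF, damaging-missense-only, missense/indels). Compositions the
precedence list does not name — pLoF plus indel atoms without missense —
fall to `pLoFmis`, and low-confidence LoF counts as a missense/indel-class
atom, matching how published mask sets group low-confidence pLoF with
missense and indels.

## Composite scores

Pathogenicity predictors are summarized as rank scores in $(0,1]$ (average
ranks for ties, divided by the number scored — the dbNSFP convention). The
`og` composite calls a variant damaging by an algorithm when its rank score
exceeds 0.67 and scores the variant by the fraction of algorithms calling
damaging; 0.67 is chosen so that roughly a third of variants are called
damaging, the rate categorical predictors typically produce. The `pc` and
`ic` composites replace algorithms by principal or independent components
of the rank-score matrix: each component's per-variant scores are re-ranked,
oriented, thresholded at 0.67, and combined as a weighted vote.

Weights are explained-variance ratios for PCA. Independent components have
no variance decomposition, so the `ic` weights are normalized L2 norms of
the mixing-matrix columns — the closest analogue, stated explicitly because
the choice is genuinely open. All components are retained in the vote; no
cutoff is imposed. The ICA fit is a symmetric fixed-point iteration with
the logcosh contrast on whitened data, written in-package, with its seed a
configuration field. One caveat documented here and reflected in the tests:
on data generated by a *single Gaussian* latent factor, independent
components are mathematically unidentifiable, so factor-recovery guarantees
are asserted for the PCA composite only.

**Orientation.** Damaging scores should be higher for rarer variants. Each
component's rank scores are tested for Pearson correlation with MAF; a
significantly positive correlation ($P < 0.01$) flips the component
($r \mapsto 1 - r + 1/N$). Post-orientation, no component correlates
significantly positively with MAF — a property the acceptance suite checks
on every fit.

Missing rank scores are imputed by round-robin conditional regression:
initialize at column means, repeatedly regress each incomplete column on
all others over its observed rows, replace missing entries with
predictions clipped to $(0,1]$, and stop when the largest change falls
below `tol` (default $10^{-4}$) or after `max_iter` sweeps (default 10).
On fixtures with known structure this beats mean imputation and recovers
collinear columns exactly.

## The burden engine

For each (mask, gene, aaf-bin) the burden is the dosage sum over mask
variants with MAF below the bin (bins 0.5, 0.01, 0.001, strict `<`;
missing dosages contribute 0 — documented so callers can pre-impute).
Tests with cumulative minor-allele count ≤ 10 are removed. The test is
ordinary least squares of the inverse-normalized trait on
[intercept, burden, covariates] with a two-sided t-test on the burden
coefficient; traits are rank-inverse-normal transformed with the Blom
offset ($k = 3/8$). Plain covariate-adjusted OLS stands in for a two-step
whole-genome ridge procedure deliberately: desk-scale synthetic cohorts
have no relatedness or polygenic background, and the statistic's contract
(beta, SE, p) is unchanged. `run_mask_scan()` evaluates the same model by
Frisch–Waugh residualization — traits and burdens are residualized on the
covariates once and the t-test formed from residual cross-products — which
is algebraically identical to the per-test fit (the suite checks agreement
to $10^{-10}$) and vectorizes over traits.

Calibration computes the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_1(1-p)) / 0.455$ per (mask, trait, bin).
Masks matching no variants are dropped, as are masks whose mean λ across
traits exceeds 1.2; the widest bin drives the exclusion decision (λ is
reported for every bin, but which bins enter the published filter is not
specified, so the widest — the one containing every test — decides).
A caution that shaped the synthetic design: λ is a *median over genes*, so
with few genes it is noisy (sd ≈ 0.2 at 150 genes per trait) and with a
high causal fraction it is shifted upward by true signal. The λ > 1.2
filter behaves as intended only in null-dominated, many-gene, many-trait
scans — which is what the default generator produces.

Conditional analysis follows the standard recipe: greedy LD clumping of
common-variant results ($p_1 = 10^{-4}$, $r^2 \geq 0.5$, 250 kb window;
defaults collected in `pipeline_config()`), then the burden test rerun with
index-variant dosages appended to the covariates; index columns collinear
with the intercept/covariates (or each other) are dropped with a message.

## Mask clustering and representatives

Round 1 represents each mask by its binary variant-membership vector,
reduces to the fewest principal components explaining ≥ 90% of variance
(deterministic sign convention: the largest-magnitude loading is positive),
and k-means-clusters the scores. k is chosen by an elbow rule: the smallest
k whose cost decrease to k+1, as a fraction of the total cost, falls below
5% ("the cost function reduces minimally beyond this k"). The drop is
measured against the *total* cost rather than the previous k's cost; the
within-cluster sum of squares falls by a roughly constant relative factor
at every k, so a previous-cost denominator never triggers. Round 2 repeats
the construction within each cluster using MAF features — the variant's MAF
where the mask includes it, 0 otherwise, the minimal encoding consistent
with round 1 — splitting clusters into subclusters; singletons are not
split. Silhouette scores are reported per round, round 2 as the mean over
subclustered clusters. k-means uses 10 random restarts under a fixed seed;
both rounds are deterministic given the configuration.

One representative per (sub)cluster — the mask with the most significant
associations in the frequency class of interest, ties to the smallest mask
id — forms a reduced strategy.

## The greedy covering optimizer

For a fixed size $m$, every mask's significant-association set is computed
at threshold $\alpha_0/m$ (sets are threshold-monotone: growing $m$ never
adds an association). Greedy then repeatedly picks the mask adding the most
uncovered associations, ties broken lexicographically. If gains hit zero
before $m$ picks, the remaining slots are filled by unused masks in id
order at zero gain: the strategy then has exactly $m$ members and the
$\alpha_0/m$ threshold it is scored at remains honest. Strategies are
compared across all $m$; ties prefer smaller $m$ (fewer tests). Selection
re-sorts eagerly after every pick, exactly as the procedure is stated.

Greedy maximum coverage is a $(1-1/e)$-approximation of the NP-hard exact
problem; the acceptance suite verifies the bound (and frequent exact
optimality) against exhaustive subset enumeration on instances with up to
12 masks. Leave-one-trait-out validation optimizes on all but one trait and
reports the held-out trait's covered fraction relative to its own optimum
(undefined when that optimum is 0).

## The synthetic-data generator

The generator produces the statistical structure the analysis assumes,
with recorded truth:

* **MAF spectrum** — 90% of variants from Beta(0.2, 50) truncated below at
  $1/(2n)$, 10% common (uniform on [0.05, 0.5]): a rare-skewed exome-like
  spectrum in which a typical gene carries enough sub-0.1%-MAF variants for
  the rare aaf-bin to clear the cMAC > 10 gate at the default cohort size.
* **Latent pathogenicity** — Bernoulli with a logit decreasing in
  $\log_{10}$ MAF (slope 0.7/decade), centered so the mean damaging rate is
  0.3; rarer variants are more likely damaging, which is also what makes
  predictor rank scores correlate negatively with MAF.
* **Predictors** — a single latent factor ($1.5 \times$ damaging + noise)
  observed by each algorithm with independent N(0, 0.8²) noise, then
  rank-transformed; 5% missingness; categorical calls at rank > 0.67. The
  single-factor link reproduces the high inter-algorithm correlation the
  composite-score module assumes. An `ORACLE_score` column equal to the
  damaging indicator supports planted-oracle recovery experiments.
* **Genotypes** — Binomial(2, MAF) per sample (Hardy–Weinberg, no LD);
  realized MAF/MAC are folded onto the minor allele and written back.
* **Phenotypes** — planted effects $\beta_g = \pm 2.5$ on a 2% causal gene
  fraction, acting on the sum of dosages over the gene's truly damaging
  variants **below MAF 1%**; plus small covariate effects (sex, array,
  5 PCs) and unit noise; then rank-inverse-normalized. Restricting planted
  effects to the rare allelic series is deliberate: per-allele effects on
  common damaging variants would dominate trait variance, shrink every
  rare-bin signal after inverse-normalization, and model a common-variant
  architecture that single-variant methods, not burden tests, target.
* **Default sizes** — 2,500 samples, 300 genes of ~50 variants, 6 traits.
  These were fixed by design calculation, not tuning: a causal gene's
  rare damaging burden reaches cMAC ≈ 14 (power ≈ 1 at
  $\alpha_0 = 2.5\times10^{-6}$ for $\beta = 2.5$), and 300 genes × 6
  traits keep the λ filter's false-exclusion rate below ~2% per mask.

The generator does **not** emulate linkage disequilibrium (beyond fixtures
constructed for the clumping tests), relatedness, population structure, or
annotation errors. Passing recovery tests therefore show the pipeline's
logic is correct under its own assumptions — not that a particular mask
ranking would transfer to real cohorts.

## Numerical choices and edge cases

* Ties in rank transforms use average ranks; ties in greedy selection,
  representative selection, and "best strategy" use lexicographic ids —
  every stochastic or order-dependent step is deterministic under a seed.
* Constant burdens (after covariate projection), constant feature matrices,
  empty coverage instances, all-missing predictor columns and
  out-of-vocabulary atoms raise errors or produce empty results rather than
  silently degenerate numbers.
* `k`-means with k equal to the number of distinct points assigns each its
  own cluster (the stock implementation rejects that case).
* Problem sizes in the test and acceptance runs (cohorts of 600–3,000
  samples, 25–300 genes, 200 random coverage instances, 10,000 null tests,
  500 planted genes, 20 recovery replicates) were chosen as the smallest
  designs whose statistical properties — binomial error bands, λ noise,
  power — make the assertions meaningful.

## Limitations

Counts of significant associations on synthetic cohorts are small and not
comparable to biobank-scale results; the package reproduces the *method*,
not any published count. The λ filter needs many genes and traits to be
reliable, as quantified above. The greedy optimizer is an approximation by
construction, and the strategy it selects is tuned to the traits it saw —
the leave-one-trait-out machinery exists precisely to measure that
transfer gap.
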