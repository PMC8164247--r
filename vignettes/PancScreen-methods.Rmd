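---
title: "PancScreen: models and methods"
author: "PancScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PancScreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(PancScreen))
```

# Scope

PancScreen analyses pooled genome-wide CRISPR knock-out and activation
drug-resistance screens from the point where sgRNA count tables exist
(e.g. MAGeCK count output), through gene-level resistance scoring,
pathway enrichment, an expression-weighted drug-sensitivity predictor,
and integration with patient survival. Read-level processing (trimming,
alignment, counting) is out of scope. Every stage can be exercised on
synthetic screens with planted ground truth, which is how the test
suite and the acceptance script validate the pipeline.

# The gene resistance statistic: the L2FC sum

The screen compares drug-treated to untreated cells after ~14 days of
selection. For guide $g$, replicate $r$ and drug $d$, the per-replicate
statistic is the log2 fold change of normalized abundance,

$$\mathrm{L2FC}_{g,d,r} = \log_2 \frac{\mathrm{CPM}^{treated}_{g,d,r}}
{\mathrm{CPM}^{control}_{g,r}},$$

where CPM is counts per million with a pseudocount (default 0.5) added
to every raw count. Because CPM is a per-sample rescaling, the global
kill imposed by the drug (dosing targets ~80% cell death) cancels, and
only *selective* enrichment or depletion survives.

The guide-level summary is the **replicate minimum**
$\min_r \mathrm{L2FC}_{g,d,r}$: a guide only scores highly if it is
enriched in *every* replicate, which suppresses single-replicate
artefacts (jackpot clones, sampling noise). The gene-level statistic,
the **L2FC sum**, ranks the surviving guides of each gene by their
replicate minimum and sums the top two:

$$S_{gene,d} = v_{(1)} + v_{(2)}, \qquad
v_{(k)} = k\text{-th largest replicate-minimum among the gene's guides}.$$

Requiring two independent guides guards against off-target single-guide
effects. Positive $S$ means resistance (enrichment under drug);
sensitivity hits occupy the negative tail of the same table. Genes with
fewer than two surviving guides are reported as `NA` rather than scored
with one guide, since a "top two" is undefined for them. Ties in the
guide ranking are broken lexicographically by guide id so results are
reproducible to the byte.

Multi-drug resistance is summarized by the mean of $S_{gene,d}$ over
the drug panel within each cell line, and across cell lines by both the
mean (hit prioritization) and the minimum (the conservative weight used
by the sensitivity predictor — a gene must score in both cell lines to
carry weight).

A consequence of the replicate-minimum worth knowing when interpreting
effect sizes: the statistic is deliberately conservative. For a planted
enrichment of $e$ log2 units in two guides, the expected L2FC sum is
$2e$ only in the low-noise limit; with realistic count noise the
minimum over replicates sits below the per-replicate mean, so observed
sums fall somewhat short of $2e$ while null genes stay near 0. The
simulator tests verify both regimes.

## Guide quality filter

Guides with fewer than 10 raw counts in the untreated control *and*
fewer than 50 in the treated sample of a comparison are excluded from
that comparison. The AND combination is the default because the
filter's purpose is to remove guides unmeasurable in both arms; a guide
at 9 control counts that jumps to 1000 under drug is real signal and is
kept. An OR variant is available (`logic = "or"`). At the default
simulated depths the filter removes well under 2% of guides; every
filtering call logs counts removed and retained. When a guide fails the
filter in only some replicates, the replicate minimum is taken over the
surviving comparisons.

## Replicate QC

`qcReplicateCorrelation()` computes guide-level L2FC Spearman
correlations for replicate pairs (same drug), non-replicate pairs
(different drugs) and a scrambled-guide null. In a healthy screen
replicate pairs correlate best, non-replicate pairs retain the
correlation induced by shared resistance mechanisms, and the scrambled
null centers at zero. A replicate whose mean replicate correlation
falls below the 75th percentile of the non-replicate distribution is
flagged — but never dropped automatically; exclusion is an explicit
analyst decision passed via `dropSamples` (mirroring the common
practice of discarding a poorly correlated replicate after inspection).
The 75th-percentile threshold is a package choice: it flags a replicate
that looks no better than cross-drug pairs while tolerating ordinary
noise.

# Pathway enrichment

For each gene the rank-1, rank-2 and rank-3 guide values (the
replicate-minimum L2FC of its top three guides — the same quantity used
for gene scoring) feed a two-sample Wilcoxon rank-sum test of member
genes against all other scored genes. Gene sets with fewer than 10
targeted genes are excluded. The three $-\log_{10} p$ values are summed
into a consolidated score, and when knock-out and activation screens
are both available their consolidated scores add
(`combinePathwayScreens()`).

Choices made here:

* **Sidedness.** The default is one-sided "members greater"
  (resistance); a mirrored run captures sensitivity, and two-sided is
  available. Resistance framing is the primary readout of this kind of
  screen.
* **Exact vs approximate.** The exact Mann–Whitney distribution is used
  when $m + n \le 50$ with no ties; otherwise the tie-corrected normal
  approximation without continuity correction. Tests check the exact
  branch against full enumeration and the approximate branch against an
  independent implementation of the tie-corrected formula.
* **Multiplicity.** Consolidated scores are sums of raw $-\log_{10} p$;
  a Benjamini–Hochberg column is emitted additionally for
  interpretation, but plays no role in the score.
* **Background.** All scored genes outside the set. Non-targeting
  controls never reach gene scoring, so they are absent from both
  sides.
* **Input values.** Either per-drug rank values or multi-drug means;
  the multi-drug mean is the default when studying multi-drug
  resistance.

Survival context is attached per pathway by aggregating member genes'
Cox p-values with Fisher's method ($-2\sum\ln p \sim \chi^2_{2m}$ under
the null), reported with the median member p alongside. This is a
reporting join, not a joint model: member p-values are treated as
independent, which they are not in correlated expression data — the
median column is the robust companion readout.

# The PancDS sensitivity score

Given a treatment-naive expression matrix, the predictor computes per
sample $s$ and drug

$$R_s = \sum_g w_g \, z_{gs},$$

where $z_{gs}$ is the gene's expression z-score across the cohort and
$w_g$ is the screen-derived weight: the minimum L2FC sum across the two
cell lines for that drug. Predicted sensitivity is $-R_s$. High
expression of genes whose activation conferred resistance pushes $R_s$
up and predicted sensitivity down.

* **Normalization.** Raw counts pass through a shifted-log CPM
  transform, $\log_2(\mathrm{CPM} + 1)$ with pseudocount 0.5, as a
  variance-damping stand-in for a dispersion-based VST. Because the
  downstream z-scoring standardizes every gene, the score is
  insensitive to the exact monotone transform; externally normalized
  matrices can be supplied directly by constructing an
  `ExpressionMatrix` with state `"normalized"`. This is a deliberate
  divergence from dispersion-based VSTs, which would require fitting a
  mean-dispersion trend that adds machinery without changing the
  rank-based downstream behavior.
* **z-scores** use the sample (n−1) standard deviation; constant genes
  are set to 0 with a warning.
* **Weights** are used raw — no rescaling is applied to the minimum
  L2FC sum — and all genes with finite weights participate by default;
  a `topK` restriction is available. Gene matching is by exact
  case-sensitive symbol; the size of the weight/expression intersection
  is logged because symbol harmonization across sources is the user's
  responsibility.
* **Grouping.** Median split on predicted sensitivity by default (ties
  to "low", for determinism), tertiles
  (resistant/intermediate/sensitive) or fixed thresholds.

Dose-response support is limited to the normalized trapezoidal AUC over
log10 dose (viability relative to vehicle; AUC 1 = flat, 0 = complete
kill) for comparing measured sensitivities with predictions — no 4PL
curve fitting.

# Survival integration

`coxPerGene()` fits a univariate Cox proportional-hazards model of
overall survival on each gene's normalized expression and reports the
log hazard ratio, its Wald p-value and a reason column for genes that
cannot be scored (zero variance, non-convergence, apparent separation
at $|\beta| > 15$). Ties are handled with the Breslow approximation
(Efron is available through `ties =`); at realistic tie rates the
difference is negligible, and Breslow keeps the classical identity that
the Cox score test at $\beta = 0$ on two groups equals the log-rank
statistic — an identity the test suite checks to $10^{-6}$.
`logrankTest()` performs the stratified comparison of predicted
high/low sensitivity groups with the standard log-rank chi-square
(df = groups − 1). The "chi-squared" patient-stratification test is
implemented as this log-rank test, the standard reading for a survival
split.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is validated.

* **Design.** 2 cell lines × 4 drugs × 3 replicates, activation-type by
  default; 500 genes × 6 guides plus 100 non-targeting controls at toy
  scale, 5×10⁵ expected reads per sample. The guide count per gene and
  the screen layout mirror a genome-wide activation library design
  scaled down ~50-fold so that hundreds of simulated screens run in
  minutes on one CPU.
* **Counts.** Guide abundances are log-normal (sdlog 0.8, reproducing
  realistic representation skew so the 10/50 filter is actually
  exercised, at under 1–2% exclusions); counts are negative binomial
  with $\mathrm{Var} = \mu + \alpha\mu^2$, $\alpha = 0.05$. Treated
  means carry a global kill factor 0.2 (~80% cell death), which CPM
  removes, isolating selective effects.
* **Planted truth.** By default 10 resistance genes (the first 10 gene
  ids — a deterministic, documented choice) receive a +3 log2
  enrichment in 2 of their 6 guides in every drug and cell line; an
  optional planted pathway shifts member genes' guides. The truth
  object records every planted (gene, guide, effect).
* **Expression cohorts.** Each sample has a latent resistance phenotype
  $r \sim N(0,1)$; weighted genes' log2 expression moves with
  $c \cdot r \cdot \mathrm{sign}(w_g)$ (default coupling $c = 1$, noise
  sd 1) around log-normal baselines.
* **Survival.** Event times are exponential with hazard
  $\lambda_0 e^{\beta r}$ ($\lambda_0 = 1/365$ per day,
  $\beta = 1$ by default); censoring is independent uniform on
  $(0, \tau)$ with $\tau$ solved numerically for the requested expected
  censoring fraction (default 0.3). A 185-sample cohort is the default
  scale for survival checks.
* **Determinism.** The same seed and configuration reproduce outputs
  byte-identically.

What the generator does *not* emulate — and therefore what passing
tests cannot certify about real data: guide-efficiency heterogeneity,
MOI and clonal drift over passages, copy-number artefacts, batch
effects between replicates, correlated expression modules, and
drug-specific (rather than shared) resistance programs unless planted
explicitly. Recovery rates measured here are upper bounds for screens
whose noise violates these simplifications.

# Numerical choices and degenerate inputs

* Pseudocount 0.5 before CPM (configurable); an all-zero sample column
  with pseudocount 0 is an error.
* Guide-rank ties break by guide id; score ties in hit tables break by
  gene symbol; competition ranking ("1224") by default, dense
  available.
* Genes with < 2 surviving guides: `NA` with `n_guides` reported.
* Wilcoxon p-values of excluded sets are `NA` with a reason string, and
  a consolidated score is never computed from them.
* Cox: 50 Newton iterations (survival's default machinery),
  zero-variance and separated genes flagged, not estimated.
* Readers reject malformed input with messages naming file, line and
  field; writers emit the canonical tab-separated dialect so that
  write–read round-trips are identities.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` validate: exact agreement of
the scoring chain with an independent straight-line re-implementation
on 100 random instances; the 10/50 filter truth table and sub-2%
exclusion at default depth; recovery of ≥ 9/10 planted resistance genes
in the top 15 across 100 seeded screens; Wilcoxon type-I error at
α = 0.05 over 1000 independent null sets and planted-pathway recovery
over 100 seeds; Spearman ≥ 0.8 between sensitivity score and latent
phenotype over 100 cohorts of 50; Cox $\hat\beta$ within ±0.25 of 1 at
n = 185 over 100 seeds plus uniform null p-values over 500 simulations;
and the full screen→weights→cohort→median-split→log-rank chain at
n = 185, β = 1 over 100 seeds. These sizes were chosen so the whole
battery completes in a few minutes on a single CPU while keeping
Monte-Carlo error well below the decision margins.

# A compact end-to-end run

```{r example, message = FALSE}
cfg <- simConfig(seed = 11, nGenes = 120, nNontargeting = 30)
sim <- simulateScreen(cfg)
res <- scoreScreen(sim$se, verbose = FALSE)
head(rankHits(res$cross_cell_line, "mean_across_lines", topK = 5))

w <- pancdsWeights(res$gene_scores, drug = "gemcitabine")
truth_w <- setNames(rep(1, 10), sim$truth$planted_genes$gene)
cohort <- simulateExpression(simGeneIds(cfg), truth_w, nSamples = 100,
                             seed = 11)
z <- zscoreGenes(vstNormalize(cohort$expr))
sc <- sensitivityScore(z, w, verbose = FALSE)
grp <- classifyScores(sc, "median")
surv <- simulateSurvival(cohort$phenotype, beta = 1, censoringRate = 0.3,
                         seed = 12)
logrankTest(setNames(grp$group, grp$sample_id), surv)[c("chisq", "p")]
```

# Known limitations

* The L2FC sum has no attached significance model; ranking is the
  readout, as in the screening design it implements. Users needing
  p-values per gene should pair the ranking with a dedicated screen
  statistic.
* The VST stand-in is not a dispersion-based transform; raw-count
  cohorts with extreme library-size ranges should be normalized
  externally and supplied with state `"normalized"`.
* Pathway survival aggregation assumes independent member p-values.
* Only univariate Cox models are provided; no adjustment for clinical
  covariates.
* Gene symbols are matched exactly and case-sensitively; no identifier
  mapping is performed.
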