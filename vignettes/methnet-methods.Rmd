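---
title: "Methods: models, parameters and design choices in methnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in methnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methnet)
```

methnet implements a network-oriented analysis of two-group CpG methylation
data of the kind produced by reduced-representation bisulfite sequencing
(RRBS) in small clinical cohorts, together with a synthetic-data generator
that emulates every input the analysis needs. This vignette is the package's
account of the underlying models, the parameters that matter, and the design
decisions taken where the methodology was genuinely open.

## 1. The differential methylation model

Per sample $s$ and CpG site $i$ we observe methylated reads $m_{is}$ out of
$t_{is}$ total reads. Within a group the counts are modelled as binomial
with a site-specific proportion; the group effect at a site is tested by a
likelihood-ratio test (LRT) comparing the binomial regression of
$(m_{is}, t_{is})$ on the group indicator against the intercept-only model,
referred to $\chi^2_1$. Because the only covariate is binary, the
alternative MLE is the coverage-pooled proportion within each group and the
null MLE the overall pooled proportion, so the deviance difference has a
closed form; the test suite checks this closed form against an independent
`glm()` fit to six decimals.

The effect size is reported as
$\Delta M = 100\,(\hat p_{\text{case}} - \hat p_{\text{control}})$
in percentage points, with $\hat p$ the coverage-pooled group proportion.
Pooling weights samples by coverage, which is the robust choice at
$n = 7$ per arm where a per-sample mean would be dominated by shallow
samples.

A site is called differentially methylated when $|\Delta M| > 20$
percentage points and the Benjamini–Hochberg $q$-value is $< 0.05$, both
strict inequalities. BH is used deliberately in place of the SLIM
$q$-value estimator sometimes paired with this workflow: SLIM's estimator
is not reproducible from its common descriptions, while BH is standard,
conservative, and stated in the call metadata (`adjust_method`).

**Assumptions.** The binomial LRT assumes no extra-binomial variation
between samples within a group. The generator satisfies this by sharing
the background proportion across samples per site; on real RRBS data,
biological replicate variability makes the test anti-conservative, which
is a known property of this test family and the reason the package keeps
the test behind a small surface (`test_sites`) where an overdispersed
variant could be substituted.

**Coverage processing.** Sites must be observed in every sample with at
least `min_coverage` (default 10) reads and at most each sample's
`max_coverage_percentile` (default 99.9) coverage quantile — conventional
RRBS guards against unobserved sites and PCR duplicates. Coverage is then
normalized between samples by median scaling: each sample is scaled by
`max(medians)/median(sample)`, totals are rounded, and methylated counts
are re-derived from the original per-site proportion so each proportion
moves by at most $0.5/t$. These defaults are declared in `params`; the
exact settings used by any given published analysis of this kind are
typically unreported, so they are decisions here, not reconstructions.

## 2. Annotation

Promoters are TSS ± 1 kb, inclusive at both ends. Feature precedence is
promoter > 5′UTR > 3′UTR > exon > intron > downstream (3 kb) > distal
intergenic; the hierarchy is the conventional annotation order (promoter
first) since only the category names, not the tie-break, are standard.
Ties at equal precedence go to the nearest TSS, then the lexicographically
smaller gene id, making annotation order-independent. CpG-island context is
island / shore / open sea with a 2 kb shore, the common convention where no
width is specified. All internal arithmetic is 1-based inclusive; BED input
is converted on read.

Synthetic genes carry a single exon spanning the gene, so UTR categories
are exercised only by dedicated fixtures that supply explicit UTR
intervals.

## 3. Network prioritization

Seed DMGs are mapped into a supplied tissue PPI edge list (no tissue
inference is performed — the "tissue-specific" restriction is exactly the
choice of edge list). First-order subnetworks contain the retained seeds,
their direct interactors, and all induced edges; whether published networks
of this type include neighbor–neighbor edges is ambiguous, so the induced-
edge convention is declared here and used consistently, including in the
brute-force union oracle the tests compare against.

Degree is counted within the constructed subnetwork (matching how the
interactive tools report it), betweenness is unnormalized shortest-path
betweenness with endpoints excluded, and hubs are *seed* nodes with degree
≥ 10 (inclusive). The disease subnetwork restricts a reference edge list to
promoter DMGs plus catalog genes having ≥ 2 supporting publications,
flags DMGs with restricted-graph degree ≥ 10 as hubs, and merges the
per-hub first-order neighborhoods by set union. DMG–DMG edges are retained
when present, since nothing in the workflow excludes them.

## 4. Overrepresentation analysis

The ORA p-value is the cumulative hypergeometric upper tail
$P(X \ge x)$ with universe size $N$, set size $K$, input size $n$ and
overlap $x$. The universe defaults to the union of all pathway sets because
published ORA runs of this kind rarely state their universe; it is a
parameter. No multiple-testing correction is applied to the $p < 0.05$
retention rule, matching the workflow being emulated, but a BH column is
emitted alongside for transparency. The input gene list defaults to *all*
nodes of the disease subnetwork (DMGs and disease genes alike), following
the reading that the enrichment input is the network, not only the DMGs.

## 5. Clinical statistics

* **Promoter score**: coverage-weighted mean methylation percentage over a
  gene's promoter dmCpGs, per sample — identical to pooling reads across
  those sites.
* **Correlations**: Shapiro–Wilk (at 0.05, on either variable) selects
  Pearson vs Spearman, a concrete rule standing in for the loose
  "Pearson or Spearman" convention; $|r| \ge 0.6$ is flagged strong and
  $p \le 0.05$ significant. Zero-variance inputs yield an explicit
  degenerate flag.
* **Group tests**: Shapiro–Wilk on each group plus an F test of variance
  homogeneity route to pooled t, Welch t, or the two-sided Wilcoxon rank
  sum test (exact when both groups are ≤ 50 without ties; otherwise normal
  approximation with tie correction).
* **Fold changes**: with $\Delta Ct = Ct_{\text{ref}} - Ct_{\text{target}}$
  (note: reference minus target), $\Delta\Delta Ct$ is the control-group
  mean $\Delta Ct$ minus the sample's $\Delta Ct$ and
  $FC = 2^{-\Delta\Delta Ct}$. This composite is the unique sign convention
  under which a target expressed one cycle above the control mean gives
  $FC = 2$, i.e. upregulation > 1; it makes FC invariant to adding any
  constant to all Ct values. Technical replicates are averaged first.
* **Risk stratification**: NYHA I–II, 6MWD > 440 m, RAP < 8 mmHg,
  CI > 2.5 L/min/m² — strict inequalities as the tool defines them; 3–4
  criteria → low, 2 → intermediate, 0–1 → high.
* **Quantile normalization** maps each column onto the distribution of
  row-means of column-sorted values (ties averaged), via
  `limma::normalizeQuantiles`.
* **Concordance**: per gene, the share of cross-platform CpGs whose
  case−control beta difference has the same sign as the RRBS call. A delta
  of exactly zero counts as non-confirming — the conservative reading of
  "confirming the trend". PVR is accepted in dyn·s·cm⁻⁵ (divide by 80 for
  Wood units).

## 6. What the generator emulates — and what it does not

`simulate_study()` draws, under one master seed with one RNG stream per
output family (annotation, methylome, graph, clinical), a complete study:

* **Annotation**: non-overlapping genes in fixed slots on one chromosome,
  random strand, gene types at 70/15/10/5% (protein-coding, lncRNA, miRNA,
  pseudogene), a CpG island over 60% of promoters.
* **Methylome**: all CpGs inside promoters (TSS ± 1 kb), background
  proportion $\pi_i \sim \mathrm{Beta}(2, 4)$ shared across samples,
  coverage $\sim \mathrm{NegBin}(\mu = 30, \text{size} = 20)$ per sample,
  methylated counts binomial. RRBS coverage is overdispersed, hence the
  negative binomial rather than Poisson; the size default keeps coverage
  almost always above the pipeline's own 10× filter at 30× mean, so planted
  sites are rarely lost to filtering. The Beta(2, 4) background reflects
  the low-to-intermediate methylation typical of promoter CpGs and leaves
  headroom for the planted shift.
* **Planted signal**: a fraction of genes (default 20 of 220, i.e. 200 of
  2200 sites) shifts its case-group proportion by a constant 0.40 at every
  promoter CpG, in whichever direction loses less of the effect to the
  [0.01, 0.99] clip (ties to hyper). Clipped sites are counted and logged,
  never dropped. Because low backgrounds dominate, most planted genes come
  out hypermethylated — consistent with the preferential hypermethylation
  reported for CD4+ T cells in PAH.
* **Networks**: a Barabási–Albert graph built from $m$ isolated nodes
  (each new node attaches $m = 2$ edges preferentially), giving exactly
  $m(n-m)$ edges; a disease catalog over non-planted genes with ~25% of
  entries at exactly one publication (to exercise the ≥ 2 filter);
  three designated planted genes wired to 12 strong-catalog genes each, and
  any accidental ≥ 10-degree non-designated DMG trimmed back — so the
  designated genes are *by construction* exactly the recoverable hubs.
  Early pathway sets are seeded with planted genes so ORA has signal.
* **Clinical**: cases satisfy the right-heart-catheterization thresholds
  (mPAP ≥ 25 mmHg, PVR ≥ 240 dyn·s·cm⁻⁵), controls sit below them. RAP and
  CI are linked to the promoter scores of two planted genes as
  $y = r z + \sqrt{1-r^2}\,\varepsilon$ on standardized scores (default
  $r = \mp 0.7$: RAP negative, CI positive), so the population correlation
  equals the target exactly; $|r| = 1$ is the allowed noise-free limit and
  $|r| > 1$ an error. Ct tables encode a 2-fold target upregulation in
  duplicate against an RPS18-like reference; the platform-B matrix reports
  true group proportions plus Gaussian noise (σ = 0.05) on 70% of sites.

Not emulated: read-level bisulfite data (FASTQ), array probe chemistry,
batch effects, biological replicate overdispersion, non-promoter CpGs, and
age–methylation dependence. Passing tests therefore demonstrate the
*pipeline's* correctness and calibration under its stated model — not
robustness to the replicate variability, covariate structure or platform
artefacts of real cohorts.

## 7. Numerical and degenerate-input choices

Strict inequalities everywhere a threshold is printed (|ΔM| > 20,
q < 0.05, ORA p < 0.05, 6MWD > 440, platform-B delta ≠ 0); inclusive
degree ≥ 10 for hubs and ≥ 2 publications for the catalog. Sites with zero
group coverage are skipped with a log message, not errors; empty seed
mappings and hub-free disease networks warn and return empty structures;
zero-variance correlation inputs are flagged degenerate. The LRT statistic
is clamped at 0 against floating-point negatives. BH q-values are computed
over all tested sites before any effect-size filtering.

## 8. Problem sizes

The shipped tests and the acceptance script use the default synthetic
cohort (14 samples × 2200 sites) for recovery checks, 2000+ null sites for
calibration, 200 simulated cohorts of 13 cases for the
hemodynamics-recovery rate, graphs of ≤ 12 nodes for the brute-force
betweenness oracle, universes of ≤ 25 genes for exhaustive hypergeometric
enumeration, and ≤ 10 observations for exact Wilcoxon enumeration — sizes
chosen so every oracle is fully enumerable while the statistics remain
stable.

## 9. Known limitations

The binomial LRT ignores biological overdispersion (Section 1); the
annotation does not handle overlapping genes beyond the precedence rule;
the PPI analysis treats edges as unweighted and undirected; the ORA
universe choice materially affects p-values and must be set deliberately
when pathway collections are partial; and the clinical correlations at
n ≤ 7 per subgroup have wide sampling variability — the package reports
signed r alongside |r| and flags rather than hides degenerate cases.
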