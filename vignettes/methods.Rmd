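---
title: "Methods: models, parameters and design choices in mda5tx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mda5tx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`mda5tx` re-implements, as a tested pipeline, a peripheral-blood
transcriptomic analysis of treatment response in anti-MDA5
antibody-positive dermatomyositis (MDA5-DM): paired pre/post-treatment
differential expression, outcome-aligned hierarchical clustering,
overrepresentation analysis, a per-sample gene-set variation score, a
type I/II/III interferon signature score, and the small-cohort clinical
statistics toolkit. Everything runs on a genes × samples log2 expression
matrix plus sample metadata; upstream read processing (trimming, alignment,
quantification) is out of scope, as are ontology files — gene sets are flat
GMT collections.

# The analysis model

## Differential expression

With expression already on the log2 scale, the per-patient fold change for
gene $g$ and patient $i$ is the column difference
$\Delta_{gi} = x_{g,\text{post}(i)} - x_{g,\text{pre}(i)}$. The group fold
change is $\bar\Delta_g$, the mean across patients, and a gene is called
differentially expressed iff $|\bar\Delta_g| \ge 1$ and $p_g < 0.05$ (both
thresholds configurable).

The source analysis does not name its test. We use a two-sided one-sample
t-test of the per-patient differences against zero — the natural paired
test for a pre/post design at $n$ as small as 3 — and offer Welch's
two-sample t on the pre and post groups (`welch_degs()`) for sensitivity
analysis. Raw p-values drive the call, matching the published "p < 0.05"
filter; Benjamini–Hochberg q-values are emitted as an extra column only.
Genes below a mean log2 expression floor (default 1.0) are excluded before
testing: the choice is ours (the source is silent), because near-zero genes
produce unstable fold changes. Genes with zero variance across patients and
a nonzero mean have no t statistic; they are flagged (`zero_variance`) and
never called.

## Clustering and outcome concordance

Patient columns of the fold-change matrix, restricted to the DEG set, are
clustered agglomeratively. Neither distance nor linkage is stated in the
source. We default to **Euclidean distance with average linkage** rather
than the more common 1 − Pearson correlation, a deliberate choice: the DEG
filter on a paired design retains genes that respond coherently within a
patient group, so within the DEG set a patient's profile is close to
constant. Correlation distance on near-constant profiles is driven entirely
by noise (we observed chance-level partitions on synthetic cohorts), while
Euclidean distance preserves the group-level magnitude signal that the
clustering claim is actually about. Correlation distance and Ward/complete
linkage remain available by argument; zero-variance patient columns are
rejected by name under correlation. Merge tie-breaking follows `hclust`'s
lowest-index convention. Agreement between the k = 2 cut and the
outcome/arm labels is quantified by the adjusted Rand index.

## Overrepresentation

For a direction-filtered DEG list of size $n$ drawn from a universe of $N$
genes (the post-prefilter gene set), a set with $K$ members in the universe
and overlap $k$ gets the hypergeometric upper-tail p-value
$P(X \ge k)$. Raw p-values are reported and sorted (ties broken by set
name), mirroring published GO tables that print raw p-values; q-values are
an extra column. No GO DAG traversal is performed.

## Gene-set variation score

The cited GSVA package's kernel-CDF estimator is out of proportion here; we
implement a clearly-labelled ssGSEA-style stand-in. Per sample, genes are
ranked by descending genewise z-score; the score is
$\sum_i (P_{hit}(i) - P_{miss}(i))$ where $P_{hit}$ accumulates set members
weighted by $|z|^\tau$ (default $\tau = 0.25$) and $P_{miss}$ steps
uniformly over non-members. At $\tau = 0$ the score is rank-only, bounded
by $\pm N/2$ (attained when the set occupies the top/bottom $K$ ranks) and
antisymmetric under ranking reversal — properties the tests assert. The
published GSVA p = 0.0198 depends on the unpublished patient data and is
not a target.

## Interferon signature score

The score follows the source's own recipe: batch mean-centering (per gene,
subtract each batch's mean; a no-op for a single batch), genewise
z-scoring pooled across *all* samples (pre and post together, so deltas
live on one scale), a coefficient $c_g \in \{+1, -1\}$ per gene, and the
signed sum $S_s = \sum_g c_g z_{gs}$. Choices the source leaves open:

* **sd denominator** — n−1 (sample sd); a flag switches to n.
* **coefficients** — +1 unless a sign sidecar file assigns −1; the source
  does not list which genes received −1, and we do not guess.
* **batch definition** — the metadata `batch` column; whether the original
  z-scored within cohorts before correction is ambiguous, so both the
  centering policy and the scoring population are explicit arguments.
* missing signature genes are skipped with a warning (annotation
  mismatches are routine); an empty intersection is an error.

The genewise outcome comparison (the violin-plot analysis) takes, per set
gene, the mean per-patient fold change within each outcome group and
applies Welch's t across genes. The unit of the test is the gene, not the
patient, matching gene-level violin distributions.

## Clinical statistics

Fisher's exact (two-sided by the point-probability rule — the convention
that reproduces the published 0.192/0.592/1.000 values; the "twice one
tail" rule does not and is not offered), Pearson chi-square without
continuity correction, Mann–Whitney U (exact by complete enumeration of
midrank splits for pooled n ≤ 12 — exact with or without ties — else
normal approximation with tie and continuity corrections), Welch's t with
Satterthwaite dof, and the standard two-group log-rank statistic
$(\sum O - \sum E)^2 / \sum V$ with the tie-corrected variance. The report
builder types variables automatically (numeric with > 2 distinct values →
continuous), supports per-variable missingness (the published anti-SS-A row
implies one unevaluated patient: 2/6 vs 0/7), and omits p-values for
single-level variables with a note.

# The synthetic cohort: what it emulates and what it does not

`default_study_design()` states the world the tests run in: six patients
(three per arm; two deceased, both in the TC arm), paired pre/post samples,
one batch per arm, and planted modules sized to the three interferon
signatures (73/94/10 genes) plus B-cell (100) and coagulation (50) modules
in disjoint gene ranges of a 1000-gene matrix. Expression is Gaussian
directly on the log2 scale:

$$x_{gs} = \beta_g + b_{batch(s)} + \text{planted}(g,s) + \varepsilon,\quad
\varepsilon \sim N(0, \sigma)$$

with $\beta_g \sim N(8, 2)$, batch offsets (0, +0.5) and $\sigma = 0.5$ —
values a bulk RNA-seq analyst would call typical for log-scale expression
and replicate noise. Post-treatment samples receive outcome-linked shifts
of magnitude 2 log2 units: survivors −2 on all interferon modules and the
B-cell module; deceased +2 on type II/III interferon and coagulation, and
+2 on type I for a configurable responder subset (default: one of the two
deceased patients, mirroring the observed heterogeneity). Effect
magnitudes are free parameters — the source never prints them — chosen
once as "clearly detectable but not caricatural" (4× the noise sd) and not
revisited. Deceased event times are uniform on (2, 3) months (sampling
happened shortly before death); survivors are censored at 12 months.

The generator does **not** model library-size effects, count overdispersion,
dropout, gene–gene correlation beyond the planted modules, or sequencing
reads. A green planted-recovery test therefore establishes that the
pipeline recovers the stated structure at realistic noise — not that the
original cohort's biology is reproduced. Conversely, the
outcome-discordant interferon shifts mean interferon genes *cannot* pass
the joint six-patient DEG filter (mean fold change $(4(-2)+2(+2))/6 =
-0.67 < 1$); the DEG set is carried by the survivor-suppressed B-cell
module, which is also why Euclidean distance is the clustering default
(above).

Determinism: one RNG stream per cohort, seeded from `design$seed`, with a
fixed draw order; identical (design, seed) pairs are bit-identical, which
the pipeline inherits (byte-identical output bundles).

# Numerical choices

* Fisher tables are evaluated in log space (`lchoose`) with the standard
  $(1 + 10^{-7})$ relative tolerance when comparing point probabilities.
* Exact Mann–Whitney enumerates $\binom{n}{n_x} \le 924$ splits; the DP
  rank-sum distribution is kept for the test oracle, not the
  implementation.
* Z-scoring refuses zero-variance genes rather than emitting NaN; callers
  prefilter (the pipeline drops them after batch centering).
* Degenerate conventions: Welch with two zero-variance equal-mean samples
  gives p = 1; all-zero fold-change rows give t = 0, p = 1; a log-rank
  with zero variance gives statistic 0, p = 1.
* All-zero walk weights at $\tau > 0$ (every set member exactly at z = 0)
  fall back to uniform weights.

# Known limitations

* The ssGSEA-style score is a stand-in, not the GSVA estimator; absolute
  score values are not comparable to GSVA's.
* The exact log-rank p 0.045 and the GO term lists of the source depend on
  unpublished per-patient data and are not reproduced.
* The clinical covariates of the synthetic cohort (age, risk factors,
  serology flags) are plumbing for the report builder, not calibrated to
  the published Table; only the published categorical counts shipped in
  `inst/extdata/` are used for the printed-value checks.
* With two patients in one outcome group, Welch comparisons run at the
  edge of validity (df ≈ 1–4); this mirrors the original cohort size and
  is the reason acceptance checks are phrased over 20 seeds.
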