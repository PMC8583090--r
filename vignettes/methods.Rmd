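---
title: "Methods: signature-reversal drug screening on synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-reversal drug screening on synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

revscreen implements a transcriptome-reversal drug-repositioning screen:
build tumor-vs-normal disease signatures, rank a library of drug
perturbation profiles by their potency to *invert* those signatures, apply
rule-based candidate selection and enrichment consensus, match model cell
lines by transcriptional similarity, and connect drug sensitivity to a
candidate copy-number biomarker. Because the real inputs of such a screen
are large external resources (expression cohorts, an L1000-style
perturbation library, pooled viability screens, SNP-array segment calls),
the package ships a synthetic-data module that emulates each of them with
*planted* ground truth, so every stage of the pipeline has a verifiable
recovery target at desk scale.

```{r setup, message = FALSE}
library(revscreen)
library(dplyr)
```

## The disease signature model

Expression cohorts are genes × samples matrices on a declared scale
(`log_intensity`, `counts`, or `log2_tpm1`) with tumor/normal labels.
Differential expression uses an empirical-Bayes moderated t-test. The
hierarchical model assumes gene-wise true variances are drawn from a scaled
inverse-chi-square prior with degrees of freedom $d_0$ and prior value
$s_0^2$; the observed sample variance $s_g^2$ (with $d$ residual degrees of
freedom) is shrunk to the posterior

$$ s_{post,g}^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
   t_g = \frac{\overline{x}_{tumor} - \overline{x}_{normal}}
              {s_{post,g}\sqrt{1/n_t + 1/n_n}}, $$

with $t_g$ referred to a t distribution on $d_0 + d$ degrees of freedom.
The hyperparameters are estimated by matching the first two moments of
$\log s_g^2$ (the spread in excess of the $\psi'(d/2)$ sampling component
identifies $d_0$ by Newton inversion of the trigamma function; the mean
then identifies $s_0^2$). Two limits are useful for testing and are exact
in the implementation: $d_0 = 0$ recovers the ordinary pooled-variance t,
and $d_0 = \infty$ gives a z-style test against $s_0^2$. Counts matrices
are converted internally to log2-CPM with pseudo-count 0.5 before testing —
a deliberate simplification relative to a negative-binomial count model,
adequate here because the synthetic counts are well above the low-count
regime where the NB likelihood matters most.

A *disease signature* applies the cutoffs adjusted p < 0.001 and
|log2FC| > 1 (the fold-change rule is read on the log2 scale), after
collapsing duplicate gene labels to the row with the lowest raw p-value.
The up-set $U$ and down-set $D$ feed everything downstream.
Multiple-testing adjustment is Benjamini–Hochberg throughout.

Matching normal references to a tumor cohort (`select_matched_normals()`)
ranks pool samples by median Spearman correlation to the tumor samples in a
20-component PCA latent space of the pooled data. This latent-space
correlation keeps the *selection intent* of deep-learning-based cohort
matching — pick the normals that share broad expression structure with the
tumors — while remaining deterministic and cheap; the autoencoder itself is
out of scope. Ties are broken lexicographically by sample label.

## The reversal score (RGES / sRGES)

Each perturbation profile (one drug × cell line × dose × time) is a ranking
of its gene universe from most induced to most repressed. The enrichment of
a gene set $S$ ($|S| = s$, hit positions $p_1 < \dots < p_s$ in a universe
of $N$) uses the connectivity-map weighted-threshold Kolmogorov–Smirnov
statistic with equal gene weights:

$$ a = \max_j\left(\tfrac{j}{s} - \tfrac{p_j}{N}\right), \qquad
   b = \max_j\left(\tfrac{p_j}{N} - \tfrac{j-1}{s}\right), $$

returning $a$ if $a \ge b$ and $-b$ otherwise (the $\ge$ tie-break keeps
the positive branch, matching the convention of the running-sum original).
The reversal score is $\mathrm{RGES} = ES_{up} - ES_{down}$ when the two
enrichment scores differ in sign (or either is zero), and 0 otherwise.
Negative RGES means the profile represses the disease's up-genes and
induces its down-genes. A useful consequence of the two-sided max rule is
that the attainable extremes are $\pm\left(2 - \tfrac{2s-1}{N}\right)$, not
$\pm 2$: at $|U| = |D| = 50$ against a 978-gene universe the perfect
reversal scores $-1.8988$. Another is that reversing a ranking negates the
score only up to discreteness: the reversed score is exactly $b - 1/N$ or
$-(a + 1/N)$, so negation within $1/N$ holds except when $a$ and $b$ are
within $2/N$ of each other.

Profiles measured away from the 10 µM / 24 h reference condition are
shifted by dose/time offsets before summarization. The offsets are median
contrasts across drugs (mean RGES at the non-reference condition minus mean
at reference) — a simpler, robust alternative to fitting a dose-response
model to scores, appropriate at the library sizes simulated here. The
summarized score is a cell-line-similarity-weighted mean of adjusted RGES
per drug (missing similarities default to weight 1, negative weights clamp
to 0), and `n_strong` counts profiles with raw RGES below −0.25.

Candidate selection keeps drugs with sRGES < −0.25 supported by at least 3
strong profiles ("more than two"), sorts ascending and truncates to the top
100; a drug qualifying for several signatures enters the merged list once,
at its lowest sRGES. The support-count reading of the selection rule is
deliberately conservative and both raw quantities (`srges`, `n_strong`) are
exposed so users can re-filter under the alternative reading (threshold on
the summarized score only).

## Enrichment and consensus

Over-representation uses the one-sided Fisher exact test (hypergeometric
upper tail) against an explicitly supplied background universe — p-values
depend on the universe directly, so the package refuses to guess it. The
combined score multiplies $-\ln p$ by a rank-deviation z-score computed
from an explicit permutation null: 200 random queries of matched size are
scored, and $z = (\bar r_{null} - r_{obs})/sd(r_{null})$. This replaces the
opaque rank-correction of enrichment web tools with a seeded, reproducible
equivalent; it is exactly zero at $p = 1$ and increases with enrichment.
Consensus lists take each signature's top-5 terms by combined score (top-20
in the cell-line variant) and retain terms over-represented (adjusted
p < 0.05) in at least one signature.

## Model lines, dose response, biomarker

Cell-line similarity is the Spearman correlation between the signature's
log2 fold changes and each line's differential expression (line minus
per-gene panel median), restricted to $U \cup D$; lines sharing fewer than
10 signature genes are skipped. Model-line selection intersects the top-k
similar lines with the cell-line consensus, falling back to plain
similarity when the intersection has fewer than 3 lines.

Dose-response curves (viability log2FC over the 8-point 4-fold ladder from
10 µM down to ~600 pM) are summarized two ways: a normalized trapezoidal
AUC over log10 dose (a flat curve at $v$ scores exactly $v$, and rescaling
the dose axis changes nothing) and a low-dose score, the mean viability at
the 3 smallest doses (≈ ≤ 0.16 µM on the default ladder). Correlating
per-dose sensitivities is also possible via the `metric` argument; AUC is
the default because a single-dose readout is noisier at 8 points per curve.
Biomarker association is the Pearson correlation, across lines, of gene
copy number [log2(relative to ploidy + 1)] or expression [log2(TPM+1)]
against the sensitivity metric, with t-based two-sided p-values;
zero-variance features are flagged rather than dropped silently.

Copy-number segments are retained when losses have ≥ 25 probes, gains ≥ 50
probes, and copy-neutral LOH spans ≥ 5 Mb; gene-level state per sample is
the type of the maximally overlapping retained segment (neutral when none
overlaps; ties between contradictory types resolve to neutral with an
ambiguity flag). Continuous copy number is discretized to the five-level
scheme (−2 homozygous deletion … +2 amplification) with cut points 0.3 /
0.8 / 1.2 / 1.55 on the log2(relative to ploidy + 1) encoding, chosen so
zero copies map to −2 and the at-ploidy value 1.0 maps to neutral;
sample-adaptive thresholding is not reproducible locally, so the cuts are
plain configurable numbers. All intervals are 0-based half-open;
`to_zero_based()` converts 1-based inclusive input.

Dependency screens are summarized per gene as efficacy (10th percentile of
the gene's dependency scores — how strong the effect is where it is
strongest) and selectivity (median minus that percentile, scaled by the
MAD-based robust spread plus a small floor). These definitions are a stated
simplification that preserves the ranking semantics of
efficacy/selectivity maps: pan-essential genes score high efficacy and
near-zero selectivity, genes lethal in a small subset score high on both.

## The synthetic study and what it does (not) show

The generators emulate the study's external inputs under one master seed,
split deterministically per stage so any stage regenerates independently:

* **Cohorts** — normals Gaussian per gene around a baseline, gene variances
  from the scaled inverse-chi-square prior ($d_0 = 4$, $s_0^2 = 0.05$ by
  default), tumors shifted by the planted signed log2FC (±2) for a planted
  10% of genes; 30 tumors vs 30 normals. Counts mode uses NB means with
  dispersion 0.1 consistent with the same fold changes. The planted DE set
  depends only on the master seed, so cohorts regenerated with different
  noise seeds share a common core — this is how multi-dataset intersection
  scenarios are built.
* **Perturbation library** — 200 drugs (20 reversers at strength 0.8), a
  978-gene profile universe, each drug profiled in 4 cell lines at
  reference (10 µM / 24 h) plus one low-dose and one short-time condition.
  Reverser values are $-\mathrm{strength} \cdot \mathrm{potency}(dose)
  \cdot \mathrm{lfc}$ plus unit Gaussian noise, with the saturating potency
  $d/(d+1)$ — near-maximal at 10 µM, mirroring typical dosing conventions;
  non-reversers are pure noise.
* **Viability screen** — 30 lines, Hill-type decreasing curves. The planted
  biomarker link is applied to the trapezoid-weighted curve depth, which
  equals the negative AUC by construction, so the copy-number/sensitivity
  Pearson correlation equals the planted value (−0.8) in expectation
  *on the metric the analysis actually measures*, independent of the
  per-line IC50 jitter. A second, uncorrelated control biomarker is always
  emitted. The first 5 lines carry a tumor-like expression pattern for the
  model-matching stage.
* **Segments** — a 32-sample cohort always containing boundary fixtures on
  both sides of every retention threshold (24/25 probes, 49/50 probes,
  4,999,999/5,000,000 bp) and 8 planted gains over the biomarker locus
  (25% alteration frequency by construction).
* **Gene sets** — one planted pathway drawn from the DE genes plus uniform
  decoys, over the full gene universe.

Passing recovery tests on these benchmarks shows the *decision logic and
statistics* are implemented correctly — it does not show field performance
on real cohorts. The generators deliberately omit probe-level array
artifacts, batch effects, inter-gene correlation, and landmark-gene
inference; planted effect sizes are large and homoscedastic across groups.
Recovery rates here are therefore upper bounds, not forecasts.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite and acceptance script: 5,000-gene
  cohorts for screening runs, 20,000 genes for calibration/prior-recovery
  checks, 1,000 random permutations for score nulls, 100-seed loops for
  correlation recovery. These sizes give stable recovery statistics while
  keeping a full run in minutes on one CPU.
* Variance-prior fit returns $d_0 = \infty$ (sentinel) when the observed
  log-variance spread does not exceed the sampling component; zero-variance
  genes under an uninformative prior are reported at $p = 1$ with a flag.
* Trigamma inversion is Newton iteration with asymptotic endpoints
  ($1/y$ for small $x$, $1/\sqrt y$ for large), converging to relative
  1e-10 in a handful of steps.
* Empty up/down sets at the cutoffs emit a flagged signature with a warning
  (reversal scoring requires both non-empty after intersection with the
  profile universe, and errors there name the offending signature).
* All-zero similarity weights fall back to uniform with a warning;
  single-condition libraries yield zero dose/time offsets with a warning.
* Determinism contract: rerunning `run_pipeline()` with the same
  configuration and seed reproduces byte-identical TSV outputs, and the run
  manifest records the seed, package version, configuration hash and
  per-stage row counts.

## A worked mini-run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = tempfile("run_"), seed = 1)
res <- run_pipeline(cfg)
glance(res$signatures[[1]])
head(res$candidates)
res$correlations
```

Plots: `autoplot()` on a signature gives the volcano view, `plot_srges()`
the ranked reversal scores with the −0.25 threshold, `autoplot()` on a
consensus list the combined-score heatmap, `plot_dose_response()` and
`plot_dependency()` the sensitivity views.

## Known limitations

* The RGES formula is a reconstruction of the cited connectivity method
  (the source tool does not print it); equal gene weights are used where
  weighted variants exist.
* The enrichment z-score emulates, but is not identical to, the
  rank-correction of the reference web tool; combined scores are therefore
  comparable within a run, not across tools.
* The counts branch tests log2-CPM values with the moderated t rather than
  an NB GLM; at very low counts this undercalls.
* Cell-line matching operates on the synthetic expression panel; alignment
  methods for batch-correcting real tumor/line compendia are out of scope.
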