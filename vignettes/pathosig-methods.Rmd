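---
title: "Methods: pan-pathogen microarray signature detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-pathogen microarray signature detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathosig)
```

## The measurement model

A pan-pathogen chip interrogates each sample with tens of thousands of
probes: a few probes per organism (a bacterial, fungal or parasitic genus,
or a viral family), plus a panel of human reference probes. Hybridization is
two-channel — the sample's amplified nucleic acid labelled green (Cy3), a
common human reference labelled red (Cy5) — so a probe in a sample yields a
pair of raw fluorescence intensities $(g, r)$. The red channel reflects
probe-specific hybridization efficiency and array-to-array technical
variation of the reference; the green channel carries the biology plus the
same technical layers.

The analysis rests on two assumptions:

1. Human reference probes are equally represented in both channels, so any
   per-array imbalance between the summed green and red human signals is
   technical. The per-array **scale factor**
   $sf = \sum_h g_h / \sum_h r_h$ captures that imbalance.
2. Background cross-hybridization of microbial probes is symmetric across
   the channels, so for a sample without the organism the normalized signal
   is centred near zero, while genuine microbial material raises the green
   channel only.

The normalized signal of a microbial probe is, in the package's default
("literal") mode,

$$N = \log_2 g - sf \cdot \log_2 r .$$

A second reading of the same normalization — the scale factor rescaling the
red intensity before the log, $N = \log_2\!\big(g / (sf \cdot r)\big)$ — is
available as `mode = "ratio"`. The two coincide exactly when $sf = 1$, and
for well-behaved arrays $sf$ sits close to 1 (the worked example in the
README shows scale factors between 0.96 and 1.03). Which reading a given
legacy analysis intended is generally undecidable from a methods paragraph;
the literal form is the default here because it is the form usually printed,
and the mode is a single config switch (`normalization.mode`) so both are
first-class. All downstream statistics operate on $N$; human probes are
excluded from everything downstream.

One practical consequence of the literal form is worth knowing: an error
$\delta$ in the scale factor shifts *every* microbial probe of that sample
by $-\delta \log_2 r$. Since $sf$ is a ratio of sums over the human panel,
its sampling error scales like $1/\sqrt{n_\text{human}}$; with a few hundred
human probes the induced shift is negligible, but with panels of a dozen
probes the per-sample shift can reach several tenths of a log2 unit and
blurs presence calls. The generator's default of 500 human probes reflects
the size of panel the method needs.

## Detection: joint probe and prevalence filters

For one case group against the controls:

* **Probe test.** One-sided Welch $t$ on $N$ per probe, alternative
  case > control ("significantly present in the cases"). Welch rather than
  pooled variance is the default because the case and control groups are
  unbalanced and there is no reason to assume equal variances; a pooled
  option (`var_equal = TRUE`) exists. Probes that are constant and equal in
  both groups get $t = 0$, one-sided $p = 0.5$ (no evidence either way);
  constant but different means give $p \in \{0, 1\}$ by direction with a
  warning.
* **Multiple testing.** Benjamini–Hochberg across all microbial probes of
  that one comparison — not across the four case groups jointly, because
  each case group is analysed against the controls as its own screen.
* **Significance.** A probe passes when $\text{log2FC} \ge 1$ *and*
  BH-adjusted $p \le 0.01$. Both knobs are exposed
  (`detection.min_log2fc`, `detection.max_adj_p`); 0.05-style nominal
  screens can be configured but the stricter adjusted-p default is the
  package's reference condition.
* **Presence and prevalence.** Prevalence needs a per-sample detection
  rule, which significance testing does not supply. The package's rule: a
  probe is present in a sample when $N$ exceeds the probe's mean control
  signal by at least `presence_delta` = 1 log2 unit — the fold-change
  cut-off applied at single-sample level. The rule is a declared convention
  of this package (reasonable alternatives exist); it is exposed as a
  threshold and used consistently for cases and controls. An organism's
  prevalence in a group is, under the default **union rule**, the
  percentage of samples in which *at least one* of its probes is present.
  A **max rule** (largest per-probe detected count) is provided because the
  natural-language description of "samples containing even one of the
  probes" admits both readings; the union is never smaller than the max,
  and both are oracle-tested.
* **Reporting.** An organism is a signature of the case group when it has
  ≥ 1 significant probe, case prevalence ≥ 40% and control prevalence
  ≤ 25%.

Reported signatures are aggregated to organism level (mean over significant
probes of per-probe group means), and percent-of-total signal shares are
computed within each (case group, organism class) cell. Normalized log2
signals can be negative; a percent-of-total is only meaningful for
non-negative quantities, so when a cell contains a negative mean all means
in the cell are shifted uniformly by minus the minimum before shares are
computed, and the shift is recorded in the output. This is a presentation
convention, not an inference step.

## Clustering and cluster count

Samples are clustered on the samples × organisms matrix of aggregated
signature signals — not on raw probes — because the signature is the unit of
interpretation and the heatmap; Euclidean distance, complete linkage, input
unscaled (the log2 normalized signal is already on a common scale, and
scaling would equalize strong and weak signatures). Agglomeration is
delegated to `stats::hclust`, which is deterministic; with continuous
signals, exact distance ties have probability zero, so platform-independent
determinism does not hinge on a tie rule.

The number of clusters is chosen by maximizing the Calinski–Harabasz index
over `k = 2 … min(10, n−1)`, smallest $k$ on ties. Two numerical edge cases
are handled explicitly: $W = 0$ (duplicated points clustered perfectly)
returns `Inf` with a warning, and $k$ outside $[2, n-1]$ is an error.

A caution on the CH index that the package's tests made concrete: for
*extremely* tight clusters (separation ≫ 10× the within-cluster spread,
e.g. 1-D Gaussian blobs at separation/SD = 100), splitting a true cluster
reduces the within-cluster sum of squares by a factor of about
$1 - 2/\pi$, which outpaces the $\,(n-k)/(k-1)\,$ penalty — the CH curve
then keeps rising in $k$ and the argmax lands at the top of the range. At
the moderate separations the index is meant for (around 10 within-blob SDs,
which is what the package's recovery tests use: 2-D blobs, SD 1, centers 10
apart), the planted count is recovered in ≥ 95% of seeded runs. Users
should read a CH curve that increases monotonically to the edge of the
k-range as "clusters much tighter than their separation", not as evidence
for many clusters.

Cluster–cluster contrasts report per-organism Welch $t$, $p$ and
logFC (mean difference of aggregated signals). Two-sided $p$-values are the
default: a contrast between data-derived clusters has no a-priori direction
(the published tables of this kind print signed $t$ with unsigned intent).
One-sided contrasts are available via `clustering.contrast_alternative`.

## Outcome association

Within a case group, each organism's aggregated signal is compared between
deceased and alive patients (unknown outcomes excluded listwise) by a
one-sided Welch $t$, in **both** directions — elevated in the deceased and
elevated in the survivors are separate, equally interesting hypotheses.
$p$-values are nominal (unadjusted) and drive the `significant` flag at
0.05; a BH-adjusted column is emitted alongside for reference, and
non-significant rows are kept and flagged `"trend"` rather than dropped,
since with cohort slices of 10–30 known outcomes per group the tests are
screens, not confirmations. `logfc` is always mean(deceased) − mean(alive)
regardless of direction, so the two directions of the same comparison are
mirror images. Cluster-level outcome summaries report the deceased
percentage among known outcomes per cluster.

## The synthetic-data generator

No raw arrays are publicly available for screens of this kind, so the
generator is the package's ground truth and its defaults *are* the
reference study conditions:

| parameter | default | meaning |
| --- | --- | --- |
| `group_sizes` | BRER 50, BRHR 34, BRTP 24, BRTN 40, control 20 | the emulated cohort |
| `n_human_probes` | 500 | human reference panel (scale-factor precision) |
| `probes_per_signature` | 5 | probes per organism |
| `n_decoy_organisms` | 20 | organisms with no planted effect (specificity) |
| `baseline_log2` | 6 | background microbial log2 signal, both channels |
| `human_log2` | 10 | human-probe log2 signal, both channels |
| `noise_sd_log2` | 0.3 | per-channel Gaussian SD on the log2 scale |
| `effect_log2` (per signature) | 2 | green-channel elevation in carriers |
| `outcome_deceased_frac` | 0.3 | fraction of case samples labelled deceased |

Raw signals are $2^{\mu + \varepsilon}$ with independent Gaussian
$\varepsilon$ per probe, sample and channel — i.e. log-normal intensities,
the simplest model under which the log2-based statistics have known
behaviour. A per-channel SD of 0.3 log2 units corresponds to a coefficient
of variation around 23%, a typical probe-level replicate noise for
glass-slide arrays; the null-calibration checks run at a harsher 0.5.
Carriers of a planted signature get `effect_log2` added to the green-channel
mean of that signature's probes only — the red channel is the common human
reference and never carries microbial effects. Carriers are chosen as
exactly `round(frac × group size)` samples by a seeded permutation rather
than by Bernoulli draws, so prevalence filters are exactly testable.
Identical configuration and seed give byte-identical fixture files.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real FFPE arrays: probe-to-probe affinity
differences, correlated (spatial or batch) noise, cross-hybridization
between related organisms, FFPE degradation, dye bias beyond the scale
factor, and realistic organism abundance distributions. The generator
validates the *pipeline's logic and calibration*, not the biology of any
particular cohort.

## Numerical conventions

* Raw signals ≤ 0 are floored at `signal_floor` = 1 fluorescence unit
  before any log, with a warning; scanner exports can contain zeros and the
  formulas need positivity.
* Readers reject malformed input (duplicate or missing probe–sample cells,
  unknown class tokens, inconsistent human flags) rather than coercing;
  error messages name the offending cell or row.
* All result tables are written tab-delimited at full double precision;
  re-reading reproduces values far beyond 6 significant digits. Dendrograms
  are exported as Newick via `ape`.
* The pipeline writes timestamps only to `run.log`; every other output is
  byte-reproducible under a fixed seed.

## Problem sizes used by the validation suite

The shipped tests run the full emulated design (168 samples, 1000 probes)
for 100 null-calibration seeds and 50 planted-recovery seeds; formula-level
checks compare scale factors, both normalization modes, BH adjustment, the
CH index, complete-linkage merge heights and both prevalence rules against
independent brute-force oracles on 1000 random small instances each;
cluster-count recovery uses 100 seeded runs per planted k ∈ {2, 3, 4}; and
outcome power/size use 100 runs of 20-vs-20 cohorts (5000 null tests for
the false-positive rate). These sizes were chosen to give stable rates
(binomial SEs of a few percent or less) while keeping the suite fast enough
to run routinely.

## Known limitations

* The presence rule behind prevalence is a package convention; prevalences
  are only comparable between analyses using the same rule and delta.
* The literal normalization mode makes $N$ sensitive to scale-factor error
  multiplied by $\log_2 r$; with small human panels prefer more human
  probes over switching modes, since the modes answer different questions.
* Percent-signal shares depend on the negative-shift convention when cells
  contain negative means; shares near the shift boundary should not be
  over-interpreted.
* The outcome tests use alive/deceased status only — no survival times, no
  covariates, no multiplicity control across organisms beyond the reported
  BH column.
* Organism identity is taken from the annotation as-is (genus or viral
  family); no taxonomic collapsing or cross-organism probe sharing is
  modelled.
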