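---
title: "Quantification, stability ranking and the two-gene stress index: methods and design choices"
author: "coralqpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coralqpcr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralqpcr)
```

## The problem

Reef-building corals bleach when elevated seawater temperature combines
with intense light, and a field-deployable molecular assay for
sub-bleaching heat-light stress would let managers assess risk from the
coral's own physiological point of view. Quantitative PCR of a small
panel of candidate genes is a practical vehicle for such an assay:
crossing-point (CP) values are cheap to collect in the field workflow,
and a well-chosen gene pair can carry most of the diagnostic signal.
`coralqpcr` implements the complete analysis path for this kind of
study — efficiency-calibrated quantification, reference-gene validation,
gene-wise mixed-model inference, and the two-gene stress index — plus a
generative simulator of the experimental designs, so every stage can be
validated against known ground truth.

## The measurement model

A qPCR reaction with per-cycle amplification factor $E$ crosses the
detection threshold at cycle $\mathrm{CP}$ when the initial template
amount is proportional to $E^{-\mathrm{CP}}$. On the log2 scale this
gives the calibrated abundance

$$\mathrm{Ca} = -\,\mathrm{CP}\cdot\log_2 E,$$

so that differences in Ca between samples or genes are log2 fold
changes. $E$ is estimated per primer pair from a serial dilution series
by ordinary least squares of CP on $\log_2(\text{input amount})$, with
$E = 2^{-1/\text{slope}}$; a perfect assay doubles its template every
cycle (slope $-1$, $E = 2$). Assays outside the accepted range
$[1.85, 2.15]$ are flagged rather than rejected: in practice such
primers are redesigned, but the pipeline must still process flagged
genes (with a warning) so that a single poor assay never silently drops
a column of data. The dilution regression is unweighted — no weighting
scheme is implied by the calibration protocol — and $r^2$ is reported
but not gated.

Technical duplicates are averaged arithmetically **on the Ca scale**
(all downstream models are linear in Ca; the alternative, averaging CP
first, differs only by the gene's fixed $\log_2 E$ factor and would
change nothing material, but the Ca-scale choice keeps the aggregation
step and the models on one scale). Duplicate runs more than 1.5 cycles
apart (configurable) are flagged and kept. Missing cells stay `NA`;
nothing is dropped silently.

Normalization subtracts, per sample, the arithmetic mean of the control
genes' Ca values. Because Ca is a log2 quantity, this is exactly the
classical geometric-mean normalization of the back-transformed relative
amounts — the package's tests verify the identity numerically — and it
cancels the per-sample template-loading factor, the dominant nuisance
in field-collected material.

## Reference-gene stability (geNorm)

For candidate reference genes $a, b$ the pairwise variation
$V_{ab}$ is the sample standard deviation ($n-1$ denominator) across
samples of $\mathrm{Ca}_a - \mathrm{Ca}_b$; a gene's stability value
$M$ is its mean $V$ against all other candidates, and ranking proceeds
by iteratively discarding the highest-$M$ gene until two remain (ties
broken lexicographically by gene id so the ranking is deterministic;
the two survivors share the final symmetric two-gene value). Loading
factors cancel inside every pairwise difference, so template-loading
variation cannot masquerade as instability. No numeric $M$ threshold is
enforced: the companion diagnostic `controlVariation()` instead
quantifies how imperfect the chosen controls are, as the fold by which
each control is regulated across conditions
($2^{\max\bar y_c - \min\bar y_c}$ of its all-controls-normalized
values) and the fold it fluctuates within a condition. The
within-condition fold is defined here as $2^{k\,\hat\sigma}$ with
pooled residual sd $\hat\sigma$ and $k = 1$ by default; $k$ is exposed
because "fold fluctuation" conventions vary between labs ($1\sigma$ vs
$2\sigma$), and no single convention is canonical.

## Gene-wise mixed models

The experimental designs are paired by coral colony: fragments of one
colony experience control and treatment conditions, making colony a
random blocking factor. Each gene is fitted individually with its
normalized Ca as the response:

* paired single-timepoint design: `ca ~ treatment + (1 | colony)`;
* stress/recovery factorial: `ca ~ timepoint + timepoint:treatment +
  (1 | colony)` — the nested coding estimates the treatment contrast
  separately at each sampling point, which is the quantity of
  scientific interest;
* replicated-tank design: `(1 | tank)` added;
* two-site field comparison: an ordinary linear model.

Fixed effects are REML estimates (lme4). For inference the package
defaults to `method = "auto"`: on balanced paired two-level designs it
uses the exact paired-difference $t$ test, whose point estimate is
identical to the REML fixed effect and whose degrees of freedom are
exact; everywhere else it uses Satterthwaite approximate-df $t$ tests
(lmerTest) with Wald intervals. A seeded parametric-bootstrap
likelihood-ratio test (`method = "pb"`, default 1000 draws) is provided
for designs where the $t$ approximations are in doubt; it is not the
default because the package's validation rests on replicated
simulation studies in which thousands of gene-wise fits are performed,
and the bootstrap's cost there is disproportionate to its benefit on
these small balanced designs, where the exact and Satterthwaite routes
target the same null distribution. Two numerical edge cases are
handled explicitly: zero-residual-variance responses (noise-free test
fixtures) short-circuit to exact least-squares arithmetic with the
interval collapsed to the point, and variance components estimated at
the zero boundary are flagged (`"boundary"`) rather than failed.

False-discovery-rate control is Benjamini–Hochberg across the gene
panel of one experiment, separately per fixed-effect term — the
correction spans genes, not terms. One subtlety the tests document:
BH-adjusted sequences are generally *not* fixed points of the
procedure (re-adjusting `(0.6, 0.8)` gives `(0.8, 0.8)`), so
idempotence is only asserted for genuine fixed points such as constant
sequences.

## The two-gene stress index

The Porites Stress Index for a sample is
$D = \mathrm{Ca}^{\mathrm{Hsp16}} - \mathrm{Ca}^{\mathrm{Actin}}$
computed on **non-normalized** Ca. Both genes are amplified from the
same cDNA, so the loading factor cancels in the difference and the
assay needs no internal control genes — its central practical
advantage. The sign convention follows the defining formula
(numerator Hsp16, denominator actin); with this orientation $D$ is
negative in unstressed corals, because the small heat-shock protein
Hsp16 sits far below actin at baseline, and rises toward or above zero
under acute stress as Hsp16 is strongly induced while actin is
repressed. Group comparisons of $D$ reuse the same model machinery
with $D$ as the response.

Marker selection is reproduced by PCA of the normalized Ca matrix
(samples as observations), centered and unscaled — the genes already
share the log2 scale, and scaling would up-weight low-variance genes;
a scale switch is provided. Principal-component signs are arbitrary, so
each component is oriented to make its largest-magnitude loading
positive, and the suggested assay pair (extreme positive and extreme
negative PC1 loadings) is invariant to sign flips by construction. The
pair is reported rather than hard-coded so the logic transfers to
other gene panels.

## What the simulator emulates

`simulateExperiment()` draws from the generative model the analysis
assumes. For sample $s$ and gene $g$,

$$a(s,g) = \text{baseline}_g + \text{colony}(s,g) + \text{tank}(s,g) +
\beta(g, \text{cell}(s)) + \varepsilon(s,g),$$

all Gaussian on the log2 (Ca) scale; a per-sample loading factor
$L(s)$ is added to every gene of the sample; and each technical run
emits $\mathrm{CP} = -(a + L)/\log_2 E_g$ plus Gaussian noise on the
CP scale. Multiplicative biology is additive in log space; cycle-level
measurement error is additive in cycles — hence the two noise scales.
Colony effects are drawn independently per gene by default, matching
the gene-wise model actually fitted; a shared-across-genes mode is a
config switch. Default variance components (colony 0.5, residual 0.5,
loading 1.0 on the log2 scale; technical 0.2 CP; tank 0.3 where tanks
exist) are plausible magnitudes for colony-level expression
heterogeneity, qPCR replicate scatter and template-loading spread in
this kind of assay, are visible in every `ScenarioConfig`, and are held
fixed across all validation studies. Every stochastic operation takes
an explicit seed; identical config and seed reproduce the CP table bit
for bit.

The presets encode the four study designs with true effects set to the
headline results they are meant to recover: `exp1` (5 paired colonies;
Hsp16 $+\log_2 800$, chromoprotein $+1$, actin $-2$, C3 $-\log_2 6$),
`exp2` (paired treatment $\times$ stress/recovery factorial; Hsp16
$+\log_2 700$ at stress and $+3$ at recovery, actin $-2$, Hsp60 $+2$,
Hsp90 $+\log_2 6$ at stress), `exp4` (5 colonies, 3 tanks per
treatment, 1–3 replicates, the fifth colony missing its treatment arm;
index shift $+3$), and `field` (9 inshore vs 7 offshore samples; index
shift $+2$, within the reported ~2–4 log2-unit range of lab stress
contrasts but attenuated as expected for a milder field temperature
difference). Reported sample sizes for the stress-recovery design vary
(8 whole colonies in the protocol description versus 12–15 pairs in
result summaries), so `exp2` exposes `nColonies` as a parameter with
default 8 rather than resolving the discrepancy. The exp4 index shift
is a package choice: the cross-species experiment showed a significant
but attenuated response whose magnitude is not pinned down, so a value
between the field and lab-stress shifts was fixed once.

The simulator reproduces the statistical structure the analysis
assumes — paired designs, per-gene variance components, loading
factors, duplicate CP noise — and deliberately nothing else. It does
not model amplification kinetics or fluorescence curves (CP is the
atomic observable), symbiont cross-amplification, outlier mechanisms
(pipetting failures, inhibition), or non-Gaussian tails. Passing
recovery tests therefore demonstrates that the pipeline is a correct
and unbiased implementation of its own model, not that real coral data
satisfy that model.

## Validation studies and problem sizes

The package's acceptance checks are, in order: closed-form identities
of the Ca transform and the dilution regression; numerical equivalence
with independent oracles (a brute-force double-loop geNorm, the
paired-difference mean, the exponentiate–geometric-mean–relog
normalization); exactness of the loading-factor invariances; replicated
parameter recovery; and error control under the global null. The
recovery studies run the full pipeline — dilution-series calibration
with 0.15-cycle noise, duplicate aggregation, normalization against the
three most stable reference genes, gene-wise mixed models — on 200
replicates of `exp1` and `exp2` and 150 of `exp4` and `field`, and
require each Monte-Carlo mean log2 estimate to sit within 2 Monte-Carlo
standard errors of its configured truth. Recovered fold changes are
summarized as $2^{\overline{B}}$ (the geometric-mean fold): the
recovery contract is unbiasedness of the log2 effect, and the
arithmetic mean of $2^{B}$ would carry a Jensen inflation of roughly
$e^{(\ln 2)^2\sigma_B^2/2}$ under the generator's variance components.
The null study (150 replicates of `exp1` with all effects zero)
records the fraction of replicates in which the BH screen declares any
discovery at the 5% level — under the global null every discovery is
false — and checks uniformity of the nominal p-values. These sizes
give Monte-Carlo standard errors of ~0.03 log2 units for the large
contrasts and ~1.8 percentage points for the null rate.

## Known limitations

* Satterthwaite p-values are approximate for the unbalanced tank
  design at these very small group counts; the parametric bootstrap is
  the fallback when that matters.
* The stability module implements the classical mean-pairwise-variation
  ranking only; the companion "how many reference genes suffice"
  criterion ($V_{n/n+1}$ cutoff) is intentionally out of scope.
* CP calling, melting-curve analytics and instrument-file parsing are
  upstream of the package's contract; input is plain CSV.
* The index is validated against the generative model and the designs
  above; calibrating it against physiological outcomes (bleaching,
  mortality risk) is explicitly future work.
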