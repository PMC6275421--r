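---
title: "Methods: twin-design discordance and heritability for qRT-PCR miRNA panels"
author: "twinMiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-design discordance and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinMiR)
```

# The model

`twinMiR` analyses miRNA expression measured by qRT-PCR in monozygotic (MZ)
and dizygotic (DZ) twin pairs. The quantity carried through the pipeline is
the comparative-Ct relative expression

$$\Delta CT_{m,s} \;=\; \overline{Ct}^{\,ref}_{s} - Ct_{m,s},$$

the per-sample mean endogenous-control Ct minus the target Ct. Two modelling
assumptions are inherited from the comparative-Ct method: amplification
efficiency is exactly 2 (one cycle = one doubling) for targets and controls
alike, and the controls are stably expressed so that their mean absorbs
sample-level differences in input amount and RT efficiency. Under those
assumptions $\Delta CT$ is a log2 expression level (larger = more abundant)
and is invariant to adding a constant number of cycles to all of a sample's
wells — a property the test suite checks directly.

## Handedness of ΔCT

Only the sign convention above makes the two downstream summaries cohere:
expression tables that rank larger ΔCT as "highest expression", and
within-pair fold changes that equal $2^{|\Delta CT_A - \Delta CT_B|}$
exactly. The package therefore fixes ΔCT = reference − target rather than
the equally common target − reference.

## Control summarization

The baseline is the arithmetic mean of the controls *on the Ct scale*. Ct is
already a log2 quantity, so this equals the geometric mean of the linear
abundances — the standard way to combine reference genes. Stability-weighted
schemes (geNorm-style) are deliberately not implemented: with two controls
they reduce to near-equal weights, and the package keeps the normalization
transparent. A sample in which only one control amplified falls back to that
control with a message; a sample with none is an error.

# Discordance folds, bins, and groups A–D

For each miRNA and pair the discordance fold is
$2^{|\Delta CT_A - \Delta CT_B|} \ge 1$, symmetric in the co-twins. Folds
are binned **low** ($< 2$), **moderate** ($[2, 10]$) or **high** ($> 10$).
The cut wording is strict ("more than", "less than"), so the boundary values
2 and 10 fall in the moderate bin — a deliberate tie-break that the tests
pin down.

Crossing the per-zygosity bins classifies each miRNA:

| group | fraternal (DZ) | identical (MZ) | reading |
|---|---|---|---|
| A | high | low | genetics dominates |
| B | high | high, MZ fold ≥ DZ fold | environment dominates |
| C | high | high, DZ fold > MZ fold | both contribute |
| D | not high | high | environment-sensitive despite genetic identity |

Equal folds in the both-high cell go to **B**: C is defined as the
"fraternal strictly larger" refinement, so B is the natural default. Any
other pattern is unclassified (`"none"`). With several pairs per zygosity
the per-zygosity fold is the geometric mean of per-pair folds (equivalently
$2^{\mathrm{mean}|\Delta\Delta Ct|}$), because folds are multiplicative.

Regression tests run the rule over a published cord-blood panel's tabulated
folds: it reproduces the published A–D membership for 20 of the 21 miRNAs
with folds tabulated in both zygosities. The single exception is miR-181d
(fraternal 128.89, identical 1.33): the stated definitions put it in A while
the original grouping lists it under C. The package follows the definitions
and the test asserts the documented exception. Two further grouped miRNAs
(miR-24, miR-19b) have no tabulated fraternal fold; since the published high
and low lists are exhaustive, their fraternal bin is necessarily moderate,
which the rule accepts as a bin-level fact and assigns D.

## Not-expressed assays

A well is non-detected when its Ct is undetermined or above the detection
limit (`maxCt`, default 40 cycles — the conventional run length of standard
real-time instruments). An assay non-detected in *every* sample is "not
expressed" study-wide. Such assays are retained in reports (group `"none"`,
flagged) but excluded from bin counts, group assignment and correlations;
counting a never-detected target as "1.00-fold, low discordance" would
inflate the low bin with assays about which the data say nothing. The
published panel itself is ambiguous on this point (its low-discordance list
prints the never-expressed miR-10b at fold 1.00, yet its stated fraternal
low count of 10 includes it while the identical count of 18 excludes it);
the package documents the exclusion rule rather than resolving the
publication's arithmetic.

# Correlations and the Falconer partition

Co-twin agreement per zygosity is the Pearson correlation between member A's
and member B's ΔCT vectors **across the miRNA panel**, after pairwise
deletion of flagged miRNAs; at least three complete pairs and nonzero
variance on both sides are required. With several pairs, per-pair
correlations are pooled on the Fisher z scale with weights $n - 3$ and the
pooled $r$ is back-transformed; the reported $n$ is the total number of
miRNA observations and the two-sided p-value refers
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ to $t_{n-2}$. How the original study pooled
its two pairs per zygosity is unstated; Fisher-z weighting is the standard
choice and reduces to the single-pair correlation when there is one pair.

Falconer's formula estimates broad-sense heritability as
$H^2 = 2(r_{MZ} - r_{DZ})$. The raw value is reported alongside a clamped
value in $[0, 1]$, and the environment share is $1 - H^2$ using the clamped
value so the partition always sums to 1. With the published correlations
$r_{MZ} = 0.61$ and $r_{DZ} = 0.15$ this gives $H^2 = 0.92$: genetics 92%,
environment 8% — the worked arithmetic the acceptance tests verify. The
correlations are computed on the ΔCT (log2) scale, not on $2^{\Delta CT}$
linear quantities, matching the scale on which expression is tabulated; the
published r values themselves cannot be recomputed here because the full
44-miRNA ΔCT matrix behind them is not tabulated, so they are exercised
through the arithmetic only.

# The simulator

`simulateTwinCt` draws twin panels from an ACE-style variance-component
model on the ΔCT scale. For miRNA $m$, pair $p$ with kinship $\rho$ (1 MZ,
0.5 DZ):

$$\Delta CT = \mu + b_m + g + c + e,$$

with $b_m \sim N(0, \sigma_b^2)$ a per-miRNA baseline shared by all samples,
a genetic score with marginal SD $\sigma_g$ and within-pair correlation
$\rho$ (twin A gets $\sigma_g Z$, twin B $\sigma_g(\rho Z +
\sqrt{1-\rho^2}Z')$), a shared-environment draw (SD $\sigma_c$) common to
the pair and a unique draw (SD $\sigma_e$) per twin. Emitted target Ct is
$refCt - \Delta CT$; the two controls sit at $refCt$ exactly; Ct above the
detection limit becomes undetermined. All randomness flows from the config
seed through a locally scoped generator (the caller's RNG state is
restored), so a seed fully determines the output.

The closed-form co-twin correlation across the panel is

$$r_{zyg} = \frac{\sigma_b^2 + \rho\,\sigma_g^2 + \sigma_c^2}
                 {\sigma_b^2 + \sigma_g^2 + \sigma_c^2 + \sigma_e^2},$$

hence $2(r_{MZ} - r_{DZ}) = \sigma_g^2 / \sigma_{tot}^2$: Falconer's
difference cancels the baseline and shared-environment terms from the
numerator, so the estimator remains unbiased for the genetic share whatever
$\sigma_b$ and $\sigma_c$ are. Note the target itself,
$\sigma_g^2/\sigma_{tot}^2$, scales with total variance, so adding baseline
variance lowers the heritability being estimated while leaving the estimator
unbiased for it — the property the acceptance suite asserts at
$\sigma_b^2 = 0$ and $4$.

The simulator mirrors the *across-panel* correlation design actually used in
small twin panels (one expression vector per twin, correlated across
miRNAs), not the conventional across-pairs design of large twin registries:
the point is to exercise the computation the pipeline performs. What it does
not emulate: dominance or epistatic genetic components, chorionicity
effects, per-cycle amplification noise, efficiency differences between
assays, or miRNA-miRNA expression correlation beyond the shared baseline.
Passing tests therefore certify the pipeline's arithmetic and the
estimator's behaviour under the stated model, not the biological validity of
Falconer's assumptions in real cord-blood data.

## Defaults and the real panel's inconsistency

Defaults emulate the motivating study design: 44 miRNAs, two pairs per
zygosity, $\mu = 10$, $refCt = 32$ cycles, component SDs
$(\sigma_b, \sigma_g, \sigma_c, \sigma_e) = (2, 1.5, 0.5, 1)$ log2 units —
chosen once so that simulated ΔCT spans roughly 5–16 log2 units, matching
the dynamic range of published cord-blood panels. One instructive
consequence of the closed form: under this across-panel design
$r_{DZ} \ge r_{MZ}/2$ always holds (baseline and shared-environment variance
enter both), so correlation pairs like (0.61, 0.15) cannot arise from any
non-negative variance configuration — a reminder that the published
correlations also reflect sampling noise at $n \approx 44$ and possibly
between-pair heterogeneity.

# Numerical and testing choices

* Folds are compared and stored unrounded; report files round to 2 decimals
  for display only.
* Round-tripping delimited files uses 17-significant-digit formatting, so
  write-then-read is bit-exact.
* Degenerate inputs fail loudly and early: duplicated assay or sample names,
  pairs without exactly two members, unknown zygosity tokens, samples
  without usable controls, constant vectors in correlations, |r| > 1.
* Test problem sizes: closed-form convergence and parameter recovery use
  panels of 4000–5000 simulated miRNAs with one pair per zygosity and 20
  seeds per condition — large enough that Monte-Carlo error
  ($\mathrm{SE}(r) \approx (1-r^2)/\sqrt{n}$) is an order of magnitude below
  the asserted tolerances, small enough that the full suite runs in about a
  minute.

# Limitations

* Falconer's formula is a moment estimator; no likelihood-based ACE/ADE
  structural-equation fit, intraclass-correlation variant, or standard error
  for $H^2$ is provided beyond the Monte-Carlo characterization in the
  tests.
* No amplification-efficiency correction or calibrator-sample ΔΔCt: co-twins
  are compared directly.
* Instrument-native run files (EDS/RDML) are out of scope; inputs are plain
  delimited text.
* The A–D classification is a deterministic rule on binned folds; it applies
  no multiple-testing control and inherits the arbitrariness of the 2- and
  10-fold cuts.
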