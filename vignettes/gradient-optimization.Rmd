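---
title: "Scan-driven LC gradient optimization: model, assumptions and design"
author: "msgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-driven LC gradient optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgrad)
```

## The problem

Reversed-phase LC-MS/MS runs are usually acquired on a simple linear
acetonitrile gradient (for example 0–40 %B over 60 min). When the sample has
been pre-fractionated at the peptide level (SAX, SCX, high-pH RP, IEF), the
fractionation is not orthogonal to the on-line reversed-phase separation:
each fraction carries a hydrophobicity bias, so its peptides elute crowded
into one part of the run while the rest of the gradient is wasted. Dense
elution regions are undersampled by the instrument's finite duty cycle, and
identifications are lost.

`msgrad` computes a per-fraction, non-linear stepped gradient from nothing
but the MS/MS scan metadata of one run acquired on the standard gradient —
no peak picking, no peptide identifications, no vendor dependence.

## The method

Let a run acquired on standard program $g_\mathrm{std}$ contain MS/MS scans
with retention times $r_j$ and total ion currents $\mathrm{TIC}_j$.

1. **Filter.** Keep MS level $\ge 2$; drop scans with known precursor charge
   below `minCharge` (default 2 — singly charged precursors are largely
   chemical contaminants; unknown-charge scans are dropped too unless
   requested otherwise); of the $M$ survivors keep the
   $K = \lceil i/100 \cdot M \rceil$ with the largest TIC. The working
   assumption is that a fraction $i$ of MS/MS spectra is identifiable and
   that those are the highest-TIC spectra; $i = 50\%$ is a typical value for
   complex lysate fractions on Orbitrap-class instruments.
2. **Map to composition.** Each retention time is converted to the percent
   solvent B at which the precursor eluted:
   $b_j = g_\mathrm{std}(r_j + t_\mathrm{MS} - t_\mathrm{dead})$, where
   $t_\mathrm{dead}$ is the LC dead-volume delay and $t_\mathrm{MS}$ the
   optional MS start delay. Scans whose effective pump time falls outside
   the program span eluted during loading or wash; by default they are
   dropped (with a logged count) rather than clamped, because clamping would
   pile them onto the first step and distort the first quantile. The sorted
   $b_{(1)} \le \dots \le b_{(N)}$ are the optimization input.
3. **Equal-fraction construction.** With analytical duration $D$ and step
   resolution $T$ (default 5 min), the optimized program has
   $S = \mathrm{round}(D/T)$ linear steps (minimum 2) at times
   $0, T, 2T, \dots$; the interior breakpoint at step $k$ is the empirical
   quantile $q_{k/S} = b_{(\lceil kN/S \rceil)}$, and the endpoints are
   pinned to the standard program's start and end %B. Every step then
   brackets an equal fraction of the $N$ scans, so under the new program
   elution is spread evenly over the run.

```{r worked}
g <- GradientProgram(c(0, 60), c(0, 40), label = "0-40%B/60min")
og <- buildOptimizedGradient(c(5, 10, 10, 20, 30, 35), g,
                             OptimizationParams(stepIntervalMin = 20))
breakpoints(program(og))
equalCountCheck(og, c(5, 10, 10, 20, 30, 35))
```

## The elution model used for evaluation

To quantify the redistribution, each observed composition $b_j$ is mapped to
a predicted retention time under a candidate program: the earliest pump time
at which the program reaches $b_j$, shifted back onto the MS clock. This
"characteristic composition" model deliberately ignores gradient-slope
effects on retention and peak width (no per-peptide linear-solvent-strength
parameters are fitted). It is exactly the assumption implicit in the
equal-fraction construction, so the evaluation is internally consistent with
the optimizer; it is not a chromatographic simulator. Predicting a run's own
compositions under its own program recovers the original retention times
exactly, which the test suite asserts.

The headline uniformity metric is the Kolmogorov–Smirnov distance of the
predicted elution times from the continuous uniform distribution over the
analytical window — parameter-free and insensitive to bin choice, unlike a
chi-square on bins. Per-step bin counts are reported alongside for
interpretability.

```{r redistribution}
tb <- generateRun(syntheticRunSpec(nScans = 2000, rtPreset = "late",
                                   seed = 42))
res <- runPipeline(tb, g, quiet = TRUE)
res$report
```

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `iPercent` | 50 | % | fraction of charge-surviving MS/MS scans kept, highest TIC first |
| `minCharge` | 2 | — | minimum known precursor charge kept |
| `includeUnknownCharge` | `FALSE` | — | keep scans with no charge record |
| `stepIntervalMin` (T) | 5 | min | step resolution of the optimized program |
| `outOfSpanPolicy` | `"drop"` | — | drop or clamp scans eluting outside the program span |
| `deadVolumeDelay` | 0 | min | pump-to-emitter composition lag (measure it for your LC) |
| `msStartDelay` | 0 | min | pump-start to MS-clock-zero offset |

Only the difference `msStartDelay - deadVolumeDelay` enters the mapping;
this algebraic fact is asserted as a test property. Measuring the
dead-volume delay is the user's job (simple tracer procedures exist); it is
not estimated from the data.

## Numerical and design choices

* **Quantile rule.** The order statistic $q_p = b_{(\lceil pN \rceil)}$ was
  chosen because it returns an actually observed (hence actually populated)
  composition and makes the per-step counts exactly $N/S$ whenever $S$
  divides $N$. Interpolating quantile definitions would place breakpoints at
  compositions no scan eluted at and make the equal-count property only
  approximate.
* **Boundary ties.** Interior breakpoints are observed values, so
  observations exactly equal to a breakpoint are common in discrete data.
  `equalCountCheck()` splits such tied observations between the adjacent
  steps the way the equal-fraction rank assignment dictates; for all-distinct
  values this reduces to plain interval counting. Without the split, a tie of
  multiplicity $m$ at a boundary can perturb naive interval counts by up to
  $m$.
* **Step grid.** $S = \mathrm{round}(D/T)$, minimum 2. When $T$ does not
  tile $D$ exactly the last step absorbs the remainder, so the optimized run
  keeps precisely the standard run's analytical duration (the comparison
  between standard and optimized runs presumes equal run time). If $T$ is
  too coarse for even two steps, an even $S+1$-point grid over $D$ is used
  instead.
* **Pinned endpoints.** The optimized program starts and ends at the
  standard program's start/end %B rather than the data's min/max, so the run
  still spans the full composition range and no analyte class is excluded.
  An alternative — jumping immediately to the first quantile — would start
  the run steeper but risks losing early-eluting material; it was not
  adopted.
* **TIC source.** Filtering uses the MS/MS scan's own TIC (instrument-
  recorded attribute when present, sum of peak intensities otherwise), not
  the precursor's MS1 intensity; the identifiability proxy is a property of
  the MS/MS spectrum itself, and using it keeps the method free of MS1
  peak picking.
* **Chimeric precursors.** When an MS/MS spectrum lists several precursors,
  the first (selected) one's charge is used; the method needs exactly one
  charge label per scan.
* **Determinism.** TIC ties at the filter cutoff break by earlier retention
  time, then lexicographic scan id; there is no randomness anywhere in the
  optimizer, so pipeline output is a pure function of input and
  configuration. Exported %B values are rounded to 0.1 (LC input
  granularity) at export time only.
* **Wash segments.** A declared trailing wash/re-equilibration block is
  exempt from monotonicity validation, excluded from optimization, and
  carried through to the optimized program verbatim — it is
  sample-independent housekeeping.
* **Degenerate inputs.** All-identical compositions produce a flat stepped
  program and a degenerate-input warning from the evaluator; fewer than 5
  evaluable scans make the uniformity metrics meaningless and the report is
  refused.

## The synthetic-run generator

`syntheticRunSpec()` / `generateRun()` emulate exactly the features the
optimizer consumes, under an explicit seed:

* **Retention-time skew.** Presets `uniform`, `early` (beta(2, 5) scaled to
  the run), `late` (beta(5, 2)) and `bimodal` (beta(8, 2)/beta(2, 8)
  mixture) reproduce the fraction-level hydrophobicity bias seen in
  pre-fractionated samples; under the `late` preset about two thirds of
  scans fall in the last third of the run.
* **TIC structure.** A two-component lognormal mixture: an "identifiable"
  component at lognormal(log 1e7, 0.6) with mixing fraction `pId` (default
  0.5, matching the default `iPercent`) over a noise component at
  lognormal(log 1e5, 0.6). Two orders of magnitude of separation makes the
  analytic misclassification probability of the rank filter negligible
  (~3e-8), so tests can assert that the TIC filter recovers the
  identifiable component.
* **Charge mix.** Categorical over 1+, 2+, 3+, 4+ and unknown with a
  typical tryptic default (0.15/0.50/0.25/0.05/0.05), drawn independently of
  retention time and TIC — the optimizer uses no joint structure, and
  independence keeps the filter's behaviour analytically predictable.
* **Fixture mzML.** `writeFixtureMzML()` writes minimal standards-conformant
  mzML with scan start times deliberately encoded in seconds, keeping the
  unit-conversion path of `readMzML()` permanently under test; TIC
  attributes can be omitted per scan to exercise the sum-of-peaks fallback.

What passing tests on synthetic runs do **not** show: real chromatography
has peak widths, tailing, column equilibration effects and duty-cycle
dynamics that the generator does not model, and the gain in peptide
identifications on a real instrument cannot be predicted from these data.
The tests establish that the construction does what it promises on its own
terms — equal per-step scan fractions and a large reduction in the
KS-to-uniform distance of predicted elution times for skewed runs
(typically from ~0.4 to ~0.05 on the `late` preset).

## Validation problem sizes

The test suite exercises the equal-fraction property over 200 random scan
sets of 50–5000 scans, redistribution on 2000-scan synthetic runs, the
identity property on 600 evenly spaced scans (optimized breakpoints within
0.2 %B of the standard line), and full mzML/TSV round trips on runs of
60–150 scans — sizes at which every property is exact or tightly bounded
while the whole suite runs in seconds.

## Limitations

* The elution model is the construction's own simplification; it cannot
  anticipate retention shifts caused by the altered gradient slope itself.
* Gradients are treated as ideal piecewise-linear composition programs; pump
  mixing dynamics, pressure and flow-rate changes are out of scope.
* Vendor RAW files are not read; convert to mzML/mzXML first with an
  external converter.
* The `chromeleon_like` export dialect is a labelled approximation of the
  vendor command format, not a bit-exact rendering.
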