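---
title: "tcd4gate: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcd4gate: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcd4gate)
```

This vignette documents the science and the engineering decisions behind
`tcd4gate`: the models, the tunable parameters with their defaults and
units, what the synthetic-data generator does and does not emulate, and the
numerical conventions. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## 1. Data model and preprocessing

A `flow_sample` carries an event-by-channel intensity matrix, channel
metadata, an optional spillover matrix, and a transform state restricted to
`raw -> compensated -> transformed`. Compensation is classic linear
unmixing in raw intensity space — `events %*% solve(S)` with `S` the
row-as-source spillover matrix ($S_{ij}$ = fraction of detector $i$'s
signal measured in detector $j$, unit diagonal). It always precedes
scaling, because spillover is linear only in raw intensities. Matrices with
condition number above $10^8$ are rejected as numerically singular.

Fluorescence channels are scaled with the logicle transform
(biexponential, parameters $T=262144$, $W=0.5$, $M=4.5$, $A=0$), the
community default for modern cytometer exports; `asinh(x/150)` is offered
as a simpler alternative and scatter channels stay linear. Transformed
units throughout the package are "display decades" in $[0, 4.5]$; raw zero
maps to $W = 0.5$. The logicle forward map has no closed form, so it is
inverted numerically: a 512-point grid bracketing $[-0.6, 1.6]$ of the
unit scale provides a starting point and six Newton iterations on the
closed-form biexponential polish it to machine precision (round-trip error
$< 10^{-12}$ relative; the package's FCS float32 writer dominates the
round-trip error at $\sim 10^{-7}$).

FCS support is deliberately narrow: list mode (`$MODE L`) in FCS 3.0/3.1,
data types F, D and unsigned I (16/32 bit), both byte orders, spillover
from `$SPILLOVER`/`SPILL`/`$COMP` keywords or a CSV matrix. Everything is
written back as FCS 3.1 float32 little-endian, single dataset. Instrument
setup, PMT calibration and acquisition protocols are out of scope.

## 2. Phenotype codes and thresholds

Each marker axis is partitioned by 1–3 strictly increasing cutpoints into
the discrete levels neg | lo | pos | hi; values exactly on a cutpoint go to
the upper level (a documented tie-break, so discretization is a pure
function). Phenotype notation follows the field's reading:

* `+` = {pos, hi} — positive at any intensity;
* `-` = {neg, lo} — *not positive*, the usual meaning of "−" on a
  cytometry axis (a dim "lo" event is not called positive);
* `-/lo` = {neg, lo} (so Treg CD127−/lo and CD127− coincide, which is the
  notation's intent);
* `hi` requires a third cutpoint — only markers with a meaningful bright
  population (CD25, CD45) need it in practice; with a single cutpoint `hi`
  collapses onto `pos`;
* `±` matches every level.

This `-` = {neg, lo} reading matters quantitatively: with Gaussian channel
noise of SD 0.25 around a negative population anchored at 0.3, a strict
`-` = {neg} cut at 0.65 would mislabel ~8% of events per constrained
marker, while the not-positive reading moves the relevant boundary to
1.6 (5σ) and makes negativity constraints essentially lossless.

Threshold fitting strategies: `valley` (minimum of a kernel density
estimate between the two largest modes; a mode is only believed if it
reaches ≥5% of the main mode's height and the valley dips below 80% of the
lower mode, otherwise the channel is called unimodal and falls back to
`quantile` with a warning), `quantile` (configured quantiles), and
`anchored` (offset above the CD3− lymphocyte reference at a configured
reference quantile, default 0.99 — the answer to the open question of what
anchors "hi": the package anchors against an internal negative reference,
configurable). Where `hi` gates are set against CD4+ non-Treg versus total
lymphocytes is instrument- and cohort-specific; the simulator's
generator-truth thresholds sidestep the question for validation.

## 3. The gating taxonomy

The tree realizes the sequential strategy: leukocytes → lymphocytes (CD45
hi, SSC low) → T cells (CD3+) → CD4 T cells (CD4+), then three branches
gated in order — Tregs (CD25 hi, CD127−/lo) first, TFH (CD185+) second,
classical Th (CD185−) last. CD185+ Tregs ("Treg-like TFH") are gated
inside the Treg branch before its subset split and mirrored as a virtual
reporting node under TFH, so both namings appear in reports while the
event is counted once. Within every branch: naïve (CD27+CD45RA+CD62L+ with
all four chemokine receptors negative), then eight receptor-defined memory
subsets — Th1 (CD183+CD194−CD196−CCR10−), Th2 (CD183−CD194+CD196−CCR10−),
Th17 (CD183−CD194+CD196+CCR10−), Th1/Th17 (CD183+CD194−CD196+CCR10−),
Th22 (CD183−CD194+CD196+CCR10+), the two novel codes CD183+CD194+CD196−CCR10−
and CD183−CD194+CD196−CCR10+, and an explicit other-memory bin — each
subdivided into CM/TM/EM/TE (EM accepts CD62L at any level). The default
tree reports 131 named populations, comfortably above the 89 the default
configuration guarantees; a `stem_cell_memory` toggle (off by default)
adds a CD183lo naïve-profile subset gated before naïve cells.

Children are evaluated in order and the first matching rule wins; events
matching no sibling stay in that level's named unclassified bin. This
makes the partition property structural: at every node, children plus the
unclassified bin sum exactly to the parent, which `check_conservation()`
verifies and the CLI enforces with a non-zero exit on violation.
cyCD154 is carried in the panel but takes no part in the default taxonomy:
it reads out activation after in-vitro stimulation, which is out of scope
for unstimulated blood.

## 4. Maturation staging

The maturation trajectory is the first principal component of the
standardized maturation markers (CD27, CD45RA, CD62L) — a deliberate
simplification of proprietary maturation tools, sufficient and fully
testable at this scale. Decisions:

* **Equal-count binning** into 20 default stages (remainder events to the
  earliest bins), not equal-width: occupancy balance is what makes the
  staged medians smooth. Ties in PC1 score break on event index, so the
  assignment is invariant to event order.
* **Orientation**: PCA sign is arbitrary, so the axis is flipped until the
  orientation marker (CD45RA, high on naïve cells) has a negative loading —
  the naïve end comes first. CD45RA is non-monotone over the full pathway
  (it returns in terminal effectors), but its loading sign still pins the
  naïve end because naïve cells dominate the CD45RA-high mass.
* **Merging**: each stage's per-marker medians are discretized and maximal
  runs of adjacent stages with identical codes are merged ("comparable
  immunophenotypes" operationalized as identical discrete codes). Merging
  is idempotent and never increases the stage count.

Geometry caveat: a 20-bin boundary that splits two clusters near 50/50 can
median into the inter-cluster gap ("lo") and create a short extra run. The
canonical five-stage reduction is exact when bin boundaries fall inside
clusters; the acceptance fixture uses N/CM/TM/EM/TE proportions
.35/.25/.18/.14/.08, chosen from the cumulative-proportion geometry before
any test was run so that every boundary bin has a clear majority cluster.
With arbitrary proportions a sixth short stage can appear (the README's
worked example shows one); that is a property of median-then-discretize
merging, not a bug.

Marker contributions are $100\,\ell_m^2 / \sum_k \ell_k^2$ on the
standardized PCA loadings — non-negative, summing to 100, invariant to the
component's sign. Markers with negligible variance relative to the most
variable marker (ratio $< 10^{-3}$) are excluded with a warning, because
standardization would otherwise inflate pure jitter to unit variance.

## 5. Database-guided automated gating

`build_reference()` pools labeled events per taxonomy node (a node owns
its subtree's events) and stores mean vectors and covariance matrices over
the gating markers in transformed space, with shrinkage
$(1-\lambda)S + \lambda\,\mathrm{diag}(S)$, $\lambda = 0.1$ by default.
Populations with fewer than 3 pooled events are omitted with a warning.

`auto_gate()` walks the tree top-down. At each level the discriminating
markers are the union of the markers constrained by the children's rules
(which reproduces the sequential marker sets: {CD45, SSC} → {CD3} → {CD4}
→ {CD25, CD127, CD185} → receptors + maturation markers). An event joins
the sibling minimizing the Gaussian discriminant score
$d^2_\Sigma(x,\mu) + \log|\Sigma|$ — the log-determinant term is needed
because internal nodes that pool maturation stages are broad, and plain
Mahalanobis lets broad clusters swallow tight ones (naïve cells would leak
into other-memory); the score reduces to plain Mahalanobis for equal
covariances and to nearest-centroid under identity covariance, which the
tests verify against an independent tree-walking oracle.

The novelty gate is `max_radius = 4` interpreted as a **χ²
quantile-equivalent** radius: with $m$ markers at a level, an event is
gated out when $d^2 > \chi^2_m$-quantile matching the two-sided 4σ
univariate content ($p = 1 - 6.3\times10^{-5}$). A literal $d \le 4$ gate
would discard $P(\chi^2_7 > 16) \approx 2.5\%$ of perfectly genuine events
at a 7-marker level — a dimension-dependent false-exclusion rate that
contradicts the design goal of a quantile-equivalent gate. Ties in the
score break by higher prior then lexicographic name, so the procedure is
deterministic end to end; re-running on the same sample and database gives
bit-identical results (acceptance target t5 measures exactly this in two
fresh processes).

The ≥10-event cluster rule applies to *reporting*, not assignment:
populations with fewer assigned events than `min_cluster` are suppressed
from the report but keep their counts internally, preserving conservation.
Levels whose children all lack reference statistics keep their events in
the unclassified bin rather than erroring (only an empty root is a hard
error): with small reference cohorts, deep stage splits legitimately lack
statistics, and failing the whole sample over them would make the tool
unusable.

## 6. Agreement, reference intervals and group comparison

* **Agreement**: per population, squared Pearson correlation across paired
  samples (with its p-value) and the mean normalized bias
  $\mathrm{MNB} = \mathrm{mean}\,100(b-a)/a$, reference = first argument
  (the convention that makes "overestimation by the second analyst"
  positive). Concordance requires $r^2 \ge 0.9$, $p \le 0.05$ and
  $|\mathrm{MNB}| \le 15\%$, all configurable. Zero-reference pairs are
  excluded from the MNB with a warning; populations missing in either
  analysis are counted separately as "not identified". Whether the ±15%
  band applies to percentages or absolute counts is not fixed by the
  concordance definition; the package applies it to percentages of parent
  (the scale-free choice) and any other paired quantity can be passed in.
* **Canonical variates**: Fisher discriminant axes from between/within
  scatter of standardized markers, shrinkage-regularized when
  ill-conditioned, contributions as normalized squared loadings on CA1.
* **Reference intervals**: per population × age band order statistics
  (min, p10, p25, p50, p75, p90, max by default) with **type-7** linear
  interpolation — the R default, chosen for reproducibility with the
  statistical tooling such cohorts are typically processed with. Default
  bands: CB (cord blood, pre-birth label), [2mo,2y), [2,5), [5,10),
  [10,18), [18,40), [40,60), [60,80), [80,120) years — anchored at the
  breakpoints that matter for lymphocyte kinetics (2 months, 2, 18, 40, 80
  years) and fully configurable. Bands with fewer than 10 samples are
  flagged rather than refused. Patient profiles are flagged low/normal/high
  against the band's p10/p90.
* **Mann–Whitney U**: exact two-sided p-values (doubling rule) — via the
  classical null distribution of U for groups ≤ 20 without ties, via full
  enumeration of all $\binom{n_1+n_2}{n_1}$ assignments when ties are
  present and enumeration is feasible (≤ 2×10⁵ arrangements), and the
  tie-corrected normal approximation with continuity correction otherwise.
  Full enumeration with ties at 20 per group would be ~10¹¹ arrangements;
  the exact bound the tests guarantee is agreement with brute force for
  ≤ 8 per group, and the approximation is verified to agree with
  enumeration within 0.01 at n = 8. No multiple-testing correction by
  default (matching common practice for descriptive cohort comparisons);
  callers can correct externally.
* **Stain index**: $(\mathrm{median}_{pos} - \mathrm{median}_{neg}) /
  (2\,\mathrm{SD}_{neg})$ on raw intensities — the reagent-separation QC
  metric; scale-free by construction.

## 7. The synthetic world

The generator is a *stated world*, not a dial. Every taxonomy leaf gets a
template: one discrete level per marker, realized as independent Gaussians
in transformed space around the level anchors neg = 0.3, lo = 1.0,
pos = 2.2, hi = 3.2 display decades with SD 0.25 (≈25% of the
smaller inter-level gaps; the anchors are invented but logicle-plausible,
as no intensity scales exist to copy). Events are inverse-transformed to
raw intensities; scatter lives on a linear scale (anchors × 5×10⁴).
Optional synthetic spillover is mixed in so compensation is exercised.
Three filler populations (monocytes with high SSC, CD3− lymphocytes,
CD3+CD4− T cells) keep pre-gating non-trivial. All randomness is seeded;
the same spec reproduces a sample bit for bit, and cohort samples derive
seeds as `base_seed + index`.

Age-band frequency plans encode the qualitative kinetics — cord blood
naïve-dominant with Th2 present and Th1/Th17, Th22 absent and TFH near
zero; memory fractions and late stages growing with age — with illustrative
numbers, *not* measured cohort values (reproducing those is explicitly out
of scope). Per-marker independence within a population (diagonal
covariance) is the simplest model that exercises every stage; real data
have correlated channels, autofluorescence, debris and doublets, none of
which the generator emulates. A green test therefore establishes the
*engine's* correctness (partitioning, determinism, recovery of a known
truth), not instrument-level realism.

Two test worlds deserve a note. The "6-SD separation" world for automated
gating uses `noise_scale = 0.65`, which makes the smallest used anchor gap
(pos→hi, 1.0 decades) ≥ 6 SD; the ≥99.9% recovery example additionally
restricts templates to leaves with frequency ≥ 0.002 so every population's
reference covariance is estimated from enough events for the Gaussian
tail-bound argument to apply — with ~10-event reference populations the
bound's known-parameter assumption fails, and accuracy is bounded by
estimation error, not separation.

## 8. Known limitations

* FCS reading covers the dialects the writer and mainstream cytometers
  emit; exotic features (multiple datasets per file, `$PnE` log-amplified
  integers, analysis segments) are not parsed.
* The taxonomy's "up to 161" extension and per-Treg/TFH stage splits
  beyond the default set are not enumerated; the default tree already
  exceeds the guaranteed 89.
* The maturation axis is a single linear component; strongly non-linear
  trajectories would need a principal curve, accepted as out of scope.
* Automated gating assumes the new sample shares the database's transform
  and panel; no cross-instrument normalization is attempted.
* CLI configuration is JSON (not YAML): no YAML parser is available in the
  supported dependency set, and JSON round-trips the run configuration
  losslessly with `jsonlite`.
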