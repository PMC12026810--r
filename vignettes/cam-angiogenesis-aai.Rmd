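---
title: "Quantifying CAM angiogenesis and the angiogenic activity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CAM angiogenesis and the angiogenic activity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camAAI)
```

## The assay and the measurement problem

The chick chorioallantoic membrane (CAM) assay scores how strongly a test
substance stimulates blood-vessel formation.  A ring placed on the membrane
delimits a region of interest; the vascular network inside the ring is
photographed before treatment (day 0) and on treatment days 2, 4 and 7, and a
set of morphometric parameters is recorded per embryo and day: the number of
junctions, total and mean vessel length, vessel density, the branch
hierarchy, embryo survival, and (once, at the end) the thickness of the
membrane.  Because baseline vascularization varies between eggs, every
longitudinal parameter is normalized per embryo as a fold change over its own
day-0 value before group averaging.

camAAI implements this pipeline from the point where a vectorized vessel
network (or an already-tabulated metrics table) exists.  Segmentation of raw
micrographs is deliberately out of scope: in practice these measurements are
traced manually, and the package's contribution is to make everything
downstream of the tracing reproducible.

## Vessel-network morphometrics

A network is a planar skeleton graph: nodes with coordinates in micrometres
and edges carrying the vessel centerline as a polyline.  Several conventions
are needed to make the visually scored quantities well defined; they are the
package's own definitions, recorded in every report's metadata:

* **Canonical segments.** `canonicalize()` merges chains through nodes of
  graph-degree 2, so a *segment* (a "sprout") is a maximal path between
  junctions and/or free ends.  Total length is conserved exactly and the
  operation is idempotent.  Closed loops — which do not occur in tree-like
  CAM networks — are kept as two arcs rather than a self-loop edge.
* **Junctions** are nodes of graph-degree at least 3 after
  canonicalization.
* **Vessel density** is total vessel length per ROI area, in um/mm^2
  (1 mm^2 = 1e6 um^2).  Other conventions exist (e.g. area fraction); this
  one needs no vessel calibre information and behaves linearly under
  sprouting.
* **Branch degree** is generation order: designated feeder segments
  (*roots*) are first degree, and each segment reached by breadth-first
  traversal is one degree deeper than its predecessor, capped at four —
  only first- to fourth-degree sprouts are scored.  Generation order was
  chosen over Strahler order because it matches how an observer follows
  vessels inward from the feeders; it is a decision, not the only
  defensible one.  Ties in the traversal are broken by ascending edge id so
  the assignment is deterministic.  When no roots are designated, segments
  touching the ROI outer boundary (within 1% of the outer radius) are taken
  as feeders, falling back to the longest segment; segments unreachable
  from any root are flagged with a warning and assigned degree 4, so branch
  counts always sum to the segment count.
* **Branch hierarchy** is the ratio of third- plus fourth-degree counts to
  first- plus second-degree counts, undefined when the denominator is zero.

## Fold changes, survival, and the AAI

For each parameter `i`, group `g` and day `d`, the angiogenic response
`AR(g, i, d)` is the group mean of per-embryo fold changes over day 0
(`AR = 1` at day 0 by construction).  The per-parameter index compares
baseline-corrected changes of a treatment group `t` against the control `c`:

\[
\mathrm{AAI}_i \;=\;
\frac{\bigl(AR_{t,d} - AR_{t,0}\bigr) - \bigl(AR_{c,d} - AR_{c,0}\bigr)}
     {AR_{c,d} - AR_{c,0}},
\]

and the final AAI is the arithmetic mean of the per-parameter indices.  An
index of 0 means control-level activity and 1 means the treatment's
baseline-corrected change is double the control's.  (A commonly quoted
reading of −1 as "halved angiogenesis" is inconsistent with the formula —
under it, halving corresponds to −0.5 and −1 to no baseline-corrected change
at all; the implementation follows the formula.)  The index depends only on
the ratio of differences and is therefore invariant under any common affine
rescaling of the responses, a property the test suite checks directly.

Six parameters enter the final AAI by default: survival, junctions,
hierarchy, total vessel length, vessel density and CAM thickness.  Mean
vessel length is tabulated in the profile but not averaged into the index.
Three parameters need special handling, each a documented design choice:

* **Aggregation.** Fold changes are averaged within group first and the
  index is applied to group means (matching how such data are reported);
  per-embryo dispersion is carried alongside as an SD.
* **Hierarchy.**  The group-level ratio is computed from branch counts
  summed across the embryos measured that day, which stays defined even
  when individual embryos have no low-degree branches; per-embryo ratios
  are reported for dispersion.
* **Survival** enters through the Kaplan-Meier product-limit estimate,
  `AR = S(day)` with `S(0) = 1`; curves and the Mantel-Cox log-rank test
  are delegated to the `survival` package and verified against
  hand-computed tables.  If both groups survive identically the control
  change is zero and the parameter is excluded with a logged reason instead
  of producing 0/0.
* **Thickness** is measured only at the final day, so its index is the
  relative difference of group medians (medians because such single-day
  thickness data are skewed and reported as median with IQR).

Degenerate controls are detected with an absolute tolerance of 1e-9 on the
control change; excluded parameters never abort a profile, they are listed
with reasons in the report and the final AAI averages what remains.

## The synthetic cohort generator

No public per-embryo CAM tracing data exist to test against, so the package
ships a generator whose statistical structure matches what the scoring
pipeline assumes, together with a closed-form oracle.  Defaults emulate a
three-group study — a medium control and two treatment groups of 17 embryos
each, observed on days 0, 2, 4 and 7:

* **Day-0 network**: six feeder trees entering the ROI (a 3 mm-radius
  disk), each a complete binary tree of depth four with deterministic
  generation lengths (400, 300, 220, 160 um) — 90 segments, 42 junctions,
  18.96 mm of vessel, random only in orientation.  Realistic CAM fields are
  denser; this size keeps simulated cohorts cheap while leaving relative
  sampling noise comparable to a carefully traced subfield.
* **Growth**: between observations every terminal segment bifurcates with
  probability `1 - exp(-rate x multiplier x days)`; a bifurcation adds one
  junction and two log-normal-length sprouts (median 120 um, sdlog 0.35)
  one generation deeper.  The control rate (0.0232 per tip-day) and the
  treatment multipliers (5.27 and 7.46 for sprouting; 0.60 and 0.48 for
  sprout length) are calibration constants chosen once so that expected
  day-7 fold changes sit at typical control/treated CAM values — junctions
  1.19 vs 2.07 and 2.54, total length 1.11 vs 1.36 and 1.42.  They live in
  the configuration object, not in code.
* **Deaths** occur at whole observation days (per-interval hazard
  `1-(1-h)^days`, default h = 0.015/day for every group, i.e. comparable
  survival across groups); dead embryos have no further metric records.
* **Thickness** for survivors is normal around 59 um (control) with group
  shifts of +17.2 and +21.5 um, SD 8 um, truncated at zero.
* **Randomness**: each embryo derives growth, death and thickness
  substreams from the single configured seed, so enlarging a cohort never
  perturbs existing embryos, and everything is reproducible.

Because the day-0 network is deterministic and every increment is linear in
the bifurcation count, the expectation of each fold change is available in
closed form (`expected_outcome()`); first and second moments of the
bifurcation process follow an exact recursion that the tests verify against
brute-force enumeration.  Two oracle values are reported per index: the
*ideal* index evaluated at the exact process expectations (0 for identical
groups, by construction), and the *sampling mean* — the expected value of
the cohort estimator itself at n = 17, which differs because the index is a
ratio of group means.  Fold-change parameters carry a second-order
delta-method correction from the exact variances; the survival index is
computed by exact binomial enumeration conditional on at least one control
death; the thickness correction is of order `Var(median)/median^2` (about
0.2% here) and is deliberately omitted.  Parameter-recovery tests simulate
200 cohorts and require the mean pipeline-computed index of every parameter
to fall inside the 99% Monte-Carlo interval of the sampling-mean oracle.

What the generator does *not* emulate is as important as what it does:
measurement error of manual tracing, biological between-embryo
heterogeneity beyond sprouting stochasticity, vessel regression and
remodelling (growth only appends, so mean vessel length can only fall
through sprouting), and any dependence between vessel growth and embryo
death.  Two consequences are visible in its output: vessel density is
exactly total length divided by a fixed ROI area, so its fold change
coincides with total length's; and junction and hierarchy fold changes are
both affine in the bifurcation count, so their indices coincide too.  Real
data decouple these parameters; passing recovery tests therefore
demonstrates correctness of the arithmetic and the estimator, not realism
of the biology.  For the same reason the generator's final AAI values
(about 2.4 and 3.4 for the default treatments) are not comparable to
indices computed on real cohorts, where small and noisy control changes can
inflate the ratio substantially.

## In vitro assay arithmetic

The scratch wound-healing readouts are `(1 - area_t/area_0) x 100` (closure
by area) and the five-position mean width expressed as a percent of
baseline.  Width results are emitted both as remaining width and as its
complement (reduction), clearly labelled, because both conventions appear
in practice; the five positions are summarized by their arithmetic mean.
Relative qPCR expression uses `2^-(CT_target - CT_housekeeping)`, with
technical replicates averaged on the CT scale, and treatment effects as
`2^-(dCT_treated - dCT_control)`.

## Numerical and interface choices

* Lengths are validated against their polylines at 1e-6 relative tolerance;
  metric identities (mean x count = total, density = length/area) hold to
  1e-9 relative.
* All floating-point CSV/JSON report output is serialized at 6 significant
  digits; computation is full precision, and repeated runs with the same
  inputs are bit-identical.
* Two ingestion modes (`graphs` and `metrics`) exist because many CAM
  datasets are hand-tabulated; both feed the identical scoring path and a
  test pins their equivalence on the same cohort.
* Graphs travel as a versioned JSON schema or GraphML; tables as RFC-4180
  CSV.  Problem sizes in the shipped tests (cohorts of 17 x 3 groups, 200
  recovery replicates, 100 random oracle graphs) were chosen so the whole
  suite runs comfortably on a laptop core.

## Known limitations

* Branch "degree" as generation order is one reading of visually scored
  hierarchy; Strahler or calibre-based orders would give different counts
  on the same network.
* The AAI has no distribution theory here — no confidence intervals are
  reported, and with a small control change the index is numerically
  unstable by construction (the degenerate-control guard only catches the
  exact-zero case).
* Printed final AAI values from manually measured studies are generally not
  recomputable from their printed group summaries, because survival,
  hierarchy and thickness enter through conversions that publications
  rarely spell out; this package fixes one documented convention for each.
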