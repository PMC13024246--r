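---
title: "Methods: stratified lipidomic differential abundance and stability selection"
author: "lipidshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified lipidomic differential abundance and stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidshift)
```

## Scope and model of the data

`lipidshift` analyzes targeted lipid panels measured in a two-group
(case/control) plasma study: a wide table of non-negative concentrations
(samples x species, micromolar-like scale) with species named in LIPID MAPS
shorthand. Five headgroup classes are supported — acylcarnitines (CAR),
diacyl phosphatidylcholines (PC), lysophosphatidylcholines (LPC),
ether-linked phosphatidylcholines (PC O-) and sphingomyelins (SM) — the
composition of a Biocrates p180-style lipid module. All statistics are
rank-based or median-based, so only the monotone structure of the
concentrations is assumed; the log-normal model appears solely in the
synthetic generator.

## Nomenclature parsing and structural stratification

`parse_lipid_name()` implements the subset of the shorthand grammar these
panels use. Species-level names (`PC 36:0`, `SM 34:1;O2`) are stored as one
*aggregate* chain: quantitative kits report sum compositions, and inventing
an sn-1/sn-2 split would add information the measurement does not carry.
Molecular-species names (`SM 18:1;O2/26:0`) are resolved per chain. Two
dialect forms occur in practice and are normalized with a recorded note: the
Unicode minus in `PC O−` and the suffix `;2.0`, which matches no shorthand
production and is read as two oxygen modifiers (`;O2`), its only
LIPID-MAPS-consistent interpretation. Oxygen modifiers are stored
generically as oxygen counts — the notation does not distinguish hydroxyl
from other oxygenation, so neither do we.

Structural stratification derives, per species, the Total FA metric (the
summed carbons and double bonds of all esterified chains — not free fatty
acids), total oxygens, the ether-bond flag, and a saturation class from the
species-level double-bond total (0 saturated, 1 mono-, 2 di-, >=3
polyunsaturated). Classification into LIPID MAPS category/subcategory/
subclass codes is a closed deterministic map of the headgroup class
(e.g. PC O- is GP0102, 1-alkyl,2-acylglycerophosphocholines).

## Biophysical annotation is a rule table, not a simulation

Membrane-biophysics labels (bilayer thickness, lateral diffusion, intrinsic
curvature, functional role, dominant cellular component) are assigned by
pure lookup in a packaged, versioned rule table
(`inst/extdata/biophys_rules.tsv`) keyed on headgroup class and bins of
total carbons / double bonds. The rules encode standard qualitative
relationships — thickness scales with chain length, diffusion inversely;
polyunsaturation (>= 4 double bonds) thins and mobilizes by one ordinal
level; the sn-1 ether bond adds one level of rigidity; lyso and carnitine
species are non-bilayer lipids with positive intrinsic curvature. Each row
carries a provenance note, and the bin boundaries are explicitly approximate
package defaults: no internal reference database for such labels is
published, so the table is reconstructed, documented and user-replaceable.
Any species outside rule coverage raises an annotation-gap error naming the
missing key rather than guessing.

## Synthetic cohort generator

The generator exists so every downstream stage is testable without patient
data. Its defaults encode the emulated study design: 30 cases vs 11
controls, 124 species (50 PC > 22 LPC >= 20 SM > 18 PC O- > 14 CAR), and a
log-normal abundance model — log2 concentration = species baseline + group
shift x 1[case] + Normal(0, sigma^2) noise, exponentiated to the linear
scale. Baselines are class-typical plasma magnitudes stored in the packaged
panel file; they are synthetic values, not estimates from any cohort.
`noise_sigma = 0.5` is the default within-group spread so that a log2 shift
of 1 is a standardized effect of 2 — a strong but realistic biomarker-scale
effect that gives reliable recovery at n = 30/11. `cll_effects()` implants
the qualitative enrichment pattern reported for treatment-naive CLL plasma:
+1 on 18 enriched species (CAR 12:0 at +2, the dominant acylcarnitine
signal), -1 on the two depleted species (PC 34:1, PC 26:0). Within-class
equicorrelation of the log-scale noise is available (`class_rho`) but off by
default: it lets tests probe selection behavior under collinearity without
asserting unmeasured structure.

What the generator does **not** emulate: limit-of-detection censoring, batch
and matrix effects, heteroscedastic or heavy-tailed noise, and real
inter-lipid correlation structure. Tests passing on this generator therefore
demonstrate correctness of the computations and recoverability of implanted
signal under idealized noise — not clinical performance on real plasma.

## Differential abundance

Transformation is `log2(x + delta)` per species with `delta` = half the
smallest positive value when zeros are present (0 otherwise); all-zero
species are dropped with a warning. Group comparison uses the two-sided
Wilcoxon–Mann–Whitney test — exact enumeration when the pooled n is <= 16
with no ties, otherwise the normal approximation with tie and continuity
correction (the regime at the emulated n = 41). Fold changes are pseudo
fold changes of medians, `(median_case + eps) / (median_control + eps)`,
with `eps` = half the smallest positive pooled value engaged only when a
median is zero. Significance combines Benjamini–Hochberg adjusted p < alpha
(0.05) with a fold-change magnitude filter `max(fc, 1/fc) > 1`; the
magnitude form makes the filter symmetric in direction, since both enriched
and depleted species are reportable, and at threshold 1 it excludes only
exact ties.

Stratified analysis (`de_by_level()`) aggregates each stratum as the
per-sample **sum** of member-species concentrations — total class abundance,
conserving mass — and repeats the same test per stratum. BH families are per
level: the species family is adjusted separately from, say, the class
family, matching how class-level adjusted p-values are conventionally
reported alongside species-level ones. PCA operates on feature-standardized
log2 abundances (constant features dropped with a warning); hierarchical
clustering uses Euclidean distance and complete linkage on z-scored values —
no metric is canonical for such panels, so the defaults are declared and
configurable.

## Shadow-attribute stability selection

The selector is Boruta-style: each iteration appends one permuted shadow
copy of every non-rejected feature (padded to at least 5 shadows), fits the
importance backend, and scores a hit for undecided features whose importance
exceeds the iteration's maximum shadow importance. From iteration 5 onwards
a two-sided binomial test of the hit count against Binomial(iterations, 0.5)
at p < 0.01, Bonferroni-adjusted across the undecided features
(`mc_adjust = TRUE`), confirms (excess hits) or rejects (deficit); rejected
features leave the model and stop contributing shadows, undecided features
at `max_iter = 100` remain tentative and are conservatively counted as not
confirmed. These defaults mirror the widely used R implementation of the
algorithm. The shadow pool is configurable: `shadow_pool = "all"` keeps a
permuted copy of *every* panel feature in play, so the null-reference bar
(the maximum over ~124 permuted importances) never weakens as features are
decided. That variant makes single-run confirmations on pure-noise data
rare but pays for it with substantial power loss on weakly realized true
effects in the 29-sample subsample condition; the canonical shrinking pool is the
default because recovering true discriminators is the protocol's purpose and
the two-condition stability gate plus shadow ratios are the intended guards
against chance confirmations (see limitations).

The default importance backend is permutation importance from a 200-tree
extremely-randomized-trees ensemble (`ranger`, single-threaded for
reproducibility). The original analysis this emulates used random-ferns
importance; the shadow-comparison contract — not the specific ensemble —
defines the method, so the backend is a plugged function `(X, y, seed) ->
named importances` and a ferns backend can be substituted without touching
the protocol. One visible consequence: permutation importances are centered
near zero under the null, so `Ratio_to_ShadowMean` values are much larger
than with positively-scaled ferns importances; ratios are comparable within
a backend, not across backends.

The stability protocol runs the selector 100 times on stratified 70%
subsamples (per-group proportional, rounded half-up — simple subsampling
could leave 11 controls degenerate) and 100 times on the full data, with
distinct seeds derived from one base seed. A feature is *stable* when
confirmed in more than half of the runs in both conditions. `medianImp` is
the median, over all confirming runs of both conditions pooled, of the
feature's per-run mean importance — a definition stable to runs of differing
iteration counts; shadow ratios divide `medianImp` by the median per-run
shadow maximum / mean.

## ROC screening

AUC is the normalized Mann–Whitney U with half credit for ties, oriented so
AUC >= 0.5 with the direction recorded. Confidence intervals use the DeLong
placement-variance estimate with normal quantiles, truncated to [0, 1]; when
the placement variance is exactly zero (perfect separation) a seeded
stratified bootstrap (2000 resamples, percentile interval) takes over. The
operating threshold maximizes Youden's J over midpoints between consecutive
distinct pooled values with infinite sentinels — midpoints are standard and
make the reported sensitivity/specificity invariant under strictly
increasing transforms; ties are broken toward higher sensitivity, then lower
threshold. Screening gates are strict inequalities (AUC > 0.80,
sensitivity > 0.70, specificity > 0.80) per their conventional "greater
than" reading.

## Gene–lipid network

Significant species are mapped to candidate lipid-metabolizing enzymes by a
packaged association table (gene, selector, provenance), where selectors
resolve to exact species, headgroup classes, or LIPID MAPS subclasses. The
packaged table is a curated synthetic stand-in assembled from standard
enzyme–substrate class annotations (CPT2 <-> acylcarnitines, SMPD3 <->
sphingomyelins, LPCAT1–4 <-> LPC reacylation, ENPP6 <-> lyso/ether choline
lipids, ...); full reaction-path tables are not reproducible from public
text, so the file documents each row and is user-replaceable. Generic
uninformative node labels (packaged blocklist, e.g. "Carnicor") are filtered
before construction. The graph is strictly bipartite (violations are
errors), degree centrality is degree/(n-1), node size scores are degrees
min-max scaled to [1, 10], and 2D coordinates come from the seeded
Kamada–Kawai stress layout with a post-hoc minimum-separation nudge.

## Numerical and design choices

* Exact-vs-approximate Wilcoxon switch at pooled n > 16 or any tie,
  continuity correction on — the common statistical-package behavior.
* One root seed per pipeline run derives all stage seeds by fixed offsets;
  runs with equal manifests produce byte-identical tabular outputs.
* Pipeline outputs are TSVs with a comment header recording stage, version
  and parameters; a JSON manifest records input hashes, seeds and stage
  outputs.
* Worked problem sizes: the test suite exercises the full protocol at a
  reduced replication (R1 = R2 = 25, 10 cohort seeds) and the selector's
  null behavior at 50 seeds of a 41 x 124 noise matrix; these sizes give
  stable Monte-Carlo estimates at desk-scale runtime.

## Known limitations

* **Chance in-sample associations bound exact-set recovery and single-run
  null calibration.** At n = 30/11 with ~120 candidate species, a sizable
  share of realized cohorts contains at least one null species whose
  realized association with the group labels approaches a weakly-realized
  true effect (occasionally a null with a non-location association even
  out-ranks a true feature). An all-relevant selector is designed to confirm any feature
  carrying in-sample signal, so such species are confirmed in the full-data
  condition almost always; the 70% subsample condition removes them only
  when their realized effect is modest. Exact recovery of an implanted
  seven-species set therefore plateaus around 70% of cohorts at this design
  size under the canonical defaults (the implanted features themselves are
  recovered in almost every cohort), and single shadow runs on pure noise
  confirm at least one chance feature in a substantial fraction of realized
  noise matrices unless `shadow_pool = "all"` is used. These are properties
  of the design size and the all-relevant semantics, not of a particular
  backend, and they are the reason the protocol reports confirmation counts
  and shadow ratios rather than a bare feature list.
* The biophysics rule table's ordinal bin boundaries are approximate and
  editable; they preserve the qualitative headgroup/chain relationships, not
  any measured thickness or diffusion scale.
* Importance magnitudes (`medianImp`, shadow ratios) are backend-specific
  scales, meaningful for ranking within one analysis.
* No covariate adjustment, paired designs, or multi-class labels.
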