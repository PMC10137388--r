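---
title: "Comparing microalgal strain lipidomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microalgal strain lipidomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algalipids)
```

`algalipids` implements the quantitative core of a multi-strain lipid
comparison for microalgae: GC-MS fatty-acid (FAME) profiling with lipid
nutritional quality indices, internal-standard-normalized LC-MS lipidomics,
radical-scavenging and COX-2 bioassay analysis, and a gated multi-group
statistical workflow. Its running example is a panel of four edible
*Chlorella vulgaris* strains — one autotrophic (C-Auto) and three
heterotrophic (C-Hetero and its chlorophyll-deficient mutants C-Honey and
C-White) — with five biological replicates per strain.

## Fatty-acid profiles

FAME peak areas are normalized by the methyl nonadecanoate (C19:0) internal
standard and expressed as percent of the summed normalized areas
(`fa_relative_abundance()`). Because the internal-standard area is a common
per-sample factor, it cancels in the percentage: profiles are invariant to
the IS scale, and the tests assert this property directly. Profiles close to
100% by construction; class sums (`fa_class_sums()`) partition the total
into SFA/MUFA/PUFA (0, 1, ≥2 double bonds), omega-3 and omega-6 totals over
PUFA members, and per-double-bond-count bins (monoenoic … hexaenoic).

Shorthand such as `C18:3(n-3)` is parsed by `parse_fa_shorthand()`; both the
ASCII hyphen and the typographic minus are accepted (extracted tables often
carry the latter), and the canonical form uses the hyphen.

## Nutritional quality indices

Five composition-based indices are computed per replicate
(`quality_indices()`), with group values summarised afterwards as
mean ± SD — not computed on a mean profile:

* atherogenic index
  $AI = \frac{C12{:}0 + 4\,C14{:}0 + C16{:}0}
             {\sum MUFA + \sum n\text{-}6 + \sum n\text{-}3}$
* thrombogenic index
  $TI = \frac{C14{:}0 + C16{:}0 + C18{:}0}
             {0.5\sum MUFA + 0.5\sum n\text{-}6 + 3\sum n\text{-}3 +
              \sum n\text{-}3 / \sum n\text{-}6}$
* hypocholesterolemic/hypercholesterolemic ratio
  $h/H = \frac{cis\text{-}C18{:}1 + \sum PUFA}{C12{:}0 + C14{:}0 + C16{:}0}$
* peroxidation index
  $PoxI = 0.025\,\%mono + 1\,\%di + 2\,\%tri + 4\,\%tetra + 6\,\%penta +
          8\,\%hexa$
* the $n\text{-}6/n\text{-}3$ ratio.

Three choices deserve comment. First, the final TI denominator term is the
*quotient* $\sum n\text{-}3/\sum n\text{-}6$ (the standard
Ulbricht–Southgate form); the product reading would put TI two orders of
magnitude below its conventional range. Second, $cis$-C18:1 in $h/H$ is the
sum of all C18:1 isomers present (n-9 plus n-7): on the bundled reference
panel only this convention reproduces the reported C-Auto value of 4.7 (the
n-9-only variant gives 4.5). Third, fatty acids absent from a panel (C12:0
in the reference data) contribute zero to every term, so the indices are
computable on any panel.

A caveat on invariance: AI, $h/H$ and $n\text{-}6/n\text{-}3$ are ratios of
linear forms and therefore exactly invariant when all abundances are
rescaled; PoxI is homogeneous of degree one. TI is *not* exactly
scale-invariant on raw vectors — its quotient term is degree-0 inside a
degree-1 denominator — but it is invariant on its intended domain, the
closed percent profile, which is what the pipeline always feeds it.

Recomputing the indices from a *rounded* published composition table leaves
small residuals against values computed from unrounded replicate data: on
the bundled reference panel TI comes out at 0.149 for C-Auto (reported 0.2)
and AI at 0.449 for C-White (reported 0.5). These are properties of the
rounded inputs, not of the formulas; the package reports full precision and
rounds only for display (1 d.p. by default).

## Lipidome quantification

LC-MS species are parsed from `CLASS(C:DB)` shorthand with an optional
variant letter for acyl-combination isomers, which remain distinct rows
throughout. Each species is normalized by the internal standard with the
*closest retention time* — deliberately not by class matching, mirroring
the acquisition protocol — with ties broken toward the lower-RT standard
for determinism. Relative abundances divide each normalized area by the
per-sample total; columns sum to one to within 1e-9, and scaling any
standard together with its assigned species cancels exactly.

Aggregation sums the eleven classes into glycolipids (MGDG + DGDG + SQDG),
phospholipids (PC + LPC + PE + PG + PI) and TG. Ceramides and
diacylglycerols belong to none of the three main groups; whether they stay
in the denominator is genuinely open in the source protocol, so
`aggregate_groups()` emits both conventions (`denominator = "all"` keeps
them; `"groups_only"` recloses over GL/PL/TG).

## Bioassays

Scavenging inhibition uses the three-well correction
$100\,(Abs_{radical} - (Abs_{sample} - Abs_{control}))/Abs_{radical}$.
IC20/IC50 are obtained by piecewise-linear interpolation between the two
observed concentrations bracketing the target level — with only four
tested concentrations and no stated model, a sigmoidal fit would add
assumptions the data cannot check; no extrapolation is performed and an
unreached level returns `NA` ("not reached"), distinct from an error.
Curves are anchored at the origin (zero dose, zero inhibition, defined by
the radical-only well), which lets a level below the lowest tested
concentration still be bracketed — necessary for Trolox, whose IC20 sits
far below its lowest tested dose.

Trolox equivalents use
$TE = \frac{IC_x^{Trolox}}{IC_x^{sample}} \times \frac{10^6}{250.29}$
µmol Trolox per g extract (250.29 g/mol). The printed unit notation of the
source equation is internally inconsistent, so the convention was fixed
empirically: the two reported DPPH IC20/TE pairs imply the same Trolox
IC20 (≈2.52 µg/mL) under this convention to within 0.02%, and the test
suite asserts that cross-ratio. A consequence worth noting: an IC20 of
2.5 µg/mL is only consistent with linear interpolation from the origin if
Trolox quenches almost completely at the lowest tested dose; the generator
therefore models Trolox as a near-complete quencher at 12.5 µg/mL in the
DPPH assay, and calibrates the ABTS Trolox curve at its IC50. The ABTS
IC20-based TE values of a real calibration cannot be reproduced by
within-range interpolation at these design concentrations; synthetic ABTS
IC20 TEs are therefore internally consistent but not comparable to
reported ones.

COX-2 inhibition is the fractional drop of the prostaglandin readout
against the uninhibited reference.

## Statistical workflow

Relative abundances are log10-transformed (base 10 fixed for
reproducibility; nothing downstream distinguishes bases). Zeros are
replaced per feature by half the smallest positive value before the log;
all-zero features are dropped with a warning.

Each feature is gated: the parametric branch (one-way ANOVA + Tukey HSD)
runs only if *every* group passes Shapiro–Wilk at α = 0.05 and the groups
pass a median-centred Levene (Brown–Forsythe) test at α = 0.05; otherwise
the rank-based branch runs (Kruskal–Wallis + Dunn). Degenerate features —
a constant group, or fewer than three observations per group — fall back
to the rank branch. Two consequences are documented rather than hidden:
(i) with four groups the null parametric rate is about
$0.95^4 \times 0.95 \approx 0.77$ (slightly higher in practice because
Shapiro–Wilk is conservative at $n = 5$), so roughly a quarter of truly
normal features are tested by ranks; (ii) the source protocol names the
two-sample Mann–Whitney test for four-group data — Kruskal–Wallis is the
applicable k-group analogue and is used instead, keeping the named Dunn
post-hoc. Dunn's test is implemented directly (tie-corrected normal
approximation) as no dedicated implementation ships with the environment.

Omnibus p-values are BH-adjusted *across features* (q-values); pairwise
p-values are BH-adjusted *within* each feature across the six group pairs.
The source protocol does not state the scope of its correction; this
default is the conventional one for feature screens. The top-k selection
takes features with q < 0.05, ascending q, ties broken by feature id,
truncated at k = 50.

PCA runs on centred, unscaled log abundances (`scale.` is an argument;
unit-variance scaling is a defensible alternative and neither choice can be
validated against the unavailable raw data). Component signs are fixed so
the largest-magnitude loading is positive. Hierarchical clustering uses
Ward's method on unsquared Euclidean distances — the classic `"ward.D"`
convention, configurable — and the heatmap matrix shows per-feature fold
difference from the grand mean on a log2 scale; both dendrograms are
computed on that displayed matrix.

## The synthetic-data generator

No raw instrument data are deposited for the motivating study, so
`generate_fa_table()`, `generate_lipidome()`, `generate_dose_response()`
and `generate_cox2_readouts()` emulate its design under a single seed.
Defaults encode the study conditions: 4 strains × 5 replicates; 316 lipid
species across 11 classes with class-typical carbon/double-bond ranges and
retention times inside the 33-min gradient; 10 internal standards with the
protocol's spiked amounts; extract concentrations 25/125/250/500 µg/mL and
Trolox 12.5/62.5/125/250 µg/mL in triplicate.

FA tables draw per-replicate percentages normally around the bundled
strain means with the published SDs, truncate at zero and renormalise —
simple additive noise matching the mean ± SD reporting convention, rather
than a logistic-normal composition model; a limitation worth knowing when
interpreting closure-sensitive statistics.

The lipidome's strain structure is carried by 40 *planted* differential
species placed among the most abundant members of their classes, with
strain-specific abundance folds: galactolipid species up in C-Auto,
TG species up in C-Hetero/C-Honey, PL species up in C-White, a small
SQDG set up in C-Hetero, and a miscellaneous set up in C-Auto. Because the
same planted species are abundant, they simultaneously produce the
strain-level class-composition differences (C-Auto glycolipid-rich,
C-Hetero/C-Honey TG-rich, C-White PL-rich) without touching the remaining
276 species. Two design details matter:

* **Closure control.** Relative abundances are compositional: if the
  planted species' total share differed between strains, every unplanted
  species would shift through the denominator and the screen would fill
  with incidental "significant" background. The fold patterns are balanced
  so each strain's expected planted total is similar, and the realized
  planted totals are pinned to their design expectation (the
  equal-mass-loaded column makes equal expected totals the physically
  sensible choice). The unplanted background is then strain-null, and a
  zero-effect run (`effect_scale = 0`) yields at most α-level discoveries.
* **Normalization-aware intensities.** Closest-RT assignment divides each
  class by a standard with a class-window-specific spiked amount, which
  inflates classes assigned to low-amount standards by up to ~2×. Class
  base intensities are therefore specified in post-normalization terms so
  the intended group ordering (e.g. TG above GL in the heterotrophic
  strains) survives normalization.

Replicate noise is lognormal with CV 0.25 — mid-range for replicated
LC-MS lipidomics — plus a small (CV 0.03) residual on standard areas.
Dose–response curves are saturating hyperbolas $I(c) = I_{max}c/(c+K)$
with $K$ calibrated so that the ICx recovered by *interpolation at the
tested concentrations* equals the template value exactly in the noiseless
limit; extracts that never exceed ~10% inhibition get a far-from-saturation
curve and correctly report "not reached".

What passing generator-based tests shows — and what it does not: the
pipeline recovers planted effects, holds its false-discovery rate on null
data, and reproduces the qualitative ordination/clustering layout
(C-Auto splitting first, then C-White). It does not certify performance on
real data with retention drift, missing peaks, correlated species noise, or
heavier-tailed replicate variation, none of which the generator simulates.
Likewise the published PCA variance split (63.0%/28.2%) and the exact
316-species identities depend on the unavailable raw data and are covered
only qualitatively.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's own scale
(316 species × 20 samples) plus a 2000-feature null screen for the
false-discovery-rate check; everything completes in a few minutes on one
CPU. Tolerances: profile closure 1e-6 (percent) and 1e-9 (fractions);
oracle comparisons 1e-10 to 1e-12; worked-example index values one unit in
the last printed decimal, with PoxI at ±0.2 for source rounding. Ties are
always broken deterministically (lower-RT standard, feature id). Degenerate
inputs error early with the offending sample or standard named.
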