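---
title: "Multiparametric cell-cycle analysis from high-content images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric cell-cycle analysis from high-content images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclegate)
library(dplyr)
```

## The measurement model

Image cytometry can reproduce the classic flow-cytometry cell-cycle
analysis on adherent cells, without detaching them, by quantifying
per-nucleus fluorescence in multichannel images.  The core assumptions
this package builds on are:

* the integrated (summed) intensity of a stoichiometric DNA stain
  (e.g. Hoechst 33342) over a nucleus is proportional to its DNA
  content, so G1 nuclei carry 1x, G2/M nuclei 2x, and S-phase nuclei
  something in between;
* EdU, a thymidine analogue incorporated during replication, marks
  cells that were in S phase during the pulse; its integrated intensity
  is strongly bimodal (negative vs positive populations separated by
  roughly an order of magnitude);
* phospho-histone H3 (S10) mean intensity marks mitotic cells;
  Ki67 mean intensity separates cycling cells from quiescent (G0)
  cells; any further marker (e.g. gammaH2AX for DNA damage) can be
  read out the same way.

The analysis chain is: segment nuclei in the DNA channel, discard
objects touching the field border, compute per-nucleus morphology and
intensity features, remove clumps and debris with a trained linear
classifier, normalise DNA sums to the G1 peak of untreated control
wells, and assign phases with rectangular gates.  Dual-pulse (EdU then
BrdU) labelling extends this to S-phase kinetics.

## Segmentation presets

`find_nuclei()` offers two presets that differ only in splitting
aggressiveness, mirroring the conservative/aggressive pairing familiar
from commercial HCS software: both use an Otsu-initialised global
threshold on a lightly smoothed image (pixels equal to the threshold
are foreground), hole filling and a minimum-area filter.  Preset B
labels 4-connected components as they are; preset M additionally splits
components with a watershed on the distance transform.  M never returns
fewer objects than B; its known failure mode is cutting one elongated
nucleus in two, which inflates the sub-G1 tail of the DNA histogram —
the reason B is the default and clump removal is instead delegated to
the classifier.  The watershed `tolerance` (default 2 distance-map
units) sets the minimum saddle depth between two peaks for a split;
lowering it splits more.

## Morphology features and the singlet classifier

Touching nuclei that segmentation merges into one object would appear
as spurious 4c "cells", so they are removed by classification rather
than geometry heuristics.  Four features drive the default model:

* axial length ratio — minor/major ellipse-equivalent axis, from the
  eigenvalues of the pixel-coordinate covariance (plus the 1/12
  per-pixel variance of the unit square);
* symmetry — the overlap fraction of the mask with its 180-degree
  rotation about the centroid;
* axial small length — the minor axis in pixels;
* roundness — `4*pi*area / perimeter^2` with a Crofton-style
  perimeter (exposed 4-edge count scaled by pi/4), so a disc scores 1.

These are this package's own fixed definitions; their contract is
discriminative power, not equivalence with any particular vendor's
feature set, because the classifier is retrained on whatever features
are present.  Training (`train_singlet_classifier()`) fits an
L2-regularised logistic regression on standardised features, with the
regularisation strength chosen by seeded 5-fold cross-validation, so
around 150 annotated examples per class suffice and training is
deterministic.  The reported `goodness` is a d-prime-style separation
index (difference of class score means over pooled score SD) — this
package's own definition, not comparable across software.  Adding
`phh3_mean` to the feature set can help retain mitotic singlets, whose
condensed chromatin mimics clump morphology.

## G1-peak normalisation and gating

`estimate_g1_peak()` locates the G1 peak as the lowest-intensity major
mode (at least 25% of the maximum density) of a Gaussian kernel density
estimate with Silverman's rule-of-thumb bandwidth.  The lowest-mode rule
makes the estimator robust to G2-dominant populations (e.g. G2-arrested
treatments); the major-mode floor keeps it off sub-G1 debris.  The peak
is estimated from pooled untreated control wells and applied to every
well on the plate, so treatment-induced shifts are visible rather than
normalised away; a manually determined value can be passed instead.

Gates are half-open intervals `[low, high)` per feature, evaluated in
priority order with first-match-wins; a value exactly on a boundary
belongs to the upper gate, and every cell is counted exactly once
(records matching nothing are an explicit "unclassified" bucket).  Two
templates ship with the package:

* `gates_dna_only()`: sub-G1 < 0.75, G1 0.75–1.25, S 1.25–1.75,
  G2/M 1.75–2.5, >G2/M >= 2.5 on normalised DNA;
* `gates_multiparametric()`: G1 = normalised DNA 0.7–1.4, log10 EdU
  sum 3.2–4.3 and pHH3 mean < 300; M = pHH3 mean >= 300 at 2c; S =
  log10 EdU sum >= 4.5; G2 analogous to G1 at 2c.

The intensity bounds are staining-, exposure- and cell-line-dependent
configuration, shipped as a template for one colorectal-carcinoma-like
setting, not universal constants.  The EdU positivity bound (4.5) and
the G2/M DNA windows (1.4–2.5) are this package's defaults chosen to
sit between the template's negative window and the simulator's positive
population; both are plain config values.  The priority order
M > G0 > S > DNA-defined classes resolves overlaps deterministically:
mitosis and quiescence are defined by specific markers and must not be
swallowed by the broad DNA windows, and EdU positivity defines S
regardless of DNA content (which is what makes the multiparametric mode
recover early/late-S cells that DNA-only gating misassigns to G1/G2 —
the package asserts this as a property, multiparametric S >= DNA-only
S on the same cells).  `gates_g0()` adds a G0 gate (G1 conditions plus
Ki67 mean < 200) ahead of G1.

## Dual-pulse S-phase kinetics

With an EdU pulse, an interval `t`, and a BrdU pulse, the fraction of
initially labelled cells that left S during the interval estimates the
exit rate: `deltaS = EdU+BrdU- / EdU+BrdU+`, `T_s = t / deltaS`, and
the doubling time `T_p = k * 100 * T_s / %BrdU+`.  The factor `k`
nominally corrects for the age distribution of a growing population;
its piecewise definition (0.8 below 50 h, 0.7 above) is circular, which
`doubling_time()` resolves with a deterministic two-pass rule: compute
with 0.8, and if the result exceeds 50 h recompute once with 0.7.
`t` is taken as the interval from the end of the first pulse to the
start of the second, but it is an explicit parameter precisely because
conventions differ.  The estimator assumes a minority exits
(`t < T_s`), steady-state S-phase occupancy, and negligible
cross-reactivity between the two labels.

The simulator's counterpart, `simulate_dual_label_counts()`, draws
exits as Bernoulli with probability `t / (t + t_s)` — the probability
that makes the ratio estimator `deltaS` consistent for `t / t_s`, so
round-tripping recovers the configured `t_s` (the package tests this
across `t` of 1, 2 and 4 h).

## What the simulator emulates — and what it does not

`simulation_config()` defaults define the reference study conditions:
512x512 fields, 115 nuclei per field (8 wells x 5 fields then yields
3000–6000 singlet events per condition, the scale at which per-well DNA
histograms are typically built), asynchronous fractions G1 0.50 /
S 0.30 / G2 0.15 / M 0.05, 10% of nuclei in touching clumps of 2–4,
mean G1 nucleus radius 8 px (free parameters in any real setup, where
they depend on magnification and cell line).  Nuclei are ellipses with
axis ratio drawn in [0.7, 1], rendered with 2x2-subsampled coverage and
a Gaussian PSF (sigma 0.6 px) normalised so each nucleus's rendered
integral equals its true integrated intensity exactly; fluorescence
adds in overlaps, and ground-truth labels in overlaps go to the nearer
centre.  Intensities are log-normal per channel and phase with
positive/negative medians at least 10x apart; DNA content is drawn with
~4% CV so the G1/G2 histogram peaks show a realistic ~5% CV after shot
noise.  Noise is Poisson on signal plus background (5 AU/px) plus
Gaussian read noise (SD 2 AU); a parabolic illumination falloff is
optional.

Deliberately not emulated: chromatin texture, cytoplasmic background,
spectral bleed-through, focus drift, camera-specific noise, mitotic
shape change, and debris with non-elliptical geometry.  Passing the
package's recovery tests therefore demonstrates that the analysis logic
is correct under the stated statistical structure — not that any
particular real cell line will be measured this accurately; on real
plates the classifier should be retrained and every gate bound reviewed
against the scatter plots (`plot_gate_scatter()`).

## Numerical choices and degenerate inputs

* Pixel grid: R's 1-based (row, col) indexing with pixel centres on
  integers, matching the rest of the R imaging ecosystem.
* Threshold ties are foreground; gate boundaries belong to the upper
  interval — one convention everywhere.
* Threshold compactness uses the 99th percentile of region intensity
  as its robust maximum, so hot pixels do not define the core.
* `log_edu()` clamps non-positive EdU sums (possible after background
  subtraction) to a tenth of the smallest positive value and reports
  the clamped count.
* A blank field segments to an empty label map, not an error; an empty
  record table flows through classification and gating as an empty
  result.
* Zero-variance classifier features are dropped with a warning; a
  zero pooled score SD makes `goodness` infinite, with a warning.
* All randomness is seed-derived: sampling, rendering noise and
  cross-validation folds each use streams derived from the configured
  seed, so identical configs are bit-identical, including
  `render_field()` run in isolation.

## Problem sizes used in the packaged checks

The package's own validation simulates one condition of 8 wells x 5
fields (~4600 nuclei, ~3600–3900 singlets after border removal and
classification) for end-to-end recovery, a 10-field clump-enriched pool
(~300–400 objects) for classifier training at the 150+150 scale, and
5000-cell dual-pulse draws for kinetics; these sizes give binomial
standard errors comfortably below the 3-percentage-point recovery
tolerance the tests assert.
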