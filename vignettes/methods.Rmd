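---
title: "Counting mixed yeast-bacteria cultures by size-exclusion image cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mixed yeast-bacteria cultures by size-exclusion image cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixcount)
```

## The problem

Sour-beer and other mixed-culture fermentations run *Saccharomyces
cerevisiae* together with lactic acid bacteria such as
*Lactiplantibacillus plantarum*.  Monitoring both populations by colony
plating needs two media, days of incubation, and careful serial dilution;
flow cytometry needs discriminating labels.  Chamber-based image cytometry
offers a third route: load a stained sample into a counting chamber of
known depth, image a few fields, count cells in software, and convert
counts to cells/mL through the chamber volume.

The twist for mixed cultures is that practical nucleic-acid stains
(acridine orange for yeast, SYTO BC for bacteria) all fluoresce in the same
green band, so the two organisms cannot be separated spectrally.  They can,
however, be separated *geometrically*: brewing yeast are large, round cells
(equivalent diameter roughly 6--10 um) while lactobacilli are small rods
(about 1 x 2.5 um).  The method this package implements counts the same
green-channel images twice with two equivalent-diameter gates --
6.0--50.0 um for yeast, 0.5--5.0 um for bacteria -- and reports each
population's concentration.  That is the whole "size exclusion" algorithm;
everything else is careful measurement and bookkeeping.

## The counting model

For each field the pipeline runs:

1. **Background**: the median intensity.  Objects cover a few percent of a
   chamber field, so the median is a robust background estimate.
2. **Threshold**: a pixel is foreground when it exceeds
   `background + (threshold/100) * (max - background)`.  The instrument
   vendor does not document its threshold units; a percentage of the
   background-subtracted dynamic range is scale-invariant and reproduces
   the ordering of the published settings (a strict 25.0 for bright AO
   yeast staining, a permissive 8.0--10.0 in mixed mode).  We make no claim
   of bit-equivalence with the instrument.
3. **Labeling**: 8-connected components, so a diagonal rod one pixel wide
   does not fall apart at the ~0.71 um pixel pitch.
4. **Declustering**: touching cells form one component.  The component's
   Euclidean distance transform is flooded from its maxima; two lobes with
   peak heights `p1 <= p2` separated by a saddle at height `h` are merged
   when `h >= factor * p1` (published factor: 0.90).  A shallow neck
   (saddle close to the lower peak) therefore merges; well-separated lobes
   split.  Each surviving centre collects the component pixels nearest to
   it, so children always partition their parent exactly.  Saddle dips
   smaller than half a pixel are always merged: a thin rod's distance
   ridge ripples by a fraction of a pixel under discretisation, and those
   ripples are not cell boundaries.
5. **Measurement**: area (pixels x pixel area), equivalent diameter
   `2*sqrt(A/pi)`, perimeter by boundary chain tracing with
   Vossepoel-Smeulders diagonal correction, isoperimetric roundness
   `4*pi*A/P^2` clamped to [0, 1], centroid, mean and peak intensity.
6. **Filtering**: inclusive equivalent-diameter gate plus minimum
   roundness.  Every published profile uses roundness 0.00, i.e. no shape
   filtering; the roundness machinery exists so the gate is available.

Concentration for the original sample is

```
cells/mL = count / (fields x field_area x depth x 1e-12)
           x staining_dilution x extra_dilution
```

with counts pooled over fields (same expectation as per-field averaging,
lower variance).  Viability, when a propidium-iodide "dead" channel is
measured, is `(total - dead) / total`.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| chamber depth | um | SD100: 100, SD025: 25 | not printed for the consumables; follows product naming, and every volume computation reads it from `chamber_spec()` |
| field area | um^2 | 1e6 (1 mm^2) | not printed; configurable, only internal consistency matters for truth-vs-estimate round trips |
| pixel area | um^2/px | 0.5 | 10X objective resolution of the instrument class |
| fields per sample | -- | 4 | acquisition protocol |
| fluorescent threshold | % of dynamic range | per profile (8--25) | published per configuration |
| decluster factor | -- | 0.90 | published |
| min. dynamic range (`min_contrast`) | fraction of full scale | 0.08 | a purely relative threshold binarises noise on object-free frames; frames with less contrast than this count zero (see below) |
| staining dilutions | fold | AO/PI 4x, SYTO BC 2x, mixed 2x | from the staining protocols |

## What the simulator emulates -- and what it does not

`sample_field_truth()` draws per-class counts from a Poisson law with mean
`(conc / staining_dilution) x field_area x depth x 1e-12`, places objects
uniformly, and sizes them from truncated normals: yeast diameters
TN(8, 0.75) on [6, 10] um, bacterial width TN(1.0, 0.15) on [0.7, 1.5] um
and length TN(2.5, 0.5) on [1.5, 4] um, orientation uniform.
`render_field()` draws yeast as flat-topped disks and bacteria as capsules,
anti-aliased by 4x supersampling with a sharpened edge ramp so the
above-half-maximum footprint matches the true area; it adds a constant
background (default 5% of full scale) and Gaussian noise (default 1%) and
quantises to 16 bits.

Two generator choices deserve emphasis:

* **Yeast sizes live inside the yeast gate.**  The published mixed-mode
  gate starts at 6.0 um; the method presumes the yeast population sits
  above it.  Had we placed yeast mass below 6 um, mixed-mode yeast counts
  would be structurally low (gate exclusion) and no unbiasedness statement
  could hold.  Sub-6-um objects, should a user configure them, surface in
  the `spillover` diagnostic of `dual_count()` rather than vanishing.
* **Objects are placed wholly inside the field** (margin = object radius),
  so the truth list is an exact counting oracle: no object is clipped by
  the frame border and the border-handling policy (keep border-touching
  objects whose centroid is interior) never has to arbitrate a truth
  object.

What a green test therefore establishes: the pipeline recovers known
counts from images whose point-spread, background and noise are idealised.
What it does not establish: robustness to debris, out-of-focus planes,
flat-field errors, chamber loading artifacts, or dye-specific intensity
distributions -- none of which the simulator models.

## Numerical choices and degenerate inputs

* Threshold comparison is `>=`; at threshold 100 exactly the frame-maximum
  pixels survive, and a flat frame yields an empty mask.
* A frame whose dynamic range `max - background` is below
  `min_contrast x full_scale` counts zero objects.  The threshold contract
  is relative to the frame maximum, so on a frame containing nothing the
  cutoff lands a fraction of a noise-sigma above background and would
  binarise speckle; the guard encodes "no signal, no cells" and is the one
  place the pipeline deviates from a literal reading of the threshold
  rule.  It is configurable down to 0.
* Single-pixel objects have no boundary chain; their perimeter is the
  pixel boundary (4 x pixel side), giving roundness pi/4.
* Roundness is clamped to 1: chain-code perimeters of small discretised
  disks undershoot the true circumference.
* `viability()` clamps dead > total with a warning and reports `NA` for a
  zero total.  `log10_concentration()` returns `NA` with a warning for
  non-positive input; below-detection samples are excluded from log means
  in the demo pipeline.
* Regression with constant response reports R^2 = 0; constant predictors
  are a degenerate-design error.
* Ties in `select_countable()` break toward the less dilute level; with
  no countable level at all, the least dilute level is returned flagged.

## Residual bias of the estimator

The concentration estimator is unbiased to within Monte-Carlo resolution
in monoculture mode at densities up to ~600 objects/mm^2.  In mixed mode
there is a small structural undercount of bacteria that grows with
density: a rod touching a yeast disk forms one component whose
distance-transform saddle equals the rod's own peak height, so the
declustering rule (merge when saddle >= 0.9 x lower peak) absorbs the rod
into the disk.  At 500 bacteria + 200 yeast per mm^2 this costs ~2% of
bacteria; at the 250--300/mm^2 densities the chamber protocol targets
(samples are diluted precisely so that cells lie mostly isolated) the
effect is negligible.  The package does not attempt to undo it: the merge
rule is the documented declustering semantics, and the bias is a property
of crowding, reported here so users know to dilute.

## Design decisions that were genuinely open

* **ANOVA model.**  The comparison layer names only "ANOVA" on per-trial
  averages.  We use one-way ANOVA with counting method as the factor and
  per-trial mean log concentrations as replicates (F on 1 and 2(T-1) df);
  a replicate-level two-way layout with a trial block is available via
  `method_anova(..., blocked = TRUE)`.
* **Percent difference.**  Defined symmetrically,
  `100 |a-b| / mean(a, b)`; the published values cannot disambiguate the
  denominator without raw data.
* **t-test.**  Welch by default; pooled variance optional.
* **Countable-plate ranges.**  25--250 colonies (bacteria), 8--80 (yeast
  spread plates) as configurable artifact conventions, not published
  values.
* **Mixed staining plan carries one green channel.**  The instrument
  nominally uses two channels with identical optical filters; duplicating
  identical images would add nothing, so `dual_count()` applies the two
  gates to the same frames, which is the same computation.
* **Decluster limit behaviour.**  As the factor approaches 0 every saddle
  merges and each component yields one child; at 1.0 splitting is maximal
  (subject to the half-pixel ripple tolerance).  The vendor's "Th factor"
  semantics are undocumented; ours are artifact-defined and tested.

## Known limitations

* No point-spread function, photobleaching, debris or focus modeling.
* Perimeter (hence roundness) is approximate for objects under ~10
  pixels; with all published roundness gates at 0.00 this cannot change
  counting results, but a user setting an aggressive roundness gate on
  bacteria-scale objects should not expect precision.
* Agreement with the commercial instrument's absolute counts is a
  non-goal; the published table arithmetic, not the raw images, is the
  reproducible quantity.
* A colony-forming unit may arise from a clump of cells; like the
  validating study, cells/mL and CFU/mL are treated as interchangeable.
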