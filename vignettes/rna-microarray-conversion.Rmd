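---
title: "Designing, planning and quantifying enzymatically converted RNA microarrays"
author: "rna2array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, planning and quantifying enzymatically converted RNA microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rna2array)
```

## The conversion workflow and what this package models

A DNA microarray becomes an RNA microarray in three enzymatic steps: a
5′-psoralen 2′-*O*-methyl RNA primer hybridizes to a primer-complement
block shared by every convertible probe and is photocrosslinked (365 nm)
at a T/A pair adjacent to the psoralen; T7 RNA polymerase extends the
crosslinked primer along the probe's variable region, producing a
surface-tethered DNA–RNA hybrid; and DNase degrades the DNA template,
leaving single-stranded RNA attached through the crosslink and a short dT
surface linker. `rna2array` models the sequence arithmetic, library
design, synthesis planning and scan quantification of that workflow — the
enzymology itself (crosslinking yield, polymerase and nuclease kinetics)
is outside its scope.

Probe architecture is fixed throughout: a transcribable probe is, 5′→3′,
`variable + revcomp(primer) + dT linker`, with the surface attachment a
3′ *flag*, never a reversal of the string. This convention (everything
stored 5′→3′) avoids the double-reversal bugs that plague surface-bound
sequence code. Chemistry (DNA, RNA, 2′-OMe) is tracked per segment, not
per base, because every species in the workflow is a block chimera; T and
U are distinct characters and only `chemConvert()` translates between
them.

## Design rules and their parameters

* **Primer** (`defaultPrimer()`): 15 nt 2′-OMe `UAGGGACACGGCGAA`,
  5′-psoralen. The class enforces a 12 nt floor: below that, a primer
  cannot remain selective on libraries of 10^5–10^6 unique sequences.
  `primerSelectivityScreen()` quantifies the risk for a concrete library
  by finding, per template, the longest primer stretch whose complement
  occurs in the variable region (either strand); stretches of ≥ 12 nt are
  flagged.
* **Linker**: dT homopolymer, default 5 nt. Short dT linkers resist
  DNase cleavage (the surface sterically shields them); longer linkers
  (≥ 15 nt) become substrates themselves, which is why the variant series
  emits dT5–dT20 for empirical comparison.
* **Crosslink site** (`validateCrosslinkSite()`): full Watson–Crick
  duplex over the primer length (U:A allowed), a U:A or T:A terminal pair
  adjacent to the psoralen, and a T as first linker base. All three are
  reported separately so a failed design explains itself.
* **Controls** (`makeControl()`): the RNA product sequence as DNA, no
  primer-complement block. They cannot be transcribed, hybridize the same
  labelled detection probe, and serve as the ssDNA reference in the
  conversion-efficiency estimator.
* **Platform limits**: 150 nt for ink-jet synthesis; photolithography is
  limited by the cycle budget, not sequence length.

Two published assay generators are first-class: `agilentSeries()` (linker
lengths dT5/10/15/20, rearrangements of the three 3′-terminal
primer-complement bases, rearrangements of the three centermost variable
bases, controls, and a primer+product ssDNA reference probe, every probe
replicated 60× at seeded random positions) and `daWalkSeries()` (21
templates with a single dA in a 61 nt TGC-concatemer variable region plus
matched controls, 85 replicates). Where the published description is
under-determined we chose once and documented: "three central positions"
defaults to the three centermost variable indices; "permutation of the
three 3′ terminal positions" means all distinct rearrangements of those
bases (multiset-deduplicated); and "a dA at the beginning" of the walk
means adjacent to the primer-complement block — i.e. surface-proximal,
extension position 1 — with insertion positions counted in the same
surface-proximal direction, giving rU positions 1, 4, …, 61 with no
collisions. The series' probe composition (A:1, T:20, G:20, C:20 in every
variant) keeps the fluorophore's sequence context constant.

## Image encoding

`quantizeRGB()` floor-bins 8-bit channels onto k = 8 levels
(`floor(v·k/256)`); floor rather than rounding keeps encoded layouts
bit-reproducible. `selectLevels()` picks the k truncation lengths whose
calibration intensities best match k targets evenly spaced from the
minimum to the maximum observed intensity (both extremes included),
minimizing the summed squared deviation with sorted lengths assigned to
ordered targets. The optimum is global over all size-k subsets; it is
computed by an exact dynamic program over length-sorted candidates (the
objective couples the j-th smallest selected length to target j, so the
DP explores exactly the subset space), with ties broken to the
lexicographically smallest length tuple. The package's calibration
stand-in, `syntheticCalibration()`, is synthetic — the measured truncation
curves are not distributed with the package — and follows the same
saturating duplex-length response as the simulator; truncations below
6 nt are excluded as they form no stable duplex under hybridization
conditions.

`encodeImage()` expands each pixel into a 2×2 feature block (red, green,
blue, plus a duplicate of the brightest channel) and tiles the expanded
image 2×2, so a 256×192 source exactly fills the 1024×768 grid of the XGA
micromirror device (786,432 features). That block/tiling arithmetic is a
documented package convention — it is the only reading under which four
such images fill the grid — and both factors are explicit arguments.
Level-0 (black) pixels receive a shared untranscribable dark control
rather than the dimmest truncation, guaranteeing zero specific signal;
truncations preserve the 3′ (primer-adjacent) end of the channel
sequence.

## Synthesis planning

`scheduleSynthesis()` converts a layout into phosphoramidite cycles with
per-cycle boolean micromirror masks. Synthesis runs 3′→5′. Linker
positions shared by all probes (the design's minimum linker length) are
emitted first as unmasked FLOOD couplings of DMTr-dT — acid deprotection
is not spatially addressed, so flooding is free — at 120 s coupling and
zero light dose. Remaining positions cycle through a fixed base order
(default `ACGT`; the real instrument's order is configuration, so it is
an argument) with BzNPPOC chemistry: 3 J/cm² photodeprotection, 15 s
coupling; NPPOC-HEG (6 J/cm², 300 s) is carried in the dose table for
non-nucleosidic linkers. Empty cycles are dropped. The number of masked
cycles is therefore bounded by `maxlen ≤ n ≤ 4·maxlen`. `replaySynthesis()`
is the verification oracle: it re-grows every feature mask by mask and
must reproduce each full probe sequence exactly — the round trip is tested
on randomized layouts and on the RGB layout at 48×64 scale.

## The scan simulator: what it emulates, what it does not

`simulateScan()` produces per-feature foreground/background tables with
the signal structure the quantification assumes:

* **Duplex-length response** `s(L) = L/(K+L)`, K = 8 nt: hybridization
  signal grows with probe-overlap length and saturates. The form is a
  modeling choice (the observation is "intensity increases with length");
  it is pluggable through `duplexResponse()`.
* **Distance decay** `d(pos) = max(decay^(pos−1), plateau)`, defaults
  0.96/nt and 0.70: fluorescence of a label incorporated farther from the
  glass decays and levels off at about 70% of position 1. These defaults
  are keyed to the published positional profile, not measured constants.
* **Arms** assign per-role multipliers of the specific signal: a
  converted arm gives transcribable features `e·s(L)` (conversion
  efficiency `e`) and degraded controls 0; an untreated arm gives ssDNA
  controls full response and templates 0 (the detection probe has nothing
  to bind); degradation arms multiply a class by the residual `r`; the
  Cy3-UTP arm replaces `s(L)` by `d(ruPosition)` and gives controls
  background only.
* **Noise**: multiplicative lognormal of unit mean with CV 0.2 (typical
  scan-to-scan fluorescence variation), background normal around 100 a.u.
  With `cv = 0` the scan is exactly noise-free, which gives the
  closed-form checks (e.g. a noise-free plateau of exactly 0.70).

It deliberately omits spatial artifacts (gradients, scratches, comet
tails), optical point-spread, scanner saturation and probe-sequence
effects beyond length. Passing recovery tests therefore shows the
estimators are correct and well-calibrated under the assumed signal
model — not that real scans are free of spatial systematics.

## Quantification choices

The analysis recipe is the published one: per-probe replicate means,
subtraction of the matched control mean, flooring of corrected values at
0 (negative corrected intensities are not meaningful), normalization to
the highest corrected signal, and — for the dA-walk — re-expression
relative to the position-1 variant, reporting the mean over the final 20
extension positions. Ratio estimators use means of replicate means, the
only fully specified recipe in the source workflow. Uncertainty is a
seeded percentile bootstrap (1000 resamples) over replicates, per pair
and pooled across pairs. The optional dust rule excludes replicates more
than 5 MADs above the probe median (off by default — by default no data
are excluded, matching the published analysis, which removed only two
dust-affected points out of 85). Degenerate inputs error loudly: all
corrected intensities ≤ 0, a missing position-1 reference, or a
non-positive denominator mean.

For conversion efficiency on simulated arms, background estimates come
from the opposite-role features of each arm (the converted arm's degraded
controls; the untreated arm's non-hybridizing templates), mirroring the
control-subtraction logic of the published recipe; backgrounds enter as
fixed scalars in the bootstrap.

## Problem sizes and determinism

The test-suite and acceptance simulations use the replicate counts of the
assays they model (8, 24, 62 and 85 replicates; 62 for the efficiency
recovery, 85 for the dA-walk), grids up to the full 1024×768 frame for
layout construction, and a 48×64 sub-grid for the synthesis round trip —
sizes chosen so each check exercises the full pipeline while running in
seconds. Every stochastic step (replicate placement, scan noise,
bootstrap) takes an explicit seed, and equal seeds give byte-identical
outputs end-to-end.

## Known limitations

* Cross-hybridization among variable regions is not screened (only
  primer selectivity is); thermodynamic duplex stability and secondary
  structure are out of scope.
* The published truncation lengths and the exact commercial design file
  are not reproduced; the level maps shipped by default derive from the
  synthetic calibration curve.
* The GPR/GAL dialects cover the column subset the pipeline needs; full
  ATF coverage and TIFF-level feature extraction are out of scope.
* Dose/time budgeting assumes the printed per-monomer constants and a
  1:1 mirror-to-feature mapping; optics are not modeled.
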