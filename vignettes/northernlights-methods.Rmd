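---
title: "Methods: simulating and quantifying 2D strandness-dependent electrophoresis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying 2D strandness-dependent electrophoresis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(northernlights)
```

## The model

The Northern Lights Assay reads DNA damage off a two-dimensional gel. In
dimension 1 native molecules migrate by length, strandness and
damage-induced conformation; after in-gel heat denaturation, dimension 2
separates single strands by length only — except that strands joined by an
interstrand crosslink travel as one covalent unit. This package models that
chain of events in three layers:

1. **Molecule model.** Duplexes carry per-strand nick lists (0-based cut
   offsets strictly inside the molecule) and a lesion table
   (`interstrand_crosslink` on both strands; `intrastrand_crosslink` and
   `monoadduct` on one strand, both treated as duplex-bending). Damage
   operations (Mbo I digestion, nicking, double-strand breakage, Poisson
   crosslinking, apoptotic internucleosomal fragmentation) and `denature()`
   are exact bookkeeping: every operation conserves the population's total
   nucleotide count and mass, and all randomness flows through one seeded
   generator per call.
2. **Mobility model.** A phenomenological semi-log law
   `d(L) = d_lim + (d_max − d_lim) · clamp(log(L_sat/L)/log(L_sat/L_min), 0, 1)`
   maps length to migration distance in each dimension. No mobility
   equation is published for this gel system; the semi-log form is the
   simplest law consistent with ladder behaviour (log-size vs distance is
   piecewise straight) and with a limiting mobility for very large DNA.
3. **Renderer.** Each projected species becomes an isotropic Gaussian spot
   whose integral is `gain × mass`; the Cy5-labeled ladder is projected
   through the same law into a second channel; additive background and
   seeded Gaussian noise complete a two-channel 16-bit raster.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `d1_lim`, `d1_max` (= d2) | 80, 950 | px | limiting-mobility row / resolving floor on a 1024² raster; leaves margins for background boxes |
| `L_min`, `L_sat` | 50, 20 000 | nt | resolving range; 20 kb is where genomic DNA effectively stops migrating |
| `ss_d1_factor` | 0.85 | – | single strands run dimension 1 visibly above the duplex arc without crossing the well |
| `bend_kappa` | 0.15 | per bend | each bending adduct retards dimension 1 by `1/(1+κn)`; 1–2 bends displace a spot clearly above the arc |
| `psf_sigma_px` | 4 | px | band FWHM ≈ 9.4 px, comparable to sharp polyacrylamide bands at this sampling |
| `noise_sd` | 327.68 | ADU | 0.5 % of the 16-bit dynamic range |
| `background_level` | 1500 | ADU | ≥ 4.5 noise sd above zero, so additive noise is almost never clipped and background statistics stay Gaussian |
| cisplatin lesion rate | 2.5e-4 | /nt/µM | ≈ 1 adduct per kb at 15 µM, the order reported for cisplatin adduct densities in vitro |
| cisplatin mix | 0.05 / 0.75 / 0.20 | – | interstrand / intrastrand / monoadduct; intrastrand adducts dominate platinum chemistry; configurable |
| local-denaturation threshold | 1/200 | lesions/nt | duplexes above this bending-adduct density unwind and run dimension 1 single-stranded |
| nucleosome repeat / core | 180 / 147 | nt | human chromatin; linker midpoints are the only cleavable positions in apoptosis |
| genomic stand-in | 40 × 30 kb | – | length-only duplexes above `L_sat`; a whole genome cannot be enumerated in tests |
| Mbo I length-only law | geometric, mean 256 | nt | expected spacing of a random 4-mer (4⁴) |

Masses are arbitrary intensity units; scenarios normalise the sample to
3e7 so that arc densities sit well above the noise floor, and ladder bands
get 2e6 each (≈ 20 000 ADU peaks).

## What the generator emulates — and what it does not

Scenarios reproduce the assay's experiment families: undigested/Mbo I pairs
of an undamaged specimen; dose-dependent crosslinking (cisplatin-like mix);
nicking-enzyme single-strand breaks; double-strand breakage; apoptotic
internucleosomal ladders with incomplete-nicking intermediates (which also
produce the vertical columns and horizontal streak seen beside real
ladders — the physical origin of those columns is unsettled, and the
simulator reproduces the observed pattern only); pre-load heat denaturation
(crosslinked molecules renature and keep native mobility; crosslink-free
DNA becomes single-stranded); and a ground-truth interstrand-fraction sweep
for parameter-recovery testing.

Not emulated: gel-running physics (field, temperature, urea chemistry),
lane warping or scanner artefacts, sequence-specific cleavage biases in
length-only mode, saturation blooming, or partial/hemi-blocked restriction
at damaged sites beyond a simple blocking window. A green round-trip test
therefore establishes that the *quantification rules are consistent with
the migration model*, not that either matches a particular wet gel.

## Quantification conventions

Several geometric rules are under-specified in assay practice (regions are
drawn by hand in densitometry software); this package fixes them
deterministically, as pure functions of the detected ladder:

* **Band edges.** Half-maximum contour around each Cy5 band; centroids are
  intensity-weighted within the edge box.
* **Corridor width.** The dsDNA region follows the arc (band centroids
  interpolated per row). Its half-width is `margin_scale` (default 2) times
  the half-max half-width: a half-max contour holds only ~76 % of a
  Gaussian band's marginal mass, twice that ~98 %. Because the arc is
  diagonal, the horizontal half-width is further scaled by
  `sqrt(1 + (dx/dy)²)` (sec of the local arc angle, from the ladder
  itself); without this a 45° corridor sheds ~5 % of band mass into each
  neighbouring region.
* **Behind region.** Strands joined by an interstrand crosslink have at
  least twice the single-strand length, which in the semi-log law is a
  *constant* leftward displacement `Δx = (x₁₀₀ − x₁₀₀₀)·log2/log10`.
  The behind region is therefore the arc corridor displaced left by Δx
  (widened by one corridor width), rather than a rigid translation by the
  region's own width — a translation by a ~20 px corridor could never
  contain an arc sitting ~100 px away.
* **Undigested vs streak.** The unmigrated region runs from the well to
  the 3000 bp band's upper edge and is bounded *right* by that band's
  right edge; the SSB streak occupies the same rows from there to
  vertically over the 100 bp band. A full-width unmigrated region would
  swallow the streak entirely, since the streak emanates from the
  unmigrated material itself. Streak signal left of the 3000 bp column is
  credited to the unmigrated fraction — an acknowledged truncation.
* **Disjointness.** Regions are clipped in priority order
  undigested > dsDNA > behind > front > ssb_streak; hand-drawn areas may
  overlap, reproducible ones must not. Percentages are relative to the five
  regions; mass outside all of them (e.g. fragments < 100 bp) is excluded
  from the denominator.
* **Background.** 64×64 px DNA-free margin window. The window whose mean is
  the *median* over candidates is used: most margin windows are signal-free,
  so the median is robust, whereas picking the minimum selects a downward
  noise fluctuation and (multiplied by region areas of 10⁵ px) manufactures
  percent-scale artefacts. Negative corrected densities clip to 0 before
  normalisation. A user-supplied box overrides auto-selection.
* **Size distributions.** Column-wise background-corrected intensity mapped
  through the x-calibration (single strands sit directly above double
  strands of equal size). The unresolved unmigrated fraction refuses size
  estimation. Peak calling smooths with a 5-column running mean and keeps
  local maxima with prominence ≥ 10 % of the maximum, merging peaks closer
  than 10 % in size.

## Comet scoring conventions

The scorer segments the head by mirror symmetry: the non-migration flank is
pure head, so with the head σ taken from the vertical FWHM, the center is
fit by log-linear regression on that flank (an intensity centroid would be
dragged toward the tail and cancel genuine tail signal). Tail = residual of
the migration side over the mirrored head, restricted to pixels above
background + 3 sd; tail length is measured from the head centroid to the
last column with ≥ 2 pixels exceeding the mirror by 5 background sd. The
tail moment is exactly the reported fraction × the reported length. The
threshold constants are documented conventions — the assay's usual ImageJ
scoring publishes none.

## Numerical choices and degenerate inputs

* Coordinates are 0-based and half-open; pixel `[r, c]` covers coordinate
  `(r−1, c−1)`; fragments re-home nicks/lesions by subtracting the
  interval start, and a nick coinciding with a cut simply becomes an end.
* Mbo I cuts 5′ of `GATC` (the enzyme's ^GATC chemistry); a lesion within
  4 nt of the site blocks the cut (adducts sterically hinder restriction —
  a convention, the enzymology at damaged sites being unpublished).
* Random nicks in `strand_mode = "both"` assign each Poisson event to a
  uniform strand, keeping the expected total at `rate × length`.
* Spot rendering truncates Gaussians at 4σ (< 0.02 % mass loss) and
  aggregates spots on a 0.25 px grid (apoptotic ladders collapse thousands
  of identical fragments into a handful of spots).
* Zero dose/rate operations return their input unchanged; `denature()` is
  idempotent; equal-variance t-tests with zero pooled variance return
  t = 0, p = 1 for equal means and error otherwise.
* Spearman rank correlations over fully tied (constant) fractions are
  reported as 0.
* Seeds: every stochastic stage derives its own 31-bit seed from the master
  seed, and the caller's RNG state is always restored.

## Design decisions that were genuinely open

* **Apoptosis peaks are read from the undigested member.** Restriction
  digestion of mono- and dinucleosomal fragments would destroy the 180/360
  ladder; break patterns are detected in the undigested aliquot by design
  of the paired assay.
* **16-bit PGM instead of TIFF.** No TIFF codec is available in this R
  stack; binary PGM (P5, maxval 65535) is lossless, universally readable,
  and accompanied by a JSON metadata sidecar and PNG previews.
* **Student's t (pooled), two-sided, α = 0.05, no multiplicity
  correction** matches the assay's reporting convention; Welch and
  Bonferroni variants are available as options.
* **Unpaired tests** across repair timepoints (pairing across replicates
  is not part of the stated analysis).

## Known limitations

Quantified percentages are relative to the five regions, so they depend on
the region conventions above; fragments below 100 bp and between the 1000
and 3000 bp bands fall outside every region and are not counted. The
mobility law is phenomenological — absolute pixel positions mean nothing
outside the simulator, only the geometry relative to the ladder does. The
comet simulator programs its ground truth directly (fraction, length,
crosslink retardation) rather than deriving it from the molecule model, so
NLA-vs-comet comparisons here are comparisons of scoring behaviour, not of
lesion chemistry.
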