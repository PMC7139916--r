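---
title: "Designing and quantifying multiplexed bead-array MALDI panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying multiplexed bead-array MALDI panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldipanel)
```

## The measurement model

In bead-array targeted MALDI proteomics an antibody-conjugated bead
captures one peptide analyte from a proteolytic digest; beads are arrayed
as micro-spots (the default layout is 26 × 88 spots at 0.8 mm pitch on a
25 × 75 mm slide, i.e. 2288 spots) and each spot is acquired by MALDI-TOF,
which yields predominantly singly charged ions. The computational problem
therefore decomposes into:

1. predicting the MH+ masses of every peptide form an assay must
   recognise,
2. decoding which assay a spot contains by matching its peaks against the
   compiled panel, and
3. quantifying the target from intensity ratios against an internal
   (SILAC) or spiked (SIS) standard.

### Masses

The MH+ mass of a peptide is the sum of its residue masses plus water and
one proton, plus the deltas of positioned modifications and isotope
labels. Residue constants ship as a versioned plain-text table
(`inst/extdata/residue_masses.tsv`) so the constant set can be pinned and
diffed; the test suite checks the summed masses of random peptides against
an independent elemental-composition oracle to 1e-4 Da. Monoisotopic
masses are authoritative throughout: linear-mode MALDI cannot resolve
isotope envelopes, but the matching tolerance (below) absorbs the
difference, and published "average" constants vary across sources by more
than the discrepancy (our average-mass output is validated against the
elemental oracle, not against any printed table).

Label schemes default to *nominal* integer shifts (K+8, R+10, V+6)
because vendor-quoted labelled peptide masses are light mass + integer
shift; `label_scheme(mode = "exact")` provides the isotopologue deltas
(8.014199, 10.008269, 6.013809) for real acquisitions. The two differ by
less than 0.05 Da per residue, well inside the linear-mode tolerance.

### Digestion and assay design

Cleavage rules are positional (e.g. trypsin: after K/R, suppressed before
proline). The digest enumerates all products with up to `max_missed`
internal uncut sites; assay design keeps every product that fully contains
the antibody's linear epitope, ranked by fewest missed cleavages, then
length, then position. Counting internal sites reproduces the usual
"nXC" nomenclature (a C-terminal peptide preceded by two retained
arginines carries those arginine sites internally). An optional flag
suppresses cleavage within one residue of a modification, mimicking the
missed cleavages that phosphorylation adjacent to K/R tends to force; it
is off by default because reference peptide sets are defined without it.

Variant enumeration is combinatorial: required modifications (either all
sites, or each non-empty subset for cross-reactive motif antibodies),
0..`max_extra` placements of a variable modification on eligible
residues, mutation alleles (wild type always retained, matching
heterozygous use cases), and a heavy channel labelling every K/R (or
scheme residue). Placements indistinguishable by mass are collapsed with
their multiplicity recorded; a hard cap (10,000 variants per assay)
guards against combinatorial explosion in heavily modified targets such
as histone tails.

### Decoding and tolerances

Peaks are matched to the nearest reference mass within tolerance; the
spot's assay is the one with the highest summed matched intensity, an
intensity-weighted vote that is robust to stray noise peaks. Linear-mode
matching uses a two-tier absolute window: strict 0.25 Da, with a
documented 0.5 Da fallback tier because observed linear-mode masses
routinely sit ~0.3 Da from calculation; reflector mode uses 25 ppm. Mass
errors are reported as observed − expected. Panel compilation reports
every cross-assay collision within the strict tolerance as a warning
(decodability check), not an error: a collided panel is still usable.

## The synthetic-data generator

`simulate_spectrum()` renders each analyte as a Gaussian of FWHM =
m/z ÷ resolution (default resolution 1000, the regime where isotope
envelopes are unresolved), on a uniform 0.05 Da grid over 750–7000 m/z
(at least four samples per FWHM at the low-mass edge), plus an
exponential-decay baseline and additive Gaussian noise, all under a
mandatory seed. `simulate_spot()` renders one assay's variant masses with
relative abundances declining 40% per extra missed cleavage and scales so
the *weakest* rendered peak sits at the requested S/N — so a stated S/N
of 20 is a worst-case floor across both channels.

What the generator deliberately does **not** emulate: isotope fine
structure and the interpolated-monoisotopic behaviour of vendor peak
detectors, matrix cluster ions, detector saturation, heteroscedastic
noise, and calibration drift. Passing round-trip tests therefore
demonstrate the correctness of the decoding and quantification logic
under the stated noise model, not instrument-grade mass accuracy on real
acquisitions.

## Numerical choices in the spectral pipeline

- **Baseline**: per-segment (25 Da) minima of a 51-point moving average,
  linearly interpolated and subtracted, floored at zero. Taking minima of
  a smoothed trace rather than the raw one keeps the estimate from
  chasing individual noise excursions.
- **Peak picking**: apexes are local maxima of a 5-point moving average;
  heights and thresholds are measured above a local median floor so that
  a zero-clipped noise pedestal cannot bias peak heights or small-ratio
  quantification. Noise is a robust scale estimate of the smoothing
  residual per 50 Da segment, taken from the upper flank of the residual
  distribution (95th percentile minus median, scaled), again for
  insensitivity to clipping; S/N ≥ 3 is the default detection threshold.
  Apexes whose half-height windows overlap are merged (one noisy peak can
  produce several smoothed local maxima), and the centroid is the
  intensity-weighted mean over the merged window.
- **Calibration fit**: least squares on log10(ratio) vs log10(spike),
  trimming one level at a time (the worst mean residual, cutoff 0.15
  log10 units) so plateau or saturated levels leave the linear fit
  without mass exclusions; the retained span is the reported dynamic
  range.
- **LOD/LOQ**: a level is *identifiable* when its matched peak reaches
  S/N ≥ 3; LOD is the lowest level identifiable in more than half of its
  replicates (2 of 3 for triplicates), LOQ additionally requires
  replicate-ratio CV below 30%. LOQ ≥ LOD holds structurally, because the
  LOQ criterion contains the LOD criterion level by level.
- **Endogenous estimate**: on a forward curve the measured ratio plateaus
  at endogenous/constant as the spike vanishes; the estimate iterates
  from the blank-level ratio, averaging ratio × constant − spike over
  levels whose spike is below half the current estimate. The top spike
  levels never enter the window.

## Open design decisions taken here

- Quantification uses peak **height**; area is recoverable from the
  simulator but height is primary, as is usual for well-resolved linear
  acquisitions.
- Ratio orientation (H:L vs L:H) is explicit metadata on every record;
  silent conventions corrupt fold changes, and undefined ratios (missing
  channel) propagate as flagged `NA`, never as zeros.
- Fold changes divide the unrounded mean ratios, so a fold change
  recomputed from rounded published ratios can differ in the second
  decimal.
- The replicate detection rule generalises to "more than n/2" for n ≠ 3.
- The noise-monotonicity of LOD is guaranteed with respect to assay
  *sensitivity* (per-fmol response) under common random draws, and as the
  deterministic rule property that adding a detection can never raise
  LOD/LOQ; it is **not** asserted against the noise CV, where a heavier
  multiplicative tail can luck a low level over threshold.

## Problem sizes used by the packaged studies

The shipped demo panel has 8 assays and 49 reference variants; decoding
studies use 100 simulated spots at worst-case S/N 20, quantification
studies 3 replicate spots per injected ratio, digestion verification
1,000 random sequences up to 100 residues against an exhaustive substring
oracle, and calibration studies a 12-point 3-fold dilution (10,000 fmol
down to 0.17 fmol plus a blank) in triplicate with 20% CV noise. These
sizes exercise every code path while keeping the default test run fast.

## Known limitations

Charge states above 1, semi-specific digestion, isotope envelope
simulation, MS/MS search (only a b/y fragment calculator is provided),
protein-level rollup across peptides, and absolute copy-number
quantification are out of scope. The demo FASTA contains synthetic
assembled region fragments (built from validated target peptides with
their flanking residues, in local coordinates), not full database
entries; assay epitope coordinates in the demo config are local to those
regions.
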