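---
title: "Indel detection by amplicon analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indel detection by amplicon analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idaa)
```

## The measurement

Nuclease-based genome editing (CRISPR/Cas9, ZFNs, TALENs) produces
double-strand breaks that error-prone end joining repairs with small
insertions and deletions at the cut site.  Indel detection by amplicon
analysis reads these out by PCR-amplifying the target region with a
fluorophore-labelled primer system and sizing the products on a DNA
capillary sequencer against a co-injected size ladder.  An allele carrying
a signed indel of $d$ bp migrates as a fragment of size $w + d$, where $w$
is the wild-type amplicon size, so the electropherogram of an edited cell
pool is a mixture of peaks whose *positions* encode the indel spectrum and
whose *areas* encode allele abundances.

The labelling uses a tri-primer design: the target-specific forward primer
carries a universal 21-nt 5' extension (`FamFExtension`,
`AGCTGACCGGCAGCAAAATTG`, 52% GC), and a 6-FAM-labelled universal primer
matching that extension labels every product in one reaction.  The
expected wild-type *labelled* amplicon is therefore the genomic amplicon
plus 21 bp — what `assayDesign()` / `expectedWtSize()` compute.

## From trace to allele table

Every sample runs through the same chain
(`analyzeSample()`/`analyzeTrace()`):

1. **Conditioning.** Each channel is Savitzky–Golay smoothed (window 9,
   order 3 — exact on cubic peak flanks) and baseline-corrected by
   morphological opening (rolling minimum then maximum, window 151
   scans).  An opening never exceeds the signal and is flat under peaks
   much narrower than the window, so slow drift is removed without biasing
   peak areas.  Negative residuals are clipped before integration so areas
   can be read as fractions.
2. **Peak detection.** Local maxima at least `minHeight` (50 RFU) high and
   `minSeparation` (10 scans) apart; boundaries at the nearest flanking
   valley or where the signal drops below `max(1% of apex, minHeight/2)`,
   whichever is closer; areas by the trapezoid rule over the boundary
   interval.  A fractional apex is refined by parabolic interpolation of
   the three top samples on the log scale (exact for a Gaussian peak);
   this is what sizing uses, giving sub-0.01-bp sizing at good
   signal-to-noise.
3. **Ladder matching.** The size standard's fragments (built-in GeneScan
   LIZ500/LIZ600 tables, or a user TSV) are assigned to detected ladder
   peaks by minimising the residual sum of squares of a straight-line fit
   of scan on size over all order-preserving injective assignments.  This
   is solved exactly by vectorised enumeration whenever
   $\binom{n}{k} \le 2\times 10^5$ (always, in practice); an iterated
   assignment-DP against a refitted line covers pathological candidate
   counts.  A straight line is only a *matching* objective; it is not used
   for sizing.
4. **Calibration.** Local Southern sizing: fragment mobility follows
   approximately $L = c/(m - m_0) + L_0$ in scan coordinate $m$; for a
   query the law is fitted exactly through each of the two triples of
   neighbouring ladder points (two below + one above, one below + two
   above) and the two estimates averaged, with a single-triple fallback at
   the range ends and a quadratic fallback if a triple is degenerate.  A
   monotone cubic spline (`method = "spline"`) is retained for robustness
   comparisons.  Per-point leave-one-out residuals quantify calibration
   quality; the pipeline flags the ladder as failed when interior LOO
   residuals exceed `maxLooResidual` (2 bp; end points are excluded
   because their refit is an extrapolation).  Note that spline LOO
   residuals are intrinsically large (~10 bp) across the sparse, strongly
   curved low end of a ladder, so raise the gate when choosing the spline.
5. **Allele calling.** Peaks within `windowBp` (150 bp) of the wild-type
   size get the integer offset `round(size − wt)`, with ties rounded away
   from zero (deterministic and insertion/deletion-symmetric); peaks
   within `clusterTolBp` (0.5 bp) of the same integer merge with
   area-weighted size.  Fractions are merged areas over total retained
   area; alleles below `minFraction` (0.5%) are dropped and fractions
   renormalised (raw fractions are kept alongside).  Cutting efficiency is
   the summed fraction of non-wild-type alleles — identically
   $1 - f_0$.  A frameshift flag marks indels not divisible by 3.

The wild-type size is preferably taken from a same-run wild-type control
trace (dominant peak ≥ 80% of area); because indels are *differences* of
sizes under one calibration, this cancels systematic mobility offsets.  A
designed expected size or an explicit number are the alternatives.

Clone genotyping counts alleles at ≥ `minAlleleFraction` (15%) and
classifies: `wild_type`, `mono_allelic` (one in-frame non-zero allele),
`all_alleles_disrupted` (no wild-type allele, every counted allele
frameshift — the clones a knockout screen wants), otherwise
`multi_allelic_mixed`.  More than `maxAlleles` (4) counted alleles raises
a clone-impurity warning rather than an error.

## The simulator and what it does (not) emulate

`simulateTrace()` renders a two-channel trace (6-FAM sample + LIZ ladder)
from a migration model, Gaussian peaks, baseline drift and seeded white
noise, quantised to the signed 16-bit instrument range.  Defaults were
chosen once to mirror a healthy fragment run on a modern capillary
instrument:

* wild type 150 bp — typical short fragment-analysis amplicon, where CE
  resolution is best;
* migration $m(L) = m_0 - c/L$ with $m_0 = 12000$, $c = 4\times10^5$ over
  a 12,000-scan trace (the trace length is set so the whole LIZ500 range,
  35–500 bp, migrates within it), giving ≈ 17.8 scans/bp at 150 bp;
* peak sd 4 scans, i.e. FWHM ≈ 0.5 bp — the regime in which real
  instruments separate 1-bp neighbours and resolve ~1% side peaks, which
  is exactly the regime the method claims;
* `amplitude` is the *integrated* sample area (2e5 fluorescence·scans —
  a single-allele apex of ≈ 20,000 RFU, comfortably below the 32,000
  saturation threshold), because peak area, not height, carries allele
  fraction; ladder fragments get 2e4 each (≈ 2,000 RFU apexes);
* noise sd 10 RFU, no drift, no stutter unless asked.

Using the same reciprocal law in the simulator and in Local Southern makes
noiseless recovery exact, which is deliberate for calibration tests; a
polynomial migration model is provided (and tested) precisely to avoid
validating the sizing method only against its own functional form.

The simulator does **not** model electrokinetic injection bias, dye
mobility shifts between channels, saturation bloom, or sequence-dependent
PCR stutter; passing tests therefore demonstrate the correctness of the
computational chain under realistic geometry and noise, not robustness to
every instrument artefact.  Stutter is available as a single −1 bp
satellite with a configurable area ratio: at 5% it is — correctly —
indistinguishable from a real 5% deletion allele and will be called as
one; below `minFraction` it is filtered.  That threshold is the boundary
between tolerable and call-corrupting stutter at default settings.

## Off-target candidate enumeration

`findOffTargets()` defines a candidate purely as a protospacer-length
window within a Hamming-distance budget whose immediately 3'-adjacent
bases match the IUPAC PAM pattern, on either strand, with ambiguous
genome bases counted as mismatches.  No position weighting, seed-region
restriction or bulges: tools that weight mismatches toward the
PAM-proximal seed will rank candidates differently and may count fewer,
so candidate counts are comparable only under the same definition.  Minus-
strand hits are reported in projected forward-strand coordinates; BED6
export uses the mismatch count as the feature name.

## Numerical choices and degenerate inputs

* Trapezoidal integration throughout; a constant 1 over a 101-point
  closed interval integrates to 100.
* Rounding of fractional offsets is half-away-from-zero, so ±0.5 bp goes
  to ±1 bp rather than to even.
* Ladder matching needs at least as many candidate peaks as fragments and
  a standard needs ≥ 4 fragments; failures surface as typed conditions
  (`idaa_ladder_error` etc.) and, in the pipeline, as a `ladder_fail`
  QC flag on an otherwise valid, call-free profile so batch runs continue.
* Empty analysis windows yield zero-row allele tables and a `no_peaks`
  flag; efficiency is then undefined (NA), never silently 0.
* ABIF writing emits version 101 with the directory after the payload and
  supports the tag subset fragment runs need (DATA1–4/105, DyeN, SMPL1,
  LANE1); unsupported element types are surfaced as raw bytes with a
  warning rather than dropped.

## Problem sizes used in validation

The shipped test-suite and the acceptance script validate on simulations
sized for a desk run: 50 seeded replicates per condition for the
resolution (magnitudes 1–5 bp, both signs, 30% allele) and sensitivity
(1% allele) properties, the full −80…+35 bp single-clone sweep at one
replicate per size, oracle comparisons on ≤ 30 kb random genomes and ≤ 9
ladder candidates, and ABIF round trips up to 10,000 scans.  These sizes
give binomial confidence adequate for ≥ 95% pass criteria while keeping
a complete run in tens of seconds.

## Known limitations

Indel *identity* (which bases were inserted or deleted) is outside the
scope of fragment sizing and needs sequencing; alleles of equal size are
indistinguishable; copy number and phasing are not inferred; quantitative
fractions assume amplification efficiency is size-independent across the
analysis window, which holds for small indels but degrades for very large
deletions.
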