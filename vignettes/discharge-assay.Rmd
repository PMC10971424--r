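---
title: "Quantifying E2 ubiquitin discharge from MALDI-TOF spectra"
author: "e2discharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying E2 ubiquitin discharge from MALDI-TOF spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2discharge)
```

## The assay and its model

E2-conjugating enzymes sit in the middle of the ubiquitylation cascade: the
E1 enzyme loads ubiquitin onto the E2 catalytic cysteine as a thioester
(E2~Ub), and the E2 then discharges ubiquitin onto an acceptor. Canonical E2s
discharge onto lysine amines (isopeptide bond); a small set of noncanonical
E2s instead target hydroxyl groups — serine, threonine, glycerol, sugars —
forming base-labile oxyesters.

The intact-protein MALDI-TOF discharge assay reads this chemistry out
directly. A reaction containing E1, an E2, ATP/Mg, ubiquitin and a
large excess of a small-molecule nucleophile is incubated and then analyzed
in linear mode. Discharge onto the nucleophile produces a covalent
ubiquitin–nucleophile adduct whose mass is the ubiquitin mass plus the
nucleophile mass minus one water — every bond chemistry involved (isopeptide,
oxyester, thioester, attachment to an alpha-amine) is a condensation, so one
arithmetic rule covers the whole panel. A known amount of uniformly
15N-labeled ubiquitin is spiked in with the quench acid and serves double
duty as a single-point mass recalibrant and as the quantification reference.

The per-well readout is the discharge percentage

$$
\%\,\mathrm{discharge} \;=\;
\frac{A_{\mathrm{adduct}}}{A_{^{15}\mathrm{N}\text{-Ub}}}
\cdot \frac{[^{15}\mathrm{N}\text{-Ub}]}{[\mathrm{Ub}]_{\mathrm{initial}}}
\cdot 100,
$$

where the $A$ are integrated peak areas. The ratio form cancels shot-to-shot
intensity variation; its validity rests on the assumption of equal molar area
response between ubiquitin species, which is reasonable for species differing
by under 2% in mass in linear mode. Values above 100% are arithmetically
possible (response mismatch, calibration problems) and are reported with an
`over_100` flag rather than clamped — clamping would hide exactly the
problems one needs to see.

When ubiquitin point mutants are assayed, the mutant and standard peaks can
overlap, so the standard is omitted (`has_standard = FALSE`). The pipeline
then reports normalized fractions, adduct area over total
analyte-plus-adduct area, which sum to one with the unreacted fraction — a
relative, conservation-based readout rather than an absolute one.

## The mass control list

Expected (M+H)+ values are computed with IUPAC 2021 average atomic weights:
residue masses summed over the 76-residue ubiquitin sequence plus one water,
plus one proton (average masses, matching broad linear-mode peaks; no
isotopic fine structure). Adducts add the nucleophile formula mass minus
18.015 Da. The 15N standard adds 105 × (15.0001086 − 14.007) Da — 105 being
the nitrogen count of the sequence. The five panel nucleophiles are fixed as
their reagent forms: Nα-acetyl-L-lysine C8H16N2O3, N-acetyl-L-serine
C5H9NO4, N-acetyl-L-threonine C6H11NO4, glycerol C3H8O3, D-glucose C6H12O6.

```{r control-list}
ub <- molecular_species("Ub", sequence = ubiquitin_sequence())
cl <- build_mass_control_list(ub, nucleophile_panel()["Ac-T"],
                              standard = "15N")
as.data.frame(cl)
```

Vendor control lists in circulation differ from this arithmetic by up to
~2 Da (and by ~2 Da in the glucose adduct specifically, where the assumed
adduct structure is not documented). `build_mass_control_list()` therefore
accepts per-entry `overrides` that echo user-supplied values exactly, and the
default ±5 Da match tolerance absorbs the residual discrepancy either way.
We default to computed masses: they are reproducible from first principles
and agree with the common printed values to well under 0.05%.

## The synthetic-data generator

No public raw spectra exist for this assay class at desk scale, so the
package ships a generator that emulates the features the processing chain
must cope with, with known ground truth:

* **Peak shape**: symmetric Gaussians in m/z, default sigma 4 Da. Linear-mode
  intact-protein peaks are broad and near-symmetric; 4 Da gives peaks that
  are resolvable but wide enough to stress the 29 Da gap between the
  Ub–glycerol adduct and the 15N standard.
* **Grid**: 8000–9200 Da at 0.5 Da, bracketing all seven panel species.
* **Abundance model**: equal molar area response; unreacted analyte
  ∝ (1 − Σfractions)·[Ub], each adduct ∝ fraction·[Ub], standard ∝ [15N],
  scaled by a response of 100 intensity units per µM.
* **Baseline**: a single exponential decaying from low m/z (amplitude 20,
  decay length 300 Da by default), the typical matrix-background shape.
* **Noise**: additive Gaussian, default SD 1. With 2 µM analyte and standard
  this puts the standard apex near S/N 200 and a 10%-discharge adduct near
  S/N 20.
* **Miscalibration**: an additive offset applied to every peak position,
  drawn per well from U(−2, 2) Da in plate simulations (typical linear-mode
  drift); any offset can be injected explicitly.

Reaction concentrations are free parameters (defaults 2 µM ubiquitin, 2 µM
standard) — reported assay recipes vary between 2 and 2.5 µM enzyme and in
final nucleophile concentration, so the generator does not hard-code one
reading.

What the generator does **not** emulate: detector saturation, matrix adduct
satellites, isotopic fine structure, mass-dependent resolution, chemical
(correlated) noise, and shot-to-shot spot heterogeneity. Passing the
recovery suites therefore demonstrates that the processing chain is correct
under its stated model, not that it is robust to every pathology of real
MALDI data; the QC-flag design (nothing silently dropped) is the hedge for
the latter.

## Peak processing: numerical choices

**Baseline.** A morphological opening — rolling minimum then rolling maximum
over a 100 Da window — followed by a short rolling mean. The opening clips
any feature narrower than the window (all real peaks here are ~10 sigma
narrower) while reconstructing smooth monotone backgrounds exactly; a plain
rolling minimum alone lags a decaying baseline by half a window and
undershoots it by ~15% at the defaults. The signal is edge-replicated by one
half-window before filtering so the reconstruction holds up to the spectrum
boundaries.

**Noise.** 1.4826 × median absolute deviation of the baseline-subtracted
residual, iteratively masking points above 3× the current estimate so peaks
do not inflate it. The estimate runs slightly high (~20–30%) on simulated
plates because baseline-filter ripple adds to the residual; this is
conservative (it raises the effective detection threshold) and is accepted.

**Detection.** Every strict local maximum of the subtracted trace with apex
≥ `snr_threshold` × noise (default 5) is reported. No merging heuristics:
the detected apex set is exactly enumerable by brute force, which the test
suite exploits as an independent oracle. Noise ripple on the flank of a tall
peak can therefore appear as an extra "peak", but such ripples inherit
near-identical centroids and areas from the shared half-height region (see
below) and are handled naturally by nearest-peak matching.

**Centroid and area.** The centroid is the intensity-weighted mean m/z over
the contiguous region above half-apex. The area is the trapezoidal integral
of the subtracted trace over a region grown from the apex to the nearest
*qualifying* valley on each side, capped at ±4σ̂ (σ̂ = FWHM/2.3548). A local
minimum only qualifies as a valley once the trace has dropped below
half-apex: without that qualification a 1-sigma noise dip right next to the
apex would truncate the integration region catastrophically. Overlapping
peaks are truncated at their shared valley; no deconvolution is attempted
(declared limitation — at default widths the closest panel pair in any
single-nucleophile well is ~29 Da apart, 7 sigma).

**Calibration.** One internal point determines one parameter, so the model
is a single additive shift: expected minus observed 15N-standard centroid,
searched within ±20 Da, nearest peak winning with ties broken toward larger
area. Calibrating twice is the identity. If no candidate exists the well is
flagged `calibration_failed` rather than quantified on a bad axis.

**Matching.** Global nearest assignment within the ±5 Da tolerance,
processed in ascending |Δm/z|; each control entry claims at most one peak
and vice versa; exact ties go to the lower-m/z entry with a warning.
Unmatched entries report zero area — a zero-discharge well is a result, not
a missing value.

**Optional smoothing.** A Savitzky–Golay filter (via the `signal` package)
can be applied before detection; it is off by default because the S/N-gated
detector plus area integration does not need it under the stated noise
model, and smoothing correlates neighboring points, which complicates the
noise estimate.

## Aggregation

Replicate aggregation uses the mean (the convention for technical-replicate
heatmaps in this assay class), with per-cell replicate counts and failed
wells reported alongside; cells with fewer than two valid replicates are
flagged. Time courses report the sample mean and the n−1 sample SD per (E2,
nucleophile, time); a single replicate yields a mean with an absent SD.
There is no silent row filtering anywhere: upstream export filters common in
vendor workflows are replaced by explicit QC flags
(`calibration_failed`, `standard_missing`, `standard_not_detected`,
`over_100`, `spectrum_unreadable`, `processing_failed`).

## Interface contacts

The structural module classifies residue–residue contacts at an E2~Ub model
interface from PDB coordinates (parsed with `bio3d`; ATOM records only,
highest-occupancy altloc kept):

* **Cation-pi**: distance from a cationic group center (Lys NZ; Arg CZ, the
  guanidinium carbon) to an aromatic ring centroid, cutoff 6.0 Å
  *inclusive* ("within the cutoff" is read as ≤). Phe/Tyr use the six-ring;
  His the imidazole; Trp's five- and six-rings are tested and reported
  separately, since the relevant face is model-dependent.
* **Hydrophobic**: any side-chain carbon pair of two apolar residues within
  4.5 Å. The cutoff is a common literature convention (no value is standard
  in this assay's reports) and is configurable. Glycine has no side chain;
  its CA stands in so that contacts to the ubiquitin Gly76 C terminus are
  representable.
* **Ionic**: a cationic side-chain nitrogen (Lys NZ; Arg NE/NH1/NH2; His
  ND1/NE2) within 4.5 Å of a carboxylate oxygen. Anionic partners include
  Asp/Glu side chains **and the chain C-terminal carboxylate oxygens** —
  the reported ionic engagement of His with ubiquitin's Gly76 is only
  interpretable against the C-terminal carboxylate, and that assumption is
  recorded here.

All cutoffs are inclusive; results are symmetric under chain swap, and
enlarging a cutoff can only add contacts.

## Problem sizes and reproducibility

The shipped test and acceptance workloads use a 23-enzyme × 5-nucleophile
plate (115 wells, one replicate for recovery statistics; two for aggregation
tests), 2401-point spectra, a 50-spectrum detector-oracle fixture, and a
200-spectrum property suite on shortened 801-point grids — sizes chosen so
the full suite runs in well under a minute on one core while every stage is
exercised end to end. All randomness flows through explicit seeds; plate
simulation, quantification and screen outputs are byte-reproducible under a
fixed seed.

## Known limitations

* Equal-molar-response is assumed, not estimated; a species-specific
  response calibration layer would be needed for absolute accuracy on real
  instruments.
* No peak deconvolution: heavily overlapping species (e.g. a glucose adduct
  vs. a lysine adduct, ~8 Da apart) cannot be quantified in the same well.
  The assay design (one nucleophile per well) avoids this; screening
  mixtures would not.
* The single-point calibration corrects offset only, not mass-dependent
  stretch; adequate over the 1200 Da window here, not for wide-range work.
* Simulated-data validation bounds, not real-data validation: see the
  generator's non-goals above.
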