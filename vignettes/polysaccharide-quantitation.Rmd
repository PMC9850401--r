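---
title: "Bottom-up polysaccharide quantitation from oligosaccharide fingerprints"
author: "glycoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up polysaccharide quantitation from oligosaccharide fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquant)
```

# The problem and the approach

Polysaccharides are the dominant carbohydrate fraction of most foods,
yet they are awkward analytes: they are too large and too heterogeneous
for direct LC-MS, and classical assays (enzymatic kits, acid
hydrolysis to monosaccharides) either target one polymer at a time or
destroy the information that distinguishes polymers built from the
same monosaccharide. A bottom-up strategy sidesteps this: an oxidative
depolymerization converts each polysaccharide into a ladder of
oligosaccharides, the ladder is reduced (borohydride, giving alditol
ends) and measured by LC-MS/MS on porous graphitized carbon (PGC), and
each parent polysaccharide is recognized by the *fingerprint* of its
oligosaccharides — their monosaccharide compositions together with
their PGC retention times. Quantitation then rides on the fingerprint:
relative amounts from extracted-ion-chromatogram (EIC) peak-area
fractions, absolute amounts from external calibration curves built
from reacted polysaccharide standards.

This package implements the computational half of that workflow:

1. **Composition arithmetic and annotation** — combinatorial matching
   of precursor m/z to monosaccharide compositions, and
   composition-level B/Y fragment annotation of tandem spectra.
2. **LC-MS I/O and chromatography** — mzML/MGF reading, EIC
   extraction, automated peak detection/integration,
   signal-to-noise estimation.
3. **Fingerprint library** — building the (polysaccharide,
   composition, retention time) catalogue from standards and assigning
   sample peaks against it.
4. **Quantitation** — top-3 averaged zero-intercept calibration,
   method detection limits, unit conversion, relative quantitation,
   bias/CV validation statistics.
5. **Synthetic data** — a seeded LC-MS run generator with ground
   truth, so every layer is testable without instrument data.

# Composition model

A composition counts residue classes, not structures: hexose (`Hex`,
residue mass 162.05282 Da), pentose (`Pnt`, 132.04226), hexuronic acid
(`HxA`, 176.03209) and N-acetylhexosamine (`HexNAc`, 203.07937), plus
O-methyl decorations (`Me`, +CH2) that ride on hexuronic acids
(4-O-methyl-glucuronic acid in xylans) and an optional alditol end
(`-red`, +H2) from the reduction step. The neutral mass is the residue
sum plus one water; adducted m/z is `(M + z*cation)/z`. Text forms
like `"Pnt4HxA1Me1-red"` parse and format losslessly.

Precursor annotation enumerates *every* composition within bounds
crossed with every adduct and keeps candidates inside the ppm
tolerance, ordered by absolute ppm error with ties broken by fewer
residue classes, then lower DP — a deterministic, fully auditable
rule. The defaults:

| parameter | default | rationale |
|---|---|---|
| mass tolerance | 15 ppm | QTOF-class accuracy |
| DP bound | 25 | hexose ladders observed up to DP 21 |
| HxA bound | 3 (Me <= HxA) | acidic xylan species are sparse |
| HexNAc | homo-series only | chitin-type ladders |
| adducts | Na+, H+, NH4+ (Na+ first) | positive-mode PGC convention |
| charge | z = 1 | singly charged dominates at these DPs |

The composition space is deliberately small (under 1e4 candidates), so
exhaustive enumeration is exact and cheap; a brute-force enumeration
oracle in the test suite confirms set-for-set agreement.

Above roughly m/z 2000 the 15 ppm window starts admitting several
compositions, and ppm alone can pick the wrong one. This is where
tandem spectra earn their keep: fragments are modelled as glycosidic
B/Y pairs at the composition level (Y keeps the water and the alditol
end, B keeps neither; O-methyls travel with their hexuronic acids),
and a spectrum is scored by the intensity-weighted fraction it shares
with a candidate's theoretical fragment set. When a peak has an MS2
spectrum, candidates are re-ranked by that coverage score before ppm;
the wrong isobaric-within-tolerance candidate typically scores near
the precursor-only floor while the right one scores near 1. Cross-ring
(A/X) ions and linkage/anomericity are out of scope — isomers share
compositions and are separated by retention time instead.

# Chromatographic layer

EIC extraction sums, per MS1 scan, all points within the ppm window of
the target; the monoisotopic trace only is quantified (isotopologue
channels are recognized by the +1.00335 spacing and discarded when a
channel one to three spacings below carries at least 40% of their
height — the floor matters because above ~100 carbons the +1
isotopologue is *taller* than the monoisotopic peak).

Peak detection replaces the manual vendor-software integration of the
original workflow with a deterministic, reproducible procedure:

- baseline = median intensity; noise = MAD scaled by 1.4826 (robust to
  the peaks themselves);
- peak geometry (regions, apexes, valleys, boundaries) is decided on a
  5-point moving-average trace so single-sample noise excursions
  neither split peaks nor truncate their tails; regions need at least
  `minPoints = 5` samples and an apex `minSnr = 3` noise units above
  baseline; co-eluting shoulders are split only where the valley drops
  below half the smaller apex;
- the area is the baseline-subtracted trapezoidal integral of the
  *raw* trace between the region boundaries (no Gaussian fit, no shape
  assumption);
- the reported S/N is peak height over `1.4826 * MAD` of flanking
  baseline windows (1 min each side) that exclude all detected peak
  spans; an exactly quiet baseline is capped at 1e6.

These choices make detection invariant to uniform intensity scaling
and keep integrated areas within 2% of programmed truth on simulated
Gaussians sampled at 0.63 spectra/s.

# Fingerprint library and matching

Library construction annotates each polysaccharide-standard run,
pools replicate runs by (composition, adduct) with retention-time
clustering at the RT tolerance (0.5 min by default, about twice a PGC
peak width), and records the area-weighted mean RT and per-run mean
area. Entries of *different* polysaccharides that collide in both m/z
(within tolerance) and RT (within tolerance) are flagged non-unique:
starch and cellulose both shed Hex~n~ ladders and are distinguishable
only chromatographically, so uniqueness is a composition-plus-RT
property, not a composition property.

Sample peaks are assigned to the entry with matching composition and
adduct and the smallest RT difference within tolerance; exact ties go
to the more abundant library entry, with a warning. Annotated peaks
matching no entry are reported as `UNASSIGNED` — they still enter the
denominator of relative quantitation, which keeps area fractions
honest when a sample contains species outside the library.

# Quantitation model

For each polysaccharide the quantitation signal is the mean EIC peak
area of its three most abundant *unique* oligosaccharides, selected
once on the standards' library abundances so the same three species
are used at every level and in every sample (for a linear arabinan
standard these are the DP 3-5 oligomers). Calibration is an
equal-weight linear fit forced through the origin over at least five
levels:

- slope: `sum(x*y) / sum(x^2)`
- r^2: `1 - sum((y - y_hat)^2) / sum(y^2)` (uncentered total sum of
  squares — the through-origin convention; a centered r^2 through the
  origin can go negative and is not comparable).

Unknowns invert the curve (`conc = area / slope`). The method
detection limit is the lowest calibration level whose averaged-peak
S/N exceeds 3; concentrations below it are flagged `below_mdl` rather
than censored, leaving the decision to downstream users. When one of
the three oligosaccharides falls below detection in a dilute standard
the available areas are averaged and `n_top3` records how many
contributed.

Concentrations convert to sample bases with the dry-matter loading
(default 25 mg dry matter per mL reacted, the factor connecting ug/mL
to % wt/wt dry) and the moisture fraction for fresh-weight units.
Accuracy is percent bias of the replicate mean against nominal;
precision is percent CV (sample SD over mean) across method
replicates.

# The synthetic-run generator

The generator is first-class, tested code, not a fixture: it defines
the study conditions under which the pipeline's claims are verified.
Nine built-in polysaccharide definitions produce oligomer ladders
(hexose ladders for starch DP 3-21, cellulose, beta-glucan, mannan and
galactan DP 3-12; pentose ladders for arabinan DP 3-15 and xylan, the
latter with 4-O-methyl-glucuronylated members; mixed hexose/pentose
ladders for xyloglucan; HexNAc ladders for chitin), each with a linear
RT-versus-DP model (PGC retention grows with DP; shared-composition
ladders are separated by distinct intercepts), a geometric per-DP
abundance decay (smallest oligomers most abundant), and a response
slope of QTOF-like magnitude.

Acquisition mirrors the targeted method: 0.63 spectra/s over a 45 min
gradient, Gaussian peaks of sigma 0.1 min, data-dependent top-5 MS2
with 30 s dynamic exclusion and the linear collision-energy function
`CE = 1.45*(m/z) - 3.5` (stored verbatim on each MS2 scan; nothing
downstream depends on its absolute scale). Peak area is exactly
proportional to concentration x decay weight x response slope. Noise
has three independent dials: additive Gaussian baseline noise on each
monoisotopic channel (default sigma 0.5% of the run's tallest signal;
an absolute-counts mode emulates constant instrument noise across a
dilution series, which is what makes detection limits
concentration-dependent), a per-oligosaccharide multiplicative area
noise (default 0; validation simulations use a 5% CV, representing
run-to-run reaction and injection variability), and a per-run mass
calibration error (sigma 2 ppm). Isotope envelopes use a
carbohydrate-like one-parameter model (Poisson in the carbon count),
sufficient because only monoisotopic traces are quantified. Runs are
byte-reproducible per seed and carry their ground truth.

What the generator does *not* emulate — and therefore what passing
tests do not demonstrate about real data — includes matrix ion
suppression, depolymerization yield chemistry and its sequence
preferences, nonlinear retention drift between runs, detector
saturation, and profile-mode peak shapes. The validation claims are
claims about the pipeline's correctness under its stated statistical
model, not about chemical accuracy on real foods.

# Validation problem sizes

The package validates itself end to end at sizes chosen to exercise
every code path while staying comfortably interactive: a
nine-polysaccharide library from one standard run each; a six-level
two-fold dilution series from 2000 ug/mL with 5% area noise; three
replicate unknowns at 500 ug/mL (recovered within 10% bias and 10% CV,
with all curve r^2 above 0.99); a three-polysaccharide 70/20/10
mixture recovered within 2 percentage points by relative
quantitation; and a 20-seed noise-doubling experiment confirming the
detection limit never decreases when noise doubles. The acceptance
script (`scripts/acceptance.R`) recomputes all of these from scratch
at a caller-supplied seed.

# Numerical and design notes

- **mzML**: files are written by a minimal built-in mzML 1.1.0
  serializer (centroid spectra, uncompressed little-endian 64-bit
  floats) and read back through `mzR`; the asymmetry is intentional —
  reading through the field-standard parser makes every round-trip
  test an interoperability check of the writer.
- **MGF**: a purpose-built line-oriented reader/writer (BEGIN
  IONS/PEPMASS/RTINSECONDS/CHARGE), yielding MS2-only records.
- **Determinism**: every stochastic step flows from one seed;
  pipeline commands log a configuration hash and the tool version, and
  identical inputs give byte-identical result tables.
- **Tie-breaks** are total orders everywhere (annotation: |ppm| then
  fewer classes then lower DP; top-3: area then lower DP then
  lexicographic; RT ties: larger library area plus a warning), so no
  result depends on input ordering.
- **Degenerate inputs** fail loudly: empty compositions, charge zero,
  sub-five-level calibrations, all-zero areas, spectra with no
  baseline, libraries with unparseable rows (reported with their line
  number).
- **Known limitations**: single charge state by default; no
  cross-ring fragments; no RT warping between instruments; fructans
  and galacturonan-type pectins are outside the supported set, as
  they are for the wet-lab method this models.
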