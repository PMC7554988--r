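---
title: "Conservation and stability analysis of the Fe-S assembly supercomplex and frataxin"
author: "FeSConserv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation and stability analysis of the Fe-S assembly supercomplex and frataxin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FeSConserv)
```

## The scientific problem

Iron-sulfur ([Fe-S]) clusters are assembled in mitochondria by a
supercomplex built around the cysteine desulfurase NFS1, which is
stabilised by ISD11/ACP, loads persulfide onto the scaffold ISCU, and is
kinetically activated by frataxin (FXN). Frataxin deficiency causes
Friedreich's Ataxia (FRDA), so the conservation of the residues that
wire this machine together — and the stability of the frataxin fold —
are of direct biomedical interest.

This package implements the quantitative analyses used to compare such a
machine across organisms:

1. **Structure-derived interfaces** — which residues of one subunit lie
   within a distance cutoff of a partner subunit or cofactor, and how
   solvent accessibility changes when the complex assembles.
2. **Homolog mapping** — pairwise alignment of subunit orthologs, with
   identity/similarity computed overall and restricted to interface
   regions, and cross-referencing of disease-annotated positions.
3. **Deep conservation profiling** — trimming and per-column statistics
   of a curated multi-genome frataxin alignment: modal-residue
   frequencies, threshold counts, absolute conservation, logo matrices.
4. **Stability thermodynamics** — two-state chemical (linear
   extrapolation) and thermal (Gibbs-Helmholtz) unfolding fits,
   chain-length (Myers) correlations, cross-homolog alanine-scanning
   ddG correlations, and sequence-derived constants.
5. **Spectroscopy** — Savitzky-Golay fourth-derivative UV analysis,
   chromophore reference mixtures and Ellman thiol stoichiometry.

Every stage has a seeded synthetic-data generator with machine-readable
ground truth, so the full pipeline is testable without downloading
structures or sequence databases.

## Interface extraction and accessibility

A contact residue is any residue with a heavy atom strictly closer than
the cutoff (default 4.0 Å) to any heavy atom of the partner. Three
conventions are deliberate and echoed in every report:

* the cutoff is **strict** (`< 4.0`), so a nearest pair at exactly
  4.000 Å is excluded;
* **heavy atoms only** — cryo-EM models carry no reliable hydrogens, so
  hydrogens, if present, are ignored;
* waters are excluded at parse time, while other hetero groups (the
  PLP-derived cofactor, metals) participate only when named explicitly
  through a `"resname:XXX"` ligand selector, making protein-cofactor
  interfaces first-class.

Alternate locations are resolved to the highest-occupancy copy, ties to
the alphabetically first altloc. Because homodimeric complexes contain
two copies of each interface, the chain used for a given role is a
required configuration entry rather than something the code guesses.

Solvent accessibility uses the Shrake-Rupley construction: each atom is
inflated by the probe radius (1.4 Å) and sampled with a deterministic
golden-spiral quadrature (960 points by default; an isolated atom
reproduces its analytic sphere area to well under 1%, and doubling the
points changes totals by < 0.5% on the shipped fixtures). Radii come
from the Bondi set (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, ...).
Relative accessibility divides by the Tien et al. (2013) theoretical
residue maxima; the change upon binding is computed by running the same
quadrature with and without the partner chains as occluders, which
guarantees `sasa_complex <= sasa_free` point-by-point. Points that fall
exactly on a neighbouring sphere (degenerate geometry such as
duplicated atoms) are assigned deterministically to the earlier-indexed
atom. An idealised fully extended Gly tripeptide built by
`makeExtendedPeptide()` recovers ~80-85% of the tabulated
conformational maximum for the central residue — the reference values
are maxima over conformers, so a single idealised backbone sits
slightly below them; the test suite asserts a band around 100% rather
than equality.

## Homolog mapping

`alignPair()` ships two parameterisations: **local** alignment with
BLASTp-style scoring (BLOSUM62, gap open 11, extend 1) for reproducing
published identity tables, and **global** (open 10, extend 0.5) for
position-mapping tasks. A gap of length L costs `open + extend * L`.
The dynamic programming engine is Biostrings; the test suite verifies
its optimum against an exhaustive enumeration oracle on short
sequences, and identity/similarity/region statistics are computed here.

Identity under the default `aligned_columns` denominator counts all
columns of the (sub)alignment including gapped ones (the BLAST
convention); similarity means a positive BLOSUM62 score. For
region-restricted identity the denominator question has no published
answer, so the conservative default counts **every** region position,
scoring unaligned positions as non-identical; `aligned_only` is
available, and the policy used is recorded in each report.

## Conservation profiling

`readTrimAlignment()` applies two curation rules: columns whose gap
fraction exceeds 0.5 ("most sequences have gaps") are removed, and
columns beyond the last residue of the reference (human) record are
cut. Trimming is idempotent and logs the removed column indices.

"Conserved in more than X% of genomes" is operationalised as the modal
amino-acid frequency strictly greater than X with denominator equal to
**all** records, so gaps count against conservation; gaps are never
modal, ties break alphabetically (and are flagged), and absolute
conservation means the modal count equals the record count. Because
the gap-denominator convention is genuinely ambiguous in the
literature, `thresholdCounts(denominator = "nongap")` exposes the
alternative without changing the default. Information content is
`log2(20)` minus the Shannon entropy of the gap-free amino-acid
distribution, the quantity rendered by sequence-logo tools.

Column-to-reference maps convert alignment columns to human residue
numbering; an `offset` argument converts domain-local numbering to
full-protein numbering (e.g. a functional-domain alignment whose first
reference residue is position 91 of the mature protein uses offset 90).

## Unfolding thermodynamics

Chemical denaturation is fitted with the six-parameter two-state model

$$y(c) = \frac{(a_N + b_N c) + (a_U + b_U c)\,K(c)}{1 + K(c)},
\qquad K(c) = e^{-(\Delta G^0 - m c)/RT},$$

with R = 1.9872e-3 kcal mol^-1 K^-1 and sloped baselines on both sides
(fluorescence baselines are rarely flat). Starting values are
data-driven — plateau linear fits, the midpoint from the apparent
unfolded-fraction crossing of 0.5, and m from the 20-80% transition
width — and the optimiser is Levenberg-Marquardt. `Cm = dG0/m` is
derived, standard errors come from the fit covariance, and a curve
whose plateaus cannot be separated raises a "no transition" error
rather than returning nonsense.

Thermal denaturation uses the Gibbs-Helmholtz stability curve

$$\Delta G(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right) +
\Delta C_p\left[(T - T_m) - T \ln\frac{T}{T_m}\right]$$

with linear baselines in temperature. ΔCp is a **fixed input**, not a
fitted parameter — a single ramp cannot constrain it — and sensitivity
to that choice is explored by refitting across a ΔCp grid. The fit
reports ΔG extrapolated to a stated reference temperature (default
293.15 K).

`myersPredict()` implements the empirical chain-length correlations
(ΔASA = −907 + 93 n; m = (374 + 0.11 ΔASA)/1000;
ΔCp = (−251 + 0.19 ΔASA)/1000). The n = 116 values are pinned in the
tests as a guard against transcription errors in the coefficients.

Cross-homolog energetics consume alanine-scanning ddG tables (computed
externally by structure-based tools and read as CSV) and report Pearson
r with a least-squares line per conservation class (all / conserved /
non-conserved / disease-linked), the standard way to ask whether two
homologs share sequence-stability constraints.

Sequence-derived constants use the Gill-von Hippel residue
contributions for the 280 nm extinction coefficient
(5500 nTrp + 1490 nTyr + 125 nCystine), Expasy average residue masses
plus one water for the chain mass, and bisection of the
Henderson-Hasselbalch net-charge equation with an EMBOSS-style pKa set
for pI. pKa-set choice moves a computed pI by roughly ±0.2 pH units, so
pI is reported as indicative rather than treated as a checkable
constant. SEC mass inference fits log10(mass) against elution volume
for globular standards and propagates the prediction SE.

## Fourth-derivative UV spectroscopy

Spectra are uniformly sampled (0.1 nm is typical); non-uniform input is
resampled by linear interpolation with a logged warning. The
Savitzky-Golay defaults — window 11 points, polynomial order 5 — are a
choice this package documents explicitly (the filter is standard; its
parameters rarely are) and records in the output metadata. The filter
reproduces polynomials up to the fitted order exactly, so the 4th
derivative annihilates smooth baselines while sharp aromatic bands
survive; the half-window edge region is marked invalid. Band positions
are local maxima filtered by topographic prominence and refined below
the sampling step by parabolic interpolation; a planted Gaussian band
is localised to within ±0.1 nm in the tests.

`referenceMixture()` converts a protein concentration and aromatic
composition into the matched NATA/NAYA/Phe chromophore mixture, and
`thiolRatio()` is the Beer-Lambert algebra of the Ellman assay. The
TNB extinction coefficient is a required input with no default: assays
are run at different detection wavelengths (some protocols monitor
around 425 nm rather than the canonical 412 nm), and published band
wavelengths occasionally carry obvious misprints (a "189.0 nm"
tryptophan-model band can only be a typo for ~289 nm), so this package
refuses to guess.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions for the test suite:

* `makeToyComplex()` — two pseudo-chains with an exact planted contact
  set (< 4 Å) and everything else beyond 6 Å. It exercises contact
  logic and ΔSASA, not realistic fold geometry.
* `makeOrthologPair()` — exact planted identity counts inside and
  outside a region. Substitutions are uniform over the other 19
  residues; no evolutionary model is implied.
* `makeMsa()` — per-column planted modal frequencies (defaults: 54
  records, 120 columns, 3 absolutely conserved columns and 49/21/10
  above 50/80/90%, mirroring a curated functional-domain alignment);
  no phylogenetic correlation between rows.
* `simulateUnfolding()` — forward two-state curves at the marginal
  stability regime of a small mesophilic frataxin (ΔG0 4.3 kcal/mol, m
  1.55 kcal/mol/M chemical; Tm 330 K, ΔHm 60 kcal/mol, ΔCp 1.6
  kcal/mol/K thermal) with Gaussian noise at 2% of the signal span for
  noisy ensembles.
* `simulateSpectrum()` — Gaussian bands on a uniform grid.

Every generator restores the caller's RNG state and is byte-identical
under a fixed seed. Passing tests therefore demonstrate correctness of
the algorithms under controlled truth; they do not demonstrate
robustness to instrument drift, alignment errors, or non-two-state
folding, none of which the generators emulate.

Real structure coordinates and database accessions are not bundled:
coordinate files are megabyte-scale and redistributable sequence sets
belong in their archives. Stages that would consume them are exercised
on the synthetic stand-ins above; applying the package to the real
inputs is a matter of pointing `runInterfaceConservation()` at the
downloaded files.

## Numerical choices and scale

Fits run on 30-40 point curves; quadratures default to 960 sphere
points; property-style tests sweep 200 generator seeds for contact and
conservation truth and 500 noisy replicates for confidence-interval
coverage (t-based 95% intervals must cover in 90-99% of replicates).
These sizes keep the full suite under half a minute on one CPU while
leaving the statistical assertions well-powered.

## Known limitations

* Two-state models only; intermediates or kinetic schemes are out of
  scope.
* ddG tables are inputs; no force-field energetics are computed here.
* The alignment engine does not perform database searches; reciprocal
  best hits and E-values belong to the upstream tools.
* Relative SASA depends on the reference maxima chosen; only the Tien
  theoretical set ships.
* pI is pKa-set dependent and reported as indicative.

## A worked example

```{r example}
toy <- makeToyComplex(8, 8, 4, seed = 31)
pair <- makeOrthologPair(8, region = toy$truth$contactsA,
                         regionIdentity = 1, backgroundIdentity = 0,
                         seed = 31)
pdb <- tempfile(fileext = ".pdb")
writeLines(toy$pdbText, pdb)
report <- runInterfaceConservation(list(
  structure = pdb,
  roleChains = list(HUB = "A", PARTNER = "B"), hubRole = "HUB",
  pairs = list(HUB = list(a = pair$seqA, b = pair$seqB)),
  alignMode = "global"))
formatReportTable(report)

fit <- fitChemicalUnfolding(
  simulateUnfolding("chemical", nPoints = 37, noiseSd = 0.02,
                    seed = 7)$curve$x,
  simulateUnfolding("chemical", nPoints = 37, noiseSd = 0.02,
                    seed = 7)$curve$y)
fit

myersPredict(116)
```
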