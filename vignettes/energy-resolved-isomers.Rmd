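---
title: "Differentiating isomeric peptides by energy-resolved CID and NIPALS PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiating isomeric peptides by energy-resolved CID and NIPALS PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpep)
library(dplyr)
```

## The analytical problem

Sequence isomers share a molecular formula, a monoisotopic mass and a
precursor m/z, so they can only be told apart by how they fall apart. For
arginine-rich peptides even that is hard: gas-phase basicity concentrates
the protons on arginine side chains, and CID then proceeds largely through
*charge-remote* neutral losses — ammonia, water, and the arginine-specific
carbodiimide (CH2N2) and guanidine (CH5N3) — repeated consecutively. These
dominant product ions carry no sequence information and are common to all
isomers. The structure-bearing fragments (conventional b/y ions, internal
ions, and scrambled b ions from macrocycle reopening) are one to two orders
of magnitude weaker.

`erpep` addresses this with three coupled tools:

1. an exact fragment model that *predicts* every candidate ion, including
   the neutral-loss combinatorics and the scrambling pathway;
2. energy-resolved summaries (Survival Yield and breakdown curves) that
   describe fragmentation as a function of collision voltage;
3. NIPALS PCA on the full spectra, whose loadings localise the weak
   isomer-specific channels that visual inspection misses.

The built-in reference system is the trio of carnosine–TAT1 conjugates
(carnosine = β-alanyl-histidine grafted onto GRKKRRQRRRPS at either end or
mid-sequence), but every function takes arbitrary sequences, residue tables
and loss catalogues.

## Mass and ion model

Residue masses are derived from elemental compositions with monoisotopic
atomic masses to 7 decimal places; β-alanine is a first-class residue code
(`bA`, C3H5NO, mass-identical to alanine). A fragment's m/z is

$$ m/z = \frac{m_\text{neutral} - \sum m_\text{loss} + z \cdot 1.007276}{z} $$

with b-type ions (conventional, internal, scrambled) weighing the sum of
their residue masses and y ions and the precursor adding one water. The
neutral-loss catalogue stores the four default losses at the 4-decimal
masses conventional in this field (17.0265, 18.0105, 42.0218, 59.0483 Da);
each is verified against its formula within 1e-4 Da in the test suite, and
users can extend the catalogue from delimited text.

One deliberate consequence of the mass model is worth knowing: the
full-length b ion equals the intact peptide minus water, so `[bn]z+` is
mass-identical to the precursor's water loss. The annotator resolves such
exact ties by a least-exotic rule (fewest losses, then conventional >
internal > scrambled, then lower charge), which assigns that peak to the b
ion — the same reading spectroscopists use.

## Fragment enumeration

`enumerate_conventional()` emits b1..bn and y1..y(n-1) at each charge up to
`max_charge` (bn included: it is a real CID product here).
`enumerate_loss_series()` expands any base ion by every multiset of neutral
losses up to `max_total` (default 4), with per-loss caps: ammonia ≤ 4,
water ≤ 2, and carbodiimide/guanidine each capped by the ion's arginine
count, since they are shed from arginine side-chain termini. Combinations
that would exceed the fragment's own mass are silently excluded.

`enumerate_scrambled()` models scrambling *combinatorially*: the b_n ion
cyclises head-to-tail and may reopen at any amide bond, so every contiguous
substring of the cyclic sequence is emitted as a b-type ion — full-length
rotations as `scrambled_b`, shorter spans as `internal_b`, with the (start,
length) span kept as provenance. No energetics are modelled; the catalogue
is a superset that must *contain* the observed pathway (for T-Car-T, the
rearrangement RRRPS·GRKKRRQ at m/z 781.99, observed only after water loss
at 772.98). The default minimum span is 2 residues; single-residue acylium
ions are chemically marginal and excluded.

`build_catalogue()` unions all of the above, deduplicating by (kind,
residue composition, charge, loss multiset) so mass-identical rotations
collapse to one m/z row with merged provenance. For a 14-residue peptide at
charge ≤ 2 this yields ~18,000 distinct candidates.

## Energy-resolved curves

The Survival Yield of a spectrum is the precursor's share of the total ion
current,

$$ SY = \frac{I_\text{precursor}}{I_\text{precursor} + \sum I_\text{fragment}}, $$

computed with all centroids within `tol` (default 0.05 Th) of the precursor
m/z counted as precursor — an explicit isotope policy; anything beyond the
window counts as fragment. Breakdown curves apply the same ratio to any
target m/z. Both are scale-invariant, so raw and TIC-normalised spectra
give identical curves; replicates are averaged as ratios so unequal TICs
cannot weight them. A voltage at which the target is absent contributes 0 —
absence is evidence (a diagnostic peak absent in the other two isomers),
not missing data. No CE50 interpolation is performed; a logistic
`fit_depletion()` utility exists for curve summaries but the curves
themselves are the result.

## Chemometrics

Spectra are TIC-normalised (each spectrum sums to 1), aligned into a
samples × variables matrix by single-linkage gap clustering (peaks sorted by
m/z, split where the gap exceeds `tol`, default 0.02 Th — appropriate for
>15,000 resolving power at m/z < 900, and configurable), and mean-centred.
**No variance scaling is applied.** This is load-bearing: with centred,
unscaled data the PCA loading magnitude of a variable is proportional to
its intensity spread, which for these designs tracks fragment abundance —
the property that lets the loading plot double as a sensitivity ranking.

NIPALS extracts components one at a time (score seeded from the
largest-sum-of-squares column, alternating regressions, deflation),
converging when the relative change of the score vector drops below `tol`
(default 1e-9, `max_iter` 500). Signs are fixed so each loading vector's
largest-magnitude element is positive. Explained variance per component is
the score's squared norm over the total centred sum of squares. Requesting
components beyond the matrix rank yields ~0%-variance components flagged
`low_variance`, with loadings completed orthonormally. With n samples of
one analyte each (or replicates of three analytes), two components of a
centred matrix of three analytes capture 100% of the variance — the rank
bound, reproduced in the tests.

Convergence note: NIPALS is a power iteration, so its rate degrades as the
top two eigenvalues approach each other. The three-isomer design is nearly
symmetric between two of the analytes, which can make PC1/PC2 nearly
degenerate; for pipeline use the default 1e-9 tolerance is appropriate,
while the oracle-equivalence tests (against a dense eigendecomposition) use
1e-13 with a large iteration cap on generic random matrices.

Diagnostic ranking (`rank_diagnostics()`) uses known analyte labels — the
score plot identifies the analytes, so unsupervised clustering is out of
scope. Each group's mean score vector (unit-normalised) is its direction in
component space; a variable's *specificity* for the group is the cosine of
its loading vector against that direction, and the ranking score is
specificity × loading magnitude, ties broken by ascending m/z. The pairwise
cosine matrix between loading vectors exposes consecutive-fragmentation
series: fragments formed by successive losses from one ion have
proportional intensity profiles, hence aligned loadings (cosine ≈ 1).

Restricting the matrix to m/z 600–800 before PCA removes the dominant
non-specific loss channels (which live in 800–900) and focuses the
components on structure-bearing variables. Rows are deliberately *not*
re-normalised after restriction: normalisation refers to the full-spectrum
TIC, and re-normalising would distort the abundance–loading relationship.

## The synthetic-data generator

No public raw spectra exist for this system, so the generator is the ground
truth for every downstream stage. It is phenomenological, not kinetic
(no RRKM theory): per analyte, precursor depletion follows
SY(V) = 1/(1 + exp((V − v50)/w)); the depleted fraction is split over
primary channels in proportion to weight × logistic gate; each consecutive
channel drains weight × gate of its parent's allocation, with per-parent
drains summing below 1. Because each child's gate opens later and its drain
is bounded by design below the parent's retention, child curves are
right-shifted with lower maxima — the defining signature of consecutive
fragmentation — and intensity is conserved exactly at every voltage
(SY + Σ channel fractions = 1), which the conservation tests exercise
end-to-end.

The default three-isomer scenario sets, once: voltage grid 20–42 V in 2 V
steps; depletion v50 = 31.2/32.0/31.6 V with width 3.2 V, so noiseless SY
at 36 V is ≈ 0.2 (the regime in which the diagnostic channels are
expressed, with Car-TAT1 depleting slightly earlier); four shared
precursor-loss channels at catalogue m/z 886.53/874.03/865.52/857.00
carrying the bulk of the fragment current; and analyte-specific channels at
1.2–5% of TIC — the y12 consecutive-loss series for Car-TAT1, the scrambled
bβ−H2O series for T-Car-T, and b10²⁺ plus its carbodiimide loss for
TAT1-Car. Every channel m/z is computed through the fragment model at call
time. Noise defaults: multiplicative log-normal σ = 0.05, additive uniform
baseline at 0.1% of the base peak, m/z jitter σ = 0.003 Th; three
replicates; everything seeded and bit-reproducible.

What the generator does *not* emulate: isotope envelopes, centroiding
artefacts from profile data (profile synthesis exists only to exercise the
Savitzky–Golay/centroiding path), detector saturation, chemical noise with
structured m/z, or voltage-dependent mass drift. Passing the recovery tests
therefore shows the pipeline is correct and sensitive under the stated
statistical structure — small group-specific channels under multiplicative
noise — not that any particular instrument will achieve the same
separation.

## Numerical and I/O choices

* Proton mass 1.007276 Da; atomic masses to ≥ 6 decimals; m/z kept at full
  double precision internally and rounded only for display/reporting at the
  2 decimals conventional for this instrument class.
* Savitzky–Golay smoothing defaults to a 5-channel window of order 2 (the
  standard order for 5-point windows); centroids are intensity-weighted
  means over threshold-exceeding segments split at interior local minima,
  which resolves peaks 0.5 Th apart at instrument-like widths.
* Annotation tolerance defaults to 0.02 Th absolute (2-dp reporting at
  >15,000 resolution), with a ppm mode; one annotation per peak by default,
  an exhaustive mode behind a flag.
* MGF identity travels in TITLE `key=value` tokens; delimited peak lists
  require a header and a metadata sidecar; mzML goes through mzR and takes
  the voltage from the standard collision-energy attribute. Missing
  voltage or analyte metadata is an error, never a default.
* Test problem sizes: oracle equivalence on random matrices up to 10 × 50;
  the scrambling oracle sweeps all sequences of length ≤ 6 over a 4-letter
  alphabet; recovery runs 20 seeded replicates of the 9-spectrum,
  3-analyte design. These sizes make the whole suite run in about a minute
  while covering every code path.

## Known limitations

* The scrambling model is combinatorial; it over-generates relative to any
  single experiment and assigns no probabilities. It is a candidate space,
  not a prediction of intensities.
* Average (non-monoisotopic) masses, isotope patterns, and non-proton
  adducts are out of scope, as are deisotoping and charge deconvolution of
  input spectra.
* Two printed-report discrepancies in the reference system are knowingly
  not reproduced: a diagnostic peak variously reported as 751.88/751.98
  (the model computes 751.97 for carbodiimide loss from 772.98, and emits
  that), and a 796.98 peak described as a precursor loss that no simple
  loss combination reaches within the default catalogue (left unassigned
  rather than forced).
* PCA assumes the aligned variables are commensurate across spectra; with
  real data, calibration drift beyond the alignment tolerance would
  fragment variables, and the tolerance should be widened accordingly.
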