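---
title: "Methods: ensemble, polymer and single-molecule models in casidp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble, polymer and single-molecule models in casidp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casidp)
```

# The scientific problem

The substrate domain of p130Cas (CasSD) is a ~306-residue, proline-rich
(~20% Pro) intrinsically disordered domain carrying 15 regularly spaced
YxxP motifs, the Src-family kinase substrate sites through which focal
adhesions report mechanical stretch. Because the domain has no single
folded structure, its characterization is statistical: a conformational
ensemble whose size statistics (radius of gyration, hydrodynamic radius,
friction ratio) and local backbone preferences (polyproline-II content)
can be compared against solution measurements, and single-molecule
force-extension experiments whose unfolding events can be fitted with the
worm-like-chain (WLC) model. `casidp` implements that full desk-side
pipeline — sequence analysis, biased ensemble generation, polymer and
hydrodynamic statistics, and AFM trace analysis — together with synthetic
generators for every input, so the whole analysis runs and is tested
without any download.

# Conformer sampling model

## Ramachandran basins

Backbone conformations are drawn per residue from four parametric basins
(`basin_library()`):

| basin    | center (phi, psi) | spread | classification rectangle |
|----------|-------------------|--------|--------------------------|
| PPII     | (-75, 145)        | sigma 15 deg | phi (-115, -40], psi (90, 180] |
| beta     | (-135, 135)       | uniform over rectangle | phi (-180, -115], psi (90, 180] |
| alpha_R  | (-63, -43)        | sigma 10 deg | phi (-140, -40], psi (-90, 40] |
| alpha_L  | (60, 45)          | sigma 10 deg | phi (20, 110], psi (-10, 100] |

The rectangles are pairwise disjoint and used both for classifying
sampled conformations (`classify_conformation()`; the two alpha basins
merge into one "alpha" label for reporting) and, for the beta basin, as
the sampling region itself. The beta basin samples *uniformly* over its
rectangle rather than from a tight Gaussian: beta-assigned dihedrals in
real coil libraries scatter across the whole upper-left region of the
Ramachandran plate, and the uniform draw keeps the degenerate
all-beta-weights case classified 100% beta while giving the beta
ensemble realistic conformational breadth. A Gaussian beta basin narrow
enough to stay inside any legal rectangle produces quasi-crystalline
strands whose ensembles are far more expanded than any observed
disordered chain.

Per-residue sampling states follow a 3-state weight profile
(`weight_profile()`): the alpha state draws from alpha_R, the beta state
from the beta basin, and the coil state from a mixture over all four
basins. The coil mixture default (`PPII : beta : alpha_R : alpha_L =
0.55 : 0.02 : 0.33 : 0.10`) was calibrated once so that a coil-biased
ensemble of the 323-residue tagged construct has a mean radius of
gyration near 50 Å, the value solution measurements of CasSD support,
while keeping PPII the majority classification of raw draws. The
calibration leans on alpha_R rather than alpha_L because only
right-handed turn interruptions compact the PPII-rich chain enough to
reach that regime; mixtures that favor alpha_L plateau near 56 Å.

Prolines have their phi clamped near -65 degrees (sigma 7) regardless of
basin, reflecting the pyrrolidine ring constraint. Each peptide bond
preceding a proline is cis (omega = 0) with probability 0.04, capped at
6 cis-prolines per chain — with ~61 prolines this gives an expected 2–3
cis bonds per conformer, inside the 0–6 range such samplers produce.
All other omega angles are exactly 180 degrees (ideal trans geometry).

## Chain growth and clash rejection

Coordinates are built with fixed ideal geometry (N–CA 1.458 Å, CA–C
1.525 Å, C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°;
carbonyl O trans to N), by natural-extension-of-reference-frame
placement. A chain is *grown* residue by residue: each newly placed
C-alpha is tested against all C-alphas at sequence separation >= 3 at a
4.0 Å threshold; on a clash the residue is redrawn (up to 50 times),
then the chain backtracks 8 residues; a chain exceeding 2000 backtracks
restarts from scratch. Growth with local retries is how
trajectory-directed ensemble samplers reach compact conformations.
Whole-chain rejection sampling was implemented first and abandoned: it
conditions the accepted ensemble on having *no* sub-4 Å contact anywhere
along 322 residues, which both collapses the acceptance rate (below 0.1%
for any mixture compact enough to be realistic) and biases the accepted
chains strongly expanded (coil means stuck near 75 Å). The clash
criterion itself is unchanged, and every accepted conformer is
re-verifiable by an independent all-pairs scan (`clash_check()`; the
test suite does exactly that).

The dihedral-to-coordinate construction round-trips: measuring dihedrals
from built coordinates reproduces the inputs to better than 1e-3
degrees (the terminal psi is recovered through the carbonyl oxygen).

## Ensemble scale

The reference analyses here use 3,000 conformers per preset of the
323-residue tagged construct, which characterizes the ensemble mean to
a standard error of ~0.2–0.3 Å; the full-scale analogue of this kind of
study (hundreds of thousands of chains) adds resolution to the
distribution tails but does not move the statistics the package reports.
`generate_ensemble(n = ...)` scales freely; runs are reproducible given
`seed`, with all randomness drawn from R's RNG so the C++ hot loop and R
wrappers share one stream.

# Polymer and hydrodynamic statistics

Radius of gyration is the RMS distance of backbone atoms (N, CA, C, O)
from their unweighted centroid; no mass weighting (the difference is
well under the calibration slack for backbone-only atom sets).
`ensemble_summary()` reports peak (modal 2 Å histogram bin center),
mean, median, SD and FWHM, the last as the distance between the
outermost half-maximum crossings of the binned density with linear
interpolation between bin centers — ensemble R_Gyr histograms are not
Gaussian, so FWHM rather than SD is the robust width.

The closed-form conversions are:

* R_H = R_Gyr / 1.06 (denatured/disordered-chain ratio), `rh_from_rgyr()`;
* Kohn scaling R_Gyr = 1.927 N^0.598 Å for a denatured chain of N
  residues, `kohn_rgyr()`;
* minimal anhydrous sphere R_min(nm) = 0.066 M^(1/3) (M in Da),
  `erickson_min_radius()` — the 0.066 coefficient is the unique value
  consistent with the standard printed example (21.6 Å at 34.9 kDa);
* friction ratio R_H / R_min with the empirical bands ~1.2–1.3 (nearly
  globular) and 2.0–3.0 (elongated), `friction_ratio()`,
  `friction_class()`;
* the tag correction Delta R_Gyr = l sqrt(c) (sqrt(N_total) -
  sqrt(N_domain)) with virtual bond l = 3.81 Å and the Flory-ratio
  constant c in [0.407, 0.595], `flory_tag_correction()` — about
  1.3 ± 0.1 Å for 17 tag residues on a 306-residue domain.

`ss_content_by_rgyr()` bins conformers into 5 Å R_Gyr windows and
reports the fraction of residue conformations classified PPII, alpha
and beta per bin; empty bins are omitted rather than reported as zero.

## What the ensembles do and do not reproduce

With the calibrated defaults, the coil-biased ensemble mean falls within
±10% of 50 Å; the orderings mean(beta) > mean(3-state) > mean(coil) and
FWHM(beta) > FWHM(coil) are stable across seeds; and PPII frequency
exceeds beta frequency in every populated bin of the coil ensemble. The
beta-biased ensemble, however, has a mean near 103 Å, well above the
~70 Å a dictionary-based beta-weighted sampler reports. That gap is
structural, not a tuning failure: reaching ~70 Å requires per-residue
dihedral scatter of roughly ±45–50 degrees, which cannot stay inside any
beta classification rectangle disjoint from the PPII rectangle. A
parametric-basin sampler therefore reproduces the qualitative beta
expansion and all orderings, but not the literal beta-ensemble mean of
an empirical-dictionary sampler; users comparing against such values
should treat the beta preset as an upper bound on expansion.

# AFM force-curve analysis

`wlc_force()` is the Marko–Siggia interpolation
F = (kB T / p) (1/(4(1 - x/L)^2) - 1/4 + x/L), with kB T = 4.114 pN nm
at the default 298 K. `detect_peaks()` finds unfolding peaks as local
maxima above the 15 pN detection floor followed by a force drop of at
least 10 pN before the next rise; the drop threshold is raised to 4x
the trace's estimated noise SD (median absolute successive difference)
so noise excursions are never called events, and terminal detachment
peaks — after whose drop the force never again reaches the floor — are
excluded. `fit_wlc_events()` least-squares fits the WLC to the rising
segment before each peak (valley-to-peak window), with the persistence
length either fitted freely or fixed at 0.4 nm (`p_fixed`), since
published protocols state neither; both modes are provided. The
contour-length increment of event i is L(i+1) - L(i), and the final
rising segment before detachment serves as the last reference contour —
this is what lets *both* I27 reference peaks in a two-domain polyprotein
trace carry a Delta-L near 28 nm, as the experimental fingerprint
requires. A trace truncated at its last peak yields NA.

`classify_trace()` applies the I27 fingerprint gate: events with
Delta-L in 28 ± 2 nm and force above 100 pN are I27 unfoldings; a trace
is rejected unless exactly two are present, type-1 if nothing else was
detected (the disordered domain stretched without measurable
resistance), type-2 otherwise. `event_scatter_stats()` summarizes the
non-I27 events (Pearson correlation of unfolding force vs Delta-L plus
observed ranges); independently drawn synthetic events give |r| < 0.1,
the signature of structurally random weak features.

# Synthetic-data generators

The generators define the study conditions and make every stage testable:

* `gen_proline_rich_sequence()` — exact motif count by construction
  (background positions never draw tyrosine, so no accidental YxxP),
  proline total hit to ±1 residue, uniform background over the 18
  remaining residues. Defaults: 306 residues, 19.9% proline, 15 motifs
  at period 20.
* `gen_alignment()` — substitution-only (no indels; identity statistics
  at this scale do not require indel modeling), motif Y/P columns never
  substituted, hotspot columns 2–9 residues before each motif tyrosine
  mutating at 0.36 vs background 0.08 — rates calibrated once by
  simulation to give ~71% mean pairwise identity for 11 rows.
* `gen_predictor_scores()` — 0/1 base signal on disordered segments with
  truncated Gaussian noise (default SD 0.05), emulating a 10-program
  disorder-predictor panel.
* `gen_afm_trace()` — WLC segments concatenated at scripted unfolding
  forces (weakest domain first), contour growing by each domain's
  increment, white Gaussian force noise, final detachment to 0 pN.
  Tether contour 60 nm and detachment at 250 pN are generic handle
  values; noise is white in force, which is sufficient to validate the
  fitter but does not emulate cantilever dynamics, drift or baseline
  curvature of real instruments.

What passing tests on these generators shows is that the *analysis
recovers what the generators encode* (motif counts exactly, Delta-L to
±0.5 nm noiseless, identity to ±2%); real data add correlated noise,
indels, instrument artifacts and predictor disagreement that the
generators deliberately omit.

# Disorder consensus and sequence statistics

Each predictor's scores are min–max normalized to 0–9 (constant-score
programs cannot be normalized and are excluded from the vote with a
warning); a residue counts as called disordered by a program when its
normalized score reaches that program's threshold (default 4.5, the
scale midpoint). The tier bands on the vote fraction are: under 0.5
"less", 0.5–0.7 "intermediate", 0.7–0.9 "disordered", 0.9 and above
"extensive". The source procedure's bands leave 60–70% (and 80–90%)
undefined and call the classification arbitrary; assigning the gaps to
the adjacent lower tier is the unique choice that keeps the tier a
monotone function of the vote fraction, which the test suite asserts as
a property.

Percent identity is the mean over all row pairs of identical ungapped
columns over ungapped columns — the simplest estimator consistent with a
single cross-domain identity figure. Column variability is 1 minus the
modal-residue frequency; hotspot columns are those above a configurable
variability quantile (default 0.75), each reported with its distance to
the nearest downstream motif tyrosine. Pseudo-repeat structure is
reported descriptively through the motif spacing table (`find_yxxp()`),
whose modal spacing is the repeat-unit length; no repeat-unit assertion
is made because the unit length is not defined numerically anywhere
authoritative.

Molecular weight is the sum of standard average residue masses plus one
water, no modifications — checked in the tests against an independent
implementation to within rounding.

# Known limitations

* Backbone-only chains: no side chains, so R_Gyr is a backbone R_Gyr;
  the offset against all-atom values is absorbed into calibration slack.
* The beta-preset mean exceeds dictionary-based values (see above).
* The clash model is C-alpha-only at 4.0 Å; atom-level excluded volume
  would reject a small additional fraction of conformers.
* The consensus procedure is deliberately crude (its source calls it
  arbitrary); it illustrates trends, not per-residue truth.
* `alignment_stats()` assumes a pre-aligned, mostly gapless input; it
  does not build alignments.
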