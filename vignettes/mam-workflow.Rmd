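---
title: "The mamtools multi-attribute workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mamtools multi-attribute workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamtools)
```

## The problem

A therapeutic monoclonal antibody carries dozens of chemical
modifications — methionine oxidation, asparagine/glutamine deamidation,
tryptophan dioxidation, N-terminal pyroglutamate, C-terminal lysine loss,
Fc N-glycosylation, lysine glycation — whose levels must be monitored
through process development and release. The multi-attribute method (MAM)
measures all of them in one tryptic peptide-map LC-MS run: each attribute
is quantified as the relative abundance of its modified peptide against
all forms of the same backbone peptide, an untargeted new-peak comparison
against a reference run guards against anything the targeted panel does
not cover, and subunit-level intact-mass analysis covers attributes (like
total light-chain glycation) that trypsin chemistry obscures at the
peptide level.

`mamtools` implements this workflow as composable R functions plus a thin
CLI. This vignette explains the models and algorithms, the parameters
that matter, what the bundled simulator does and does not emulate, and
the design decisions taken where the method definition was genuinely
open.

## Mass arithmetic and the target-species panel

All masses are monoisotopic (subunit species excepted, below). A target
species is one molecular form of a tryptic backbone peptide:

```
neutral mass = sum(residue masses) + water
             + n_Cys * 57.021464        (fixed carbamidomethyl)
             + sum(modification deltas)
             + glycan mass (at most one)
```

Carbamidomethylation is treated as fixed because cysteines are alkylated
with iodoacetamide before digestion; a species therefore never appears in
both alkylated and free form. Glycan masses are additive over
monosaccharide residues (hexose 162.05282, HexNAc 203.07937, fucose
146.05791, NeuAc 291.09542 Da). m/z conversion uses the proton mass
1.0072765 Da and round-trips exactly.

Digestion uses the Keil rule — cleave C-terminal of K/R unless the next
residue is proline — with a default maximum of one missed cleavage.
Panel enumeration scans every fully cleaved backbone for eligible sites;
N-terminal pyroglutamate applies only to a chain-position-1 Q or E,
lysine loss only to a C-terminal K, and glycoforms only to a validated
N-X-S/T sequon (X != P). The relative-abundance denominator of an
attribute holds every enumerated form of its backbone exactly once:
modified, unmodified, and sibling modifications of the same peptide.

Deamidation is assigned per site without distinguishing Asp/isoAsp
products, which co-elute too closely to separate reliably in this kind
of gradient.

## XIC quantification

The quantification contract, with its defaults:

| parameter | default | unit | role |
|---|---|---|---|
| XIC width | 0.02 (batch) / 0.025 (characterization) | Da, full window | intensity summation around the theoretical m/z |
| Gaussian smooth width | 1.0 | points (sigma) | pre-detection smoothing |
| noise percentage | 40 | % of points | noise = mean of the lowest 40% of trace intensities |
| S/N threshold | 3 | ratio | apex gate together with... |
| minimum peak height | 50 | counts | ...the absolute intensity floor |
| minimum peak width | 3 | points | rejects spikes |
| baseline window | 2 | points | boundary means anchoring the linear baseline |
| peak splitting | 2 | apex/valley ratio | split threshold for adjacent apexes |
| m/z match tolerance | 5 | ppm | apex-spectrum confirmation of the target ion |

Peak detection runs on the smoothed trace: local maxima at or above
`max(min height, S/N threshold x noise)`, boundaries at the flanking
local minima, and adjacent apexes merged into one peak unless the ratio
of the smaller of (the group's tallest apex, the candidate apex) to the
intervening valley reaches the splitting threshold — comparing against
the group's tallest apex prevents a weak shoulder between two resolved
peaks from chaining them together. Areas are trapezoidal on the raw
trace after subtracting a linear baseline anchored on
`baseline window`-point means at each boundary, so integration is exactly
scale-covariant. Width-type parameters are interpreted in points (scan
units), not seconds: the scan cycle is fixed, and points keep the
contract grid-exact and testable.

Species measurement extracts one XIC per monitored charge (default 2–4,
configurable), keeps the largest integrated peak inside the expected
retention-time window (apex of the characterization run +/- 1 min by
default; the global maximum when no window is known), requires a
centroid within 5 ppm of the theoretical m/z in the apex spectrum, and
sums areas over charge states before applying the relative-abundance
formula. Summing charges ahead of the ratio makes the abundance
independent of the charge-state distribution as long as modified and
unmodified forms share it.

The XIC targets the monoisotopic peak only (isotope summation off by
default). One consequence worth knowing: forms with very different
masses have different monoisotopic envelope fractions, so a light form
(e.g. an aglycosylated peptide against 2.5 kDa-heavier glycopeptides) is
over-weighted by roughly the ratio of those fractions. For modification
pairs differing by one oxygen the effect is negligible; across a glycan
panel it stays inside the one-percent band the tests enforce, and it
cancels entirely from run-to-run comparisons of the same form.

MS/MS confirmation counts theoretical b/y ions (modification deltas
applied to the fragments containing the site) matched within 0.03 Da and
scores `10 x matched/theoretical`; auto-validation at score >= 3 maps to
at least 30% ion coverage, a deliberate re-interpretation of an opaque
vendor score scale onto an explicit ion-coverage fraction.

## New-peak detection

Candidate ions are built by clustering per-spectrum centroids over
retention time by m/z gap, assigning charge from the isotope spacing
(`~1.00335/z`, 10 ppm + 0.01 Da tolerance) and absorbing the
non-monoisotopic cluster members. Features must exceed 500 counts apex
height; singly charged features are excluded by default (dominated by
solvent and singly charged background in this m/z range). Peak quality
is defined as the Pearson correlation between the feature's trace
segment and its moment-fitted Gaussian, clipped to [0, 1] — an explicit
stand-in for an undocumented vendor metric, keeping the published 0.6
gate.

Cross-run pairing is greedy nearest-match by ppm distance, then RT
distance, gated at 10 ppm and 0.2 min; each feature pairs at most once.
Flags follow the rule table: test-only and passing the gates -> *new*;
reference-only -> *missing*; present in both -> *changed* when the area
fold change (test/reference) is >= 20 (untargeted) or >= 3 (targeted)
**or** at or below the inverse — the rule is symmetric because a
"difference in abundance above a threshold" has no direction; the
direction is recorded separately. Fold changes use areas, not heights.
Gate failures are reported as *below_threshold* with per-rule booleans
rather than dropped silently.

## Subunit deconvolution and glycation

At resolving power 2500 a ~23 kDa isotope cluster is unresolved, so
subunit species use average masses computed from average residue masses.
The reconstruction is an iterative peak-stripping scheme keyed to the
published parameter names: candidate neutral masses on a grid over the
configured mass range (step = mass / (2 x resolution)) are scored by the
summed spectrum intensity at the predicted m/z of every charge (default
8–35, clipped to the 400–3000 m/z window); each round refines the best
candidate — first by continuous optimisation of the score, then as the
amplitude-weighted mean of per-charge intensity-centroid mass estimates,
which averages grid and noise error across the charge states — subtracts
its predicted Gaussian envelope (FWHM = m/z / resolution, apex heights
taken above a local annulus-median baseline), and repeats for up to 20
rounds or until the best remaining apex falls below S/N 20. Total
glycation is the area share of all glycated stoichiometries (+162.0528,
+324.1056, ... Da) among the matched light-chain species (+/- 5 Da).
The deconvolved spectrum is the charge-averaged MS1 profile; per-scan
deconvolution is not attempted.

Local-baseline subtraction matters quantitatively: without it the noise
floor adds to every predicted charge position and biases a 5% minor
species upward by about one percentage point at realistic noise.

## QC statistics

Relative abundances classify as not-detected (< 0.1%), detected
(0.1–1%), or quantifiable (>= 1%). Pass/fail verdicts allow a deviation
of `m x SD(reference)` with `m` = 2.0 below 5% reference abundance, 1.5
between 5 and 15% (both boundaries read as the closed interval, so
exactly 5% and exactly 15% take 1.5x), and 1.0 above 15%. Because the
tiers are absolute, the verdict is scale-covariant only within a tier —
rescaling a reference across a tier boundary legitimately changes the
allowed band. RSD is `100 x SD/mean`, undefined (flagged `NA`) at zero
mean. Bland-Altman reports the mean bias of paired differences — sign
convention lab1 − lab2, recorded in the output — and limits of agreement
at bias +/- 1.96 x sample SD. Kruskal-Wallis group comparisons are
delegated to `stats::kruskal.test` with Holm-adjusted pairwise Wilcoxon
post-hocs as a convenience report.

## The simulator

`build_ground_truth` + `simulate_peptide_run` emulate a QTOF DDA
peptide-map acquisition: MS1 centroid spectra every 1.35 s over 300–1800
m/z, each species contributing per charge an averagine-approximated
isotope envelope (five isotopes, exact elemental convolution of the
averagine composition) scaled by a Gaussian elution profile (sigma 0.05
min), plus additive noise. Species retention times are drawn without
collision at >= 0.5 min spacing by adding fixed spacings to sorted
uniforms on the slack interval, which is always feasible and exactly
uniform given the spacing constraint. Noise magnitudes are drawn as
|N(0, sd)| — folding rather than zero-clipping keeps a realistic
positive baseline so the S/N machinery is actually exercised — with
default sd 5 counts and 40 random noise centroids per spectrum; per-site
backbone groups carry 2e5 counts so that a 0.5% form still clears the
50-count floor by an order of magnitude, matching an instrument operated
well above its detection limit. The subunit simulator places Gaussian
peaks at `(M + z * 1.0072765)/z` for the plain and glycated chain at
resolution 2500, log-normal charge weights around charge 15, apex height
5000 counts and noise sd 20.

Everything is bit-reproducible per (seed, config): ground-truth
construction and each simulation call seed the RNG explicitly.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: chromatographic tailing
and drift (peaks are pure Gaussians at fixed RT; there is no cross-run
RT alignment, matching a fixed-gradient assumption), co-elution and
interference beyond constructed fixtures, DDA precursor-selection
dynamics, in-source fragmentation, detector saturation, and real
isotope fine structure. Recovery tolerances (+/- 0.5 absolute percent
for PQA levels in the 0.5–6% range, +/- 1 for glycoforms, +/- 1 Da and
+/- 0.5 absolute percent for subunit deconvolution) are statements about
the workflow's numerics under these idealised conditions, not about
instrument accuracy.

Problem sizes used throughout the tests and the acceptance script: 8 min
gradients (~356 MS1 spectra), five-site oxidation panels over three
seeds, one eight-glycoform profile, ten subunit seeds, and oracle checks
on random chains up to 50 residues and traces up to 200 points — sizes
chosen so the full suite characterises every stage while remaining quick
to run routinely.

## Degenerate inputs and tie-breaks

* Empty XIC traces integrate to an empty peak table; noise of an
  all-zero trace is 0 and S/N is reported as infinite when noise is 0.
* A zero relative-abundance denominator yields abundance 0 with an
  explicit `denominator_zero` flag rather than NaN.
* Zero reference SD makes pass/fail demand exact equality, with a
  warning.
* Two theoretical subunit species claiming one reconstructed peak:
  the closer wins, with a warning; ties keep the first listed.
* Feature pairing ties are resolved by ppm first, then RT delta, then
  input order.
* Profile (non-centroided) spectra are accepted and flagged; the
  subunit deconvolution interpolates them directly.

## Known limitations

Site-resolved glycation is out of scope (trypsin miscleavage at
glycated lysines defeats peptide-level quantification — the subunit
route exists precisely for this); sequence-variant and host-cell-protein
searching, RT prediction, label-based or absolute quantification, and
vendor raw formats are likewise out of scope. NPD flags are not
identified — flagged features need manual re-analysis of the MS data.
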