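---
title: "Inferring quaternary structure from native mass spectrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring quaternary structure from native mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatMS)
```

This vignette is the package's account of its science: the models each
stage implements, the assumptions they rest on, the parameters that
matter, and the choices made where the design was genuinely open.

## 1. The inference chain

A native mass spectrum of an intact, noncovalently assembled complex
contains three layers of structural information, and the package treats
each as a separate, composable stage:

1. **Mass.** The charge-state envelope fixes the neutral mass.
2. **Stoichiometry.** The neutral mass, against a catalog of subunit
   masses, constrains the integer subunit counts.
3. **Connectivity.** Surface-induced dissociation (SID) releases folded
   subcomplexes; their compositions eliminate candidate arrangements.

A fourth, orthogonal readout — ion-mobility drift time, calibrated to a
collision cross section — reports on overall shape and is included as a
calibration utility.

## 2. Charge assignment and neutral mass

**Model.** Electrospray from ammonium acetate charges complexes by
protonation only, so an ion of neutral mass $M$ at charge $z$ appears at
$m/z = (M + z\,m_p)/z$ with $m_p = 1.007276$ Da. Salt adducts are treated
as mass heterogeneity, not charge carriers. All masses are *average*
masses: at a couple of hundred kilodaltons isotope structure is
unresolved, so monoisotopic bookkeeping would be spurious precision.

**Algorithm.** For adjacent peaks $p_1 > p_2$ in $m/z$, the unique charge
consistent with both being the same species at consecutive charges is
$z = \mathrm{round}\big((p_2 - m_p)/(p_1 - p_2)\big)$ for $p_1$. Envelopes
are maximal runs whose implied neutral masses agree within `tolPpm`
(parts per million, default 50 for clean data; several hundred is
appropriate when metal heterogeneity broadens and shifts centroids). The
mass estimate is the intensity-weighted mean of $z(m/z - m_p)$ over
members; its quoted FWHM is the median of $z \cdot \mathrm{fwhm}_{m/z}$,
since the $m/z$ axis is the mass axis compressed $z$-fold.

**Uncertainty regimes.** Peak width, not instrument accuracy, dominates
the error budget for heterogeneous complexes: a 55 Th wide peak at
$z = 29$ is ~1.6 kDa of mass-domain width, and that is the natural
composition-matching tolerance for the intact complex. For sub-10 kDa
fragments, widths of a couple of Da apply instead.

## 3. Centroiding

Profile spectra are reduced to peaks by local-maximum detection with two
thresholds, both expressed as fractions of the base peak: a minimum
apex intensity (`minRelIntensity`, default 0.01) and a minimum
prominence (`minProminence`, default 0). Apex positions are refined by a
weighted quadratic fit to log intensity over the peak top (points above
30% of the apex). For a Gaussian profile the log is exactly quadratic,
so the refinement is exact regardless of how the sampling grid is
aligned with the peak, and the least-squares averaging suppresses
point noise far better than a three-point parabola; the three-point
parabola remains as a fallback for peaks sampled by fewer than five
points. FWHM is linearly interpolated to half maximum on both flanks and
reported as 0 when a flank is truncated by the spectrum edge or an
overlapping neighbour — downstream code treats 0 as "width unknown".

**Profile/centroid auto-detection.** A spectrum is treated as profile
when its point spacings are near-uniform (coefficient of variation
below 1% — data on a sampling grid) or dense (≥5% of spacings below
0.05 Th); otherwise it is treated as centroided. The uniform-grid test
matters because envelope-level profile data of large complexes are
legitimately sampled at several Th per point, which a purely
spacing-threshold rule would misread as centroids. The flag `profile`
overrides the heuristic in either direction.

## 4. Integer stoichiometry

`solveCompositions()` is an exhaustive bounded enumeration, not a
branch-and-bound: realistic catalogs here have ≤3–4 subunit types with
tens of copies at most, the full grid is thousands of states, and
exhaustiveness makes the brute-force oracle test exact. The search
refuses (with guidance) above $10^8$ states.

Adducts (metals, covalent artefacts) are enumerated jointly with
subunits but *reported* per subunit stoichiometry: all Cu-count variants
of one count vector collapse into a single row carrying the
best-fitting count and the admissible range. Ranking is by absolute
mass error (rounded to $10^{-6}$ Da so floating-point summation order
cannot flip ties), then fewer total copies (parsimony), then
lexicographic names — fully deterministic and invariant to catalog row
order. Near-equal subunit masses make count swaps mass-degenerate at
intact-complex tolerance; the solver returns the whole ambiguity set
and leaves discrimination to the dissociation data, which is the honest
outcome for this kind of input.

**Cu mass convention.** The Cu adduct defaults to the atomic average
63.546 Da. Whether each bound Cu displaces 0, 1 or 2 protons is an
instrument- and chemistry-dependent convention that mass data alone do
not fix; it is exposed as `cuDisplacedProtons`
($\Delta m = 63.546 - d \cdot 1.008$) with default 0, and results that
depend on it should be reported with the convention stated.

## 5. Topology elimination

**Physical picture.** SID deposits a large amount of energy in a single
surface collision; cleavage happens at inter-subunit interfaces faster
than subunits unfold. The fragments that can appear intact are therefore
exactly the *connected induced subgraphs* of the assembly's contact
graph. CID, by contrast, slowly heats the complex, unfolds and ejects
single monomers, and strips weakly bound metals — useful for
composition, nearly useless for connectivity.

**Enumeration.** Candidate arrangements are enumerated one
representative per equivalence class. For rings this is bracelet
equivalence (rotation + reflection), with the lexicographically smallest
rotation/reflection of the label sequence as the canonical, stable
identifier. A pendant subunit (e.g. a large catalytic subunit riding on
an accessory ring) is modelled as one extra node attached to
`pendantDegree` contiguous ring nodes — default *all* of them, i.e. a
single pendant–ring super-interface, since fragment data constrain the
ring order but not the pendant's attachment map. Tree and unconstrained
connected families are provided for generality with igraph-based
labelled-isomorphism deduplication, bounded to small n (7 and 6 nodes)
where brute force is exact and fast.

**Scoring.** Observed fragment compositions are classed
major/minor/trace/absent; the score of an arrangement is the sum over
the union of predicted and observed labels of a weight indexed by
(predicted?, class), with predicted-but-unobserved labels counted as
absent. The default weights

| | major | minor | trace | absent |
|---|---|---|---|---|
| predicted | +2 | +1 | 0 | −2 |
| not predicted | −3 | −1 | 0 | 0 |

encode the elimination logic: a predicted fragment that is never seen
(a homodimer arc of a blocked arrangement, say) is strong evidence
against; an abundant fragment no arc can produce is stronger evidence
still; trace species are excusable as secondary dissociation products.
With `secondaryDissociation = TRUE`, trace labels contained in some
predicted fragment contribute exactly zero even under user weight
matrices that would otherwise penalise them.

**Multiplicities are not compared to intensities.** A symmetric ring
predicts symmetric arc multiplicities, but observed abundances of
symmetric arcs need not be equal — interface energetics, transmission
and secondary dissociation all distort intensities. Observed trimer
ratios can sit at 2:1 where the arc count says 1:1. Presence/absence
and abundance class carry the reliable evidence, so only they are
scored; intensity-level comparison is deliberately out of the default
path.

**Abundance thresholds.** Classes are assigned relative to the most
abundant fragment: major ≥20%, minor ≥2%, trace ≥0.5%, absent below.
These are conventions (configurable), chosen to separate "clearly
present", "reproducibly present", and "at the noise floor" in typical
SID spectra.

## 6. CCS calibration

Travelling-wave drift times calibrate to cross sections through the
standard power law: corrected time
$t' = t_d - \mathrm{edc}\sqrt{m/z}/1000$ (EDC transport delay, default
coefficient 1.57), reduced cross section
$\mathrm{CCS}' = \mathrm{CCS}\sqrt{\mu}/z$ with
$\mu = m\,m_\mathrm{gas}/(m + m_\mathrm{gas})$ (nitrogen, 28.0134 Da, by
default), and an ordinary least-squares fit of
$\ln \mathrm{CCS}' = \ln a + b \ln t'$. The power law is fit in log-log
space rather than as a linearised polynomial because that is the
simplest defensible standard practice; with two calibrants the fit is an
exact line and $R^2$ is reported as 1 by construction.

## 7. The synthetic-data module

The generators define the reference conditions under which the chain is
validated:

* `mnxGroundTruth()` — one 138.8 kDa pendant subunit on an alternating
  ring of three 12.05 kDa and three 11.91 kDa subunits. The subunit
  masses are *synthetic* stand-ins (the exact values are user-supplied
  inputs in real use): they were chosen once so that (a) the bare
  complex plus the expected 9-Cu load sits at the measured intact mass
  of 211,216 Da, and (b) the E–F mass difference (143 Da ≈ 2.25 Cu)
  sits maximally far from the Cu-mass lattice, so that
  composition recovery is a fair test rather than an accident of
  near-degeneracy in either direction.
* Metal occupancies encode the qualitative binding picture: the
  high-affinity subunit at {0.05, 0.9, 0.05} over 0–2 Cu, the
  low-affinity one triangular {0.25, 0.5, 0.25}, the catalytic subunit
  {0.25, 0.5, 0.25} over 2–4.
* `simulateSpectrum()` — Gaussian peaks at the forward-model positions
  for each charge (discretised Gaussian envelope over $z$, default
  29 ± 4) and each total-metal variant (convolution of per-copy
  occupancies), 55 Th FWHM, 1% uniform additive noise.
* `simulateDissociation()` — SID low energy emits the pendant-cleavage
  pair; SID high energy samples contiguous ring arcs with
  $P(k) \propto \exp(-|k - n/2|/\tau)$, $\tau = 1.5$, chosen so all
  sizes from monomer to full ring appear; per-metal retention 0.9 (SID)
  versus 0.1 (CID). The two-level low/high energy model is a deliberate
  simplification of a continuous energy dependence.
* `simulateCalibrants()` — inverts the CCS forward model for plausible
  protein ions ($\mathrm{CCS} \approx 2.6\,m^{2/3}$ Å², charge
  $\approx 0.07\sqrt{m}$).

Every generator is a pure function of (parameters, seed): one integer
seed is threaded through, no hidden global RNG state is used, and the
caller's RNG stream is restored afterwards.

**What the simulations do not capture.** No isotope envelopes, no
detector/transmission efficiency, no overlapping contaminant envelopes,
no peak-shape asymmetry, no collision dynamics, and no secondary
dissociation in the fragment generator. Passing the recovery tests
therefore demonstrates the *inference logic* is sound under the stated
noise model — it does not certify performance on real instrument data,
where envelope overlap and baseline chemistry dominate the difficulty.

**Problem sizes.** The validation suite uses 200 simulated repeats of
the full chain (spectrum → deconvolution → composition; dissociation →
topology ranking) with 500 dissociation events per repeat, spectra of
~900 grid points, and the complete 3+3 bracelet set; these sizes give
stable recovery fractions while keeping the suite quick to run.

## 8. Design choices on open questions

* **Pipeline surface.** The orchestration layer is an R function
  (`runPipeline()`) taking a flat key map — an R list, or a JSON/YAML
  file. JSON/YAML were preferred over other config formats because
  parsers ship with the package's existing dependencies; unknown keys
  are rejected so typos fail loudly, and flags override file values by
  ordinary list modification.
* **Occupancy anchor.** Adduct-series detection anchors occupancy 0 at
  the lowest-m/z member of the supplied series. Modification-shifted
  series (gluconoylated protein and its metal satellites) are handled
  by running the detection once per modification mass on a filtered
  list, not by guessing anchors.
* **Residual mass.** When a subunit's apparent mass exceeds its
  sequence mass (extra ligands, unknown modifications), the solver
  reports the residual via `massError`; the package deliberately does
  not interpret it.
* **Envelope selection.** When several envelopes are found, the
  pipeline uses the one with the most members; competing assignments
  within a run are resolved toward lower RMS mass disagreement, then
  lower maximum charge — determinism over cleverness.

## 9. Known limitations

* Overlapping charge envelopes of co-occurring species are not
  deconvolved; the assignment is run-based, not Bayesian.
* Homodimer/heterodimer discrimination rests entirely on mass; isobaric
  compositions cannot be separated at any tolerance.
* Arc-abundance modelling (interface energies from SID intensities) is
  intentionally absent — the field has no validated forward model.
* The ring-plus-pendant family covers the one-pendant case only;
  multi-pendant assemblies need the general `connected` family, which
  is bounded to small n.
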