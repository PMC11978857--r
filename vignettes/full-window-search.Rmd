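---
title: "Full isolation-window search for co-fragmented peptides: methods and design"
author: "CoFrag"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Full isolation-window search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The identification model

A chimeric MS2 spectrum contains b/y fragment series from every
peptide ion that was transmitted through the isolation window and
fragmented. CoFrag treats identification as a spectrum-centric search
over the *entire* window rather than over a narrow tolerance around
the one precursor the instrument reported, followed by targeted
precursor verification and a greedy decomposition of the spectrum
into co-fragmented components.

## Candidate retrieval

A peptide of neutral monoisotopic mass $M$ is a candidate for a
spectrum with window center $c$ and width $w$ at assumed charge $z$
and isotope error $e$ when

$$\frac{M + e\,\Delta + z\,m_p}{z} \in [c - w/2,\; c + w/2],$$

with $m_p = 1.007276466$ Da the proton mass and $\Delta = 1.00235$ Da
the averaged neutral spacing of peptide isotope peaks. Isotope errors
$e \in \{0,1,2\}$ are needed even for narrow (0.7 Th) windows, where
the instrument frequently centers on the M+1 peak. Retrieval is a
binary search per $(z, e)$ over the mass-sorted peptide list; one
candidate per (peptide, charge) is kept, at the smallest qualifying
isotope error. Assumed charges default to $\{2,3,4\}$: the reported
charge describes only the selected precursor and must not restrict
co-isolated ions.

## Fragment index and hyperscore

All b/y ions (ordinals $1..L-1$, fragment charge 1 by default) of all
database peptides are binned at 0.02 Th — commensurate with a 20 ppm
fragment tolerance at 1000 Th — with entries within each bin ordered
by parent peptide mass. Matching walks spectrum peaks, collects
candidate fragments from the touched bins, and resolves each
theoretical fragment to its nearest in-tolerance peak (ties to the
lower m/z peak). This is provably identical to naive per-candidate
matching and is verified against it exactly in the test suite.

The match score is the classical hyperscore,
$H = \log_{10}\!\big(N_b!\,N_y!\,\max(\Sigma I_b,1)\,\max(\Sigma I_y,1)\big)$,
with factorial arguments capped at 64 and evaluated via
$\ln\Gamma$. The literature that introduced the score cites it
without a canonical printed form; this log-factorial form is the
X!Tandem lineage and is isolated in a single function so alternates
can be swapped. Matched intensities enter raw (no rank transform);
spectra are reduced to their 150 most intense peaks above 1% of the
base peak before scoring (ties at the cutoff keep the lower m/z
peak).

PSMs with fewer than `min_matched = 4` matched fragments are
discarded; the 5 best PSMs per spectrum (ties: more matched peaks,
then proximity of the theoretical precursor to the window center,
then sequence) enter refinement. Five is a deliberate, configurable
choice for "a small list of top candidates"; with 2–4 true
co-fragmented peptides per WWA spectrum it leaves headroom without
inflating the refinement cost.

## Targeted precursor refinement

Because the theoretical m/z and charge are known *after* the search,
precursor evidence can be collected by targeted XIC extraction — no
untargeted feature detection or isotope-cluster deconvolution, whose
failure on weak features is precisely what this design avoids. For
isotope $k$ the trace m/z is $m/z + k\Delta/z$; in every MS1 scan
within ±30 s of the MS2 retention time the most intense peak within
10 ppm is appended to trace $k$. The monoisotopic trace is trimmed to
the contiguous block of detections around the MS2's parent scan.

The per-isotope intensity sums $P$ are compared with the averagine
envelope $Q$ (unit composition C~4.9384~H~7.7583~N~1.3577~O~1.4773~S~0.0417~
per 111.1254 Da, element counts rounded, elemental isotope
distributions convolved by squaring, truncated and renormalized)
through $KL(P\|Q) = \sum_i p_i \ln(p_i/q_i)$, $0\ln 0 = 0$. The
number of requested isotopes covers 95% of the envelope, bounded to
[2, 5].

A PSM survives when at least 2 isotope traces are detected, the
monoisotopic trace spans at least 2 consecutive MS1 scans, and
$KL \le 0.5$ nats. These thresholds are intentionally permissive —
the point of the method is that low-quality but real precursor
signals are kept — and all three are configuration knobs, since the
upstream work does not publish its values. The observed charge is
taken to be the assumed charge, validated implicitly by the isotope
spacing: a wrong charge misplaces the M+1 trace and fails the
2-isotope requirement rather than triggering re-assignment.

## Greedy shared-fragment rescoring

Per spectrum, iteratively: (1) emit the top-scoring live PSM at its
current score; (2) remove every peak it matched — including peaks
shared with other candidates, which is the point of the procedure;
(3) re-match and re-score all remaining PSMs against the reduced peak
set; (4) drop PSMs below `min_matched` (the same floor as the search:
one knob operationalizes "insufficient fragment peaks"); (5) re-rank
and repeat, up to 5 emissions. The first emission is therefore the
global top scorer at its full-spectrum score; later emissions carry
current-state scores, so emission order need not be score-monotone.
Decoy PSMs compete in the loop on equal terms — necessary for
unbiased FDR on chimeric emissions. XIC filtering runs *before*
rescoring, matching the pipeline order (detect precursors → filter →
rescore).

## FDR and entrapment FDP

Reversed decoys (full protein reversal, one per target — and per
entrapment protein when present) give
$\mathrm{FDR}(s) = \#\{\text{decoy} \ge s\} / \max(1, \#\{\text{target} \ge s\})$,
monotonized into q-values from the bottom of the ranked list; tied
scores share a q-value. No +1 numerator correction is applied (a
flag-free, transparent ratio; the formula is the tested contract).
Peptide-level q-values use the best score per (sequence, mods) key;
stripped-sequence counts are reported alongside because conventions
differ on collapsing modified forms.

For FDP evaluation, each target protein is shuffled once into an
entrapment protein with the enzymatic cleavage-site residues held
fixed — interpreted as fixing every K/R cut site (honoring the
proline exception) so the entrapment digest preserves the targets'
peptide-termini structure and count statistics; whether residues
adjacent to blocked sites should also be fixed is unspecified
upstream, and only true cut sites are fixed here. Entrapment records
count as targets during q-value estimation and are distinguished only
in the report:
$\mathrm{FDP_{lower}} = N_e/(N_t+N_e)$,
$\mathrm{FDP_{upper}} = (N_e + N_e/r)/(N_t+N_e)$, so with $r = 1$ the
upper bound is exactly twice the lower.

# The synthetic generator

The generator emulates the features of real runs this method's claims
depend on: Gaussian elution profiles (FWHM 10–30 s), log-normal
abundances (σ = 1), averagine isotope envelopes in MS1, exponential
noise centroids in both MS levels, ppm-scale mass jitter, DDA top-N
precursor selection with 20 s dynamic exclusion (so low-abundance
co-isolated peptides stay unselected — the population the method is
designed to recover), window geometries from 0.7 to 48 Th, and a
configurable fraction (default 20%) of co-fragmenting peptides with
no MS1 envelope at all. The number of peptides placed on the gradient
is calibrated from `chimera_rate` (expected co-isolated peptides per
MS2) via the peptide m/z span, window width, gradient length and mean
elution duration.

It does **not** emulate realistic fragmentation intensity patterns
(per-fragment intensities are uniform draws fixed per peptide),
retention-time structure, charge-state envelopes beyond z ∈ {2,3},
ion mobility, or correlated chemical noise. Passing tests therefore
demonstrate the *algorithmic* properties — candidate retrieval,
scoring, decomposition of overlapping fragment sets, calibration of
FDR/FDP under a truthful null — not instrument-level performance on
real data.

A known physical ambiguity shows up deliberately: a planted
"precursor-absent" peptide can coincide in m/z (within 10 ppm) with a
real co-eluting peptide's isotope peak, in which case the XIC filter
legitimately sees precursor evidence. The tests allow for this rare
collision rather than pretending the detector can distinguish
identical m/z.

# Numerical choices and degenerate inputs

* Masses: monoisotopic residue table, water 18.0105646863 Da, proton
  1.007276466 Da. m/z of protonated ions uses the proton mass (not
  the hydrogen-atom mass) throughout.
* Stored peptide masses reproduce recomputation from sequence + mods
  to 1e-6 Da; the mod-string encoding keeps 9 significant digits for
  that reason.
* Empty spectra, empty candidate sets, zero-MS2 runs, empty PSM lists
  and empty accepted sets all return empty-but-typed results; the
  all-zero observed isotope pattern is a caller error for the KL
  function and is guarded by `n_isotopes_detected >= 2`.
* Ties are broken deterministically everywhere (documented in each
  function); run-level results are byte-identical across re-runs and
  independent of scan processing order.
* Isolation widths are read from mzML lower/upper offsets, falling
  back to a configurable default — essential for WWA files with
  sparse metadata, where a silent narrow default would be wrong.
  Retention times are normalized to seconds on read.

# Problem sizes used by the test suite

The end-to-end benchmarks run a 40-protein synthetic proteome
(~1200–1300 database peptides with reversed decoys; double that with
entrapment), a 300 s gradient at 1.5 s MS1 cycles, ~200 MS2 scans
with 12 Th windows and 2–4 planted peptides per spectrum. These sizes
make the statistical assertions (10-replicate mode comparison,
20-replicate FDP-bound containment) reproducible on a single CPU in a
few minutes while keeping ~250 accepted peptides per run, enough for
1%-FDR statements to be meaningful.

# Limitations

* Closed search only: no open/mass-offset/labile modes, no shifted
  fragment matching; semi- and non-specific digestion are out of
  scope (their search spaces defeat the full-window approach's
  candidate counts).
* No machine-learned rescoring or protein-level inference; q-values
  come from the plain hyperscore ranking, so absolute sensitivity on
  real data would be below a pipeline with learned rescoring.
* Fragment charge defaults to 1+; high-charge precursors with
  dominant 2+ fragments would need `max_frag_charge = 2`, at index
  size cost.
* The XIC charge check is implicit; a co-isolated ion whose wrong
  charge hypothesis lands on another ion's isotope spacing can
  survive refinement (rare, and bounded by the KL gate).
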