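---
title: "Building DIA/PRM spectral libraries with dialib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building DIA/PRM spectral libraries with dialib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialib)
```

# The problem

DIA (SWATH) mass spectrometry fragments everything inside sequential wide
isolation windows; the resulting chromatograms are only interpretable
against an assay library that says, for each peptide precursor, which
product ions to extract, at what relative intensities, and when the
peptide elutes on a normalized retention-time scale. This package builds
that library from DDA search results: PSM tables plus their fragment
spectra go in, a calibrated, decoy-appended transition list comes out.

The pipeline is `import → filter → calibrate → consensus → transition
selection → decoys → export`, and every stage is available as a plain
function as well as through `run_build()`.

# Retention-time calibration and CiRT landmarks

## The model

Retention times are mapped onto the dimensionless iRT scale by an affine
model per run,

$$\mathrm{iRT} = a \cdot \mathrm{RT} + b,$$

fit by ordinary least squares followed by iterative outlier rejection:
points whose absolute residual exceeds 3 times the median absolute
deviation (MAD, with the usual 1.4826 consistency constant) of the
residuals are dropped and the line refit, repeated to a fixpoint with at
most 5 rounds. An affine model is the standard iRT convention and is
adequate for reasonably linear LC gradients; nonlinear (lowess/spline)
alignment is deliberately out of scope. Degenerate inputs error early:
fewer than 3 pairs, fewer than 3 survivors after rejection, or zero RT
variance. A numerically exact fit drives the residual MAD to ~0; the
iteration then stops keeping all points rather than rejecting everything.

## CiRT selection

When synthetic spike-in (SiRT) landmark peptides are absent, calibration
needs endogenous landmarks: abundant, reliably identified peptides that
tile the gradient. `select_cirt()` implements the five criteria —
proteotypic, unmodified, intensity strictly above the 3rd quartile of all
quantified precursors, charge 2 or 3, and uniform RT coverage via
equal-width binning of the gradient with one pick per bin.

Defaults and the reasoning behind them:

| parameter            | default | unit  | rationale                                        |
|----------------------|---------|-------|--------------------------------------------------|
| `n_bins`             | 20      | bins  | one landmark per bin tiles the gradient densely enough for a 2-parameter fit with outlier margin |
| `intensity_quantile` | 0.75    | —     | the 3rd-quartile abundance gate; type-7 (linear interpolation) sample quantile |
| `allowed_charges`    | 2, 3    | —     | the dominant, well-behaved tryptic charge states |
| `require_unmodified` | TRUE    | —     | modified forms are less reproducibly observed    |
| `require_proteotypic`| TRUE    | —     | shared peptides risk chimeric identifications    |

Choices the criteria leave open, decided here once:

* **Within-bin pick**: the highest-intensity candidate (ties: higher
  score, then lexicographically first sequence). Intensity is the only
  abundance signal the criteria reference, and determinism requires a
  total order.
* **Gradient window**: the `[min, max]` of observed candidate RTs, not the
  nominal gradient length — robust to dead volume and late ramps. A
  consequence worth knowing: if candidate RTs cluster tightly, the bins
  subdivide that narrow span rather than the nominal gradient.
* **Empty bins** yield fewer than `n_bins` landmarks rather than borrowing
  from neighbours; a warning is raised when more than 25 % of bins are
  empty.
* **Reference iRT assignment** (`assign_reference_irt()`): two anchoring
  strategies are provided, neither privileged — evaluate a SiRT-anchored
  fit at each landmark's reference-run RT, or, with no anchor at all,
  min–max scale the landmark RTs onto [0, 100]. The scaled variant defines
  a self-consistent library-internal scale; it is not comparable across
  libraries anchored differently.

# Consensus spectra

Replicate PSM spectra of one precursor are merged by greedy clustering:
the most intense unclustered peak seeds a cluster, which absorbs the
nearest unclustered peak within ±0.03 Th from each other replicate.
Clusters present in at least `min_replicate_fraction` (default 0.6) of
replicates survive; consensus m/z is the intensity-weighted mean and
consensus intensity the **median** of member intensities — median rather
than mean for robustness against a single aberrant replicate.

Two deliberate edge rules:

* The fraction rule applies only from 3 replicates upward. With 2
  replicates, `ceiling(0.6 × 2) = 2` would demand presence in *both*
  members, silencing genuine peaks that one acquisition happened to miss;
  instead peaks from either member are kept and downstream quality
  filtering arbitrates.
* Peaks within ±1.5 Th of the precursor m/z are removed before clustering
  — residual precursor and its isotopes carry no fragment information and
  distort the intensity ranking.

`quality_filter()` then drops entries with fewer than 4 annotated b/y
peaks or insufficient replicate support.

# Transition selection and decoys

From each consensus spectrum, peaks matching theoretical b/y ions (charges
1–2) are candidates; those outside 300–1800 Th or within ±9 Th of the
precursor are excluded; the top 6 by library intensity are kept (exact
intensity ties broken by lower product m/z, for determinism). The b/y,
charge ≤ 2 restriction and the m/z bounds follow the conventions of the
targeted-proteomics tools this library format feeds; the ±9 Th exclusion
is roughly half a typical DIA isolation window, so co-isolated precursor
signal never masquerades as a transition. All of these are configurable
in `transition_config()`, and the choices are recorded in the library
metadata.

Decoys are pseudo-reversed: residues 1..n−1 reversed, the C-terminal
residue fixed, modifications travelling with their residues. This
preserves the precursor mass and the tryptic y1 ion while scrambling
internal fragments — the property decoy scoring relies on. Product m/z
values are recomputed for the same (series, ordinal, charge) annotations;
intensities and iRT are kept from the target. Palindromic prefixes (e.g.
`AAAAK`) fall back to a seeded shuffle of the prefix, 10 attempts, after
which the entry is skipped and counted. Decoys pair 1:1 with their targets
via the `DECOY_`-prefixed transition names, and merging or subsetting a
library keeps a decoy exactly when its target survives.

# Protein groups and statistics

A protein group is one protein whose peptide set is contained in no other
protein's set, or several proteins sharing an identical set or subsets of
one. `build_protein_groups()` inverts the peptide→protein map, merges
identical peptide sets, then absorbs every strict-subset accession into
its superset group, to transitive closure. Where a set is a strict subset
of several incomparable supersets, the larger peptide set wins, with
lexicographic tie-break — an arbitrary but deterministic rule for a case
the definition leaves open. The implementation is verified against a
brute-force closure oracle on randomized maps in the test suite.

Peptides mapping to exactly one accession are proteotypic; a protein
counts as proteotypic when it is Swiss-Prot canonical (FASTA `sp|`
namespace, no isoform suffix) and owns at least one proteotypic peptide.
Library statistics count distinct transition groups, modified peptide
sequences (stripped sequences are reported alongside, since either
convention is found in the wild), protein groups and proteotypic
proteins, over target entries only.

Protein abundance, when fragment-level quantities are available, is the
median over all detected fragment intensities of all precursors assigned
to the group; missing fragments are omitted, never zero-filled, and the
even-count median is the mean of the central pair.

# Serialization

The canonical on-disk form is the OpenSWATH transition TSV (bit-exact
column names, `Tr_recalibrated` holding iRT); reading accepts unknown
extra columns. TraML export writes PSI-style XML and is validated against
a reduced schema bundled with the package
(`inst/extdata/traml-reduced-synthetic.xsd`, an offline-authored subset of
the TraML 1.0.0 structure covering the elements written here); the test
suite additionally re-parses the XML with an independent parser and checks
m/z round-trip to 1e-4. PRM inclusion lists are exported in minutes
(instrument convention; internals are seconds throughout), with windows of
±5 min around the inverse-calibrated iRT and a warning when more than 100
windows overlap at any time point.

# The simulator, and what passing tests mean

`generate_proteome()` + `simulate_runs()` produce a fully known ground
truth: random protein sequences, tryptic digestion (cleave after K/R, not
before P), hidden iRT values uniform on [0, 100], log-normal precursor
abundances (meanlog 12, sdlog 1.2 — the heavy-tailed distribution the
third-quartile intensity gate presumes), charges drawn 1:2:3:4 =
0.05:0.6:0.3:0.05, per-run affine RT transforms with Gaussian jitter
(default σ = 5 s on a 3600 s gradient), and spectra composed of a fixed
true b/y intensity profile plus Poisson-count uniform noise peaks.

The simulator emulates the *statistical* shape of DDA inputs, not their
physics: no realistic fragmentation intensities, no chimeric spectra, no
missed identifications correlated with abundance, no charge-state
dependent fragmentation. Passing end-to-end tests therefore demonstrates
that the pipeline's bookkeeping and numerics are correct — every library
entry traces to a true precursor, annotations match true fragment ions,
calibrated iRTs recover hidden iRTs — not that the defaults are optimal
on any particular instrument's data.

Test problem sizes were chosen to exercise every code path at interactive
speed: unit fixtures of 3–40 proteins and a few hundred PSMs; 100-seed
property suites for consensus recovery and protein grouping; 200
replicates for calibration parameter recovery (20 landmarks, σ = 5 s);
and a dense single run of ~1000 precursors for landmark selection.

# Known limitations

* Fragment chemistry is b/y at charges 1–2; no neutral losses, a/c/x/z
  ions, or isotope envelopes.
* RT calibration is strictly affine; strongly nonlinear gradients need
  external alignment first.
* Protein inference is set-theoretic parsimony, with no error-probability
  propagation and no gene-level rollup.
* SpectraST binary formats (`.splib`) are not read or written; TSV and
  TraML carry the library.
* PSM-level FDR is assumed controlled upstream by the search engine; the
  score filter is an optional extra gate, off by default.
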