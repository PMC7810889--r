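---
title: "Presence-absence metabolomics for ancient organic residues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-absence metabolomics for ancient organic residues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residomics)
```

## The analytical problem

Organic residues absorbed into the walls of archaeological ceramics can be
recovered by solvent extraction and profiled by untargeted LC-MS. Each run
yields hundreds to thousands of *mass spectral features* — (m/z, retention
time) pairs standing in for compounds, adducts, fragments and isotopologues.
Because compound libraries for such material barely exist, identification
proceeds by comparison: residues from a collection of vessels are profiled
alongside extracts of candidate reference plants, and the question becomes
which reference signals recur in which vessels.

residomics implements this comparison as a fully tested pipeline:

1. **Alignment** of per-extract feature observations into consensus features
   by m/z and RT tolerance.
2. **Blank subtraction** — removal of every compound encountered in
   solvent-only control runs.
3. **Extract merging and binarization** into a features-by-samples presence
   matrix.
4. **Multivariate exploration**: Jaccard distances, Ward minimum-variance
   clustering, PCA by singular value decomposition.
5. **Unique-feature analysis**: compounds detected in exactly one reference
   sample, scored by their ubiquity across vessels.
6. **Formula annotation**: exhaustive CHNOPS enumeration around an accurate
   mass, replacing a database lookup with a local, reproducible computation.

A synthetic-study generator with planted ground truth makes every stage
testable without instrument data.

## Study design emulated by the generator

The generator reproduces the structure of the archaeological study the
pipeline targets: 12 reference samples — *Nicotiana tabacum* (NT) and
*N. rustica* (NR), each freeze-dried (FD) and cured for 10 and 30 days
(C10/C30), plus Mexican marigold (TLU), water lily (NSP), lilac tree (LVI),
diviner's sage (SDI), sacred datura (DWR) and yopo (APE) — 14 miniature
vessels (12 previously curated museum pieces, 2 untreated recent
excavations), and one blank per solvent system (TA, APW, MTBE). The
instrument constants are fixed by the acquisition protocol: scan range
100-1200 m/z, 16-minute analysis time.

### Feature classes and sharing structure

Each planted feature has one origin:

* **plant-core** — compounds common to plant extracts generally (sugars,
  amino acids, ubiquitous phenolics). Each reference's metabolome draws a
  `plant_core_fraction` (default 0.5) of its features from this shared
  pool. Without such a pool every non-tobacco reference pair would sit at
  the maximal Jaccard distance 1.0 — strictly farther from each other than
  from the vessels — and no linkage method could ever reproduce the
  empirically observed geometry in which references cluster together before
  joining the vessels. The default is chosen from a Ward cost
  decomposition: writing the inter-cluster merge cost as
  $\frac{n_1 n_2}{n_1+n_2}\,(\overline{d^2}_{\text{between}} -
  \overline{W}_1 - \overline{W}_2)$, the decisive three-cluster comparison
  ("references unite" vs "non-tobacco references join the vessels") is at
  the boundary for a core fraction near 0.3 and robustly favors the
  reference cluster at 0.5.
* **shared-backbone** — tobacco genus compounds common to NT and NR,
  `shared_backbone_fraction` (default 0.4) of the non-core remainder.
* **species-specific** — the rest of each species' metabolome; for
  single-sample species these are unique by construction.
* **curing-induced** — 20 features per cured tobacco sample, absent from
  the freeze-dried state; the markers behind the curing analysis.
* **soil** — a handful of site-specific features shared by vessels buried
  at the same site; deliberately small, encoding the finding that the
  burial matrix matters less than the contents.
* **contaminant** — laboratory contaminants (30 per solvent system)
  observed in their own solvent blank, carried over into the other blanks
  and into any sample extract with probability 0.8.

Reference metabolome sizes are Poisson with mean 600 (LVI: 300, matching
the observation that bark yields far fewer extractable compounds than leaf
or seed material).

### Vessels, survival and calibration

Each vessel contains cured tobacco with probability 0.9 and marigold with
probability 0.7 — the planted mixture signal. Content features pass a
taphonomic Bernoulli thinning (`taphonomic_survival = 0.1151`); curated
vessels pass an additional cleansing thinning
(`curation_survival = 0.4433`) applied uniformly to content and soil
features. These two rates are the generator's calibration: they are derived
in closed form so that, in expectation, untreated vessels retain ~97
features and curated vessels ~43 after blank subtraction,

$$E[\text{retained}] = p \cdot \big(0.9\,|\text{NT}_{cured}| +
0.7\,|\text{TLU}| - 0.63\,|\text{overlap}|\big) \cdot (1 - q_{miss}) +
|\text{soil}|,$$

with the plant-core overlap between the two content species accounted for
and $q_{miss} \approx 0.009$ the per-sample detection miss rate. The 43/97
contrast is what drives the curated-vs-untreated comparison downstream.

### Measurement model

Observed m/z values are jittered with a truncated normal: sd 3 ppm, hard
cap ±5 ppm (`mz_jitter_cap_ppm`); RT with sd 0.02 min capped at ±0.05 min.
The caps model a lock-mass-corrected Q-TOF whose residual calibration error
stays below half the matching window — the regime in which tolerance-based
alignment is provably exact. This boundedness matters: under an unbounded
error distribution every feature has a nonzero probability of splitting at
the matching tolerance, so exact-recovery properties (zero false unique
features, complete contaminant removal) could not hold even in principle.
True feature m/z values sit on a grid with 0.06 Da minimum spacing (five
times the 10-ppm window at the top of the scan range), making alignment
ground truth unambiguous. Each observation is dropped with probability
0.02 (`detection_dropout`). Intensities are log-normal and carry no signal
beyond positivity; the pipeline binarizes them.

One global random stream, consumed in fixed order, makes each study a pure
function of its seed.

### What the generator does not emulate

No chromatographic peak shapes, isotopologues, adducts, in-source
fragments, retention drift between runs, or intensity structure. Passing
tests therefore demonstrate that the *computational* chain recovers planted
structure under realistic sharing, thinning and noise — not that the
pipeline is robust to peak-picking artifacts upstream of it.

## Algorithmic choices

### Alignment

Observations are sorted by (m/z, RT, sample, extract) and swept once. A new
consensus feature opens when the m/z gap to the group's **last accepted
observation** exceeds `max(mz_ppm * center/1e6, mz_abs_min)` — on the m/z
axis this is exactly single-linkage clustering at the tolerance — or when
the RT gap to the group's running mean exceeds `rt_min`. The join decision
deliberately uses the last-member gap and the unweighted running mean
rather than the intensity-weighted consensus: with heavy-tailed intensities
a single strong observation can pin a weighted centroid to one edge of a
group and split features observed in many extracts (measured: 2-3% of
contaminants, which are seen in ~60 extracts each, split under a
weighted-centroid rule). Reported consensus m/z and RT are
intensity-weighted means of the retained members, with duplicate
(sample, extract) members resolved by keeping the higher intensity.

Defaults (10 ppm, 0.003 Da floor, 0.1 min) are conventional for the
instrument class; the original processing parameters are not published, so
no claim of parameter equivalence is made.

### Blank subtraction

Global mode removes any aligned feature with at least one blank member,
then additionally removes features whose consensus lies within the matching
tolerance of a removed blank feature — guaranteeing the invariant that
nothing in the output matches a blank compound. Per-solvent mode is
provided for sensitivity analysis: members from extracts of solvent S are
removed only when the feature occurs in the blank of S. Global is the
default because the source protocol subtracts "all compounds encountered in
solvent blanks" without qualification. With no blanks in the metadata the
input is returned unchanged under a machine-greppable warning
(`no_blanks:`).

### Presence matrix

A cell is 1 when the feature has a positive-intensity member in *any* of
the sample's three extracts — union, not intersection, because the three
solvent systems were chosen to capture complementary polarity ranges, and
the downstream statistics treat each vessel as one column. No minimum
intensity threshold is applied (none is published); thresholding can be
emulated upstream.

### Jaccard, Ward, PCA

Distances, clustering and PCA are implemented from first principles
(the published analysis names the methods but not their settings, so a
transparent implementation is preferable to a black box, and the standard
library routines — `vegan::vegdist`, `hclust`, `prcomp` — serve as
independent oracles in the test suite):

* Jaccard: $d = 1 - |A \cap B| / |A \cup B|$, two empty profiles at
  distance 0 by convention.
* Ward: Lance-Williams recurrence on squared dissimilarities (`ward_d2`,
  default, reporting unsquared heights) or raw dissimilarities (`ward_d`);
  ties broken by the smallest active slot pair, heights asserted
  non-decreasing on every run. Which variant the original figures used is
  unknowable from the publication, so structure-level claims are made at
  topology level only.
* PCA: SVD of the mean-centered binary matrix (scaling options: none, unit,
  Pareto; default none, since no transformation settings are published and
  the binary matrix is the only one defined by the pipeline). Sign fixed by
  requiring each loading vector to sum non-negative, so score tables are
  byte-reproducible.

### Unique features and ubiquity

Uniqueness is evaluated at the reference-**sample** level (NT10 distinct
from NTFD and NT30), because curing-induced compounds are markers in their
own right — the occurrence table's columns are attributed to curing states,
not species. A species-level aggregation is available for reporting.
Computing uniqueness on a matrix that skipped blank subtraction is refused
unless explicitly overridden (contaminants shared by reference and vessel
runs would masquerade as shared unique compounds); matrices read from disk
carry unknown provenance and are taken as given. Vessel ranking by shared
fraction is restricted to references whose full unique-feature counts are
supplied when `totals` is given, since fractions are only comparable across
references with known library sizes.

### Formula enumeration

The CHNOPS lattice is searched exhaustively with partial-mass pruning: the
heteroatom skeleton is enumerated first and the hydrogen count solved from
the residual mass window. Bounds admitting more than $10^8$ lattice points
are refused rather than silently truncated. Two [M+H]⁺ conventions are
implemented because the published lock-mass value (556.2771 for leucine
enkephalin) follows the hydrogen-atom convention while strict physics adds
a proton (556.2766); the hydrogen-atom convention is the default to stay in
the instrument's reference frame. The nitrogen parity rule is off by
default — for even-electron [M+H]⁺ ions the textbook rule inverts and
silently discards valid compositions. RDBE uses trivalent phosphorus
(+1/2 per P). Published occurrence-table m/z values carry only one decimal
place, far too coarse for meaningful enumeration, so annotation
demonstrations anchor on the lock mass.

## Numerical conventions and degenerate inputs

* Empty observation sets align to an empty feature list (not an error).
* A constant matrix under mean centering yields all-zero scores and zero
  explained variance (not an error).
* Ward requires $n \ge 2$ and a symmetric non-negative matrix; merge
  heights are clamped monotone at the last ulp to absorb floating-point
  inversions.
* Newick branch lengths are height differences (leaf depth equals the root
  merge height); serialization is done in-package because the common
  hclust-to-phylo conversion halves merge heights, which would break the
  height-difference contract.
* All delimited output is UTF-8, comma-separated, `.` decimal, LF endings;
  presence marks `X`/`x`/`1` are accepted on input so published occurrence
  tables can be transcribed near-verbatim.
* Feature identifiers are opaque strings; no numeric ordering is assumed.

## Problem sizes used in validation

The packaged validation runs 20 synthetic studies at the default
configuration (~2,600 planted features, ~18,000 observations, 29 samples
per study) through the full chain and checks: contaminant removal ≥ 99%
(residual misses arise only when detection dropout hides a contaminant
from all three blanks, probability ~$10^{-3}$ per contaminant); a
two-group Ward cut separating references from vessels (Rand index vs.
truth); mean retained features within 15% of the 43 (curated) and 97
(untreated) calibration targets; and exact uniqueness recovery (every
surviving planted unique feature found, no shared-origin feature reported
unique). Oracle suites check Jaccard metric axioms, the Lance-Williams
worked example (merge heights 0.2 then ≈ 0.9764 on the three-point
configuration), agreement with `hclust` on random inputs, PCA
reconstruction and orthonormality against `prcomp`, and formula-enumeration
equivalence with a naive full-lattice search plus completeness at 5 ppm for
100 random in-bounds compositions.

## Known limitations

* Alignment is one-dimensional in m/z with an RT gate; co-eluting isomers
  closer than the m/z tolerance cannot be separated (the generator's grid
  spacing sidesteps this; real data would not).
* Binary presence discards intensity information entirely; whether the
  original multivariate figures used binary or intensity data is not
  stated, and both remain available via the scaling/centering knobs.
* The taphonomic and curation survival rates are calibration constants, not
  mechanistic estimates; soil and contaminant loads are free parameters the
  source material does not quantify.
* Formula annotation is element-bounded and positive-mode [M+H]⁺ only; no
  isotope-pattern or fragmentation evidence is used.
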