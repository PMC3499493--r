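---
title: "Distance-based species delineation with barcodeGap"
author: "barcodeGap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based species delineation with barcodeGap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeGap)
```

## The problem

DNA barcoding identifies animal specimens from a ~655 bp fragment of the
mitochondrial COI gene. Identification rests on a separation of scales: two
individuals of one species differ little (conspecific divergence), while
even the most similar congeneric species differ several-fold more. The
interval between the largest conspecific and the smallest congeneric
divergence — the *barcoding gap* — is what makes a distance threshold
usable for delineating species, and what makes violations informative:
a heterospecific pair *inside* the conspecific range suggests a mislabelled
reference record or a synonymy, while a conspecific pair stranded inside
the gap suggests a deep intraspecific lineage, cryptic species, or again a
mislabel.

barcodeGap packages that reasoning as a pipeline over labelled barcode
alignments (`accession|Genus species` FASTA headers): quality control,
Kimura 2-parameter distances, neighbor-joining cluster cohesion, gap
thresholds, anomaly flags, and a classifier for reference-database
similarity reports. A sequence simulator with truth tables provides the
validation surface.

## Distance model

Distances are Kimura 2-parameter (K2P), the de facto standard for COI
barcodes. For a pair of aligned sequences, let `P` and `Q` be the
proportions of comparable sites showing a transition (A↔G, C↔T) and a
transversion, respectively. Then

    d = -1/2 * ln( (1 - 2P - Q) * sqrt(1 - 2Q) )

in expected substitutions per site. Only columns where both sequences
carry an unambiguous base are comparable (*pairwise deletion*, the
default); `deletion = "complete"` instead drops every column containing
any gap or ambiguity in any record before counting. Pairwise deletion is
the default because barcode data sets are typically trimmed unevenly at
the ends and complete deletion would discard most of the alignment.

When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the correction diverges
(saturation); such pairs are recorded as *undefined* rather than raised as
errors, and downstream stages either drop the records involved (tree
building) or simply never see those pairs (threshold statistics, which
operate on defined pairs only).

Distances are reported to 3 decimal places in the TSV outputs — the
precision at which such thresholds are conventionally quoted — while full
precision is kept internally.

## Quality control

Two rules, both exposed as parameters:

* **Length.** The ungapped length must strictly exceed `min_length`
  (default 600 sites): amplicons comfortably above 600 bp are unlikely to
  be nuclear mitochondrial pseudogene (NUMT) co-amplifications, whose
  lengths rarely reach 600 bp. The boundary is strict — 601 is kept, 600
  is rejected. Surveys that deliberately retain a few shorter sequences
  can lower `min_length`.
* **Reading frame.** At least one forward frame must be free of internal
  stop codons under the vertebrate mitochondrial code (stops TAA, TAG,
  AGA, AGG). A stop in the final complete codon of a frame is not
  "internal" — genuine coding fragments may end on one. Codons containing
  N or ambiguity codes translate to unknown and never count as stops.
  Reverse frames are not examined because the barcode orientation is fixed
  by the amplification primers. The check can be disabled
  (`check_frame = FALSE`) for input that is not codon-structured — notably
  the output of the package's own simulator, which evolves sites
  independently and therefore does not maintain a reading frame.

## Trees and cohesion

The neighbor-joining tree is built from the K2P matrix by the Saitou–Nei
agglomeration (delegated to `ape::nj`, which recovers additive inputs
exactly); negative branch-length estimates, an artifact of the
least-squares step, are clamped to zero. Clade supports come from
resampling alignment columns with replacement, rebuilding the distance
matrix and tree per replicate, and scoring each internal edge of the
original tree by the percentage of successful replicates containing the
same leaf bipartition. Replicates that produce an undefined pair are
dropped and counted; if more than 10% drop, the run errors rather than
report supports from a biased subsample.

A species is *cohesive* when one edge of the tree separates exactly its
leaves from everything else (an exclusive clade under some rooting);
singletons are cohesive by convention. Cohesion is purely topological by
default; `min_support` optionally requires the separating edge to carry at
least a given bootstrap percentage, for analyses that prefer the stricter
(>95%) convention.

## Thresholds, the gap, and anomaly flags

Defined pairs are partitioned by the records' labels into conspecific,
congeneric, and cross-genus ("other") classes. Thresholds use only species
that are cohesive on the tree:

* `max_conspecific` — the largest divergence over conspecific pairs of
  cohesive species;
* `min_congeneric` — the smallest divergence over congeneric pairs whose
  two species are both cohesive;
* `gap_fold = min_congeneric / max_conspecific`, reported to two decimals.

Cross-genus pairs never enter the thresholds: the gap is a statement about
nearest congeners, and deeper comparisons would only pad the numerator.

Flags then compare *every* defined pair against the thresholds:

| flag | condition |
|---|---|
| `conspecific_merge` | heterospecific pair with `d <= max_conspecific` |
| `deep_conspecific_divergence` | conspecific pair with `d > max_conspecific` |
| `subthreshold_congeneric` | congeneric pair with `max_conspecific < d < min_congeneric` |

Equality with `max_conspecific` counts as a merge — the conservative
choice for a statistic whose job is to raise suspicion. A species is
*delineated* when it is cohesive and none of its records appear in any
flag; otherwise it is *ambiguous* with its flags attached.

### The self-masking problem and the midgap screen

A deep intraspecific lineage elevates all of its record's conspecific
distances at once. If its species is otherwise cohesive, those pairs
*become* the conspecific maximum — and a pair can never exceed a threshold
it defines, so the anomaly silently disappears into the statistic meant to
catch it. Iterating the threshold computation cannot help: the offending
pairs are never flagged in the first pass.

The `trim = "midgap"` option addresses this with a single deterministic
screen applied before the maximum is taken: a record whose *smallest*
conspecific divergence exceeds `sqrt(median_conspecific * min_congeneric)`
— the geometric midpoint between the typical conspecific divergence and
the congeneric floor, the natural boundary on the fold scale the gap is
defined on — has its pairs set aside (returned in `$trimmed`, and visible
downstream as deep-divergence flags). Requiring *all* of a record's
conspecific distances to sit beyond the midpoint is what distinguishes a
genuinely displaced lineage from a single noisy pair.

The screen is off by default: without it the computation is a strict
single pass and clean data cannot produce a spurious deep-divergence flag.
With it enabled on data satisfying the generator's default conditions
(below), simulation shows the screen recovers every injected anomaly,
at the price of a small spurious-flag rate (well under 1% of clean runs)
when divergences happen to crowd the gap — the inherent cost of detecting
displaced lineages whose estimated divergence can approach the upper tail
of clean conspecific estimates at 655 sites.

## Classifying database-similarity reports

Identification surveys also query their consensus sequences against
reference databases (BLASTN against GenBank, the BOLD identification
engine) and report the best match per database: matched species name and
percent similarity. The classifier consumes such a table (TSV:
`query_species`, `database`, `match_species` or `NO_MATCH`, `similarity`)
and grades it:

* **Bands.** `>= 97` significant, `[92, 97)` moderate, `< 92`
  insignificant. The conventional printed bands (97–100, 92–96, ≤91) leave
  fractional similarities such as 96.5 unassigned; closing the bands at 97
  and 92 preserves every printed assignment while making the
  classification total on `[0, 100]`.
* **Definitive identity**: every returned match, across databases, bears
  the query's own name and is significant. A database returning no match
  is ignored — absence of reference data does not contradict the other
  database.
* Otherwise one or more **ambiguity categories** apply: cat1 (significant
  matches to both the same and a different name), cat2 (same-named matches
  both significant and insignificant), cat3 (best same-named match only
  moderate), cat4 (same-named insignificant with no same-named significant
  match), cat5 (only different-named, non-significant matches — no usable
  reference data). Categories are assigned per match and unioned per
  species, so one species can be cat3 and cat4 simultaneously. An
  insignificant different-named extra never adds a category when specific
  or significant evidence exists: the dominant conflict wins.

`resolve_with_flags()` reconciles the categories with the distance
analysis: cat1/cat2 conflicts that trace to records flagged as merges (or
a lone deviant same-named record) are promoted to
*identified-with-mislabel-note*; unflagged cat5 species — whose own
records cluster cleanly and which merely lack references — are identified;
cat3/cat4 species carrying deep-divergence flags stay inconclusive, as the
data cannot distinguish cryptic lineages from misidentified references.

## The simulator

`simulate_dataset()` generates alignments with exactly the structure the
analysis assumes, so that recovery is a model-exact target rather than a
hopeful approximation:

* a uniform-composition ancestral sequence evolves down a star-of-stars
  genealogy (genus stems, species stems, individual tips) under a
  continuous-time K2P process with transition/transversion rate ratio
  `kappa` (default 3, a typical fish mitochondrial bias), rates normalised
  so branch lengths are expected substitutions per site;
* divergences are specified as *expected pairwise* amounts: species stems
  are drawn so congeneric pairs land in `inter_divergence_range` (default
  U(0.10, 0.15)), individual tips so conspecific pairs land in
  `intra_divergence_range` (default U(0, 0.02)) — a ≥5-fold configured
  gap mirroring the separation reported for real catfish COI surveys;
* genus stems are deep enough that cross-genus pairs always exceed
  congeneric ones;
* a *mislabel* relabels a record into a congeneric species (the truth
  table keeps both names); a *deep lineage* evolves one record down an
  extra branch equal to the midpoint of (intra max, inter min), placing
  its expected conspecific divergence strictly inside the gap;
* everything is reproducible from `seed`, and
  `truth_expected_divergence()` returns the exact expectation for every
  pair, which `expected_k2p()` (the closed-form K2P transition
  probabilities) connects to the estimator: `k2p(expected_k2p(d, kappa))`
  returns `d` to numerical precision.

The default taxonomy (5 genera × 2 species × 3 individuals, 655 sites) is
a runtime-scaled emulation of a multi-genus survey of ~100 sequences; the
test-suite's property checks run 20 replicate datasets at these sizes, and
the heaviest check (full bootstrap support on two separated clusters) uses
1000 replicates on 10 records.

What the simulator does *not* emulate — and what passing tests therefore
do not demonstrate about field data: indels and alignment error (real
barcode studies report indel-free COI alignments, so none are simulated),
rate heterogeneity across sites or lineages, base-composition bias,
coalescent structure within species, and codon structure (sites evolve
independently, so simulated records fail the reading-frame QC by design —
pipeline runs on simulated data set `check_frame = FALSE`).

## Numerical and degenerate-input choices

* Saturated pairs: recorded, never raised; tree building requires the
  caller to drop the records involved (`drop_undefined()` removes the
  greedily-worst offenders).
* Consensus sequences: per-column strict majority over unambiguous bases;
  ties emit the covering IUPAC code; columns with no unambiguous base emit
  `N` (`-` if entirely gaps).
* NJ ties are resolved by the agglomeration's deterministic scan order, so
  identical inputs give identical trees; permuting input order gives the
  same tree up to relabelling.
* Bootstrap supports are attached to the original tree's bipartitions
  (not a consensus topology), as identification studies conventionally
  annotate their NJ figures.
* All-singleton data sets have no conspecific pairs and no threshold;
  this is an error, not a silent zero.
* `gap_fold` is scale-invariant: multiplying all distances by a constant
  leaves it unchanged.

## Limitations

The pipeline is deliberately confined to the distance-threshold paradigm:
it implements no model-based delimitation (GMYC, bPTP, ABGD/ASAP), no
substitution models beyond K2P, no rate-heterogeneity corrections, and no
live database queries — similarity tables are consumed as data. The
barcoding-gap statistic itself inherits the paradigm's known fragility:
with very dense species sampling the gap can close for honest biological
reasons, and the fold ratio is only as meaningful as the cohesion
assessment feeding it.
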