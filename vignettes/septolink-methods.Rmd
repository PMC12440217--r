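---
title: "Methods: gene-neighborhood linkage and single-cell septal quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-neighborhood linkage and single-cell septal quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septolink)
```

This vignette is the package's own account of what it computes, the
choices made where the underlying procedures were underspecified, and
what the synthetic-data tests do and do not demonstrate.

## 1. The comparative-genomics model

### Annotation tables and coordinates

The input is a table of genes across genomes, each with a replicon,
coordinates, strand, and a set of namespaced functional labels
(`PFAM:`, `KEGG:`, `TIGRFAM:`). Internally all coordinates are **0-based
half-open** `[start, end)`; GFF3's 1-based inclusive convention is
converted at the I/O boundary. Half-open intervals make length and gap
arithmetic pure subtraction: for genes with `end1 <= start2` the
intergenic gap is `start2 - end1`, and abutting genes (`end1 == start2`)
have gap 0 with no ±1 bookkeeping.

Replicons default to *linear with unknown length*; circular topology must
be declared explicitly. Wraparound (shorter-arc) distances are computed
only on declared-circular replicons with known length — silent wraparound
on draft assemblies would corrupt the distance distribution, and most
annotation dumps do not state topology. Label namespaces and accessions
are upper-cased on load, because case drifts between database releases;
unknown namespaces are preserved verbatim (and noted in a message) rather
than rejected.

### Families as boolean queries

A family is a triple of term sets; a gene with label set $L$ matches iff

$$L \cap \mathrm{include} \neq \emptyset
  \;\wedge\; L \cap \mathrm{exclude} = \emptyset
  \;\wedge\; \mathrm{require} \subseteq L.$$

The four built-in definitions (sddA, envC, gpmM, amiC) are shipped as a
YAML config file rather than hard-coded, because PFAM/KEGG/TIGRFAM
assignments drift between database versions and users will need to
re-pin them. The envC definition excludes exactly the three named LytM
paralogue terms (MepM, NlpD, YgeR) and nothing else; other LytM-like
annotations are deliberately not excluded, keeping the definition as
narrow as its source. A gene may match several families and is then
reported in each — family definitions are independent queries, not a
partition.

### Closest pairs and linkage statistics

For two families in one genome, the statistic of interest is the
**closest admissible pair**: two *distinct* genes, one per family, on a
*shared replicon*, minimizing the intergenic gap. A single gene matching
both families is never paired with itself (a self-pair at distance 0
would be meaningless). Ties at the minimal gap are broken by the
lexicographically smallest *unordered* id pair. The more obvious
tie-break — ordered `(gene_a, gene_b)` — is not invariant under swapping
the two queries: with two pairs tied at the minimal gap but differing in
strand parity, the ordered rule can return a different distance/strand
outcome depending on which family is "A". The unordered rule is equally
deterministic and makes swap invariance exact, so the package uses it.

Aggregation over genomes distinguishes two denominators, and reports
both:

* `n_genomes_with_both` — genomes where both families occur at all
  (presence semantics, the phyletic-profile view);
* `n_genomes_with_pair` — genomes where they additionally share a
  replicon, the denominator of the same-strand fraction and the distance
  histogram ("within the same chromosome" semantics).

The headline `fraction_within_threshold` uses an **inclusive** bound
(`distance_bp <= threshold_bp`, default 2000), so a planted gap drawn
from an inclusive uniform range `[0, 2000]` is recovered as fraction 1.
The histogram uses half-open 500-bp bins on [0, 10000) plus an overflow
bin; its counts always sum to `n_genomes_with_pair`.

### Phyletic profiles and export

The profile matrix is plain copy counts (absent = 0, never missing).
Taxon aggregation reports, per taxon and family, the genome count, the
fraction of genomes with ≥ 1 copy, and the mean copy number; genomes
without taxonomy at the requested rank are pooled as `"unassigned"` so
totals are conserved. The iTOL export writes a `DATASET_MULTIBAR` text
block (iTOL v6 dialect, best effort — the exact dataset type and colors
used for published figures are a rendering choice, not data). A Newick
tree, when given, is used *only* to order rows; no tree inference or
ancestral-state reconstruction is attempted.

## 2. The single-cell model

### Medial axis

Cell geometry is measured from the label mask alone. Per cell:

1. the binary footprint is **thinned** with the Guo–Hall two-subiteration
   algorithm. Guo–Hall was chosen over Zhang–Suen because the latter's
   parallel deletion disconnects 2-pixel-wide diagonal bands — exactly
   what the near-final skeleton of an obliquely oriented rod looks like —
   which truncates the recovered axis; Guo–Hall preserves connectivity
   there. (No installed imaging package exposes 2-D skeletonization, so
   it is implemented here, on per-cell bounding boxes.)
2. the skeleton is pruned to its **longest geodesic path** (double-sweep
   BFS on the 8-connected pixel graph, restricted to the largest
   component; ties broken by lexicographically smallest coordinates);
3. both ends are **extended to the boundary** along the terminal
   tangents, reaching the poles that thinning erodes;
4. the polyline is smoothed with a 5-point moving average (endpoints
   fixed) and resampled at 1-px arc steps.

Pixel-grid thinning is not rotation-equivariant, which would make
measured lengths and midcell intensities depend on image orientation. The
axis is therefore computed in a **canonical orientation**: among the four
grid rotations of the footprint, the landscape one with the
lexicographically smallest pixel pattern is selected — a rule invariant
under rotations of the input — and the axis is mapped back afterwards.
With this, rotating an image by 90° changes *nothing* in the measured
length or midcell intensity (the package's rotation test observes
exactly 0 difference), where naive per-orientation thinning produced
up-to-10% discrepancies.

Length is the axis arc length × pixel size; pixel size is a required
parameter (label masks carry no physical calibration; the instrument
setups behind the defaults in this package use 0.1 µm/px). Width at each
axis position is the transverse chord of the footprint through that
position — near the poles, the chord *inside* the mask — and
`mean_width` averages over the full axis. Note what that average means
for a spherocylinder of pole-to-pole length $L$ and diameter $w$: chords
shrink over the hemispherical caps, so the axial mean chord is

$$\bar{w} = \frac{(L - w)\,w + \pi w^2/4}{L} < w .$$

The synthetic truth table records both $w$ and $\bar{w}$, and recovery
tests compare the measurement against $\bar{w}$ — the quantity it
estimates — not against the diameter. Cells below 20 px area are skipped
(segmentation debris), cells touching the image border are flagged (and
excluded by default in `measure_cells`), and cells with aspect ratio
below 1.5 are flagged `non_rod`, since an axis through a round cell is
not meaningful (for a disk the procedure returns length ≈ diameter and
mean width ≈ $\pi/4$ × diameter).

### Profiles, demographs, midcell intensity

The per-position intensity $I_i$ sums **5 pixels perpendicular** to the
axis (offsets −2..2 px along the local normal, nearest-pixel lookup,
clipped to the image). Nearest-pixel sampling rather than interpolation
is deliberate: the quantity is a count over discrete camera pixels, and
interpolation would correlate neighboring positions. Raw intensities are
summed; no background subtraction is applied at this stage. Profiles are
normalized as

$$I_i^{\mathrm{norm}} = \frac{I_i \cdot n}{\sum_{j=1}^{n} I_j},$$

with $n$ the profile length, giving every cell mean 1 regardless of
expression level; $\sum_i I_i^{\mathrm{norm}} = n$ is asserted for every
processed cell as a pipeline invariant. All-zero profiles are an error
(the normalization is undefined), not a silent NaN.

Demographs stack normalized profiles as rows sorted ascending by cell
length, each row centred on a common midcell column in **absolute
pixels** — profiles are not rescaled to relative cell coordinates, so the
length range stays visible, as in standard demograph displays. Positions
outside a cell hold the sentinel `NA`. No additional smoothing is applied
to the rows.

The midcell measure uses a transverse band of **3-px width along the
axis** at arc position 0.5 L, clipped to the cell mask; background is the
mean of the same-shaped bands at 0.25 L *and* 0.75 L. The two-sided
background is a deliberate choice: segmentation assigns cell polarity
arbitrarily, so a one-sided quarter reading would silently depend on
label orientation; averaging both quarters removes that choice
(`quarter = "one"` reproduces a single-sided reading). Cells too short
for three non-overlapping bands are skipped with a `"short"` flag rather
than measured badly. `net = midcell − background` may legitimately be
negative. Relative midcell intensity divides `net` by the per-replicate
median `net` of a designated reference sample; replicates normalize
independently, the reference median maps to 1.0, and a replicate without
reference cells (or with non-positive reference median) is an error
naming the replicate.

## 3. The synthetic generators

### Pangenome

Each genome gets each family independently with the configured presence
probability (defaults 0.7–0.9; single copy). When the two focal families
co-occur, with probability `p_link` (default 0.8) they are planted
adjacent, co-oriented, with an intergenic gap drawn uniformly (inclusive)
from `gap_range` (default [0, 2000] bp). Everything else — unplanted
genes and decoys — is placed uniformly at random without overlap on a
4.6-Mb replicon (an *E. coli*-sized chromosome), strands Bernoulli(0.5),
gene lengths uniform in 300–3000 bp (typical bacterial ORF range; the
value only has to avoid pathological overlaps). Decoy genes carry label
combinations that the built-in queries must reject — e.g. {K22719,
K06194} (an EnvC term plus the NlpD exclusion) and {PF01520} without
PF11741 — so exclusion/requirement logic is exercised, not just the happy
path. A two-phylum synthetic taxonomy supports the aggregation API.
Under this model the expected same-strand fraction of closest pairs is
`p_link + (1 − p_link)/2` (planted pairs are always co-oriented;
unplanted closest pairs are co-oriented half the time), the quantity the
recovery tests check.

What this emulates: the *structure* of an annotation dump with planted
operon linkage. What it does not: real phylogenetic correlation of
presence/absence, paralogue expansions, assembly fragmentation, or
annotation errors. Tests passing on it show the query/linkage machinery
is correct, not that any particular biological database will be clean.

### Cells

Cells are spherocylinders: a pixel belongs to a cell iff its distance to
the (gently curved) centerline is ≤ width/2, which renders the
hemispherical poles automatically. Defaults emulate exponential-phase
*E. coli* on a 100 nm/px camera: pole-to-pole lengths uniform 1.5–6 µm,
widths 0.8–1.2 µm, orientation uniform, centerline sagitta below 5% of
the spine (small enough that the longest geodesic path is unambiguous).
The septal model adds a transverse Gaussian band (σ = 2 px along the
arc) of amplitude 60 a.u. over a 100 a.u. baseline at arc position
0.5 L; signal is blurred with a σ = 1 px Gaussian (a PSF proxy) and
degraded with additive Gaussian noise (SD 10 a.u., i.e. band amplitude =
6× noise). The label mask is exact — segmentation is assumed solved, per
scope. Intensities are quantized to integer counts only when written as
16-bit TIFF.

Known behavior at the edges of the parameter space: for the shortest
cells (~15 px axis) the quarter-position background bands sit in the
tails of the blurred septal band, compressing `net` towards zero; the
septal/uniform separation tests hold at the default amplitude-to-noise
ratio, but discrimination will degrade for shorter cells or weaker
bands. Real images additionally contain uneven illumination,
out-of-focus light and segmentation errors that this renderer does not
model; passing recovery tests demonstrates the measurement code, not
robustness to those artifacts.

## 4. Problem sizes and numerical choices

The test suite and the acceptance script run, per invocation: a
500-genome pangenome for linkage recovery, 100 random ≤50-gene genomes
against an exhaustive O(n²) closest-pair oracle, and 200 rendered cells
(five 512×512 fields of 40) for geometry/midcell recovery — sizes at
which the binomial standard errors of the recovered fractions are a few
percent, matched to the tolerances asserted.

Numerical details fixed by decision rather than derivation: moving-window
smoothing width 5 axis points; boundary marching step 0.25 px;
perpendicular chord search capped at 50 px half-width; normalization
identity asserted at 1e-6 relative (achieved ~1e-15); minimum cell area
20 px; non-rod aspect threshold 1.5. Degenerate inputs error loudly
(all-zero profiles, empty demographs, replicates without reference) or
are flagged and skipped (tiny cells, short axes) — never silently
imputed.
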