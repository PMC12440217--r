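# septolink

Tools for two analyses that together characterize a bacterial
cell-division gene: **how tightly it is genetically linked to its operon
partner across bacterial genomes**, and **how its product (or a reporter)
localizes within single cells**.

The motivating biology is the *envC–sddA* operon of *E. coli*: *envC*
encodes the activator of the septum-splitting amidases, *sddA* a divergent
polysaccharide deacetylase acting on denuded peptidoglycan glycan strands
at the division septum. Establishing that this pairing is a conserved
operon — and that the protein accumulates at midcell — requires exactly
the two computations this package provides.

## What it computes

**Comparative genomics** (from annotation tables in GFF3 or TSV):

* *Gene families as boolean annotation queries.* A gene belongs to a
  family iff its label set L satisfies
  `L ∩ include ≠ ∅  ∧  L ∩ exclude = ∅  ∧  require ⊆ L`
  over namespaced PFAM/KEGG/TIGRFAM terms. The four built-in definitions
  (shipped as an editable YAML file) are: sddA = PF04748 ∪ K09798;
  envC = K22719 minus the other LytM-activator terms
  {K19304, K06194, K12943}; gpmM = TIGR01307; amiC = (K01448 ∪ PF01520)
  requiring the AMIN domain PF11741.
* *Phyletic profiles*: per-genome copy-number matrices, taxon-level
  aggregation, and export as TSV plus an iTOL `DATASET_MULTIBAR` text
  block for display along a phylogenetic tree.
* *Neighborhood linkage*: for every genome carrying both families, the
  closest admissible pair (distinct genes on a shared replicon,
  minimal intergenic gap; half-open intervals, so abutting or overlapping
  genes have gap 0, and declared-circular replicons use the shorter arc).
  Aggregates are the same-strand fraction and the intergenic-distance
  histogram with a headline fraction within 2 kb — the two statistics that
  diagnose operon-style linkage.

**Single-cell image analysis** (from integer label masks, e.g. Omnipose
output, plus matched fluorescence TIFFs):

* *Medial-axis morphometrics*: per cell, a pole-to-pole centerline from
  skeletonization (Guo–Hall thinning, longest geodesic path, tangent
  extension to the boundary, smoothing, 1-px arc resampling), giving cell
  length and the width averaged along the axis.
* *Axis intensity profiles*: at each axis position i the sum I_i of 5
  perpendicular pixels, normalized as
  `I_i^norm = I_i · n / Σ_j I_j`
  (n = profile length), so every cell's profile has mean 1.
* *Demographs*: normalized profiles stacked as rows, sorted by cell
  length, midcell-aligned in absolute pixels.
* *Midcell intensity*: mean intensity in a 3-px transverse band at 0.5 L
  minus the quarter-position background (0.25 L and 0.75 L averaged),
  optionally divided by the per-replicate median of a reference (wild
  type) sample — the "relative midcell intensity".

Two synthetic generators — an annotated pangenome with planted
operon-style linkage and decoy labels, and a renderer of spherocylindrical
cells with uniform/septal/membrane signal models — emit ground truth so
the whole pipeline is testable end to end without the (undeposited)
source data.

## Worked example

```r
library(septolink)

## comparative genomics on a synthetic pangenome ------------------------
sim <- generate_pangenome(pangenome_config(n_genomes = 200), seed = 11)
linkage <- linkage_summary(sim$table, builtin_query("envC"),
                           builtin_query("sddA"))
linkage
#> linkage_summary: 130 genome(s) with both families, 130 with a same-replicon pair
#>   same strand: 121/130 (93.1%); within 2000 bp: 76.9%
```

130 of the 200 genomes carry both families; in 93% of them the closest
envC–sddA pair is co-oriented, and 77% lie within 2 kb — the pattern
expected of a conserved operon (the generator plants linkage in 80% of
co-occurring genomes; unlinked genomes contribute ~50% same-strand pairs
at random distances).

```r
m <- profile_matrix(sim$table, lapply(c("sddA","envC","gpmM","amiC"),
                                      builtin_query))
head(m, 3)
#>       sddA envC gpmM amiC
#> g0001    1    1    1    1
#> g0002    1    1    1    1
#> g0003    1    1    1    1
export_tree_dataset(m, "profile.tsv")   # writes profile.tsv + profile.itol.txt

## single-cell quantification on rendered cells -------------------------
field <- generate_cells(cell_sim_config(n_cells = 30), seed = 3)
res <- analyze_cells(field$mask, field$fluor, pixel_size_um = 0.1)
length_stats(res$cells$length_um)
#>   group  n  mean_um    sd_um flag
#> 1   all 30 3.817756 1.411137

head(res$cells[, c("cell_id", "length_um", "mean_width_um", "net")], 3)
#>   cell_id length_um mean_width_um      net
#> 1       1  2.232200     0.9072917 46.94133
#> 2       2  2.042501     0.7738636 44.63990
#> 3       3  3.878575     0.9200000 51.06682

dg <- build_demograph(res$profiles)
dg
#> demograph: 30 cells x 59 axis positions, lengths 1.56-5.78 um
plot_demograph(dg, pixel_size = 0.1)
```

The `net` column is the background-subtracted midcell intensity; for
these septal-model cells (band amplitude 60 over baseline 100, noise SD
10) it sits around 45 a.u., while uniform cells scatter around 0.

## Scope

Labels are taken as given (no HMM scanning or re-annotation), masks are
taken as given (no segmentation), and no statistical hypothesis testing
beyond descriptive statistics is included. The iTOL export is a
best-effort `DATASET_MULTIBAR` block (iTOL v6 dialect); tree input is
used only to order rows.
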