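# evoregions

Phylogeny-aware bioregionalization from gridded species assemblages, for
comparative biogeographers asking where lineages diversified and whether
two interacting taxa (e.g. parasites and their hosts) share those
regions. The package identifies **evoregions** — biogeographic regions
whose resident species mostly descend from one or several ancestors that
diversified within them — together with **evolutionary transition
zones** (belts of high phylogenetic turnover between regions), assigns
species and ancestral nodes to regions, and quantifies the spatial
congruence of two independent regionalizations.

## Method

Starting from a rooted phylogeny and a binary cells × species occurrence
matrix on an equal-angle grid (presence when a range covers ≥ 12.5 % of
a cell; empty cells dropped):

1. **Phylogenetic fuzzy weighting.** Patristic distances *d* are turned
   into similarities *s* = 1 − *d*/max(*d*); column-standardizing *s*
   gives the species × species membership matrix **Q** (columns sum
   to 1). The row-standardized product of the presence matrix with **Q**
   gives **P**, the phylogeny-weighted composition of every cell
   assemblage (rows sum to 1).
2. **PCPS ordination.** Principal coordinates of the square-rooted
   Bray–Curtis dissimilarities between the rows of **P**; axes with
   strictly more than 5 % relative variance are retained as gradients
   of phylogenetic turnover.
3. **Classification.** The number of evoregions *k* is chosen by the
   elbow (maximum chord distance) of the best-of-restarts k-means WSS
   curve; k-means labels are refined by a discriminant analysis of
   principal components (DAPC), yielding per-cell assignment
   probabilities.
4. **Affiliation and transition zones.** A cell's affiliation is 1 minus
   its mean dissimilarity to the other cells of its evoregion; cells
   below the within-region lower quartile that border another region
   form transition zones (4-neighbour components).
5. **Species and ancestors.** A species belongs to the evoregion holding
   ≥ 60 % of its occupied cells (otherwise *widespread*); ancestral
   evoregions are reconstructed by stochastic character mapping under an
   equal-rates Mk model with the widespread class as a state.
6. **Congruence.** Two regionalizations are compared with the V-measure,
   the harmonic mean *V* = 2*hc*/(*h*+*c*) of the entropy-based
   homogeneity *h* = 1 − H(R|Z)/H(R) and completeness
   *c* = 1 − H(Z|R)/H(Z).

A synthetic-data module generates Yule phylogenies and clade-structured
faunas on a grid with known latent regions, so the entire pipeline is
verifiable end to end without external data.

## Worked example

The scripts under `analysis/` run the whole study on a simulated
parasite/host pair with fully congruent latent geometry
(`Rscript analysis/01_simulate_faunas.R` … `05_congruence.R`):

```
host: k = 4 evoregions, ARI vs latent truth = 1.000
parasite: k = 4 evoregions, ARI vs latent truth = 1.000

host affiliation: median 0.811 | 36 transition-flagged cells in 6 zones
  zone 1: 17 cells, borders A/B/C/D
  ...
host association: A 28, B 29, C 31, D 30, WIDESPREAD 2
  fitted ER rate 0.628; mean 18.6 changes per map

V-measure = 1.000 (homogeneity 1.000, completeness 1.000) over 144 shared cells
harmonic mean of printed h = 0.33, c = 0.34: 0.33493 -> 0.33
```

Both taxa recover the four latent regions exactly (adjusted Rand index 1
against the generator's truth), transition cells concentrate along the
region borders, nearly every species is assigned to its region by the
60 % rule, and the two maps are fully congruent (V = 1). The same
machinery is available programmatically:

```r
library(evoregions)
truth <- simulate_regional_fauna(scenario_config(seed = 7))
g <- align_to_tree(drop_empty_cells(truth$grid), truth$tree)
d <- patristic_distances(truth$tree)[g$species, g$species]
p <- phylo_composition(g, fuzzy_membership(phylo_similarity(d)))
regions <- classify_evoregions(p, seed = 7)
regions
#> evoregion classification: 144 cells in 4 evoregions
#>  A  B  C  D
#> 36 36 36 36
```

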