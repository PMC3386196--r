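# iotu — integrated DNA barcoding taxonomy with optimum divergence thresholds

`iotu` is an R toolkit for mitochondrial DNA-barcode surveys (coxI and
similar protein-coding markers) aimed at people who have to turn a pile of
barcode sequences, field identifications and sampling localities into
defensible taxonomic statements: which samples form molecular entities,
which entities are plain species matches, which are marker failures, which
are candidate cryptic species — and what the morphologically unidentifiable
samples are.

## The method in brief

**Distances.** All divergences are Kimura 2-parameter distances under
pairwise deletion,

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

with `P`/`Q` the transition/transversion proportions over sites where both
sequences carry an unambiguous base. Saturated pairs are reported as
undefined and excluded.

**Threshold calibration.** On a reference dataset of trusted labels, every
candidate threshold `t` is charged Type I errors (conspecific pairs with
`d > t`) and Type II errors (heterospecific pairs with `d < t`); the
optimum threshold (OT) minimises the cumulative error (MCE), with errors
expressed as percentages of all compared pairs.

**Entities and ranks.** Samples are partitioned into molecular entities by
single linkage at the OT, divergent intraspecific lineages are detected at
a 2% criterion (with NJ bootstrap support as corroboration), and each
entity receives a rank:

| rank | meaning |
|---|---|
| `SPECIES_MATCH` | entity == one nominal species |
| `MT_MOTU` | one entity, several nominal species (marker failure) |
| `IOTU` | molecular split corroborated by disjoint locality groups |
| `UCS` | molecular split (or sub-OT lineage structure) with no second character |

**Identification.** Unknown queries are assigned to the species with the
smallest minimum distance when it falls below the OT, with an explicit tie
margin for ambiguous cases.

A simulator (`simulate_barcodes()`) generates coding barcode alignments
under a K2P substitution process with controlled intra/interspecific
divergence, injectable MT-MOTU / IOTU / UCS scenarios and known ground
truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(iotu)
library(dplyr)

sim <- simulate_barcodes(sim_config(
  n_species = 6, samples_per_species = 6,
  scenarios = list(scenario_iotu_split()),   # deep 9% split, NIT vs CIT/SIT
  n_unknown = 4, seed = 11))

res <- run_pipeline(sim$records,
                    exclusions = attr(sim$truth, "ot_exclusions"))
res
#> Integrated barcoding pipeline
#>   42 samples (30 reference, 4 unknown queries)
#>   OT = 2.30%, MCE = 0.000%
#>   7 molecular entities: IOTU=2, SPECIES_MATCH=5
#>   queries: 4 assigned, 0 ambiguous, 0 unassigned

res$ranks |> select(entity_id, rank, n_samples, species, evidence)
#> # A tibble: 7 × 5
#>   entity_id rank          n_samples species    evidence
#>   <chr>     <chr>             <int> <chr>      <chr>
#> 1 E01       IOTU                  4 Species_01 "DIVERGENCE_GT_OT;GEOGRAPHY_CONGRUENT"
#> 2 E02       IOTU                  4 Species_01 "DIVERGENCE_GT_OT;GEOGRAPHY_CONGRUENT"
#> 3 E03       SPECIES_MATCH         7 Species_02 ""
#> 4 E04       SPECIES_MATCH         8 Species_03 ""
#> 5 E05       SPECIES_MATCH         6 Species_04 ""
#> 6 E06       SPECIES_MATCH         6 Species_05 ""
#> 7 E07       SPECIES_MATCH         7 Species_06 ""
```

Reading the output: the reference dataset (the deep-split species excluded
from calibration, as one would for a taxon already known to be structured)
has a clean barcode gap, so the MCE is zero and the OT lands just above the
intraspecific tail at 2.3%. The injected 9% split in `Species_01` is far
above the OT, so the species separates into two entities whose locality
sets (`NIT` vs `CIT`/`SIT`) are disjoint — molecular divergence plus a
congruent geographic character, hence two IOTUs. All four unlabelled
queries fall below the OT with exactly one species and are assigned.

`autoplot(res$ot_scan, ot = res$ot)` draws the Type I/Type II/cumulative
error curves; `plot_divergence(res$pairs, ot = res$ot)` shows the
intra/interspecific divergence histograms around the threshold. The methods
vignette (`vignettes/barcode-taxonomy.Rmd`) documents the model, the rank
rules and the simulator's scope.

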