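# barcodeLib

Curation and blind species assignment with COI-5P DNA barcode reference
libraries, in R.

Regional barcode reference libraries — collections of mitochondrial
*cytochrome c oxidase I* (COI-5P, ~652 bp) sequences tied to
morphologically identified voucher specimens — are the diagnostic backbone
for identifying fish and other animals from tissue of unknown origin.
`barcodeLib` implements the full curation-and-assignment workflow such
libraries are built for, aimed at researchers auditing a reference library
or assigning species to query sequences against one:

- **Sequence QC**: reading-frame detection and stop-codon screening under
  the vertebrate mitochondrial code, length and ambiguity checks
  (`qc_record()`, `read_library()`).
- **K2P distance engine**: pairwise Kimura 2-parameter distances
  *d* = −½·ln[(1 − 2P − Q)·√(1 − 2Q)], with P and Q the transition and
  transversion proportions over pairwise-deleted sites, undefined
  (saturated) pairs tracked explicitly (`distance_matrix()`), and
  conspecific / congeneric / confamilial summaries (`summarize_ranks()`).
- **Tree and clusters**: neighbour-joining on the K2P matrix with bootstrap
  support (`build_nj()`, `bootstrap_support()`), and extraction of maximal
  monophyletic clusters whose within-cluster divergence is below 2%
  (`extract_clusters()`).
- **A–E reliability grading** of reference species from external
  concordance, sample size, intraspecific divergence and monophyly
  (`grade_library()`).
- **Blind two-stage assignment**: queries are stripped of their labels,
  placed on the merged tree and assigned through pure sub-2% reference
  clusters; queries left over are matched against an external snapshot at a
  ≥98% identity floor over the barcode length (`assign_by_cluster()`,
  `identity_search()`, `classify_outcome()`), then audited against
  morphology (confirmed / mismatch / ambiguous / new record).
- **Deep-divergence flagging** of putative cryptic lineages (>2%
  intraspecific K2P), with sub-cluster counts and geographic sorting
  (`flag_deep_divergences()`).
- **A truth-tracked simulator** of barcode libraries with planted cryptic
  splits and morphology misidentifications (`simulate_library()`), so every
  stage can be validated against known truth.

`run_pipeline()` orchestrates all stages from a `pipeline_config()` (or a
YAML file) and renders report tables in the layouts used for published
barcode-library audits.

## Worked example

```r
library(barcodeLib)

sim <- simulate_library(simulation_config(seed = 7))
sim$library
#> barcode_library: 144 records, 48 species; 128 reference / 16 query; 144 QC-passed

rb <- run_pipeline(pipeline_config(reference = sim$library,
                                   query = sim$library, seed = 7))
rb
#> report_bundle
#>  - qc: 128/144 reference and 16/144 query records passed
#>  - grading: B=27 C=5 D=16
#>  - clusters: 53 total, 9 single-entry
#>  - assignment: 16/16 cluster-matched; 16 confirmed

render_distance_table(rb$distance_summary)
#>   Comparison   N Minimum    Mean_SE Maximum
#> 1    Species 128    0.00  0.83±0.13    5.76
#> 2      Genus 352    6.42  9.28±0.12   16.18
#> 3     Family 480   12.01 16.08±0.08   21.70

rb$flagged[, c("species", "max_intra_pct", "n_subclusters", "geographic_sorting")]
#>         species max_intra_pct n_subclusters geographic_sorting
#> 1 Genus001 sp01      5.764506             2               TRUE
#> 2 Genus001 sp02      5.253100             2               TRUE
#> 3 Genus003 sp02      5.416760             2               TRUE
#> 4 Genus012 sp01      4.939038             2               TRUE
#> 5 Genus013 sp02      5.759863             2               TRUE
```

Reading the output: the rank table shows the classic barcode gap — mean
conspecific distance below 1% against ~9% between congeners — computed from
3452-style pair counts at each level. Grades split the 48 reference species
into well-corroborated entries (B here, A when an external snapshot is
supplied), deep-divergence cases (C), and thin sampling (D). All 16 blind
queries fell inside pure sub-2% reference clusters and were confirmed
against their morphology labels. The five flagged species are exactly the
simulator's planted 6% two-lineage splits, each sorting perfectly into its
NEA/MED regions.

Real libraries are read from FASTA plus a tab-separated specimen table with
`read_library()`; `write_library()` round-trips them.

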