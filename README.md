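# barcodebin

Confronting traditional species taxonomy with sequence-cluster taxonomy for
DNA barcodes.

DNA barcoding identifies animal species from a ~658 bp fragment of the
mitochondrial COI gene. Reference libraries increasingly delimit species
operationally, by clustering barcode sequences into BIN-like operational
taxonomic units (OTUs) with a two-stage *refined single-linkage* algorithm.
`barcodebin` implements the full analytical chain used to ask how well such
clusters agree with named species across a continental fauna, and who is
affected when they disagree. It is aimed at researchers curating barcode
reference libraries and at anyone validating automated species delimitation
against a well-known taxonomy.

The chain, each stage an exported function over plain tibbles:

* **Distances** — Kimura 2-parameter (K2P) distances with pairwise deletion.
  With `P` and `Q` the transition (A↔G, C↔T) and transversion proportions
  over the sites comparable in a pair,

  d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]

  Saturated pairs (non-positive log argument) are reported as undefined,
  never clamped.
* **OTU delimitation** — single-linkage seed clusters at a 2.2% threshold,
  refined by Markov clustering (MCL: expansion = matrix power, inflation =
  element-wise power with column renormalization) inside any seed cluster
  whose diameter exceeds 4%; stable `OTU.NNNN` identifiers; optional
  neighbour-joining tree.
* **Concordance** — every species classified as MATCH (1:1 with a cluster),
  SHARE (only co-occupied clusters), SPLIT (several exclusive clusters) or
  MIXTURE (both); sharing pairs graded *identical* (zero minimum
  interspecific distance) vs *diagnosable*; diagnosability and regional
  re-identification percentages.
* **Barcode gap** — per-species mean/max intraspecific variation,
  nearest-neighbour and congeneric divergence; per-genus summaries;
  randomized accumulation curves.
* **Geography** — great-circle (haversine) distances, 10-km reporting
  classes, sympatry = minimum distance under 100 km, and the genetic ×
  geographic table of split-cluster pairs.
* **Synthetic surveys** — a seeded generator that plants known species,
  clusters, sharing/split/mixture events and coordinates, so every stage is
  testable against ground truth without downloads.

## Worked example

```r
library(barcodebin)

sim <- sim_mixed_survey(seed = 1)          # 66-species planted survey
run <- run_pipeline(sim$data, seed = 1)
run
#> Barcode concordance run
#>   573 specimens (0 dropped as short), 66 species, 74 clusters
#>   match 67% | share 17% | split 18% (mixtures: 1)
#>   diagnostic barcodes 91%, within natural range 91%
#>   mean K2P: intra 1.36%, congeneric 9.81%, nearest neighbour 5.60%
```

573 simulated specimens fall into 74 OTUs for 66 species: 67% of species
match their cluster exactly, 17% share a cluster with another species and
18% are split over several clusters (one species does both, and is counted
in both percentages). Three species pairs share identical haplotypes in
sympatry, so 91% of species remain unambiguously identifiable. Every table
behind these numbers is on the run object (`run$classified`, `run$sharing`,
`run$gap`, `run$splits`, `run$regional`, ...), `tidy(run)`/`glance(run)`
give the per-species classification and the one-row summary, and
`plot_barcode_gap()`, `plot_split_geography()`, `plot_records_per_species()`
and `autoplot()` on accumulation curves draw the standard figures. Real
data enter through `read_barcodes(fasta, metadata_tsv)`.

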