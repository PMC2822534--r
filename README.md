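# mirsieve

Deep sequencing of small-RNA libraries produces, after collapsing identical
reads, a count table whose low end is a large cloud of sporadic, poorly
reproducible tags and whose upper end holds the genuinely expressed miRNAs.
mirsieve is an R package for everyone who needs to separate the two in a
defensible way: it selects the **minimum count threshold of biological
significance** directly from biological replicates, and carries that
threshold through a complete miRNA profiling workflow — mapping,
genome-browser peak tracks, abundance tiers with replicate-agreement
statistics, abundance rankings, and common-node sieving of gene-interaction
networks with housekeeping-normalised expression ratios.

## The statistic at the core

For a candidate threshold *t*, retain the tags with count ≥ *t* in each of
two replicates and compute the exact two-sample Kolmogorov–Smirnov distance
between the retained count distributions,

    D(t) = sup_x | F_a^(t)(x) − F_b^(t)(x) |.

D(t) is a cost function: it is large while irreproducible low-count noise
dominates, falls as the threshold climbs out of the noise, and flattens at a
small sampling floor once only the shared high-abundance component remains.
The selected threshold is the *first instance of a minimum point* of D —
the smallest t forming an interior local minimum of the curve (exact
plateaus resolve to their smallest t; a monotone curve falls back to the
first global minimum). Counts are then partitioned into Low (< 32),
Mid (32–10,000) and High (> 10,000) tiers, and replicate agreement per tier
is quantified by Venn overlap and Cohen's kappa over the observed tag
universe.

## Worked example

Rank a published intracellular count table (shipped as a plain-TSV fixture)
at the 32-read threshold:

```r
library(mirsieve)
t1 <- read_count_table(system.file("extdata", "table1_intracellular.tsv",
                                   package = "mirsieve"))
rank_mirnas(t1, "intracellular_2", min_count = 32)
#> # A tibble: 16 × 3
#>    rank name              count
#>   <int> <chr>             <int>
#> 1     1 hsa-let-7f      1076532
#> 2     2 hsa-let-7g       425364
#> 3     3 hsa-miR-199a-3p  406433
#> 4     4 hsa-let-7a       256612
#> 5     5 hsa-miR-29a      179887
#> # i 11 more rows
```

The let-7 family dominates the head of the list; all 16 transcripts sit in
the High tier (the smallest sample-1 count is 10,037).

Select a threshold from a synthetic replicate pair whose structure mimics a
real library — a shared log-normal signal component above 32 reads and a
replicate-discordant exponential noise cloud below it:

```r
tab <- simulate_count_replicates(mixture_spec(), seed = 1)
sweep <- adaptive_threshold(tab, "rep1", "rep2")
sweep
#> <ks_sweep> replicates rep1 vs rep2; t in [1, 6653]
#> selected threshold: 33 (D = 0.00857)
autoplot(sweep)   # the D(t) cost curve with the selected threshold marked
```

A single draw lands within a step or two of the generator's boundary of 32
(the median over 25 seeds is exactly 32; the test suite asserts this). The
tier machinery then shows what the threshold is protecting you from — the
Mid tier is almost perfectly reproducible across replicates while the Low
(sub-threshold) tier agrees no better than chance:

```r
tiers <- assign_tiers(tab)
tier_venn(tiers, "rep1", "rep2", "Mid")
#> # A tibble: 1 × 5
#>   tier  set_a_size set_b_size intersection_size union_size
#>   <chr>      <int>      <int>             <int>      <int>
#> 1 Mid         1968       1969              1968       1969
```

Kappa for the Mid tier over the observed universe is 0.9997; for the Low
tier it is −0.21.

Everything composes with the pipe, and `run_pipeline()` (or the thin
`exec/mirsieve` command-line wrapper) orchestrates all stages from a YAML
config, writing TSV/BED/wiggle outputs plus a reproducibility manifest.

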