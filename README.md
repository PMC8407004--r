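# gefseq

Base-pair-resolution footprint calling for in-cell DNase I digestion
assays (GeF-seq and relatives), written for analysts studying where
and *when* a DNA-binding protein sits on a bacterial chromosome — for
example a nucleoid-associated protein such as IHF across the
synchronized cell cycle.

In these assays the protein shields ~70–110 bp of DNA from DNase I;
the protected fragments are sequenced as 100 bp paired-end reads, so
reads run through the short insert into the library adapter, and the
genomic/adapter boundary inside each read marks a digestion edge at
single-base precision.

## What the package computes

Given fragments `[s, e)` on a genome of length `L`, the caller builds
per-base depth `d(p)` and fragment-end profiles
`l(p) = #{s = p}`, `r(p) = #{e − 1 = p}`, and calls as a *component*
any window `[i, j+1)` with

* `ewf ≤ j − i + 1 ≤ ewt` (defaults 70, 110),
* `l(i) ≥ m` and `r(j) ≥ m` (end support, default `m = 3`),
* mean depth `(1/w) Σ_{p=i..j} d(p) ≥ T`,

selected greedily by score with near-identical-edge deduplication
(±2 bp on both edges); overlapping components with distinct edges are
kept, and their transitive overlap closure forms *peaks*.  The
threshold is scaled to each library's sequencing depth,

    T_sample = floor(T_ref · N_sample / N_ref),

with `N` the mapped-fragment counts.  Cross-condition occupancy uses
the normalized reads number `read_count / N` per component and labels
each component by its above-threshold pattern over the conditions
(0 min, 10 min, 20 min, random): pre-initiation-specific,
post-initiation-transient, constitutive, or sporadic.  IUPAC
degenerate-consensus scanning (e.g. `WATCARnnnnTTR`) and
position-frequency summaries describe the called regions.

A fully tested synthetic-data generator (genome, planted sites with
per-condition occupancies, protected/background fragments,
adapter-padded paired reads, truth files) and a read-preparation stage
(adapter-boundary trimming, exact-match pair placement) make the whole
pipeline runnable end to end without any external data.

## Worked example

Simulate the standard four-condition cell-cycle experiment (100 kb
genome; one origin-like site occupied at 0 min only, one transient
site occupied at 10 min only, ten constitutive sites) and recover the
site timing:

```r
library(gefseq)
ex  <- cell_cycle_experiment(seed = 1L)
occ <- ex$occupancy
head(occ[order(-occ$avg_depth_0min),
         c("start", "end", "avg_depth_0min", "avg_depth_10min", "specificity")], 5)
#>  start   end avg_depth_0min avg_depth_10min             specificity
#>  28484 28665          174.3            23.7 pre-initiation-specific
#>  42765 42938          129.5           112.2            constitutive
#>  78477 78656          129.1           121.7            constitutive
#>  14211 14375          126.4           103.7            constitutive
#>  49915 50086          126.4           112.7            constitutive
ex$thresholds
#>   0min  10min  20min random
#>     80     79     79     79
```

The top row is the origin-like site (planted at 28,568): mean depth
174 at 0 min against a scaled threshold of 80, but 24 at 10 min —
bound before replication initiation, released after — and it is the
rank-1 binding region at 0 min.  The per-library thresholds differ
because each library's mapped count scales the base threshold of 80.

The same scaling arithmetic applied to published library sizes:

```r
scale_threshold(10000, 15289849, 29977846)   # 19606
round(display_scale(15289849, 29977846), 2)  # 1.96
```

`run_pipeline(pipeline_config(seed = 1L), "out/")` runs the read-level
version (simulate → trim → map → call → compare → scan) and writes
per-condition `fragments.bed`, `components.tsv`, depth/end bedGraph
tracks, and the cross-condition `occupancy.tsv` / `specificity.tsv`.
A thin command-line front end with the same stages as subcommands is
in `inst/cli/gefseq.R`.

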