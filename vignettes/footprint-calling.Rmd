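---
title: "Base-pair-resolution footprint calling from DNase I-protected fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-pair-resolution footprint calling from DNase I-protected fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gefseq)
```

## The assay and the inference problem

Genome footprinting with high-throughput sequencing (GeF-seq) digests
chromatin with DNase I inside fixed cells, affinity-purifies the
protein of interest, and sequences the short DNA fragments the protein
shielded from digestion.  For a nucleoid-associated protein such as
integration host factor (IHF), the protected fragments are about
70–110 bp long.  Because libraries are sequenced as 100 bp paired-end
reads, a read from a fragment shorter than 100 bp runs off the end of
the insert and continues into the library adapter; the genomic/adapter
boundary inside the read is therefore itself a DNase I digestion edge,
and recovering it precisely is what gives the assay base-pair
resolution.

The inference task this package implements is: given a set of
protected-fragment intervals on a reference genome, find the 70–110 bp
regions ("components") bounded on the left by a pile-up of fragment 5′
starts and on the right by a pile-up of fragment 3′ ends, with mean
read depth above a library-size-scaled threshold; group overlapping
components into peaks; compare component occupancy across cell-cycle
timepoints; and summarize the sequence content of the called regions.

## The caller

For fragments `[s, e)` (all coordinates 0-based half-open) we
accumulate three profiles: per-base depth, 5′-start counts at `s`, and
3′-end counts at `e − 1` (the last covered base).  Two conservation
identities tie the profiles to the input and are asserted throughout
the test suite: total depth equals total fragment length, and each end
profile sums to the fragment count.

A *candidate* is any window `[i, j + 1)` with

* width `j − i + 1` between `ewf` (default 70) and `ewt` (default 110),
* at least `end_support_min` (default 3) fragment starts exactly at
  `i` and as many fragment ends exactly at `j`,

scored by its mean depth.  Candidates scoring at least the library's
threshold are selected greedily in descending score order; ties prefer
the wider, then the leftmost window, which makes the output
deterministic.  A candidate is discarded only when **both** of its
edges fall within ±2 bp of an already selected component's edges:
overlapping components with genuinely distinct edges are retained,
because adjacent binding events inside one broad peak are exactly what
the method is meant to resolve.  Peaks are then the transitive closure
of components under ≥1 bp overlap; abutting half-open intervals do not
overlap.

Two points of this procedure are design choices of this package rather
than properties forced by the assay, and are therefore explicit,
documented parameters.  First, "high" fragment-end support at an edge
is quantified as an exact-position count (`end_support_min`), with the
±2 bp edge bucket used only for deduplication.  Second, the greedy
scoring/deduplication rule above is this package's own resolution of
how to reduce the highly redundant candidate set; it is validated
against an independent brute-force enumeration of every `(i, j)` pair
on small genomes, where the two must agree exactly, both before and
after the greedy pass.

### Threshold scaling across libraries

Depth thresholds are comparable across libraries only after scaling by
sequencing depth.  The reference library is assigned `base_threshold`;
a library with `sample_mapped` mapped fragments receives

```
threshold = floor(base_threshold * sample_mapped / ref_mapped)
```

computed with exact arithmetic (the products stay far below 2^53).
Truncation, rather than rounding to nearest, is used because it is the
only rule consistent with all the published threshold values this
convention is checked against; this inference is deliberate and is
pinned by unit tests:

```{r}
scale_threshold(10000, 15289849, 29977846)
scale_threshold(10000, 15289849, 17885459)
scale_threshold(10000, 15289849, 19546737)
```

The same mapped-count ratio, kept at full precision, is the
`display_scale()` factor used to expand a library's vertical plotting
scale (e.g. `r round(display_scale(15289849, 29977846), 2)`-fold for a
29,977,846-read library against a 15,289,849-read reference).

## Cross-condition occupancy

Components called independently per condition are matched across
conditions by ≥50 % reciprocal overlap (single-linkage closure) into
union rows.  Reciprocal overlap is a standard, testable matching rule;
the published analyses match loci by shared component identity without
stating one.  Each row records, per condition:

* `read_count` — fragments overlapping the row by ≥1 bp.  The ≥1 bp
  rule is the simplest monotone choice and is stated in the output
  headers, since "overlapping" versus "contained" is not otherwise
  pinned down.
* `normalized_reads` = `read_count / total_mapped`, the depth-free
  occupancy measure.
* `avg_depth` — mean depth over the row's *representative member
  interval*: the member component with the highest depth in its own
  condition.  A union span can be wider than `ewt` when members jitter
  across conditions, and averaging over that wider span would dilute
  depth systematically; evaluating on the representative member keeps
  the window inside the caller's width bounds.  Above/below threshold
  is `avg_depth >= scale_threshold(...)` per condition, so the flags
  are reproducible from the table itself with no hidden state.

Rows above threshold at 0 min only are labelled
`pre-initiation-specific` (origin-like behaviour: bound before
replication initiation, released afterwards); above at 10 min only,
`post-initiation-transient`; above everywhere, `constitutive`;
anything else, `sporadic`.  Ranking within a condition is by
`avg_depth`, with ties broken by `normalized_reads` then position.

Helpers for the companion quantitative-PCR arithmetic are included:
`chap_yield()` (percent of input recovered after affinity
purification) and `copy_ratio()` (origin/terminus copy ratio
normalized to a reference timepoint, which is exactly 1 by
construction).

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the caller's statistical behaviour is demonstrated.

* **Genome** — i.i.d. bases at a configurable G+C fraction over 100 kb
  by default.  The genome is circular; the generator fixes the
  linearization point so that no fragment spans the join (background
  starts are uniform over `[0, L − length]`, and sites must sit at
  least one maximum fragment length from the ends).  This
  operationalizes join handling without split intervals; regions at
  the join itself are outside the generator's reach, a documented
  limitation rather than a caller guard band.
* **Sites** — IUPAC patterns (default the canonical 13-mer IHF-binding
  consensus `WATCARnnnnTTR`) instantiated by uniform sampling of each
  degenerate position and written into the genome.  Each site carries
  an occupancy probability per condition.
* **Fragments** — per site and condition,
  `Binomial(enrichment_depth, occupancy)` protected fragments, each
  with length uniform on {70..110} and a start jittered uniformly
  subject to containing the motif; plus uniform background fragments
  with the same length law.  Uniform lengths are an assumption: the
  assay constrains only the 70–110 bp range, not the within-range
  distribution.
* **Reads** — read 1 is the top-strand fragment sequence, read 2 its
  reverse complement, each padded to 100 bp with the leading bases of
  a standard library adapter; fragments ≥100 bp give pure genomic
  reads.  Base qualities are a constant Q40 placeholder (nothing
  downstream uses qualities), and sequencing errors are off by
  default.

The standard cell-cycle experiment plants twelve sites: one
origin-like site with occupancy 0.9 at 0 min and 0.05/0.05/0.2
elsewhere, one transient site with 0.8 at 10 min only, and ten
constitutive sites at 0.6, over 20,000 background fragments per
library with `enrichment_depth` 200.  The published libraries carry
15–30 million mapped reads; the simulated libraries are scaled down by
three orders of magnitude (roughly 21,000 fragments over 100 kb keeps
the background depth, site depth, and threshold in the same relative
proportions at desk scale), with `base_threshold` 80 playing the role
of the published 10,000-read threshold.  What these simulations *do*
show: edge-pileup calling recovers planted sites at base-pair-scale
accuracy, threshold scaling keeps calls comparable across libraries of
unequal depth, and the specificity labels recover the planted
occupancy schedules in ≥95 % of seeded replicates.  What they do *not*
show: robustness to sequencing error, PCR duplicates, replication-fork
dosage gradients, GC-dependent digestion bias, or repeat-induced
multi-mapping — none of which the generator emulates (the first is
available as an option, the rest deliberately out of scope).

## Read preparation

`trim_adapter()` returns the smallest offset `b` whose read suffix
matches an adapter prefix: overlaps of ≥6 bases tolerate a 10 %
mismatch rate (a cutadapt-like convention, stated explicitly because
no published value exists); shorter read-end overlaps — down to a
single base — must match exactly.  The single-base case matters: a
fragment one base short of the read length leaves exactly one adapter
base on the read, and without removing it the pair cannot be placed
under the perfect-match contract.  The price is that trimming is not
strictly idempotent: a kept genomic prefix that coincidentally ends in
the adapter's first bases would be trimmed again on a second pass.
This is inherent to any suffix-overlap trimmer that handles 1–2 base
read-through, and is documented rather than hidden.

`map_read_pairs()` places the trimmed mates by exact full-length
matching (candidates anchored with a 25-mer seed dictionary):
read 1 must place uniquely on the forward strand, read 2 uniquely as
its reverse complement downstream (convergent orientation), and the
implied fragment length must lie in `(0, ewt + 40]`.  Multi-mapping
pairs are discarded as ambiguous — repeat artifacts are excluded by
construction instead of by after-the-fact curation.  On error-free
simulated data from a repeat-free genome this recovers ≥99 % of truth
intervals exactly; spurious 1–3 bp tail trims do not move the
recovered interval because the fragment start comes from read 1's
placement and the end from read 2's.

## Motif summaries

`iupac_scan()` reports every (overlapping) occurrence of a degenerate
IUPAC pattern on either strand, with minus-strand hits mapped to
plus-strand coordinates.  A reference `N` matches nothing except a
pattern `N` — an ambiguous reference base is not evidence for any
specific base.  `consensus_fraction()` counts each region once no
matter how many hits it contains.  `build_pwm()` summarizes aligned
region sequences as column frequencies with optional pseudocounts and
per-column information content `2 + Σ f log₂ f` bits against a uniform
background (a genome-composition background is a config option).
De-novo motif discovery is delegated: `export_region_fasta()` writes
called regions (with optional flanks) for external tools, so the
positional offsets such tools attach to their own alignments are not
reproduced here.  Shipped presets (`motif_presets()`) include the
canonical consensus, the per-timepoint consensus elements, and the
transient-site consensus `TAAnnnnTTGATW`.

## Numerical and convention choices

* Coordinates are 0-based half-open internally and in all BED-family
  files; only the human-readable TSV uses 1-based inclusive positions
  with thousands separators (`"3,925,749 to 3,925,842"` for the
  internal `[3925748, 3925842)`).
* Threshold rounding is floor; display-scale rounding (2 decimals) is
  presentation-only.
* Greedy ties are broken wider-first then leftmost; ranking ties by
  normalized reads then position.  All outputs are deterministic under
  a fixed seed, byte for byte.
* The depth-doubling consistency property (duplicating every fragment
  doubles depth and, at doubled threshold, preserves the called
  intervals) holds exactly when the end-support floor does not bind
  (`end_support_min = 1`); with a higher floor, duplication can
  legitimately promote edges past the support cutoff.
* `avg_depth` counts fragments, not paired reads; a fragment is the
  unit of evidence everywhere.

## Problem sizes used in the checks

The test suite exercises the caller against the brute-force oracle on
100 random genomes of 0.8–2.5 kb; uniformity and composition checks
use 50–100 kb sequences; the cell-cycle recovery check runs 20 seeded
replicates of the 100 kb fragment-level experiment; and the
determinism check runs the full read-level pipeline (four libraries of
roughly 21,000 pairs each) twice.  These sizes were chosen so the
whole suite demonstrates every claimed property in a few minutes on a
single CPU while keeping the statistical margins wide (site depth is
about 6 standard deviations above threshold in the recovery check).

## Known limitations

* No statistical test for differential occupancy is provided — the
  comparison is threshold- and rank-based, as in the analysis it
  reproduces.
* Calls cannot span the circular join (see above).
* The mapper is exact-match only; data with sequencing errors need an
  external aligner, whose output enters through `load_fragments()`
  (BED/BEDPE).
* Whether published normalized-read counts use overlapping or
  contained fragments is unknowable from the outputs alone; the ≥1 bp
  overlap choice here is explicit in the headers.
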