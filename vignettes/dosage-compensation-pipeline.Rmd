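---
title: "Methods: fragment-resolved ChIP profiling and the orthologue-set conservation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-resolved ChIP profiling and the orthologue-set conservation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagelens)
```

# Scope and model

`dosagelens` implements the computational chain used to study facultative
dosage compensation: MNase ChIP fragments are partitioned by size into
protein footprints and nucleosome-scale fragments, turned into normalized
coverage and meta-profile matrices, peaks are merged, assigned to
promoters and clustered, FLASH crosslinking reads are demultiplexed and
deduplicated by random tag, and gene sets derived from the binding data
are tested for coherent expression shifts in knockout data through a
resampling test with Benjamini–Hochberg correction.

The package assumes mapped data: fragment tables (chrom, start, end,
mapping quality) stand in for BAM files, and synthetic FLASH reads carry
an accompanying alignment table. Read alignment, peak calling (MACS2) and
differential-expression model fitting (DESeq2) are deliberately out of
scope; their outputs are inputs here.

All internal coordinates are 0-based half-open (BED convention). GTF input
is converted at the boundary (`read_gtf()`: GTF start 1 becomes internal
0) and converted back on writing, so the conversion is its own inverse.
The TSS of a minus-strand gene is `end − 1`, the last covered base of a
half-open interval.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `footprint_max_len` | 140 | bp | small/large fragment boundary, inclusive-small |
| `min_mapq` (ChIP) | 10 | — | fragments with quality < 10 removed (10 kept) |
| `flash_min_mapq` | 10 | — | FLASH tags kept only when quality > 10 (10 removed) |
| `coverage_binsize` | 2 | bp | coverage track resolution |
| `matrix_binsize` | 10 | bp | meta-profile column width |
| `peak_merge_gap` | 10 | bp | replicate-peak merge distance (bedtools `-d` semantics) |
| `tss_assign_dist` | 200 | bp | promoter assignment window (closed) |
| `tss_peak_dist_mouse` | 1000 | bp | peak-bearing gene sets in the mouse comparison |
| `ref_point_flank` | 800 | bp | reference-point matrix half-window |
| `unscaled_flank` / `scaled_body` | 500 / 1000 | bp | scaled-gene-body geometry |
| `pair_min_overlap_chip` / `flash` | 10 / 30 | nt | read-pair merge thresholds |
| `max_barcode_hamming` | 2 | — | demultiplexing distance, unique match required |
| `de_fdr` | 0.05 | — | per-clone DE cutoff |
| `bootstrap_B` | 10000 | — | resamples of the set test |
| `has_proximal_max_dist` | 2344 | bp | HAS-proximal gene distance, inclusive |
| `kmeans_k` | 3 | — | autosomal peak clusters |
| `log2_pseudocount` | 1.0 | — | log2-ratio stabilization |

Note the two mapping-quality conventions coexist on purpose: the ChIP
filter is inclusive at 10, the FLASH filter exclusive. Each module follows
the rule of its own data type.

# The synthetic study

The generator's defaults define the package's reference study: one X plus
two autosomal arms of 300 kb, 60 genes per chromosome with non-overlapping
bodies of at least 1.5 kb (so scaled-region matrices are defined for every
gene), 30 HAS on the X, and three clusters of 20 autosomal sites planted
within 200 bp of distinct gene TSSs. Bound sites emit footprint fragments
centered on the site and nucleosome-scale fragments at phased offsets of
±200 bp; the background is uniform. Fragment lengths come from truncated
normals — footprints: mean 90, sd 15, truncated to [40, 140];
nucleosomal: mean 165, sd 12, truncated to [141, 250] — so the planted
classes land on the 140 bp partition boundary by construction. X fragment
rates scale with sex ploidy (one X in males, two in females), which makes
the male X sit at half autosomal input coverage. Five percent of fragments
receive mapping quality below 10 and five percent are duplicated exactly,
giving the filters something to remove.

FLASH libraries use four 6 nt barcodes with pairwise Hamming distance 6,
so distance-2 demultiplexing is unambiguous by construction, a 7 nt random
tag, and a PCR duplication of `1 + Poisson(3)` reads per molecule. Random
tags are drawn *without replacement within each gene*: with replacement, a
library of several hundred molecules per gene would suffer birthday
collisions among the 4^7 tags and the deduplicated count would
systematically undershoot the planted truth. Real libraries do collide;
the round-trip exactness the tests assert is a property of this idealized
library, not of real data.

DE tables put a planted shift (default −0.5 log2FC on the cluster-1 set)
plus Normal(0, 0.3) per-gene, per-clone noise on every gene; p-values come
from a one-sample z-model with known sd and are BH-adjusted within each
clone. This stands in for the out-of-scope DE fitter. A consequence worth
stating: at shift −0.5 and noise 0.3 (1.7 sd) genes are detectable as a
*set* but essentially never individually FDR-significant — the per-gene DE
filter only fires in strong-effect scenarios (≥ 4–5 sd).

qPCR plates draw Ct values under a shared detection threshold `C`
(`level · E^Ct = C`), so the efficiency-corrected quantity `E^(−Ct)`
equals `level / C` for every primer regardless of its efficiency, and
ratios to the geometric mean of the reference genes recover the planted
levels exactly at zero noise. Each primer gets a four-point ten-fold
dilution series; a perfect doubling assay has slope −3.32 cycles per
decade.

Sample sizes were chosen for desk-scale statistics, not sequencing
realism: 250–300 kb chromosomes at 0.02 background fragments per bp give
X:autosome coverage ratios with about 1% sampling error, and 1,500-molecule
FLASH libraries keep the full chain under a second. The generator has no
sequence error model, no mappability structure and no aligner emulation.

# Numerical choices

* **Coverage.** Bin value = summed per-base depth over the bin divided by
  the bin size (a trailing partial bin is zero-padded), which makes
  coverage mass exactly equal to total fragment length. A `midpoint` mode
  counts only each fragment's center base — the dyad-density convention of
  nucleosome positioning work. Positional assertions (footprint peak at
  the site center, phased-nucleosome peaks at ±200 bp, to ±1 column) use
  midpoint mode: full-fragment coverage convolves positions with a
  ~165 bp box kernel whose flat top makes an argmax location test
  meaningless at 10 bp resolution.
* **Depth equalization.** For log2-ratio and subtraction modes both tracks
  are scaled to the *smaller* total coverage mass over non-excluded
  chromosomes (readCount-style), then combined per bin with pseudocount
  1.0 for the ratio. The X (or any configured chromosome list) is excluded
  from all scaling statistics.
* **Matrix geometry.** Region center = `floor((start + end) / 2)`.
  Out-of-bounds bases are masked as NA, never zero, and masked cells are
  excluded from column means. In scaled-region mode, virtual body base `k`
  (of 1000) reads the real body base `floor(k · (L − 500) / 1000)`; genes
  with body ≤ 500 bp are dropped with a warning rather than padded,
  mirroring common meta-gene practice. Minus-strand rows are traversed in
  gene orientation. Both geometries are pinned to independent per-base
  brute-force resamplers in the test suite.
* **k-means.** `stats::kmeans` (Hartigan–Wong) with 10 restarts and a
  fixed seed; each track is standardized to zero mean and unit variance
  over all cells before concatenation so no track dominates by scale.
  Because raw k-means labels are arbitrary, clusters are relabelled 1..k
  by descending mean signal of the first supplied track, which also pins
  the within-cluster sort; at the planted separations used in the tests
  the restart strategy recovers the partition exactly and row-permutation
  invariantly.
* **Bootstrap test.** Default null: sampling *without* replacement
  (random gene sets of the same size); a with-replacement bootstrap is
  available. Empirical p uses the +1 correction and is never exactly 0.
  The set statistic is the mean log2FC (median available); the default
  alternative for the conservation question is `less` (coherent
  downregulation), with `greater` and a centered two-sided variant
  available. Under the null the `less` p-value is uniform, which the
  calibration test checks at the 5% level against the exact binomial 99%
  interval.
* **DE filter.** Beyond FDR < 0.05 in every clone, the default requires
  the log2FC sign to agree across clones ("in both clones" read as
  reproducible direction); `require_sign_consistency = FALSE` gives the
  literal FDR-only rule.
* **Fisher, BH, Welch, k-means, linear fits** are delegated to
  `stats::fisher.test`, `stats::p.adjust`, `stats::t.test` and
  `stats::lm`; the tests pin them to independent closed-form or
  enumeration oracles rather than to themselves.

# Open design points, decided

* The exact 2×2 construction behind the X-overrepresentation test is not
  uniquely determined by a count table alone; both natural readings are
  implemented — factor A versus factor B (default) and factor A versus the
  chromosome-length expectation — and neither is asserted as canonical.
* Whether the conservation bootstrap samples with or without replacement,
  and one- versus two-sided, are configurable; the defaults (without
  replacement, `less`) are the package's choice, recorded here.
* The FLASH adapter layout ([barcode][tag][insert] on the merged read,
  lengths from the configuration) is configurable because real custom
  adapters vary; pair merging requires an exact overlap match, keeping the
  operation fully specifiable and testable.
* The matrix column width is 10 bp by default (the coverage track is
  2 bp); any multiple of the track binsize that divides the window is
  accepted.

# What passing tests do and do not show

The suite demonstrates internal correctness (exact oracles for coverage,
matrix geometry, Fisher, BH, Welch, qPCR algebra), recovery of planted
structure (footprint and nucleosome positions, cluster labels, FLASH
molecule counts, the −0.5 × 66-gene expression shift against four null
control sets, across 100 seeded replicates), and statistical calibration
of the resampling test under the null. It does not demonstrate robustness
to alignment artifacts, sequence error, GC or mappability bias,
overdispersed count noise, or annotation mismatch — none of which the
generator emulates. Problem sizes in the tests (≤ 10 kb chromosomes for
exact oracles, 250 kb–1 Mb genomes for statistical checks, B = 2,000 for
calibration and B = 10,000 for the conservation scenario) are the
package's reference conditions.
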