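---
title: "Methods: staged chromatin accessibility analysis with acrstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged chromatin accessibility analysis with acrstage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`acrstage` implements a desk-scale analysis pipeline for accessible
chromatin regions (ACRs) profiled by ATAC-seq across ordered
developmental stages, integrated with stage-matched RNA-seq counts.
The pipeline covers: consensus peak calling across replicates, genomic
feature annotation, permutation fold enrichment, stage-specific/common
partitioning, differential accessibility (DPI) and differential
expression (DEG) testing, promoter-ACR/expression integration, k-means
temporal clustering, and motif enrichment. A deterministic synthetic
study generator provides ground-truth bundles for validation.

# Interval model

All intervals are held as `GenomicRanges::GRanges` (1-based, closed).
File IO converts at the boundary: BED and narrowPeak starts are 0-based
half-open on disk and shifted on read/write; GTF is 1-based closed and
passes through unchanged. The midpoint of an interval with 1-based
start $s$ and width $w$ is $s + \lfloor w/2 \rfloor$.

# Consensus peaks and stage partition

A stage's consensus ACRs are the base-level intersection of all its
replicate peak sets: each replicate is first merged
(`GenomicRanges::reduce`), then intersected pairwise across replicates,
and runs of bases present in every replicate become consensus peaks
(`consensus_peaks()`, minimum width 1 by default). Genome coverage is
the reduced union length divided by total genome length.

`stage_partition()` labels a stage's consensus peak *stage-specific*
when it has no overlap of at least 1 bp with any other stage's
consensus set, and takes *common* peaks from the reference (earliest)
stage as those overlapped by every other stage.

# Annotation

`classify_intervals()` assigns each interval, by its midpoint, one of
`promoter`, `tts`, `exon`, `intron`, `intergenic` with that priority.
Windows (strand-aware, clipped to the chromosome):

* promoter: TSS $-2000$ to $+100$ (`promoter_upstream`,
  `promoter_downstream`),
* proximal promoter: TSS $-1000$ to $+100$ (used for the
  integration map),
* TTS: transcription end $-100$ to $+1000$.

Nearest-TSS distances are signed in gene orientation (negative =
upstream); ties go to the lexicographically smaller `gene_id` so output
is deterministic.

# Permutation fold enrichment

For each feature class, `fold_enrichment()` compares the observed
class counts of the peak midpoints against `n_perm` (default 5000)
sets of random regions with the same length spectrum; for each random
region the chromosome is drawn with probability proportional to its
length among chromosomes long enough to hold the region, and the start
uniformly. Fold = observed / mean permuted count; the permutation SD is
reported alongside. Normalized chromosome length is
$\text{total peaks} \times \ell_i / \sum_j \ell_j$, compared with
per-chromosome peak counts by Pearson correlation ($r$, $r^2$).

Peak lengths across feature classes are compared by one-way ANOVA with
Tukey HSD post-hoc tests; compact letter groupings are computed by an
insert-absorb algorithm over the significant pairs.

# Differential testing

`nb_differential()` is a negative-binomial Wald test:

1. size factors by median-of-ratios against the geometric-mean
   pseudo-reference (library-size fallback with a warning when no
   feature is nonzero everywhere);
2. pooled method-of-moments dispersion per feature, floored at
   $10^{-8}$;
3. $\log_2$ fold change with pseudo-count 0.5;
4. delta-method Wald statistic referred to a **t distribution with
   $n_A + n_B - 2$ degrees of freedom**. A normal reference inflates
   the type-I error to roughly 0.10 at 4 vs 4 replicates; the t
   reference restores it to ~0.05. This calibration was run before the
   implementation was fixed;
5. Benjamini–Hochberg adjustment over tested (not-all-zero) features;
   untested features get `NA`.

Significance defaults: adjusted p < 0.05 and $|\log_2 FC| > 1$.
RNA-seq genes are filtered to those with FPKM
($= c \times 10^9 / (\ell \times N)$) strictly above 1 in at least 3
samples of some stage.

# Integration

Proximal-promoter ACRs are joined to genes (`map_promoter_acrs()`);
per-gene ACR length statistics (`single`, `max`, `total`) are sorted
descending and cut into three equal groups at ranks
$\mathrm{round}(n/3)$ and $\mathrm{round}(2n/3)$. A run of equal values
straddling a cut moves wholly to the side initially holding the
majority of the run; an even split goes to the lower (shorter-length)
group. This generalizes the worked example where a 3-long run with one
member in the middle group and two in the bottom group moves entirely
to the bottom, giving a 30/29/31 top/middle/bottom split of 90 genes.

Stage-mean FPKM values are binned left-closed/right-open at
2/5/10/30 (bins B1–B5), and group-by-bin tables are row-normalized to
percentages. DEGs are clustered by k-means (k = 6, `nstart = 10`) on
per-gene z-scores of stage-mean expression; cluster labels are
renumbered by decreasing size (ties by first-stage center) so labels
are stable. Cluster/DEG-set overlaps are scored with the upper-tail
hypergeometric test; an adjusted Rand index utility is included.

# Motif scanning

PWMs are read from minimal MEME files, converted to log-odds with
pseudo-count $10^{-3}$ against the file's background. Scanning slides
over both strands (reverse strand by reversing the matrix and
complement-reordering columns); windows containing N are skipped; the
default hit threshold is 0.8 of the maximum attainable log-odds score.
Enrichment compares target vs background sequence sets (200 bp windows
centered on peak midpoints) with a pooled 2x2 hypergeometric test on
sequences carrying at least one hit, flagged at alpha = 0.01.

# Synthetic study generator

`generate_synthetic_study()` writes a complete text bundle —
chrom.sizes, FASTA, GTF, per-replicate narrowPeak files, peak and gene
count matrices, sample sheet, MEME motifs, and a JSON truth record —
from a single seed; identical seeds give byte-identical bundles.

Defaults are desk-scale stand-ins for a 3-stage, 4-replicate design:
2 Mb genome over four chromosomes (800/600/400/200 kb), 180 genes on a
5 kb slot grid with 2 kb two-exon bodies, 240 common plus 60-per-stage
specific peaks (40% planted in promoters), NB counts with mean 100 and
dispersion 0.05, planted $|\log_2 FC| = 2$ accessibility shifts, six
DEG expression archetypes of 10 genes each, and the motif `TGACGTCA`
planted in half of the stage-1-specific windows (plus an unplanted
decoy). The generator emulates the *structure* of such a study —
replicate concordance, jitter, noise peaks, depth variation — not read-
level sequencing artifacts: there are no alignment errors, GC effects,
or copy-number confounders, and counts come directly from the NB model.

# Limitations

* The NB test uses a pooled per-feature dispersion, not shrinkage
  across features; at very low replication it is noisier than
  DESeq2-style estimators (a cross-check against DESeq2 log2FC is part
  of the test suite).
* Random-region sampling matches length and chromosome occupancy but
  not GC content or mappability.
* Motif enrichment counts sequences with at least one hit; it does not
  model per-sequence hit multiplicity.
* The generator's truth guarantees (exact round trips) hold in the
  noise-free configuration; noisy defaults are validated statistically
  (power, false-call rate, ARI) instead.
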