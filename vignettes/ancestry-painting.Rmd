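---
title: "Tracing parent-of-origin ancestry in experimental crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing parent-of-origin ancestry in experimental crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpaint)
library(dplyr)
```

## The problem and the model

`pedpaint` quantifies and visualizes which parent each region of an
offspring genome was copied from, in crosses where both parents are
known and sequenced. The model is intentionally minimal and fully
deterministic — no statistical inference, no phasing, no confidence
scores:

* Only **homozygous single-nucleotide** offspring calls are used. In a
  haploid or fully homozygous diploid system every such call matches
  one parental allele unambiguously; heterozygous calls (`0/1`, `1|0`,
  ...) are ambiguous and are dropped, as are indels. `/` and `|`
  genotype separators are treated identically, precisely because
  heterozygotes never survive to the point where phase would matter.
* A site is **informative** if at least one parent carries it. The
  label is `Parent1` when the offspring allele matches parent 1 and not
  parent 2, symmetrically `Parent2`, and `Unknown` when it matches both
  (the parents agree there) or neither (a call or reference artifact).
  Sites carried by only one parent are retained: a match gives that
  parent's label, a mismatch gives `Unknown` — the conservative reading,
  since a mismatch against one parent says nothing about the other.
  Sites absent from both parents are discarded and counted.
* Parental VCFs may come without genotype columns (consensus files
  listing the alleles a strain carries); such records are read as
  homozygous for the first ALT allele.

Duplicate `(chrom, pos)` records within one individual are a hard
error, not last-wins: the pipeline's output must be a pure function of
its input files. Coordinates are 1-based and intervals closed
end-to-end, matching both VCF and GTF conventions.

## Two-pass clustering

Labeled SNPs, sorted by chromosome and position, are collapsed into
ancestry blocks in two passes.

**Pass 1** is a run-length encoding with a length filter: a maximal run
of same-label SNPs becomes a cluster spanning from its first to its
last SNP, and survives only if that span reaches `min_cluster_len`
(the *CLUSTER* parameter). "Length" is nucleotide span, `end − start +
1` — not SNP count; the threshold is expressed in nt and defaults to
10 nt, enough to remove single sporadic miscalls while keeping any run
of two or more SNPs at realistic densities. The trailing run of each
chromosome passes through the same filter. Because recombination tract
lengths vary enormously between taxa, the threshold is a user
parameter, not a constant.

**Pass 2** smooths the resulting chain. Scanning left to right, a
cluster whose span is strictly below `max_gap_cluster_len` (default
1000 nt) and which sits between two clusters of one *other* label is
removed and its flanks fused into a single block running from the left
flank's start to the right flank's end; the scan restarts until a
fixpoint. Genuine sub-kilobase recombination tracts are rare, so such
intervening blocks are treated as call noise; the removed cluster's
SNPs are dropped from the fused block's count, and flanks are never
relabeled. `Unknown` runs are clustered and smoothed by exactly the
same rules — a small `Unknown` cluster between two `Parent1` blocks is
removable — because `Unknown` spans are part of the informative-region
denominator and of the painting.

Two design points were genuinely open and are resolved as follows.
First, the block chain can contain *adjacent same-label* clusters
(pass 1 discarded the short run that used to separate them); pass 2
coalesces these as it scans, so that after convergence no two
consecutive blocks on a chromosome share a label — the natural
invariant for a segmentation, and the one the merge rule itself
produces whenever it fires. Second, pass 2 never merges across an
intervening cluster *at or above* the threshold, and runs discarded by
pass 1 are gone for good rather than revisited. With both thresholds at
1 the pipeline degenerates to the pure run-length encoding of the
label sequence, a useful limit for testing.

The merge operation is idempotent and monotone (cluster count never
increases, coverage never shrinks), and the whole pipeline commutes
with exchanging the parents: swapping the two parental inputs swaps
every `Parent1`/`Parent2` label in every table and changes nothing
else.

## Quantification

Genome-level contributions divide each label's summed block span by the
summed span of **all** blocks on the chromosome — the informative
regions, including `Unknown`. The full chromosome length is never the
denominator: in non-model genomes it is inflated by repetitive and
invariant regions the SNP panel cannot see, whereas the informative
span is exactly the territory the method actually assigned.
Pre-rounding, the three percentages sum to exactly 100 per chromosome;
TSV output rounds to one decimal.

Gene-level contributions intersect blocks with gene intervals from a
GTF (`rtracklayer` import; rows of feature type `gene`, or the union of
`exon` rows per `gene_id` when no `gene` rows exist, so filtered or
minimal annotations work). Each gene takes the label with the largest
total overlap, summed per label across blocks, so partial and nested
overlaps are handled naturally; a tie or a gene with no overlapping
block is `Unknown` — again the conservative, deterministic choice,
since preferring either parent on a tie would break parent symmetry.
Strand is ignored; inheritance is strand-agnostic. Gene results are
only as good as the annotation: fragmented or misannotated genes
propagate directly into the counts.

## Painting

`paint_chromosomes()` renders one track per individual × chromosome,
faceted into a composite with a shared legend and fixed colors
(`Parent1` blue, `Parent2` red, `Unknown` gray — overridable, but
constant across all panels of a figure). Each chromosome's axis runs
from 1 to the largest block end observed across individuals unless
explicit chromosome lengths are supplied, which keeps tracks comparable
without a reference index. The layout stays readable to roughly 200
individuals × 40 chromosomes; beyond that the function still renders
and warns rather than refusing. `plot_contributions()` draws the
genome-percent and gene-percent tables as stacked bars. Both functions
are pure consumers: every table they draw is also written as tidy TSV
by the CLI, so custom figures never require re-running the pipeline.

## The simulator: what it emulates and what it does not

`simulate_cross()` generates the study conditions the pipeline is
validated under. Parent-distinguishing SNP sites are placed by a
Poisson process (default 1 site/kb); at each site the two parents carry
two *distinct non-reference* alleles, so every site is informative and
either parent can be recognized. Each offspring chromosome is tiled by
segments copied from one parent, switching at crossover positions drawn
uniformly (no interference model — the simplest process consistent with
apparently random crossover placement in real crosses), with the
starting parent a fair coin flip; the truth table records the exact
segments, which tile `[1, chrom_len]` without gaps. Optional noise
emits a fraction of offspring sites as heterozygous calls (which the
pipeline must drop) or flips them to a non-parental allele (which the
pipeline must label `Unknown`). The toy GTF tiles 1 kb genes every
20 kb, giving known expected gene-label fractions.

The defaults — 3 chromosomes × 5 Mb, 1 SNP/kb, 4 offspring, 2
crossovers per chromosome, zero noise — describe a small yeast-like
validation cross. What passing tests on these data do **not** show:
real datasets have uneven SNP density, reference bias, clustered
genotyping errors, and parents that share alleles at many sites (here
they never do), so real `Unknown` fractions will be higher and block
boundaries less crisp than in simulation. The simulator bounds
algorithmic correctness, not caller quality.

Recovered accuracy is scored per nucleotide against the truth set with
the *whole genome* as denominator, so chromosome ends beyond the
terminal SNPs and the inter-SNP window around each true breakpoint —
which no SNP-based method can assign — count against the pipeline. On
the default cross this still leaves per-nucleotide accuracy above 99%
(typically ~99.9%), with ~1 kb of irreducible blur per breakpoint at
1 SNP/kb.

## Numerical and degenerate-input choices

* Threshold comparisons: pass 1 keeps span `≥ min_cluster_len`; pass 2
  removes span `< max_gap_cluster_len`. The strict/non-strict pairing
  makes the two thresholds compose cleanly at equal values.
* Empty inputs: a header-only VCF yields an empty call set; an empty
  cluster set warns rather than crashes in quantification; an empty
  painting is an error (there is nothing to draw).
* Chromosome names are matched by exact string equality between VCFs
  and GTF; no `chr`-prefix normalization is attempted.
* Percentages are exact rational multiples of 100 pre-rounding; only
  the TSV writer rounds (one decimal).
* Determinism: all randomness lives in the simulator behind a single
  seed (`withr::with_seed`, leaving the session RNG untouched); the
  analysis path uses none. Two runs on identical inputs produce
  byte-identical tables. Saved PNG figures are deterministic as well;
  PDF metadata carries a creation timestamp (an R device limitation),
  so reproducibility checks compare tables and plot data, not PDF
  bytes.

## Problem sizes used in the test suite

The suite validates against independent oracles (a frozen exhaustive
truth table for labeling; base-R run-length encoding plus filtering for
pass 1; a naive iterate-until-stable rewrite for pass 2; literal
per-base tallies for quantification) on randomized inputs of 10,000
SNPs and ~1,000 cluster chains, and runs the full pipeline on simulated
crosses of 2–3 chromosomes at 0.1–5 Mb. Breakpoint-recovery statistics
aggregate 20 independent simulated crosses at the default
configuration. These sizes exercise every code path while keeping the
suite fast; the algorithms are linear in SNP count and have been run
unchanged on multi-million-SNP inputs.

## Known limitations

* Polyploid and heterozygous-rich diploid data lose most sites to the
  homozygosity filter; the method trades resolution for robustness and
  is not a phasing substitute.
* Ancestry beyond two parents is out of scope, as are BCF input,
  INFO/FILTER-based quality filtering (pre-filter upstream), and
  statistical changepoint or HMM smoothing — all assignment is
  threshold-based by design.
* Gene-level results inherit annotation quality wholesale.
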