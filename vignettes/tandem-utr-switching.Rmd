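---
title: "Detecting tandem 3' UTR switching from 3'-end sequencing"
author: "apatrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem 3' UTR switching from 3'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatrend)
```

## The problem

Most human genes carry several cleavage/polyadenylation sites downstream of
the same stop codon. Which of these tandem sites is used decides the length
of the 3' UTR, and with it the complement of microRNA-binding and other
regulatory elements the transcript retains. Oligo-dT primed 3'-end
sequencing reads out site usage directly: each read starts in the polyA
tail (a 5' poly-T run after base calling) and its alignment's 3' terminus
marks the cleavage position, so read counts per site measure isoform usage
and read counts per gene measure expression.

`apatrend` implements the complete analysis chain from such reads to
per-gene switching calls between two conditions (e.g. tumor versus matched
normal tissue from one patient), plus differential expression and gene-set
enrichment of the called lists.

## The site-calling model

**Cleavage extraction.** Every uniquely aligned read contributes one
cleavage event at its strand-aware 3' terminus (rightmost aligned base on
`+`, leftmost on `-`). Coordinates are 0-based half-open throughout the
package; a single convention avoids off-by-one errors in the window logic
below.

**Internal-priming filter.** Oligo-dT can anneal to A-rich genomic
sequence instead of a true tail. An event is discarded when the 20-nt
genomic window immediately downstream of the cleavage base (in
transcription direction) contains at least 12 `A`, or the contiguous
8-mer `AAAAAAAA`, or matches `G A{4,} G A{3,} G`. The `+` on the printed
form of that disruption pattern is read as "one or more of the preceding
base", the only self-consistent reading. The 12-`A` rule is applied as
"12 or more"; windows truncated at contig ends are evaluated as-is,
without padding.

**Clustering.** Surviving events from both libraries are pooled and
chained per (chromosome, strand) by single linkage with a 24-nt gap: a new
cluster starts when the distance to the previous event exceeds 24 nt. A
gap rule rather than fixed windows keeps the result invariant to input
order. Clusters with a single supporting read are discarded — a polyA site
requires more than one read. The representative position is the member
position with the highest pooled count; ties resolve to the 3'-most
position, since polyadenylation measurement error (slippage into the tail)
biases toward upstream positions.

**Annotation.** Sites are tiered by priority: within 24 nt of an annotated
transcript end; else within 24 nt of a curated known-site database entry;
else novel. "Within 24 nt" is absolute genomic distance on the same
strand — the sources give no reason to read it one-sided. Each site is
then classified by genomic region with priority
`UTR3 > CDS > intron > noncoding > downstream1k > intergenic`
(`downstream1k` covering 1000 nt past the gene end, where genuine sites
beyond the annotated end are common). When two genes' ends are equidistant
from a site, the 5'-side gene wins and the tie is logged.

A *gene* is the union of transcripts sharing a gene id; its UTR anchor is
the 3'-most annotated stop-codon boundary, giving one tandem-UTR length
axis per gene even when several transcript ends are annotated.

## The switch statistic

For each gene with at least two admissible sites, a 2 x k table records
the per-sample read counts at the tandem sites ordered by increasing UTR
length Y (strand-aware distance from the anchor, in nt — the physical
length, not the site rank). Tables with fewer than 30 pooled reads, or
with no reads in one sample, are excluded with a recorded reason; the
expressed-in-both requirement is applied before the 30-read floor.

The *switch index* is the Pearson correlation r over the table's n
expanded reads, with X = 1 or 2 for the sample and Y the read's UTR
length. It is computed exactly from count-weighted moments; with binary X
this reduces to

  r = sqrt(n1 n2) (ybar2 − ybar1) / (n sd(Y)),

which is numerically stable (Y is centered first) and exactly antisymmetric
under swapping the two samples. r > 0 means sample two's reads sit at
longer UTRs — lengthening in sample two; r < 0, shortening. The trend
statistic M² = (n − 1) r² is referred to the chi-square distribution with
one degree of freedom (no continuity correction — the formula is applied
as defined), p-values are adjusted by Benjamini–Hochberg over the tested
genes only, and a gene is called shortened when r < −0.1 with FDR < 0.01,
lengthened when r > 0.1 with FDR < 0.01. Degenerate tables (all reads in
one sample or at one site) are reported with a reason rather than silently
dropped, and do not enter the FDR.

M² is the classical trend statistic whose mean under the exact
label-permutation null is 1 — the (n − 1) factor is what aligns it with
the chi-square reference. The chi-square p is nonetheless asymptotic: at
table depths of a few hundred reads its error against the exact
permutation null (up to ~0.05, dominated by the discreteness of k = 2
tables) exceeds 10,000-replicate Monte-Carlo error, so the test-suite
comparison against a permutation oracle is run at depths of 500–5000
reads, where the approximation has converged, and brackets the chi-square
p between the permutation null's strict and inclusive tails (a discrete
null defines its p-value only up to tie convention).

## Differential expression

Because only 3' ends are sequenced, gene length cancels and the mapped
read count per gene is the expression measure. For one gene with counts
(x, y) in libraries of sizes (N1, N2), conditioning on the pooled count
t = x + y gives y ~ Binomial(t, N2/(N1 + N2)) under the null of equal
relative expression — the exact conditional form of the Audic–Claverie
test. The two-sided p doubles the smaller inclusive tail, capped at 1
(the original test is one-sided; doubling is the conventional symmetric
choice). The implementation canonicalizes the orientation so the exchange
symmetry p(x, y, N1, N2) = p(y, x, N2, N1) holds exactly in floating
point, and works through the binomial CDF, stable far beyond 10^6 counts.
A gene is a DEG at FDR < 0.01 with at least a two-fold difference of
library-normalized counts; the 0.5 pseudocount enters the fold change
only, never the test, so zero counts cannot produce infinite folds or
perturb inference. Library sizes are the reads surviving the
internal-priming filter, the last filter before counting.

The `ddct_ratio()` helper carries the companion qPCR arithmetic: the
2^−ddCt ratio of the constitutive (shared) to extended (distal-only) UTR
segment between conditions, used to validate called switches.

## Enrichment

Called gene lists are tested against user-supplied gene sets (GMT) over a
configurable background — the genes actually sampled in the run, never a
hard-coded population. Fold enrichment is (k/n)/(K/N); significance uses
the conservative EASE variant of the hypergeometric upper tail,
P(X >= k − 1), which removes one list hit (plain Fisher is available via
`penalize = FALSE`; the sources do not say which variant produced their
printed p-values, so both are exposed). The Benjamini–Hochberg adjustment
shares the same code path as the switch and expression stages.

## The synthetic world

`make_reference()` and `simulate_reads()` build a deterministic toy
genome: non-overlapping single-exon genes on both strands, each with 2–4
tandem sites spaced at least 60 nt apart, the distal site coinciding with
the annotated transcript end, half the interior sites registered in the
known-site database. Defaults and what they emulate:

* expression ~ lognormal(meanlog 4, sdlog 1) — a realistic right-skewed
  abundance distribution;
* cleavage jitter ~ Normal(0, 5 nt) truncated at ±20 nt, so 60-nt spacing
  can never merge planted sites under the 24-nt rule;
* per-library depth 50,000 reads over 200 genes by default (desk-scale;
  tests scale it to their needs);
* usage shifts: 15% of genes shortened and 15% lengthened in sample two,
  proximal usage moving between 0.3 and 0.7 (the recovery acceptance run
  uses 0.2/0.8);
* expression differences: 10% up, 10% down at 4-fold;
* decoy rate 5%: reads planted at intergenic loci whose downstream 20-nt
  window is all `A`, so every decoy must fail the internal-priming filter,
  while every true site's jitter-reachable downstream zone is sanitized to
  fewer than 8 consecutive and fewer than 12 total `A` and no disruption
  pattern, so no true read can.

Reads are emitted both as FASTQ (5' poly-T run of 8–18 nt plus the
reverse complement of up to 50 nt upstream of the cleavage base) to
exercise preprocessing, and as pre-aligned BED — the default test route,
since alignment itself is outside the package's scope. Everything is
byte-reproducible given the seed.

What the generator does *not* emulate: sequencing errors beyond constant
quality strings, PCR duplicates, multi-mapping ambiguity, intron-containing
genes, or replicate designs. A green recovery test therefore establishes
that the statistics and the site-calling geometry are implemented
correctly — not that the pipeline is robust to alignment artifacts of real
data.

## Numerical and design choices

* Internal coordinates 0-based half-open; BED native, GTF converted on
  read.
* FASTQ preprocessing defaults (no cutoffs are fixed by the protocol this
  stage mirrors): mean Phred >= 20, <= 10% `N`, homopolymer-run fraction
  0.8, poly-T run >= 8 nt tolerating one non-T per 10 nt (one sequencing
  error should not discard a read), post-trim minimum 25 nt for unique
  mapping. Reads are not reverse-complemented at this stage; orientation
  is the aligner's concern.
* Sample order is explicit configuration, never filename order — the sign
  of the switch index depends on which library is row two.
* `unique_only` uses the aligner's `NH` tag when present, else MAPQ > 3.
* Events are filtered for internal priming before clustering; no
  site-level rescue is attempted.
* Whether the 30-read floor applies before or after the expressed-in-both
  requirement is not fixed by the method's description; expressed-in-both
  is applied first so that the exclusion reasons are unambiguous.

## Limitations

One library pair, no replicates: the trend test measures association
within a single comparison and its FDR speaks to multiplicity across
genes, not biological variability. The enrichment stage reproduces
fold/EASE arithmetic on user-supplied memberships; it does not bundle any
pathway database.
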