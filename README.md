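# apatrend

Genome-wide analysis of **tandem 3′ UTR switching** (alternative
polyadenylation) from oligo-dT primed 3′-end sequencing libraries, for
transcriptomics analysts comparing polyA-site usage between two conditions
— typically tumor versus matched normal tissue.

Most genes carry several polyA sites downstream of one stop codon; which
site is used sets the 3′ UTR length and the regulatory elements (miRNA
sites, AU-rich elements) the mRNA retains. In a 3′-end library each read
begins in the polyA tail, so its alignment's 3′ terminus marks the
cleavage position: read counts per site measure isoform usage, and per
gene, expression.

The package covers the whole chain:

* **preprocess** — FASTQ quality/homopolymer filtering and 5′ poly-T
  detection/trimming;
* **sitecall** — cleavage extraction from alignments (BED6/SAM/BAM),
  internal-priming filtering against A-rich downstream genomic windows
  (≥12 A of 20 nt, `AAAAAAAA`, or `GA{4,}GA{3,}G`), 24-nt single-linkage
  clustering with a ≥2-read site rule, three-tier annotation
  (transcript-end / known-site DB / novel) and genomic-region classes;
* **apaswitch** — the core statistic. Per gene, a 2 × k count table over
  tandem sites ordered by UTR length *Y*; the switch index is the
  count-weighted Pearson correlation

  *r* = cov(X, Y) / (σ_X σ_Y),  X ∈ {1, 2} the sample of each read,

  tested with the linear trend statistic *M²* = (n − 1) r² ~ χ²₁, BH-FDR
  over genes; a gene is *shortened* if r < −0.1 ∧ FDR < 0.01 and
  *lengthened* if r > 0.1 ∧ FDR < 0.01 (tables with < 30 reads excluded);
* **expression** — the exact Audic–Claverie conditional test
  (y | x + y ~ Binomial(x + y, N₂/(N₁+N₂))) with BH-FDR and a two-fold
  normalized-count rule, plus the qPCR 2^−ΔΔCt cUTR/eUTR helper;
* **enrich** — fold enrichment (k/n)/(K/N) and EASE-style hypergeometric
  testing of called gene lists against user-supplied GMT sets;
* **simdata** — a deterministic synthetic 3′-end world (toy genome,
  tandem sites, usage shifts, expression differences, internal-priming
  decoys) with ground truth for recovery scoring.

## Worked example

Simulate a two-library experiment with planted switches, run the site
caller and the switch model, and score against the generator's truth:

```r
library(apatrend)

cfg <- sim_config(n_genes = 60, depth = 20000, seed = 7)
ref <- make_reference(cfg)
sim <- simulate_reads(ref)

events <- rbind(sim$events$sample1[, 1:4], sim$events$sample2[, 1:4])
ip    <- internal_priming_filter(events, ref$genome)
sites <- cluster_events(ip$kept, gap = 24, samples = c("sample1", "sample2"))
sites <- annotate_sites(sites, ref$transcripts, ref$known_db)
table(sites$tier)
#>  novel TianDB   UCSC
#>     59     60     60

fit <- apa_switch(build_tandem_tables(sites))
fit
#> Tandem 3' UTR switch fit: 60 genes tested, 0 excluded
#>   shortened 8 | lengthened 9 | none 43  (|r| > 0.1, FDR < 0.01)
head(coef(fit), 3)
#>       G0002       G0004       G0006
#>  0.01857768  0.04628266 -0.14201910

rec <- score_recovery(sites, ref, fit)
rec$site_sensitivity
#> [1] 1
rec$switch_confusion
#>             call
#> truth        lengthened none shortened
#>   lengthened          9    0         0
#>   null                0   42         0
#>   shortened           0    1         8
```

Every planted site is recovered (sensitivity 1), the tier split matches
the planted design (60 distal sites at annotated ends, 60 interior sites
registered in the known DB, 59 novel), and 17 of the 18 planted usage
shifts are called with the correct sign with no false positives among the
null genes. `coef()` returns the per-gene switch index: positive values
mean the gene's 3′ UTR is longer in sample two, negative shorter
(G0006's −0.14 is a called shortening).

`run_apa_pipeline()` wires the same stages end-to-end from files (FASTA +
BED12/GTF + alignment BEDs) and writes manifest-stamped result tables;
`call_degs()` and `enrich_list()` handle expression and gene-set stages.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, with the installed package, the published worked-example
quantities — the fold-enrichment values of the reported pathway gene sets
from their printed contingency counts — and writes them as JSON, one entry
per target id.
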