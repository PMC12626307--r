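# intropa

Detection, typing, quantification and differential analysis of
**intronic polyadenylation (IPA)** events from short-read RNA-seq
coverage.

IPA is a form of alternative polyadenylation in which a transcript is
cleaved and polyadenylated inside an intron, truncating the coding
region. Truncated isoforms can lose functional domains (tumor
suppressors are a recurrent casualty) or gain novel C-terminal
peptides, so calling these events — and how their usage shifts between
conditions — matters for both transcriptome annotation and disease
biology. Standard APA tools concentrate on tandem 3'-UTR events; this
package targets the intronic case.

## Method

For every candidate polyA site inside an **independent intron** (an
intronic interval overlapping no exon of any isoform of the gene), the
caller computes a **truncation ratio**

```
TR = C2 / C1
```

where `C2` is the mean read coverage of the putative truncated terminal
region and `C1` the mean coverage over the gene's merged exons. Events
are typed by their coverage geometry:

* **Type 1** — splicing of the downstream intron is inhibited and the
  intron is retained up to the cleavage site: `C2` is measured from the
  upstream exon boundary to the site, and the call requires a coverage
  drop past the site plus contiguity with the upstream exon.
* **Type 2** — a cryptic exon inside the intron becomes the new
  3'-terminal exon: its boundary is the longest interval ending at the
  site whose mean coverage reaches at least 80% of `C1`, separated from
  the upstream exon by a low-coverage gap; `C2` is measured over that
  interval.

Calls require `TR >= 0.2` and `C2 > 10`, with at most one event per
intron (highest TR). Candidate sites come from any combination of an
annotated polyA-site database (BED), 3'-end-seq peaks, and a scan for
canonical polyadenylation-signal hexamers (AATAAA/ATTAAA). Differential
usage between conditions is tested per event with a Pearson chi-squared
test on intronic-vs-exonic read counts (no replicates) or a Wilcoxon
rank-sum test on per-replicate TRs (replicates), significant when
`p < 0.05` and `|TR1 - TR2| > 0.2`. Truncated-isoform peptides are
reconstructed by splicing the annotated upstream CDS onto the retained
intron (Type 1, annotated frame) or the cryptic exon (Type 2, all three
frames) and translating to the first stop codon.

A built-in generator (`simulate_ipa_sample()` / `simulate_ipa_pair()`)
plants Type 1 and Type 2 events with known TRs in Poisson-expressed
synthetic gene models, and the evaluation harness scores calls against
the ground truth (±50 bp one-to-one matching, sensitivity, false-call
rate, rank-statistic AUC).

## Worked example

```r
library(intropa)

# a small synthetic sample: 60 genes, 15 + 15 planted events, ~50x
sim <- simulate_ipa_sample(sim_config(
  n_genes = 60, n_type1 = 15, n_type2 = 15, n_decoys = 20,
  depth = 50, genome = TRUE, seed = 5))

catalog <- build_catalog(sim$annotation, db_sites = data.frame(
  chrom = sim$sites$chrom, pos = sim$sites$pos, strand = sim$sites$strand))
events <- detect_sample(sim$annotation, catalog, sim$coverage)
print(events)
#> ipa_events: 29 event(s) (15 Type 1, 14 Type 2) in 29 gene(s)
#>     gene_id chrom strand    pos ipa_type    c1    c2     tr
#> 1  gene0003  chr1      -  22097        2 56.66 49.02 0.8652
#> 2  gene0005  chr1      +  40571        1 56.76 44.75 0.7883
#> 3  gene0007  chr1      +  55477        2 52.06 46.84 0.8998
#> 4  gene0008  chr1      -  59593        1 53.25 19.63 0.3686
#> ...

print(evaluate_calls(events, sim$truth, tol = 50))
#> eval_report: 29/30 truth matched (sensitivity 0.967), 29 called, false-call rate 0.000
```

Each `ipa_events` row is one called site: `c1`/`c2` are the exonic and
terminal-region mean depths, `tr` their ratio (the event's usage
score), and Type 2 rows carry the cryptic-exon interval. The
evaluation report says 29 of the 30 planted events were recovered
within ±50 bp (one Type 2 event fell below the detection thresholds in
this noise draw) and no spurious site was called.

File-based workflows mirror the two analysis modes:
`run_single()` (BAM/bedGraph + GTF → events TSV/BED, peptide FASTA,
nucleotide-composition profile) and `run_differential()` (two samples
or a replicate sample sheet → tested events TSV). A thin CLI wrapper
lives at `inst/cli/intropa.R`:

```sh
Rscript inst/cli/intropa.R single --coverage sample.bam --gtf genes.gtf \
    --genome genome.fa --polya-bed polya.bed --out results/
```

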