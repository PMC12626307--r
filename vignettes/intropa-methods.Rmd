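---
title: "Calling intronic polyadenylation events from RNA-seq coverage"
author: "intropa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling intronic polyadenylation events from RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intropa)
```

## The problem and the model

Intronic polyadenylation (IPA) cleaves and polyadenylates a transcript
inside an intron, producing a truncated isoform. On RNA-seq coverage
this leaves one of two signatures. In a **Type 1** event, splicing of
the downstream intron is inhibited and transcription runs from the
upstream exon into the intron until the cleavage site: coverage stays
elevated from the exon boundary to the site and drops sharply beyond
it. In a **Type 2** event, an unannotated (cryptic) exon inside the
intron becomes the new terminal exon: an isolated block of elevated
coverage ends at the cleavage site, separated from the upstream exon
by the spliced-out (low-coverage) intron.

Both signatures are quantified by the **truncation ratio**
$TR = C_2 / C_1$, where $C_1$ is the mean per-base coverage over the
gene's merged exons (all isoforms) and $C_2$ the mean coverage of the
truncated terminal region: the exon-boundary-to-site stretch for
Type 1, the cryptic-exon interval for Type 2. $TR$ estimates the usage
of the truncated isoform relative to overall gene expression; it is a
within-sample ratio, so no cross-sample normalisation is required, and
it can exceed 1 when the terminal region outruns the exon-union mean
(e.g. when most transcripts terminate early).

Candidate sites are considered only inside **independent introns** —
intronic intervals overlapping no exon of any isoform of the gene —
which removes ambiguity from alternative splicing and annotated
transcript ends. When an intron of one isoform contains another
isoform's exon, the sub-intervals outside that exon remain eligible,
each anchored at its nearest exon-union boundary; this maximises
recall while honouring the non-overlap rule. Genes are processed
independently, so an intron of gene A overlapping an exon of gene B on
the other strand is still independent *for A*. We take the strict
reading of "intronic": the interval must be intronic in *every*
isoform; the permissive alternative (intronic in at least one isoform)
would re-admit exactly the ambiguous regions the restriction is meant
to exclude.

## The candidate catalog

Three evidence sources feed the catalog, in decreasing order of
trust: annotated polyA-site databases (BED), 3'-end-seq peak summits,
and a sequence scan for canonical polyadenylation-signal (PAS)
hexamers (AATAAA and ATTAAA by default; `pas_motifs(variants = TRUE)`
adds the 1-mismatch neighborhood of AATAAA). Sites from different
sources within 50 nt of each other collapse to one site, keeping the
highest-trust source's position; 50 nt matches the ±50 bp tolerance
used throughout evaluation. The PAS scan reports a cleavage position
21 nt downstream of the hexamer start in transcript orientation — the
midpoint of the canonical 10–30 nt PAS-to-cleavage spacing — and both
the offset and the merge window are configurable. Peak calling from
3'-end read termini is single-linkage clustering with a 24 nt merge
gap and a 5-read support floor, with the summit at the modal position
(ties to the leftmost); these defaults are deliberately conservative
and exposed as arguments, since peak extraction conventions vary
between 3'-end-seq protocols.

## Detection rules and their parameters

All parameters live in one `ipa_params()` object; units are
nucleotides for lengths and fractions of a mean depth for thresholds.

* `tr_min = 0.2` and `c2_min = 10`: an event must have $TR \ge 0.2$
  and $C_2 > 10$ reads/base. These are the two hard filters; the
  second removes low-coverage artifacts that produce unstable ratios.
* `drop_window = 100`, `drop_frac = 0.5`: a Type 1 call requires mean
  coverage over the 100 nt past the site to fall below half of $C_2$.
  A genuinely cleaved transcript pool produces a sharp drop; a fully
  retained intron does not, and this check keeps retained introns out
  of the call set.
* `contig_frac = 0.5`: a Type 1 call also requires the 50 nt of intron
  adjacent to the upstream exon to hold at least half of $C_2$. The
  retained-intron stretch is by definition contiguous with the exon;
  without this check a detached cryptic-exon block close enough to the
  site would satisfy the mean-and-drop criteria and be mistyped as
  Type 1, since Type 1 is attempted first.
* `ce_frac = 0.8`: the cryptic-exon boundary is the longest interval
  ending at the site whose mean coverage reaches 80% of $C_1$.
  Numerically the boundary is found with a 50 nt rolling-mean
  threshold scan and then trimmed of trailing sub-threshold bases, so
  on a sharp step profile the reported interval is exactly the
  elevated block; a plain "longest mean-above-threshold interval"
  would absorb background bases until the mean dilutes to the
  threshold, systematically overshooting the boundary and biasing the
  Type 2 TR toward $0.8$.
* `ce_min_len = 50`, `ce_max_len = 2000`: plausible terminal-exon
  length bounds; `ce_gap = 50` and `ce_gap_frac = 0.2`: the block must
  be separated from the upstream exon by at least 50 nt below 20% of
  $C_1$, distinguishing a true internal exon from an exon extension
  (which is a Type 1 signature).

Type 1 is attempted first at each site; Type 2 only if Type 1 fails.
At most one event is emitted per independent intron — the highest TR
wins, ties go to the most upstream site in transcript orientation
(the earliest truncation). Genes with zero exonic coverage are
skipped. $C_1$ uses the exon union of all isoforms rather than a
single canonical isoform: the union is well-defined without an
expression-based isoform choice and is what the per-gene coverage
actually averages over.

Coverage itself is strand-agnostic by default (the common unstranded
library case; `stranded = TRUE` restricts BAM fetches to sense-strand
alignments). Spliced alignments contribute only aligned (CIGAR M/=/X)
bases — the N gaps of exon-junction reads must not inflate intronic
coverage. Secondary alignments are excluded and duplicates kept by
default, both flag-configurable, since duplicate marking conventions
differ across pipelines.

## Differential usage

Without replicates, each event (called in either sample) is tested
with a Pearson chi-squared statistic (no continuity correction, 1 df)
on the 2×2 table of condition × (terminal-region reads, exonic reads),
where read counts are coverage totals divided by the read length. The
contingency construction is a declared choice — coverage totals are
what the caller already computes, and dividing by read length restores
count units so the chi-squared null is on the right scale. TR is
recomputed at the same coordinates in both samples, so an event below
threshold in one condition still gets its actual (not zero) TR there.

With replicates, per-replicate TRs are compared by a two-sided
Wilcoxon rank-sum test. The default is the normal approximation with
tie correction and **without** continuity correction: an exact
two-sided test on the standard 3 + 3 design has a minimum attainable
p-value of $2/\binom{6}{3} = 0.1$ and can never reach the 0.05
threshold, while the uncorrected approximation assigns fully separated
triplicates $p \approx 0.0495$. In other words, at three replicates
the criterion effectively asks for perfect rank separation plus a mean
TR difference above 0.2. The exact null is available via
`exact = TRUE` for larger designs. In all cases significance requires
both $p < 0.05$ and $|TR_1 - TR_2| > 0.2$; raw p-values are used by
design (matching the published criterion), with an optional
Benjamini–Hochberg mode (`adjust_differential()`) for parity with
FDR-based tools.

## Peptide reconstruction

For a Type 1 event the annotated CDS of the upstream exons is spliced
together and extended with the retained-intron sequence up to the
site, then translated in the annotated reading frame across the
exon–intron junction — frame inheritance is the coherent choice for a
splicing-inhibited extension, and re-scanning would discard the known
phase. For a Type 2 event the cryptic exon's "tentative start" is the
5' boundary found by the coverage scan, and all three frames from that
start are translated and appended to the upstream CDS peptide, since
the splice-in phase of an unannotated exon is unknown. Translation
uses the standard nuclear code, stops before the first stop codon, and
renders N-containing codons as X; selenocysteine recoding is not
supported. The full truncated protein is emitted (not only the novel
tail) with `novel_tail_start` marking where it departs from the
annotated protein — downstream domain-level analyses need the full
sequence, and the index preserves the tail information.

## The synthetic benchmark

`simulate_ipa_sample()` generates multi-exon gene models (3–6 exons of
150–400 nt, introns of 0.8–3 kb) tiled along synthetic chromosomes,
with per-gene expression $\lambda \sim \mathrm{Poisson}(d)$ around the
depth parameter $d$ and per-base exon coverage
$\mathrm{Poisson}(\lambda)$. The default benchmark plants 1,000 events
— 500 Type 1 and 500 Type 2 — in genes from the top half of the
expression distribution, with $d = 50$ as the 50-million-read
equivalent (≈50× exonic coverage; $d = 5$ is the 5M equivalent). A
Type 1 event sets the intron to $\mathrm{Poisson}(tr \cdot \lambda)$
from the exon boundary to the site; a Type 2 event plants an elevated
block ending at the site; everywhere else introns carry a 2% of
$\lambda$ background, representing unspliced pre-mRNA carryover.
Type 1 TRs are uniform on $[0.3, 0.9]$; Type 2 TRs are drawn from
$[0.85, 0.95]$ because the 80%-of-$C_1$ boundary rule makes a cryptic
exon below $0.8\lambda$ undetectable by construction — a single TR
range cannot apply to both types under that rule. An AATAAA hexamer is
planted 21 nt transcript-upstream of every truth site when a genome is
synthesized, and decoy candidate sites (default: as many as there are
events) are placed in introns of non-event genes as ROC negatives.

`simulate_ipa_pair()` shares structures and expression across two
conditions, plants per-condition TRs differing by a draw from
$[0.25, 0.5]$ (direction random) for differential events and equal TRs
for non-differential ones, and Poisson-resamples each replicate. The
paired benchmark plants Type 1 coverage geometry for all events: the
differential test operates on TRs recomputed at fixed coordinates, so
the typing geometry is orthogonal to what the test measures.

Coverage-level simulation is the default — it is fast and gives exact
control over the planted TR. A read-level mode
(`write_coverage_bam()`) decomposes the depth profile into
variable-length (≤ read length) alignments whose pileup reproduces
the profile exactly, for end-to-end tests through the BAM reader.
What the generator deliberately does **not** model: sequencing error,
fragment-length and positional bias, isoform-consistent exon coverage
downstream of the event, overlapping genes, and mapping ambiguity.
Passing the benchmark therefore demonstrates correctness of the
detection logic under the stated noise model, not performance on real
libraries, where boundary precision and the false-call rate will
degrade with coverage bias and annotation error.

## Evaluation

Calls are matched to truth one-to-one within ±50 bp (greedy by
distance, ties to the leftmost truth). Sensitivity is matched truths
over truths; the **false-call rate** reported here is the fraction of
calls not matching any truth — i.e. $1 - \mathrm{precision}$, a
deliberately nonstandard use of "false positive rate" that matches
how the benchmark literature quotes it. Ranking quality is the
rank-statistic AUC, $P(s^+ > s^-) + \frac12 P(s^+ = s^-)$, with the
candidate's TR as score; sub-threshold candidates (including decoys)
receive their computed TR rather than zero, so the AUC reflects the
ranking variable and not the hard filters.

## Problem sizes and numerical choices

The shipped test-suite benchmarks use the full 1,000-event single
sample (2,000 genes) and a 4,000-gene paired design with 1,000
differential + 1,000 non-differential events and three replicates per
condition; module tests use 40–150-gene versions of the same
generator. All RNG flows from a single seed argument; a fixed seed
reproduces every output byte for byte. Mean-depth comparisons use
double precision throughout; the TR identity $tr = c_2/c_1$ is exact
to 1e-9 on all emitted events, and noiseless-mode recovery of the
planted TR is within ±0.02 (discretization of rounded expected
depths). Degenerate inputs have defined behavior: zero-coverage genes
are skipped, single-exon genes have no independent introns, empty
candidate sets yield empty (typed) results, a 2×2 table with a zero
margin returns p = 1 with a warning, and identical replicate TRs give
p = 1.

## Known limitations

Single-cell data is out of scope (coverage-based TRs need bulk-level
depth). The caller does not model 3'-UTR (tandem) APA, does not
assemble transcripts, and trusts the supplied annotation: an
unannotated exon in the reference will read as cryptic. The
chi-squared contingency construction and the peak-calling defaults are
declared conventions, not derived quantities, and should be revisited
when matched 3'-end-seq data with known peak structure is available.
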