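## The two standard workflows: single-sample event discovery and
## two-condition differential analysis, from files on disk to result
## files on disk. A thin command-line wrapper lives in inst/cli/.

open_coverage <- function(path, ...) {
  if (grepl("\\.bam$", path, ignore.case = TRUE))
    coverage_from_bam(path, ...)
  else coverage_from_bedgraph(path)
}

#' Single-sample IPA discovery workflow
#'
#' Reads annotation and coverage, builds the candidate catalog from any
#' combination of an annotated polyA-site BED, a 3'-end peak BED and a
#' PAS scan of the genome, calls events, and writes `events.tsv`,
#' `events.bed`, and -- when a genome is supplied -- `peptides.fa`,
#' `composition.tsv` and `composition.png`.
#'
#' @param coverage_path BAM (indexed) or bedGraph path.
#' @param annotation_path GTF or refFlat path.
#' @param annotation_format `"gtf"` or `"refflat"`.
#' @param genome_path optional FASTA path.
#' @param polya_bed optional annotated polyA-site BED path.
#' @param peaks_bed optional 3'-end peak BED path (rows are read
#'   3'-termini or precomputed peaks; summits are re-derived with
#'   [call_peaks()]).
#' @param out_dir output directory.
#' @param params an [ipa_params()] list.
#' @param plots render the composition plot PNG (default TRUE).
#' @return the `ipa_events` data.frame, invisibly.
#' @export
run_single <- function(coverage_path, annotation_path,
                       annotation_format = "gtf", genome_path = NULL,
                       polya_bed = NULL, peaks_bed = NULL,
                       out_dir = ".", params = ipa_params(),
                       plots = TRUE) {
  ann <- read_annotation(annotation_path, annotation_format)
  cov <- open_coverage(coverage_path)
  db <- if (!is.null(polya_bed)) read_bed(polya_bed) else NULL
  peaks <- if (!is.null(peaks_bed)) {
    b <- read_bed(peaks_bed)
    call_peaks(data.frame(chrom = b$chrom, pos = b$pos,
                          strand = b$strand))
  } else NULL
  genome <- if (!is.null(genome_path)) Rsamtools::FaFile(genome_path)
            else NULL
  catalog <- build_catalog(ann, db_sites = db, peaks = peaks,
                           genome = genome)
  message("catalog: ", nrow(catalog), " candidate site(s)")
  events <- detect_sample(ann, catalog, cov, params)
  message("events: ", sum(events$ipa_type == 1L), " Type 1, ",
          sum(events$ipa_type == 2L), " Type 2")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_events_tsv(events, file.path(out_dir, "events.tsv"))
  write_events_bed(events, file.path(out_dir, "events.bed"))
  if (!is.null(genome) && nrow(events)) {
    peps <- sample_peptides(events, ann, genome)
    write_peptides_fasta(peps, file.path(out_dir, "peptides.fa"))
    prof <- composition_profile(events, genome)
    write_profile_tsv(prof, file.path(out_dir, "composition.tsv"))
    if (plots) {
      grDevices::png(file.path(out_dir, "composition.png"), 900, 500)
      plot(prof)
      grDevices::dev.off()
    }
  }
  invisible(events)
}

#' Two-condition differential IPA workflow
#'
#' With one sample per condition the chi-squared path is used; with a
#' replicate sample sheet (TSV: `sample_id`, `condition`, `path`, two
#' conditions with >= 2 replicates each) the Wilcoxon rank-sum path is
#' used. Writes `differential.tsv`; per-significant-event coverage
#' plots (`plots/<gene>_<pos>.png`) show both conditions around the
#' site.
#'
#' @param coverage_a,coverage_b per-condition coverage paths (no
#'   replicates), or `NULL` when `sheet` is given.
#' @param sheet sample-sheet TSV path.
#' @param annotation_path,annotation_format,genome_path,polya_bed,peaks_bed,params
#'   as in [run_single()].
#' @param out_dir output directory.
#' @param fdr apply Benjamini-Hochberg adjustment
#'   ([adjust_differential()]).
#' @param plots render per-significant-event coverage plots.
#' @return the `ipa_differential` data.frame, invisibly.
#' @export
run_differential <- function(coverage_a = NULL, coverage_b = NULL,
                             sheet = NULL, annotation_path,
                             annotation_format = "gtf",
                             genome_path = NULL, polya_bed = NULL,
                             peaks_bed = NULL, out_dir = ".",
                             params = ipa_params(), fdr = FALSE,
                             plots = FALSE) {
  ann <- read_annotation(annotation_path, annotation_format)
  db <- if (!is.null(polya_bed)) read_bed(polya_bed) else NULL
  genome <- if (!is.null(genome_path)) Rsamtools::FaFile(genome_path)
            else NULL
  peaks <- if (!is.null(peaks_bed)) {
    b <- read_bed(peaks_bed)
    call_peaks(data.frame(chrom = b$chrom, pos = b$pos,
                          strand = b$strand))
  } else NULL
  catalog <- build_catalog(ann, db_sites = db, peaks = peaks,
                           genome = genome)
  if (!is.null(sheet)) {
    sh <- read.table(sheet, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    conds <- unique(sh$condition)
    if (length(conds) != 2L) stop("sample sheet must have 2 conditions")
    covs <- lapply(conds, function(cn)
      lapply(sh$path[sh$condition == cn], open_coverage))
    if (any(lengths(covs) < 2L))
      stop("each condition needs >= 2 replicates; ",
           "use coverage_a/coverage_b for the no-replicate path")
    ev1 <- detect_sample(ann, catalog, covs[[1]][[1]], params)
    ev2 <- detect_sample(ann, catalog, covs[[2]][[1]], params)
    events <- union_events(ev1, ev2)
    res <- differential_replicates(ann, events, covs[[1]], covs[[2]])
    covA <- covs[[1]][[1]]; covB <- covs[[2]][[1]]
  } else {
    if (is.null(coverage_a) || is.null(coverage_b))
      stop("either a sample sheet or both condition coverages required")
    covA <- open_coverage(coverage_a)
    covB <- open_coverage(coverage_b)
    evA <- detect_sample(ann, catalog, covA, params)
    evB <- detect_sample(ann, catalog, covB, params)
    if (nrow(evA) == 0L && nrow(evB) == 0L)
      stop("no events detected in either condition")
    res <- differential_no_reps(ann, evA, evB, covA, covB, params)
  }
  if (fdr) res <- adjust_differential(res)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_differential_tsv(res, file.path(out_dir, "differential.tsv"))
  message("differential: ", nrow(res), " event(s), ",
          sum(res$significant), " significant")
  if (plots && any(res$significant)) {
    pdir <- file.path(out_dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    sig <- res[res$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig)))
      plot_event_coverage(sig[i, ], covA, covB,
        file.path(pdir, sprintf("%s_%d.png", sig$gene_id[i], sig$pos[i])))
  }
  invisible(res)
}

# side-by-side coverage around a differential event in both conditions
plot_event_coverage <- function(ev, covA, covB, path, flank = 500L) {
  s <- max(0L, ev$pos - flank); e <- ev$pos + flank
  ta <- fetch_coverage(covA, ev$chrom, s, e)
  tb <- fetch_coverage(covB, ev$chrom, s, e)
  grDevices::png(path, 900, 400)
  on.exit(grDevices::dev.off())
  x <- s:(e - 1L)
  graphics::plot(x, ta$depths, type = "l", col = "steelblue",
                 ylim = c(0, max(ta$depths, tb$depths, 1)),
                 xlab = sprintf("%s position", ev$chrom),
                 ylab = "coverage",
                 main = sprintf("%s %s:%d (dTR %.2f, p %.2g)",
                                ev$gene_id, ev$chrom, ev$pos, ev$delta,
                                ev$pvalue))
  graphics::lines(x, tb$depths, col = "firebrick")
  graphics::abline(v = ev$pos, lty = 2)
  graphics::legend("topright", c("condition 1", "condition 2"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
}
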