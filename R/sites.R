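## Candidate IPA-site catalog: annotated polyA databases (BED),
## 3'-end-seq peaks, and polyadenylation-signal (PAS) hexamer scans,
## restricted to independent introns and deduplicated.

#' Canonical PAS hexamers
#'
#' `AATAAA` and `ATTAAA`; with `variants = TRUE` additionally the
#' 1-mismatch neighborhood of `AATAAA`.
#'
#' @param variants include single-nucleotide variants of AATAAA.
#' @return character vector of uppercase DNA 6-mers.
#' @export
pas_motifs <- function(variants = FALSE) {
  base <- c("AATAAA", "ATTAAA")
  if (!variants) return(base)
  v <- character(0)
  for (i in 1:6) for (b in c("A", "C", "G", "T")) {
    m <- "AATAAA"
    substr(m, i, i) <- b
    v <- c(v, m)
  }
  unique(c(base, v))
}

# fetch uppercase sequence [start, end) 0-based from a DNAStringSet,
# FaFile or FASTA path; errors if the region leaves the chromosome
get_genome_seq <- function(genome, chrom, start, end) {
  stopifnot(end >= start, start >= 0)
  if (is.character(genome)) genome <- Rsamtools::FaFile(genome)
  if (is(genome, "FaFile")) {
    if (!file.exists(paste0(BiocGenerics::path(genome), ".fai")))
      Rsamtools::indexFa(BiocGenerics::path(genome))
    len <- GenomeInfoDb::seqlengths(Rsamtools::seqinfo(genome))[[chrom]]
    if (end > len) stop("region outside chromosome ", chrom)
    s <- Rsamtools::scanFa(genome, GenomicRanges::GRanges(chrom,
           IRanges::IRanges(start + 1L, end)))[[1]]
    return(toupper(as.character(s)))
  }
  if (is(genome, "DNAStringSet")) {
    if (end > Biostrings::width(genome[chrom]))
      stop("region outside chromosome ", chrom)
    return(toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                   start + 1L, end))))
  }
  stop("unsupported genome source")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Scan a region for polyadenylation-signal hexamers
#'
#' Finds every occurrence of any motif on the sense strand of the gene
#' (the reverse complement of the reference for minus-strand genes) and
#' reports a putative cleavage position `offset` nt downstream of the
#' motif start in transcript orientation. Soft-masked sequence is
#' uppercased before matching.
#'
#' @param genome FASTA path, [Rsamtools::FaFile] or
#'   [Biostrings::DNAStringSet].
#' @param chrom,start,end 0-based half-open region.
#' @param strand gene strand.
#' @param motifs uppercase DNA 6-mers (default [pas_motifs()]).
#' @param offset PAS-to-cleavage spacing in nt (default 21, the midpoint
#'   of the canonical 10-30 nt range).
#' @return data.frame with `chrom`, `pos` (0-based cleavage position),
#'   `strand`, `source = "pas"`, `hexamer`; sites whose cleavage position
#'   falls outside `[start, end)` are dropped.
#' @export
scan_pas <- function(genome, chrom, start, end, strand,
                     motifs = pas_motifs(), offset = 21L) {
  stopifnot(strand %in% c("+", "-"), length(motifs) >= 1L,
            all(nchar(motifs) == 6L))
  seq <- get_genome_seq(genome, chrom, start, end)
  sense <- if (strand == "+") seq else revcomp(seq)
  hits_start <- integer(0); hits_motif <- character(0)
  subj <- Biostrings::DNAString(sense)
  for (m in unique(motifs)) {
    mp <- Biostrings::matchPattern(m, subj)
    if (length(mp)) {
      hits_start <- c(hits_start, BiocGenerics::start(mp) - 1L) # 0-based in sense
      hits_motif <- c(hits_motif, rep(m, length(mp)))
    }
  }
  if (!length(hits_start))
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), source = character(0),
                      hexamer = character(0)))
  # sense offset -> genomic position
  pos_sense <- hits_start + offset
  pos <- if (strand == "+") start + pos_sense
         else end - 1L - pos_sense
  keep <- pos >= start & pos < end
  o <- order(pos[keep])
  n_keep <- sum(keep)
  data.frame(chrom = rep(chrom, n_keep), pos = pos[keep][o],
             strand = rep(strand, n_keep),
             source = rep("pas", n_keep), hexamer = hits_motif[keep][o])
}

#' Call 3'-end peaks from read 3'-terminus positions
#'
#' Single-linkage clustering: sorted positions on the same chromosome
#' and strand are chained while consecutive positions are within
#' `merge_gap` nt; clusters supported by at least `min_reads` positions
#' become peaks with the summit at the modal position (ties broken to
#' the leftmost).
#'
#' @param positions data.frame with `chrom`, `pos` (0-based 3'-terminus),
#'   `strand`, and optional `count` (default 1 per row).
#' @param min_reads minimum supporting reads per peak (default 5).
#' @param merge_gap maximum within-cluster spacing in nt (default 24).
#' @return data.frame of peaks: `chrom`, `start`, `end`, `strand`,
#'   `summit`, `count`.
#' @export
call_peaks <- function(positions, min_reads = 5L, merge_gap = 24L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      summit = integer(0), count = integer(0))
  if (is.null(positions) || nrow(positions) == 0L) return(empty)
  if (is.null(positions$count)) positions$count <- 1L
  out <- list()
  for (key in unique(paste(positions$chrom, positions$strand))) {
    p <- positions[paste(positions$chrom, positions$strand) == key, ]
    p <- p[order(p$pos), ]
    brk <- c(0L, cumsum(diff(p$pos) > merge_gap))
    for (cl in split(p, brk)) {
      total <- sum(cl$count)
      if (total < min_reads) next
      tallies <- tapply(cl$count, cl$pos, sum)
      summit <- as.integer(names(tallies)[which.max(tallies)]) # ties: leftmost
      out[[length(out) + 1L]] <-
        data.frame(chrom = cl$chrom[1], start = min(cl$pos),
                   end = max(cl$pos) + 1L, strand = cl$strand[1],
                   summit = summit, count = total)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Read / write BED6
#'
#' `read_bed()` returns 0-based site records (`pos` = interval start);
#' `write_bed()` writes one 1-bp interval per site.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `pos`, `strand`, `name`, `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = BiocGenerics::start(gr) - 1L,
             strand = as.character(BiocGenerics::strand(gr)),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) gr$score else 0)
}

#' @rdname read_bed
#' @param sites data.frame with `chrom`, `pos`, `strand` and optional
#'   `name`, `score` columns.
#' @export
write_bed <- function(sites, path) {
  name <- if (!is.null(sites$name)) sites$name else
    sprintf("site%d", seq_len(nrow(sites)))
  score <- if (!is.null(sites$score)) sites$score else 0L
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$pos,
                     sites$pos + 1L, name, as.integer(score), sites$strand),
             path)
  invisible(path)
}

#' Build the candidate IPA-site catalog
#'
#' Unions annotated polyA database sites, 3'-end-seq peak summits and
#' PAS hexamer scan hits; keeps only sites inside an independent intron
#' of a gene on the matching strand; and merges sites within
#' `dedup_window` nt of each other in the same intron with source
#' preference db > peak > pas (the preferred site's position is kept).
#'
#' @param ann an `ipa_annotation`.
#' @param db_sites optional data.frame from [read_bed()] (annotated
#'   polyA sites).
#' @param peaks optional peak data.frame from [call_peaks()].
#' @param genome optional genome source; when given, every independent
#'   intron is scanned with [scan_pas()].
#' @param motifs,pas_offset passed to [scan_pas()].
#' @param dedup_window merge distance in nt (default 50, matching the
#'   evaluation tolerance).
#' @return data.frame of class `ipa_catalog`: `gene_id`, `chrom`,
#'   `strand`, `pos`, `source`, `hexamer`, `intron_start`, `intron_end`,
#'   `upstream_exon_end`.
#' @export
build_catalog <- function(ann, db_sites = NULL, peaks = NULL, genome = NULL,
                          motifs = pas_motifs(), pas_offset = 21L,
                          dedup_window = 50L) {
  if (is.null(db_sites) && is.null(peaks) && is.null(genome))
    stop("at least one site source (db_sites, peaks, genome) is required")
  src_rank <- c(db = 1L, peak = 2L, pas = 3L)
  pool <- list()
  if (!is.null(db_sites) && nrow(db_sites))
    pool$db <- data.frame(chrom = db_sites$chrom, pos = db_sites$pos,
                          strand = db_sites$strand, source = "db",
                          hexamer = NA_character_)
  if (!is.null(peaks) && nrow(peaks))
    pool$peak <- data.frame(chrom = peaks$chrom, pos = peaks$summit,
                            strand = peaks$strand, source = "peak",
                            hexamer = NA_character_)
  out <- list()
  for (g in ann) {
    intr <- g$introns
    if (!nrow(intr)) next
    cand <- list()
    for (nm in names(pool)) {
      p <- pool[[nm]]
      sel <- p$chrom == g$chrom & p$strand == g$strand
      if (any(sel)) cand[[nm]] <- p[sel, , drop = FALSE]
    }
    if (!is.null(genome)) {
      for (i in seq_len(nrow(intr))) {
        hits <- scan_pas(genome, g$chrom, intr$start[i], intr$end[i],
                         g$strand, motifs = motifs, offset = pas_offset)
        if (nrow(hits)) cand[[length(cand) + 1L]] <- hits
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    # assign to hosting independent intron; outside -> dropped
    idx <- findInterval(cand$pos, intr$start)
    inside <- idx >= 1L & cand$pos < intr$end[pmax(idx, 1L)]
    cand <- cand[inside, , drop = FALSE]
    idx <- idx[inside]
    if (!nrow(cand)) next
    cand$intron <- idx
    for (ii in unique(idx)) {
      ci <- cand[cand$intron == ii, , drop = FALSE]
      ci <- ci[order(src_rank[ci$source], ci$pos), , drop = FALSE]
      kept <- integer(0)
      for (j in seq_len(nrow(ci))) {
        if (!length(kept) ||
            all(abs(ci$pos[kept] - ci$pos[j]) > dedup_window))
          kept <- c(kept, j)
      }
      ci <- ci[kept, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        pos = ci$pos, source = ci$source, hexamer = ci$hexamer,
        intron_start = intr$start[ii], intron_end = intr$end[ii],
        upstream_exon_end = intr$upstream_exon_end[ii])
    }
  }
  if (!length(out))
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), pos = integer(0),
                      source = character(0), hexamer = character(0),
                      intron_start = integer(0), intron_end = integer(0),
                      upstream_exon_end = integer(0))
  else {
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$pos), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("ipa_catalog", "data.frame")
  res
}
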