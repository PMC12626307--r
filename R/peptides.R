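## Truncated-isoform peptide reconstruction: splice the annotated
## upstream CDS, append the retained-intron (Type 1) or cryptic-exon
## (Type 2) sequence, and translate to the first stop codon.

#' Translate DNA in a given frame up to the first stop codon
#'
#' Standard nuclear code; translation starts at `frame` (0..2) and stops
#' before the first stop codon or at the last complete codon. Codons
#' containing N translate to `X`.
#'
#' @param dna uppercase DNA string (ACGTN).
#' @param frame 0, 1 or 2.
#' @return amino-acid string (possibly empty), never containing `*`.
#' @export
translate_dna <- function(dna, frame = 0L) {
  stopifnot(frame %in% 0:2)
  n <- nchar(dna) - frame
  if (n < 3L) return("")
  sub <- substr(dna, frame + 1L, frame + (n %/% 3L) * 3L)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(sub), if.fuzzy.codon = "X",
    no.init.codon = TRUE)))
  sub("\\*.*$", "", aa)
}

# spliced CDS sequence of the exon portions transcript-upstream of an
# intron, in transcript orientation (minus strand reverse-complemented)
upstream_cds_seq <- function(tx, g, intron_start, intron_end, genome) {
  cds <- tx$cds
  if (is.null(cds)) return(NULL)
  ex <- tx$exons
  parts <- character(0)
  for (i in seq_len(nrow(ex))) {
    s <- max(ex$start[i], cds[1]); e <- min(ex$end[i], cds[2])
    if (g$strand == "+") e <- min(e, intron_start) else s <- max(s, intron_end)
    if (s < e) parts <- c(parts, get_genome_seq(genome, g$chrom, s, e))
  }
  if (!length(parts)) return(NULL)
  if (g$strand == "+") paste(parts, collapse = "")
  else paste(vapply(rev(parts), revcomp, ""), collapse = "")
}

# transcripts with a CDS and an exon abutting the intron's upstream
# boundary, i.e. isoforms whose reading frame runs into this intron
junction_transcripts <- function(g, intron_start, intron_end) {
  Filter(function(tx) {
    if (is.null(tx$cds)) return(FALSE)
    if (g$strand == "+") any(tx$exons$end == intron_start)
    else any(tx$exons$start == intron_end)
  }, g$transcripts)
}

#' Reconstruct peptides for a called IPA event
#'
#' Type 1: the annotated CDS of the upstream exons is concatenated with
#' the retained-intron sequence up to the IPA site and translated in the
#' annotated reading frame continuing across the exon-intron junction
#' (one record). Type 2: the spliced upstream CDS peptide is extended by
#' the cryptic-exon sequence translated in each of the three frames from
#' the cryptic-exon start (up to three records). `novel_tail_start` is
#' the 1-based index of the first amino acid not encoded purely by the
#' annotated CDS, or `NA` when a stop abuts the junction and the novel
#' tail is empty.
#'
#' @param event one-row slice of an `ipa_events` data.frame.
#' @param g the `gene_model` of the event's gene.
#' @param genome genome source (FASTA path, FaFile or DNAStringSet).
#' @return data.frame with `event_id`, `gene_id`, `chrom`, `pos`,
#'   `ipa_type`, `frame`, `aa_sequence`, `novel_tail_start`; zero rows
#'   with a warning when no CDS-bearing isoform abuts the intron.
#' @export
event_peptides <- function(event, g, genome) {
  txs <- junction_transcripts(g, event$intron_start, event$intron_end)
  if (!length(txs)) {
    warning("no CDS-bearing transcript upstream of event at ",
            event$chrom, ":", event$pos, "; skipped")
    return(empty_peptides())
  }
  tx <- txs[[1]]
  cds_up <- upstream_cds_seq(tx, g, event$intron_start, event$intron_end,
                             genome)
  if (is.null(cds_up)) {
    warning("empty upstream CDS for event at ", event$chrom, ":",
            event$pos, "; skipped")
    return(empty_peptides())
  }
  event_id <- sprintf("%s|%s:%d|type%d", event$gene_id, event$chrom,
                      event$pos, event$ipa_type)
  if (event$ipa_type == 1L) {
    tail_seq <- oriented_seq(genome, g,
                             if (g$strand == "+") event$intron_start else event$pos,
                             if (g$strand == "+") event$pos + 1L else event$intron_end)
    aa <- translate_dna(paste0(cds_up, tail_seq), 0L)
    n_up_aa <- nchar(cds_up) %/% 3L
    data.frame(event_id = event_id, gene_id = event$gene_id,
               chrom = event$chrom, pos = event$pos, ipa_type = 1L,
               frame = 0L, aa_sequence = aa,
               novel_tail_start = if (nchar(aa) > n_up_aa) n_up_aa + 1L
                                  else NA_integer_)
  } else {
    ce_seq <- oriented_seq(genome, g, event$cryptic_start,
                           event$cryptic_end)
    aa_up <- translate_dna(cds_up, 0L)
    recs <- lapply(0:2, function(f) {
      aa_tail <- translate_dna(ce_seq, f)
      data.frame(event_id = event_id, gene_id = event$gene_id,
                 chrom = event$chrom, pos = event$pos, ipa_type = 2L,
                 frame = f, aa_sequence = paste0(aa_up, aa_tail),
                 novel_tail_start = if (nchar(aa_tail) > 0)
                   nchar(aa_up) + 1L else NA_integer_)
    })
    do.call(rbind, recs)
  }
}

# genomic interval [s, e) in transcript orientation
oriented_seq <- function(genome, g, s, e) {
  seq <- get_genome_seq(genome, g$chrom, s, e)
  if (g$strand == "+") seq else revcomp(seq)
}

empty_peptides <- function()
  data.frame(event_id = character(0), gene_id = character(0),
             chrom = character(0), pos = integer(0), ipa_type = integer(0),
             frame = integer(0), aa_sequence = character(0),
             novel_tail_start = integer(0))

#' Peptides for all events of a sample
#'
#' @param events an `ipa_events` data.frame.
#' @param ann an `ipa_annotation`.
#' @param genome genome source.
#' @return row-bound [event_peptides()] records (empty sequences are
#'   dropped).
#' @export
sample_peptides <- function(events, ann, genome) {
  recs <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    g <- ann[[ev$gene_id]]
    if (is.null(g)) return(empty_peptides())
    event_peptides(ev, g, genome)
  })
  out <- do.call(rbind, c(recs, list(empty_peptides())))
  out[nchar(out$aa_sequence) > 0, , drop = FALSE]
}

#' Write / read peptide FASTA
#'
#' Headers: `>gene_id|chrom:pos|type{1,2}|frame{0-2}`.
#'
#' @param peptides data.frame from [sample_peptides()].
#' @param path file path.
#' @export
write_peptides_fasta <- function(peptides, path) {
  aas <- Biostrings::AAStringSet(peptides$aa_sequence)
  names(aas) <- sprintf("%s|frame%d", peptides$event_id, peptides$frame)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' @rdname write_peptides_fasta
#' @export
read_peptides_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  data.frame(name = names(aas), aa_sequence = as.character(aas))
}
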