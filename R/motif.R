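## Positional nucleotide composition around called IPA sites.

#' Nucleotide composition profile around IPA sites
#'
#' Extracts `2*flank + 1` nt windows centered on each site in transcript
#' orientation (minus-strand windows reverse-complemented, so negative
#' offsets are transcript-upstream of the site) and tabulates per-offset
#' base frequencies. N bases are excluded from the per-offset
#' denominator. Sites whose window leaves the contig are dropped with a
#' warning; if all sites are dropped, an error is raised.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param genome genome source (FASTA path, FaFile or DNAStringSet).
#' @param flank half-window in nt (default 50).
#' @return object of class `composition_profile`: list with `offsets`
#'   (-flank..flank), `freqs` (4 x (2*flank+1) matrix, rows A,C,G,T,
#'   columns summing to 1), `n_sites`.
#' @export
composition_profile <- function(sites, genome, flank = 50L) {
  stopifnot(nrow(sites) >= 1L, flank >= 1L)
  if (is.character(genome)) genome <- Rsamtools::FaFile(genome)
  lens <- genome_lengths(genome)
  w <- 2L * flank + 1L
  seqs <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites$pos[i] - flank
    e <- sites$pos[i] + flank + 1L
    if (s < 0 || e > lens[[sites$chrom[i]]]) { dropped <- dropped + 1L; next }
    seq <- get_genome_seq(genome, sites$chrom[i], s, e)
    if (sites$strand[i] == "-") seq <- revcomp(seq)
    seqs <- c(seqs, seq)
  }
  if (dropped > 0L)
    warning(dropped, " site(s) within ", flank, " nt of a contig edge dropped")
  if (!length(seqs)) stop("all sites fall near contig edges")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                    baseOnly = TRUE)
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  freqs <- sweep(counts, 2L, colSums(counts), "/")
  structure(list(offsets = seq(-flank, flank), freqs = freqs,
                 n_sites = length(seqs)),
            class = "composition_profile")
}

genome_lengths <- function(genome) {
  if (is(genome, "FaFile")) {
    if (!file.exists(paste0(BiocGenerics::path(genome), ".fai")))
      Rsamtools::indexFa(BiocGenerics::path(genome))
    as.list(GenomeInfoDb::seqlengths(Rsamtools::seqinfo(genome)))
  } else if (is(genome, "DNAStringSet")) {
    as.list(setNames(Biostrings::width(genome), names(genome)))
  } else stop("unsupported genome source")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: %d site(s), offsets %d..%d\n",
              x$n_sites, min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Line plot of a composition profile
#'
#' Plots the four base frequencies against offset from the IPA site.
#'
#' @param x a `composition_profile`.
#' @param ... passed to [graphics::matplot()].
#' @method plot composition_profile
#' @export
plot.composition_profile <- function(x, ...) {
  graphics::matplot(x$offsets, t(x$freqs), type = "l", lty = 1,
                    col = c("forestgreen", "blue", "orange", "red"),
                    xlab = "offset from IPA site (nt)",
                    ylab = "base frequency", ...)
  graphics::legend("topright", legend = rownames(x$freqs), lty = 1,
                   col = c("forestgreen", "blue", "orange", "red"),
                   bty = "n")
  invisible(x)
}

#' Write a composition profile as TSV (offset x A,C,G,T frequencies)
#'
#' @param profile a `composition_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(offset = profile$offsets, t(profile$freqs))
  colnames(df) <- c("offset", "A", "C", "G", "T")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
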