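## Per-base read coverage over genomic windows, backed by a BAM file, a
## bedGraph file, or an in-memory run-length encoded depth list (the
## representation the simulator produces).

#' Open a coverage source
#'
#' @description
#' `coverage_from_bedgraph()` reads a 4-column bedGraph (0-based
#' half-open) fully into run-length encoded per-chromosome depth
#' vectors. `coverage_from_bam()` wraps a coordinate-sorted, indexed BAM
#' and extracts coverage lazily per window; aligned bases of primary
#' alignments are counted (CIGAR `N` gaps of spliced reads contribute
#' nothing), secondary alignments are excluded, duplicates kept, and
#' reads below `mapq_min` dropped. `coverage_from_rle()` wraps an
#' existing [IRanges::RleList] of depths.
#'
#' @param path file path.
#' @param mapq_min minimum mapping quality (default 0).
#' @param keep_duplicates count flagged duplicates (default TRUE).
#' @param stranded restrict to alignments on `strand` when fetching
#'   (default FALSE: strand-agnostic, the unstranded RNA-seq default).
#' @return an object of class `ipa_coverage`.
#' @name ipa_coverage
NULL

#' @rdname ipa_coverage
#' @export
coverage_from_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  coverage_from_rle(cov)
}

#' @rdname ipa_coverage
#' @param rle a named [IRanges::RleList] of per-chromosome depths,
#'   position 1 of each Rle being genomic coordinate 0.
#' @export
coverage_from_rle <- function(rle) {
  structure(list(type = "rle", rle = rle), class = "ipa_coverage")
}

#' @rdname ipa_coverage
#' @export
coverage_from_bam <- function(path, mapq_min = 0L, keep_duplicates = TRUE,
                              stranded = FALSE) {
  if (!file.exists(path)) stop("BAM not found: ", path)
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM is not indexed: ", path,
         " -- index it first (e.g. `samtools index` or Rsamtools::indexBam)")
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  structure(list(type = "bam", path = path, targets = hdr,
                 mapq_min = mapq_min, keep_duplicates = keep_duplicates,
                 stranded = stranded),
            class = "ipa_coverage")
}

#' @export
print.ipa_coverage <- function(x, ...) {
  if (x$type == "bam")
    cat(sprintf("ipa_coverage (BAM %s, %d contigs)\n", x$path,
                length(x$targets)))
  else
    cat(sprintf("ipa_coverage (in-memory, %d contigs)\n", length(x$rle)))
  invisible(x)
}

#' Fetch per-base coverage over a window
#'
#' @param src an `ipa_coverage` source.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @param strand strand used only when the source was opened with
#'   `stranded = TRUE`.
#' @return a `coverage_track`: list with `chrom`, `start` and integer
#'   `depths` of length `end - start`. Bases absent from the source are 0.
#' @export
fetch_coverage <- function(src, chrom, start, end, strand = "*") {
  stopifnot(inherits(src, "ipa_coverage"), start >= 0, end > start)
  n <- end - start
  depths <- integer(n)
  if (src$type == "rle") {
    r <- src$rle[[chrom]]
    if (!is.null(r) && start < length(r)) {
      hi <- min(end, length(r))
      depths[seq_len(hi - start)] <-
        as.integer(S4Vectors::window(r, start + 1L, hi))
    }
  } else {
    tlen <- src$targets[[chrom]]
    if (is.null(tlen)) stop("contig not in BAM header: ", chrom)
    qend <- end
    if (end > tlen) {
      warning("window beyond contig ", chrom, " (", tlen, "); clipped")
      qend <- tlen
    }
    if (start < qend) {
      which <- GenomicRanges::GRanges(chrom,
                 IRanges::IRanges(start + 1L, qend))
      flag <- Rsamtools::scanBamFlag(
        isSecondaryAlignment = FALSE, isUnmappedQuery = FALSE,
        isDuplicate = if (src$keep_duplicates) NA else FALSE)
      param <- Rsamtools::ScanBamParam(which = which, flag = flag,
                                       mapqFilter = src$mapq_min)
      gal <- GenomicAlignments::readGAlignments(src$path, param = param)
      if (src$stranded && strand %in% c("+", "-"))
        gal <- gal[BiocGenerics::strand(gal) == strand]
      cov <- GenomicRanges::coverage(gal)[[chrom]]
      if (!is.null(cov) && start < length(cov)) {
        hi <- min(qend, length(cov))
        depths[seq_len(hi - start)] <-
          as.integer(S4Vectors::window(cov, start + 1L, hi))
      }
    }
  }
  structure(list(chrom = chrom, start = start, depths = depths),
            class = "coverage_track")
}

#' Mean per-base depth of a coverage track
#'
#' @param track a `coverage_track` from [fetch_coverage()].
#' @param sub optional 0-based half-open `c(start, end)` sub-interval in
#'   genomic coordinates; must lie within the track.
#' @return arithmetic mean depth (float).
#' @export
mean_depth <- function(track, sub = NULL) {
  d <- track$depths
  if (!is.null(sub)) {
    s <- sub[1] - track$start; e <- sub[2] - track$start
    if (s < 0 || e > length(d)) stop("sub-interval outside track")
    if (e <= s) stop("zero-length interval has no mean depth")
    d <- d[(s + 1L):e]
  }
  if (!length(d)) stop("zero-length interval has no mean depth")
  mean(d)
}

# slice a track to a genomic sub-interval, returning the raw depths
track_slice <- function(track, start, end) {
  s <- start - track$start; e <- end - track$start
  stopifnot(s >= 0, e <= length(track$depths), e >= s)
  if (e == s) return(integer(0))
  track$depths[(s + 1L):e]
}

#' Write an in-memory coverage source as bedGraph
#'
#' @param src an `ipa_coverage` of type `rle`.
#' @param path output path.
#' @export
write_bedgraph <- function(src, path) {
  stopifnot(inherits(src, "ipa_coverage"), src$type == "rle")
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(src$rle)) {
    r <- src$rle[[chrom]]
    v <- S4Vectors::runValue(r); l <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(l)); s <- e - l
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", chrom, as.integer(s[keep]),
                         as.integer(e[keep]), as.integer(v[keep])), con)
  }
  invisible(path)
}
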