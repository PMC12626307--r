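## Gene annotation: parse GTF / refFlat, build per-gene exon structures,
## merge exon unions across isoforms and derive independent introns
## (intronic intervals overlapping no exon of any isoform of the gene).

#' Merge possibly overlapping intervals into a disjoint sorted union
#'
#' @param start,end integer vectors of 0-based half-open intervals.
#' @return a data.frame with disjoint, sorted `start`, `end` columns.
#' @keywords internal
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(start < end))
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {          # overlapping or bookended: merge
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Build a gene model from exon (and optional CDS) records
#'
#' Constructs the per-gene structure used throughout the package: all
#' isoform exon lists, the merged exon union, and the independent introns
#' (see [independent_introns()]).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts named list; each element a list with `exons`
#'   (data.frame `start`,`end`, 0-based half-open, sorted) and optional
#'   `cds` (length-2 vector `c(start, end)`).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1L)
  for (tx in transcripts) {
    ex <- tx$exons
    stopifnot(is.data.frame(ex), nrow(ex) >= 1L, all(ex$start < ex$end))
    if (is.unsorted(ex$start)) stop("transcript exons must be sorted")
  }
  all_ex <- do.call(rbind, lapply(transcripts, function(tx)
    tx$exons[, c("start", "end")]))
  g <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    transcripts = transcripts,
    exon_union = merge_intervals(all_ex$start, all_ex$end)
  ), class = "gene_model")
  g$introns <- independent_introns(g)
  g
}

#' Independent introns of a gene
#'
#' An independent intron is an intronic interval that overlaps no exon of
#' any isoform of the gene, i.e. a gap between consecutive intervals of
#' the merged exon union. The `upstream_exon_end` field is the boundary
#' of the flanking exon on the transcript-5' side (the gap start on the
#' plus strand, the gap end on the minus strand).
#'
#' @param g a `gene_model`.
#' @return data.frame with columns `start`, `end`, `upstream_exon_end`
#'   (0-based half-open), disjoint and sorted; zero rows for single-exon
#'   genes.
#' @export
independent_introns <- function(g) {
  eu <- g$exon_union
  n <- nrow(eu)
  if (n < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      upstream_exon_end = integer(0)))
  s <- eu$end[-n]
  e <- eu$start[-1]
  keep <- s < e
  data.frame(start = s[keep], end = e[keep],
             upstream_exon_end = if (g$strand == "+") s[keep] else e[keep])
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s:%s) %d transcript(s), %d exon-union interval(s), %d independent intron(s)\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts),
              nrow(x$exon_union), nrow(x$introns)))
  invisible(x)
}

#' Read gene annotation into gene models
#'
#' Parses a GTF (1-based inclusive; requires `gene_id` and
#' `transcript_id` attributes on exon records) or a UCSC refFlat
#' (11-column, already 0-based half-open) file and returns one
#' [gene_model()] per gene. Genes whose isoforms span multiple
#' chromosomes or strands are rejected with a warning, and transcripts
#' with zero exons are skipped with a warning.
#'
#' @param path annotation file path.
#' @param format `"gtf"` or `"refflat"`.
#' @return a named list of `gene_model` objects (class
#'   `ipa_annotation`).
#' @export
read_annotation <- function(path, format = c("gtf", "refflat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  recs <- if (format == "gtf") parse_gtf(path) else parse_refflat(path)
  build_annotation(recs$exons, recs$cds)
}

# exons: data.frame(gene_id, transcript_id, chrom, strand, start, end)
# cds:   data.frame(transcript_id, start, end) or NULL
build_annotation <- function(exons, cds = NULL) {
  genes <- list()
  cds_by_tx <- NULL
  if (!is.null(cds) && nrow(cds)) {
    cds_by_tx <- lapply(split(cds, cds$transcript_id), function(d)
      c(min(d$start), max(d$end)))
  }
  for (gid in unique(exons$gene_id)) {
    ge <- exons[exons$gene_id == gid, , drop = FALSE]
    if (length(unique(ge$chrom)) > 1L || length(unique(ge$strand)) > 1L) {
      warning("gene ", gid,
              " has isoforms on multiple chromosomes/strands; skipped")
      next
    }
    txs <- list()
    for (tid in unique(ge$transcript_id)) {
      te <- ge[ge$transcript_id == tid, , drop = FALSE]
      if (nrow(te) == 0L) { warning("transcript ", tid, " has no exons; skipped"); next }
      te <- te[order(te$start), ]
      txs[[tid]] <- list(id = tid,
                         exons = data.frame(start = te$start, end = te$end),
                         cds = cds_by_tx[[tid]])
    }
    if (!length(txs)) next
    genes[[gid]] <- gene_model(gid, ge$chrom[1], ge$strand[1], txs)
  }
  structure(genes, class = "ipa_annotation")
}

#' @export
print.ipa_annotation <- function(x, ...) {
  cat(sprintf("ipa_annotation: %d gene(s), %d independent intron(s)\n",
              length(x), sum(vapply(x, function(g) nrow(g$introns), 0L))))
  invisible(x)
}

parse_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", which(nf != 9L)[1], ": expected 9 fields, got ",
         nf[nf != 9L][1])
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop("malformed GTF line ", bad[1], ": non-numeric coordinates")
  type <- m[, 3]
  keep <- type %in% c("exon", "CDS")
  attr_field <- m[keep, 9]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attr_field)
  tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attr_field)
  if (any(gid == attr_field) || any(tid == attr_field))
    stop("GTF records lack gene_id/transcript_id attributes")
  df <- data.frame(gene_id = gid, transcript_id = tid,
                   chrom = m[keep, 1], strand = m[keep, 7],
                   start = start1[keep] - 1L, end = end1[keep],  # -> 0-based half-open
                   type = type[keep])
  list(exons = df[df$type == "exon", 1:6],
       cds = df[df$type == "CDS", c("transcript_id", "start", "end")])
}

parse_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 11L))
    stop("malformed refFlat line ", which(nf != 11L)[1],
         ": expected 11 fields")
  ex_list <- list()
  cds_list <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    n_ex <- as.integer(f[9])
    if (is.na(n_ex) || n_ex == 0L) {
      warning("transcript ", f[2], " has no exons; skipped"); next
    }
    es <- as.integer(strsplit(f[10], ",")[[1]])
    ee <- as.integer(strsplit(f[11], ",")[[1]])
    if (length(es) != n_ex || length(ee) != n_ex || any(is.na(c(es, ee))))
      stop("malformed refFlat line ", i, ": exon lists do not match exonCount")
    ex_list[[i]] <- data.frame(gene_id = f[1], transcript_id = f[2],
                               chrom = f[3], strand = f[4],
                               start = es, end = ee)
    cs <- as.integer(f[7]); ce <- as.integer(f[8])
    if (!is.na(cs) && !is.na(ce) && cs < ce)
      cds_list[[i]] <- data.frame(transcript_id = f[2], start = cs, end = ce)
  }
  list(exons = do.call(rbind, ex_list), cds = do.call(rbind, cds_list))
}

#' Write gene models as GTF
#'
#' Emits exon and CDS records (1-based inclusive coordinates) with
#' `gene_id`/`transcript_id` attributes; round-trips through
#' [read_annotation()].
#'
#' @param ann an `ipa_annotation`.
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  out <- character(0)
  for (g in ann) {
    for (tx in g$transcripts) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, tx$id)
      out <- c(out, sprintf("%s\tintropa\texon\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, tx$exons$start + 1L, tx$exons$end,
                            g$strand, attrs))
      if (!is.null(tx$cds)) {
        # clip CDS bounds to exon intervals
        cs <- pmax(tx$exons$start, tx$cds[1])
        ce <- pmin(tx$exons$end, tx$cds[2])
        keep <- cs < ce
        if (any(keep))
          out <- c(out, sprintf("%s\tintropa\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, cs[keep] + 1L, ce[keep],
                                g$strand, attrs))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
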