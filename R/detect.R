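## Per-sample IPA event calling: truncation ratio TR = C2/C1, Type 1
## (exon-intron hybrid terminal exon) vs Type 2 (cryptic terminal exon),
## coverage-drop and cryptic-exon boundary rules, and event filters.

#' Detection parameters
#'
#' @param tr_min minimum truncation ratio (events with TR < 0.2 are
#'   filtered out).
#' @param c2_min C2 must strictly exceed this depth (default 10).
#' @param drop_window nt downstream of a Type 1 site over which coverage
#'   must drop (default 100).
#' @param drop_frac the downstream mean must be below this fraction of
#'   C2 (default 0.5).
#' @param contig_frac Type 1 events must keep mean coverage over the
#'   first `ce_gap` nt of the intron (adjacent to the upstream exon) at
#'   or above this fraction of C2 (default 0.5) -- the retained-intron
#'   stretch is contiguous with the exon, which is what distinguishes a
#'   Type 1 profile from a detached cryptic-exon block.
#' @param ce_frac cryptic-exon mean coverage threshold as a fraction of
#'   C1 (default 0.8).
#' @param ce_min_len,ce_max_len cryptic exon length bounds in nt
#'   (defaults 50, 2000).
#' @param ce_gap minimum low-coverage separation between a cryptic exon
#'   and the upstream exon (default 50 nt).
#' @param ce_gap_frac "low coverage" threshold for that gap as a
#'   fraction of C1 (default 0.2).
#' @param read_len nominal read length used to convert coverage totals
#'   into read counts for the chi-squared contingency table (default 100).
#' @return a list of class `ipa_params`.
#' @export
ipa_params <- function(tr_min = 0.2, c2_min = 10, drop_window = 100L,
                       drop_frac = 0.5, contig_frac = 0.5, ce_frac = 0.8,
                       ce_min_len = 50L, ce_max_len = 2000L, ce_gap = 50L,
                       ce_gap_frac = 0.2, read_len = 100L) {
  stopifnot(tr_min > 0, c2_min > 0, drop_window > 0, ce_min_len >= 1)
  structure(list(tr_min = tr_min, c2_min = c2_min,
                 drop_window = as.integer(drop_window),
                 drop_frac = drop_frac, contig_frac = contig_frac,
                 ce_frac = ce_frac, ce_min_len = as.integer(ce_min_len),
                 ce_max_len = as.integer(ce_max_len),
                 ce_gap = as.integer(ce_gap), ce_gap_frac = ce_gap_frac,
                 read_len = as.integer(read_len)),
            class = "ipa_params")
}

#' Mean exonic coverage of a gene (C1)
#'
#' Mean per-base depth over the gene's merged exon union (all isoforms).
#'
#' @param g a `gene_model`.
#' @param cov an `ipa_coverage` source or a `coverage_track` spanning
#'   the gene.
#' @return mean depth (float).
#' @export
compute_c1 <- function(g, cov) {
  track <- gene_track(g, cov)
  eu <- g$exon_union
  tot <- 0; len <- 0
  for (i in seq_len(nrow(eu))) {
    tot <- tot + sum(track_slice(track, eu$start[i], eu$end[i]))
    len <- len + (eu$end[i] - eu$start[i])
  }
  tot / len
}

# fetch one coverage track spanning all exons and introns of a gene
gene_track <- function(g, cov) {
  if (inherits(cov, "coverage_track")) return(cov)
  span <- gene_span(g)
  fetch_coverage(cov, g$chrom, span[1], span[2], strand = g$strand)
}

gene_span <- function(g)
  c(min(g$exon_union$start), max(g$exon_union$end))

# mean over [s, e), 0 for empty interval
.mean0 <- function(track, s, e) {
  if (e <= s) return(0)
  mean(track_slice(track, s, e))
}

#' Detect a Type 1 event at a candidate site
#'
#' C2 is the mean depth of the intron stretch from the upstream exon
#' boundary to the site (transcript orientation). The event is emitted
#' when the coverage drops downstream of the site (mean over
#' `drop_window` nt < `drop_frac * C2`), the stretch is contiguous with
#' the upstream exon (see [ipa_params()] `contig_frac`), and the filters
#' TR >= `tr_min` and C2 > `c2_min` hold.
#'
#' @param site one-row slice of an `ipa_catalog` (or list with `pos`,
#'   `strand`, `intron_start`, `intron_end`, `upstream_exon_end`,
#'   `gene_id`, `chrom`, `source`).
#' @param c1 mean exonic coverage from [compute_c1()].
#' @param cov coverage source or gene-spanning `coverage_track`.
#' @param params an [ipa_params()] list.
#' @return a one-row `ipa_events` data.frame, or `NULL`.
#' @export
detect_type1 <- function(site, c1, cov, params = ipa_params()) {
  track <- site_track(site, cov)
  pos <- site$pos
  if (site$strand == "+") {
    c2 <- .mean0(track, site$intron_start, pos + 1L)
    drop <- .mean0(track, pos + 1L,
                   min(pos + 1L + params$drop_window, site$intron_end))
    adj <- .mean0(track, site$intron_start,
                  min(site$intron_start + params$ce_gap, pos + 1L))
  } else {
    c2 <- .mean0(track, pos, site$intron_end)
    drop <- .mean0(track, max(site$intron_start, pos - params$drop_window),
                   pos)
    adj <- .mean0(track, max(pos, site$intron_end - params$ce_gap),
                  site$intron_end)
  }
  if (c1 <= 0) return(NULL)
  tr <- c2 / c1
  if (tr < params$tr_min || c2 <= params$c2_min) return(NULL)
  if (drop >= params$drop_frac * c2) return(NULL)
  if (adj < params$contig_frac * c2) return(NULL)
  event_row(site, 1L, c1, c2, tr, NA_integer_, NA_integer_)
}

#' Locate a cryptic-exon interval ending at a candidate site
#'
#' Scans upstream (transcript orientation) from the site for the longest
#' contiguous interval ending at the site whose mean depth reaches at
#' least `ce_frac` (80%) of C1, with length within
#' `[ce_min_len, ce_max_len]`; the interval must additionally be
#' separated from the upstream exon by at least `ce_gap` nt of low
#' coverage (< `ce_gap_frac * C1`), so an exon-contiguous block (a
#' Type 1 signature) is not reported.
#'
#' @inheritParams detect_type1
#' @return `c(start, end)` 0-based half-open, or `NULL`.
#' @export
find_cryptic_exon <- function(site, c1, cov, params = ipa_params()) {
  if (c1 <= 0) return(NULL)
  track <- site_track(site, cov)
  pos <- site$pos
  if (site$strand == "+") {
    d <- track_slice(track, site$intron_start, pos + 1L)
    d <- rev(d)                      # index 1 = base at the site
  } else {
    d <- track_slice(track, pos, site$intron_end)
  }
  n <- length(d)
  w <- params$ce_min_len
  if (n < w) return(NULL)
  thr <- params$ce_frac * c1
  cs <- cumsum(as.numeric(d))
  # rolling means of w-nt windows, window j covering d[j .. j+w-1]
  roll <- (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
  if (roll[1] < thr) return(NULL)
  run <- which(roll < thr)
  L <- min(if (length(run)) (run[1] - 1L) + w - 1L else n,
           params$ce_max_len)
  # trim trailing sub-threshold bases so a sharp step profile yields
  # exactly the elevated block (the window run overshoots by < w nt)
  while (L > w && d[L] < thr) L <- L - 1L
  if (L < w || cs[L] / L < thr) return(NULL)
  # low-coverage separation from the upstream exon
  gap_avail <- n - L
  if (gap_avail < params$ce_gap) return(NULL)
  gap_mean <- (cs[L + params$ce_gap] - cs[L]) / params$ce_gap
  if (gap_mean >= params$ce_gap_frac * c1) return(NULL)
  if (site$strand == "+") c(pos + 1L - L, pos + 1L) else c(pos, pos + L)
}

#' Detect a Type 2 (cryptic terminal exon) event at a candidate site
#'
#' Attempted only when [detect_type1()] returned `NULL` for the site.
#' C2 is the mean depth over the cryptic-exon interval located by
#' [find_cryptic_exon()]; the same TR >= `tr_min` and C2 > `c2_min`
#' filters apply.
#'
#' @inheritParams detect_type1
#' @return a one-row `ipa_events` data.frame with cryptic-exon bounds,
#'   or `NULL`.
#' @export
detect_type2 <- function(site, c1, cov, params = ipa_params()) {
  if (c1 <= 0) return(NULL)
  ce <- find_cryptic_exon(site, c1, cov, params)
  if (is.null(ce)) return(NULL)
  track <- site_track(site, cov)
  c2 <- .mean0(track, ce[1], ce[2])
  tr <- c2 / c1
  if (tr < params$tr_min || c2 <= params$c2_min) return(NULL)
  event_row(site, 2L, c1, c2, tr, ce[1], ce[2])
}

site_track <- function(site, cov) {
  if (inherits(cov, "coverage_track")) return(cov)
  fetch_coverage(cov, site$chrom, site$intron_start, site$intron_end,
                 strand = site$strand)
}

event_row <- function(site, type, c1, c2, tr, ce_s, ce_e) {
  data.frame(gene_id = site$gene_id, chrom = site$chrom,
             strand = site$strand, pos = site$pos, ipa_type = type,
             c1 = c1, c2 = c2, tr = tr,
             cryptic_start = ce_s, cryptic_end = ce_e,
             source = if (!is.null(site$source)) site$source else NA,
             intron_start = site$intron_start,
             intron_end = site$intron_end,
             upstream_exon_end = site$upstream_exon_end)
}

#' Call IPA events in one sample
#'
#' For every candidate site of every gene, a Type 1 event is attempted
#' first; a Type 2 event is attempted only when no Type 1 event is found
#' at the site. At most one event is emitted per independent intron (the
#' highest TR wins; ties go to the most upstream site in transcript
#' orientation). Genes with zero exonic coverage are skipped.
#'
#' @param ann an `ipa_annotation`.
#' @param catalog an `ipa_catalog` from [build_catalog()].
#' @param cov an `ipa_coverage` source.
#' @param params an [ipa_params()] list.
#' @return data.frame of class `ipa_events`, sorted by genomic position:
#'   `gene_id`, `chrom`, `strand`, `pos`, `ipa_type`, `c1`, `c2`, `tr`,
#'   `cryptic_start`, `cryptic_end`, `source`.
#' @export
detect_sample <- function(ann, catalog, cov, params = ipa_params()) {
  out <- list()
  cat_by_gene <- split(seq_len(nrow(catalog)), catalog$gene_id)
  for (gid in names(cat_by_gene)) {
    g <- ann[[gid]]
    if (is.null(g)) next
    track <- gene_track(g, cov)
    c1 <- compute_c1(g, track)
    if (c1 <= 0) next
    sites <- catalog[cat_by_gene[[gid]], , drop = FALSE]
    for (is_ in unique(sites$intron_start)) {
      si <- sites[sites$intron_start == is_, , drop = FALSE]
      best <- NULL
      for (j in seq_len(nrow(si))) {
        site <- si[j, ]
        ev <- detect_type1(site, c1, track, params)
        if (is.null(ev)) ev <- detect_type2(site, c1, track, params)
        if (is.null(ev)) next
        if (is.null(best) || ev$tr > best$tr ||
            (ev$tr == best$tr && upstream_of(ev$pos, best$pos, g$strand)))
          best <- ev
      }
      if (!is.null(best)) out[[length(out) + 1L]] <- best
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_events()
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ipa_events", "data.frame")
  res
}

upstream_of <- function(a, b, strand) if (strand == "+") a < b else a > b

empty_events <- function()
  data.frame(gene_id = character(0), chrom = character(0),
             strand = character(0), pos = integer(0), ipa_type = integer(0),
             c1 = numeric(0), c2 = numeric(0), tr = numeric(0),
             cryptic_start = integer(0), cryptic_end = integer(0),
             source = character(0), intron_start = integer(0),
             intron_end = integer(0), upstream_exon_end = integer(0))

#' @export
print.ipa_events <- function(x, ...) {
  cat(sprintf("ipa_events: %d event(s) (%d Type 1, %d Type 2) in %d gene(s)\n",
              nrow(x), sum(x$ipa_type == 1L), sum(x$ipa_type == 2L),
              length(unique(x$gene_id))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x)[,
    c("gene_id", "chrom", "strand", "pos", "ipa_type", "c1", "c2", "tr")],
    10L), digits = 4)
  invisible(x)
}

#' Write called events as TSV / BED6
#'
#' The BED score is `round(1000 * min(TR, 1))`.
#'
#' @param events an `ipa_events` data.frame.
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("gene_id", "chrom", "strand", "pos", "ipa_type", "c1", "c2",
            "tr", "cryptic_start", "cryptic_end", "source")
  write.table(as.data.frame(events)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
write_events_bed <- function(events, path) {
  df <- data.frame(chrom = events$chrom, pos = events$pos,
                   strand = events$strand,
                   name = sprintf("%s|type%d", events$gene_id,
                                  events$ipa_type),
                   score = round(1000 * pmin(events$tr, 1)))
  write_bed(df, path)
}
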