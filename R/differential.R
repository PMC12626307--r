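## Differential IPA usage between two conditions: chi-squared on region
## read counts without replicates, Wilcoxon rank-sum on per-replicate
## truncation ratios with replicates. Significance always requires both
## p < 0.05 and |TR1 - TR2| > 0.2.

#' Pearson chi-squared test on a 2x2 table
#'
#' Plain Pearson statistic \eqn{\sum (O-E)^2/E} without continuity
#' correction, compared against the chi-squared distribution with one
#' degree of freedom. A table with a zero row or column margin is
#' undefined; it returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `statistic` and `pvalue`.
#' @export
chi_squared_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    warning("zero marginal in 2x2 table; test undefined, returning p = 1")
    return(list(statistic = NA_real_, pvalue = 1))
  }
  e <- outer(rs, cs) / n
  stat <- sum((table - e)^2 / e)
  list(statistic = stat, pvalue = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test on per-replicate truncation ratios
#'
#' Two-sided rank-sum test comparing per-replicate TRs between
#' conditions. The default is the normal approximation with tie
#' correction and without continuity correction; `exact = TRUE` uses the
#' exact null distribution (ties fall back to the approximation). Note
#' that an exact two-sided test on 3 vs 3 replicates can never reach
#' p < 0.05 (its minimum is 2/20 = 0.1), so the approximation is the
#' default for the standard triplicate design. Identical values across
#' both groups give p = 1.
#'
#' @param trs1,trs2 numeric vectors of per-replicate TRs (>= 2 each).
#' @param exact use the exact null distribution.
#' @param delta_min significance additionally requires
#'   `|mean(trs1) - mean(trs2)| > delta_min` (default 0.2).
#' @param p_max significance threshold on the p-value (default 0.05).
#' @return list with `pvalue`, `tr1`, `tr2`, `delta`, `significant`.
#' @export
differential_with_reps <- function(trs1, trs2, exact = FALSE,
                                   delta_min = 0.2, p_max = 0.05) {
  stopifnot(length(trs1) >= 2L, length(trs2) >= 2L)
  if (all(c(trs1, trs2) == c(trs1, trs2)[1])) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(trs1, trs2, exact = exact, correct = FALSE)$p.value)
  }
  tr1 <- mean(trs1); tr2 <- mean(trs2)
  delta <- abs(tr1 - tr2)
  list(pvalue = p, tr1 = tr1, tr2 = tr2, delta = delta,
       significant = (p < p_max) && (delta > delta_min))
}

# recompute TR of each event at fixed coordinates in one sample:
# Type 1 -> upstream intron stretch, Type 2 -> cryptic-exon interval.
# Also returns the coverage totals used for count-based testing.
quantify_events <- function(ann, events, cov) {
  n <- nrow(events)
  tr <- c1v <- c2v <- intr_total <- exon_total <- numeric(n)
  for (gid in unique(events$gene_id)) {
    g <- ann[[gid]]
    idx <- which(events$gene_id == gid)
    track <- gene_track(g, cov)
    c1 <- compute_c1(g, track)
    eu <- g$exon_union
    etot <- sum(vapply(seq_len(nrow(eu)), function(i)
      sum(track_slice(track, eu$start[i], eu$end[i])), 0))
    for (i in idx) {
      ev <- events[i, ]
      reg <- event_region(ev)
      d <- track_slice(track, reg[1], reg[2])
      c1v[i] <- c1
      c2v[i] <- mean(d)
      tr[i] <- if (c1 > 0) c2v[i] / c1 else NA_real_
      intr_total[i] <- sum(d)
      exon_total[i] <- etot
    }
  }
  data.frame(tr = tr, c1 = c1v, c2 = c2v, intr_total = intr_total,
             exon_total = exon_total)
}

# the terminal region an event's C2 is measured over, 0-based half-open
event_region <- function(ev) {
  if (ev$ipa_type == 2L && !is.na(ev$cryptic_start))
    return(c(ev$cryptic_start, ev$cryptic_end))
  if (ev$strand == "+") c(ev$intron_start, ev$pos + 1L)
  else c(ev$pos, ev$intron_end)
}

# union of events called in either sample, keyed by gene and site
union_events <- function(eventsA, eventsB) {
  both <- rbind(as.data.frame(eventsA), as.data.frame(eventsB))
  key <- paste(both$gene_id, both$pos)
  both[!duplicated(key), , drop = FALSE]
}

#' Differential IPA usage without replicates (chi-squared path)
#'
#' Events called in either sample are united; for each event a 2x2
#' contingency table of (condition) x (intronic terminal-region read
#' count, exonic read count) is tested with [chi_squared_2x2()]. Read
#' counts are coverage totals divided by the read length and rounded.
#' TR is recomputed at the event's coordinates in both samples, so an
#' event undetected in one sample gets its actual (not zero) TR there.
#'
#' @param ann an `ipa_annotation`.
#' @param eventsA,eventsB `ipa_events` from [detect_sample()] on the
#'   same catalog.
#' @param covA,covB coverage sources of the two conditions.
#' @param params an [ipa_params()] list (`read_len` is used here).
#' @param delta_min,p_max significance thresholds (defaults 0.2, 0.05).
#' @return data.frame of class `ipa_differential`: per event `tr1`,
#'   `tr2`, `delta`, `statistic`, `pvalue`, `test = "chi_squared"`,
#'   `significant`.
#' @export
differential_no_reps <- function(ann, eventsA, eventsB, covA, covB,
                                 params = ipa_params(), delta_min = 0.2,
                                 p_max = 0.05) {
  ev <- union_events(eventsA, eventsB)
  if (!nrow(ev)) return(empty_differential())
  qA <- quantify_events(ann, ev, covA)
  qB <- quantify_events(ann, ev, covB)
  rl <- params$read_len
  n <- nrow(ev)
  stat <- pv <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(round(c(qA$intr_total[i], qA$exon_total[i],
                          qB$intr_total[i], qB$exon_total[i]) / rl),
                  nrow = 2L, byrow = TRUE)
    res <- suppressWarnings(chi_squared_2x2(tab))
    stat[i] <- if (is.null(res$statistic)) NA_real_ else res$statistic
    pv[i] <- res$pvalue
  }
  delta <- abs(qA$tr - qB$tr)
  out <- data.frame(gene_id = ev$gene_id, chrom = ev$chrom,
                    strand = ev$strand, pos = ev$pos,
                    ipa_type = ev$ipa_type, tr1 = qA$tr, tr2 = qB$tr,
                    delta = delta, statistic = stat, pvalue = pv,
                    test = "chi_squared",
                    significant = pv < p_max & delta > delta_min)
  class(out) <- c("ipa_differential", "data.frame")
  out
}

#' Differential IPA usage with replicates (rank-sum path)
#'
#' Computes the per-replicate TR of every event at fixed coordinates in
#' every sample and applies [differential_with_reps()] per event.
#'
#' @param ann an `ipa_annotation`.
#' @param events `ipa_events` (or truth-like data.frame with `gene_id`,
#'   `chrom`, `strand`, `pos`, `ipa_type`, `cryptic_start`,
#'   `cryptic_end`, `intron_start`, `intron_end`) defining the tested
#'   sites.
#' @param covs1,covs2 lists of `ipa_coverage` sources (>= 2 replicates
#'   per condition).
#' @param exact,delta_min,p_max passed to [differential_with_reps()].
#' @return data.frame of class `ipa_differential` with
#'   `test = "wilcoxon"`.
#' @export
differential_replicates <- function(ann, events, covs1, covs2,
                                    exact = FALSE, delta_min = 0.2,
                                    p_max = 0.05) {
  stopifnot(length(covs1) >= 2L, length(covs2) >= 2L)
  if (!nrow(events)) return(empty_differential())
  t1 <- vapply(covs1, function(cv) quantify_events(ann, events, cv)$tr,
               numeric(nrow(events)))
  t2 <- vapply(covs2, function(cv) quantify_events(ann, events, cv)$tr,
               numeric(nrow(events)))
  t1 <- matrix(t1, nrow = nrow(events))
  t2 <- matrix(t2, nrow = nrow(events))
  res <- lapply(seq_len(nrow(events)), function(i)
    differential_with_reps(t1[i, ], t2[i, ], exact = exact,
                           delta_min = delta_min, p_max = p_max))
  out <- data.frame(gene_id = events$gene_id, chrom = events$chrom,
                    strand = events$strand, pos = events$pos,
                    ipa_type = events$ipa_type,
                    tr1 = vapply(res, `[[`, 0, "tr1"),
                    tr2 = vapply(res, `[[`, 0, "tr2"),
                    delta = vapply(res, `[[`, 0, "delta"),
                    statistic = NA_real_,
                    pvalue = vapply(res, `[[`, 0, "pvalue"),
                    test = "wilcoxon",
                    significant = vapply(res, `[[`, TRUE, "significant"))
  class(out) <- c("ipa_differential", "data.frame")
  out
}

empty_differential <- function() {
  out <- data.frame(gene_id = character(0), chrom = character(0),
                    strand = character(0), pos = integer(0),
                    ipa_type = integer(0), tr1 = numeric(0),
                    tr2 = numeric(0), delta = numeric(0),
                    statistic = numeric(0), pvalue = numeric(0),
                    test = character(0), significant = logical(0))
  class(out) <- c("ipa_differential", "data.frame")
  out
}

#' @export
print.ipa_differential <- function(x, ...) {
  cat(sprintf("ipa_differential: %d event(s), %d significant (%s)\n",
              nrow(x), sum(x$significant),
              paste(unique(x$test), collapse = ",")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x)[,
    c("gene_id", "pos", "ipa_type", "tr1", "tr2", "delta", "pvalue",
      "significant")], 10L), digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg adjustment of differential results
#'
#' Optional parity with FDR-based criteria of other tools: replaces the
#' raw p-value criterion by BH-adjusted p < `p_max` (the |dTR| criterion
#' is unchanged).
#'
#' @param x an `ipa_differential` data.frame.
#' @param p_max,delta_min thresholds (defaults 0.05, 0.2).
#' @return the data.frame with `padj` added and `significant` redefined.
#' @export
adjust_differential <- function(x, p_max = 0.05, delta_min = 0.2) {
  x$padj <- stats::p.adjust(x$pvalue, method = "BH")
  x$significant <- x$padj < p_max & x$delta > delta_min
  x
}

#' @rdname write_events_tsv
#' @export
write_differential_tsv <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
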