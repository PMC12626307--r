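## Scoring detector output against ground truth: one-to-one tolerance
## matching, sensitivity, false-call rate, and rank-statistic ROC AUC.

#' One-to-one matching of called positions to truth positions
#'
#' Greedy nearest-neighbor matching within `tol` nt on the same
#' chromosome: candidate pairs are ranked by distance (ties: leftmost
#' truth position), and each truth matches at most one call and vice
#' versa.
#'
#' @param called data.frame with `chrom`, `pos` (or a numeric vector of
#'   positions on one chromosome).
#' @param truth same shape as `called`.
#' @param tol matching tolerance in nt (default 50).
#' @return list with `pairs` (data.frame `call_idx`, `truth_idx`,
#'   `dist`) and `n_matched`.
#' @export
match_events <- function(called, truth, tol = 50L) {
  stopifnot(tol >= 0)
  if (is.numeric(called))
    called <- data.frame(chrom = rep(".", length(called)), pos = called)
  if (is.numeric(truth))
    truth <- data.frame(chrom = rep(".", length(truth)), pos = truth)
  pairs <- list()
  for (chrom in intersect(unique(called$chrom), unique(truth$chrom))) {
    ci <- which(called$chrom == chrom)
    ti <- which(truth$chrom == chrom)
    dmat <- abs(outer(called$pos[ci], truth$pos[ti], "-"))
    hit <- which(dmat <= tol, arr.ind = TRUE)
    if (!nrow(hit)) next
    cand <- data.frame(call_idx = ci[hit[, 1]], truth_idx = ti[hit[, 2]],
                       dist = dmat[hit])
    cand <- cand[order(cand$dist, truth$pos[cand$truth_idx],
                       cand$call_idx), ]
    used_c <- logical(nrow(called)); used_t <- logical(nrow(truth))
    for (k in seq_len(nrow(cand))) {
      i <- cand$call_idx[k]; j <- cand$truth_idx[k]
      if (!used_c[i] && !used_t[j]) {
        used_c[i] <- TRUE; used_t[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- cand[k, ]
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(call_idx = integer(0), truth_idx = integer(0),
               dist = integer(0))
  rownames(pairs) <- NULL
  list(pairs = pairs, n_matched = nrow(pairs))
}

#' Rank-statistic ROC AUC
#'
#' \eqn{AUC = P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)} computed from
#' midranks (the Wilcoxon statistic identity), equal to brute-force
#' pairwise comparison.
#'
#' @param scores_pos,scores_neg numeric scores of positive / negative
#'   instances (both non-empty).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L) stop("both score sets must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' True/false positive rates over all score thresholds (descending),
#' suitable for plotting the curve whose area [roc_auc()] computes.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores_pos, scores_neg) {
  th <- sort(unique(c(scores_pos, scores_neg, Inf)), decreasing = TRUE)
  data.frame(threshold = th,
             tpr = vapply(th, function(t) mean(scores_pos >= t), 0),
             fpr = vapply(th, function(t) mean(scores_neg >= t), 0))
}

#' Score called events against ground truth
#'
#' Sensitivity = matched truths / truths; the false-call rate is the
#' fraction of calls not matching any truth within the tolerance
#' (1 - precision). When `scores_pos`/`scores_neg` are supplied, a
#' rank-statistic AUC and ROC points are added.
#'
#' @param called `ipa_events` (or data.frame with `chrom`, `pos`).
#' @param truth truth data.frame with `chrom`, `pos`.
#' @param tol matching tolerance in nt (default 50).
#' @param scores_pos,scores_neg optional ranking scores (event TR) of
#'   true and decoy candidates.
#' @return list of class `eval_report`: `n_truth`, `n_called`,
#'   `true_positives`, `sensitivity`, `false_call_rate`, and `auc`,
#'   `roc` when scores are given.
#' @export
evaluate_calls <- function(called, truth, tol = 50L, scores_pos = NULL,
                           scores_neg = NULL) {
  m <- match_events(called, truth, tol)
  n_called <- if (is.numeric(called)) length(called) else nrow(called)
  n_truth <- if (is.numeric(truth)) length(truth) else nrow(truth)
  rep <- list(n_truth = n_truth, n_called = n_called,
              true_positives = m$n_matched,
              sensitivity = if (n_truth) m$n_matched / n_truth else NA_real_,
              false_call_rate = if (n_called)
                1 - m$n_matched / n_called else NA_real_,
              matching = m$pairs)
  if (!is.null(scores_pos) && !is.null(scores_neg)) {
    rep$auc <- roc_auc(scores_pos, scores_neg)
    rep$roc <- roc_points(scores_pos, scores_neg)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: %d/%d truth matched (sensitivity %.3f), %d called, false-call rate %.3f%s\n",
    x$true_positives, x$n_truth, x$sensitivity, x$n_called,
    x$false_call_rate,
    if (!is.null(x$auc)) sprintf(", AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' Write an evaluation report as JSON (and optional ROC TSV)
#'
#' @param report an `eval_report`.
#' @param path JSON output path.
#' @param roc_path optional TSV path for the ROC points.
#' @export
write_eval_json <- function(report, path, roc_path = NULL) {
  out <- report[c("n_truth", "n_called", "true_positives", "sensitivity",
                  "false_call_rate")]
  if (!is.null(report$auc)) out$auc <- report$auc
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_path) && !is.null(report$roc))
    write.table(report$roc, roc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Truncation ratios of candidate sites regardless of event filters
#'
#' Computes each candidate's TR as the mean depth of its upstream intron
#' stretch (Type 1 geometry) over the gene's mean exonic depth, with no
#' thresholds applied -- the ranking score used for ROC analysis, so
#' sub-threshold candidates still receive their computed value. Genes
#' without exonic coverage give TR 0.
#'
#' @param ann an `ipa_annotation`.
#' @param catalog an `ipa_catalog`.
#' @param cov coverage source.
#' @return numeric vector of TRs aligned with `catalog` rows.
#' @export
candidate_tr <- function(ann, catalog, cov) {
  tr <- numeric(nrow(catalog))
  for (gid in unique(catalog$gene_id)) {
    g <- ann[[gid]]
    idx <- which(catalog$gene_id == gid)
    track <- gene_track(g, cov)
    c1 <- compute_c1(g, track)
    for (i in idx) {
      s <- catalog[i, ]
      c2 <- if (s$strand == "+")
        .mean0(track, s$intron_start, s$pos + 1L)
      else .mean0(track, s$pos, s$intron_end)
      tr[i] <- if (c1 > 0) c2 / c1 else 0
    }
  }
  tr
}
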