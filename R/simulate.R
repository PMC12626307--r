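## Synthetic benchmark generator: multi-exon gene models tiled along
## synthetic chromosomes, Poisson-distributed expression, planted Type 1
## and Type 2 IPA events with known truncation ratios, decoy candidate
## sites, optional genome sequence with planted PAS hexamers, optional
## paired case/control conditions with replicates, and ground truth.

#' Simulation configuration
#'
#' Defaults reproduce the reference benchmark conditions: 1,000 planted
#' events (500 Type 1 + 500 Type 2) in highly expressed genes, gene
#' expression Poisson-distributed around `depth` (50 = a 50M-read
#' equivalent, roughly 50x exonic coverage; scale to 5 for the
#' 5M-equivalent), planted Type 1 truncation ratios uniform in
#' `tr_range`, and an equal number of decoy candidate sites in introns
#' of non-event genes. Type 2 TRs are drawn from `tr_range_type2`,
#' bounded below by the 80% cryptic-exon coverage rule (a cryptic exon
#' below 0.8x exonic coverage is undetectable by construction).
#'
#' @param n_genes number of genes (default 2000).
#' @param n_type1,n_type2 planted event counts (defaults 500 each).
#' @param depth mean gene expression lambda; exon per-base depth is
#'   Poisson(lambda) (default 50).
#' @param tr_range planted Type 1 TR interval (default c(0.3, 0.9)).
#' @param tr_range_type2 planted Type 2 TR interval
#'   (default c(0.85, 0.95)).
#' @param intron_background background intronic coverage as a fraction
#'   of lambda (default 0.02, unspliced pre-mRNA carryover).
#' @param n_decoys decoy candidate sites in non-event genes (default
#'   `n_type1 + n_type2`).
#' @param read_len nominal read length (default 100).
#' @param noiseless use exact rounded expected depths instead of Poisson
#'   draws.
#' @param top_quantile events are planted only in genes at or above this
#'   expression quantile (default 0.5, the top half).
#' @param overdispersion Gamma-Poisson mixing coefficient for expression
#'   (0 = pure Poisson, the default).
#' @param genome synthesize a genome sequence with an AATAAA hexamer
#'   planted 21 nt transcript-upstream of every truth site.
#' @param differential `NULL`, or a list with `n_diff` (events whose TR
#'   differs by > 0.2 between conditions), `n_same` (events planted
#'   identically in both conditions), `delta_range` (planted |dTR|
#'   interval, default c(0.25, 0.5)) and `n_replicates` (default 3).
#' @param seed RNG seed applied at generation time (`NULL` = leave RNG
#'   state alone).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_type1 = 500L, n_type2 = 500L,
                       depth = 50, tr_range = c(0.3, 0.9),
                       tr_range_type2 = c(0.85, 0.95),
                       intron_background = 0.02,
                       n_decoys = n_type1 + n_type2, read_len = 100L,
                       noiseless = FALSE, top_quantile = 0.5,
                       overdispersion = 0, genome = FALSE,
                       differential = NULL, seed = NULL) {
  if (is.null(differential) && n_type1 + n_type2 > n_genes)
    stop("infeasible config: more events than genes")
  if (!is.null(differential)) {
    differential$n_same <- differential$n_same %||% 0L
    differential$delta_range <- differential$delta_range %||% c(0.25, 0.5)
    differential$n_replicates <- differential$n_replicates %||% 3L
    if (differential$n_diff + differential$n_same > n_genes)
      stop("infeasible config: more events than genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_type1 = as.integer(n_type1),
                 n_type2 = as.integer(n_type2), depth = depth,
                 tr_range = tr_range, tr_range_type2 = tr_range_type2,
                 intron_background = intron_background,
                 n_decoys = as.integer(n_decoys),
                 read_len = as.integer(read_len), noiseless = noiseless,
                 top_quantile = top_quantile,
                 overdispersion = overdispersion, genome = genome,
                 differential = differential, seed = seed),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gene structures tiled along synthetic chromosomes (100 genes/chrom)
sim_structures <- function(cfg) {
  n <- cfg$n_genes
  genes <- vector("list", n)
  chrom_lens <- integer(0)
  offset <- 0L; chrom_i <- 1L
  per_chrom <- 100L
  for (i in seq_len(n)) {
    if ((i - 1L) %% per_chrom == 0L && i > 1L) {
      chrom_lens[paste0("chr", chrom_i)] <- offset + 500L
      chrom_i <- chrom_i + 1L; offset <- 0L
    }
    chrom <- paste0("chr", chrom_i)
    n_ex <- sample(3:6, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(800:3000, n_ex - 1L, replace = TRUE)
    start <- offset + 500L
    s <- integer(n_ex); e <- integer(n_ex)
    p <- start
    for (k in seq_len(n_ex)) {
      s[k] <- p; e[k] <- p + ex_len[k]
      p <- e[k] + if (k < n_ex) in_len[k] else 0L
    }
    gid <- sprintf("gene%04d", i)
    strand <- sample(c("+", "-"), 1L)
    tx <- list(id = paste0(gid, ".t1"),
               exons = data.frame(start = s, end = e),
               cds = c(s[1], e[n_ex]))
    genes[[i]] <- gene_model(gid, chrom, strand, list(tx))
    names(genes)[i] <- gid
    offset <- e[n_ex]
  }
  chrom_lens[paste0("chr", chrom_i)] <- offset + 500L
  list(ann = structure(genes, class = "ipa_annotation"),
       chrom_lens = chrom_lens)
}

# choose an intron and a site position with room for the event profile
place_site <- function(g, type) {
  intr <- g$introns
  ok <- which(intr$end - intr$start >= 800L)
  ii <- if (length(ok) > 1L) sample(ok, 1L) else ok[1]
  s <- intr$start[ii]; e <- intr$end[ii]
  len <- e - s
  if (type == 2L) {
    ce_len <- sample(100:min(500L, len - 350L), 1L)
    # >= 150 nt gap to the upstream exon, >= 150 nt of low coverage after
    u <- sample(150:(len - ce_len - 150L), 1L)
    if (g$strand == "+") {
      ce_start <- s + u; pos <- ce_start + ce_len - 1L
    } else {
      ce_end <- e - u; pos <- ce_end - ce_len; ce_start <- pos
    }
    list(intron = ii, pos = pos, ce_start = ce_start,
         ce_end = ce_start + ce_len)
  } else {
    # truncation stretch >= 200 nt, >= 150 nt of low coverage after
    u <- sample(200:(len - 150L), 1L)
    pos <- if (g$strand == "+") s + u - 1L else e - u
    list(intron = ii, pos = pos, ce_start = NA_integer_,
         ce_end = NA_integer_)
  }
}

# per-gene expected depth runs for one condition; tr = NA -> no event
gene_runs <- function(g, lambda, bg, event) {
  eu <- g$exon_union
  intr <- g$introns
  vals <- numeric(0); lens <- integer(0)
  add <- function(v, l) {
    if (l > 0L) { vals <<- c(vals, v); lens <<- c(lens, l) }
    invisible(NULL)
  }
  for (k in seq_len(nrow(eu))) {
    add(lambda, eu$end[k] - eu$start[k])
    if (k < nrow(eu)) {
      s <- eu$end[k]; e <- eu$start[k + 1]
      if (!is.null(event) && event$intron == k) {
        tr_l <- event$tr * lambda
        if (event$type == 1L) {
          if (g$strand == "+") {
            add(tr_l, event$pos + 1L - s); add(bg, e - event$pos - 1L)
          } else {
            add(bg, event$pos - s); add(tr_l, e - event$pos)
          }
        } else {
          add(bg, event$ce_start - s)
          add(tr_l, event$ce_end - event$ce_start)
          add(bg, e - event$ce_end)
        }
      } else {
        add(bg, e - s)
      }
    }
  }
  list(vals = vals, lens = lens)
}

# assemble per-chromosome expected-depth RleLists for each condition
build_expected <- function(ann, chrom_lens, lambdas, events_by_gene,
                           bg_frac, n_cond) {
  conds <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    rl <- list()
    for (chrom in names(chrom_lens)) {
      gs <- Filter(function(g) g$chrom == chrom, ann)
      vals <- numeric(0); lens <- integer(0)
      cursor <- 0L
      for (g in gs) {
        span <- gene_span(g)
        if (span[1] > cursor) {
          vals <- c(vals, 0); lens <- c(lens, span[1] - cursor)
        }
        ev <- events_by_gene[[g$gene_id]]
        if (!is.null(ev)) ev$tr <- ev$trs[ci]
        lam <- lambdas[[g$gene_id]]
        gr <- gene_runs(g, lam, bg_frac * lam, ev)
        vals <- c(vals, gr$vals); lens <- c(lens, gr$lens)
        cursor <- span[2]
      }
      if (cursor < chrom_lens[[chrom]]) {
        vals <- c(vals, 0); lens <- c(lens, chrom_lens[[chrom]] - cursor)
      }
      rl[[chrom]] <- S4Vectors::Rle(vals, lens)
    }
    conds[[ci]] <- IRanges::RleList(rl, compress = FALSE)
  }
  conds
}

#' Draw a coverage sample from an expected depth profile
#'
#' Per-base depths are independent Poisson draws around the expected
#' profile (or exact rounded values in noiseless mode).
#'
#' @param expected a numeric [IRanges::RleList] of expected depths.
#' @param noiseless round instead of sampling.
#' @return an `ipa_coverage` source.
#' @export
sample_coverage <- function(expected, noiseless = FALSE) {
  rl <- lapply(names(expected), function(chrom) {
    mu <- as.numeric(expected[[chrom]])
    d <- if (noiseless) as.integer(round(mu))
         else as.integer(rpois(length(mu), mu))
    S4Vectors::Rle(d)
  })
  names(rl) <- names(expected)
  coverage_from_rle(IRanges::RleList(rl, compress = FALSE))
}

sim_core <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  st <- sim_structures(cfg)
  ann <- st$ann
  n <- cfg$n_genes
  lam_mean <- if (cfg$overdispersion > 0)
    cfg$depth * stats::rgamma(n, shape = 1 / cfg$overdispersion,
                              scale = cfg$overdispersion)
  else rep(cfg$depth, n)
  lambdas <- setNames(as.list(rpois(n, lam_mean)), names(ann))
  hi <- names(ann)[unlist(lambdas) >=
                     quantile(unlist(lambdas), 1 - cfg$top_quantile)]
  list(ann = ann, chrom_lens = st$chrom_lens, lambdas = lambdas, hi = hi)
}

pick_event_genes <- function(core, n_events) {
  if (length(core$hi) < n_events)
    stop("infeasible config: not enough highly expressed genes")
  sample(core$hi, n_events)
}

decoy_sites <- function(core, event_gids, n_decoys) {
  pool <- setdiff(names(core$ann), event_gids)
  if (n_decoys == 0L || !length(pool))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), pos = integer(0)))
  gids <- sample(pool, min(n_decoys, length(pool)))
  recs <- lapply(gids, function(gid) {
    g <- core$ann[[gid]]
    pl <- place_site(g, 1L)
    data.frame(gene_id = gid, chrom = g$chrom, strand = g$strand,
               pos = pl$pos)
  })
  do.call(rbind, recs)
}

sites_table <- function(truth, decoys) {
  rbind(data.frame(chrom = truth$chrom, pos = truth$pos,
                   strand = truth$strand,
                   name = sprintf("truth|%s", truth$gene_id),
                   score = rep(1L, nrow(truth))),
        data.frame(chrom = decoys$chrom, pos = decoys$pos,
                   strand = decoys$strand,
                   name = sprintf("decoy|%s", decoys$gene_id),
                   score = rep(0L, nrow(decoys))))
}

#' Simulate one sample with planted IPA events
#'
#' Generates gene models, Poisson expression, planted Type 1 / Type 2
#' events in highly expressed genes, decoy candidate sites in non-event
#' genes, a coverage profile, and the ground truth. With
#' `genome = TRUE`, a random genome sequence is synthesized with an
#' AATAAA hexamer planted 21 nt transcript-upstream of every truth site.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `ipa_sim`: `config`, `annotation`,
#'   `chrom_lens`, `lambdas`, `expected` (numeric RleList), `coverage`
#'   (an `ipa_coverage`), `truth`, `decoys`, `sites` (truth + decoys,
#'   BED-like), `genome` (DNAStringSet or NULL).
#' @export
simulate_ipa_sample <- function(cfg = sim_config()) {
  core <- sim_core(cfg)
  n_events <- cfg$n_type1 + cfg$n_type2
  gids <- pick_event_genes(core, n_events)
  types <- c(rep(1L, cfg$n_type1), rep(2L, cfg$n_type2))
  truth <- vector("list", n_events)
  events_by_gene <- list()
  for (i in seq_len(n_events)) {
    g <- core$ann[[gids[i]]]
    pl <- place_site(g, types[i])
    tr <- if (types[i] == 1L)
      runif(1, cfg$tr_range[1], cfg$tr_range[2])
    else runif(1, cfg$tr_range_type2[1], cfg$tr_range_type2[2])
    intr <- g$introns[pl$intron, ]
    truth[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      pos = pl$pos, type = types[i], planted_tr = tr,
      ce_start = pl$ce_start, ce_end = pl$ce_end,
      intron_start = intr$start, intron_end = intr$end,
      upstream_exon_end = intr$upstream_exon_end)
    events_by_gene[[g$gene_id]] <-
      list(intron = pl$intron, pos = pl$pos, type = types[i],
           ce_start = pl$ce_start, ce_end = pl$ce_end, trs = tr)
  }
  truth <- if (n_events) do.call(rbind, truth) else NULL
  decoys <- decoy_sites(core, gids, cfg$n_decoys)
  expected <- build_expected(core$ann, core$chrom_lens, core$lambdas,
                             events_by_gene, cfg$intron_background, 1L)[[1]]
  genome <- if (cfg$genome)
    sim_genome(core$chrom_lens, truth) else NULL
  structure(list(config = cfg, annotation = core$ann,
                 chrom_lens = core$chrom_lens, lambdas = core$lambdas,
                 expected = expected,
                 coverage = sample_coverage(expected, cfg$noiseless),
                 truth = truth, decoys = decoys,
                 sites = sites_table(truth, decoys), genome = genome),
            class = "ipa_sim")
}

#' Simulate paired case/control conditions with replicates
#'
#' Shares gene structures, expression and event placement across
#' conditions; `n_diff` events get per-condition TRs differing by more
#' than 0.2 (planted |dTR| drawn from `delta_range`, direction random),
#' `n_same` events are planted identically in both conditions, and each
#' condition gets `n_replicates` independent Poisson-resampled coverage
#' samples.
#'
#' @param cfg a [sim_config()] with a `differential` spec.
#' @return a list of class `ipa_sim_pair`: `config`, `annotation`,
#'   `chrom_lens`, `truth` (with `tr1`, `tr2`, `differential` columns),
#'   `decoys`, `sites`, `expected` (list of two RleLists), `samples`
#'   (list of two lists of `ipa_coverage` replicates).
#' @export
simulate_ipa_pair <- function(cfg) {
  d <- cfg$differential
  if (is.null(d)) stop("cfg$differential spec is required")
  core <- sim_core(cfg)
  n_events <- d$n_diff + d$n_same
  gids <- pick_event_genes(core, n_events)
  is_diff <- c(rep(TRUE, d$n_diff), rep(FALSE, d$n_same))
  truth <- vector("list", n_events)
  events_by_gene <- list()
  for (i in seq_len(n_events)) {
    g <- core$ann[[gids[i]]]
    pl <- place_site(g, 1L)                 # Type 1 coverage profile
    if (is_diff[i]) {
      delta <- runif(1, d$delta_range[1], d$delta_range[2])
      lo <- runif(1, 0.05, 0.95 - delta)
      trs <- if (runif(1) < 0.5) c(lo, lo + delta) else c(lo + delta, lo)
    } else {
      trs <- rep(runif(1, cfg$tr_range[1], cfg$tr_range[2]), 2L)
    }
    intr <- g$introns[pl$intron, ]
    truth[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      pos = pl$pos, type = 1L, ipa_type = 1L, tr1 = trs[1], tr2 = trs[2],
      differential = is_diff[i], ce_start = NA_integer_,
      ce_end = NA_integer_, cryptic_start = NA_integer_,
      cryptic_end = NA_integer_, intron_start = intr$start,
      intron_end = intr$end, upstream_exon_end = intr$upstream_exon_end)
    events_by_gene[[g$gene_id]] <-
      list(intron = pl$intron, pos = pl$pos, type = 1L,
           ce_start = NA_integer_, ce_end = NA_integer_, trs = trs)
  }
  truth <- do.call(rbind, truth)
  decoys <- decoy_sites(core, gids, cfg$n_decoys)
  expected <- build_expected(core$ann, core$chrom_lens, core$lambdas,
                             events_by_gene, cfg$intron_background, 2L)
  samples <- lapply(1:2, function(ci)
    lapply(seq_len(d$n_replicates), function(r)
      sample_coverage(expected[[ci]], cfg$noiseless)))
  structure(list(config = cfg, annotation = core$ann,
                 chrom_lens = core$chrom_lens, lambdas = core$lambdas,
                 truth = truth, decoys = decoys,
                 sites = sites_table(truth, decoys),
                 expected = expected, samples = samples),
            class = "ipa_sim_pair")
}

# random genome with planted AATAAA 21 nt transcript-upstream of truth
sim_genome <- function(chrom_lens, truth) {
  seqs <- lapply(names(chrom_lens), function(chrom) {
    v <- sample(c("A", "C", "G", "T"), chrom_lens[[chrom]], replace = TRUE)
    tr <- truth[truth$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      pos <- tr$pos[i]
      if (tr$strand[i] == "+") {
        if (pos - 21L >= 0L)
          v[(pos - 21L):(pos - 16L) + 1L] <- c("A","A","T","A","A","A")
      } else {
        if (pos + 22L <= chrom_lens[[chrom]])
          v[(pos + 16L):(pos + 21L) + 1L] <- c("T","T","T","A","T","T")
      }
    }
    paste(v, collapse = "")
  })
  gen <- Biostrings::DNAStringSet(unlist(seqs))
  names(gen) <- names(chrom_lens)
  gen
}

#' @export
print.ipa_sim <- function(x, ...) {
  cat(sprintf("ipa_sim: %d gene(s), %d truth event(s) (%d Type 1, %d Type 2), %d decoy(s), depth %s\n",
              length(x$annotation), nrow(x$truth),
              sum(x$truth$type == 1L), sum(x$truth$type == 2L),
              nrow(x$decoys), format(x$config$depth)))
  invisible(x)
}

#' @export
print.ipa_sim_pair <- function(x, ...) {
  cat(sprintf("ipa_sim_pair: %d truth event(s) (%d differential), %d replicate(s)/condition\n",
              nrow(x$truth), sum(x$truth$differential),
              x$config$differential$n_replicates))
  invisible(x)
}

#' Write a simulated sample to standard formats
#'
#' Emits `annotation.gtf`, `coverage.bedGraph`, `sites.bed`,
#' `truth.tsv`, plus `genome.fa` when the simulation carries a genome
#' and `reads.bam` (coverage-exact synthetic alignments, see
#' [write_coverage_bam()]) when `reads = TRUE`.
#'
#' @param sim an `ipa_sim`.
#' @param dir output directory (created if needed).
#' @param reads also synthesize a BAM whose pileup equals the coverage.
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir, reads = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_bedgraph(sim$coverage, file.path(dir, "coverage.bedGraph"))
  write_bed(sim$sites, file.path(dir, "sites.bed"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$genome)) {
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, fa)
    Rsamtools::indexFa(fa)
  }
  if (reads)
    write_coverage_bam(sim$coverage, sim$chrom_lens,
                       file.path(dir, "reads.bam"),
                       read_len = sim$config$read_len)
  invisible(dir)
}

#' Synthesize a BAM whose pileup equals a coverage profile
#'
#' Decomposes each chromosome's depth vector into reads of length at
#' most `read_len` (FIFO open/close, force-closing reads at `read_len`
#' and reopening while depth persists), so the per-base alignment pileup
#' reproduces the profile exactly. Writes SAM text, converts, sorts and
#' indexes with Rsamtools.
#'
#' @param src an in-memory `ipa_coverage`.
#' @param chrom_lens named chromosome lengths.
#' @param path output BAM path.
#' @param read_len maximum read length (default 100).
#' @return the BAM path, invisibly.
#' @export
write_coverage_bam <- function(src, chrom_lens, path, read_len = 100L) {
  stopifnot(src$type == "rle")
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens),
                       as.integer(chrom_lens))), con)
  rid <- 0L
  for (chrom in names(chrom_lens)) {
    r <- src$rle[[chrom]]
    if (is.null(r)) next
    d <- c(as.integer(r), 0L)
    open <- integer(0)                     # start positions, FIFO
    lines <- character(0)
    emit <- function(s, e) {
      rid <<- rid + 1L
      lines[length(lines) + 1L] <<-
        sprintf("r%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                rid, chrom, s + 1L, e - s)
    }
    for (p in seq_along(d)) {
      pos <- p - 1L                        # 0-based
      while (length(open) && pos - open[1] >= read_len) {
        emit(open[1], pos); open <- open[-1]
      }
      dp <- d[p]
      while (length(open) > dp) { emit(open[1], pos); open <- open[-1] }
      if (dp > length(open)) open <- c(open, rep(pos, dp - length(open)))
    }
    # emitted reads are ordered by end; re-sort by start for the writer
    writeLines(lines, con)
  }
  close(con)
  bam0 <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam0, sub("\\.bam$", "", path))
  Rsamtools::indexBam(sorted)
  unlink(c(sam, bam0))
  invisible(sorted)
}
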