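# Independent brute-force oracles and shared toy fixtures.

# --- codon-table walk, independent of the implementation's translator ---
# canonical NCBI layout, base order T C A G
.aa64 <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  setNames(.aa64, codons)
})

oracle_translate <- function(dna, frame) {
  dna <- chartr("U", "T", toupper(dna))
  out <- character(0)
  i <- frame + 1L
  while (i + 2L <= nchar(dna)) {
    codon <- substr(dna, i, i + 2L)
    if (grepl("[^ACGT]", codon)) {
      out <- c(out, "X")
    } else {
      aa <- .codon_table[[codon]]
      if (aa == "*") break
      out <- c(out, aa)
    }
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# --- pairwise AUC ---
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# --- exact two-sided rank-sum p by enumeration (no ties) ---
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ws <- apply(utils::combn(n1 + n2, n1), 2L,
              function(idx) sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(ws <= w_obs); hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# --- per-base interval membership ---
bases_of <- function(start, end)
  unlist(mapply(function(s, e) if (s < e) s:(e - 1L) else integer(0),
                start, end, SIMPLIFY = FALSE))

# --- in-memory coverage from a named list of depth vectors ---
cov_from_vectors <- function(vecs) {
  rl <- lapply(vecs, S4Vectors::Rle)
  coverage_from_rle(IRanges::RleList(rl, compress = FALSE))
}

# single-isoform plus/minus toy gene: exons and one long intron
toy_gene <- function(gene_id = "g1", chrom = "chrT", strand = "+",
                     exons = data.frame(start = c(0L, 2000L),
                                        end = c(500L, 2500L)),
                     cds = NULL) {
  tx <- list(id = paste0(gene_id, ".t1"), exons = exons, cds = cds)
  gene_model(gene_id, chrom, strand, list(tx))
}

toy_annotation <- function(...) {
  gs <- list(...)
  names(gs) <- vapply(gs, function(g) g$gene_id, "")
  structure(gs, class = "ipa_annotation")
}

# a catalog row for a site inside a gene's independent intron
toy_site <- function(g, pos, intron = 1L) {
  intr <- g$introns[intron, ]
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             pos = pos, source = "db", hexamer = NA_character_,
             intron_start = intr$start, intron_end = intr$end,
             upstream_exon_end = intr$upstream_exon_end)
}

# --- shared medium-size simulation, computed once per test run ---
.fixture_env <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_ipa_sample(sim_config(
      n_genes = 120L, n_type1 = 30L, n_type2 = 30L, n_decoys = 40L,
      depth = 50, genome = TRUE, seed = 421L))
  }
  .fixture_env$sim
}

fixture_catalog <- function() {
  if (is.null(.fixture_env$catalog)) {
    sim <- fixture_sim()
    .fixture_env$catalog <- build_catalog(
      sim$annotation,
      db_sites = data.frame(chrom = sim$sites$chrom, pos = sim$sites$pos,
                            strand = sim$sites$strand))
  }
  .fixture_env$catalog
}

fixture_events <- function() {
  if (is.null(.fixture_env$events)) {
    sim <- fixture_sim()
    .fixture_env$events <-
      detect_sample(sim$annotation, fixture_catalog(), sim$coverage)
  }
  .fixture_env$events
}
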