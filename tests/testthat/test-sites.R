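test_that("PAS scan finds sense-strand hexamers with the cleavage offset", {
  gen <- Biostrings::DNAStringSet(c(chrT = "GGGAATAAAGGG"))
  hits <- scan_pas(gen, "chrT", 0L, 12L, "+", motifs = "AATAAA",
                   offset = 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos, 3L)           # motif start at offset 3
  expect_equal(hits$hexamer, "AATAAA")

  # all C/G sequence has no hits
  gcg <- Biostrings::DNAStringSet(c(chrT = strrep("CG", 50)))
  expect_equal(nrow(scan_pas(gcg, "chrT", 0L, 100L, "+", offset = 0L)), 0L)

  # minus-strand gene: reference TTTATT is a sense-strand AATAAA
  genm <- Biostrings::DNAStringSet(c(chrT = "GGGTTTATTGGG"))
  hitm <- scan_pas(genm, "chrT", 0L, 12L, "-", motifs = "AATAAA",
                   offset = 0L)
  expect_equal(nrow(hitm), 1L)
  # sense motif start = reverse-complement position of reference pos 8
  expect_equal(hitm$pos, 8L)

  # soft-masked sequence is uppercased before matching
  soft <- Biostrings::DNAStringSet(c(chrT = "gggaataaaggg"))
  expect_equal(nrow(scan_pas(soft, "chrT", 0L, 12L, "+",
                             motifs = "AATAAA", offset = 0L)), 1L)

  expect_error(scan_pas(gen, "chrT", 0L, 99L, "+"), "outside")
})

test_that("PAS scan is mirror-symmetric under reverse complement", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  gen <- Biostrings::DNAStringSet(c(f = seq))
  rc <- Biostrings::DNAStringSet(c(f = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))))
  fwd <- scan_pas(gen, "f", 0L, 400L, "+", offset = 10L)
  rev_ <- scan_pas(rc, "f", 0L, 400L, "-", offset = 10L)
  expect_equal(sort(399L - rev_$pos), sort(fwd$pos))
})

test_that("default motif set is the two canonical hexamers plus variants on request", {
  expect_setequal(pas_motifs(), c("AATAAA", "ATTAAA"))
  v <- pas_motifs(variants = TRUE)
  expect_true(all(c("AATAAA", "ATTAAA", "CATAAA", "AATAAC") %in% v))
  expect_true(all(nchar(v) == 6L))
})

test_that("peak calling clusters by single linkage with modal summits", {
  pos <- data.frame(chrom = "chr1",
                    pos = rep(c(100L, 101L, 103L), each = 5L),
                    strand = "+")
  pk <- call_peaks(pos, min_reads = 5L, merge_gap = 24L)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$count, 15L)
  expect_equal(pk$summit, 100L)        # tie over 100/101/103 -> leftmost

  # below threshold
  sparse <- data.frame(chrom = "chr1", pos = c(100L, 1100L), strand = "+")
  expect_equal(nrow(call_peaks(sparse, min_reads = 5L)), 0L)

  # modal position wins
  m <- call_peaks(data.frame(chrom = "chr1",
                             pos = c(rep(100L, 3), rep(102L, 4)),
                             strand = "+"), min_reads = 5L)
  expect_equal(m$summit, 102L)

  expect_equal(nrow(call_peaks(NULL)), 0L)
})

test_that("catalog restricts to independent introns and deduplicates by source rank", {
  g <- toy_gene(exons = data.frame(start = c(0L, 2000L),
                                   end = c(500L, 2500L)))
  ann <- toy_annotation(g)
  # db site at intron midpoint retained
  db <- data.frame(chrom = "chrT", pos = 1250L, strand = "+")
  cat1 <- build_catalog(ann, db_sites = db)
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$source, "db")
  expect_equal(cat1$intron_start, 500L)

  # db at 1000 + peak summit at 1030 merge into the db site
  peaks <- data.frame(chrom = "chrT", start = 1020L, end = 1040L,
                      strand = "+", summit = 1030L, count = 10L)
  cat2 <- build_catalog(ann, db_sites = data.frame(
    chrom = "chrT", pos = 1000L, strand = "+"), peaks = peaks)
  expect_equal(nrow(cat2), 1L)
  expect_equal(cat2$pos, 1000L)
  expect_equal(cat2$source, "db")

  # a db site inside an exon is dropped
  cat3 <- build_catalog(ann, db_sites = data.frame(
    chrom = "chrT", pos = 100L, strand = "+"))
  expect_equal(nrow(cat3), 0L)

  # wrong strand is dropped too
  cat4 <- build_catalog(ann, db_sites = data.frame(
    chrom = "chrT", pos = 1250L, strand = "-"))
  expect_equal(nrow(cat4), 0L)

  expect_error(build_catalog(ann), "at least one")
})

test_that("catalog size is monotone in evidence sources and sites stay intronic", {
  sim <- fixture_sim()
  db <- data.frame(chrom = sim$sites$chrom, pos = sim$sites$pos,
                   strand = sim$sites$strand)
  c_db <- build_catalog(sim$annotation, db_sites = db)
  c_all <- build_catalog(sim$annotation, db_sites = db,
                         genome = sim$genome)
  expect_gte(nrow(c_all), nrow(c_db))
  expect_true(all(c_all$pos >= c_all$intron_start &
                    c_all$pos < c_all$intron_end))
  # every site is inside an independent intron of its own gene
  for (i in sample(nrow(c_all), 25L)) {
    g <- sim$annotation[[c_all$gene_id[i]]]
    hit <- any(c_all$pos[i] >= g$introns$start &
                 c_all$pos[i] < g$introns$end)
    expect_true(hit)
  }
})
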