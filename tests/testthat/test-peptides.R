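test_that("translation stops at the first stop codon and handles edge cases", {
  expect_equal(translate_dna("ATGTAA", 0L), "M")
  expect_equal(translate_dna("ATGGCCTGA", 0L), "MA")
  expect_equal(translate_dna("AT", 0L), "")
  expect_equal(translate_dna("AT", 2L), "")
  expect_equal(translate_dna("AATGGCC", 1L), "MA")
  expect_equal(translate_dna("ATGNNTGCC", 0L), "MXA")
})

test_that("translation matches a codon-table oracle on random sequences", {
  set.seed(19)
  for (i in 1:300) {
    n <- sample(3:60, 1)
    dna <- paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    for (f in 0:2)
      expect_equal(translate_dna(dna, f), oracle_translate(dna, f),
                   info = paste(dna, f))
  }
})

# toy world: plus-strand gene, exon1 [0,6) = ATGGCC (CDS), intron [6,20)
# beginning AAATAG, exon2 [20,26)
toy_pep_world <- function() {
  seq <- paste0("ATGGCC", "AAATAGGGGCCCCC", "ATGTAA",
                strrep("G", 74))
  g <- toy_gene(gene_id = "pg", exons = data.frame(start = c(0L, 20L),
                                                   end = c(6L, 26L)),
                cds = c(0L, 26L))
  list(g = g, genome = Biostrings::DNAStringSet(c(chrT = seq)))
}

test_that("Type 1 peptides continue the annotated frame into the intron", {
  w <- toy_pep_world()
  ev <- data.frame(gene_id = "pg", chrom = "chrT", strand = "+",
                   pos = 8L, ipa_type = 1L, cryptic_start = NA_integer_,
                   cryptic_end = NA_integer_, intron_start = 6L,
                   intron_end = 20L, upstream_exon_end = 6L)
  pep <- event_peptides(ev, w$g, w$genome)
  expect_equal(nrow(pep), 1L)
  expect_equal(pep$aa_sequence, "MAK")   # ATG GCC AAA, stop at TAG
  expect_equal(pep$novel_tail_start, 3L)
  expect_equal(pep$frame, 0L)
})

test_that("Type 2 peptides emit all three frames from the cryptic start", {
  w <- toy_pep_world()
  ev <- data.frame(gene_id = "pg", chrom = "chrT", strand = "+",
                   pos = 18L, ipa_type = 2L, cryptic_start = 9L,
                   cryptic_end = 19L, intron_start = 6L,
                   intron_end = 20L, upstream_exon_end = 6L)
  pep <- event_peptides(ev, w$g, w$genome)
  expect_equal(nrow(pep), 3L)
  expect_equal(pep$frame, 0:2)
  ce <- "TAGGGGCCCC"                     # cryptic-exon sequence
  up <- "MA"                             # upstream CDS peptide
  expect_equal(pep$aa_sequence, paste0(up, vapply(0:2, function(f)
    oracle_translate(ce, f), "")))
  # frame 0 hits an immediate stop: empty novel tail is still emitted
  expect_equal(pep$aa_sequence[1], up)
  expect_true(is.na(pep$novel_tail_start[1]))
  expect_equal(pep$novel_tail_start[2], 3L)
})

test_that("peptide construction is strand-symmetric", {
  w <- toy_pep_world()
  L <- Biostrings::width(w$genome)[1]
  mirror <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(w$genome[[1]]))
  names(mirror) <- "chrT"
  gm <- toy_gene(gene_id = "pg", strand = "-",
                 exons = data.frame(start = L - c(26L, 6L),
                                    end = L - c(20L, 0L)),
                 cds = c(L - 26L, L))
  evm <- data.frame(gene_id = "pg", chrom = "chrT", strand = "-",
                    pos = L - 9L, ipa_type = 1L,
                    cryptic_start = NA_integer_,
                    cryptic_end = NA_integer_,
                    intron_start = L - 20L, intron_end = L - 6L,
                    upstream_exon_end = L - 6L)
  pep <- event_peptides(evm, gm, mirror)
  expect_equal(pep$aa_sequence, "MAK")
})

test_that("events without a CDS-bearing upstream transcript are skipped", {
  g <- toy_gene(gene_id = "nc", exons = data.frame(start = c(0L, 20L),
                                                   end = c(6L, 26L)))
  ev <- data.frame(gene_id = "nc", chrom = "chrT", strand = "+",
                   pos = 8L, ipa_type = 1L, cryptic_start = NA_integer_,
                   cryptic_end = NA_integer_, intron_start = 6L,
                   intron_end = 20L, upstream_exon_end = 6L)
  gen <- Biostrings::DNAStringSet(c(chrT = strrep("A", 100)))
  expect_warning(pep <- event_peptides(ev, g, gen), "no CDS")
  expect_equal(nrow(pep), 0L)
})

test_that("peptide FASTA round-trips and contains only standard residues", {
  sim <- fixture_sim()
  ev <- fixture_events()
  peps <- sample_peptides(ev, sim$annotation, sim$genome)
  expect_gt(nrow(peps), 0L)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps$aa_sequence)))
  fa <- tempfile(fileext = ".fa")
  write_peptides_fasta(peps, fa)
  back <- read_peptides_fasta(fa)
  expect_equal(back$aa_sequence, peps$aa_sequence)
  expect_equal(back$name,
               sprintf("%s|frame%d", peps$event_id, peps$frame))
  # record count: one per Type 1, up to three per Type 2
  n1 <- sum(ev$ipa_type == 1L); n2 <- sum(ev$ipa_type == 2L)
  expect_lte(nrow(peps), n1 + 3L * n2)
  expect_gte(nrow(peps), n1)
})
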