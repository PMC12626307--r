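# build a one-gene world with a hand-specified depth profile:
# exon [0,500) at depth c1_depth, intron [500,2500), exon [2500,3000)
profile_world <- function(intron_depths, c1_depth = 100L, strand = "+") {
  stopifnot(length(intron_depths) == 2000L)
  g <- toy_gene(strand = strand,
                exons = data.frame(start = c(0L, 2500L),
                                   end = c(500L, 3000L)))
  depths <- c(rep(c1_depth, 500L), as.integer(intron_depths),
              rep(c1_depth, 500L))
  cov <- cov_from_vectors(list(chrT = depths))
  list(g = g, cov = cov)
}

test_that("C1 is the mean over the merged exon union", {
  g <- toy_gene(exons = data.frame(start = c(0L, 20L),
                                   end = c(10L, 30L)))
  cov <- cov_from_vectors(list(chrT = c(rep(10L, 10), rep(0L, 10),
                                        rep(20L, 10))))
  expect_equal(compute_c1(g, cov), 15)
  empty <- cov_from_vectors(list(chrT = rep(0L, 30)))
  expect_equal(compute_c1(g, empty), 0)
  uni <- cov_from_vectors(list(chrT = rep(7L, 30)))
  expect_equal(compute_c1(g, uni), 7)
})

test_that("Type 1 calls require TR, C2 and downstream-drop thresholds", {
  # upstream stretch depth 40 for 1000 nt, then 2 -> TR 0.4 at c1=100
  w <- profile_world(c(rep(40L, 1000L), rep(2L, 1000L)))
  site <- toy_site(w$g, pos = 1499L)
  ev <- detect_type1(site, 100, w$cov)
  expect_equal(ev$ipa_type, 1L)
  expect_equal(ev$tr, 0.4)
  expect_equal(ev$c2, 40)

  # TR 0.15 < 0.2 is filtered out
  w2 <- profile_world(c(rep(15L, 1000L), rep(0L, 1000L)))
  expect_null(detect_type1(toy_site(w2$g, 1499L), 100, w2$cov))

  # C2 = 8 <= 10 is filtered regardless of TR
  w3 <- profile_world(c(rep(8L, 1000L), rep(0L, 1000L)))
  expect_null(detect_type1(toy_site(w3$g, 1499L), 20, w3$cov))

  # no downstream drop (fully retained intron) is not called
  w4 <- profile_world(rep(40L, 2000L))
  expect_null(detect_type1(toy_site(w4$g, 1499L), 100, w4$cov))
})

test_that("Type 1 detection is strand-symmetric", {
  w <- profile_world(rev(c(rep(40L, 1000L), rep(2L, 1000L))),
                     strand = "-")
  # minus strand: upstream stretch is the genomic right part
  ev <- detect_type1(toy_site(w$g, 1500L), 100, w$cov)
  expect_equal(ev$tr, 0.4)
})

test_that("cryptic exon boundary follows the 80%-of-C1 step rule", {
  # intron: 1 x 300nt, 90 x 200nt ending at the site, then low tail
  prof <- c(rep(1L, 300L), rep(90L, 200L), rep(1L, 1500L))
  w <- profile_world(prof)
  site <- toy_site(w$g, pos = 500L + 500L - 1L)  # block ends at pos 999
  ce <- find_cryptic_exon(site, 100, w$cov)
  expect_equal(ce, c(800L, 1000L))               # exactly the 200 nt block

  # uniform 0.5 * c1 never reaches 80%
  w2 <- profile_world(rep(50L, 2000L))
  expect_null(find_cryptic_exon(toy_site(w2$g, 999L), 100, w2$cov))

  # a block contiguous with the upstream exon fails the gap rule
  prof3 <- c(rep(90L, 500L), rep(1L, 1500L))
  w3 <- profile_world(prof3)
  expect_null(find_cryptic_exon(toy_site(w3$g, 999L), 100, w3$cov))
})

test_that("Type 2 calls carry cryptic bounds and allow TR above one", {
  prof <- c(rep(1L, 300L), rep(90L, 200L), rep(1L, 1500L))
  w <- profile_world(prof)
  site <- toy_site(w$g, pos = 999L)
  ev <- detect_type2(site, 100, w$cov)
  expect_equal(ev$ipa_type, 2L)
  expect_equal(ev$tr, 0.9)
  expect_equal(c(ev$cryptic_start, ev$cryptic_end), c(800L, 1000L))

  # TR may exceed 1 when the cryptic block outruns mean exon coverage
  ev2 <- detect_type2(site, 60, w$cov)
  expect_equal(ev2$tr, 1.5)

  # no qualifying block
  w2 <- profile_world(rep(2L, 2000L))
  expect_null(detect_type2(toy_site(w2$g, 999L), 100, w2$cov))
})

test_that("one event per intron: best TR wins, ties to most upstream", {
  # two valid Type 1 sites in one intron: TR 0.6 at 899, TR 0.425 at 1299
  prof <- c(rep(60L, 400L), rep(25L, 400L), rep(1L, 1200L))
  w <- profile_world(prof)
  catalog <- rbind(toy_site(w$g, 899L), toy_site(w$g, 1299L))
  class(catalog) <- c("ipa_catalog", "data.frame")
  expect_equal(detect_type1(toy_site(w$g, 1299L), 100, w$cov)$tr, 0.425)
  ev <- detect_sample(toy_annotation(w$g), catalog, w$cov)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pos, 899L)
  expect_equal(ev$tr, 0.6)

  # gene with no candidate sites yields nothing
  ev0 <- detect_sample(toy_annotation(w$g), catalog[0, ], w$cov)
  expect_equal(nrow(ev0), 0L)
})

test_that("all emitted events satisfy the TR and C2 filters", {
  ev <- fixture_events()
  expect_gt(nrow(ev), 0L)
  expect_true(all(ev$tr >= 0.2))
  expect_true(all(ev$c2 > 10))
  expect_true(all(abs(ev$tr - ev$c2 / ev$c1) < 1e-9))
  # type-2 events carry cryptic bounds inside their intron; type-1 none
  t2 <- ev[ev$ipa_type == 2L, ]
  expect_true(all(!is.na(t2$cryptic_start)))
  expect_true(all(t2$cryptic_start >= t2$intron_start &
                    t2$cryptic_end <= t2$intron_end))
  expect_true(all(is.na(ev$cryptic_start[ev$ipa_type == 1L])))
  # at most one event per intron
  expect_false(any(duplicated(paste(ev$gene_id, ev$intron_start))))
})

test_that("TR is invariant under uniform depth scaling while C2 scales", {
  sim <- fixture_sim()
  catalog <- fixture_catalog()
  ev <- fixture_events()
  k <- 3L
  scaled <- coverage_from_rle(sim$coverage$rle * k)
  ev_k <- detect_sample(sim$annotation, catalog, scaled)
  shared <- merge(as.data.frame(ev), as.data.frame(ev_k),
                  by = c("gene_id", "pos"))
  expect_gt(nrow(shared), 0.9 * nrow(ev))
  expect_equal(shared$tr.y, shared$tr.x, tolerance = 1e-9)
  expect_equal(shared$c2.y, k * shared$c2.x, tolerance = 1e-9)
})

test_that("planted events are recovered with the correct type and TR", {
  sim <- fixture_sim()
  ev <- fixture_events()
  rep <- evaluate_calls(ev, sim$truth)
  expect_gte(rep$sensitivity, 0.9)     # 20-event-scale spec floor is 18/20
  m <- rep$matching
  expect_true(all(sim$truth$type[m$truth_idx] ==
                    ev$ipa_type[m$call_idx]))
})

test_that("noiseless simulation recovers planted TR within discretization", {
  sim <- simulate_ipa_sample(sim_config(
    n_genes = 60L, n_type1 = 15L, n_type2 = 15L, n_decoys = 0L,
    depth = 100, noiseless = TRUE, seed = 77L))
  catalog <- build_catalog(sim$annotation, db_sites = data.frame(
    chrom = sim$sites$chrom, pos = sim$sites$pos,
    strand = sim$sites$strand))
  ev <- detect_sample(sim$annotation, catalog, sim$coverage)
  m <- evaluate_calls(ev, sim$truth)$matching
  expect_equal(nrow(m), nrow(sim$truth))
  expect_lt(max(abs(ev$tr[m$call_idx] -
                      sim$truth$planted_tr[m$truth_idx])), 0.02)
})
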