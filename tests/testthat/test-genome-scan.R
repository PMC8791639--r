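test_that("the free-energy track matches a naive per-position oracle", {
  m <- random_test_model(61, n_dinuc = 2)
  g <- random_dna(2000)
  tr <- energy_track(g, m)
  orc <- oracle_track(g, m)
  off <- min(orc, na.rm = TRUE)
  expect_equal(which(is.na(tr$F)), which(is.na(orc)))
  ok <- !is.na(orc)
  expect_lt(max(abs(tr$F[ok] - (orc[ok] - off))), 1e-9)
  expect_equal(min(tr$F, na.rm = TRUE), 0)
})

test_that("homopolymers give a flat zero track and circular mode wraps", {
  m <- demo_energy_model()
  tr <- energy_track(strrep("A", 200), m)
  # translation invariance holds wherever every spacer variant fits; the
  # few leading positions that only fit shorter spacers sit higher
  interior <- tr$F[35:200]
  expect_true(all(abs(interior) < 1e-12))
  expect_true(all(tr$F[!is.na(tr$F)] >= 0))
  trc <- energy_track(random_genome(300, 0.5, 3), m, circular = TRUE)
  expect_false(anyNA(trc$F))
  expect_error(energy_track(strrep("A", 20), m), "shorter")
})

test_that("a planted consensus site is the genome-wide minimum", {
  m <- demo_energy_model()
  g <- random_genome(5000, 0.5, seed = 5)
  cons <- consensus_sequence(m)
  substr(g, 2001, 2000 + nchar(cons)) <- cons
  tr <- energy_track(g, m)
  expect_equal(which.min(tr$F), 2000 + nchar(cons))  # its -10 end
})

test_that("reverse-strand inclusion only strengthens the track", {
  m <- random_test_model(62, n_dinuc = 0)
  g <- random_dna(800)
  f_only <- energy_track(g, m)
  both <- energy_track(g, m, include_rc = TRUE)
  ok <- !is.na(f_only$raw) & !is.na(both$raw)
  expect_true(all(both$raw[ok] <= f_only$raw[ok] + 1e-12))
})

test_that("annotation partition masks follow the exclusion rules", {
  ann <- data.frame(type = c("gene", "CDS", "tRNA"),
                    start = c(1, 11, 151), end = c(50, 60, 160))
  g <- random_genome(100, 0.5, 7)
  pr <- partition_regions(ann[1:2, ], 100, genome = g)
  expect_equal(mean(pr$within_genes), 0.6)
  expect_equal(mean(pr$intergenic), 0.4)
  expect_true(all(!(pr$within_genes & pr$intergenic)))
  # a tRNA feature removes positions from the inter-genic class without
  # making them genic
  pr2 <- partition_regions(ann, 200)
  expect_true(all(!pr2$intergenic[151:160]))
  expect_true(all(!pr2$within_genes[151:160]))
  # no annotation: everything inter-genic
  pr3 <- partition_regions(ann[0, ], 50)
  expect_true(all(pr3$intergenic))
  expect_equal(pr3$summary$fraction, c(0, 1))
})

test_that("GC-null depletion p-values behave at the boundaries", {
  m <- demo_energy_model()
  g <- random_genome(60000, 0.5, seed = 9)
  tr <- energy_track(g, m)
  mask <- rep(FALSE, 60000); mask[1:20000] <- TRUE
  dep <- depletion_test_gc_null(tr, mask, gc = 0.5, m,
                                synthetic_length = 60000, seed = 10)
  expect_true(all(dep$p_value >= 0 & dep$p_value <= 1))
  # an i.i.d. region matched to its own null is not depleted
  expect_lte(mean(dep$p_value < 0.05), 0.10)
  # empty bins on both sides: Poisson mass at 0 with mean 0 is 1
  dep0 <- depletion_test_gc_null(tr, mask, gc = 0.5, m,
                                 synthetic_length = 60000,
                                 bin_edges = c(-1), seed = 11)
  expect_equal(dep0$p_value, 1)
  expect_error(depletion_test_gc_null(tr, rep(FALSE, 60000), 0.5, m),
               "empty region")
  # a region purged of strong sites is strongly depleted in the low bins
  purge <- tr$F > 6 & !is.na(tr$F)
  dep2 <- depletion_test_gc_null(tr, purge, gc = 0.5, m,
                                 synthetic_length = 60000,
                                 bin_edges = c(3, 4, 5), seed = 12)
  expect_true(all(dep2$observed == 0))
  expect_true(all(dep2$p_value < 0.05))
})

test_that("shuffled-matrix nulls preserve column structure", {
  m <- demo_energy_model()
  g <- random_genome(5000, 0.5, seed = 13)
  # identity permutation reproduces the real model exactly
  ident <- thermoprom:::shuffle_model_columns(m, 1:24)
  tr1 <- energy_track(g, m)
  tr2 <- energy_track(g, ident)
  expect_equal(tr1$raw, tr2$raw)
  # column-constant matrix: every permutation gives the same track
  mc <- m
  mc$upstream[] <- rep(c(0, 1, 2, 3), 12)
  mc$downstream[] <- rep(c(0, 1, 2, 3), 12)
  dsh <- depletion_test_shuffled(g, mc, n_shuffles = 5, seed = 14)
  expect_true(all(dsh$shuffle_sd == 0))
  expect_equal(dsh$observed, dsh$shuffle_mean)
  # random genome, real model: observed counts sit inside the band
  # (full-scale calibration runs in the acceptance suite)
  g2 <- random_genome(20000, 0.5, seed = 17)
  dsh2 <- depletion_test_shuffled(g2, m, n_shuffles = 30,
                                  bin_edges = seq(2, 8, by = 0.5), seed = 15)
  inband <- dsh2$observed >= dsh2$band_lo & dsh2$observed <= dsh2$band_hi
  expect_gte(mean(inband), 0.7)
})

test_that("promoter free energies integrate the window Boltzmann sum", {
  m <- demo_energy_model()
  g <- random_genome(3000, 0.5, seed = 16)
  cons <- consensus_sequence(m)
  substr(g, 1501, 1500 + nchar(cons)) <- cons
  tr <- energy_track(g, m)
  pf <- promoter_free_energy(tr, anchors = c(1520, 800, 40), window = 40)
  # direct summation oracle over the window
  direct <- function(a) {
    idx <- (a - 20):(a + 19)
    idx <- idx[idx >= 1 & idx <= tr$length]
    v <- tr$F[idx]; v <- v[!is.na(v)]
    -log(sum(exp(-v)))
  }
  expect_equal(pf$free_energy, vapply(c(1520, 800, 40), direct, 0),
               tolerance = 1e-9)
  # the window holding the planted strong site is dominated by it
  site <- tr$F[1500 + nchar(cons)]
  expect_lt(abs(pf$free_energy[1] - site), 0.05)
  expect_true(pf$truncated[3])
  expect_false(pf$truncated[1])
  # disjoint windows on a homopolymer are identical
  trh <- energy_track(strrep("A", 400), m)
  pfh <- promoter_free_energy(trh, anchors = c(100, 300), window = 40)
  expect_equal(pfh$free_energy[1], pfh$free_energy[2])
})
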