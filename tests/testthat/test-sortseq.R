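make_lib <- function(counts, sequences = NULL, reference = NULL, ...) {
  counts <- as.matrix(counts)
  if (is.null(sequences))
    sequences <- vapply(seq_len(nrow(counts)), function(i)
      random_dna(40), "")
  sortseq_library(sequences, counts, reference = reference, ...)
}

test_that("filter rules act as pure predicates with attrition accounting", {
  set.seed(11)
  counts <- rbind(c(10, 10, 9, 0),    # coverage 29: fails threshold 30
                  c(10, 10, 10, 0),   # coverage 30: passes
                  c(40, 0, 40, 0),    # ambiguous gap distribution
                  c(5, 30, 30, 0))    # passes everything
  lib <- make_lib(counts)
  res <- filter_library(lib, rules = list(coverage_min = 30,
                                          bin_ambiguity = list(threshold = 0.1)))
  expect_equal(length(res$library), 2L)
  expect_equal(res$attrition$count[res$attrition$rule == "coverage_min"], 1)
  expect_equal(res$attrition$count[res$attrition$rule == "bin_ambiguity"], 1)
  expect_equal(res$attrition$count[res$attrition$rule == "retained"], 2)
  # retained set is rule-order independent
  res2 <- filter_library(lib, rules = list(bin_ambiguity = list(threshold = 0.1),
                                           coverage_min = 30))
  expect_setequal(res$library$sequences, res2$library$sequences)
  # passing records are unchanged
  kept <- match(res$library$sequences, lib$sequences)
  expect_identical(res$library$counts, lib$counts[kept, ])
  expect_error(filter_library(lib, rules = list(nope = 1)), "unknown")
})

test_that("random-core length and flank-similarity rules apply in 36N mode", {
  spec <- random36_library_spec(size = 5)
  tab <- generate_library(spec, seed = 12)
  good <- tab$sequence
  bad_len <- paste0(substr(good[1], 1, 32), strrep("A", 39),
                    substr(good[1], 69, 100))  # 39-bp core
  bad_flank <- paste0(random_dna(32), substr(good[2], 33, 100))
  lib <- make_lib(matrix(20, length(good) + 2, 2),
                  sequences = c(good, bad_len, bad_flank))
  res <- filter_library(lib, rules = list(
    flanks = list(flank5 = spec$flank5, flank3 = spec$flank3,
                  min_similarity = 0.75, core_target = 36L, core_tol = 2L)))
  expect_true(all(good %in% res$library$sequences))
  expect_false(bad_len %in% res$library$sequences)
  expect_false(bad_flank %in% res$library$sequences)
})

test_that("ancestor-distance and RBS-position rules filter local libraries", {
  wt <- synthetic_wildtype()
  near <- wt$bases
  substr(near, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(wt$bases, 5, 5))[1]
  far <- paste0(paste(rev(strsplit(substr(wt$bases, 1, 50), "")[[1]]),
                      collapse = ""), substr(wt$bases, 51, 100))
  norbs <- gsub("AGGAG", "ACCAG", wt$bases, fixed = TRUE)
  lib <- make_lib(matrix(50, 4, 2),
                  sequences = c(wt$bases, near, far, norbs),
                  rbs_start = wt$rbs_start)
  res <- filter_library(lib, rules = list(
    ancestor = list(sequence = wt$bases, max_frac = 0.25),
    rbs = list(motif = "AGGAG", position = wt$rbs_start)))
  expect_setequal(res$library$sequences, c(wt$bases, near))
})

test_that("bin-ambiguity filter drops gap distributions only", {
  expect_true(bin_ambiguity_filter(c(50, 50, 0, 0)))
  expect_false(bin_ambiguity_filter(c(50, 0, 50, 0)))
  expect_true(bin_ambiguity_filter(c(100, 0, 0, 0)))
  # mass below the threshold on one side does not trigger the rule
  expect_true(bin_ambiguity_filter(c(95, 0, 5, 0), threshold = 0.1))
})

test_that("spike-in debiasing follows the ratio formula", {
  # two bins: reference (1, 2), raw (2, 2) -> (2/1, 2/2) renormalized
  lib <- make_lib(rbind(c(2, 2)), reference = list(sequence = "ACGT",
                                                   counts = c(1, 2)))
  out <- debias_12bin(lib)
  expect_equal(unname(out$probs[1, ]), c(2 / 3, 1 / 3))
  # uniform reference: debiasing equals plain normalization (idempotent)
  lib2 <- make_lib(rbind(c(3, 9), c(5, 5)),
                   reference = list(sequence = "ACGT", counts = c(7, 7)))
  out2 <- debias_12bin(lib2)
  expect_equal(out2$probs, lib2$counts / rowSums(lib2$counts),
               tolerance = 1e-12)
  out2b <- debias_12bin(out2)
  expect_equal(out2b$probs, out2$probs)
  # zero-reference bins are unobservable and excluded
  lib3 <- make_lib(rbind(c(4, 4, 2)),
                   reference = list(sequence = "ACGT", counts = c(2, 0, 2)))
  out3 <- debias_12bin(lib3)
  expect_equal(unname(out3$probs[1, ]), c(2 / 3, 0, 1 / 3))
  expect_equal(out3$meta$unobservable_bins, 2L)
  expect_error(debias_12bin(make_lib(rbind(c(1, 1)))), "reference")
})

test_that("mode templates nullify stray outlier mass", {
  B <- 12
  # 30 sequences concentrated at bin 10, one with a stray count in bin 1
  probs <- matrix(0, 31, B)
  probs[, 10] <- 0.8; probs[, 11] <- 0.2
  probs[31, ] <- c(0, 0.3, 0, 0, 0, 0, 0, 0, 0, 0.6, 0.1, 0)
  lib <- make_lib(matrix(100, 31, B))
  lib$probs <- probs
  out <- template_filter(lib, min_members = 10)
  expect_equal(unname(out$probs[31, 2]), 0)          # stray mass removed
  expect_equal(rowSums(out$probs), rep(1, 31))
  expect_equal(out$probs[1, ], probs[1, ])           # in-support unchanged
})

test_that("expression estimates follow the bin-index and facs formulas", {
  expect_equal(estimate_expression(c(10, 0, 0, 0))$eps_bin, 0)
  expect_equal(estimate_expression(rep(1, 12))$eps_bin, 5.5)
  # geometric bin medians make eps_facs affine in eps_bin
  m_i <- 10^seq(0.5, 6, by = 0.5)
  a <- matrix(stats::runif(60), 5, 12)
  lib <- make_lib(a, rbs_start = NA)
  lib$probs <- a / rowSums(a)
  est <- estimate_expression(lib, bin_medians = m_i)
  fit <- stats::lm(est$eps_facs ~ est$eps_bin)
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-9)
  # missing medians: eps_facs NA, eps_bin still present
  est2 <- estimate_expression(lib)
  expect_true(all(is.na(est2$eps_facs)) && all(is.finite(est2$eps_bin)))
})

test_that("mapping scores are 1 for identity and degrade with distance", {
  ref <- random_dna(30)
  expect_equal(mapping_score(ref, ref), 1, tolerance = 1e-5)
  mut <- ref
  substr(mut, 4, 9) <- strrep("A", 6)
  expect_lt(mapping_score(mut, ref), 1)
  expect_gt(mapping_score(mut, ref), 0.5)
  expect_lt(mapping_score(random_dna(30), ref), 0.75)
})

test_that("count tables round-trip through TSV", {
  lib <- make_lib(matrix(rpois(40, 20), 10, 4),
                  reference = list(sequence = "ACGTACGT",
                                   counts = c(5, 6, 7, 8)))
  f <- tempfile(fileext = ".tsv")
  write_sortseq_tsv(lib, f)
  lib2 <- read_sortseq_tsv(f)
  expect_equal(lib2$sequences, lib$sequences)
  expect_equal(unname(lib2$counts), unname(lib$counts))
  expect_equal(lib2$reference$counts, lib$reference$counts)
})
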