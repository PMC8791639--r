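test_that("the candidate enumeration matches the screening-scan layout", {
  m <- demo_energy_model()
  cands <- dinuc_candidates(m)
  expect_equal(nrow(cands), choose(24, 2) * 16)  # 4416
  expect_true(all(cands$pos_i < cands$pos_j))
  # the analytic screening score at a candidate equals the numerical
  # derivative of the log-likelihood in that candidate's interaction
  # energy at zero (same candidate ordering)
  lib <- local({
    tab <- generate_library(library_spec("local",
                                         wildtype = synthetic_wildtype(),
                                         size = 120), seed = 31)
    simulate_sortseq(tab, sortsim_spec(m, default_gates(4)), seed = 32)
  })
  data <- thermoprom:::fit_data(lib)
  x <- thermoprom:::model_loglik(data, m, list(a = rep(0, 4), b = rep(0, 4)),
                                 extended_features())$x
  link <- fit_logistic(x, data$y, data$wgt, B = 4)
  fl <- thermoprom:::feature_flags(m, extended_features())
  dn <- thermoprom:::dinuc_cpp(m)
  score <- thermoprom:::cpp_dinuc_score(
    data$codes, data$rbs, m$upstream, m$downstream,
    as.integer(names(m$spacer_penalties)), unname(m$spacer_penalties),
    dn$pos, dn$de, m$mu, fl$R, m$rbs_occlusion_cutoff, fl$use_spen,
    fl$use_occl, fl$use_rc, fl$use_dinuc, data$y, data$wgt, link$a, link$b)
  expect_equal(length(score), nrow(cands))
  set.seed(33)
  for (ci in sample.int(nrow(cands), 4)) {
    row <- cands[ci, ]
    eps <- 1e-5
    ll_at <- function(d) {
      m2 <- m
      m2$dinucleotides <- rbind(m2$dinucleotides,
                                data.frame(row, delta_e = d))
      thermoprom:::model_loglik(data, m2, link, extended_features())$ll
    }
    num <- (ll_at(eps) - ll_at(-eps)) / (2 * eps)
    expect_equal(score[ci], num, tolerance = 1e-4)
  }
})

test_that("the fast single-interaction profile equals the full likelihood", {
  m <- demo_energy_model()
  lib <- local({
    tab <- generate_library(library_spec("local",
                                         wildtype = synthetic_wildtype(),
                                         size = 100), seed = 41)
    simulate_sortseq(tab, sortsim_spec(m, default_gates(4)), seed = 42)
  })
  data <- thermoprom:::fit_data(lib)
  x <- thermoprom:::model_loglik(data, m, list(a = rep(0, 4), b = rep(0, 4)),
                                 extended_features())$x
  link <- fit_logistic(x, data$y, data$wgt, B = 4)
  fl <- thermoprom:::feature_flags(m, extended_features())
  dn <- thermoprom:::dinuc_cpp(m)
  row <- data.frame(pos_i = 4L, base_i = "T", pos_j = 18L, base_j = "A")
  ex <- thermoprom:::cpp_dinuc_extract(
    data$codes, data$rbs, m$upstream, m$downstream,
    as.integer(names(m$spacer_penalties)), unname(m$spacer_penalties),
    dn$pos, dn$de, m$mu, fl$R, m$rbs_occlusion_cutoff, fl$use_spen,
    fl$use_occl, fl$use_rc, fl$use_dinuc,
    row$pos_i - 1L, 3L, row$pos_j - 1L, 0L)
  for (d in c(-0.4, 0, 0.25)) {
    fast <- thermoprom:::cpp_dinuc_ll(ex$S_on, ex$S_np, ex$m_seq, ex$m_t,
                                      ex$m_on, d, fl$R, data$y, data$wgt,
                                      link$a, link$b)
    m2 <- m
    m2$dinucleotides <- rbind(m2$dinucleotides,
                              data.frame(row, delta_e = d))
    full <- thermoprom:::model_loglik(data, m2, link,
                                      extended_features())$ll
    expect_equal(fast, full, tolerance = 1e-8)
  }
})

test_that("a zero-interaction ground truth yields an empty accepted set", {
  truth <- demo_energy_model()   # no dinucleotide terms planted
  tab <- generate_library(library_spec("local",
                                       wildtype = synthetic_wildtype(),
                                       size = 1200), seed = 51)
  lib <- simulate_sortseq(tab, sortsim_spec(truth, default_gates(4)),
                          seed = 52)
  sp <- split_library(lib, seed = 53)
  sel <- select_dinucleotides(sp$training, sp$validation, truth,
                              seed = 54)
  expect_lte(nrow(sel), 1L)
  expect_true(all(c("candidates", "stage1") %in%
                    names(attr(sel, "funnel"))))
})

test_that("stage-1 grid profiles equal full-likelihood evaluation", {
  m <- demo_energy_model()
  tab <- generate_library(library_spec("local",
                                       wildtype = synthetic_wildtype(),
                                       size = 150), seed = 61)
  lib <- simulate_sortseq(tab, sortsim_spec(m, default_gates(4)), seed = 62)
  data <- thermoprom:::fit_data(lib)
  feats <- setdiff(extended_features(), c("clearance", "dinucleotides"))
  x <- thermoprom:::model_loglik(data, m, list(a = rep(0, 4), b = rep(0, 4)),
                                 feats)$x
  link <- fit_logistic(x, data$y, data$wgt, B = 4)
  fl <- thermoprom:::feature_flags(m, c(feats, "dinucleotides"))
  dn <- thermoprom:::dinuc_cpp(m)
  pe <- thermoprom:::cpp_prune_extract(
    data$codes, data$rbs, m$upstream, m$downstream,
    as.integer(names(m$spacer_penalties)), unname(m$spacer_penalties),
    dn$pos, dn$de, m$mu, fl$R, m$rbs_occlusion_cutoff, fl$use_spen,
    fl$use_occl, fl$use_rc, fl$use_dinuc, 1e-9)
  grid <- c(-0.3, 0.2)
  dll <- thermoprom:::cpp_stage1_grid(pe$S_on, pe$S_np, pe$t, pe$on, pe$seq,
                                      pe$contacts, data$y, data$wgt,
                                      link$a, link$b, fl$R, grid)
  cands <- dinuc_candidates(m)
  ll0 <- thermoprom:::model_loglik(data, m, link, feats)$ll
  set.seed(63)
  for (ci in sample.int(nrow(cands), 5)) {
    for (gi in 1:2) {
      m2 <- m
      m2$dinucleotides <- data.frame(cands[ci, ], delta_e = grid[gi])
      full <- thermoprom:::model_loglik(data, m2, link,
                                        c(feats, "dinucleotides"))$ll - ll0
      expect_lt(abs(dll[ci, gi] - full), 1e-6)
    }
  }
})
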