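test_that("Kimura fixation has the right limits and tails", {
  # neutral limit: 1/(2N)
  expect_equal(kimura_fixation(0, 100, 100), 1 / 200)
  expect_equal(kimura_fixation(1e-16, 100, 250), 1 / 500, tolerance = 1e-6)
  # N = 1 reduces algebraically to the logistic 1/(1 + exp(-2 s dphi))
  for (d in c(-0.5, -0.01, 0.02, 1)) {
    expect_equal(kimura_fixation(d, 3, 1), 1 / (1 + exp(-2 * 3 * d)),
                 tolerance = 1e-12)
  }
  # deleterious mutations fix less often than neutral ones
  expect_lt(kimura_fixation(-0.01, 100, 100), 1 / 200)
  # extreme effects neither overflow nor leave [0, 1]
  expect_equal(kimura_fixation(-50, 100, 1000), 0)
  expect_equal(kimura_fixation(50, 100, 1000), 1, tolerance = 1e-8)
  expect_true(all(kimura_fixation(seq(-5, 5, by = 0.25), 100, 100) >= 0))
})

test_that("neutral proposals fix at rate 1/(2N)", {
  # a mutable region with a constant phenotype map: every proposal is
  # neutral, so the long-run fixation fraction is 1/(2N)
  m <- tiny_model(e_by_base_up = c(A = 0, C = 0, G = 0, T = 0),
                  e_by_base_dn = c(A = 0, C = 0, G = 0, T = 0), mu = -3)
  spec <- evolution_spec(m, "extended", s = 100, N_pop = 20,
                         threshold = 10,   # unreachable
                         seq_length = 30L, max_steps = 4000L)
  run <- evolve(spec, random_dna(30), seed = 17)
  expect_true(run$censored)
  p_hat <- nrow(run$mutations) / run$exit_time
  p0 <- 1 / (2 * 20)
  se <- sqrt(p0 * (1 - p0) / run$exit_time)
  expect_lt(abs(p_hat - p0), 3 * se)
})

test_that("evolution runs stop, censor and record consistently", {
  m <- demo_energy_model()
  spec <- evolution_spec(m, "extended", threshold = -5.5, N_pop = 50,
                         seq_length = 115L)
  starts <- random_nonexpressing_starts(2, 115, list(spec), seed = 19)
  # threshold below the start's phenotype: immediate exit
  lo_spec <- evolution_spec(m, "extended", threshold = -50, N_pop = 50,
                            seq_length = 115L)
  run0 <- evolve(lo_spec, starts[1], seed = 20)
  expect_equal(run0$exit_time, 0L)
  expect_equal(nrow(run0$mutations), 0L)
  # a frozen mutable region censors at max_steps
  frozen <- evolution_spec(m, "extended", threshold = -2, N_pop = 10,
                           seq_length = 115L, mutable_length = 0L)
  runf <- evolve(frozen, starts[1], seed = 21)
  expect_true(runf$censored)
  expect_equal(runf$exit_time, frozen$max_steps)
  # trajectory bookkeeping: final phi re-derives from the final sequence
  run <- evolve(spec, starts[2], seed = 22)
  expect_equal(run$final_phi,
               log10_pon(run$final_sequence, m, mode = "extended"),
               tolerance = 1e-12)
  nm <- sum(strsplit(run$final_sequence, "")[[1]] !=
              strsplit(starts[2], "")[[1]])
  expect_lte(nm, nrow(run$mutations))  # back-mutations may cancel
  # determinism under the seed
  run2 <- evolve(spec, starts[2], seed = 22)
  expect_identical(run$mutations, run2$mutations)
})

test_that("mean exit times match an absorbing-Markov-chain oracle", {
  # single-site toy landscape: a 2-bp sequence under the minimal
  # footprint model is one configuration whose phenotype is additive in
  # its two contact residues; SSWM over the 16 sequence states is a
  # finite Markov chain whose mean absorption times solve (I-Q)t = 1
  up <- c(A = 0, C = 0.8, G = 1.6, T = 2.4)
  dn <- c(A = 0, C = 0.6, G = 1.2, T = 1.8)
  m <- tiny_model(e_by_base_up = up, e_by_base_dn = dn,
                  spacer = c("0" = 0), mu = -2)
  s_sel <- 400; N <- 40
  phi_of <- function(b1, b2) {
    # single forward site; rc states exist but are part of the same
    # phenotype map used by both the chain and the simulator
    log10_pon(paste0(b1, b2), m, mode = "extended")
  }
  bases <- c("A", "C", "G", "T")
  states <- expand.grid(b1 = bases, b2 = bases, stringsAsFactors = FALSE)
  phis <- mapply(phi_of, states$b1, states$b2)
  thr <- max(phis) - 1e-9   # absorb at the optimal sequence (phi max)
  absorbing <- phis >= thr
  n <- nrow(states)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (absorbing[i]) next
    for (pos in 1:2) {
      cur <- states[i, pos]
      for (alt in setdiff(bases, cur)) {
        j <- which(states$b1 == (if (pos == 1) alt else states$b1[i]) &
                   states$b2 == (if (pos == 2) alt else states$b2[i]))
        # proposal prob (1/2 position * 1/3 base) times fixation prob
        P[i, j] <- P[i, j] + (1 / 6) *
          kimura_fixation(phis[j] - phis[i], s_sel, N)
      }
    }
    P[i, i] <- 1 - sum(P[i, ])
  }
  Q <- P[!absorbing, !absorbing, drop = FALSE]
  t_exact <- solve(diag(nrow(Q)) - Q, rep(1, nrow(Q)))
  # simulate from the worst state and compare
  worst <- which.min(phis)
  spec <- evolution_spec(m, "extended", s = s_sel, N_pop = N,
                         threshold = thr, seq_length = 2L,
                         max_steps = 100000L)
  set.seed(23)
  sims <- vapply(1:200, function(r)
    evolve(spec, paste0(states$b1[worst], states$b2[worst]),
           seed = 1000 + r)$exit_time, 0)
  idx <- match(worst, which(!absorbing))
  se <- stats::sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - t_exact[idx]), 3 * se + 1)
})

test_that("batch summaries are reproducible and threshold-ordered", {
  m <- demo_energy_model()
  se <- evolution_spec(m, "extended", threshold = -5.5, N_pop = 30,
                       seq_length = 115L)
  ss <- evolution_spec(m, "standard", threshold = -5.5, N_pop = 30,
                       seq_length = 115L)
  starts <- random_nonexpressing_starts(3, 115, list(se, ss), seed = 29)
  b1 <- batch_evolve(list(standard = ss, extended = se), starts,
                     runs_per_start = 3, seed = 31)
  b2 <- batch_evolve(list(standard = ss, extended = se), starts,
                     runs_per_start = 3, seed = 31)
  expect_identical(b1$runs, b2$runs)
  expect_equal(nrow(b1$summary), 6)
  expect_true(all(c("mean_exit", "se_exit", "censored_fraction") %in%
                    names(b1$summary)))
})
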