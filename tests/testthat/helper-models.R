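# Random fixture models and sequences used across the suite.

random_dna <- function(L) paste(sample(BASES4, L, replace = TRUE),
                                collapse = "")

# A random energy model with consensus structure: every column has one
# zero (strongest) residue and random positive penalties elsewhere.
random_test_model <- function(seed, n_dinuc = 2L, R = 0.3, mu = NULL) {
  set.seed(seed)
  rand_block <- function(L) {
    M <- matrix(stats::runif(4 * L, 0.2, 3), 4, L)
    M <- sweep(M, 2, apply(M, 2, min))
    rownames(M) <- BASES4
    M
  }
  sp <- stats::runif(5, 0, 2.5); sp[3] <- 0; names(sp) <- 7:11
  dn <- if (n_dinuc > 0) {
    cand <- dinuc_candidates(list(upstream = matrix(0, 4, 12),
                                  downstream = matrix(0, 4, 12)))
    pick <- cand[sample.int(nrow(cand), n_dinuc), ]
    pick$delta_e <- stats::runif(n_dinuc, -0.4, 0.4)
    pick
  } else empty_dinucleotides()
  energy_model(rand_block(12), rand_block(12), sp, dinucleotides = dn,
               mu = if (is.null(mu)) stats::runif(1, -8, -2) else mu,
               clearance_rate = R)
}

# Minimal single-contact geometry: one upstream and one downstream
# contact with a single spacer length, so short sequences have exactly
# one configuration per strand.
tiny_model <- function(e_by_base_up = c(A = 0, C = 1, G = 2, T = 3),
                       e_by_base_dn = c(A = 0, C = 2, G = 1, T = 3),
                       spacer = c("1" = 0), mu = 0, R = 0) {
  energy_model(matrix(e_by_base_up, 4, 1,
                      dimnames = list(BASES4, NULL)),
               matrix(e_by_base_dn, 4, 1,
                      dimnames = list(BASES4, NULL)),
               spacer, mu = mu, clearance_rate = R)
}
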