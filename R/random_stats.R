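#' Expression statistics of random sequences
#'
#' Samples uniform random sequences and reports, under a given model and
#' measurable-expression cutoff (in log10 P_on): the fraction of
#' sequences with measurable expression under the Extended and Standard
#' models, the fraction of non-expressing sequences rescued by at least
#' one point mutation (the best single mutant crosses the cutoff), and
#' the overall fraction of all possible point mutations that rescue.
#'
#' @param model an `energy_model`.
#' @param cutoff measurable-expression cutoff in log10 P_on.
#' @param n number of random sequences (default 1e5).
#' @param length sequence length (default 115 bp, a typical inter-genic
#'   region).
#' @param mutants_n number of non-expressing sequences subsampled for the
#'   exhaustive point-mutant scan (default 300).
#' @param seed RNG seed.
#' @return list with `fraction_expressing_extended`,
#'   `fraction_expressing_standard`, `rescued_fraction`,
#'   `rescuing_mutation_fraction`, and the sample sizes used.
#' @export
random_sequence_stats <- function(model, cutoff, n = 1e5, length = 115L,
                                  mutants_n = 300L, seed = 1L) {
  set.seed(seed)
  codes <- lapply(seq_len(n), function(i)
    sample.int(4L, length, replace = TRUE) - 1L)
  batch_x <- function(cl, mode) {
    fl <- if (mode == "extended") feature_flags(model, extended_features())
          else list(sum_mode = FALSE, use_spen = FALSE, use_occl = FALSE,
                    use_rc = FALSE, use_dinuc = FALSE, R = 0)
    dn <- dinuc_cpp(model)
    cpp_log10_pon(cl, rep(-1L, length(cl)), model$upstream, model$downstream,
                  as.integer(names(model$spacer_penalties)),
                  unname(model$spacer_penalties), dn$pos, dn$de, model$mu,
                  fl$R, model$rbs_occlusion_cutoff, fl$sum_mode, fl$use_spen,
                  fl$use_occl, fl$use_rc, fl$use_dinuc)
  }
  x_ext <- batch_x(codes, "extended")
  x_std <- batch_x(codes, "standard")
  nonexp <- which(x_ext < cutoff)
  pick <- nonexp[seq_len(min(mutants_n, length(nonexp)))]
  rescued <- logical(length(pick))
  resc_frac <- numeric(length(pick))
  for (k in seq_along(pick)) {
    cs <- codes[[pick[k]]]
    muts <- vector("list", 3L * length)
    idx <- 0L
    for (p in seq_len(length)) {
      for (bb in setdiff(0:3, cs[p])) {
        idx <- idx + 1L
        m <- cs; m[p] <- bb
        muts[[idx]] <- m
      }
    }
    xm <- batch_x(muts, "extended")
    rescued[k] <- any(xm >= cutoff)
    resc_frac[k] <- mean(xm >= cutoff)
  }
  list(fraction_expressing_extended = mean(x_ext >= cutoff),
       fraction_expressing_standard = mean(x_std >= cutoff),
       rescued_fraction = mean(rescued),
       rescuing_mutation_fraction = mean(resc_frac),
       n_sequences = n, n_mutant_scans = length(pick))
}
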