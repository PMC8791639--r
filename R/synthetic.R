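#' Synthetic wildtype promoter construct
#'
#' A fully synthetic 100-bp reporter construct used as the default
#' wildtype for local mutant libraries: a 67-bp promoter region carrying
#' one strong near-consensus sigma70 site (upstream block at positions
#' 30-41, 9-bp spacer, downstream block at 51-62), followed by a fixed
#' 28-bp untranslated leader and the AGGAG Shine-Dalgarno sequence, so
#' that the RBS starts 28 bp downstream of the -10 end of the strongest
#' site. The background is a fixed arbitrary sequence; nothing in it is
#' derived from any natural promoter.
#'
#' @param model the `energy_model` whose consensus is planted.
#' @return a `promoter_sequence` with `rbs_start = 91` and an attribute
#'   `mutable_region = c(1, 67)`.
#' @export
synthetic_wildtype <- function(model = demo_energy_model()) {
  # fixed arbitrary background; part of the construct definition
  bg <- with_fixed_seed(20260101, sample(DNA_BASES, 120, replace = TRUE))
  cons <- strsplit(consensus_sequence(model), "")[[1]]
  ch <- bg[1:100]
  ch[30:62] <- cons  # 12 + 9 + 12 footprint, -10 end at 62
  ch[63:90] <- bg[63:90]
  ch[91:95] <- c("A", "G", "G", "A", "G")
  ch[96:100] <- c("C", "A", "T", "C", "C")
  ps <- promoter_sequence(paste(ch, collapse = ""), id = "synthetic_wt",
                          rbs_start = 91L)
  attr(ps, "mutable_region") <- c(1L, 67L)
  ps
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a mutant library
#'
#' Local-mutant mode draws sequences around a wildtype with a per-position
#' total mutation rate (each of the three non-wildtype bases equally
#' likely); fully-random mode draws a uniform random core of fixed length
#' between fixed flanks.
#'
#' @param mode `"local"` or `"random"`.
#' @param wildtype `promoter_sequence` (local mode).
#' @param mutation_rate per-position total mutation rate (default 0.12,
#'   i.e. each alternative base at rate 0.04; use 0.09 for a P_L-like
#'   library).
#' @param mutable_region integer range mutated in local mode (defaults to
#'   the wildtype's `mutable_region` attribute, else the whole sequence).
#' @param core_length random-core length (random mode, default 36).
#' @param flank5,flank3 fixed flanking sequences (random mode).
#' @param rbs_start RBS position of the assembled random-mode construct.
#' @param size number of library members to draw.
#' @return a `library_spec` list.
#' @export
library_spec <- function(mode = c("local", "random"), wildtype = NULL,
                         mutation_rate = 0.12, mutable_region = NULL,
                         core_length = 36L, flank5 = NULL, flank3 = NULL,
                         rbs_start = NA_integer_, size = 10000L) {
  mode <- match.arg(mode)
  if (mode == "local") {
    if (is.null(wildtype)) wildtype <- synthetic_wildtype()
    if (is.null(mutable_region)) {
      mutable_region <- attr(wildtype, "mutable_region")
      if (is.null(mutable_region)) mutable_region <- c(1L, nchar(wildtype$bases))
    }
    rbs_start <- wildtype$rbs_start
  }
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  structure(list(mode = mode, wildtype = wildtype,
                 mutation_rate = mutation_rate,
                 mutable_region = mutable_region,
                 core_length = as.integer(core_length),
                 flank5 = flank5, flank3 = flank3,
                 rbs_start = as.integer(rbs_start),
                 size = as.integer(size)),
            class = "library_spec")
}

#' Default fully-random (36N-like) library specification
#'
#' A uniform random 36-bp core between two fixed, arbitrary,
#' non-expressing 32-bp flanks, with the reporter RBS downstream.
#'
#' @param size library size.
#' @return a `library_spec`.
#' @export
random36_library_spec <- function(size = 10000L) {
  # fixed arbitrary flanks; part of the construct definition
  fl <- with_fixed_seed(20260102, sample(DNA_BASES, 59, TRUE))
  f5 <- paste(fl[1:32], collapse = "")
  f3core <- paste(fl[33:59], collapse = "")
  f3 <- paste0(f3core, "AGGAG")  # RBS at the end of the 3' flank
  library_spec(mode = "random", core_length = 36L, flank5 = f5, flank3 = f3,
               rbs_start = 32L + 36L + 28L, size = size)
}

#' Draw a mutant library
#'
#' @param spec a [library_spec()].
#' @param seed RNG seed.
#' @return data frame with columns `sequence` and `multiplicity`
#'   (duplicates collapsed), with attributes `rbs_start` and (local mode)
#'   `wildtype`.
#' @export
generate_library <- function(spec, seed = 1L) {
  set.seed(seed)
  n <- spec$size
  if (spec$mode == "local") {
    wt <- strsplit(spec$wildtype$bases, "")[[1]]
    L <- length(wt)
    reg <- spec$mutable_region[1]:spec$mutable_region[2]
    seqs <- character(n)
    for (i in seq_len(n)) {
      ch <- wt
      hit <- reg[stats::runif(length(reg)) < spec$mutation_rate]
      for (p in hit)
        ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
    rbs <- spec$wildtype$rbs_start
  } else {
    cores <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, spec$core_length, TRUE), collapse = ""), "")
    seqs <- paste0(spec$flank5, cores, spec$flank3)
    rbs <- spec$rbs_start
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab),
                    multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rbs_start") <- rbs
  if (spec$mode == "local") attr(out, "wildtype") <- spec$wildtype
  out
}

#' Specification of a simulated sort-seq experiment
#'
#' Cells carrying each sequence acquire a noisy expression phenotype
#' (Gaussian in log10 P_on, emulating log-fluorescence FACS noise), are
#' gated into bins, and bin counts are downsampled to sequencing depth.
#' In 12-bin mode a per-bin sequential-sorting bias multiplies read
#' recovery and a reference spike-in (a fixed number of reference-carrying
#' cells added to every bin) is appended for later debiasing.
#'
#' @param model ground-truth `energy_model`.
#' @param gates increasing bin boundaries in log10 P_on (length B-1).
#' @param n_cells sorted cells per sequence (default 1000).
#' @param noise_sd cell-level noise sd in log10 P_on units (default 0.3).
#' @param depth sequencing reads per sequence (default 100).
#' @param bias per-bin read-recovery factors (default 1 for 4-bin mode;
#'   geometric 1.3^bin in 12-bin mode, emulating the longer sorting of
#'   sparse high-expression bins).
#' @param spikein_cells reference cells added to each bin (default 1000).
#' @param reference reference `promoter_sequence` for the spike-in
#'   (12-bin mode; default the synthetic wildtype).
#' @return a `sortsim_spec`.
#' @export
sortsim_spec <- function(model, gates = default_gates(4L), n_cells = 1000L,
                         noise_sd = 0.3, depth = 100L, bias = NULL,
                         spikein_cells = 1000L, reference = NULL) {
  stopifnot(all(diff(gates) > 0), depth > 0)
  B <- length(gates) + 1L
  if (is.null(bias)) bias <- if (B >= 12L) 1.3^(seq_len(B) - 1L) else rep(1, B)
  if (B >= 12L && is.null(reference)) reference <- synthetic_wildtype()
  structure(list(model = model, gates = gates, B = B,
                 n_cells = as.integer(n_cells), noise_sd = noise_sd,
                 depth = as.integer(depth), bias = bias,
                 spikein_cells = as.integer(spikein_cells),
                 reference = reference),
            class = "sortsim_spec")
}

#' Default FACS gate boundaries in log10 P_on
#'
#' 4-bin mode mirrors a no/low/medium/high gating (no-expression gate at
#' the measurable threshold, high gate holding wildtype-level
#' expression). 12-bin gates follow the anchoring used for random-core
#' sorting: the lowest gate boundary sits at the median of the
#' non-expressing bulk, the second at the measurable-expression
#' threshold (about 10 percent of random cores exceed it), the top gate
#' at strong wildtype-level expression, with equal log-spaced boundaries
#' between.
#'
#' @param B number of bins (4 or 12).
#' @return numeric vector of B-1 increasing boundaries.
#' @export
default_gates <- function(B) {
  if (B == 4L) c(-5.5, -4.5, -3.5)
  else if (B == 12L) c(-7.8, seq(-7.1, -2.2, length.out = 10L))
  else stop("default gates defined for 4 or 12 bins")
}

# True gate-occupancy probabilities for a phenotype x under Gaussian noise.
gate_probs <- function(x, gates, noise_sd) {
  if (noise_sd == 0) {
    p <- numeric(length(gates) + 1L)
    p[findInterval(x, gates) + 1L] <- 1
    return(p)
  }
  diff(c(0, stats::pnorm(gates, mean = x, sd = noise_sd), 1))
}

#' Simulate a sort-seq experiment
#'
#' @param seqs a library table from [generate_library()] (or a character
#'   vector of sequences).
#' @param sim a [sortsim_spec()].
#' @param seed RNG seed.
#' @return a [sortseq_library()] whose `meta$truth` records the true
#'   log10 P_on and the noise-free mean bin of every sequence.
#' @export
simulate_sortseq <- function(seqs, sim, seed = 1L) {
  set.seed(seed)
  if (is.character(seqs)) seqs <- data.frame(sequence = seqs, multiplicity = 1L)
  rbs <- attr(seqs, "rbs_start")
  if (is.null(rbs)) rbs <- NA_integer_
  x <- log10_pon(seqs$sequence, sim$model, mode = "extended",
                 rbs_start = rbs)
  B <- sim$B
  n <- nrow(seqs)
  counts <- matrix(0L, n, B)
  mean_bin <- numeric(n)
  for (i in seq_len(n)) {
    p <- gate_probs(x[i], sim$gates, sim$noise_sd)
    mean_bin[i] <- sum(p * (seq_len(B) - 1L))
    cells <- stats::rmultinom(1, sim$n_cells, p)[, 1]
    rp <- cells * sim$bias
    if (sum(rp) == 0) next
    counts[i, ] <- stats::rmultinom(1, sim$depth, rp)[, 1]
  }
  reference <- NULL
  if (!is.null(sim$reference)) {
    # spike-in: the same number of reference cells lands in every bin
    rp <- rep(sim$spikein_cells, B) * sim$bias
    ref_counts <- stats::rmultinom(1, sim$depth * 10L, rp)[, 1]
    reference <- list(sequence = sim$reference$bases, counts = ref_counts)
  }
  sortseq_library(sequences = seqs$sequence, counts = counts,
                  rbs_start = rbs, reference = reference,
                  meta = list(mode = if (B == 4L) "4bin" else "12bin",
                              gates = sim$gates,
                              bin_medians = 10^bin_centers(sim$gates),
                              truth = data.frame(sequence = seqs$sequence,
                                                 x_true = x,
                                                 mean_bin_true = mean_bin)))
}

# Representative log10 phenotype per bin (midpoints; outer bins extended by
# half the neighboring gate step).  Used as synthetic bin "median
# fluorescence" values.
bin_centers <- function(gates) {
  step <- if (length(gates) > 1) diff(gates)[1] else 1
  c(gates[1] - step / 2,
    (utils::head(gates, -1) + utils::tail(gates, -1)) / 2,
    gates[length(gates)] + step / 2)
}
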