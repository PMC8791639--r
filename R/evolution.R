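#' Kimura fixation probability
#'
#' Probability that a mutation changing the phenotype by `dphi` under
#' selection strength `s` fixes in a population of size `N_pop`:
#' P_fix = (1 - exp(-2 s dphi)) / (1 - exp(-4 N s dphi)).
#' The neutral limit (dphi -> 0) is 1 / (2 N_pop). Computed stably for
#' strongly deleterious effects.
#'
#' @param dphi phenotypic effect of the mutation (here: change in
#'   log10 P_on).
#' @param s selection strength on the phenotype (only the product
#'   s * dphi, the selection coefficient, matters).
#' @param N_pop population size (>= 1).
#' @return fixation probability in [0, 1].
#' @export
kimura_fixation <- function(dphi, s, N_pop) {
  stopifnot(N_pop >= 1)
  u <- 2 * s * dphi
  out <- numeric(length(u))
  for (i in seq_along(u)) {
    ui <- u[i]
    if (abs(ui) < 1e-12) {
      out[i] <- 1 / (2 * N_pop)
    } else if (-2 * N_pop * ui > 700) {
      # strongly deleterious: expm1(-2Nu) overflows;
      # P ~ (exp(-u)-1) * exp(2Nu), and for -u > 700 simply exp((2N-1)u)
      out[i] <- if (-ui > 700) exp((2 * N_pop - 1) * ui)
                else expm1(-ui) * exp(2 * N_pop * ui)
    } else {
      out[i] <- expm1(-ui) / expm1(-2 * N_pop * ui)
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Specification of an SSWM evolution simulation
#'
#' Strong-selection-weak-mutation: one mutation arises per step (time
#' unit 1 / mutation rate), drawn uniformly over the mutable region and
#' the three alternative bases, and fixes with the Kimura probability of
#' its phenotypic effect. The phenotype is phi = log10 P_on under the
#' chosen model. The run stops when phi reaches the threshold, or is
#' censored at `max_steps` (default 10 * N_pop).
#'
#' @param model an `energy_model`.
#' @param mode `"extended"` or `"standard"` (phenotype map).
#' @param s selection strength (default 100, placing typical selection
#'   coefficients in 0.1-1 for mutational effects of 1e-3 to 1e-2).
#' @param N_pop population size (default 100).
#' @param threshold phi* to reach (log10 P_on units).
#' @param seq_length full sequence length (default 115 bp).
#' @param mutable_length length of the central contiguous mutable region
#'   (default the full sequence).
#' @param max_steps censoring horizon (default 10 * N_pop).
#' @return an `evolution_spec`.
#' @export
evolution_spec <- function(model, mode = c("extended", "standard"), s = 100,
                           N_pop = 100L, threshold = -5.5,
                           seq_length = 115L, mutable_length = seq_length,
                           max_steps = 10L * N_pop) {
  mode <- match.arg(mode)
  stopifnot(N_pop >= 1, mutable_length <= seq_length, mutable_length >= 0)
  structure(list(model = model, mode = mode, s = s,
                 N_pop = as.integer(N_pop), threshold = threshold,
                 seq_length = as.integer(seq_length),
                 mutable_length = as.integer(mutable_length),
                 max_steps = as.integer(max_steps)),
            class = "evolution_spec")
}

# Fast phenotype closure: log10 P_on of integer-coded sequences.
phi_closure <- function(model, mode) {
  fl <- if (mode == "extended") feature_flags(model, extended_features())
        else list(sum_mode = FALSE, use_spen = FALSE, use_occl = FALSE,
                  use_rc = FALSE, use_dinuc = FALSE, R = 0)
  dn <- dinuc_cpp(model)
  sp <- as.integer(names(model$spacer_penalties))
  spv <- unname(model$spacer_penalties)
  function(codes) {
    cpp_log10_pon(list(codes), -1L, model$upstream, model$downstream, sp,
                  spv, dn$pos, dn$de, model$mu, fl$R,
                  model$rbs_occlusion_cutoff, fl$sum_mode, fl$use_spen,
                  fl$use_occl, fl$use_rc, fl$use_dinuc)[1]
  }
}

#' Evolve one sequence to an expression threshold
#'
#' @param spec an [evolution_spec()].
#' @param start starting sequence (character string of length
#'   `spec$seq_length`).
#' @param seed RNG seed.
#' @return an `evolution_run`: the start, the table of fixed mutations
#'   (position, from, to, dphi, step), exit time in steps (units of
#'   inverse mutation rate), censoring flag and final phi.
#' @export
evolve <- function(spec, start, seed = 1L) {
  set.seed(seed)
  codes <- encode_dna(start)
  L <- length(codes)
  stopifnot(L == spec$seq_length)
  phi <- phi_closure(spec$model, spec$mode)
  lo <- (L - spec$mutable_length) %/% 2L + 1L
  region <- if (spec$mutable_length > 0) lo:(lo + spec$mutable_length - 1L)
            else integer()
  cur <- phi(codes)
  fixed <- list()
  step <- 0L
  exit <- NA_integer_
  if (cur >= spec$threshold) exit <- 0L
  while (is.na(exit) && step < spec$max_steps) {
    step <- step + 1L
    if (!length(region)) next
    pos <- region[sample.int(length(region), 1L)]
    newb <- sample(setdiff(0:3, codes[pos]), 1L)
    old <- codes[pos]
    codes[pos] <- newb
    prop <- phi(codes)
    dphi <- prop - cur
    if (stats::runif(1) < kimura_fixation(dphi, spec$s, spec$N_pop)) {
      fixed[[length(fixed) + 1L]] <-
        data.frame(position = pos, from = DNA_BASES[old + 1L],
                   to = DNA_BASES[newb + 1L], dphi = dphi, step = step)
      cur <- prop
      if (cur >= spec$threshold) exit <- step
    } else {
      codes[pos] <- old
    }
  }
  structure(list(start = start,
                 mutations = if (length(fixed)) do.call(rbind, fixed)
                             else data.frame(position = integer(),
                                             from = character(),
                                             to = character(),
                                             dphi = numeric(),
                                             step = integer()),
                 exit_time = if (is.na(exit)) spec$max_steps else exit,
                 censored = is.na(exit), final_phi = cur,
                 final_sequence = decode_dna(codes)),
            class = "evolution_run")
}

#' Random non-expressing starting sequences
#'
#' Uniform random sequences whose phenotype is below the threshold under
#' every supplied model/mode pair (so that comparative runs start from a
#' common, genuinely non-expressing pool).
#'
#' @param n number of sequences.
#' @param length sequence length (default 115).
#' @param specs list of `evolution_spec`s whose thresholds must all be
#'   unmet.
#' @param seed RNG seed.
#' @return character vector of sequences.
#' @export
random_nonexpressing_starts <- function(n, length = 115L, specs, seed = 1L) {
  set.seed(seed)
  phis <- lapply(specs, function(sp) phi_closure(sp$model, sp$mode))
  thr <- vapply(specs, `[[`, 0, "threshold")
  out <- character(n)
  i <- 0L
  while (i < n) {
    codes <- sample.int(4L, length, replace = TRUE) - 1L
    ok <- all(vapply(seq_along(phis),
                     function(k) phis[[k]](codes) < thr[k], logical(1)))
    if (ok) { i <- i + 1L; out[i] <- decode_dna(codes) }
  }
  out
}

#' Replicated evolution runs over many starts
#'
#' @param specs named list of `evolution_spec`s (e.g. standard and
#'   extended phenotype maps sharing thresholds).
#' @param starts character vector of starting sequences.
#' @param runs_per_start independent replicate runs per start and spec.
#' @param seed base RNG seed; each (spec, start, run) gets a distinct
#'   derived seed.
#' @return list with `runs` (one row per run: spec, start index, exit
#'   time, censored) and `summary` (per spec and start: mean exit time,
#'   standard error, censoring fraction).
#' @export
batch_evolve <- function(specs, starts, runs_per_start = 20L, seed = 1L) {
  if (is.null(names(specs))) names(specs) <- paste0("spec", seq_along(specs))
  rows <- list()
  for (m in names(specs)) {
    sp <- specs[[m]]
    for (i in seq_along(starts)) {
      for (r in seq_len(runs_per_start)) {
        run_seed <- (seed * 1000003L + i * 1009L + r * 7L +
                       match(m, names(specs))) %% .Machine$integer.max
        run <- evolve(sp, starts[i], seed = run_seed)
        rows[[length(rows) + 1L]] <-
          data.frame(spec = m, start = i, run = r,
                     exit_time = run$exit_time, censored = run$censored,
                     final_phi = run$final_phi)
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs[c("spec", "start")]),
    function(d) data.frame(
      spec = d$spec[1], start = d$start[1],
      mean_exit = mean(d$exit_time),
      se_exit = stats::sd(d$exit_time) / sqrt(nrow(d)),
      censored_fraction = mean(d$censored))))
  rownames(agg) <- NULL
  list(runs = runs, summary = agg)
}
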