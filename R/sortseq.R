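#' Sort-seq library container
#'
#' A table of unique sequences with per-bin read counts, optional
#' processed bin distributions, bin metadata and an optional reference
#' (spike-in) record.
#'
#' @param sequences character vector of unique sequences.
#' @param counts integer matrix, one row per sequence, one column per bin
#'   (bins ordered low to high expression).
#' @param rbs_start RBS position shared by the construct (or `NA`).
#' @param reference optional `list(sequence=, counts=)` spike-in record.
#' @param probs optional processed (normalized/debiased) distributions.
#' @param meta list of metadata (mode, gates, bin_medians, truth, ...).
#' @return an object of class `sortseq_library`.
#' @export
sortseq_library <- function(sequences, counts, rbs_start = NA_integer_,
                            reference = NULL, probs = NULL, meta = list()) {
  counts <- as.matrix(counts)
  stopifnot(length(sequences) == nrow(counts),
            !anyDuplicated(sequences))
  structure(list(sequences = sequences, counts = counts,
                 rbs_start = as.integer(rbs_start), reference = reference,
                 probs = probs, meta = meta),
            class = "sortseq_library")
}

#' @export
print.sortseq_library <- function(x, ...) {
  cat(sprintf("<sortseq_library> %d sequences x %d bins%s%s\n",
              nrow(x$counts), ncol(x$counts),
              if (!is.null(x$reference)) ", with spike-in reference" else "",
              if (!is.null(x$probs)) ", processed" else ""))
  invisible(x)
}

#' @export
length.sortseq_library <- function(x) nrow(x$counts)

#' Per-sequence read coverage
#' @param lib a `sortseq_library`.
#' @return integer vector of total reads per sequence.
#' @export
coverage <- function(lib) rowSums(lib$counts)

# Normalized bin distributions: processed probabilities when present,
# otherwise plain count normalization.
bin_distributions <- function(lib) {
  if (!is.null(lib$probs)) return(lib$probs)
  cv <- rowSums(lib$counts)
  cv[cv == 0] <- 1
  lib$counts / cv
}

subset_library <- function(lib, idx) {
  sortseq_library(lib$sequences[idx], lib$counts[idx, , drop = FALSE],
                  rbs_start = lib$rbs_start, reference = lib$reference,
                  probs = if (is.null(lib$probs)) NULL
                          else lib$probs[idx, , drop = FALSE],
                  meta = local({
                    m <- lib$meta
                    if (!is.null(m$truth))
                      m$truth <- m$truth[match(lib$sequences[idx],
                                               m$truth$sequence), ]
                    m
                  }))
}

#' Write / read a sort-seq count table
#'
#' TSV with columns `sequence`, `count_bin_0` ... `count_bin_{B-1}`; the
#' spike-in reference, when present, is stored as an extra row flagged in
#' an `is_reference` column.
#'
#' @param lib a `sortseq_library`.
#' @param path TSV path.
#' @export
write_sortseq_tsv <- function(lib, path) {
  B <- ncol(lib$counts)
  df <- data.frame(sequence = lib$sequences, lib$counts,
                   is_reference = FALSE)
  names(df)[2:(B + 1)] <- paste0("count_bin_", seq_len(B) - 1L)
  if (!is.null(lib$reference)) {
    rr <- data.frame(sequence = lib$reference$sequence,
                     t(lib$reference$counts), is_reference = TRUE)
    names(rr) <- names(df)
    df <- rbind(df, rr)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sortseq_tsv
#' @param rbs_start RBS position to attach.
#' @export
read_sortseq_tsv <- function(path, rbs_start = NA_integer_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cc <- grep("^count_bin_", names(df))
  if (!length(cc)) stop("no count_bin_* columns in ", path)
  is_ref <- if ("is_reference" %in% names(df)) df$is_reference else
    rep(FALSE, nrow(df))
  reference <- NULL
  if (any(is_ref)) {
    i <- which(is_ref)[1]
    reference <- list(sequence = df$sequence[i],
                      counts = as.numeric(df[i, cc]))
  }
  keep <- !is_ref
  sortseq_library(df$sequence[keep],
                  as.matrix(df[keep, cc, drop = FALSE]),
                  rbs_start = rbs_start, reference = reference)
}

#' Bin-distribution ambiguity filter
#'
#' Sort-seq passaging can over- or under-represent a mutant in one bin
#' relative to adjacent bins. A record is dropped when an empty bin
#' separates two occupied bins that each hold more than `threshold` of
#' the record's reads (the distribution is then not attributable to a
#' single expression level).
#'
#' @param a_raw numeric vector of per-bin counts (or fractions).
#' @param threshold minimum flanking mass (fraction of total) for the gap
#'   rule to fire (default 0.1).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
bin_ambiguity_filter <- function(a_raw, threshold = 0.1) {
  tot <- sum(a_raw)
  if (tot == 0) return(FALSE)
  f <- a_raw / tot
  B <- length(f)
  if (B < 3) return(TRUE)
  for (k in 2:(B - 1)) {
    if (f[k] == 0 &&
        max(f[1:(k - 1)]) > threshold &&
        max(f[(k + 1):B]) > threshold)
      return(FALSE)
  }
  TRUE
}

#' Flank-mapping similarity score
#'
#' Local-alignment similarity in [0, 1] between an observed read and a
#' reference mapping region: match score 1/L, symmetric gap open and
#' extension penalty 1/(2L), mismatches scoring 0, with L the length of
#' the reference region. Identical sequences score 1.
#'
#' @param observed,reference character strings.
#' @return numeric similarity.
#' @export
mapping_score <- function(observed, reference) {
  L <- nchar(reference)
  sm <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(sm) <- 1 / L
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(observed), Biostrings::DNAString(reference),
    type = "local", substitutionMatrix = sm,
    gapOpening = 1 / (2 * L), gapExtension = 1 / (2 * L))
  Biostrings::score(al)
}

# Segment a random-core read into (flank5 match end, core, flank3 match
# start) by exact flank search with fallback to expected coordinates.
locate_core <- function(read, flank5, flank3) {
  # scores against both flanks
  s5 <- mapping_score(substr(read, 1, nchar(flank5) + 4), flank5)
  n <- nchar(read)
  s3 <- mapping_score(substr(read, max(1, n - nchar(flank3) - 4 + 1), n), flank3)
  core_len <- n - nchar(flank5) - nchar(flank3)
  list(score5 = s5, score3 = s3, core_length = core_len)
}

#' Filter a sort-seq library
#'
#' Applies the configured per-record acceptance rules and reports a
#' per-rule attrition table. Each rule is a pure predicate, so the final
#' retained set does not depend on rule order.
#'
#' Available rules: `coverage_min` (total reads, default 30);
#' `length_window = c(min, max)`; `rbs = list(motif, position)` (the
#' Shine-Dalgarno motif must sit at the expected position);
#' `ancestor = list(sequence, max_frac)` (Hamming distance to the
#' ancestral sequence at most `max_frac` of its length, default 0.25);
#' `flanks = list(flank5, flank3, min_similarity, core_target, core_tol)`
#' (random-core mode: both flanks must map with similarity at least 0.75
#' and the core length must be within `core_tol` of `core_target`);
#' `bin_ambiguity = list(threshold)` (see [bin_ambiguity_filter()]).
#'
#' @param lib a `sortseq_library`.
#' @param rules named list of rules (see Details). Unknown rule names are
#'   an error.
#' @return `list(library=, attrition=)` where attrition is a data frame
#'   of per-rule removal counts (evaluated sequentially in the given
#'   order) plus the final retained count.
#' @export
filter_library <- function(lib, rules = list(coverage_min = 30)) {
  known <- c("coverage_min", "length_window", "rbs", "ancestor", "flanks",
             "bin_ambiguity")
  bad <- setdiff(names(rules), known)
  if (length(bad)) stop("unknown filter rule(s): ", paste(bad, collapse = ", "))
  n <- length(lib$sequences)
  pass <- matrix(TRUE, n, length(rules),
                 dimnames = list(NULL, names(rules)))
  for (rn in names(rules)) {
    rv <- rules[[rn]]
    pass[, rn] <- switch(rn,
      coverage_min = coverage(lib) >= rv,
      length_window = {
        len <- nchar(lib$sequences)
        len >= rv[1] & len <= rv[2]
      },
      rbs = {
        pos <- vapply(lib$sequences, find_rbs, integer(1),
                      motif = rv$motif %||% "AGGAG")
        !is.na(pos) & pos == (rv$position %||% lib$rbs_start)
      },
      ancestor = {
        anc <- strsplit(rv$sequence, "")[[1]]
        maxd <- (rv$max_frac %||% 0.25) * length(anc)
        vapply(lib$sequences, function(s) {
          ch <- strsplit(s, "")[[1]]
          length(ch) == length(anc) && sum(ch != anc) <= maxd
        }, logical(1))
      },
      flanks = {
        minsim <- rv$min_similarity %||% 0.75
        target <- rv$core_target %||% 36L
        tol <- rv$core_tol %||% 2L
        vapply(lib$sequences, function(s) {
          lc <- locate_core(s, rv$flank5, rv$flank3)
          lc$score5 >= minsim && lc$score3 >= minsim &&
            abs(lc$core_length - target) <= tol
        }, logical(1))
      },
      bin_ambiguity = {
        thr <- if (is.list(rv)) rv$threshold %||% 0.1 else 0.1
        apply(lib$counts, 1, bin_ambiguity_filter, threshold = thr)
      })
  }
  # sequential attrition accounting (final set is order-independent)
  remaining <- rep(TRUE, n)
  removed <- integer(length(rules))
  for (j in seq_along(rules)) {
    removed[j] <- sum(remaining & !pass[, j])
    remaining <- remaining & pass[, j]
  }
  attrition <- data.frame(rule = c(names(rules), "retained"),
                          count = c(removed, sum(remaining)))
  list(library = subset_library(lib, which(remaining)),
       attrition = attrition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike-in debiasing of a 12-bin library
#'
#' The sequential sorting of 12 bins biases read recovery per bin. Since
#' a known, equal number of reference cells was added to every bin, the
#' reference read distribution measures the bias directly: each
#' sequence's distribution is divided by the reference distribution and
#' renormalized, a_i = (alpha_i / ref_i) / sum_j(alpha_j / ref_j).
#' Bins where the reference has zero reads are unobservable: they are
#' excluded from the ratio and the renormalization (and recorded in the
#' result's `meta$unobservable_bins`).
#'
#' @param lib a `sortseq_library` with a reference record.
#' @return the library with debiased distributions in `$probs`.
#' @export
debias_12bin <- function(lib) {
  if (is.null(lib$reference))
    stop("spike-in reference record required for 12-bin debiasing")
  ref <- lib$reference$counts
  usable <- ref > 0
  ratio <- ifelse(usable, 1 / ref, 0)
  probs <- sweep(lib$counts, 2, ratio, `*`)
  rs <- rowSums(probs)
  rs[rs == 0] <- 1
  probs <- probs / rs
  lib$probs <- probs
  lib$meta$unobservable_bins <- which(!usable)
  lib
}

#' Mode-template outlier filter
#'
#' After debiasing, a single stray read in a low-occupancy bin can be
#' inflated enormously. For each distribution mode (argmax bin), an
#' average template distribution is built over all sequences sharing that
#' mode; a background level is estimated from the template's far tail
#' (bins more than 3 away from the mode), and bins where the background
#' exceeds one third of the template value are declared outlier bins for
#' that mode. Each sequence's distribution is masked by its mode's
#' filter and renormalized.
#'
#' @param lib a debiased `sortseq_library` (see [debias_12bin()]).
#' @param background_ratio maximum background-to-template ratio for a bin
#'   to be kept (default 1/3).
#' @param min_members minimum sequences per mode to build a template
#'   (default 10); smaller modes pass through unmasked and are flagged.
#' @return the library with masked, renormalized `$probs`; all-zero
#'   masked records are dropped with a warning.
#' @export
template_filter <- function(lib, background_ratio = 1 / 3,
                            min_members = 10L) {
  probs <- bin_distributions(lib)
  B <- ncol(probs)
  modes <- max.col(probs, ties.method = "first")
  unfiltered_modes <- integer()
  masks <- matrix(TRUE, B, B)  # per-mode keep-mask, mode x bin
  for (m in sort(unique(modes))) {
    members <- which(modes == m)
    if (length(members) < min_members) {
      unfiltered_modes <- c(unfiltered_modes, m)
      next
    }
    template <- colMeans(probs[members, , drop = FALSE])
    far <- abs(seq_len(B) - m) > 3
    # the template's far tail is signal-free for a unimodal sorter output,
    # so its largest value is a conservative noise-floor estimate
    background <- if (any(far)) max(template[far]) else 0
    keep <- background <= background_ratio * template
    keep[m] <- TRUE
    masks[m, ] <- keep
  }
  out <- probs
  for (i in seq_len(nrow(probs))) out[i, ] <- probs[i, ] * masks[modes[i], ]
  rs <- rowSums(out)
  dead <- rs == 0
  if (any(dead)) {
    warning(sum(dead), " record(s) had all mass masked and were dropped")
  }
  out <- out / ifelse(rs == 0, 1, rs)
  lib$probs <- out
  lib$meta$unfiltered_modes <- unfiltered_modes
  if (any(dead)) lib <- subset_library(lib, which(!dead))
  lib
}

#' Expression estimates from bin distributions
#'
#' Two per-sequence estimates from the normalized distribution a_i over
#' bins i = 0..B-1: eps_bin = sum a_i * i (bin-index units) and
#' eps_facs = sum a_i * log10(m_i) with m_i the per-bin median
#' fluorescence. For bins with geometrically spaced medians the two are
#' affinely related.
#'
#' @param lib a `sortseq_library` (or a single distribution vector).
#' @param bin_medians per-bin median fluorescence m_i (defaults to
#'   `lib$meta$bin_medians`); when absent, `eps_facs` is `NA`.
#' @return data frame with columns `eps_bin`, `eps_facs`.
#' @export
estimate_expression <- function(lib, bin_medians = NULL) {
  if (is.numeric(lib)) {
    a <- lib / sum(lib)
    a <- matrix(a, 1)
  } else {
    a <- bin_distributions(lib)
    if (is.null(bin_medians)) bin_medians <- lib$meta$bin_medians
  }
  B <- ncol(a)
  eps_bin <- as.numeric(a %*% (seq_len(B) - 1L))
  eps_facs <- if (!is.null(bin_medians) && all(bin_medians > 0))
    as.numeric(a %*% log10(bin_medians)) else rep(NA_real_, nrow(a))
  data.frame(eps_bin = eps_bin, eps_facs = eps_facs)
}

#' Observed expression bin per sequence
#'
#' The per-sequence statistic regressed against log10 P_on: the median
#' read bin for 4-bin libraries (robust with few bins) and the rounded
#' mean bin for 12-bin libraries.
#'
#' @param lib a `sortseq_library`.
#' @param mode `"median"`, `"mean"`, or `NULL` to choose by bin count
#'   (median for <= 4 bins).
#' @return integer vector of bin indices (0-based).
#' @export
observed_bin <- function(lib, mode = NULL) {
  B <- ncol(lib$counts)
  if (is.null(mode)) mode <- if (B <= 4L) "median" else "mean"
  if (mode == "median") {
    apply(lib$counts, 1, function(cnt) {
      tot <- sum(cnt)
      if (tot == 0) return(NA_integer_)
      cum <- cumsum(cnt)
      as.integer(which(cum >= tot / 2)[1] - 1L)
    })
  } else {
    as.integer(round(estimate_expression(lib)$eps_bin))
  }
}
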