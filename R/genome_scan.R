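#' Per-position free binding energy over a genome
#'
#' For every genome position p (taken as the -10 end, i.e. the last
#' downstream contact, of a binding configuration), the free energy of
#' binding is the thermodynamic sum over all spacer lengths,
#' F(p) = -log sum_s exp(-E(p, s)). The track is offset so that its
#' genome-wide minimum is zero. Positions too close to the start for a
#' full configuration are NA in linear mode; circular mode wraps.
#'
#' @param genome character string (or `promoter_sequence`).
#' @param model an `energy_model`.
#' @param include_rc also sum configurations on the reverse strand whose
#'   -10 end maps to the same forward position (default FALSE: the track
#'   is strand-explicit).
#' @param circular treat the genome as circular (default FALSE).
#' @return a `genome_energy_track`: list with `F` (offset values), `raw`
#'   (un-offset values), `offset` (the subtracted constant), and the
#'   genome length.
#' @export
energy_track <- function(genome, model, include_rc = FALSE,
                         circular = FALSE) {
  if (inherits(genome, "promoter_sequence")) genome <- genome$bases
  if (nchar(genome) < min_footprint(model))
    stop("genome shorter than one binding configuration")
  codes <- encode_dna(genome)
  dn <- dinuc_cpp(model)
  sp <- as.integer(names(model$spacer_penalties))
  spv <- unname(model$spacer_penalties)
  raw <- cpp_energy_track(codes, model$upstream, model$downstream, sp, spv,
                          dn$pos, dn$de, nrow(dn$pos) > 0, circular)
  if (include_rc) {
    rc <- rev(3L - codes)
    raw_rc <- rev(cpp_energy_track(rc, model$upstream, model$downstream, sp,
                                   spv, dn$pos, dn$de, nrow(dn$pos) > 0,
                                   circular))
    lo <- pmin(raw, raw_rc)
    hi <- pmax(raw, raw_rc)
    both <- lo - log1p(exp(-(hi - lo)))
    both[is.na(raw)] <- raw_rc[is.na(raw)]
    both[is.na(raw_rc)] <- raw[is.na(raw_rc)]
    raw <- both
  }
  off <- min(raw, na.rm = TRUE)
  structure(list(F = raw - off, raw = raw, offset = off,
                 length = length(codes)),
            class = "genome_energy_track")
}

#' @export
print.genome_energy_track <- function(x, ...) {
  cat(sprintf("<genome_energy_track> %d positions, %d defined, offset %.3f\n",
              x$length, sum(!is.na(x$F)), x$offset))
  invisible(x)
}

#' Write a free-energy track as bedgraph-style TSV
#' @param track a `genome_energy_track`.
#' @param path output path.
#' @param chrom chromosome name written in the first column.
#' @export
write_track_tsv <- function(track, path, chrom = "chr") {
  ok <- which(!is.na(track$F))
  utils::write.table(
    data.frame(chrom = chrom, start = ok - 1L, end = ok, value = track$F[ok]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Annotation types whose presence removes a position from the inter-genic
# class.
INTERGENIC_EXCLUDE <- c("misc_feature", "mobile_element", "repeat_region",
                        "tRNA", "STS", "tmRNA", "rRNA", "CDS", "gene",
                        "ncRNA")

#' Partition a genome by annotation
#'
#' `within_genes`: positions covered by a CDS or gene feature.
#' `intergenic`: positions covered by none of the excluded annotation
#' types (misc_feature, mobile_element, repeat_region, tRNA, STS, tmRNA,
#' rRNA, CDS, gene, ncRNA). The two masks are disjoint by construction.
#'
#' @param annotations data frame with columns `type`, `start`, `end`
#'   (1-based, inclusive), or a GFF3 file path (read via rtracklayer).
#' @param genome_length total genome length.
#' @param genome optional sequence for GC summaries.
#' @return a `region_partition`: masks plus a summary data frame with
#'   genome fractions and GC content per region.
#' @export
partition_regions <- function(annotations, genome_length, genome = NULL) {
  if (is.character(annotations) && length(annotations) == 1) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(annotations)
    annotations <- data.frame(type = as.character(gr$type),
                              start = BiocGenerics::start(gr),
                              end = BiocGenerics::end(gr))
  }
  cover <- function(types) {
    mask <- logical(genome_length)
    sel <- annotations$type %in% types
    for (i in which(sel)) {
      s <- max(1L, annotations$start[i])
      e <- min(genome_length, annotations$end[i])
      if (s <= e) mask[s:e] <- TRUE
    }
    mask
  }
  within <- cover(c("CDS", "gene"))
  intergenic <- !cover(INTERGENIC_EXCLUDE)
  gc_of <- function(mask) {
    if (is.null(genome) || !any(mask)) return(NA_real_)
    ch <- strsplit(genome, "")[[1]][mask]
    mean(ch %in% c("G", "C"))
  }
  summary <- data.frame(
    region = c("within_genes", "intergenic"),
    fraction = c(mean(within), mean(intergenic)),
    gc = c(gc_of(within), gc_of(intergenic)))
  structure(list(within_genes = within, intergenic = intergenic,
                 summary = summary),
            class = "region_partition")
}

#' Random genome with fixed GC content
#' @param length genome length.
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return character string.
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

# Cumulative counts of track values below each bin edge.
cumulative_counts <- function(values, edges) {
  values <- values[!is.na(values)]
  vapply(edges, function(e) sum(values <= e), numeric(1))
}

#' Binding-site depletion test against a GC-matched synthetic genome
#'
#' Compares the cumulative histogram of free binding energies in a region
#' of the real genome with the expectation from an i.i.d. synthetic
#' genome of the same GC content, rescaled to the region size. Per energy
#' bin, the one-tailed p-value is the Poisson cumulative mass at the
#' observed count with mean equal to the synthetic expectation (small
#' p-values indicate depletion of strong sites).
#'
#' @param track `genome_energy_track` of the real genome.
#' @param mask logical mask of the region tested (e.g. from
#'   [partition_regions()]).
#' @param gc GC content used for the synthetic genome (typically the
#'   region's own).
#' @param model the `energy_model` (re-scanned over the synthetic
#'   genome).
#' @param synthetic_length length of the synthetic genome (default 1e7).
#' @param bin_edges cumulative energy bin edges, in kB*T above the real
#'   track's minimum (default 0.5 to 10 by 0.5).
#' @param seed RNG seed for the synthetic genome.
#' @return data frame with per-edge observed and expected cumulative
#'   counts and one-tailed Poisson p-values.
#' @export
depletion_test_gc_null <- function(track, mask, gc, model,
                                   synthetic_length = 1e7,
                                   bin_edges = seq(0.5, 10, by = 0.5),
                                   seed = 1L) {
  if (!any(mask)) stop("empty region")
  obs_vals <- track$raw[mask] - track$offset
  n_obs <- sum(!is.na(obs_vals))
  synth <- random_genome(synthetic_length, gc, seed = seed)
  st <- energy_track(synth, model)
  # shared energy scale: offset the synthetic values by the real track's
  # offset so both histograms measure energy above the real minimum
  synth_vals <- st$raw - track$offset
  n_synth <- sum(!is.na(synth_vals))
  observed <- cumulative_counts(obs_vals, bin_edges)
  expected <- cumulative_counts(synth_vals, bin_edges) * (n_obs / n_synth)
  data.frame(edge = bin_edges, observed = observed, expected = expected,
             p_value = stats::ppois(observed, expected))
}

# Rebuild a model with the contact columns permuted (within-column
# structure intact); dinucleotide terms do not transfer across a column
# permutation and are dropped.
shuffle_model_columns <- function(model, perm) {
  L35 <- ncol(model$upstream)
  M <- cbind(model$upstream, model$downstream)[, perm, drop = FALSE]
  model$upstream <- M[, seq_len(L35), drop = FALSE]
  model$downstream <- M[, -seq_len(L35), drop = FALSE]
  model$dinucleotides <- empty_dinucleotides()
  model
}

#' Binding-site depletion test against shuffled energy matrices
#'
#' The columns of the energy matrix are permuted (keeping each column's
#' internal structure) `n_shuffles` times; each shuffled matrix is
#' evaluated over the same genome and its cumulative energy histogram
#' recorded. Per bin, the observed count is compared with the shuffle
#' distribution via a one-tailed Gaussian p-value, and the 3rd/97th
#' percentile band is reported (an illustration of the 95% confidence
#' interval).
#'
#' @param genome character string.
#' @param model the `energy_model`.
#' @param n_shuffles number of shuffled matrices (default 100).
#' @param bin_edges cumulative energy bin edges above the real minimum.
#' @param seed RNG seed.
#' @return data frame with observed counts, shuffle mean/sd, Gaussian
#'   p-values and the percentile band per bin edge.
#' @export
depletion_test_shuffled <- function(genome, model, n_shuffles = 100L,
                                    bin_edges = seq(0.5, 10, by = 0.5),
                                    seed = 1L) {
  stopifnot(n_shuffles >= 2)
  set.seed(seed)
  base_model <- model
  base_model$dinucleotides <- empty_dinucleotides()
  real <- energy_track(genome, base_model)
  observed <- cumulative_counts(real$F, bin_edges)
  nct <- ncol(model$upstream) + ncol(model$downstream)
  counts <- matrix(0, n_shuffles, length(bin_edges))
  for (k in seq_len(n_shuffles)) {
    m2 <- shuffle_model_columns(base_model, sample.int(nct))
    tr <- energy_track(genome, m2)
    # same energy scale: values above the real track's minimum
    counts[k, ] <- cumulative_counts(tr$raw - real$offset, bin_edges)
  }
  mu <- colMeans(counts)
  sdv <- apply(counts, 2, stats::sd)
  data.frame(edge = bin_edges, observed = observed, shuffle_mean = mu,
             shuffle_sd = sdv,
             p_value = stats::pnorm(observed, mu, ifelse(sdv == 0, 1e-12,
                                                         sdv)),
             band_lo = apply(counts, 2, stats::quantile, probs = 0.03),
             band_hi = apply(counts, 2, stats::quantile, probs = 0.97))
}

#' Integrated promoter free energy
#'
#' Free energy of a promoter region: -log of the summed Boltzmann weights
#' of all configurations whose -10 end lies in a symmetric window
#' (default 40 bp) around each anchor (e.g. a transcript start site).
#'
#' @param track a `genome_energy_track`.
#' @param anchors integer positions (1-based).
#' @param window window width in bp (default 40; the window is
#'   `[anchor - window/2, anchor + window/2 - 1]`).
#' @return data frame with per-anchor free energy (on the track's offset
#'   scale) and a flag for windows truncated at the genome edge.
#' @export
promoter_free_energy <- function(track, anchors, window = 40L) {
  half <- window %/% 2L
  out <- lapply(anchors, function(a) {
    lo <- a - half; hi <- a + half - 1L
    idx <- max(1L, lo):min(track$length, hi)
    v <- track$F[idx]
    # windows cut by the genome edge (out of bounds or positions without
    # a full configuration) are flagged
    truncated <- lo < 1L || hi > track$length || anyNA(v)
    v <- v[!is.na(v)]
    fe <- if (!length(v)) NA_real_ else {
      m <- min(v)
      m - log(sum(exp(-(v - m))))
    }
    data.frame(anchor = a, free_energy = fe, truncated = truncated)
  })
  do.call(rbind, out)
}

#' Read a genome from FASTA
#' @param path FASTA file; the first record is used.
#' @return character string.
#' @export
read_genome_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path)[[1]])
}
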