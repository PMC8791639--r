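#' @useDynLib thermoprom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed residue order used everywhere (matrix rows, integer codes 0..3).
DNA_BASES <- c("A", "C", "G", "T")

#' Thermal energy unit
#'
#' All binding energies in this package are expressed in units of
#' \eqn{k_B T}. At room temperature \eqn{k_B T = 0.59} kcal/mol.
#' @export
KBT_KCAL_MOL <- 0.59

#' Convert energies between kB*T and kcal/mol
#'
#' @param x numeric energies.
#' @return `x` converted to the other unit.
#' @export
kbt_to_kcal <- function(x) x * KBT_KCAL_MOL

#' @rdname kbt_to_kcal
#' @export
kcal_to_kbt <- function(x) x / KBT_KCAL_MOL

#' Construct a sigma70-RNAP binding-energy model
#'
#' An `energy_model` bundles every parameter needed to evaluate the
#' occupancy models: two additive energy-matrix blocks (the -35 element
#' plus flanking contacts, and the -10 element plus flanks), per-length
#' spacer penalties, optional dinucleotide interaction terms between
#' contact positions, the chemical potential, the relative clearance rate,
#' and the RBS occlusion cutoff.
#'
#' Matrix rows are always A, C, G, T (in that order); columns run from the
#' most upstream to the most downstream contact position. Energies are
#' penalties in units of kB*T, normalized so that the lowest-energy
#' (strongest-binding) residue in each column is zero. Spacer penalties are
#' likewise normalized to zero at the optimal length.
#'
#' @param upstream 4 x L35 numeric matrix (the -35 block).
#' @param downstream 4 x L10 numeric matrix (the -10 block).
#' @param spacer_penalties named numeric vector; names are spacer lengths
#'   in bp of the gap between the two blocks. Must contain a zero.
#' @param dinucleotides data frame with columns `pos_i`, `base_i`, `pos_j`,
#'   `base_j`, `delta_e`: interaction energies between contact positions
#'   (1-based over the L35+L10 contacts, upstream block first).
#' @param mu chemical potential (dimensionless, energy in kB*T units).
#' @param clearance_rate relative RNAP clearance rate R >= 0.
#' @param rbs_occlusion_cutoff distance in bp from the -10 end of a binding
#'   site to the RBS start at or below which binding is unproductive
#'   (default 11).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(upstream, downstream, spacer_penalties,
                         dinucleotides = empty_dinucleotides(),
                         mu = 0, clearance_rate = 0,
                         rbs_occlusion_cutoff = 11L) {
  upstream <- as.matrix(upstream)
  downstream <- as.matrix(downstream)
  rownames(upstream) <- rownames(downstream) <- DNA_BASES
  sp <- spacer_penalties
  if (is.null(names(sp))) stop("spacer_penalties must be named by length (bp)")
  sp <- sp[order(as.integer(names(sp)))]
  m <- structure(list(
    upstream = upstream,
    downstream = downstream,
    spacer_penalties = sp,
    dinucleotides = dinucleotides,
    mu = as.numeric(mu),
    clearance_rate = as.numeric(clearance_rate),
    rbs_occlusion_cutoff = as.integer(rbs_occlusion_cutoff)
  ), class = "energy_model")
  validate_energy_model(m)
  m
}

#' @export
empty_dinucleotides <- function() {
  data.frame(pos_i = integer(), base_i = character(),
             pos_j = integer(), base_j = character(),
             delta_e = numeric(), stringsAsFactors = FALSE)
}

#' Validate an energy model
#'
#' Checks the container invariants: non-negative matrix entries with a zero
#' in every column, a zero minimum spacer penalty, valid dinucleotide
#' contact positions, and a non-negative clearance rate.
#'
#' @param m an `energy_model`.
#' @param tol numeric tolerance on the zero-minimum checks.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_energy_model <- function(m, tol = 1e-8) {
  stopifnot(inherits(m, "energy_model"))
  for (blk in c("upstream", "downstream")) {
    M <- m[[blk]]
    if (nrow(M) != 4L) stop(blk, " block must have 4 rows (A,C,G,T)")
    if (any(M < -tol)) stop(blk, " block has negative entries")
    if (any(abs(apply(M, 2, min)) > tol))
      stop(blk, " block columns must be normalized to minimum zero")
  }
  if (any(m$spacer_penalties < -tol)) stop("negative spacer penalty")
  if (abs(min(m$spacer_penalties)) > tol)
    stop("spacer penalties must have minimum zero at the optimal length")
  if (m$clearance_rate < 0) stop("clearance_rate must be >= 0")
  nct <- ncol(m$upstream) + ncol(m$downstream)
  dn <- m$dinucleotides
  if (nrow(dn)) {
    if (any(dn$pos_i < 1L | dn$pos_i > nct | dn$pos_j < 1L | dn$pos_j > nct))
      stop("dinucleotide positions outside the contact footprint")
    if (!all(dn$base_i %in% DNA_BASES) || !all(dn$base_j %in% DNA_BASES))
      stop("dinucleotide bases must be A/C/G/T")
  }
  invisible(m)
}

#' @export
print.energy_model <- function(x, ...) {
  cat("sigma70-RNAP energy model\n")
  cat(sprintf("  contact footprint: %d (-35 block) + %d (-10 block) positions\n",
              ncol(x$upstream), ncol(x$downstream)))
  sp <- x$spacer_penalties
  cat(sprintf("  spacers: %s bp (optimal %s)\n",
              paste(names(sp), collapse = ","),
              names(sp)[which.min(sp)]))
  cat(sprintf("  dinucleotide terms: %d\n", nrow(x$dinucleotides)))
  cat(sprintf("  mu = %.4g, clearance rate R = %.4g, RBS occlusion cutoff = %d bp\n",
              x$mu, x$clearance_rate, x$rbs_occlusion_cutoff))
  invisible(x)
}

#' Consensus (minimum-energy) sequence of a model
#'
#' Returns the sequence built from the lowest-energy residue in each contact
#' column, with the two blocks separated by `spacer` arbitrary bases
#' (default the optimal spacer length, filled with "A").
#'
#' @param m an `energy_model`.
#' @param spacer spacer length; default the optimal one.
#' @param fill base used to fill the spacer.
#' @return a character string.
#' @export
consensus_sequence <- function(m, spacer = optimal_spacer(m), fill = "A") {
  up <- DNA_BASES[apply(m$upstream, 2, which.min)]
  dn <- DNA_BASES[apply(m$downstream, 2, which.min)]
  paste0(paste(up, collapse = ""),
         strrep(fill, spacer),
         paste(dn, collapse = ""))
}

#' @rdname consensus_sequence
#' @export
optimal_spacer <- function(m) {
  as.integer(names(m$spacer_penalties)[which.min(m$spacer_penalties)])
}

# Minimal footprint width (shortest spacer).
min_footprint <- function(m) {
  ncol(m$upstream) + min(as.integer(names(m$spacer_penalties))) +
    ncol(m$downstream)
}

# Dinucleotide table in the 0-based integer layout the C++ core expects.
dinuc_cpp <- function(m) {
  dn <- m$dinucleotides
  if (!nrow(dn)) {
    return(list(pos = matrix(integer(), 0, 4), de = numeric()))
  }
  pos <- cbind(dn$pos_i - 1L, match(dn$base_i, DNA_BASES) - 1L,
               dn$pos_j - 1L, match(dn$base_j, DNA_BASES) - 1L)
  storage.mode(pos) <- "integer"
  list(pos = pos, de = dn$delta_e)
}

#' Normalize a model to its canonical gauge
#'
#' Energy matrices are defined only up to a per-column offset (absorbed by
#' the chemical potential) and the spacer penalties up to a shared offset.
#' This shifts every column and the spacer table so their minima are zero,
#' compensating through `mu` so that all occupancies are unchanged.
#'
#' @param m an `energy_model` (possibly un-normalized, e.g. mid-fit).
#' @return an equivalent, normalized `energy_model`.
#' @export
normalize_energy_model <- function(m) {
  shift <- 0
  for (blk in c("upstream", "downstream")) {
    mins <- apply(m[[blk]], 2, min)
    m[[blk]] <- sweep(m[[blk]], 2, mins)
    shift <- shift + sum(mins)
  }
  smin <- min(m$spacer_penalties)
  m$spacer_penalties <- m$spacer_penalties - smin
  shift <- shift + smin
  m$mu <- m$mu - shift
  m
}

#' Consensus-prior starting model
#'
#' A generic initialization for fitting: the canonical sigma70 hexamers
#' (TTGACA in the upstream block, TATAAT in the downstream block, at the
#' package's standard block layout) with a uniform `strength` penalty for
#' non-consensus residues, zero flank penalties, a mildly quadratic
#' spacer-penalty prior and no dinucleotide terms. Fitting from an
#' informative consensus prior is what anchors the optimization in the
#' physically meaningful basin; from a flat matrix the thermodynamic sum
#' carries almost no sequence information and the likelihood has a
#' stationary point the optimizer cannot leave.
#'
#' @param strength penalty (kB*T) for non-consensus hexamer residues
#'   (default 2).
#' @param mu starting chemical potential (default -5).
#' @return an `energy_model`.
#' @export
consensus_prior_model <- function(strength = 2, mu = -5) {
  up <- matrix(0, 4, 12, dimnames = list(DNA_BASES, NULL))
  dn <- matrix(0, 4, 12, dimnames = list(DNA_BASES, NULL))
  set_cons <- function(M, cols, cons) {
    for (k in seq_along(cols)) {
      M[, cols[k]] <- strength
      M[match(cons[k], DNA_BASES), cols[k]] <- 0
    }
    M
  }
  up <- set_cons(up, 4:9, c("T", "T", "G", "A", "C", "A"))
  dn <- set_cons(dn, 6:11, c("T", "A", "T", "A", "A", "T"))
  spacers <- c("7" = 0.8, "8" = 0.2, "9" = 0, "10" = 0.2, "11" = 0.8)
  energy_model(up, dn, spacers, mu = mu)
}

#' Built-in demonstration model
#'
#' A fully synthetic sigma70-RNAP parameter bundle used by the examples,
#' the synthetic-data generator and the test suite. The 12-position
#' upstream block carries the TTGACA -35 element flanked by 3 weakly
#' contacting positions on each side; the 12-position downstream block
#' carries TATAAT preceded by 5 and followed by 1 flanking position.
#' The internal spacer optimum of 9 bp corresponds to the canonical 17 bp
#' between the -10 and -35 hexamers. Penalties are deterministic and
#' loosely shaped like published sigma70 matrices; they are not fitted to
#' any experimental data.
#'
#' @param mu chemical potential (default -5).
#' @param clearance_rate relative clearance rate (default 0).
#' @param dinucleotides optional dinucleotide table to plant.
#' @return an `energy_model`.
#' @export
demo_energy_model <- function(mu = -5, clearance_rate = 0,
                              dinucleotides = empty_dinucleotides()) {
  core35 <- c("T", "T", "G", "A", "C", "A")
  core10 <- c("T", "A", "T", "A", "A", "T")
  mk_col <- function(consensus, strength, off) {
    v <- strength * (1 + 0.25 * sin(seq(0.3, 2.7, length.out = 4) + off))
    v[match(consensus, DNA_BASES)] <- 0
    v
  }
  up <- matrix(0, 4, 12, dimnames = list(DNA_BASES, NULL))
  dn <- matrix(0, 4, 12, dimnames = list(DNA_BASES, NULL))
  flank35 <- c("A", "T", "G")             # weak upstream flank preferences
  for (j in 1:3)  up[, j] <- mk_col(flank35[j], 0.35, j)
  for (j in 4:9)  up[, j] <- mk_col(core35[j - 3], 2.1, j)
  for (j in 10:12) up[, j] <- mk_col(c("T", "G", "A")[j - 9], 0.4, j)
  flank10 <- c("G", "T", "A", "T", "A")   # extended -10 contacts
  for (j in 1:5)  dn[, j] <- mk_col(flank10[j], 0.5, j + 12)
  for (j in 6:11) dn[, j] <- mk_col(core10[j - 5], 2.4, j + 12)
  dn[, 12] <- mk_col("A", 0.3, 24)
  spacers <- c("7" = 2.2, "8" = 0.6, "9" = 0, "10" = 0.6, "11" = 2.2)
  energy_model(up, dn, spacers, dinucleotides = dinucleotides,
               mu = mu, clearance_rate = clearance_rate)
}
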