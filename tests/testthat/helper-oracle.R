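# Independent brute-force oracles: plain R loops that share no code with
# the package's scanning engine.

BASES4 <- c("A", "C", "G", "T")

oracle_revcomp <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(bases, "")[[1]]])), collapse = "")
}

# Enumerate every configuration with its energy and class by naive loops
# (vectors are preallocated for speed; the energy walk itself stays a
# plain position-by-position loop).
oracle_configs <- function(bases, m, rbs = NA) {
  L35 <- ncol(m$upstream); L10 <- ncol(m$downstream)
  v_strand <- character(); v_off <- integer(); v_sp <- integer()
  v_e <- numeric(); v_k <- character()
  for (strand in c("+", "-")) {
    ch <- strsplit(if (strand == "+") bases else oracle_revcomp(bases),
                   "")[[1]]
    L <- length(ch)
    idx <- match(ch, BASES4)
    for (s in as.integer(names(m$spacer_penalties))) {
      w <- L35 + s + L10
      if (w > L) next
      for (o in 1:(L - w + 1)) {
        ci <- c(idx[o:(o + L35 - 1)], idx[(o + L35 + s):(o + w - 1)])
        e <- m$spacer_penalties[[as.character(s)]]
        for (j in 1:L35) e <- e + m$upstream[ci[j], j]
        for (j in 1:L10) e <- e + m$downstream[ci[L35 + j], j]
        dd <- m$dinucleotides
        if (nrow(dd)) for (k in 1:nrow(dd)) {
          if (ci[dd$pos_i[k]] == match(dd$base_i[k], BASES4) &&
              ci[dd$pos_j[k]] == match(dd$base_j[k], BASES4))
            e <- e + dd$delta_e[k]
        }
        klass <- if (strand == "-") "rc"
          else if (!is.na(rbs) && (rbs - (o + w - 1) - 1) <=
                     m$rbs_occlusion_cutoff) "occ" else "on"
        n1 <- length(v_e) + 1L
        v_strand[n1] <- strand; v_off[n1] <- o; v_sp[n1] <- s
        v_e[n1] <- e; v_k[n1] <- klass
      }
    }
  }
  data.frame(strand = v_strand, offset = v_off, spacer = v_sp,
             energy = v_e, klass = v_k, stringsAsFactors = FALSE)
}

# Extended-model occupancy by direct evaluation of the weight formula.
oracle_pon_extended <- function(bases, m, rbs = NA) {
  cf <- oracle_configs(bases, m, rbs)
  if (!nrow(cf)) return(0)
  w <- 1 / (m$clearance_rate + exp(cf$energy - m$mu))
  on <- cf$klass == "on"
  if (!any(on)) return(0)
  sum(w[on]) / (1 + sum(w[!on]) + sum(w[on]))
}

# Standard model: strongest forward site, no spacer penalties, no
# dinucleotides, no unproductive states.
oracle_pon_standard <- function(bases, m) {
  m2 <- m
  m2$spacer_penalties[] <- 0
  m2$dinucleotides <- m2$dinucleotides[0, ]
  cf <- oracle_configs(bases, m2, rbs = NA)
  cf <- cf[cf$strand == "+", ]
  stopifnot(nrow(cf) > 0)
  1 / (1 + exp(min(cf$energy) - m$mu))
}

# Naive per-position free-energy track (forward strand).
oracle_track <- function(bases, m) {
  L <- nchar(bases)
  cf <- local({ m0 <- m; m0$mu <- 0; oracle_configs(bases, m0, rbs = NA) })
  cf <- cf[cf$strand == "+", ]
  ten_end <- cf$offset + ncol(m$upstream) + cf$spacer + ncol(m$downstream) - 1
  out <- rep(NA_real_, L)
  for (p in unique(ten_end)) {
    e <- cf$energy[ten_end == p]
    out[p] <- -log(sum(exp(-e)))
  }
  out
}
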