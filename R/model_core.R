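#' Structural features of the Extended occupancy model
#'
#' The Extended model adds six structural features on top of the Standard
#' single-strongest-site model: spacer-length penalties, cumulative binding
#' over all configurations, occlusive unproductive binding near the RBS,
#' occlusive binding on the reverse complement, dinucleotide interactions,
#' and the RNAP clearance rate.
#'
#' @return character vector of feature names.
#' @export
extended_features <- function() {
  c("spacer_penalty", "cumulative", "occlusive", "reverse_complement",
    "dinucleotides", "clearance")
}

# Translate a feature subset into the flags of the C++ core.
feature_flags <- function(model, features) {
  features <- match.arg(features, extended_features(), several.ok = TRUE)
  list(sum_mode = "cumulative" %in% features,
       use_spen = "spacer_penalty" %in% features,
       use_occl = "occlusive" %in% features,
       use_rc = "reverse_complement" %in% features,
       use_dinuc = "dinucleotides" %in% features && nrow(model$dinucleotides) > 0,
       R = if ("clearance" %in% features) model$clearance_rate else 0)
}

CONFIG_CLASSES <- c("productive", "occlusive_unproductive",
                    "reverse_complement_unproductive")

#' Energy of a single binding configuration
#'
#' Walks the sequence position by position: upstream-block sum +
#' downstream-block sum + spacer penalty + the sum of matching
#' dinucleotide terms. This is the reference (readable) implementation;
#' the batch scans in the compiled core must agree with it exactly.
#'
#' @param seq a `promoter_sequence` or character string.
#' @param strand `"+"` (forward) or `"-"` (reverse complement).
#' @param offset 1-based position, on the forward strand, of the
#'   configuration's most upstream contact residue.
#' @param spacer spacer length in bp; must be present in the model's
#'   penalty table.
#' @param model an `energy_model`.
#' @return energy in kB*T.
#' @export
configuration_energy <- function(seq, strand, offset, spacer, model) {
  if (is.character(seq)) seq <- promoter_sequence(seq)
  L35 <- ncol(model$upstream); L10 <- ncol(model$downstream)
  sp_name <- as.character(spacer)
  if (!sp_name %in% names(model$spacer_penalties))
    stop("spacer length ", spacer, " not in the model's penalty table")
  w <- L35 + spacer + L10
  L <- nchar(seq$bases)
  if (offset < 1L || offset + w - 1L > L)
    stop("configuration placement out of sequence bounds")
  bases <- if (strand == "+") seq$bases else reverse_complement(seq$bases)
  o <- if (strand == "+") offset else L - offset - w + 2L
  ch <- strsplit(bases, "")[[1]]
  contact <- c(ch[o:(o + L35 - 1L)],
               ch[(o + L35 + spacer):(o + L35 + spacer + L10 - 1L)])
  idx <- match(contact, DNA_BASES)
  if (anyNA(idx)) stop("sequence contains bases outside {A,C,G,T}")
  e <- 0
  for (j in seq_len(L35)) e <- e + model$upstream[idx[j], j]
  for (j in seq_len(L10)) e <- e + model$downstream[idx[L35 + j], j]
  e <- e + model$spacer_penalties[[sp_name]]
  dn <- model$dinucleotides
  if (nrow(dn)) {
    for (k in seq_len(nrow(dn))) {
      if (contact[dn$pos_i[k]] == dn$base_i[k] &&
          contact[dn$pos_j[k]] == dn$base_j[k])
        e <- e + dn$delta_e[k]
    }
  }
  unname(e)
}

#' Classify a binding configuration
#'
#' Reverse-complement configurations are always unproductive. A forward
#' configuration is occlusive-unproductive when the distance from its -10
#' end (last downstream contact) to the RBS start is at or below the
#' model's occlusion cutoff (default 11 bp); otherwise it is productive.
#' Sequences without an annotated RBS have only productive forward
#' configurations.
#'
#' @param strand `"+"` or `"-"`.
#' @param offset 1-based forward-strand offset of the configuration.
#' @param spacer spacer length in bp.
#' @param rbs_start 1-based RBS start, or `NA`.
#' @param model an `energy_model`.
#' @return one of `"productive"`, `"occlusive_unproductive"`,
#'   `"reverse_complement_unproductive"`.
#' @export
classify_configuration <- function(strand, offset, spacer, rbs_start, model) {
  if (strand == "-") return("reverse_complement_unproductive")
  if (is.na(rbs_start)) return("productive")
  ten_end <- offset + ncol(model$upstream) + spacer + ncol(model$downstream) - 1L
  distance <- rbs_start - ten_end - 1L
  if (distance <= model$rbs_occlusion_cutoff) "occlusive_unproductive"
  else "productive"
}

#' Enumerate all binding configurations of a sequence
#'
#' Every placement of the full footprint (upstream block + spacer +
#' downstream block) on both strands, for every spacer length in the
#' model's table, each with its energy (including spacer penalty and
#' dinucleotide terms) and productive/unproductive class.
#'
#' @param seq a `promoter_sequence` or character string.
#' @param model an `energy_model`.
#' @return data frame with columns `strand`, `offset` (1-based, forward
#'   coordinates of the most upstream contact), `spacer`, `energy`,
#'   `klass`. Sequences shorter than the minimal footprint yield a
#'   zero-row table.
#' @export
enumerate_configurations <- function(seq, model) {
  if (is.character(seq)) seq <- promoter_sequence(seq)
  codes <- encode_dna(seq$bases)
  dn <- dinuc_cpp(model)
  rbs0 <- if (is.na(seq$rbs_start)) -1L else seq$rbs_start - 1L
  tab <- cpp_config_table(codes, model$upstream, model$downstream,
                          as.integer(names(model$spacer_penalties)),
                          unname(model$spacer_penalties), dn$pos, dn$de,
                          model$mu, model$clearance_rate, rbs0,
                          model$rbs_occlusion_cutoff, nrow(dn$pos) > 0)
  data.frame(strand = c("+", "-")[tab$strand + 1L],
             offset = tab$offset + 1L,
             spacer = tab$spacer,
             energy = tab$energy,
             klass = CONFIG_CLASSES[tab$klass + 1L],
             stringsAsFactors = FALSE)
}

#' log10 occupancy for a set of sequences
#'
#' Batch evaluation of log10 P_on under the Standard model, the full
#' Extended model, or any intermediate feature subset.
#'
#' @param seqs character vector, `promoter_sequence`, or list thereof.
#' @param model an `energy_model`.
#' @param mode `"extended"` (default) or `"standard"`; ignored when
#'   `features` is given.
#' @param features optional character subset of [extended_features()];
#'   overrides `mode`.
#' @param rbs_start used when `seqs` are plain strings.
#' @return numeric vector of log10 P_on (-Inf when a sequence has no
#'   productive configuration).
#' @export
log10_pon <- function(seqs, model, mode = c("extended", "standard"),
                      features = NULL, rbs_start = NA_integer_) {
  mode <- match.arg(mode)
  sl <- as_promoter_list(seqs, rbs_start)
  if (is.null(features)) {
    features <- if (mode == "extended") extended_features() else character()
  }
  fl <- if (length(features)) feature_flags(model, features) else
    list(sum_mode = FALSE, use_spen = FALSE, use_occl = FALSE,
         use_rc = FALSE, use_dinuc = FALSE, R = 0)
  codes <- lapply(sl, function(s) encode_dna(s$bases))
  rbs <- vapply(sl, function(s)
    if (is.na(s$rbs_start)) -1L else s$rbs_start - 1L, integer(1))
  dn <- dinuc_cpp(model)
  cpp_log10_pon(codes, rbs, model$upstream, model$downstream,
                as.integer(names(model$spacer_penalties)),
                unname(model$spacer_penalties), dn$pos, dn$de,
                model$mu, fl$R, model$rbs_occlusion_cutoff,
                fl$sum_mode, fl$use_spen, fl$use_occl, fl$use_rc,
                fl$use_dinuc)
}

#' Standard-model occupancy
#'
#' Single strongest forward-strand binding site: P_on = 1 / (1 +
#' exp(min_i E_i - mu)), all spacer lengths allowed with no spacer
#' penalty, no unproductive states, no dinucleotide terms, clearance
#' ignored. Ties in the minimum are broken by smallest offset, then
#' shortest spacer.
#'
#' @param seq a `promoter_sequence` or character string.
#' @param model an `energy_model`.
#' @return P_on in (0, 1).
#' @export
pon_standard <- function(seq, model) {
  x <- log10_pon(seq, model, mode = "standard")
  if (!is.finite(x))
    stop("no valid binding configuration: occupancy undefined")
  10^x
}

#' Extended-model occupancy
#'
#' Thermodynamic sum over every configuration on both strands with weights
#' w_i = 1 / (R + exp(E_i - mu)):
#' P_on = sum_on w / (1 + sum_np w + sum_on w). With R = 0 the weights
#' reduce to Boltzmann factors exp(-(E_i - mu)). Computed in log space.
#' An empty configuration set gives P_on = 0 (no productive state).
#'
#' @inheritParams pon_standard
#' @param features feature subset, default the full Extended set.
#' @return P_on in [0, 1).
#' @export
pon_extended <- function(seq, model, features = extended_features()) {
  x <- log10_pon(seq, model, features = features)
  ifelse(is.finite(x), 10^x, 0)
}
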