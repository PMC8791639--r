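BUNDLE_SCHEMA <- "thermoprom-bundle-1"

fmt_num <- function(x) sprintf("%.17g", x)

#' Save an energy model as a parameter bundle
#'
#' Writes a JSON master file plus sibling TSV tables: the two matrix
#' blocks (rows A,C,G,T in fixed order, columns upstream to downstream),
#' the spacer-penalty table and the dinucleotide-term table. All numeric
#' fields round-trip at full double precision and the JSON key order is
#' canonical, so save -> load -> save is byte-identical.
#'
#' @param model an `energy_model`.
#' @param path path of the JSON master file (e.g. `"bundle.json"`).
#' @return `path`, invisibly.
#' @export
save_energy_model <- function(model, path) {
  validate_energy_model(model)
  stem <- sub("\\.json$", "", path)
  base_stem <- basename(stem)
  files <- list(
    upstream = paste0(stem, "_upstream.tsv"),
    downstream = paste0(stem, "_downstream.tsv"),
    spacers = paste0(stem, "_spacers.tsv"),
    dinucleotides = paste0(stem, "_dinucleotides.tsv"))
  write_block <- function(M, f) {
    df <- data.frame(base = DNA_BASES,
                     matrix(fmt_num(M), 4, ncol(M),
                            dimnames = list(NULL, paste0("pos", seq_len(ncol(M))))),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_block(model$upstream, files$upstream)
  write_block(model$downstream, files$downstream)
  utils::write.table(
    data.frame(spacer = names(model$spacer_penalties),
               penalty = fmt_num(unname(model$spacer_penalties))),
    files$spacers, sep = "\t", quote = FALSE, row.names = FALSE)
  dn <- model$dinucleotides
  utils::write.table(
    data.frame(pos_i = dn$pos_i, base_i = dn$base_i, pos_j = dn$pos_j,
               base_j = dn$base_j, delta_e = fmt_num(dn$delta_e)),
    files$dinucleotides, sep = "\t", quote = FALSE, row.names = FALSE)
  obj <- list(
    schema = BUNDLE_SCHEMA,
    upstream_tsv = paste0(base_stem, "_upstream.tsv"),
    downstream_tsv = paste0(base_stem, "_downstream.tsv"),
    spacer_tsv = paste0(base_stem, "_spacers.tsv"),
    dinucleotide_tsv = paste0(base_stem, "_dinucleotides.tsv"),
    mu = model$mu,
    clearance_rate = model$clearance_rate,
    rbs_occlusion_cutoff = model$rbs_occlusion_cutoff)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

read_block_tsv <- function(f, row_order = DNA_BASES) {
  df <- utils::read.delim(f, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"base" %in% names(df))
    stop("matrix TSV ", f, " lacks the 'base' column")
  M <- as.matrix(df[, setdiff(names(df), "base"), drop = FALSE])
  if (anyNA(M))
    stop("matrix TSV ", f, " has a missing value at position column ",
         paste(which(apply(is.na(M), 2, any)), collapse = ","))
  storage.mode(M) <- "double"
  rownames(M) <- df$base
  M <- M[row_order, , drop = FALSE]
  unname_cols <- M
  dimnames(unname_cols) <- list(DNA_BASES, NULL)
  unname_cols
}

#' Load an energy-model parameter bundle
#'
#' Reads the JSON master written by [save_energy_model()]. A `mapping`
#' list can adapt foreign layouts (e.g. a released supplementary table):
#' any of `upstream_tsv`, `downstream_tsv`, `spacer_tsv`,
#' `dinucleotide_tsv`, `row_order`, `mu`, `clearance_rate`,
#' `rbs_occlusion_cutoff` given in `mapping` overrides the JSON fields;
#' `row_order` names the row identity of the matrix TSVs when they are
#' not in A,C,G,T order.
#'
#' @param path JSON master file.
#' @param mapping optional list of overrides (see Details).
#' @return an `energy_model`.
#' @export
load_energy_model <- function(path, mapping = NULL) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, BUNDLE_SCHEMA))
    stop("parameter-bundle schema mismatch: expected '", BUNDLE_SCHEMA,
         "', found '", obj$schema, "'")
  for (nm in names(mapping)) obj[[nm]] <- mapping[[nm]]
  dir <- dirname(path)
  row_order <- if (is.null(obj$row_order)) DNA_BASES else obj$row_order
  up <- read_block_tsv(file.path(dir, obj$upstream_tsv), row_order)
  dn <- read_block_tsv(file.path(dir, obj$downstream_tsv), row_order)
  sp_df <- utils::read.delim(file.path(dir, obj$spacer_tsv),
                             stringsAsFactors = FALSE)
  sp <- stats::setNames(as.numeric(sp_df$penalty), sp_df$spacer)
  dn_df <- utils::read.delim(file.path(dir, obj$dinucleotide_tsv),
                             stringsAsFactors = FALSE)
  if (!nrow(dn_df)) dn_df <- empty_dinucleotides()
  energy_model(up, dn, sp, dinucleotides = dn_df, mu = obj$mu,
               clearance_rate = obj$clearance_rate,
               rbs_occlusion_cutoff = obj$rbs_occlusion_cutoff)
}

#' Predict expression for a set of sequences
#'
#' Per-sequence log10 P_on under both models, together with the strongest
#' binding configuration and, when a measurable-expression cutoff is
#' supplied, the number of "framed" states: configurations bound strongly
#' enough to independently lead to measurable expression.
#'
#' @param seqs sequences (character vector, `promoter_sequence`, list, or
#'   a FASTA path).
#' @param model an `energy_model`.
#' @param measurable_cutoff optional log10 P_on cutoff; a configuration is
#'   framed when it alone (as a single-state system) would exceed it.
#' @param rbs_start RBS position for plain-string input.
#' @return data frame, one row per sequence.
#' @export
predict_expression <- function(seqs, model, measurable_cutoff = NULL,
                               rbs_start = NA_integer_) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
    seqs <- read_promoter_fasta(seqs, rbs = "auto")
  sl <- as_promoter_list(seqs, rbs_start)
  if (!length(sl)) {
    return(data.frame(id = character(), log10_pon_standard = numeric(),
                      log10_pon_extended = numeric()))
  }
  xs <- log10_pon(sl, model, mode = "standard")
  xe <- log10_pon(sl, model, mode = "extended")
  best <- lapply(sl, function(s) {
    cf <- enumerate_configurations(s, model)
    if (!nrow(cf)) {
      return(list(offset = NA_integer_, spacer = NA_integer_,
                  strand = NA_character_, energy = NA_real_, framed = 0L))
    }
    i <- order(cf$energy, cf$offset, cf$spacer)[1]
    framed <- 0L
    if (!is.null(measurable_cutoff)) {
      single <- -log10(1 + exp(cf$energy - model$mu))  # one-state occupancy
      framed <- sum(single >= measurable_cutoff)
    }
    list(offset = cf$offset[i], spacer = cf$spacer[i], strand = cf$strand[i],
         energy = cf$energy[i], framed = as.integer(framed))
  })
  out <- data.frame(
    id = vapply(sl, `[[`, "", "id"),
    log10_pon_standard = xs,
    log10_pon_extended = xe,
    best_offset = vapply(best, `[[`, 1L, "offset"),
    best_spacer = vapply(best, `[[`, 1L, "spacer"),
    best_strand = vapply(best, `[[`, "", "strand"),
    best_energy = vapply(best, `[[`, 1, "energy"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(measurable_cutoff))
    out$n_framed_states <- vapply(best, `[[`, 1L, "framed")
  out
}
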