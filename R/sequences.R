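#' Promoter sequence container
#'
#' A light container for a DNA sequence together with an optional ribosome
#' binding site (Shine-Dalgarno) position. All coordinates on the R side
#' are 1-based and inclusive.
#'
#' @param bases character string over A/C/G/T.
#' @param id identifier (default "seq").
#' @param rbs_start 1-based position of the first base of the
#'   Shine-Dalgarno sequence, or `NA` when the sequence carries no
#'   annotated RBS (e.g. genome fragments, raw random sequences).
#' @return an object of class `promoter_sequence`.
#' @export
promoter_sequence <- function(bases, id = "seq", rbs_start = NA_integer_) {
  bases <- toupper(as.character(bases))
  if (!nzchar(bases)) stop("empty sequence")
  if (grepl("[^ACGT]", bases))
    stop("sequence '", id, "' contains bases outside {A,C,G,T}")
  rbs_start <- as.integer(rbs_start)
  if (!is.na(rbs_start) && (rbs_start < 1L || rbs_start > nchar(bases)))
    stop("rbs_start outside sequence bounds")
  structure(list(id = id, bases = bases, rbs_start = rbs_start),
            class = "promoter_sequence")
}

#' @export
print.promoter_sequence <- function(x, ...) {
  cat(sprintf("<promoter_sequence %s> %d bp, RBS at %s\n", x$id,
              nchar(x$bases),
              if (is.na(x$rbs_start)) "NA" else x$rbs_start))
  invisible(x)
}

# Coerce strings / promoter_sequence objects / lists thereof to a list of
# promoter_sequence.
as_promoter_list <- function(seqs, rbs_start = NA_integer_) {
  if (inherits(seqs, "promoter_sequence")) return(list(seqs))
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    rbs_start <- rep_len(as.integer(rbs_start), length(seqs))
    return(Map(function(b, i, r) promoter_sequence(b, i, r),
               seqs, ids, rbs_start))
  }
  if (is.list(seqs)) {
    stopifnot(all(vapply(seqs, inherits, TRUE, "promoter_sequence")))
    return(seqs)
  }
  stop("cannot interpret 'seqs' as promoter sequences")
}

# Integer encoding A=0 C=1 G=2 T=3 used by the C++ core.
encode_dna <- function(bases) {
  v <- match(strsplit(bases, "")[[1]], DNA_BASES) - 1L
  if (anyNA(v)) stop("sequence contains bases outside {A,C,G,T}")
  v
}

decode_dna <- function(codes) paste(DNA_BASES[codes + 1L], collapse = "")

#' Reverse complement of a DNA string
#' @param bases character string over A/C/G/T.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(bases) {
  unname(chartr("ACGT", "TGCA",
                vapply(bases, function(b)
                  paste(rev(strsplit(b, "")[[1]]), collapse = ""), "")))
}

#' Locate a Shine-Dalgarno motif
#'
#' Finds the first occurrence of the RBS core motif (default "AGGAG") and
#' returns its 1-based start, or `NA` when absent.
#'
#' @param bases character string.
#' @param motif motif to search (default AGGAG).
#' @return integer position or `NA`.
#' @export
find_rbs <- function(bases, motif = "AGGAG") {
  p <- regexpr(motif, bases, fixed = TRUE)
  if (p < 0) NA_integer_ else as.integer(p)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file (multi-record).
#' @param rbs either `NA` (no RBS), `"auto"` (locate the AGGAG motif in
#'   each record), a single integer applied to all records, or the path of
#'   a two-column TSV (id, rbs_start).
#' @return list of `promoter_sequence`.
#' @export
read_promoter_fasta <- function(path, rbs = NA) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  bases <- as.character(ss)
  n <- length(bases)
  if (identical(rbs, "auto")) {
    rpos <- vapply(bases, find_rbs, integer(1))
  } else if (is.character(rbs) && length(rbs) == 1 && file.exists(rbs)) {
    tab <- utils::read.delim(rbs, header = TRUE, stringsAsFactors = FALSE)
    rpos <- tab[[2]][match(ids, tab[[1]])]
  } else {
    rpos <- rep_len(as.integer(rbs), n)
  }
  Map(function(b, i, r) promoter_sequence(b, i, r), bases, ids,
      as.integer(rpos))
}
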