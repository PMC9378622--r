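#' Global pairwise protein alignment against the reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, the built-in
#' pairwise substitute for an externally computed multiple alignment. The
#' dynamic program is delegated to \code{Biostrings::pairwiseAlignment}
#' (deterministic traceback), with BLOSUM62 and gap open 10 / extend 0.5
#' penalties as defaults.
#'
#' @param query,reference \code{ProteinRecord} objects (query is the GPCR to
#'   annotate, reference the anchor, e.g. rhodopsin).
#' @param matrix Substitution matrix name shipped with Biostrings
#'   (e.g. "BLOSUM62", "BLOSUM50", "PAM250").
#' @param gap_open,gap_extend Positive gap penalties.
#' @return Object of class \code{AlignedPair}: \code{ref_id}, \code{qry_id},
#'   \code{ref_aln}, \code{qry_aln} (equal-length gapped strings) and
#'   \code{score}.
#' @export
align_pairwise <- function(query, reference, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(query, "ProteinRecord"),
            inherits(reference, "ProteinRecord"))
  mat <- tryCatch(get_substitution_matrix(matrix),
                  error = function(e) stop("align_pairwise: unknown substitution matrix '",
                                           matrix, "'", call. = FALSE))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query$seq),
    subject = Biostrings::AAString(reference$seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ap <- aligned_pair(ref_id = reference$id, qry_id = query$id,
                     ref_aln = as.character(Biostrings::alignedSubject(pa)),
                     qry_aln = as.character(Biostrings::alignedPattern(pa)),
                     score = Biostrings::score(pa))
  ap
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  suppressWarnings(utils::data(list = name, package = "Biostrings",
                               envir = e))
  get(name, envir = e)
}

#' Construct and validate an aligned pair
#'
#' @param ref_id,qry_id Sequence identifiers.
#' @param ref_aln,qry_aln Gapped alignment rows of equal length; no column
#'   may be a gap in both rows.
#' @param score Alignment score.
#' @return An \code{AlignedPair}.
#' @export
aligned_pair <- function(ref_id, qry_id, ref_aln, qry_aln, score = NA_real_) {
  if (nchar(ref_aln) != nchar(qry_aln))
    stop("aligned_pair: rows have unequal length")
  r <- strsplit(ref_aln, "")[[1]]
  q <- strsplit(qry_aln, "")[[1]]
  if (any(r == "-" & q == "-"))
    stop("aligned_pair: column gapped in both rows")
  structure(list(ref_id = ref_id, qry_id = qry_id,
                 ref_aln = ref_aln, qry_aln = qry_aln, score = score),
            class = "AlignedPair")
}

#' Ingest a pre-computed multiple sequence alignment
#'
#' Reads the output of an external multiple aligner (e.g. MUSCLE) in aligned
#' FASTA or Clustal format and validates equal row lengths.
#'
#' @param path Alignment file.
#' @param format \code{"aligned-fasta"} or \code{"clustal"}.
#' @return Object of class \code{Msa}: \code{rows} (named character vector of
#'   gapped rows) and \code{length} (column count).
#' @export
ingest_msa <- function(path, format = c("aligned-fasta", "clustal")) {
  format <- match.arg(format)
  ma <- tryCatch(
    Biostrings::readAAMultipleAlignment(
      path, format = if (format == "clustal") "clustal" else "fasta"),
    error = function(e) stop("ingest_msa: cannot parse '", path, "' as ",
                             format, ": ", conditionMessage(e), call. = FALSE))
  rows <- as.character(ma)
  names(rows) <- vapply(strsplit(names(rows), "\\s+"), `[[`, character(1), 1L)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("ingest_msa: ragged alignment rows in '", path, "'")
  if (any(!nzchar(gsub("-", "", rows, fixed = TRUE))))
    stop("ingest_msa: row with no residues")
  structure(list(rows = rows, length = unname(lens[1L])), class = "Msa")
}

#' Extract a reference/target pair from an MSA
#'
#' Columns in which both selected rows are gaps are dropped, yielding a valid
#' \code{AlignedPair} on which domain projection operates.
#'
#' @param msa An \code{Msa}.
#' @param ref_id,target_id Row identifiers.
#' @return An \code{AlignedPair}.
#' @export
msa_pair <- function(msa, ref_id, target_id) {
  for (id in c(ref_id, target_id))
    if (!id %in% names(msa$rows))
      stop("msa_pair: alignment does not contain row '", id, "'")
  r <- strsplit(msa$rows[[ref_id]], "")[[1]]
  q <- strsplit(msa$rows[[target_id]], "")[[1]]
  keep <- !(r == "-" & q == "-")
  aligned_pair(ref_id, target_id,
               paste(r[keep], collapse = ""),
               paste(q[keep], collapse = ""))
}
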