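#' @keywords internal
"_PACKAGE"

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                      "M","N","P","Q","R","S","T","V","W","Y","X")
DNA_ALPHABET <- c("A","C","G","T")
STOP_CODONS <- c("TAA","TAG","TGA")

#' Protein sequence record
#'
#' A minimal identified protein sequence. Residues are restricted to the 20
#' canonical amino acids plus \code{X}; anything else is rejected rather than
#' silently remapped, because downstream chimera synthesis requires the exact
#' sequence.
#'
#' @param id Identifier (non-empty string).
#' @param seq Amino-acid sequence (uppercased on construction).
#' @param description Optional free-text description.
#' @return An object of class \code{ProteinRecord} with fields \code{id},
#'   \code{seq}, \code{description}.
#' @export
protein_record <- function(id, seq, description = "") {
  seq <- toupper(as.character(seq))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(seq)) stop("protein_record: empty sequence for '", id, "'")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), PROTEIN_ALPHABET)
  if (length(bad) > 0L) {
    stop("protein_record: record '", id, "' contains invalid residue(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, seq = seq, description = description),
            class = "ProteinRecord")
}

#' Coding DNA sequence record
#'
#' An in-frame open reading frame (frame 0), e.g. a CCDS-style CDS. Length
#' must be divisible by 3; if \code{has_stop}, the final codon must be a stop
#' and no internal in-frame stop codons may occur. \code{U} is rejected: the
#' DNA dialect only.
#'
#' @param id Identifier.
#' @param seq DNA sequence over ACGT (uppercased on construction).
#' @param has_stop Does the sequence end in a stop codon?
#' @return An object of class \code{CdsRecord} with fields \code{id},
#'   \code{seq}, \code{frame} (always 0) and \code{has_stop}.
#' @export
cds_record <- function(id, seq, has_stop = TRUE) {
  seq <- toupper(as.character(seq))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(seq)) stop("cds_record: empty sequence for '", id, "'")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("cds_record: record '", id, "' contains invalid base(s): ",
         paste(bad, collapse = ", "))
  }
  if (nchar(seq) %% 3L != 0L)
    stop("cds_record: length of '", id, "' (", nchar(seq),
         ") is not divisible by 3")
  codons <- codon_split(seq)
  internal_stops <- which(codons[-length(codons)] %in% STOP_CODONS)
  if (has_stop) {
    if (!(codons[length(codons)] %in% STOP_CODONS))
      stop("cds_record: '", id, "' declared has_stop but final codon is ",
           codons[length(codons)])
    if (length(internal_stops) > 0L)
      stop("cds_record: '", id, "' has internal stop codon(s) at codon ",
           paste(internal_stops, collapse = ", "))
  }
  structure(list(id = id, seq = seq, frame = 0L, has_stop = has_stop),
            class = "CdsRecord")
}

codon_split <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Standard-code translation of a \code{CdsRecord} or DNA string; a trailing
#' stop codon is dropped from the peptide.
#'
#' @param cds A \code{CdsRecord} or in-frame DNA string.
#' @return The encoded amino-acid string (no stop symbol).
#' @export
translate_cds <- function(cds) {
  seq <- if (inherits(cds, "CdsRecord")) cds$seq else toupper(cds)
  if (nchar(seq) %% 3L != 0L) stop("translate_cds: length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
  sub("\\*$", "", aa)
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat("ProteinRecord", x$id, "(", nchar(x$seq), "aa )\n")
  invisible(x)
}

#' @export
print.CdsRecord <- function(x, ...) {
  cat("CdsRecord", x$id, "(", nchar(x$seq), "nt,",
      if (x$has_stop) "with stop" else "no stop", ")\n")
  invisible(x)
}
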