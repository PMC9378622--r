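#' Read a FASTA file into validated records
#'
#' Wraps the Biostrings FASTA reader and validates every record against the
#' requested alphabet. Identifiers are taken from the header up to the first
#' whitespace, sequences are uppercased, and alignment gaps (\code{-}) are
#' rejected unless \code{allow_gaps = TRUE}.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either \code{"protein"} or \code{"dna"}.
#' @param allow_gaps Accept '-' characters (aligned FASTA)? Default FALSE.
#' @param has_stop For DNA input, passed through to [cds_record()].
#' @return A list of [protein_record()] or [cds_record()] objects; an empty
#'   list for an empty file.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       allow_gaps = FALSE, has_stop = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) {
                   stop("read_fasta: malformed FASTA in '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (length(ss) == 0L) return(list())
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("read_fasta: duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  descs <- sub("^\\S+\\s*", "", names(ss))
  seqs <- toupper(as.character(ss))
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    s <- seqs[[i]]
    if (grepl("-", s, fixed = TRUE)) {
      if (!allow_gaps)
        stop("read_fasta: record '", ids[i],
             "' contains gap characters; use allow_gaps for aligned input")
    }
    s_nogap <- gsub("-", "", s, fixed = TRUE)
    out[[i]] <- if (alphabet == "protein") {
      r <- protein_record(ids[i], s_nogap, descs[i])
      if (allow_gaps) r$aligned_seq <- s
      r
    } else {
      cds_record(ids[i], s_nogap, has_stop = has_stop)
    }
  }
  names(out) <- ids
  out
}

#' Write records to a FASTA file
#'
#' @param records A list of \code{ProteinRecord}/\code{CdsRecord} objects, or
#'   a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    ids <- names(records)
    seqs <- unname(records)
    descs <- rep("", length(records))
  } else {
    ids <- vapply(records, `[[`, character(1), "id")
    seqs <- vapply(records, `[[`, character(1), "seq")
    descs <- vapply(records, function(r)
      if (is.null(r$description)) "" else r$description, character(1))
  }
  con <- file(path, "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(ids)) {
    hdr <- if (nzchar(descs[i])) paste(ids[i], descs[i]) else ids[i]
    writeLines(paste0(">", hdr), con, sep = "\n")
    n <- nchar(seqs[i])
    starts <- seq(1L, n, by = width)
    writeLines(substring(seqs[i], starts, pmin(starts + width - 1L, n)),
               con, sep = "\n")
  }
  invisible(path)
}
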