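#' Project a reference domain annotation onto a target sequence
#'
#' The central library-building step: every segment boundary of the anchored
#' reference annotation (which must tile the reference protein) is mapped
#' through alignment columns to target residue coordinates, transferring the
#' reference architecture (N-term, TM1-7, ECL1-3, ICL1-3, C-term) onto any
#' aligned GPCR.
#'
#' Boundary-in-gap rule: a target residue aligned against a reference gap is
#' assigned to the segment of the nearest preceding reference residue, so
#' insertions in the target extend the segment they interrupt; target
#' residues aligned entirely before the first reference residue extend the
#' N-terminus, and trailing insertions extend the C-terminus. Projected
#' segments are therefore ordered and disjoint by construction. A segment
#' whose reference residues are all deleted in the target collapses to zero
#' length and is dropped with a warning.
#'
#' @param ref_annotation \code{DomainAnnotation} tiling the reference.
#' @param alignment An \code{AlignedPair} or an \code{Msa}.
#' @param target_id Target row id (required for an \code{Msa}; for an
#'   \code{AlignedPair} defaults to its query).
#' @return \code{DomainAnnotation} for the target. Dropped segments are
#'   listed in attribute \code{"warnings"}.
#' @export
project_domains <- function(ref_annotation, alignment, target_id = NULL) {
  if (inherits(alignment, "Msa")) {
    if (is.null(target_id))
      stop("project_domains: target_id required with an Msa")
    alignment <- msa_pair(alignment, ref_annotation$protein_id, target_id)
  }
  stopifnot(inherits(alignment, "AlignedPair"))
  if (alignment$ref_id != ref_annotation$protein_id)
    stop("project_domains: alignment reference '", alignment$ref_id,
         "' does not match annotation '", ref_annotation$protein_id, "'")
  if (is.null(target_id)) target_id <- alignment$qry_id

  r <- strsplit(alignment$ref_aln, "")[[1]]
  q <- strsplit(alignment$qry_aln, "")[[1]]
  ref_len <- sum(r != "-")
  qry_len <- sum(q != "-")
  if (!annotation_tiles(ref_annotation, ref_len))
    stop("project_domains: reference annotation must tile the aligned reference (length ",
         ref_len, ")")

  # column index (1-based) of each reference residue; cumulative count of
  # target residues up to and including each column
  ref_col <- which(r != "-")
  qry_cum <- cumsum(q != "-")

  # t(a): number of target residues in columns strictly before the column
  # carrying reference residue a (0-based). t(0) := 0 and t(ref_len) :=
  # target length implement the terminal-extension rule.
  t_of <- function(a) {
    if (a <= 0L) return(0L)
    if (a >= ref_len) return(qry_len)
    col <- ref_col[a + 1L]                 # column of ref residue index a
    if (col == 1L) 0L else qry_cum[col - 1L]
  }

  seg <- ref_annotation$segments
  starts <- vapply(seg$start, t_of, integer(1))
  ends <- vapply(seg$end, t_of, integer(1))
  keep <- ends > starts
  dropped <- seg$label[!keep]
  for (lab in dropped)
    warning("project_domains: segment ", lab, " of ", target_id,
            " collapsed to zero length (aligned entirely to gaps)")
  ann <- domain_annotation(target_id,
                           data.frame(label = seg$label[keep],
                                      start = starts[keep], end = ends[keep]),
                           seq_length = qry_len)
  attr(ann, "warnings") <- dropped
  ann
}

#' Extract signaling-domain sequences into a library
#'
#' Builds one library entry per protein, holding the ICL1-3 and C-terminal
#' amino-acid sequences cut out of the protein by its domain annotation --
#' the substrate for chimera design. Proteins whose annotation lacks any
#' signaling segment (e.g. an ambiguous seventh transmembrane helix) are
#' skipped with a warning.
#'
#' @param annotations List of \code{DomainAnnotation}.
#' @param proteins List of \code{ProteinRecord} covering the annotated ids.
#' @return data.frame with columns \code{gpcr_id}, \code{ICL1}, \code{ICL2},
#'   \code{ICL3}, \code{C.term}; skipped ids in attribute \code{"skipped"}.
#' @export
export_signaling_library <- function(annotations, proteins) {
  prot_by_id <- stats::setNames(proteins,
                                vapply(proteins, `[[`, character(1), "id"))
  rows <- list()
  skipped <- character(0)
  for (ann in annotations) {
    p <- prot_by_id[[ann$protein_id]]
    if (is.null(p))
      stop("export_signaling_library: no protein record for '",
           ann$protein_id, "'")
    missing <- setdiff(signaling_labels(), ann$segments$label)
    if (length(missing) > 0L) {
      warning("export_signaling_library: skipping ", ann$protein_id,
              " (missing ", paste(missing, collapse = ", "), ")")
      skipped <- c(skipped, ann$protein_id)
      next
    }
    pull <- function(lab) {
      s <- annotation_segment(ann, lab)
      substring(p$seq, s$start + 1L, s$end)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gpcr_id = ann$protein_id,
      ICL1 = pull("ICL1"), ICL2 = pull("ICL2"), ICL3 = pull("ICL3"),
      C.term = pull("C-term"), stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gpcr_id = character(0), ICL1 = character(0),
               ICL2 = character(0), ICL3 = character(0),
               C.term = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a signaling-domain library to TSV
#' @param library data.frame from [export_signaling_library()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_signaling_library <- function(library, path) {
  df <- library
  names(df)[names(df) == "C.term"] <- "C-term"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
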