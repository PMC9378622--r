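#' Canonical GPCR segment labels
#'
#' The fifteen-segment architecture of a class A GPCR in N- to C-terminal
#' order: N-terminus, seven transmembrane helices, three intracellular and
#' three extracellular loops alternating, and the C-terminus.
#'
#' @return Character vector of the 15 labels in canonical order.
#' @export
canonical_labels <- function() {
  c("N-term", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2", "TM4",
    "ECL2", "TM5", "ICL3", "TM6", "ECL3", "TM7", "C-term")
}

#' Signaling-domain labels (swapped into chimeras)
#' @return Character vector: ICL1-3 and C-term.
#' @export
signaling_labels <- function() c("ICL1", "ICL2", "ICL3", "C-term")

#' Domain annotation of one protein
#'
#' An ordered, non-overlapping set of labeled segments on a protein.
#' Coordinates are 0-based half-open throughout the package; human-facing
#' exports (GenBank, TSV reports) convert to 1-based inclusive.
#'
#' @param protein_id Protein identifier.
#' @param segments data.frame with columns \code{label}, \code{start},
#'   \code{end} (0-based half-open).
#' @param seq_length Optional protein length used to compute coverage.
#' @return Object of class \code{DomainAnnotation}: list with
#'   \code{protein_id}, \code{segments} (sorted by start) and \code{coverage}
#'   (fraction of residues assigned, \code{NA} if \code{seq_length} unknown).
#' @export
domain_annotation <- function(protein_id, segments, seq_length = NA_integer_) {
  stopifnot(is.data.frame(segments),
            all(c("label", "start", "end") %in% names(segments)))
  segments <- segments[, c("label", "start", "end")]
  segments$label <- as.character(segments$label)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  bad <- setdiff(segments$label, canonical_labels())
  if (length(bad) > 0L)
    stop("domain_annotation: unknown segment label(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(segments$label))
    stop("domain_annotation: duplicated segment label(s)")
  if (any(segments$start < 0L) || any(segments$start >= segments$end))
    stop("domain_annotation: segments must satisfy 0 <= start < end")
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] < segments$end[-nrow(segments)]))
    stop("domain_annotation: overlapping segments in '", protein_id, "'")
  cov <- if (is.na(seq_length)) NA_real_ else
    sum(segments$end - segments$start) / seq_length
  structure(list(protein_id = protein_id, segments = segments,
                 seq_length = as.integer(seq_length), coverage = cov),
            class = "DomainAnnotation")
}

annotation_segment <- function(ann, label) {
  i <- match(label, ann$segments$label)
  if (is.na(i)) NULL else ann$segments[i, , drop = FALSE]
}

#' Does an annotation tile its protein completely?
#'
#' TRUE when the segments cover every residue from 0 to the protein length
#' with no holes and appear in canonical architectural order.
#'
#' @param ann A \code{DomainAnnotation}.
#' @param seq_length Protein length; defaults to the one stored in \code{ann}.
#' @return Logical scalar.
#' @export
annotation_tiles <- function(ann, seq_length = ann$seq_length) {
  seg <- ann$segments
  if (is.na(seq_length) || nrow(seg) == 0L) return(FALSE)
  contiguous <- seg$start[1L] == 0L &&
    seg$end[nrow(seg)] == seq_length &&
    (nrow(seg) == 1L || all(seg$start[-1L] == seg$end[-nrow(seg)]))
  in_order <- !is.unsorted(match(seg$label, canonical_labels()),
                           strictly = TRUE)
  contiguous && in_order
}

#' Read a reference domain annotation from YAML
#'
#' The reference (rhodopsin-style) annotation anchors domain identification
#' for every other GPCR. The YAML schema is \code{protein_id}, \code{source}
#' (free-text provenance) and \code{segments}, a list of \code{{label, start,
#' end}} in 0-based half-open coordinates. The annotation must contain the
#' complete canonical 15-segment architecture and tile the reference protein.
#'
#' @param path YAML file path.
#' @return A \code{DomainAnnotation} with an extra \code{source} field.
#' @export
read_reference_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$protein_id) || is.null(y$segments))
    stop("read_reference_annotation: YAML must contain protein_id and segments")
  seg <- do.call(rbind, lapply(y$segments, function(s)
    data.frame(label = s$label, start = s$start, end = s$end,
               stringsAsFactors = FALSE)))
  len <- if (!is.null(y$seq_length)) y$seq_length else max(seg$end)
  ann <- domain_annotation(y$protein_id, seg, seq_length = len)
  if (!setequal(ann$segments$label, canonical_labels()))
    stop("read_reference_annotation: reference must contain all 15 canonical segments")
  if (!annotation_tiles(ann))
    stop("read_reference_annotation: reference segments must tile the protein")
  ann$source <- if (is.null(y$source)) "" else y$source
  ann
}

#' Write a reference annotation to YAML
#' @param ann A complete \code{DomainAnnotation}.
#' @param path Output path.
#' @param source Provenance string recorded in the file.
#' @return Invisibly, \code{path}.
#' @export
write_reference_annotation <- function(ann, path, source = "synthetic") {
  y <- list(protein_id = ann$protein_id,
            seq_length = ann$seq_length,
            source = source,
            segments = lapply(seq_len(nrow(ann$segments)), function(i)
              list(label = ann$segments$label[i],
                   start = ann$segments$start[i],
                   end = ann$segments$end[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write domain annotations as a TSV table
#'
#' One row per segment with 1-based inclusive coordinates for human
#' consumption.
#'
#' @param annotations List of \code{DomainAnnotation}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation_tsv <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(protein_id = a$protein_id, label = a$segments$label,
               start = a$segments$start + 1L, end = a$segments$end,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read domain annotations from TSV (inverse of [write_annotation_tsv()])
#' @param path TSV path with columns protein_id, label, start, end (1-based
#'   inclusive).
#' @return Named list of \code{DomainAnnotation}.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$protein_id), function(d)
    domain_annotation(d$protein_id[1L],
                      data.frame(label = d$label, start = d$start - 1L,
                                 end = d$end),
                      seq_length = max(d$end)))
  out[unique(df$protein_id)]
}

#' @export
print.DomainAnnotation <- function(x, ...) {
  cat("DomainAnnotation for", x$protein_id, "-", nrow(x$segments),
      "segments, coverage", format(x$coverage, digits = 3), "\n")
  print(x$segments)
  invisible(x)
}
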