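#' Map protein segments to codon coordinates in a CDS
#'
#' Verifies that the CDS translates exactly to the protein, then maps every
#' protein segment [a, b) to DNA [3a, 3b) (0-based half-open on both axes).
#' A synonymous codon difference is invisible to this check; a missense
#' difference is reported at the first differing residue.
#'
#' @param protein A \code{ProteinRecord}.
#' @param annotation Its \code{DomainAnnotation}.
#' @param cds A \code{CdsRecord} for the same gene.
#' @return data.frame with columns \code{label}, \code{aa_start},
#'   \code{aa_end}, \code{nt_start}, \code{nt_end}.
#' @export
map_protein_segments_to_cds <- function(protein, annotation, cds) {
  stopifnot(inherits(protein, "ProteinRecord"), inherits(cds, "CdsRecord"))
  aa <- translate_cds(cds)
  if (aa != protein$seq) {
    pa <- strsplit(protein$seq, "")[[1]]
    ca <- strsplit(aa, "")[[1]]
    n <- min(length(pa), length(ca))
    diff <- which(pa[seq_len(n)] != ca[seq_len(n)])
    at <- if (length(diff) > 0L) diff[1L] else n + 1L
    stop("map_protein_segments_to_cds: CDS of '", cds$id,
         "' does not translate to protein '", protein$id,
         "'; first difference at residue ", at)
  }
  seg <- annotation$segments
  data.frame(label = seg$label, aa_start = seg$start, aa_end = seg$end,
             nt_start = 3L * seg$start, nt_end = 3L * seg$end,
             stringsAsFactors = FALSE)
}

#' Assemble the synthesis-ready coding sequence of a chimera
#'
#' Splices DNA for the chimeric protein: receptor segments keep the native
#' codons of their parent of origin (cut from the donor or acceptor CDS at
#' the codon coordinates recorded in the chimera provenance), while tag
#' segments -- which have no natural CDS -- are back-translated with the
#' configured codon table. Because the donor's initiator methionine residue
#' is dropped during protein assembly, its original ATG codon never enters
#' the construct; the single initiator ATG (when enabled) is the one written
#' for the prepended Met. One stop codon is appended. The defining
#' postcondition, translation of the ORF equals the chimera protein, is
#' verified before returning.
#'
#' @param donor_cds,acceptor_cds \code{CdsRecord}s for the two parents, each
#'   consistent with its protein (see [map_protein_segments_to_cds()]).
#' @param chimera A \code{ChimeraProtein} from [assemble_protein()].
#' @param codon_table Codon table name for tag back-translation (see
#'   [back_translate()]).
#' @param stop_codon Stop codon to append (default \code{"TAA"}).
#' @return Object of class \code{ConstructRecord}: \code{name}, \code{dna},
#'   \code{orf} = c(start, end) 0-based half-open span of the ORF including
#'   stop, \code{features} (label, origin, start, end on the DNA),
#'   \code{protein}, and empty flank slots to be filled by
#'   [add_restriction_flanks()].
#' @export
assemble_cds <- function(donor_cds, acceptor_cds, chimera,
                         codon_table = "human-most-frequent",
                         stop_codon = "TAA") {
  stopifnot(inherits(chimera, "ChimeraProtein"))
  if (!stop_codon %in% STOP_CODONS)
    stop("assemble_cds: invalid stop codon ", stop_codon)
  parent_dna <- list(donor = donor_cds$seq, acceptor = acceptor_cds$seq)
  prov <- chimera$provenance
  feats <- list()
  dna_pieces <- character(0)
  nt_pos <- 0L
  for (i in seq_len(nrow(prov))) {
    row <- prov[i, ]
    aa_piece <- substring(chimera$seq, row$start + 1L, row$end)
    piece <- if (row$origin == "tag") {
      bt <- back_translate(aa_piece, codon_table = codon_table,
                           add_stop = FALSE)
      bt$seq
    } else {
      src <- parent_dna[[row$origin]]
      substring(src, 3L * row$src_start + 1L, 3L * row$src_end)
    }
    feats[[length(feats) + 1L]] <- data.frame(
      label = row$label, origin = row$origin, start = nt_pos,
      end = nt_pos + nchar(piece), stringsAsFactors = FALSE)
    dna_pieces <- c(dna_pieces, piece)
    nt_pos <- nt_pos + nchar(piece)
  }
  dna <- paste0(paste(dna_pieces, collapse = ""), stop_codon)
  construct <- structure(
    list(name = chimera$name, dna = dna, orf = c(0L, nchar(dna)),
         features = do.call(rbind, feats), enzymes_5p = NULL,
         enzymes_3p = NULL, protein = chimera),
    class = "ConstructRecord")
  validate_construct(construct)
  construct
}

construct_orf <- function(construct) {
  substring(construct$dna, construct$orf[1L] + 1L, construct$orf[2L])
}

validate_construct <- function(construct) {
  orf <- construct_orf(construct)
  if (translate_cds(orf) != construct$protein$seq)
    stop("ConstructRecord '", construct$name,
         "': ORF translation does not match the chimera protein")
  if (nrow(construct$features) > 0L &&
      any(construct$features$end > nchar(construct$dna)))
    stop("ConstructRecord '", construct$name, "': feature out of bounds")
  invisible(TRUE)
}

#' @export
print.ConstructRecord <- function(x, ...) {
  cat("ConstructRecord", x$name, "(", nchar(x$dna), "bp,",
      nrow(x$features), "features )\n")
  if (!is.null(x$enzymes_5p))
    cat("  flanks:", x$enzymes_5p, "/", x$enzymes_3p, "\n")
  invisible(x)
}
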