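#' N-terminal modifications for chimeric receptors
#'
#' The engineered N-terminus prepended to every construct: a
#' hemagglutinin-derived signal peptide supporting membrane incorporation,
#' a VSV-G epitope for surface staining, and a short linker. The printed
#' signal peptide carries no initiator methionine, so by default a Met is
#' prepended to give the ORF a start codon (a documented design choice).
#' Set all strings empty and \code{include_initiator_met = FALSE} (or use
#' \code{no_mods()}) for an unmodified receptor.
#'
#' @param signal_peptide Signal-peptide sequence.
#' @param epitope Epitope-tag sequence.
#' @param linker Linker sequence.
#' @param include_initiator_met Prepend an initiator Met?
#' @return Object of class \code{NTerminalMods}.
#' @export
n_terminal_mods <- function(signal_peptide = "KTIIALSYIFCLVFA",
                            epitope = "YTDIEMNRLGK",
                            linker = "DSL",
                            include_initiator_met = TRUE) {
  for (s in c(signal_peptide, epitope, linker)) {
    if (nzchar(s)) {
      bad <- setdiff(unique(strsplit(toupper(s), "")[[1]]), PROTEIN_ALPHABET)
      if (length(bad) > 0L)
        stop("n_terminal_mods: invalid residue(s): ",
             paste(bad, collapse = ", "))
    }
  }
  structure(list(signal_peptide = toupper(signal_peptide),
                 epitope = toupper(epitope), linker = toupper(linker),
                 include_initiator_met = isTRUE(include_initiator_met)),
            class = "NTerminalMods")
}

#' Empty N-terminal modifications (unmodified receptor)
#' @return An \code{NTerminalMods} with no tags and no added Met.
#' @export
no_mods <- function() {
  n_terminal_mods("", "", "", include_initiator_met = FALSE)
}

mods_enabled <- function(mods) {
  nzchar(mods$signal_peptide) || nzchar(mods$epitope) ||
    nzchar(mods$linker) || mods$include_initiator_met
}

#' Specify a chimeric receptor design
#'
#' A design names the ligand-binding donor (the DREADD scaffold, e.g.
#' hM3Dq), the signaling-domain acceptor (the GPCR-of-interest) and the set
#' of signaling segments to swap: all four for a full-fidelity chimera, or a
#' subset (e.g. ICL2 and ICL3 only) for designs in the style of rM3Ds.
#'
#' @param donor_id,acceptor_id Parent identifiers.
#' @param swap_set Non-empty subset of \code{signaling_labels()}. "Cterm" is
#'   accepted as an alias for "C-term".
#' @param mods [n_terminal_mods()] object.
#' @param name Construct name (default donor-acceptor).
#' @return Object of class \code{ChimeraDesign}.
#' @export
chimera_design <- function(donor_id, acceptor_id,
                           swap_set = signaling_labels(),
                           mods = n_terminal_mods(), name = NULL) {
  swap_set <- sub("^Cterm$", "C-term", swap_set)
  bad <- setdiff(swap_set, signaling_labels())
  if (length(bad) > 0L)
    stop("chimera_design: invalid swap segment(s): ",
         paste(bad, collapse = ", "))
  if (length(swap_set) == 0L) stop("chimera_design: empty swap_set")
  structure(list(donor_id = donor_id, acceptor_id = acceptor_id,
                 swap_set = unique(swap_set), mods = mods,
                 name = if (is.null(name))
                   paste0(donor_id, "-", acceptor_id) else name),
            class = "ChimeraDesign")
}

#' Assemble a chimeric receptor protein
#'
#' Walks the donor annotation segment by segment in sequence order, replacing
#' each segment named in the design's swap set with the acceptor's
#' corresponding segment, then prepends the N-terminal modifications
#' ([Met] + signal peptide + epitope + linker). When modifications are
#' applied, the donor's own initiator methionine is dropped so that
#' translation cannot initiate downstream of the tag. Provenance is tracked
#' per segment, including the source interval in the parent protein, which
#' later allows the DNA assembly to splice native parent codons.
#'
#' @param donor List of \code{(protein, annotation)} for the ligand-binding
#'   donor; annotation must tile the donor protein.
#' @param acceptor List of \code{(protein, annotation)} for the signaling
#'   acceptor; annotation must contain every swap segment.
#' @param design A \code{ChimeraDesign}.
#' @return Object of class \code{ChimeraProtein}: fields \code{seq},
#'   \code{name} and \code{provenance}, a data.frame tiling \code{seq} with
#'   columns \code{label}, \code{origin} (donor/acceptor/tag), \code{start},
#'   \code{end} (chimera coordinates) and \code{src_start}, \code{src_end}
#'   (parent coordinates; NA for tag segments).
#' @export
assemble_protein <- function(donor, acceptor, design) {
  dp <- donor[[1]]; da <- donor[[2]]
  ap <- acceptor[[1]]; aa <- acceptor[[2]]
  stopifnot(inherits(dp, "ProteinRecord"), inherits(da, "DomainAnnotation"),
            inherits(ap, "ProteinRecord"), inherits(aa, "DomainAnnotation"))
  if (!annotation_tiles(da, nchar(dp$seq)))
    stop("assemble_protein: donor annotation does not tile the donor protein")
  for (lab in design$swap_set) {
    if (is.null(annotation_segment(da, lab)))
      stop("assemble_protein: donor annotation lacks segment ", lab)
    if (is.null(annotation_segment(aa, lab)))
      stop("assemble_protein: acceptor annotation lacks segment ", lab)
  }
  mods_on <- mods_enabled(design$mods)

  prov <- list()
  pieces <- character(0)
  pos <- 0L
  add_piece <- function(label, origin, seq_piece, src_start, src_end) {
    if (!nzchar(seq_piece)) return(invisible())
    prov[[length(prov) + 1L]] <<- data.frame(
      label = label, origin = origin, start = pos,
      end = pos + nchar(seq_piece), src_start = src_start,
      src_end = src_end, stringsAsFactors = FALSE)
    pieces <<- c(pieces, seq_piece)
    pos <<- pos + nchar(seq_piece)
  }

  if (mods_on) {
    if (design$mods$include_initiator_met)
      add_piece("init_Met", "tag", "M", NA_integer_, NA_integer_)
    add_piece("signal_peptide", "tag", design$mods$signal_peptide,
              NA_integer_, NA_integer_)
    add_piece("VSV-G", "tag", design$mods$epitope, NA_integer_, NA_integer_)
    add_piece("DSL_linker", "tag", design$mods$linker,
              NA_integer_, NA_integer_)
  }

  for (i in seq_len(nrow(da$segments))) {
    lab <- da$segments$label[i]
    if (lab %in% design$swap_set) {
      s <- annotation_segment(aa, lab)
      add_piece(lab, "acceptor",
                substring(ap$seq, s$start + 1L, s$end), s$start, s$end)
    } else {
      s0 <- da$segments$start[i]; e0 <- da$segments$end[i]
      # drop the donor's initiator Met when mods are applied
      if (mods_on && i == 1L && substring(dp$seq, 1L, 1L) == "M")
        s0 <- s0 + 1L
      add_piece(lab, "donor", substring(dp$seq, s0 + 1L, e0), s0, e0)
    }
  }

  structure(list(name = design$name, seq = paste(pieces, collapse = ""),
                 provenance = do.call(rbind, prov),
                 donor_id = dp$id, acceptor_id = ap$id,
                 swap_set = design$swap_set, mods = design$mods),
            class = "ChimeraProtein")
}

#' @export
print.ChimeraProtein <- function(x, ...) {
  cat("ChimeraProtein", x$name, "(", nchar(x$seq), "aa )\n")
  print(x$provenance)
  invisible(x)
}
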