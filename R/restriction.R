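#' Restriction enzyme recognition sites used for cloning flanks
#' @return Named character vector of recognition sequences.
#' @export
enzyme_sites <- function() {
  c(EcoRI = "GAATTC", NotI = "GCGGCCGC", BamHI = "GGATCC")
}

count_site <- function(dna, site) {
  length(Biostrings::matchPattern(site, Biostrings::DNAString(dna)))
}

site_positions <- function(dna, site) {  # 0-based starts
  Biostrings::start(Biostrings::matchPattern(site,
                                             Biostrings::DNAString(dna))) - 1L
}

#' Add restriction-site flanks to a construct
#'
#' Prepends the 5' enzyme's recognition site and appends the 3' enzyme's
#' (cloning convention: EcoRI or NotI upstream, BamHI downstream), then
#' screens the whole construct so that each chosen site occurs exactly once.
#' An occurrence inside the ORF is eliminated by exhaustive synonymous
#' recoding of the codons overlapping it: all combinations of synonymous
#' codons at those positions are tried in deterministic order and the first
#' combination that removes the site without altering the translation or
#' creating a new site of either enzyme is taken. If no combination exists,
#' a design error lists the offending positions.
#'
#' @param construct A \code{ConstructRecord} without flanks.
#' @param five_prime 5' enzyme: \code{"EcoRI"} or \code{"NotI"}.
#' @param three_prime 3' enzyme (default \code{"BamHI"}).
#' @return The flanked \code{ConstructRecord}: \code{dna} gains the two
#'   sites, all feature and ORF coordinates shift by the 5' site length, and
#'   two \code{restriction_site} features are added.
#' @export
add_restriction_flanks <- function(construct, five_prime = c("EcoRI", "NotI"),
                                   three_prime = "BamHI") {
  five_prime <- match.arg(five_prime)
  sites <- enzyme_sites()
  if (!three_prime %in% names(sites))
    stop("add_restriction_flanks: unknown enzyme ", three_prime)
  if (!is.null(construct$enzymes_5p))
    stop("add_restriction_flanks: construct already has flanks")
  site5 <- unname(sites[five_prime])
  site3 <- unname(sites[three_prime])

  orf <- construct_orf(construct)
  for (site in unique(c(site5, site3)))
    orf <- recode_internal_sites(orf, site,
                                 all_sites = unique(c(site5, site3)),
                                 name = construct$name)

  dna <- paste0(site5, orf, site3)
  off <- nchar(site5)
  feats <- construct$features
  feats$start <- feats$start + off
  feats$end <- feats$end + off
  feats <- rbind(
    data.frame(label = paste0(five_prime, "_site"), origin = "flank",
               start = 0L, end = nchar(site5), stringsAsFactors = FALSE),
    feats,
    data.frame(label = paste0(three_prime, "_site"), origin = "flank",
               start = nchar(dna) - nchar(site3), end = nchar(dna),
               stringsAsFactors = FALSE))
  out <- construct
  out$dna <- dna
  out$orf <- construct$orf + off
  out$features <- feats
  out$enzymes_5p <- five_prime
  out$enzymes_3p <- three_prime
  validate_construct(out)
  # uniqueness invariant: each flank site exactly once in the full construct
  for (enz in c(five_prime, three_prime)) {
    n <- count_site(dna, unname(sites[enz]))
    if (n != 1L)
      stop("add_restriction_flanks: ", enz, " site occurs ", n,
           " times in construct '", construct$name, "'")
  }
  out
}

# Remove every occurrence of `site` from an ORF by synonymous recoding of the
# codons it overlaps. Exhaustive over the cartesian product of synonymous
# codons at those positions (<= 3 codons for sites up to 8 nt).
recode_internal_sites <- function(orf, site, all_sites, name = "construct") {
  repeat {
    pos <- site_positions(orf, site)
    if (length(pos) == 0L) return(orf)
    p <- pos[1L]
    codon_idx <- unique((p:(p + nchar(site) - 1L)) %/% 3L)  # 0-based codons
    codons <- codon_split(orf)
    aas <- strsplit(translate_cds_with_stop(orf), "")[[1]]
    alt_sets <- lapply(codon_idx, function(ci) {
      sort(unique(c(codons[ci + 1L],
                    synonymous_codons(aas[ci + 1L]))))
    })
    combos <- expand.grid(alt_sets, stringsAsFactors = FALSE)
    fixed <- NULL
    for (k in seq_len(nrow(combos))) {
      cand <- codons
      cand[codon_idx + 1L] <- as.character(combos[k, ])
      cand_orf <- paste(cand, collapse = "")
      # the substitution must kill this occurrence and introduce no new
      # occurrence of any chosen enzyme's site
      ok <- !p %in% site_positions(cand_orf, site)
      if (ok) {
        for (s in all_sites) {
          if (length(site_positions(cand_orf, s)) >
              length(site_positions(orf, s)) - as.integer(s == site))
            ok <- FALSE
        }
      }
      if (ok) { fixed <- cand_orf; break }
    }
    if (is.null(fixed))
      stop("add_restriction_flanks: internal ", site,
           " site at ORF position ", p + 1L, " of '", name,
           "' cannot be removed by synonymous recoding")
    orf <- fixed
  }
}

translate_cds_with_stop <- function(orf) {
  as.character(Biostrings::translate(Biostrings::DNAString(orf)))
}
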