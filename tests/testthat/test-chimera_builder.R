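# Hand-sized parents used in several blocks: donor "M AAA WWWWW RRR WWWWW KKK"
# with architecture N-term, TM1, ICL1, TM2, C-term (a 2-TM miniature).
mini_parent <- function(id, icl1 = "RRR", cterm = "KKK") {
  seqs <- c("M", "AAA", "WWWWW", icl1, "WWWWW", cterm)
  labels <- c("N-term", "TM1", "ICL1", "TM2", "C-term")
  pieces <- c(paste0(seqs[1], seqs[2]), seqs[3], seqs[4], seqs[5], seqs[6])
  ends <- cumsum(nchar(pieces))
  list(protein = protein_record(id, paste(pieces, collapse = "")),
       annotation = domain_annotation(id, data.frame(
         label = labels, start = c(0L, ends[-length(ends)]), end = ends),
         seq_length = sum(nchar(pieces))))
}

test_that("segment swap replaces exactly the designed signaling domains", {
  don <- mini_parent("don")
  acc <- mini_parent("acc", icl1 = "QQQQ", cterm = "EEEE")
  ch <- assemble_protein(list(don$protein, don$annotation),
                         list(acc$protein, acc$annotation),
                         chimera_design("don", "acc", swap_set = "ICL1",
                                        mods = no_mods()))
  expect_equal(ch$seq, paste0("MAAA", "WWWWW", "QQQQ", "WWWWW", "KKK"))
  prov <- ch$provenance
  expect_equal(prov$origin[prov$label == "ICL1"], "acceptor")
  expect_setequal(prov$origin[prov$label != "ICL1"], "donor")
  # provenance tiles the chimera exactly
  expect_equal(prov$start, c(0L, cumsum(prov$end - prov$start))[seq_len(nrow(prov))])
  expect_equal(prov$end[nrow(prov)], nchar(ch$seq))
})

test_that("self-swap without mods is the identity; assembly is idempotent", {
  pair <- toy_pair(41, 41)
  g <- pair$don
  design <- chimera_design(g$protein$id, g$protein$id, mods = no_mods())
  ch <- assemble_protein(list(g$protein, g$annotation),
                         list(g$protein, g$annotation), design)
  expect_equal(ch$seq, g$protein$seq)

  # applying the same swap to the resulting chimera again changes nothing
  ann2 <- domain_annotation(g$protein$id,
                            ch$provenance[, c("label", "start", "end")],
                            seq_length = nchar(ch$seq))
  ch2 <- assemble_protein(list(protein_record(g$protein$id, ch$seq), ann2),
                          list(g$protein, g$annotation), design)
  expect_equal(ch2$seq, ch$seq)
})

test_that("default N-terminal mods prepend Met + signal peptide + VSV-G + linker and drop the donor Met", {
  pair <- toy_pair(43, 44)
  ch <- assemble_protein(list(pair$don$protein, pair$don$annotation),
                         list(pair$acc$protein, pair$acc$annotation),
                         chimera_design("don43", "acc44"))
  expect_true(startsWith(ch$seq, "MKTIIALSYIFCLVFAYTDIEMNRLGKDSL"))
  # donor initiator Met dropped: N-term provenance starts at source residue 1
  nterm <- ch$provenance[ch$provenance$label == "N-term", ]
  expect_equal(nterm$src_start, 1L)
  # length conservation identity
  swap_len <- function(ann) sum(ann$segments$end[ann$segments$label %in%
                                                   signaling_labels()] -
                                ann$segments$start[ann$segments$label %in%
                                                     signaling_labels()])
  tags <- nchar("KTIIALSYIFCLVFAYTDIEMNRLGKDSL")
  expect_equal(nchar(ch$seq),
               nchar(pair$don$protein$seq) - swap_len(pair$don$annotation) +
                 swap_len(pair$acc$annotation) + tags + 1L - 1L)
  # missing acceptor segment is a design error naming the segment
  chopped <- pair$acc$annotation
  chopped$segments <- chopped$segments[chopped$segments$label != "ICL2", ]
  expect_error(assemble_protein(list(pair$don$protein, pair$don$annotation),
                                list(pair$acc$protein, chopped),
                                chimera_design("don43", "acc44")), "ICL2")
})

test_that("protein-to-CDS mapping is 3x arithmetic and missense-sensitive", {
  g <- make_toy_gpcr(toy_gpcr_spec(seed = 51), id = "m1")
  cds <- back_translate(g$protein, seed = 3)
  m <- map_protein_segments_to_cds(g$protein, g$annotation, cds)
  expect_equal(m$nt_start, 3L * m$aa_start)
  expect_equal(m$nt_end, 3L * m$aa_end)
  # concatenating mapped DNA blocks and translating reproduces the protein
  blocks <- substring(cds$seq, m$nt_start + 1L, m$nt_end)
  expect_equal(translate_cds(paste(blocks, collapse = "")), g$protein$seq)

  # a synonymous codon change still passes; a missense change errors with
  # the residue position
  syn <- cds$seq
  stopifnot(substr(syn, 4, 6) %in% c("AGC", "TCA", "TCC", "TCG", "TCT",
                                     "AGT", "GGA", "GGC", "GGG", "GGT"))
  aa2 <- substr(g$protein$seq, 2, 2)
  alt <- setdiff(synonymous_codons(aa2), substr(syn, 4, 6))[1]
  substr(syn, 4, 6) <- alt
  expect_silent(map_protein_segments_to_cds(
    g$protein, g$annotation, cds_record("m1", syn)))
  mis <- cds$seq
  substr(mis, 4, 6) <- if (substr(mis, 4, 6) == "TGG") "TGC" else "TGG"
  expect_error(map_protein_segments_to_cds(
    g$protein, g$annotation, cds_record("m1", mis)), "residue 2")
})

test_that("CDS assembly splices native parent codons and excludes the donor ATG", {
  pair <- toy_pair(61, 62)
  # distinguishable synonymous styles: donor uses most-frequent human codons,
  # acceptor uses seeded random synonymous codons
  dcds <- back_translate(pair$don$protein)
  acds <- back_translate(pair$acc$protein, "uniform-random", seed = 9)
  ch <- assemble_protein(list(pair$don$protein, pair$don$annotation),
                         list(pair$acc$protein, pair$acc$annotation),
                         chimera_design("don61", "acc62"))
  con <- assemble_cds(dcds, acds, ch)
  expect_equal(translate_cds(construct_orf_seq(con)), ch$seq)
  # spliced blocks match their parent of origin codon-for-codon
  for (i in seq_len(nrow(con$features))) {
    f <- con$features[i, ]
    if (f$origin == "tag") next
    src <- if (f$origin == "donor") dcds$seq else acds$seq
    row <- ch$provenance[i, ]
    expect_equal(substring(con$dna, f$start + 1L, f$end),
                 substring(src, 3L * row$src_start + 1L, 3L * row$src_end))
  }
  # exactly one in-frame ATG-initiated start; donor's original first codon
  # does not survive at the junction
  expect_equal(substr(con$dna, 1, 3), "ATG")
  nterm_feat <- con$features[con$features$label == "N-term", ]
  expect_false(substring(con$dna, nterm_feat$start + 1L,
                         nterm_feat$start + 3L) == "ATG")
  expect_true(grepl("TAA$", con$dna))
})

test_that("restriction flanks are unique, internal sites recoded or rejected", {
  pair <- toy_pair(71, 72)
  ch <- assemble_protein(list(pair$don$protein, pair$don$annotation),
                         list(pair$acc$protein, pair$acc$annotation),
                         chimera_design("don71", "acc72"))
  dcds <- back_translate(pair$don$protein, seed = 4)
  acds <- back_translate(pair$acc$protein, seed = 5)
  con <- assemble_cds(dcds, acds, ch)
  for (enz5 in c("EcoRI", "NotI")) {
    fl <- add_restriction_flanks(con, enz5, "BamHI")
    sites <- enzyme_sites()
    expect_equal(nchar(fl$dna), nchar(con$dna) + nchar(sites[[enz5]]) + 6L)
    for (enz in c(enz5, "BamHI")) {
      hits <- gregexpr(sites[enz], fl$dna, fixed = TRUE)[[1]]
      expect_length(hits, 1L)
    }
    expect_true(startsWith(fl$dna, sites[enz5]))
    expect_true(endsWith(fl$dna, sites["BamHI"]))
    expect_equal(translate_cds(construct_orf_seq(fl)), ch$seq)
    expect_error(add_restriction_flanks(fl, enz5), "already has flanks")
  }

  # engineered internal BamHI site (GGA|TCC = Gly-Ser) is synonymously
  # recoded; translation unchanged, zero internal sites afterwards
  prot <- protein_record("gs", "MAGSWAAK")
  cds <- cds_record("gs", "ATGGCTGGATCCTGGGCTGCTAAATAA")
  ann <- domain_annotation("gs", data.frame(
    label = c("N-term", "C-term"), start = c(0, 4), end = c(4, 8)),
    seq_length = 8)
  ch2 <- assemble_protein(list(prot, ann), list(prot, ann),
                          chimera_design("gs", "gs", swap_set = "C-term",
                                         mods = no_mods()))
  con2 <- assemble_cds(cds, cds, ch2)
  expect_true(grepl("GGATCC", con2$dna))
  fl2 <- add_restriction_flanks(con2, "EcoRI", "BamHI")
  expect_length(gregexpr("GGATCC", fl2$dna, fixed = TRUE)[[1]], 1L)
  expect_equal(translate_cds(construct_orf_seq(fl2)), ch2$seq)
  # the recoding agrees with an exhaustive synonymous-codon search: collect
  # every synonymous combination at the two offending codons and check the
  # recoder picked one of exactly the site-free ones
  gly_ser <- expand.grid(synonymous_codons("G"), synonymous_codons("S"),
                         stringsAsFactors = FALSE)
  all_variants <- paste0("ATGGCT", gly_ser[[1]], gly_ser[[2]],
                         "TGGGCTGCTAAATAA")
  escapes <- all_variants[!grepl("GGATCC", all_variants, fixed = TRUE)]
  expect_true(length(escapes) > 0L)
  orf2 <- substring(fl2$dna, fl2$orf[1] + 1L, fl2$orf[2])
  expect_true(orf2 %in% escapes)
})

test_that("a site whose overlapping codons admit no synonymous escape is a design error", {
  # Met and Trp are the only residues with a single codon, so a recognition
  # site tiled exactly by ATG+TGG cannot be recoded away; the real cloning
  # sites always overlap a degenerate codon, so exercise the branch with a
  # synthetic site
  orf <- "ATGTGGAAATAA"  # M W K stop
  expect_error(
    gpcrchimera:::recode_internal_sites(orf, "ATGTGG",
                                        all_sites = "ATGTGG", name = "toy"),
    "cannot be removed")
  # and the degenerate-codon case on the same path succeeds
  fixed <- gpcrchimera:::recode_internal_sites("ATGGGATCCTAA", "GGATCC",
                                               all_sites = "GGATCC",
                                               name = "toy")
  expect_false(grepl("GGATCC", fixed, fixed = TRUE))
  expect_equal(gpcrchimera:::translate_cds_with_stop(fixed),
               gpcrchimera:::translate_cds_with_stop("ATGGGATCCTAA"))
})
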