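test_that("pairwise alignment matches exhaustive affine-gap oracle on tiny pairs", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  # self-alignment: no gaps, score = sum of diagonal entries
  p <- protein_record("a", "ACDE")
  self <- align_pairwise(p, protein_record("b", "ACDE"))
  expect_equal(self$qry_aln, "ACDE")
  expect_equal(self$ref_aln, "ACDE")
  expect_equal(self$score, sum(diag(mat[c("A","C","D","E"), c("A","C","D","E")])))

  # single gap placed opposite the extra residue
  ap <- align_pairwise(protein_record("q", "ACE"), protein_record("r", "ACDE"))
  expect_equal(ap$qry_aln, "AC-E")
  expect_equal(ap$ref_aln, "ACDE")

  # score equals the exhaustive enumeration oracle on random <=5-residue pairs
  set.seed(99)
  for (k in 1:12) {
    a <- paste(sample(AA20, sample(2:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(AA20, sample(2:5, 1), replace = TRUE), collapse = "")
    got <- align_pairwise(protein_record("a", a), protein_record("b", b))
    expect_equal(got$score, nw_score_oracle(a, b, mat), tolerance = 1e-9,
                 label = paste("score", a, b))
    # role symmetry
    swapped <- align_pairwise(protein_record("b", b), protein_record("a", a))
    expect_equal(got$score, swapped$score, tolerance = 1e-9)
  }
  expect_error(align_pairwise(p, p, matrix = "NOSUCH62"), "unknown")
})

test_that("aligned pairs reject ragged rows and all-gap columns", {
  expect_error(aligned_pair("r", "q", "AC-", "AC"), "unequal")
  expect_error(aligned_pair("r", "q", "A-C", "A-C"), "both rows")
  ok <- aligned_pair("r", "q", "A-C", "AGC")
  expect_s3_class(ok, "AlignedPair")
})

test_that("MSA ingestion validates shape and cross-format parses agree", {
  rows <- c(REF = "MKT-IA", QRY = "MK-LIA", THR = "M--LIA")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(rows), function(n) c(paste0(">", n), rows[[n]]))), fa)
  msa <- ingest_msa(fa)
  expect_equal(msa$length, 6L)
  expect_equal(msa$rows, rows)

  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               sprintf("%-6s %s", names(rows), rows)), cl)
  msa2 <- ingest_msa(cl, format = "clustal")
  expect_equal(msa2$rows, msa$rows)

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "ACD"), ragged)
  expect_error(ingest_msa(ragged), "parse|ragged")
  expect_error(msa_pair(msa, "RHO", "QRY"), "RHO")
})

test_that("projection through a hand-built alignment shifts segments past insertions", {
  # reference MAAAWWWWWRRRR with N-term [0,4) TM1 [4,9) ICL1 [9,13);
  # target carries a 2-residue insertion inside TM1
  ref_ann <- domain_annotation("REF", data.frame(
    label = c("N-term", "TM1", "ICL1"), start = c(0, 4, 9), end = c(4, 9, 13)),
    seq_length = 13)
  ap <- aligned_pair("REF", "QRY",
                     "MAAAWW--WWWRRRR",
                     "MAAAWWGGWWWRRRR")
  got <- project_domains(ref_ann, ap)
  expect_equal(got$segments,
               data.frame(label = c("N-term", "TM1", "ICL1"),
                          start = c(0L, 4L, 11L), end = c(4L, 11L, 15L)))
})

test_that("self-projection is the identity and terminal insertions extend the termini", {
  g <- make_toy_gpcr(toy_gpcr_spec(seed = 5), id = "REF")
  self <- aligned_pair("REF", "REF", g$protein$seq, g$protein$seq)
  expect_equal(project_domains(g$annotation, self)$segments,
               g$annotation$segments)

  # leading and trailing target-only residues are claimed by N-term / C-term
  ref_ann <- domain_annotation("REF", data.frame(
    label = c("N-term", "TM1", "C-term"), start = c(0, 2, 5),
    end = c(2, 5, 8)), seq_length = 8)
  ap <- aligned_pair("REF", "QRY", "--SSWWWSSS--", "GGSSWWWSSSGG")
  got <- project_domains(ref_ann, ap)
  expect_equal(got$segments$start, c(0L, 4L, 7L))
  expect_equal(got$segments$end, c(4L, 7L, 12L))
})

test_that("a segment deleted in the target is dropped with a warning", {
  ref_ann <- domain_annotation("REF", data.frame(
    label = c("N-term", "TM1", "ICL1"), start = c(0, 2, 5), end = c(2, 5, 8)),
    seq_length = 8)
  ap <- aligned_pair("REF", "QRY", "SSWWWSSS", "SS---SSS")
  expect_warning(got <- project_domains(ref_ann, ap), "TM1")
  expect_false("TM1" %in% got$segments$label)
  expect_equal(attr(got, "warnings"), "TM1")
})

test_that("projection agrees exactly with the per-column label-transfer oracle", {
  for (s in 1:40) {
    fx <- make_random_alignment(s)
    got <- suppressWarnings(project_domains(fx$annotation, fx$pair))
    exp <- project_oracle(fx$annotation, fx$pair)
    expect_equal(got$segments, exp, label = paste("seed", s))
    # monotone, disjoint
    expect_true(!is.unsorted(got$segments$start, strictly = TRUE))
    expect_true(all(got$segments$start[-1L] >=
                      got$segments$end[-nrow(got$segments)]))
  }
})

test_that("signaling library export skips incomplete annotations and splices back", {
  pair <- toy_pair(31, 32)
  lib <- export_signaling_library(list(pair$don$annotation, pair$acc$annotation),
                                  list(pair$don$protein, pair$acc$protein))
  expect_equal(nrow(lib), 2L)
  expect_equal(lib$gpcr_id, c("don31", "acc32"))
  # splice-reassembly: substituting the exported strings back into their
  # coordinates reproduces the source protein
  for (i in 1:2) {
    g <- list(pair$don, pair$acc)[[i]]
    for (lab in c("ICL1", "ICL2", "ICL3", "C-term")) {
      seg <- g$annotation$segments[g$annotation$segments$label == lab, ]
      col <- if (lab == "C-term") "C.term" else lab
      expect_equal(lib[[col]][i],
                   substring(g$protein$seq, seg$start + 1, seg$end))
    }
  }
  # annotation lacking C-term: skipped with a warning
  chopped <- pair$don$annotation
  chopped$segments <- chopped$segments[chopped$segments$label != "C-term", ]
  expect_warning(
    lib2 <- export_signaling_library(list(chopped), list(pair$don$protein)),
    "C-term")
  expect_equal(nrow(lib2), 0L)
  expect_equal(attr(lib2, "skipped"), "don31")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_signaling_library(lib, tsv)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(names(back), c("gpcr_id", "ICL1", "ICL2", "ICL3", "C-term"))
  expect_equal(back$ICL2, lib$ICL2)
})
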