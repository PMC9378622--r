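# Independent oracles and randomized fixture builders shared by the tests.
# These deliberately re-derive expected results by the dumbest correct route
# (per-column walks, exhaustive enumeration) so they cannot share a bug with
# the implementation paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# --- projection oracle: per-column label transfer -------------------------
# Each target residue takes the label of the reference segment covering the
# reference residue in its column; in a reference-gap column it takes the
# label of the nearest preceding reference residue (first segment if none).
# Maximal runs of one label become segments.
project_oracle <- function(ref_annotation, ap) {
  r <- strsplit(ap$ref_aln, "")[[1]]
  q <- strsplit(ap$qry_aln, "")[[1]]
  seg <- ref_annotation$segments
  label_of_ref_residue <- function(idx) {  # 0-based residue index
    hit <- which(seg$start <= idx & idx < seg$end)
    seg$label[hit]
  }
  labels <- character(0)
  ref_idx <- -1L  # last reference residue index seen
  for (cc in seq_along(r)) {
    if (r[cc] != "-") ref_idx <- ref_idx + 1L
    if (q[cc] != "-") {
      lab <- if (ref_idx < 0L) seg$label[1L] else label_of_ref_residue(ref_idx)
      labels <- c(labels, lab)
    }
  }
  if (length(labels) == 0L) return(NULL)
  run_ends <- c(which(labels[-1L] != labels[-length(labels)]),
                length(labels))
  run_starts <- c(1L, run_ends[-length(run_ends)] + 1L)
  data.frame(label = labels[run_starts], start = run_starts - 1L,
             end = run_ends, stringsAsFactors = FALSE)
}

# --- random alignment + annotation fixture --------------------------------
# Builds a reference with a full 15-segment tiling annotation and a target
# derived from it through random match/delete/insert ops, returning the
# implied gapped alignment directly (no aligner involved).
make_random_alignment <- function(seed) {
  set.seed(seed)
  labels <- gpcrchimera::canonical_labels()
  lens <- 1L + stats::rpois(length(labels), 2)
  ref_len <- sum(lens)
  ends <- cumsum(lens)
  ann <- gpcrchimera::domain_annotation(
    "REF", data.frame(label = labels, start = c(0L, ends[-length(ends)]),
                      end = ends), seq_length = ref_len)
  ref_seq <- paste(sample(AA20, ref_len, replace = TRUE), collapse = "")
  r_chars <- strsplit(ref_seq, "")[[1]]
  ref_aln <- character(0); qry_aln <- character(0)
  emit_ins <- function(n) {
    ref_aln <<- c(ref_aln, rep("-", n))
    qry_aln <<- c(qry_aln, sample(AA20, n, replace = TRUE))
  }
  if (stats::runif(1) < 0.3) emit_ins(sample.int(3L, 1L))  # leading insertion
  for (i in seq_len(ref_len)) {
    u <- stats::runif(1)
    if (u < 0.15) {            # deletion: ref residue unmatched
      ref_aln <- c(ref_aln, r_chars[i]); qry_aln <- c(qry_aln, "-")
    } else {                   # match
      ref_aln <- c(ref_aln, r_chars[i])
      qry_aln <- c(qry_aln, sample(AA20, 1L))
    }
    if (stats::runif(1) < 0.1) emit_ins(sample.int(2L, 1L))
  }
  if (stats::runif(1) < 0.3) emit_ins(sample.int(3L, 1L))  # trailing insertion
  if (all(qry_aln == "-")) {   # degenerate: force one aligned residue
    qry_aln[1L] <- sample(AA20, 1L)
  }
  list(annotation = ann,
       pair = gpcrchimera::aligned_pair("REF", "QRY",
                                        paste(ref_aln, collapse = ""),
                                        paste(qry_aln, collapse = "")))
}

# --- exhaustive global-alignment score oracle -----------------------------
# Enumerates every global alignment of two tiny sequences and scores it with
# affine gaps (a gap run of length L costs open + L * extend). Returns the
# optimal score.
nw_score_oracle <- function(a, b, mat, open = 10, extend = 0.5) {
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > nchar(a) && j > nchar(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b))
      rec(i + 1L, j + 1L,
          score + mat[substr(a, i, i), substr(b, j, j)], "M")
    if (i <= nchar(a))
      rec(i + 1L, j, score - extend - if (prev == "Ib") 0 else open, "Ib")
    if (j <= nchar(b))
      rec(i, j + 1L, score - extend - if (prev == "Ia") 0 else open, "Ia")
  }
  rec(1L, 1L, 0, "start")
  best
}

# --- misc helpers ---------------------------------------------------------
toy_pair <- function(seed_donor, seed_acceptor, ...) {
  don <- gpcrchimera::make_toy_gpcr(gpcrchimera::toy_gpcr_spec(seed = seed_donor, ...),
                                    id = paste0("don", seed_donor))
  acc <- gpcrchimera::make_toy_gpcr(gpcrchimera::toy_gpcr_spec(seed = seed_acceptor, ...),
                                    id = paste0("acc", seed_acceptor))
  list(don = don, acc = acc)
}

random_protein <- function(n, seed) {
  set.seed(seed)
  gpcrchimera::protein_record(paste0("p", seed),
                              paste(sample(AA20, n, replace = TRUE),
                                    collapse = ""))
}

construct_orf_seq <- function(con) {
  substring(con$dna, con$orf[1] + 1L, con$orf[2])
}
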