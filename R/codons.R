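# Codon tables for back-translation of tag segments and for synonymous
# recoding during restriction-site screening. Receptor segments themselves
# are never back-translated: they keep their native parent codons.

#' Most-frequent human codon per amino acid
#'
#' Deterministic back-translation table (the single most used codon per
#' residue in the human genome).
#'
#' @return Named character vector, amino acid -> codon.
#' @export
human_codon_table <- function() {
  c(A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
    E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
    M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
    Y = "TAC", V = "GTG")
}

#' All synonymous codons for an amino acid (standard code)
#' @param aa Single-letter amino acid.
#' @return Character vector of codons encoding \code{aa}.
#' @export
synonymous_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == aa])
}

#' Back-translate a protein to a coding sequence
#'
#' Either deterministic (most-frequent human codon per residue) or sampled
#' uniformly over synonymous codons with a seed, so that two seeds give
#' synonymous but generally unequal DNA with identical translation.
#'
#' @param protein A \code{ProteinRecord} or amino-acid string.
#' @param codon_table \code{"human-most-frequent"} (deterministic) or
#'   \code{"uniform-random"}.
#' @param seed Integer seed used when sampling.
#' @param add_stop Append a TAA stop codon (default TRUE).
#' @return A \code{CdsRecord} whose translation equals the input protein.
#' @export
back_translate <- function(protein, codon_table = c("human-most-frequent",
                                                    "uniform-random"),
                           seed = 1L, add_stop = TRUE) {
  codon_table <- match.arg(codon_table)
  seq <- if (inherits(protein, "ProteinRecord")) protein$seq else
    toupper(protein)
  id <- if (inherits(protein, "ProteinRecord")) protein$id else "cds"
  aa <- strsplit(seq, "")[[1]]
  if ("X" %in% aa)
    stop("back_translate: cannot back-translate residue X")
  dna <- if (codon_table == "human-most-frequent") {
    unname(human_codon_table()[aa])
  } else {
    rng <- local_rng(seed)
    vapply(aa, function(a) {
      syn <- synonymous_codons(a)
      syn[rng$int(length(syn))]
    }, character(1))
  }
  cds_record(id, paste0(paste(dna, collapse = ""),
                        if (add_stop) "TAA" else ""),
             has_stop = add_stop)
}

# Small self-contained RNG handle: isolates all fixture/sampler randomness
# from the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  assign("state", local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  }), env)
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", get("state", env), globalenv())
    on.exit({
      assign("state", get(".Random.seed", globalenv()), env)
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    int = function(n) with_state(function() sample.int(n, 1L)),
    sample = function(x, size, replace = FALSE)
      with_state(function() sample(x, size, replace = replace)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd))
  )
}
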