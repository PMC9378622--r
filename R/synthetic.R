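# Seeded fixture generators. Every generator restores the caller's RNG
# state, so fixture randomness never leaks into user code.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a toy multi-pass membrane protein
#'
#' Parameters of the synthetic 7TM fixture family. Transmembrane blocks are
#' drawn from moderately hydrophobic residues and loops from mildly polar
#' ones; the two alphabets are chosen so that the windowed Kyte-Doolittle
#' hydropathy of the default predictor crosses its threshold within two
#' residues of each planted block edge, making the planted annotation a
#' usable ground truth for boundary-accuracy checks.
#'
#' @param n_tm Number of transmembrane blocks (default 7).
#' @param tm_len TM block length in residues (default 21).
#' @param loop_len Loop length (applies to all ICLs/ECLs; default 15).
#' @param nterm_len,cterm_len Terminal segment lengths (defaults 25, 40).
#' @param hydrophobic_alphabet,polar_alphabet Disjoint residue sets for TM
#'   blocks and loops/termini.
#' @param weak_tm Optional index of a TM block to build from the polar
#'   alphabet instead, emulating a helix a hydropathy predictor misses.
#' @param start_met Begin the N-terminus with an initiator methionine
#'   (default TRUE, as in a natural ORF).
#' @param seed Integer seed.
#' @return List of class \code{ToyGpcrSpec}.
#' @export
toy_gpcr_spec <- function(n_tm = 7L, tm_len = 21L, loop_len = 15L,
                          nterm_len = 25L, cterm_len = 40L,
                          hydrophobic_alphabet = c("A", "M"),
                          polar_alphabet = c("S", "G"),
                          weak_tm = NULL, start_met = TRUE, seed = 1L) {
  if (n_tm < 1L) stop("toy_gpcr_spec: n_tm must be >= 1")
  if (any(c(tm_len, loop_len, nterm_len, cterm_len) <= 0L))
    stop("toy_gpcr_spec: all lengths must be positive")
  if (length(intersect(hydrophobic_alphabet, polar_alphabet)) > 0L)
    stop("toy_gpcr_spec: hydrophobic and polar alphabets overlap")
  structure(list(n_tm = n_tm, tm_len = tm_len, loop_len = loop_len,
                 nterm_len = nterm_len, cterm_len = cterm_len,
                 hydrophobic_alphabet = hydrophobic_alphabet,
                 polar_alphabet = polar_alphabet, weak_tm = weak_tm,
                 start_met = isTRUE(start_met), seed = seed),
            class = "ToyGpcrSpec")
}

#' Generate a toy 7TM protein with known domain architecture
#'
#' Builds N-term + alternating TM/loop blocks + C-term (loops alternate
#' intracellular, extracellular starting with ICL1 after TM1, matching the
#' canonical GPCR topology) and returns both the protein and its exact
#' ground-truth annotation. Deterministic per seed.
#'
#' @param spec A [toy_gpcr_spec()].
#' @param id Identifier for the protein record.
#' @return List with \code{protein} (\code{ProteinRecord}) and
#'   \code{annotation} (\code{DomainAnnotation} tiling the protein).
#' @export
make_toy_gpcr <- function(spec = toy_gpcr_spec(), id = "toy1") {
  stopifnot(inherits(spec, "ToyGpcrSpec"))
  with_seed(spec$seed, {
    draw <- function(alpha, n)
      paste(sample(alpha, n, replace = TRUE), collapse = "")
    labels <- character(0); lens <- integer(0); pieces <- character(0)
    add <- function(lab, piece) {
      labels <<- c(labels, lab); lens <<- c(lens, nchar(piece))
      pieces <<- c(pieces, piece)
    }
    nterm <- draw(spec$polar_alphabet, spec$nterm_len)
    if (spec$start_met) nterm <- paste0("M", substring(nterm, 2L))
    add("N-term", nterm)
    for (k in seq_len(spec$n_tm)) {
      tm_alpha <- if (!is.null(spec$weak_tm) && k == spec$weak_tm)
        spec$polar_alphabet else spec$hydrophobic_alphabet
      add(paste0("TM", k), draw(tm_alpha, spec$tm_len))
      if (k < spec$n_tm) {
        loop_lab <- if (k %% 2L == 1L) paste0("ICL", (k + 1L) %/% 2L)
          else paste0("ECL", k %/% 2L)
        add(loop_lab, draw(spec$polar_alphabet, spec$loop_len))
      }
    }
    add("C-term", draw(spec$polar_alphabet, spec$cterm_len))
    ends <- cumsum(lens)
    starts <- c(0L, ends[-length(ends)])
    protein <- protein_record(id, paste(pieces, collapse = ""))
    ann <- domain_annotation(id, data.frame(label = labels, start = starts,
                                            end = ends),
                             seq_length = nchar(protein$seq))
    list(protein = protein, annotation = ann)
  })
}

#' Simulated grouped expression matrix with planted enrichment
#'
#' Emulates the structure of a cell-type-resolved expression study: groups
#' of biological replicates per cell type, lognormal measurement noise, and
#' a planted set of genes whose expression is multiplied by \code{fold} in
#' one target group. Used to test whether the specificity statistic recovers
#' known enrichment.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of replicate counts per cell group
#'   (default: 8 groups in triplicate, the first named "microglia").
#' @param enriched_genes Integer indices of the planted genes.
#' @param target_group Group receiving the enrichment.
#' @param fold Multiplicative enrichment (> 1).
#' @param noise_sigma Lognormal sigma of the replicate noise.
#' @param base_meanlog,base_sdlog Lognormal parameters of per-gene baseline
#'   expression.
#' @param seed Integer seed.
#' @return List with \code{expr} (genes x samples matrix), \code{grouping}
#'   (named sample -> group vector) and \code{enriched_genes}.
#' @export
make_expression_matrix <- function(n_genes = 200L,
                                   groups = stats::setNames(
                                     rep(3L, 8L),
                                     c("microglia", paste0("cellgroup", 2:8))),
                                   enriched_genes = 1:10,
                                   target_group = names(groups)[1L],
                                   fold = 4, noise_sigma = 0.3,
                                   base_meanlog = log(100), base_sdlog = 1,
                                   seed = 1L) {
  if (fold <= 1) stop("make_expression_matrix: fold must be > 1")
  if (any(groups < 1L)) stop("make_expression_matrix: empty group")
  if (length(enriched_genes) > 0L &&
      (min(enriched_genes) < 1L || max(enriched_genes) > n_genes))
    stop("make_expression_matrix: enriched_genes out of range")
  if (!target_group %in% names(groups))
    stop("make_expression_matrix: unknown target group")
  with_seed(seed, {
    samples <- unlist(lapply(names(groups), function(g)
      paste0(g, "_rep", seq_len(groups[[g]]))))
    sample_group <- rep(names(groups), unname(groups))
    base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    expr <- matrix(0, nrow = n_genes, ncol = length(samples),
                   dimnames = list(paste0("gene", seq_len(n_genes)),
                                   samples))
    for (j in seq_along(samples)) {
      mu <- base
      if (sample_group[j] == target_group)
        mu[enriched_genes] <- mu[enriched_genes] * fold
      expr[, j] <- mu * stats::rlnorm(n_genes, 0, noise_sigma)
    }
    list(expr = expr,
         grouping = stats::setNames(sample_group, samples),
         enriched_genes = enriched_genes)
  })
}
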