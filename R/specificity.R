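#' Collapse replicate expression columns to per-group means
#'
#' Builds the "Mean Data" matrix: one column per biological group (e.g. a
#' cell type measured in triplicate), each entry the arithmetic mean of that
#' gene's expression over the group's samples.
#'
#' @param expr Numeric genes x samples matrix (non-negative, no missing
#'   values) with column names.
#' @param grouping Named character vector mapping every sample (column name)
#'   to its group.
#' @return Numeric genes x groups matrix, group columns in first-appearance
#'   order.
#' @export
compute_mean_data <- function(expr, grouping) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (anyNA(expr)) stop("compute_mean_data: missing values in matrix")
  unmapped <- setdiff(colnames(expr), names(grouping))
  if (length(unmapped) > 0L)
    stop("compute_mean_data: unmapped sample(s): ",
         paste(unmapped, collapse = ", "))
  groups <- unique(unname(grouping[colnames(expr)]))
  out <- vapply(groups, function(g) {
    cols <- colnames(expr)[grouping[colnames(expr)] == g]
    if (length(cols) == 0L)
      stop("compute_mean_data: group '", g, "' has no samples")
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), groups))
  out
}

#' Specificity ratio of one gene
#'
#' The enrichment statistic for a gene given a selected combination (sc) of
#' cell groups and a disjoint non-selected combination (n-sc): the minimum
#' expression over the sc groups divided by the maximum over the n-sc
#' groups. A ratio above 1 means the gene is higher in every selected group
#' than in any non-selected group. When the n-sc maximum is zero the ratio
#' is undefined (infinite enrichment) and is returned as \code{Inf} rather
#' than raising an error.
#'
#' @param sc_row,nsc_row Non-empty numeric vectors of group means.
#' @return Numeric scalar \code{min(sc_row) / max(nsc_row)}; \code{Inf}
#'   (with attribute \code{undefined = TRUE}) when \code{max(nsc_row) == 0}.
#' @export
specificity_ratio <- function(sc_row, nsc_row) {
  if (length(sc_row) == 0L || length(nsc_row) == 0L)
    stop("specificity_ratio: empty row")
  m <- max(nsc_row)
  if (m == 0) {
    return(structure(Inf, undefined = TRUE))
  }
  min(sc_row) / m
}

#' Wilcoxon rank-sum p-value (exact for small samples)
#'
#' Rank-sum comparison of a gene's selected-group values against its
#' non-selected values. For combined sample sizes of at most
#' \code{exact_max} the p-value is computed by full enumeration of every
#' assignment of the pooled values to the two groups (midranks for ties),
#' which is reliable at the triplicate scale of grouped expression data; for
#' larger samples a tie-corrected normal approximation is used. Both paths
#' are deterministic. All values tied across both groups give p = 1.
#'
#' @param sc_row,nsc_row Numeric vectors (combined length >= 2).
#' @param alternative \code{"two-sided"} or \code{"greater"} (sc tends
#'   larger).
#' @param exact_max Largest combined n for the exact path (default 12).
#' @return p-value in (0, 1].
#' @export
rank_sum_p <- function(sc_row, nsc_row,
                       alternative = c("two-sided", "greater"),
                       exact_max = 12L) {
  alternative <- match.arg(alternative)
  m <- length(sc_row); n <- length(nsc_row)
  if (m + n < 2L || m == 0L || n == 0L)
    stop("rank_sum_p: need at least one value per group")
  pooled <- c(sc_row, nsc_row)
  rk <- rank(pooled)  # midranks
  w_obs <- sum(rk[seq_len(m)])
  if (m + n <= exact_max) {
    combos <- utils::combn(m + n, m)
    w_all <- colSums(matrix(rk[combos], nrow = m))
    e_w <- m * (m + n + 1) / 2
    p <- switch(alternative,
                greater = mean(w_all >= w_obs - 1e-9),
                `two-sided` = mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9))
  } else {
    e_w <- m * (m + n + 1) / 2
    ties <- table(pooled)
    N <- m + n
    var_w <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (var_w <= 0) return(1)
    z <- (w_obs - e_w) / sqrt(var_w)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                `two-sided` = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Row-maximum normalization for heatmap display
#'
#' Divides each gene row of a Mean Data matrix by its row maximum, so the
#' highest group is exactly 1. All-zero rows are left at zero and flagged.
#'
#' @param mean_data Numeric genes x groups matrix.
#' @return Matrix of the same shape with values in [0, 1]; attribute
#'   \code{zero_rows} lists row indices that were all zero.
#' @export
heatmap_normalize <- function(mean_data) {
  mx <- apply(mean_data, 1L, max)
  zero <- which(mx == 0)
  scale <- ifelse(mx == 0, 1, mx)
  out <- mean_data / scale
  attr(out, "zero_rows") <- zero
  out
}

#' Per-gene specificity analysis of a Mean Data matrix
#'
#' Convenience wrapper computing, for every gene, the specificity ratio and
#' Wilcoxon rank-sum p-value of the selected against the non-selected cell
#' groups, plus the row-normalized values for heatmap display.
#'
#' @param mean_data Genes x groups matrix (see [compute_mean_data()]).
#' @param sc Character vector of selected group (column) names.
#' @param nsc Character vector of non-selected group names, disjoint from
#'   \code{sc}; defaults to all remaining groups.
#' @param alternative Passed to [rank_sum_p()].
#' @return data.frame with columns \code{gene}, \code{sr}, \code{p},
#'   \code{sr_undefined}, then one \code{norm_<group>} column per group.
#' @export
specificity_analysis <- function(mean_data, sc, nsc = NULL,
                                 alternative = "two-sided") {
  groups <- colnames(mean_data)
  if (is.null(nsc)) nsc <- setdiff(groups, sc)
  if (length(sc) == 0L || length(nsc) == 0L)
    stop("specificity_analysis: sc and nsc must be non-empty")
  if (length(intersect(sc, nsc)) > 0L)
    stop("specificity_analysis: sc and nsc overlap")
  missing <- setdiff(c(sc, nsc), groups)
  if (length(missing) > 0L)
    stop("specificity_analysis: unknown group(s): ",
         paste(missing, collapse = ", "))
  sr <- numeric(nrow(mean_data)); undef <- logical(nrow(mean_data))
  p <- numeric(nrow(mean_data))
  for (i in seq_len(nrow(mean_data))) {
    s <- specificity_ratio(mean_data[i, sc], mean_data[i, nsc])
    sr[i] <- as.numeric(s)
    undef[i] <- isTRUE(attr(s, "undefined"))
    p[i] <- rank_sum_p(mean_data[i, sc], mean_data[i, nsc],
                       alternative = alternative)
  }
  norm <- heatmap_normalize(mean_data)
  genes <- if (is.null(rownames(mean_data)))
    paste0("gene", seq_len(nrow(mean_data))) else rownames(mean_data)
  out <- data.frame(gene = genes, sr = sr, p = p, sr_undefined = undef,
                    stringsAsFactors = FALSE)
  norm_df <- as.data.frame(norm)
  names(norm_df) <- paste0("norm_", colnames(mean_data))
  rownames(out) <- NULL
  cbind(out, norm_df, row.names = NULL)
}

#' Read an expression matrix and sample grouping from TSV
#' @param expr_path Genes x samples TSV (first column gene ids, header row of
#'   sample ids).
#' @param groups_path Two-column TSV \code{sample}, \code{group}.
#' @return List with \code{expr} (matrix) and \code{grouping} (named vector).
#' @export
read_expression_tsv <- function(expr_path, groups_path) {
  df <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df[[1L]]
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  list(expr = expr, grouping = stats::setNames(g$group, g$sample))
}
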