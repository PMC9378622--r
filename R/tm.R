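#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector over the 20 canonical residues; \code{X}
#'   scores 0.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
}

#' Construct a transmembrane-helix prediction
#'
#' @param protein_id Identifier.
#' @param helices data.frame with 0-based half-open \code{start}, \code{end}.
#' @param source \code{"builtin-hydropathy"} or \code{"external"}.
#' @param min_len Minimum helix length enforced on validation (set 1 to
#'   accept externally produced short spans).
#' @return Object of class \code{TmPrediction}.
#' @export
tm_prediction <- function(protein_id, helices,
                          source = c("builtin-hydropathy", "external"),
                          min_len = 1L) {
  source <- match.arg(source)
  helices <- data.frame(start = as.integer(helices$start),
                        end = as.integer(helices$end))
  helices <- helices[order(helices$start), , drop = FALSE]
  rownames(helices) <- NULL
  if (nrow(helices) > 0L) {
    if (any(helices$end - helices$start < min_len))
      stop("tm_prediction: helix shorter than ", min_len, " residues")
    if (nrow(helices) > 1L &&
        any(helices$start[-1L] < helices$end[-nrow(helices)]))
      stop("tm_prediction: overlapping helix intervals")
  }
  structure(list(protein_id = protein_id, helices = helices, source = source),
            class = "TmPrediction")
}

#' Predict transmembrane helices by sliding-window hydropathy
#'
#' A hydropathy-based stand-in for a dedicated topology predictor: the mean
#' Kyte-Doolittle hydropathy is computed over a sliding window; maximal runs
#' of window centers above \code{threshold} are extended to the window edges,
#' merged when separated by fewer than 3 residues, and discarded when shorter
#' than \code{min_len}. Fully deterministic.
#'
#' @param protein A \code{ProteinRecord}.
#' @param window Odd window size in residues (default 19).
#' @param threshold Mean-hydropathy call threshold (default 1.6).
#' @param min_len Minimum reported helix length (default 15).
#' @return A \code{TmPrediction} (0-based half-open intervals). A sequence
#'   shorter than the window yields an empty prediction with a warning.
#' @export
predict_tm <- function(protein, window = 19L, threshold = 1.6,
                       min_len = 15L) {
  stopifnot(inherits(protein, "ProteinRecord"))
  if (window %% 2L != 1L) stop("predict_tm: window must be odd")
  n <- nchar(protein$seq)
  if (n < window) {
    warning("predict_tm: sequence ", protein$id, " shorter than window")
    return(tm_prediction(protein$id, data.frame(start = integer(0),
                                                end = integer(0))))
  }
  h <- unname(kyte_doolittle()[strsplit(protein$seq, "")[[1]]])
  win_mean <- as.numeric(stats::filter(h, rep(1 / window, window),
                                       sides = 2))
  half <- (window - 1L) %/% 2L
  centers <- which(!is.na(win_mean) & win_mean > threshold)  # 1-based
  if (length(centers) == 0L)
    return(tm_prediction(protein$id, data.frame(start = integer(0),
                                                end = integer(0))))
  run_break <- which(diff(centers) > 1L)
  run_start <- centers[c(1L, run_break + 1L)]
  run_end <- centers[c(run_break, length(centers))]
  # extend each run of above-threshold centers to the window edges
  start0 <- pmax(run_start - 1L - half, 0L)
  end0 <- pmin(run_end - 1L + half + 1L, n)
  # merge runs separated by < 3 residues
  merged <- list(c(start0[1L], end0[1L]))
  for (i in seq_along(start0)[-1L]) {
    last <- merged[[length(merged)]]
    if (start0[i] - last[2L] < 3L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], end0[i]))
    } else {
      merged[[length(merged) + 1L]] <- c(start0[i], end0[i])
    }
  }
  hx <- do.call(rbind, merged)
  hx <- data.frame(start = hx[, 1L], end = hx[, 2L])
  hx <- hx[hx$end - hx$start >= min_len, , drop = FALSE]
  tm_prediction(protein$id, hx, source = "builtin-hydropathy",
                min_len = min_len)
}

#' Read an external TM prediction table
#'
#' Tabular dialect: columns \code{id}, \code{start}, \code{end}, 1-based
#' inclusive (converted to internal 0-based half-open on read).
#'
#' @param path TSV path.
#' @param protein_id Keep only rows for this id (default: the single id
#'   present; error if several and none specified).
#' @return A \code{TmPrediction} with \code{source = "external"}.
#' @export
ingest_tm_table <- function(path, protein_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "start", "end") %in% names(df)))
    stop("ingest_tm_table: need columns id, start, end")
  if (is.null(protein_id)) {
    ids <- unique(df$id)
    if (length(ids) != 1L)
      stop("ingest_tm_table: multiple ids present; specify protein_id")
    protein_id <- ids
  }
  df <- df[df$id == protein_id, , drop = FALSE]
  tm_prediction(protein_id,
                data.frame(start = df$start - 1L, end = df$end),
                source = "external")
}

#' Write a TM prediction table (inverse of [ingest_tm_table()])
#' @param tm A \code{TmPrediction}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tm_table <- function(tm, path) {
  df <- data.frame(id = tm$protein_id, start = tm$helices$start + 1L,
                   end = tm$helices$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Check that predicted TM helices tightly flank the signaling domains
#'
#' The verification gate used before committing a design to synthesis: each
#' intracellular loop identified by alignment should sit immediately between
#' two predicted transmembrane helices, and the C-terminus immediately after
#' the last one. Each annotated TM segment is matched to the predicted helix
#' overlapping it most; the flanking gap of a signaling segment is the
#' absolute offset between the matched helix boundary and the segment
#' boundary. A signaling segment whose required neighboring TM has no
#' matching predicted helix at all (e.g. a seventh helix the predictor missed)
#' is reported as MISSING and fails.
#'
#' @param annotation \code{DomainAnnotation} containing TM and signaling
#'   segments (e.g. from [project_domains()]).
#' @param tm A \code{TmPrediction} for the same protein.
#' @param seamless_tol Max gap (residues) still called seamless (default 0).
#' @param minor_tol Max gap still called minor-deviation (default 5).
#' @return Object of class \code{FlankingReport}: data.frame with one row per
#'   signaling segment and columns \code{segment}, \code{upstream_gap},
#'   \code{downstream_gap} (in residues; NA when the flanking helix is
#'   missing or, for the C-terminus, not required), logical
#'   \code{upstream_missing}/\code{downstream_missing} flags, and
#'   \code{verdict} in \{seamless, minor-deviation, fail\}.
#' @export
check_flanking <- function(annotation, tm, seamless_tol = 0L,
                           minor_tol = 5L) {
  seg <- annotation$segments
  sig <- seg[seg$label %in% signaling_labels(), , drop = FALSE]
  if (nrow(sig) == 0L)
    stop("check_flanking: annotation has no signaling segment")
  tm_labels <- paste0("TM", 1:7)
  ann_tms <- seg[seg$label %in% tm_labels, , drop = FALSE]

  # match each annotated TM to the predicted helix with maximal overlap
  match_helix <- function(tm_label) {
    a <- ann_tms[ann_tms$label == tm_label, , drop = FALSE]
    if (nrow(a) == 0L || nrow(tm$helices) == 0L) return(NULL)
    ov <- pmin(tm$helices$end, a$end) - pmax(tm$helices$start, a$start)
    if (max(ov) <= 0L) return(NULL)
    tm$helices[which.max(ov), , drop = FALSE]
  }
  flank_tm <- function(label, side) {
    # ICL_k sits between TM_{2k-1} (upstream) and TM_{2k} (downstream);
    # the C-terminus follows TM7
    if (label == "C-term") return(match_helix("TM7"))
    k <- as.integer(sub("ICL", "", label))
    match_helix(paste0("TM", if (side == "up") 2L * k - 1L else 2L * k))
  }

  rows <- lapply(seq_len(nrow(sig)), function(i) {
    lab <- sig$label[i]
    s <- sig$start[i]; e <- sig$end[i]
    up <- flank_tm(lab, "up")
    up_gap <- if (is.null(up)) NA_integer_ else abs(s - up$end)
    up_missing <- is.null(up)
    if (lab == "C-term") {
      dn_gap <- NA_integer_; dn_missing <- FALSE; dn_required <- FALSE
    } else {
      dn <- flank_tm(lab, "down")
      dn_gap <- if (is.null(dn)) NA_integer_ else abs(dn$start - e)
      dn_missing <- is.null(dn)
      dn_required <- TRUE
    }
    gaps <- c(up_gap, if (dn_required) dn_gap)
    verdict <- if (up_missing || (dn_required && dn_missing)) {
      "fail"
    } else if (all(gaps <= seamless_tol)) {
      "seamless"
    } else if (all(gaps <= minor_tol)) {
      "minor-deviation"
    } else {
      "fail"
    }
    data.frame(segment = lab, upstream_gap = up_gap,
               upstream_missing = up_missing, downstream_gap = dn_gap,
               downstream_missing = dn_missing, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$protein_id <- annotation$protein_id
  class(rep) <- c("FlankingReport", "data.frame")
  rep
}
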