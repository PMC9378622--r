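#' Long-format plate-trace container
#'
#' Validates a long-format table of kinetic luminescence reads: one row per
#' well per time point.
#'
#' @param df data.frame with columns \code{well}, \code{condition},
#'   \code{time_min}, \code{lum} (extra condition columns are kept).
#' @return The validated data.frame with class \code{PlateTrace}.
#' @export
plate_trace <- function(df) {
  need <- c("well", "condition", "time_min", "lum")
  if (!all(need %in% names(df)))
    stop("plate_trace: need columns ", paste(need, collapse = ", "))
  if (any(!is.finite(df$lum))) stop("plate_trace: non-finite luminescence")
  for (w in unique(df$well)) {
    tt <- df$time_min[df$well == w]
    if (is.unsorted(tt, strictly = TRUE))
      stop("plate_trace: time not strictly increasing in well ", w)
  }
  class(df) <- c("PlateTrace", "data.frame")
  df
}

#' Fold change over the pre-stimulus baseline
#'
#' Normalizes each well's luminescence to the mean of its own baseline
#' window (the reads before ligand application), yielding the fold change in
#' bioluminescence over time. Applying the normalization twice is a no-op.
#'
#' @param trace A \code{PlateTrace}.
#' @param baseline_window Numeric \code{c(from, to)} in minutes (inclusive);
#'   must contain at least one read per well.
#' @return The trace with \code{lum} replaced by baseline fold change and a
#'   \code{baseline_mean} column recording each well's divisor.
#' @export
baseline_fold_change <- function(trace, baseline_window) {
  stopifnot(length(baseline_window) == 2L)
  out <- trace
  out$baseline_mean <- NA_real_
  for (w in unique(trace$well)) {
    sel <- trace$well == w
    in_base <- sel & trace$time_min >= baseline_window[1L] &
      trace$time_min <= baseline_window[2L]
    if (!any(in_base))
      stop("baseline_fold_change: no baseline reads in well ", w)
    b <- mean(trace$lum[in_base])
    if (b == 0) stop("baseline_fold_change: zero baseline mean in well ", w)
    out$lum[sel] <- trace$lum[sel] / b
    out$baseline_mean[sel] <- b
  }
  out
}

#' Normalize treated traces to the vehicle-control mean per time point
#'
#' Divides each well's (typically already baseline-normalized) values at
#' every time point by the mean of the vehicle-control wells at that same
#' time point.
#'
#' @param traces A \code{PlateTrace} containing the vehicle wells.
#' @param vehicle_group Value of the \code{condition} column identifying the
#'   vehicle wells.
#' @return The traces with \code{lum} divided by the per-time vehicle mean.
#' @export
vehicle_normalize <- function(traces, vehicle_group) {
  veh <- traces[traces$condition == vehicle_group, , drop = FALSE]
  if (nrow(veh) == 0L)
    stop("vehicle_normalize: no wells in vehicle group '", vehicle_group, "'")
  veh_mean <- tapply(veh$lum, veh$time_min, mean)
  out <- traces
  key <- as.character(traces$time_min)
  missing <- setdiff(unique(key), names(veh_mean))
  if (length(missing) > 0L)
    stop("vehicle_normalize: vehicle group lacks time point(s) ",
         paste(missing, collapse = ", "))
  out$lum <- traces$lum / as.numeric(veh_mean[key])
  out
}

#' Dual-luciferase reporter fold change
#'
#' Firefly luminescence normalized to renilla luminescence (controlling for
#' transfection efficiency), divided by the mean firefly/renilla ratio of
#' the matched vehicle control.
#'
#' @param firefly,renilla Luminescence values (renilla strictly positive).
#' @param vehicle_mean_ratio Mean firefly/renilla ratio of the vehicle
#'   triplicate.
#' @return Fold change values.
#' @export
dual_reporter_fold <- function(firefly, renilla, vehicle_mean_ratio) {
  if (any(renilla <= 0)) stop("dual_reporter_fold: non-positive renilla")
  if (vehicle_mean_ratio <= 0)
    stop("dual_reporter_fold: non-positive vehicle ratio")
  (firefly / renilla) / vehicle_mean_ratio
}

#' RT-qPCR fold changes by double Cq normalization
#'
#' For every sample, each target gene's mean Cq is normalized to the
#' geometric mean of the reference genes measured in the same sample
#' (dCq = geometric mean of reference Cqs minus target Cq); dCq is then
#' normalized to the control condition (ddCq = dCq - dCq of control) and
#' transformed to linear scale (fold change = 2^ddCq). Note the sign
#' convention: the reference geomean comes first, so fold = 2^ddCq with no
#' negation.
#'
#' @param cq data.frame with columns \code{sample}, \code{gene}, \code{cq}
#'   and logical \code{is_reference}.
#' @param control_sample Name of the control condition sample.
#' @return data.frame with columns \code{sample}, \code{gene}, \code{dcq},
#'   \code{ddcq}, \code{fold} for every non-reference gene.
#' @export
ddcq_fold_change <- function(cq, control_sample) {
  need <- c("sample", "gene", "cq", "is_reference")
  if (!all(need %in% names(cq)))
    stop("ddcq_fold_change: need columns ", paste(need, collapse = ", "))
  if (any(!is.finite(cq$cq))) stop("ddcq_fold_change: non-finite Cq")
  if (!control_sample %in% cq$sample)
    stop("ddcq_fold_change: control sample '", control_sample, "' absent")
  samples <- unique(cq$sample)
  ref_geo <- vapply(samples, function(s) {
    refs <- cq$cq[cq$sample == s & cq$is_reference]
    if (length(refs) == 0L)
      stop("ddcq_fold_change: sample '", s, "' has no reference genes")
    if (any(refs <= 0))
      stop("ddcq_fold_change: non-positive reference Cq in sample '", s, "'")
    exp(mean(log(refs)))
  }, numeric(1))
  tg <- cq[!cq$is_reference, , drop = FALSE]
  tg$dcq <- ref_geo[tg$sample] - tg$cq
  ctl <- tg[tg$sample == control_sample, , drop = FALSE]
  dcq_ctl <- stats::setNames(ctl$dcq, ctl$gene)
  missing <- setdiff(unique(tg$gene), names(dcq_ctl))
  if (length(missing) > 0L)
    stop("ddcq_fold_change: control lacks gene(s) ",
         paste(missing, collapse = ", "))
  tg$ddcq <- tg$dcq - as.numeric(dcq_ctl[tg$gene])
  tg$fold <- 2^tg$ddcq
  rownames(tg) <- NULL
  tg[, c("sample", "gene", "dcq", "ddcq", "fold")]
}

#' Lentiviral titer in transforming units per milliliter
#'
#' Titer = (transduced cell count x percent EGFP-positive x dilution
#' factor) / (virus volume in ml x 100).
#'
#' @param cells_transduced Number of cells seeded for transduction.
#' @param pct_egfp Percent EGFP-positive cells on the 0-100 scale.
#' @param dilution_factor Virus dilution factor.
#' @param volume_ml Virus volume in milliliters.
#' @return Titer in TU/ml.
#' @export
lentiviral_titer <- function(cells_transduced, pct_egfp, dilution_factor,
                             volume_ml) {
  if (any(c(cells_transduced, pct_egfp, dilution_factor, volume_ml) <= 0))
    stop("lentiviral_titer: all arguments must be positive")
  if (pct_egfp > 100)
    stop("lentiviral_titer: pct_egfp must be on the 0-100 scale")
  (cells_transduced * pct_egfp * dilution_factor) / (volume_ml * 100)
}
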