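#' Construct a chromatographic peak table
#'
#' One integrated chromatogram: retention times, areas and (optionally)
#' analyte assignments, with the run metadata that matters for
#' correction-factor durability (instrument, column, flow rate, column
#' temperature).
#'
#' @param rt_min Retention times in minutes, positive and unique.
#' @param area Peak areas in detector units, non-negative.
#' @param analyte Assigned analyte codes, `NA` for unassigned peaks.
#' @param sample_id Sample identifier.
#' @param instrument,column Labels for the run hardware.
#' @param flow_rate Mobile-phase flow rate in mL/min.
#' @param temperature Column temperature in degrees C.
#'
#' @return A data frame of class `peak_table` with columns `rt_min`,
#'   `area`, `analyte`, sorted by retention time; metadata are attributes.
#' @export
peak_table <- function(rt_min, area, analyte = NA_character_,
                       sample_id = "sample",
                       instrument = "default", column = "default",
                       flow_rate = 1.0, temperature = 25) {
  if (length(rt_min) != length(area)) {
    stop("rt_min and area must have the same length", call. = FALSE)
  }
  if (any(!is.finite(rt_min)) || any(rt_min <= 0)) {
    stop("retention times must be positive", call. = FALSE)
  }
  if (anyDuplicated(rt_min)) {
    stop("retention times must be unique within a table", call. = FALSE)
  }
  if (any(!is.finite(area)) || any(area < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  analyte <- rep_len(as.character(analyte), length(rt_min))
  ord <- order(rt_min)
  out <- data.frame(rt_min = rt_min[ord], area = area[ord],
                    analyte = analyte[ord], stringsAsFactors = FALSE)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "run_meta") <- list(instrument = instrument, column = column,
                                flow_rate = flow_rate,
                                temperature = temperature)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' @export
print.peak_table <- function(x, ...) {
  meta <- attr(x, "run_meta")
  cat(sprintf("Peak table '%s' (%d peaks; %s / %s, %.1f mL/min, %g C)\n",
              attr(x, "sample_id"), nrow(x), meta$instrument, meta$column,
              meta$flow_rate, meta$temperature))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Relative retention times across assigned runs
#'
#' For peak assignment that survives instrument and column changes, each
#' analyte is located by its signed retention-time offset from the
#' internal-standard (reference) peak, delta_t = t_analyte - t_reference.
#' Given several runs whose peaks are already assigned, this averages the
#' offsets and reports their cross-run RSD.
#'
#' @param tables List of assigned [peak_table()] runs; each must contain
#'   the reference analyte and at least one other assigned analyte.
#' @param reference Reference analyte code.
#' @param tolerance Matching tolerance in minutes carried to
#'   [locate_peaks()]; default 0.5.
#'
#' @return A data frame of class `rrt_table` with columns `analyte`,
#'   `delta_rt` (mean signed offset, minutes) and `rsd` (percent of the
#'   mean offset across runs; 0 for a single run). The reference row has
#'   offset exactly 0. Attributes `reference` and `tolerance`.
#' @export
compute_rrt <- function(tables, reference, tolerance = 0.5) {
  check_scalar_positive(tolerance, "tolerance")
  offsets <- list()
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    stopifnot(inherits(tb, "peak_table"))
    ref_rt <- tb$rt_min[!is.na(tb$analyte) & tb$analyte == reference]
    if (length(ref_rt) != 1L) {
      stop(sprintf("location error: run '%s' has no assigned reference peak (%s)",
                   attr(tb, "sample_id"), reference), call. = FALSE)
    }
    assigned <- tb[!is.na(tb$analyte), , drop = FALSE]
    if (nrow(assigned) < 2L) {
      stop(sprintf("run '%s' must assign the reference and at least one other analyte",
                   attr(tb, "sample_id")), call. = FALSE)
    }
    offsets[[i]] <- stats::setNames(assigned$rt_min - ref_rt, assigned$analyte)
  }
  codes <- unique(unlist(lapply(offsets, names)))
  codes <- c(reference, setdiff(codes, reference))
  stat <- t(vapply(codes, function(code) {
    d <- unlist(lapply(offsets, function(o) o[[code]]))
    m <- mean(d)
    r <- if (length(d) < 2L || m == 0) 0 else abs(100 * stats::sd(d) / m)
    c(m, r)
  }, numeric(2L)))
  out <- data.frame(analyte = codes, delta_rt = stat[, 1L], rsd = stat[, 2L],
                    stringsAsFactors = FALSE)
  out$delta_rt[out$analyte == reference] <- 0
  out$rsd[out$analyte == reference] <- 0
  attr(out, "reference") <- reference
  attr(out, "tolerance") <- tolerance
  class(out) <- c("rrt_table", "data.frame")
  out
}

#' Nominal relative retention times from a panel definition
#'
#' Builds an `rrt_table` from the nominal retention times stored in an
#' [analyte_panel()], for assigning peaks when no previously assigned
#' reference runs are available.
#'
#' @param panel An [analyte_panel()] with `rt_min` filled in.
#' @param tolerance Matching tolerance in minutes.
#' @return An `rrt_table` (see [compute_rrt()]).
#' @export
panel_rrt <- function(panel, tolerance = 0.5) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (anyNA(panel$rt_min)) {
    stop("panel retention times are not all set", call. = FALSE)
  }
  ref <- internal_standard(panel)
  out <- data.frame(analyte = panel$code,
                    delta_rt = panel$rt_min - panel$rt_min[panel$internal_standard],
                    rsd = 0, stringsAsFactors = FALSE)
  attr(out, "reference") <- ref
  attr(out, "tolerance") <- tolerance
  class(out) <- c("rrt_table", "data.frame")
  out
}

#' Assign chromatographic peaks by relative retention time
#'
#' The reference (internal standard) peak is taken as the peak nearest
#' `expected_reference_time`; every other analyte is matched to the
#' unassigned peak whose offset from the reference is nearest its expected
#' signed offset, within the tolerance. Matching is greedy by smallest
#' absolute deviation, so two analytes never claim one peak; exact ties
#' are broken by analyte code. Analytes with no peak in tolerance are
#' flagged absent rather than silently dropped.
#'
#' @param table A [peak_table()] (any existing assignments are ignored and
#'   redone, so the operation is idempotent).
#' @param rrt An `rrt_table` from [compute_rrt()] or [panel_rrt()].
#' @param expected_reference_time Expected retention time of the reference
#'   peak, minutes.
#' @param tolerance Matching tolerance in minutes; defaults to the
#'   tolerance stored in `rrt`.
#'
#' @return The peak table with its `analyte` column filled in; codes with
#'   no matching peak are listed in the `absent` attribute.
#' @export
locate_peaks <- function(table, rrt, expected_reference_time,
                         tolerance = attr(rrt, "tolerance")) {
  stopifnot(inherits(table, "peak_table"), inherits(rrt, "rrt_table"))
  if (nrow(table) == 0L) stop("peak table is empty", call. = FALSE)
  check_scalar_positive(tolerance, "tolerance")
  reference <- attr(rrt, "reference")

  table$analyte <- NA_character_
  dev_ref <- abs(table$rt_min - expected_reference_time)
  if (min(dev_ref) > tolerance) {
    stop(sprintf("reference peak not found within %.3g min of %.4g min",
                 tolerance, expected_reference_time), call. = FALSE)
  }
  ref_idx <- which.min(dev_ref)
  table$analyte[ref_idx] <- reference
  ref_rt <- table$rt_min[ref_idx]

  todo <- rrt[rrt$analyte != reference, , drop = FALSE]
  cand <- expand.grid(peak = setdiff(seq_len(nrow(table)), ref_idx),
                      ai = seq_len(nrow(todo)))
  if (nrow(todo) && nrow(cand)) {
    cand$dev <- abs((table$rt_min[cand$peak] - ref_rt) -
                      todo$delta_rt[cand$ai])
    cand <- cand[cand$dev <= tolerance, , drop = FALSE]
    cand <- cand[order(cand$dev, todo$analyte[cand$ai]), , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      pk <- cand$peak[j]
      code <- todo$analyte[cand$ai[j]]
      if (is.na(table$analyte[pk]) && !code %in% table$analyte) {
        table$analyte[pk] <- code
      }
    }
  }
  attr(table, "absent") <- setdiff(rrt$analyte, table$analyte)
  table
}
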