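#' Construct a standard dilution series
#'
#' Pairs of (concentration, detector area) for one analyte, ordered by
#' increasing concentration. Five or more levels are recommended so that
#' LOD/LOQ and correction-factor RSDs are meaningful; two suffice for a
#' line fit.
#'
#' @param analyte Analyte code.
#' @param concentration Concentrations in ug/mL, strictly positive and
#'   distinct.
#' @param area Detector peak areas, strictly positive, same length.
#'
#' @return A data frame of class `standard_series` with columns
#'   `concentration` and `area`, sorted by concentration, and an
#'   `analyte` attribute.
#' @export
standard_series <- function(analyte, concentration, area) {
  if (length(concentration) != length(area)) {
    stop("concentration and area must have the same length", call. = FALSE)
  }
  if (length(concentration) < 2L) {
    stop("a standard series needs at least 2 levels", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(concentration)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  ord <- order(concentration)
  out <- data.frame(concentration = concentration[ord], area = area[ord])
  attr(out, "analyte") <- as.character(analyte)
  class(out) <- c("standard_series", "data.frame")
  out
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of detector area (y) on concentration (x),
#' the standard detector-response model for HPLC-UV quantification. The
#' reported R is the Pearson correlation of x and y; the linear range is
#' the span of observed concentrations. LOD/LOQ are left unset until
#' [estimate_lod_loq()] supplies a baseline noise level.
#'
#' @param series A [standard_series()].
#'
#' @return An object of class `calibration_curve`: a list with `analyte`,
#'   `slope` (area per ug/mL), `intercept` (area), `r`, `range` (ug/mL),
#'   `lod`, `loq` and `n_levels`.
#' @export
#' @examples
#' s <- standard_series("GC", c(1, 2, 5, 10), 1815300 * c(1, 2, 5, 10) + 8028)
#' fit_calibration(s)
fit_calibration <- function(series) {
  stopifnot(inherits(series, "standard_series"))
  x <- series$concentration
  y <- series$area
  if (length(x) < 2L) stop("at least 2 levels are required", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate fit: concentrations have zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  curve <- list(
    analyte = attr(series, "analyte"),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r = stats::cor(x, y),
    range = range(x),
    lod = NA_real_,
    loq = NA_real_,
    n_levels = length(x)
  )
  class(curve) <- "calibration_curve"
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve for %s: y = %.6gx %s %.6g\n",
              x$analyte, x$slope, if (x$intercept >= 0) "+" else "-",
              abs(x$intercept)))
  cat(sprintf("  R = %.4f over %.4g-%.4g ug/mL (%d levels)\n",
              x$r, x$range[1L], x$range[2L], x$n_levels))
  if (!is.na(x$lod)) {
    cat(sprintf("  LOD %.3g ug/mL, LOQ %.3g ug/mL\n", x$lod, x$loq))
  }
  invisible(x)
}

#' Detection and quantification limits from baseline noise
#'
#' LOD and LOQ are the concentrations whose signal equals 3 and 10 times
#' the baseline noise standard deviation, the usual signal-to-noise
#' definition. Their ratio is therefore always 10/3.
#'
#' @param curve A fitted [calibration_curve][fit_calibration()] with a
#'   positive slope.
#' @param noise_sd Baseline noise standard deviation in detector units,
#'   non-negative.
#'
#' @return Named numeric vector `c(lod = , loq = )` in ug/mL.
#' @export
estimate_lod_loq <- function(curve, noise_sd) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  if (curve$slope <= 0) stop("curve slope must be positive", call. = FALSE)
  c(lod = 3 * noise_sd / curve$slope, loq = 10 * noise_sd / curve$slope)
}

#' Relative correction factor of one analyte against the internal standard
#'
#' At each shared dilution level the relative correction factor is the
#' ratio of unit-concentration responses, f = (As/Cs) / (Ak/Ck), where s
#' is the internal standard and k the analyte. The reported factor is the
#' arithmetic mean over levels, with its relative standard deviation.
#'
#' @param internal [standard_series()] of the internal standard.
#' @param analyte [standard_series()] of the analyte, with the same number
#'   of levels, paired by dilution level.
#'
#' @return A list of class `rcf` with `analyte`, `internal_standard`,
#'   `per_level_f`, `mean_f` and `rsd_f` (percent; `NA` with fewer than
#'   2 levels would be impossible since series require 2).
#' @export
compute_rcf <- function(internal, analyte) {
  stopifnot(inherits(internal, "standard_series"),
            inherits(analyte, "standard_series"))
  if (nrow(internal) != nrow(analyte)) {
    stop("pairing error: series have different numbers of levels", call. = FALSE)
  }
  bad <- which(internal$area == 0 | internal$concentration == 0 |
                 analyte$area == 0 | analyte$concentration == 0)
  if (length(bad)) {
    stop(sprintf("division error: zero area or concentration at level %d",
                 bad[1L]), call. = FALSE)
  }
  f <- (internal$area / internal$concentration) /
    (analyte$area / analyte$concentration)
  out <- list(
    analyte = attr(analyte, "analyte"),
    internal_standard = attr(internal, "analyte"),
    per_level_f = f,
    mean_f = mean(f),
    rsd_f = rsd(f)
  )
  class(out) <- "rcf"
  out
}

#' Relative correction factors for a whole panel
#'
#' Applies [compute_rcf()] to every analyte in a named list of standard
#' series, against the series named by `internal`. The internal standard's
#' own factor is identically 1 with zero RSD.
#'
#' @param series Named list of [standard_series()], one per analyte; names
#'   are the analyte codes.
#' @param internal Code of the internal standard; must name an element of
#'   `series`.
#'
#' @return A data frame of class `rcf_set` with columns `analyte`,
#'   `mean_f`, `rsd_f`; per-level factors are kept in the `per_level`
#'   attribute (a named list) and the internal standard code in the
#'   `internal_standard` attribute.
#' @export
rcf_set <- function(series, internal) {
  if (is.null(names(series)) || !internal %in% names(series)) {
    stop("series must be a named list containing the internal standard",
         call. = FALSE)
  }
  entries <- lapply(names(series), function(code) {
    compute_rcf(series[[internal]], series[[code]])
  })
  out <- data.frame(
    analyte = vapply(entries, `[[`, "", "analyte"),
    mean_f = vapply(entries, `[[`, 0, "mean_f"),
    rsd_f = vapply(entries, `[[`, 0, "rsd_f"),
    stringsAsFactors = FALSE
  )
  attr(out, "per_level") <- stats::setNames(
    lapply(entries, `[[`, "per_level_f"), out$analyte)
  attr(out, "internal_standard") <- internal
  class(out) <- c("rcf_set", "data.frame")
  out
}

#' Cross-condition durability of relative correction factors
#'
#' Correction factors are only useful if they transfer across instruments,
#' columns, flow rates and temperatures. Given factor sets measured under
#' several conditions, this computes the per-analyte RSD of the mean
#' factor across conditions and flags the panel as durable when every RSD
#' is below `rsd_limit` (default 5%).
#'
#' @param rcf_sets List of at least two [rcf_set()] objects over the same
#'   analyte panel.
#' @param rsd_limit Pass threshold in percent.
#'
#' @return A list with `per_analyte` (data frame: analyte, mean_f across
#'   conditions, rsd percent) and `pass` (logical).
#' @export
durability_rcf <- function(rcf_sets, rsd_limit = 5) {
  if (length(rcf_sets) < 2L) {
    stop("at least 2 conditions are required", call. = FALSE)
  }
  panels <- lapply(rcf_sets, function(s) sort(s$analyte))
  if (!all(vapply(panels[-1L], identical, TRUE, panels[[1L]]))) {
    stop("all conditions must cover the same analyte panel", call. = FALSE)
  }
  codes <- rcf_sets[[1L]]$analyte
  f_mat <- matrix(vapply(rcf_sets, function(s) s$mean_f[match(codes, s$analyte)],
                         numeric(length(codes))),
                  nrow = length(codes))
  rsds <- apply(f_mat, 1L, rsd)
  per <- data.frame(analyte = codes,
                    mean_f = rowMeans(f_mat),
                    rsd = rsds,
                    stringsAsFactors = FALSE)
  list(per_analyte = per, pass = all(rsds < rsd_limit))
}
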