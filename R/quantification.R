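#' Sample preparation constants
#'
#' Mass of powdered material extracted, extract volume, and any further
#' dilution, used to convert a solution concentration (ug/mL) to a mass
#' fraction of the dry material (mg/g). Defaults follow the reference
#' extraction: 0.25 g of powder refluxed in 10 mL of methanol.
#'
#' @param sample_mass_g Sample mass in grams.
#' @param extract_volume_ml Extraction solvent volume in mL.
#' @param dilution_factor Post-extraction dilution factor.
#' @return A list of class `sample_prep`.
#' @export
sample_prep <- function(sample_mass_g = 0.25, extract_volume_ml = 10,
                        dilution_factor = 1) {
  check_scalar_positive(sample_mass_g, "sample_mass_g")
  check_scalar_positive(extract_volume_ml, "extract_volume_ml")
  check_scalar_positive(dilution_factor, "dilution_factor")
  structure(list(sample_mass_g = sample_mass_g,
                 extract_volume_ml = extract_volume_ml,
                 dilution_factor = dilution_factor),
            class = "sample_prep")
}

#' Concentration by the external standard method
#'
#' Conventional quantification against the analyte's own standard: either
#' inversion of the fitted regression line, or a single-point ratio
#' against the unit-concentration response As/Cs. Regression-mode results
#' below zero (area under the intercept) are clamped to 0 and flagged in
#' the `clamped` attribute.
#'
#' @param area Peak area(s) in detector units.
#' @param curve A [calibration_curve][fit_calibration()] (regression mode).
#' @param mode `"regression"` or `"single_point"`.
#' @param unit_response Unit-concentration response As/Cs in area per
#'   ug/mL (single-point mode).
#' @return Concentration(s) in ug/mL; in regression mode with a `clamped`
#'   logical attribute marking negatives floored at 0.
#' @export
esm_quantify <- function(area, curve = NULL,
                         mode = c("regression", "single_point"),
                         unit_response = NULL) {
  mode <- match.arg(mode)
  if (mode == "regression") {
    if (is.null(curve)) stop("regression mode needs a fitted curve", call. = FALSE)
    if (curve$slope == 0) stop("division error: zero slope", call. = FALSE)
    conc <- (area - curve$intercept) / curve$slope
    clamped <- conc < 0
    conc[clamped] <- 0
    attr(conc, "clamped") <- clamped
    conc
  } else {
    if (is.null(unit_response)) {
      stop("single_point mode needs the unit-concentration response As/Cs",
           call. = FALSE)
    }
    if (unit_response == 0) stop("division error: zero unit response", call. = FALSE)
    area / unit_response
  }
}

#' Concentration by single-marker quantification
#'
#' The analyte concentration from its own peak area, the internal
#' standard's unit-concentration response, and the analyte's relative
#' correction factor: Ck = Ak / (As/Cs) * fk. With f = 1 this is exactly
#' the single-point external standard result.
#'
#' @param area Analyte peak area(s).
#' @param unit_response Internal standard's unit-concentration response
#'   As/Cs, area per ug/mL, positive.
#' @param f Relative correction factor of the analyte, positive.
#' @return Concentration(s) in ug/mL.
#' @export
qams_quantify <- function(area, unit_response, f) {
  check_scalar_positive(unit_response, "unit_response")
  check_scalar_positive(f, "f")
  area / unit_response * f
}

#' Solution concentration to mass fraction of the dry sample
#'
#' @param conc Concentration(s) in ug/mL.
#' @param prep A [sample_prep()].
#' @return Mass fraction(s) in mg/g.
#' @export
mass_fraction <- function(conc, prep = sample_prep()) {
  stopifnot(inherits(prep, "sample_prep"))
  conc * prep$extract_volume_ml * prep$dilution_factor /
    (prep$sample_mass_g * 1000)
}

#' Relative standard deviation
#'
#' 100 times the sample standard deviation (n - 1 denominator) over the
#' mean — the universal precision metric of analytical method validation.
#'
#' @param values At least two numeric values with non-zero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(0.98, 1.00, 1.02))
rsd <- function(values) {
  if (length(values) < 2L) {
    stop("rsd needs at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("rsd undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Spike recovery
#'
#' @param original_amount Analyte amount in the unspiked sample (mg).
#' @param added_amount Spiked amount (mg), positive.
#' @param found_amount Amount measured in the spiked sample (mg).
#' @return Recovery in percent: 100 (found - original) / added.
#' @export
recovery <- function(original_amount, added_amount, found_amount) {
  if (any(added_amount <= 0)) {
    stop("added_amount must be positive", call. = FALSE)
  }
  100 * (found_amount - original_amount) / added_amount
}

#' Compare external-standard and single-marker contents
#'
#' Cell-wise relative error RE = (qams - esm) / esm * 100 and per-analyte
#' Pearson correlation across batches between the two methods. Cells with
#' a zero external-standard value have undefined RE and are flagged `NA`.
#' The summary flag `within_5` is true when every defined |RE| is at most
#' `re_limit` percent.
#'
#' @param esm,qams Content matrices: data frames with a `batch` column
#'   and one numeric column per analyte (mg/g), same batches and analytes.
#' @param re_limit Relative-error acceptance bound in percent.
#' @return A list of class `method_comparison`: `cells` (long data frame
#'   batch/analyte/esm/qams/relative_error), `correlations` (named
#'   vector), `within_5` (logical), `re_limit`.
#' @export
compare_methods <- function(esm, qams, re_limit = 5) {
  acols <- setdiff(names(esm), "batch")
  if (!identical(sort(acols), sort(setdiff(names(qams), "batch"))) ||
      !identical(esm$batch, qams$batch)) {
    stop("esm and qams must cover the same batches and analytes", call. = FALSE)
  }
  cells <- do.call(rbind, lapply(acols, function(a) {
    e <- esm[[a]]
    q <- qams[[a]]
    re <- ifelse(e > 0, (q - e) / e * 100, NA_real_)
    data.frame(batch = esm$batch, analyte = a, esm = e, qams = q,
               relative_error = re, stringsAsFactors = FALSE)
  }))
  correlations <- vapply(acols, function(a) stats::cor(esm[[a]], qams[[a]]),
                         numeric(1L))
  out <- list(cells = cells,
              correlations = correlations,
              within_5 = all(abs(cells$relative_error) <= re_limit,
                             na.rm = TRUE),
              re_limit = re_limit)
  class(out) <- "method_comparison"
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison over %d cells (%d analytes)\n",
              nrow(x$cells), length(x$correlations)))
  cat(sprintf("  all |RE| <= %g%%: %s\n", x$re_limit,
              if (x$within_5) "yes" else "NO"))
  cat("  per-analyte Pearson r:\n")
  print(round(x$correlations, 6))
  invisible(x)
}

#' Method validation report
#'
#' Summarizes the standard validation experiments: instrument precision,
#' intermediate precision, stability and repeatability as per-analyte
#' RSDs of replicate measurements, and accuracy as mean spike recovery
#' with its RSD. Missing categories yield `NA` columns and a warning, so
#' a partial report never masquerades as a complete one.
#'
#' @param replicates Named list. Each of `instrument_precision`,
#'   `intermediate_precision`, `stability`, `repeatability` is a numeric
#'   matrix or data frame (replicates in rows, analytes in columns);
#'   `recovery` is a list per analyte of data frames with columns
#'   `original`, `added`, `found` (mg).
#' @param rsd_limit RSD pass threshold in percent for the precision-type
#'   categories.
#' @param recovery_window Acceptable mean-recovery window in percent.
#' @return A data frame of class `validation_report`, one row per analyte,
#'   with RSD columns, `mean_recovery`, `recovery_rsd` and a `pass` flag.
#' @export
validate_method <- function(replicates, rsd_limit = 3,
                            recovery_window = c(95, 105)) {
  rsd_cats <- c("instrument_precision", "intermediate_precision",
                "stability", "repeatability")
  present <- intersect(c(rsd_cats, "recovery"), names(replicates))
  missing_cats <- setdiff(c(rsd_cats, "recovery"), present)
  if (length(missing_cats)) {
    warning("partial validation report; missing: ",
            paste(missing_cats, collapse = ", "), call. = FALSE)
  }
  codes <- NULL
  for (cat_ in intersect(rsd_cats, present)) {
    codes <- union(codes, colnames(replicates[[cat_]]))
  }
  if ("recovery" %in% present) codes <- union(codes, names(replicates$recovery))
  if (is.null(codes)) stop("no validation data supplied", call. = FALSE)

  out <- data.frame(analyte = codes, stringsAsFactors = FALSE)
  for (cat_ in rsd_cats) {
    out[[cat_]] <- if (cat_ %in% present) {
      m <- as.matrix(replicates[[cat_]])
      if (nrow(m) < 2L) stop(cat_, " needs at least 2 replicates", call. = FALSE)
      vapply(codes, function(a)
        if (a %in% colnames(m)) rsd(m[, a]) else NA_real_, numeric(1L),
        USE.NAMES = FALSE)
    } else NA_real_
  }
  if ("recovery" %in% present) {
    rec <- lapply(codes, function(a) {
      d <- replicates$recovery[[a]]
      if (is.null(d)) return(c(NA_real_, NA_real_))
      r <- recovery(d$original, d$added, d$found)
      c(mean(r), rsd(r))
    })
    out$mean_recovery <- vapply(rec, `[`, 0, 1L)
    out$recovery_rsd <- vapply(rec, `[`, 0, 2L)
  } else {
    out$mean_recovery <- NA_real_
    out$recovery_rsd <- NA_real_
  }
  rsd_ok <- apply(as.matrix(out[rsd_cats]), 1L,
                  function(v) all(v[!is.na(v)] < rsd_limit))
  rec_ok <- is.na(out$mean_recovery) |
    (out$mean_recovery >= recovery_window[1L] &
       out$mean_recovery <= recovery_window[2L] &
       out$recovery_rsd < rsd_limit)
  out$pass <- rsd_ok & rec_ok
  attr(out, "rsd_limit") <- rsd_limit
  attr(out, "recovery_window") <- recovery_window
  class(out) <- c("validation_report", "data.frame")
  out
}
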