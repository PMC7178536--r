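#' Read and write peak tables as CSV
#'
#' The interchange format is a plain CSV with header columns `sample_id`,
#' `rt_min`, `area` and optionally `analyte`; run metadata travel in
#' extra columns (`instrument`, `column`, `flow_rate`, `temperature`)
#' when present, so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return [read_peak_table()] returns a [peak_table()];
#'   [write_peak_table()] returns `path` invisibly.
#' @export
read_peak_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("sample_id", "rt_min", "area")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !raw[[col]] %in% c("", "NA"))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric '%s' in column %s, row %d",
                   raw[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
    v
  }
  meta <- function(col, default) {
    if (col %in% names(raw)) raw[[col]][1L] else default
  }
  peak_table(
    rt_min = num("rt_min"),
    area = num("area"),
    analyte = if ("analyte" %in% names(raw)) {
      ifelse(raw$analyte == "", NA_character_, raw$analyte)
    } else NA_character_,
    sample_id = raw$sample_id[1L],
    instrument = meta("instrument", "default"),
    column = meta("column", "default"),
    flow_rate = as.numeric(meta("flow_rate", 1.0)),
    temperature = as.numeric(meta("temperature", 25))
  )
}

#' @param x A [peak_table()].
#' @rdname read_peak_table
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  meta <- attr(x, "run_meta")
  out <- data.frame(sample_id = attr(x, "sample_id"),
                    rt_min = x$rt_min, area = x$area, analyte = x$analyte,
                    instrument = meta$instrument, column = meta$column,
                    flow_rate = meta$flow_rate,
                    temperature = meta$temperature,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Integrate a detector trace over peak windows
#'
#' A simple integrator for rendered or exported traces: within each
#' (start, end) window the area is the trapezoidal integral of the
#' signal above a straight baseline drawn between the window endpoints.
#' Negative net areas are clamped to 0 and flagged. Peak retention times
#' are the intensity-weighted apex (time of maximum signal above
#' baseline).
#'
#' @param time Strictly increasing time axis, minutes.
#' @param intensity Detector signal, same length.
#' @param windows Two-column matrix or list of `c(start, end)` pairs,
#'   non-overlapping and within the time range.
#' @return A [peak_table()] with one row per window and a `clamped`
#'   attribute marking windows whose net area was negative.
#' @export
integrate_trace <- function(time, intensity, windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2L)
  if (length(time) != length(intensity)) {
    stop("time and intensity must have the same length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (any(windows[, 1L] >= windows[, 2L]) ||
      any(windows < min(time)) || any(windows > max(time))) {
    stop("windows must be (start < end) pairs within the time range",
         call. = FALSE)
  }
  ord <- order(windows[, 1L])
  w <- windows[ord, , drop = FALSE]
  if (nrow(w) > 1L && any(w[-1L, 1L] < w[-nrow(w), 2L])) {
    stop("overlapping windows", call. = FALSE)
  }
  res <- apply(w, 1L, function(win) {
    sel <- time >= win[1L] & time <= win[2L]
    t <- time[sel]
    y <- intensity[sel]
    base <- y[1L] + (y[length(y)] - y[1L]) * (t - t[1L]) / (t[length(t)] - t[1L])
    net <- y - base
    area <- sum(diff(t) * (net[-1L] + net[-length(net)]) / 2)
    c(area = area, apex = t[which.max(net)])
  })
  clamped <- res["area", ] < 0
  areas <- pmax(res["area", ], 0)
  out <- peak_table(rt_min = res["apex", ], area = areas,
                    sample_id = "trace")
  attr(out, "clamped") <- clamped
  out
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the workflow in one list: the
#' analyte panel, sample-prep constants, peak-matching tolerance, the
#' quality thresholds, the score coefficients and component weights, the
#' clustering settings, and the simulation seed. All defaults are the
#' published values.
#'
#' @param panel An [analyte_panel()].
#' @param prep A [sample_prep()].
#' @param tolerance_min Peak-matching tolerance, minutes.
#' @param re_limit Method-agreement relative-error bound, percent.
#' @param rsd_limit Precision/repeatability RSD bound, percent.
#' @param durability_rsd_limit Correction-factor durability bound, percent.
#' @param thresholds Grading thresholds (see [grade_batch()]).
#' @param coefficients Score coefficient table (analyte, Z1, Z2).
#' @param component_weights Weights (w1, w2) of the composite score.
#' @param hca_k Number of quality clusters.
#' @param hca_linkage Linkage method for [hca_split()].
#' @param hca_exclusions Batch ids excluded from clustering.
#' @param seed Simulation seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = default_panel(),
                            prep = sample_prep(),
                            tolerance_min = 0.5,
                            re_limit = 5,
                            rsd_limit = 3,
                            durability_rsd_limit = 5,
                            thresholds = list(qualified_min = 3,
                                              superior_total = 8,
                                              superior_ratio = 10),
                            coefficients = NULL,
                            component_weights = c(0.62614, 0.17646),
                            hca_k = 2,
                            hca_linkage = "ward.D2",
                            hca_exclusions = NULL,
                            seed = 1L) {
  stopifnot(inherits(panel, "analyte_panel"), inherits(prep, "sample_prep"))
  check_scalar_positive(tolerance_min, "tolerance_min")
  check_scalar_positive(re_limit, "re_limit")
  stopifnot(all(unlist(thresholds) > 0))
  if (!internal_standard(panel) %in% panel$code) {
    stop("internal standard must be in the panel", call. = FALSE)
  }
  cfg <- list(panel = panel, prep = prep, tolerance_min = tolerance_min,
              re_limit = re_limit, rsd_limit = rsd_limit,
              durability_rsd_limit = durability_rsd_limit,
              thresholds = thresholds, coefficients = coefficients,
              component_weights = component_weights,
              hca_k = hca_k, hca_linkage = hca_linkage,
              hca_exclusions = hca_exclusions, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read and write the plain-text key-value configuration
#'
#' Scalar configuration entries are stored one per line as `key = value`;
#' `#` starts a comment. Panel and coefficient tables live in their CSV
#' files and are not serialized here.
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @return [read_config()] returns a `pipeline_config` with the file's
#'   scalar overrides applied to the defaults; [write_config()] returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  }
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  pipeline_config(
    prep = sample_prep(num("sample_mass_g", 0.25),
                       num("extract_volume_ml", 10),
                       num("dilution_factor", 1)),
    tolerance_min = num("tolerance_min", 0.5),
    re_limit = num("re_limit", 5),
    rsd_limit = num("rsd_limit", 3),
    durability_rsd_limit = num("durability_rsd_limit", 5),
    thresholds = list(qualified_min = num("qualified_min", 3),
                      superior_total = num("superior_total", 8),
                      superior_ratio = num("superior_ratio", 10)),
    component_weights = c(num("w1", 0.62614), num("w2", 0.17646)),
    hca_k = num("hca_k", 2),
    hca_exclusions = if ("hca_exclusions" %in% names(vals)) {
      trimws(strsplit(vals[["hca_exclusions"]], ";")[[1L]])
    } else NULL,
    seed = as.integer(num("seed", 1))
  )
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- c(
    "# qams pipeline configuration",
    sprintf("sample_mass_g = %g", config$prep$sample_mass_g),
    sprintf("extract_volume_ml = %g", config$prep$extract_volume_ml),
    sprintf("dilution_factor = %g", config$prep$dilution_factor),
    sprintf("tolerance_min = %g", config$tolerance_min),
    sprintf("re_limit = %g", config$re_limit),
    sprintf("rsd_limit = %g", config$rsd_limit),
    sprintf("durability_rsd_limit = %g", config$durability_rsd_limit),
    sprintf("qualified_min = %g", config$thresholds$qualified_min),
    sprintf("superior_total = %g", config$thresholds$superior_total),
    sprintf("superior_ratio = %g", config$thresholds$superior_ratio),
    sprintf("w1 = %g", config$component_weights[1L]),
    sprintf("w2 = %g", config$component_weights[2L]),
    sprintf("hca_k = %g", config$hca_k),
    if (length(config$hca_exclusions)) {
      sprintf("hca_exclusions = %s",
              paste(config$hca_exclusions, collapse = ";"))
    },
    sprintf("seed = %d", as.integer(config$seed))
  )
  writeLines(lines, path)
  invisible(path)
}
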