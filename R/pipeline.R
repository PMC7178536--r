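#' Run the full quantification and grading pipeline
#'
#' Composes the stages end to end: calibration and correction factors
#' from standard series; peak assignment and dual-method quantification
#' of sample runs; method comparison; and chemometric scoring and grading
#' of the batch content matrix. Outputs are deterministic given the
#' config and inputs; every CSV is written only after all requested
#' stages have succeeded, so a failing stage never leaves partial output.
#'
#' @param config A [pipeline_config()].
#' @param inputs A list with any of: `standards` (named list of
#'   [standard_series()] covering the panel), `samples` (list of
#'   [peak_table()] runs, assigned or not), `reference_runs` (assigned
#'   runs for [compute_rrt()]; otherwise nominal panel times are used),
#'   `contents` (a content matrix to score directly, e.g. a packaged
#'   fixture).
#' @param outdir Output directory, created if needed; `NULL` skips
#'   writing.
#' @return (Invisibly) a list with whichever of `curves`, `rcf`, `rrt`,
#'   `located`, `contents_esm`, `contents_qams`, `comparison`, `pca`,
#'   `scores` (with threshold-cluster and grade columns), `report` the
#'   inputs allowed.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = list(),
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  panel <- config$panel
  is_code <- internal_standard(panel)
  res <- list()
  log <- c(sprintf("qams pipeline (seed %d)", as.integer(config$seed)))

  if (!is.null(inputs$standards)) {
    std <- inputs$standards
    missing_std <- setdiff(panel$code, names(std))
    if (length(missing_std)) {
      stop("calibration: standards missing for ",
           paste(missing_std, collapse = ", "), call. = FALSE)
    }
    res$curves <- lapply(std[panel$code], fit_calibration)
    res$rcf <- rcf_set(std[panel$code], internal = is_code)
    log <- c(log, sprintf(
      "calibration: %d curves fitted; min R = %.5f; RCF vs %s computed",
      length(res$curves), min(vapply(res$curves, `[[`, 0, "r")), is_code))
  }

  if (!is.null(inputs$samples)) {
    if (is.null(res$curves)) {
      stop("quantification needs standards for calibration", call. = FALSE)
    }
    res$rrt <- if (!is.null(inputs$reference_runs)) {
      compute_rrt(inputs$reference_runs, reference = is_code,
                  tolerance = config$tolerance_min)
    } else {
      panel_rrt(panel, tolerance = config$tolerance_min)
    }
    expected_ref <- panel$rt_min[panel$internal_standard]
    res$located <- lapply(inputs$samples, function(tb) {
      locate_peaks(tb, res$rrt, expected_reference_time = expected_ref)
    })
    unit_response <- res$curves[[is_code]]$slope
    f <- stats::setNames(res$rcf$mean_f, res$rcf$analyte)
    quantify_run <- function(tb) {
      vapply(panel$code, function(code) {
        i <- which(!is.na(tb$analyte) & tb$analyte == code)
        if (!length(i)) return(c(esm = 0, qams = 0))
        a <- tb$area[i]
        c(esm = mass_fraction(as.numeric(
            esm_quantify(a, res$curves[[code]])), config$prep),
          qams = mass_fraction(
            qams_quantify(a, unit_response, f[[code]]), config$prep))
      }, numeric(2L))
    }
    q <- lapply(res$located, quantify_run)
    ids <- vapply(res$located, attr, "", "sample_id")
    res$contents_esm <- data.frame(batch = ids,
                                   t(vapply(q, function(m) m["esm", ],
                                            numeric(nrow(panel)))))
    res$contents_qams <- data.frame(batch = ids,
                                    t(vapply(q, function(m) m["qams", ],
                                             numeric(nrow(panel)))))
    res$comparison <- compare_methods(res$contents_esm, res$contents_qams,
                                      re_limit = config$re_limit)
    log <- c(log, sprintf(
      "quantification: %d runs; all |RE| <= %g%%: %s; min method r = %.4f",
      length(q), config$re_limit,
      if (res$comparison$within_5) "yes" else "NO",
      min(res$comparison$correlations, na.rm = TRUE)))
  }

  contents <- if (!is.null(inputs$contents)) inputs$contents else res$contents_qams
  if (!is.null(contents)) {
    res$pca <- fit_pca(contents)
    coefficients <- if (is.null(config$coefficients)) {
      load_fixture("table5")
    } else config$coefficients
    res$scores <- comprehensive_score(contents, coefficients,
                                      config$component_weights)
    th0 <- config$thresholds
    res$scores$cluster_total <- threshold_split(
      stats::setNames(res$scores$total, res$scores$batch),
      th0$superior_total, exclusions = config$hca_exclusions)
    res$scores$cluster_ratio <- threshold_split(
      stats::setNames(res$scores$aglycone_ratio, res$scores$batch),
      th0$superior_ratio, exclusions = config$hca_exclusions)
    res$scores$grade <- grade_batch(res$scores$total,
                                    res$scores$aglycone_ratio,
                                    config$thresholds)
    th <- config$thresholds
    log <- c(log,
      sprintf("scoring: PC1 %.3f%%, PC2 %.3f%% (cumulative %.3f%%)",
              res$pca$variance_explained[1L], res$pca$variance_explained[2L],
              sum(res$pca$variance_explained[1:2])),
      sprintf("scoring: cor(Z, total) = %.4f",
              correlation_with_total(res$scores)),
      sprintf("grading: %d unqualified (< %g mg/g), %d qualified, %d superior (> %g mg/g and > %g%%)",
              sum(res$scores$grade == "unqualified"), th$qualified_min,
              sum(res$scores$grade == "qualified"),
              sum(res$scores$grade == "superior"),
              th$superior_total, th$superior_ratio))
  }

  res$report <- log
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, file) utils::write.csv(x, file.path(outdir, file),
                                             row.names = FALSE)
    if (!is.null(res$curves)) {
      wr(data.frame(analyte = names(res$curves),
                    slope = vapply(res$curves, `[[`, 0, "slope"),
                    intercept = vapply(res$curves, `[[`, 0, "intercept"),
                    r = vapply(res$curves, `[[`, 0, "r")), "curves.csv")
      wr(as.data.frame(res$rcf), "rcf.csv")
    }
    if (!is.null(res$contents_esm)) {
      wr(res$contents_esm, "contents_esm.csv")
      wr(res$contents_qams, "contents_qams.csv")
      wr(res$comparison$cells, "comparison.csv")
    }
    if (!is.null(res$scores)) {
      wr(res$scores, "scores.csv")
      wr(data.frame(component = seq_along(res$pca$eigenvalues),
                    eigenvalue = res$pca$eigenvalues,
                    variance_explained = res$pca$variance_explained),
         "pca_summary.csv")
      wr(cbind(analyte = rownames(res$pca$loadings),
               as.data.frame(res$pca$loadings)), "pca_loadings.csv")
    }
    writeLines(log, file.path(outdir, "report.txt"))
  }
  invisible(res)
}
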