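# Runs expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' True detector response underlying simulated runs
#'
#' Per-analyte linear response (slope, intercept) and retention time,
#' plus the noise model: multiplicative Gaussian noise on areas
#' (CV-parameterized, the dominant variability of HPLC peak integration),
#' an optional additive detector noise for detection-limit experiments,
#' and additive Gaussian jitter on retention times. Defaults are the
#' published calibration coefficients and the panel's nominal retention
#' times; the default noise levels (area CV 0.5%, retention jitter SD
#' 0.05 min) sit in the range the validation experiments report.
#'
#' @param panel An [analyte_panel()].
#' @param slope,intercept Per-analyte response coefficients (area per
#'   ug/mL; area). Default: the packaged calibration table, matched by
#'   code.
#' @param rt_min Per-analyte retention times (minutes). Default: the
#'   panel's nominal times.
#' @param area_cv Multiplicative area noise, percent CV.
#' @param area_sd Additive area noise, detector units.
#' @param rt_sd Retention-time jitter, minutes.
#' @return A data frame of class `response_truth` with noise parameters
#'   as attributes.
#' @export
response_truth <- function(panel = default_panel(),
                           slope = NULL, intercept = NULL, rt_min = NULL,
                           area_cv = 0.5, area_sd = 0, rt_sd = 0.05) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (is.null(slope) || is.null(intercept)) {
    t1 <- load_fixture("table1")
    m <- match(panel$code, t1$analyte)
    if (is.null(slope)) slope <- t1$slope[m]
    if (is.null(intercept)) intercept <- t1$intercept[m]
  }
  if (is.null(rt_min)) rt_min <- panel$rt_min
  if (any(!is.finite(slope)) || any(slope <= 0)) {
    stop("slopes must be positive", call. = FALSE)
  }
  if (area_cv < 0 || area_sd < 0 || rt_sd < 0) {
    stop("noise levels must be non-negative", call. = FALSE)
  }
  out <- data.frame(analyte = panel$code, slope = slope,
                    intercept = intercept, rt_min = rt_min,
                    stringsAsFactors = FALSE)
  attr(out, "area_cv") <- area_cv
  attr(out, "area_sd") <- area_sd
  attr(out, "rt_sd") <- rt_sd
  attr(out, "internal_standard") <- internal_standard(panel)
  class(out) <- c("response_truth", "data.frame")
  out
}

noisy_area <- function(true_area, truth, n = length(true_area)) {
  cv <- attr(truth, "area_cv")
  sd_add <- attr(truth, "area_sd")
  a <- true_area * (1 + stats::rnorm(n, 0, cv / 100))
  if (sd_add > 0) a <- a + stats::rnorm(n, 0, sd_add)
  a
}

#' Simulate a standard dilution ladder
#'
#' Concentrations are the per-analyte stock concentration divided by each
#' dilution factor; areas follow the true linear response perturbed by
#' the truth's noise model. Bit-reproducible under a fixed `seed`.
#'
#' @param truth A [response_truth()].
#' @param dilution_factors Distinct factors >= 1.
#' @param stock_ug_ml Named stock concentrations in ug/mL; defaults to
#'   1000 x the panel stocks stored in [default_panel()] when the truth
#'   was built from it, otherwise required.
#' @param panel Panel supplying default stocks.
#' @param seed Optional integer seed.
#' @return Named list of [standard_series()], one per analyte.
#' @export
make_standard_series <- function(truth,
                                 dilution_factors = c(1, 2, 5, 10, 20, 50, 100),
                                 stock_ug_ml = NULL,
                                 panel = default_panel(),
                                 seed = NULL) {
  stopifnot(inherits(truth, "response_truth"))
  if (any(dilution_factors < 1) || anyDuplicated(dilution_factors)) {
    stop("dilution factors must be distinct and >= 1", call. = FALSE)
  }
  if (is.null(stock_ug_ml)) {
    stock_ug_ml <- stats::setNames(panel$stock_mg_ml * 1000, panel$code)
  }
  if (any(!is.finite(stock_ug_ml)) || any(stock_ug_ml <= 0)) {
    stop("stock concentrations must be positive", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(seq_len(nrow(truth)), function(i) {
      code <- truth$analyte[i]
      conc <- stock_ug_ml[[code]] / dilution_factors
      area <- noisy_area(truth$slope[i] * conc + truth$intercept[i], truth)
      standard_series(code, conc, area)
    })
    stats::setNames(out, truth$analyte)
  })
}

#' Simulate an integrated sample chromatogram
#'
#' The inverse of the quantification chain: true mass fractions are
#' converted to solution concentrations through the sample prep, areas
#' follow the true response with the truth's noise model, and retention
#' times are jittered around the true positions. Analytes with zero
#' content emit no peak. The returned peaks are unassigned, ready for
#' [locate_peaks()].
#'
#' @param true_contents Named vector of mass fractions (mg/g) per analyte.
#' @param prep A [sample_prep()].
#' @param truth A [response_truth()].
#' @param sample_id Sample identifier.
#' @param seed Optional integer seed.
#' @return A [peak_table()] with one peak per non-zero analyte.
#' @export
make_sample_peak_table <- function(true_contents, prep = sample_prep(),
                                   truth = response_truth(),
                                   sample_id = "synthetic", seed = NULL) {
  stopifnot(inherits(truth, "response_truth"), inherits(prep, "sample_prep"))
  if (any(true_contents < 0)) stop("contents must be >= 0", call. = FALSE)
  keep <- truth$analyte[truth$analyte %in% names(true_contents)[true_contents > 0]]
  with_seed(seed, {
    i <- match(keep, truth$analyte)
    conc <- true_contents[keep] * prep$sample_mass_g * 1000 /
      (prep$extract_volume_ml * prep$dilution_factor)
    area <- noisy_area(truth$slope[i] * conc + truth$intercept[i], truth)
    rt <- truth$rt_min[i]
    if (attr(truth, "rt_sd") > 0) {
      rt <- rt + stats::rnorm(length(i), 0, attr(truth, "rt_sd"))
    }
    peak_table(rt_min = rt, area = area, sample_id = sample_id)
  })
}

#' Replicate measurements around true values
#'
#' Small helper for validation-style experiments: n replicates per
#' analyte, multiplicative Gaussian noise at the given CV.
#'
#' @param true_values Named vector of true per-analyte values.
#' @param n Number of replicates.
#' @param cv_percent Coefficient of variation in percent.
#' @param seed Optional integer seed.
#' @return Matrix with n rows and one named column per analyte.
#' @export
make_replicates <- function(true_values, n = 6, cv_percent = 1, seed = NULL) {
  with_seed(seed, {
    m <- vapply(true_values, function(v) {
      v * (1 + stats::rnorm(n, 0, cv_percent / 100))
    }, numeric(n))
    colnames(m) <- names(true_values)
    m
  })
}

#' True between-batch content distribution
#'
#' Per-analyte means and SDs plus a correlation matrix describing how the
#' six contents co-vary across batches, and the distribution family used
#' to draw them. By default every moment is computed from the packaged
#' 55-batch content matrix, so the simulated population mirrors the
#' published spread (totals roughly 3-11 mg/g).
#'
#' @param contents Content matrix to take moments from; default the
#'   packaged 55-batch table.
#' @param family `"truncated-normal"` (multivariate normal, negatives set
#'   to 0) or `"lognormal"` (moment-matched marginals on a Gaussian
#'   copula).
#' @return A list of class `population_truth`: `mean`, `sd`,
#'   `correlation`, `family`.
#' @export
population_truth <- function(contents = load_fixture("table4"),
                             family = c("truncated-normal", "lognormal")) {
  family <- match.arg(family)
  acols <- setdiff(names(contents), "batch")
  X <- as.matrix(contents[acols])
  out <- list(mean = colMeans(X),
              sd = apply(X, 2L, stats::sd),
              correlation = stats::cor(X),
              family = family)
  class(out) <- "population_truth"
  out
}

#' Simulate a batch content matrix
#'
#' Draws `n_batches` content vectors from the population described by a
#' [population_truth()]: multivariate normal with the target moments and
#' correlation (negatives truncated to 0), or moment-matched lognormal
#' marginals coupled through the same correlation on the Gaussian scale.
#'
#' @param truth A [population_truth()].
#' @param n_batches Number of batches, at least 2.
#' @param seed Optional integer seed.
#' @return A content matrix: data frame with `batch` = 1..n and one
#'   column per analyte (mg/g).
#' @export
make_content_matrix <- function(truth = population_truth(), n_batches,
                                seed = NULL) {
  stopifnot(inherits(truth, "population_truth"))
  if (n_batches < 2L) stop("n_batches must be at least 2", call. = FALSE)
  R <- truth$correlation
  p <- length(truth$mean)
  live <- truth$sd > 0
  Rl <- R[live, live, drop = FALSE]
  if (any(live) &&
      any(eigen(Rl, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("decomposition error: correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  X <- matrix(rep(truth$mean, each = n_batches), n_batches, p,
              dimnames = list(NULL, names(truth$mean)))
  if (any(live)) {
    with_seed(seed, {
      if (truth$family == "truncated-normal") {
        D <- diag(truth$sd[live], sum(live))
        Sigma <- D %*% Rl %*% D
        draw <- MASS::mvrnorm(n_batches, mu = truth$mean[live], Sigma = Sigma)
        X[, live] <- pmax(matrix(draw, ncol = sum(live)), 0)
      } else {
        z <- MASS::mvrnorm(n_batches, mu = rep(0, sum(live)), Sigma = Rl)
        z <- matrix(z, ncol = sum(live))
        m <- truth$mean[live]
        s <- truth$sd[live]
        sdlog <- sqrt(log(1 + (s / m)^2))
        meanlog <- log(m) - sdlog^2 / 2
        X[, live] <- exp(sweep(sweep(z, 2L, sdlog, "*"), 2L, meanlog, "+"))
      }
    })
  }
  out <- data.frame(batch = seq_len(n_batches))
  out[colnames(X)] <- as.data.frame(X)
  out
}
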