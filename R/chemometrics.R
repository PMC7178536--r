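#' Per-batch total content
#'
#' @param contents Content matrix: data frame with a `batch` column and
#'   one numeric column (mg/g) per analyte.
#' @return Named numeric vector of row totals (mg/g), names = batch ids.
#' @export
batch_totals <- function(contents) {
  acols <- setdiff(names(contents), "batch")
  stats::setNames(rowSums(contents[acols]), contents$batch)
}

#' Aglycone share of the total content
#'
#' The percentage of the six-compound total contributed by the sugar-free
#' aglycones. Batches with zero total have an undefined ratio and return
#' `NA` with a warning.
#'
#' @param contents Content matrix (see [batch_totals()]).
#' @param aglycones Codes of the aglycone columns.
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
aglycone_ratio <- function(contents, aglycones = c("C", "V", "H")) {
  acols <- setdiff(names(contents), "batch")
  if (!all(aglycones %in% acols)) {
    stop("aglycone codes missing from the content matrix", call. = FALSE)
  }
  tot <- rowSums(contents[acols])
  agl <- rowSums(contents[aglycones])
  out <- ifelse(tot > 0, 100 * agl / tot, NA_real_)
  if (anyNA(out)) warning("zero-total batches have undefined ratio", call. = FALSE)
  stats::setNames(out, contents$batch)
}

#' Correlation-matrix principal component analysis of batch contents
#'
#' Columns are standardized to z-scores and the 6 x 6 correlation matrix
#' is eigendecomposed, so each component explains 100 * lambda / p percent
#' of the variance. Loadings are eigenvectors scaled by sqrt(lambda)
#' (component-variable correlations), with each component's sign fixed so
#' its loading sum is non-negative.
#'
#' @param contents Content matrix with at least 3 batches and no constant
#'   analyte column.
#' @return An object of class `chromone_pca`: list with `center`, `scale`,
#'   `eigenvalues`, `variance_explained` (percent), `loadings` (analytes x
#'   components) and `scores` (standardized data times loadings).
#' @export
fit_pca <- function(contents) {
  acols <- setdiff(names(contents), "batch")
  X <- as.matrix(contents[acols])
  if (nrow(X) < 3L) stop("at least 3 batches are required", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate correlation: constant column ",
         paste(acols[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  signs <- sign(colSums(e$vectors))
  signs[signs == 0] <- 1
  vectors <- sweep(e$vectors, 2L, signs, "*")
  loadings <- sweep(vectors, 2L, sqrt(pmax(e$values, 0)), "*")
  dimnames(loadings) <- list(acols, paste0("PC", seq_along(e$values)))
  out <- list(
    center = attr(Z, "scaled:center"),
    scale = attr(Z, "scaled:scale"),
    eigenvalues = e$values,
    variance_explained = 100 * e$values / length(e$values),
    loadings = loadings,
    scores = Z %*% loadings
  )
  class(out) <- "chromone_pca"
  out
}

#' @export
print.chromone_pca <- function(x, ...) {
  cat("Correlation-matrix PCA of batch contents\n")
  ve <- x$variance_explained
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.3f%%", seq_along(ve), ve),
                    collapse = ", ")))
  cat(sprintf("  PC1+PC2 cumulative: %.3f%%\n", sum(ve[1:2])))
  invisible(x)
}

#' Composite quality score from the first two components
#'
#' Standardizes the contents to z-scores, forms the two component scores
#' Z1 and Z2 as weighted sums with the supplied per-analyte coefficients,
#' and combines them as Z = w1 Z1 + w2 Z2, the component weights
#' defaulting to the variance fractions of the published two-component
#' model. Coefficients default to the published coefficient table.
#'
#' @param contents Content matrix.
#' @param coefficients Data frame with columns `analyte`, `Z1`, `Z2`
#'   covering every analyte column of `contents`.
#' @param component_weights Numeric length-2 weights (w1, w2).
#' @return A data frame of class `score_table`: batch, Z1, Z2, Z, total
#'   (mg/g), aglycone_ratio (percent).
#' @export
comprehensive_score <- function(contents,
                                coefficients = load_fixture("table5"),
                                component_weights = c(0.62614, 0.17646)) {
  acols <- setdiff(names(contents), "batch")
  if (!all(acols %in% coefficients$analyte)) {
    stop("coefficient panel does not cover the content matrix", call. = FALSE)
  }
  co <- coefficients[match(acols, coefficients$analyte), ]
  X <- as.matrix(contents[acols])
  sds <- apply(X, 2L, stats::sd)
  Z <- sweep(sweep(X, 2L, colMeans(X)), 2L, ifelse(sds > 0, sds, 1), "/")
  z1 <- drop(Z %*% co$Z1)
  z2 <- drop(Z %*% co$Z2)
  out <- data.frame(
    batch = contents$batch,
    Z1 = z1,
    Z2 = z2,
    Z = component_weights[1L] * z1 + component_weights[2L] * z2,
    total = unname(batch_totals(contents)),
    aglycone_ratio = unname(aglycone_ratio(
      contents, intersect(c("C", "V", "H"), acols))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  out
}

#' Correlation between the composite score and the total content
#'
#' @param scores A [score_table][comprehensive_score()] (or any data frame
#'   with `Z` and `total` columns) covering at least 3 batches.
#' @return Pearson correlation coefficient.
#' @export
correlation_with_total <- function(scores) {
  if (nrow(scores) < 3L) stop("at least 3 batches are required", call. = FALSE)
  if (stats::sd(scores$Z) == 0 || stats::sd(scores$total) == 0) {
    stop("correlation undefined: constant column", call. = FALSE)
  }
  stats::cor(scores$Z, scores$total)
}

#' Split batches into quality clusters on a 1-D indicator
#'
#' Agglomerative hierarchical clustering (Ward linkage, Euclidean
#' distance) of a per-batch indicator (total content or aglycone ratio),
#' cut at `k` clusters. Batches listed in `exclusions` (e.g. singletons
#' that would dominate the dendrogram) are labelled `"excluded"` and left
#' out of the clustering. On a 1-D indicator the clusters are contiguous
#' in sorted order.
#'
#' @param values Named numeric vector (names = batch ids) or plain vector.
#' @param k Number of clusters, at least 2.
#' @param exclusions Batch ids to exclude.
#' @param method Linkage passed to [stats::hclust()]; `"ward.D2"` operates
#'   on Euclidean distances.
#' @return Character vector of cluster labels (`"1"`, `"2"`, ... in order
#'   of increasing cluster mean, or `"excluded"`), named by batch id.
#' @export
hca_split <- function(values, k = 2, exclusions = NULL, method = "ward.D2") {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  ids <- if (is.null(names(values))) as.character(seq_along(values)) else names(values)
  keep <- !ids %in% as.character(exclusions)
  v <- values[keep]
  if (length(v) < k) stop("k exceeds the number of batches", call. = FALSE)
  hc <- stats::hclust(stats::dist(v), method = method)
  cl <- stats::cutree(hc, k = k)
  # relabel so cluster numbers increase with the cluster mean
  means <- tapply(v, cl, mean)
  relabel <- match(cl, as.integer(names(sort(means))))
  labels <- rep("excluded", length(values))
  labels[keep] <- as.character(relabel)
  stats::setNames(labels, ids)
}

#' Split batches at a fixed indicator threshold
#'
#' The companion to [hca_split()]: a two-group partition of a 1-D quality
#' indicator at a stated cut-off (e.g. 8 mg/g total content, 10% aglycone
#' share). This is the partition the quality thresholds define, and the
#' reference against which a dendrogram cut can be judged.
#'
#' @param values Named numeric vector of the indicator.
#' @param threshold Cut-off; values strictly greater fall in cluster 2.
#' @param exclusions Batch ids labelled `"excluded"`.
#' @return Character labels `"1"` (at or below), `"2"` (above) or
#'   `"excluded"`, named by batch id.
#' @export
threshold_split <- function(values, threshold, exclusions = NULL) {
  ids <- if (is.null(names(values))) as.character(seq_along(values)) else names(values)
  labels <- ifelse(values > threshold, "2", "1")
  labels[ids %in% as.character(exclusions)] <- "excluded"
  stats::setNames(labels, ids)
}

#' Flag batches isolated from the rest of the indicator distribution
#'
#' A helper for choosing hierarchical-clustering exclusions: flags batches
#' whose nearest-neighbour distance on the indicator exceeds `factor`
#' times the median nearest-neighbour distance.
#'
#' @param values Named numeric vector of the indicator.
#' @param factor Multiplier of the median nearest-neighbour distance.
#' @return Character vector of flagged batch ids (possibly empty).
#' @export
flag_singletons <- function(values, factor = 3) {
  ids <- if (is.null(names(values))) as.character(seq_along(values)) else names(values)
  nn <- vapply(seq_along(values), function(i) {
    min(abs(values[-i] - values[i]))
  }, numeric(1L))
  ids[nn > factor * stats::median(nn)]
}

#' Grade a batch from its total content and aglycone ratio
#'
#' The decision rule: unqualified when the six-compound total falls below
#' the qualification minimum (3 mg/g); superior when the total exceeds
#' 8 mg/g and the aglycone share exceeds 10%; qualified otherwise.
#' Qualification is inclusive (total of exactly 3 mg/g qualifies); the
#' superior bounds are strict.
#'
#' @param total Total content(s), mg/g.
#' @param ratio Aglycone ratio(s), percent.
#' @param thresholds List with `qualified_min` (mg/g), `superior_total`
#'   (mg/g) and `superior_ratio` (percent).
#' @return Character vector: `"unqualified"`, `"qualified"` or
#'   `"superior"`.
#' @export
#' @examples
#' grade_batch(c(2.9, 3.047, 8.335), c(50, 10.06, 14.62))
grade_batch <- function(total, ratio,
                        thresholds = list(qualified_min = 3,
                                          superior_total = 8,
                                          superior_ratio = 10)) {
  stopifnot(all(unlist(thresholds) > 0), length(total) == length(ratio))
  ifelse(total < thresholds$qualified_min, "unqualified",
         ifelse(total > thresholds$superior_total &
                  ratio > thresholds$superior_ratio,
                "superior", "qualified"))
}
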