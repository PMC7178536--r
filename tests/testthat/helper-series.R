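# Noiseless dilution ladders straight from the packaged calibration
# coefficients; the workhorse fixture for calibration and factor tests.
noiseless_series <- function(codes = c("GC", "C", "GV", "V", "GH", "H"),
                             factors = c(1, 2, 5, 10, 20, 50, 100)) {
  truth <- response_truth(area_cv = 0, rt_sd = 0)
  make_standard_series(truth, dilution_factors = factors)[codes]
}

# A series lying exactly on y = slope * x + intercept.
exact_series <- function(analyte, slope, intercept, conc) {
  standard_series(analyte, conc, slope * conc + intercept)
}

# Minimal rcf_set look-alike for durability tests where only the mean
# factors matter.
fake_rcf_set <- function(mean_f, codes = names(mean_f)) {
  out <- data.frame(analyte = codes, mean_f = unname(mean_f),
                    rsd_f = 0, stringsAsFactors = FALSE)
  class(out) <- c("rcf_set", "data.frame")
  out
}

# Closed-form OLS oracle, independent of lm().
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Brute-force optimal 2-partition of a 1-D vector: the contiguous split
# of the sorted values minimizing total within-cluster sum of squares.
optimal_split_sizes <- function(v) {
  s <- sort(v)
  sse <- vapply(seq_len(length(s) - 1L), function(i) {
    a <- s[seq_len(i)]
    b <- s[-seq_len(i)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1L))
  i <- which.min(sse)
  sort(c(i, length(s) - i))
}
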