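test_that("fit_calibration recovers exact lines and validates input", {
  conc <- 209.6 / c(1, 2, 5, 10, 20, 50, 100)
  fit <- fit_calibration(exact_series("GC", 1815300, 8028, conc))
  expect_equal(fit$slope, 1815300)
  expect_equal(fit$intercept, 8028)
  expect_equal(fit$r, 1)
  expect_equal(fit$range, range(conc))

  two <- fit_calibration(standard_series("X", c(1, 2), c(2, 4)))
  expect_equal(two$slope, 2)
  expect_equal(two$intercept, 0, tolerance = 1e-12)
  expect_equal(two$r, 1)

  expect_error(standard_series("X", 1, 10), "at least 2 levels")
  expect_error(standard_series("X", c(1, 1), c(2, 3)), "distinct")
  expect_error(standard_series("X", c(0, 1), c(2, 3)), "positive")
})

test_that("fit_calibration agrees with the closed-form OLS oracle", {
  set.seed(42)
  for (i in 1:20) {
    conc <- sort(runif(7, 1, 300))
    area <- 2e6 * conc + 5e3 + rnorm(7, 0, 2e4)
    fit <- fit_calibration(standard_series("X", conc, area))
    oracle <- ols_oracle(conc, area)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-8)
  }
})

test_that("1% multiplicative noise leaves the fitted slope within 2% of truth", {
  truth <- response_truth(area_cv = 1, rt_sd = 0)
  std <- make_standard_series(truth, seed = 7)
  for (code in names(std)) {
    fit <- fit_calibration(std[[code]])
    true_slope <- truth$slope[truth$analyte == code]
    expect_lt(abs(fit$slope / true_slope - 1), 0.02)
  }
})

test_that("LOD and LOQ follow the S/N = 3 and 10 definition", {
  curve <- fit_calibration(standard_series("X", c(1, 2, 3), c(30, 60, 90)))
  expect_equal(unname(estimate_lod_loq(curve, 0)), c(0, 0))
  ll <- estimate_lod_loq(curve, curve$slope / 30)
  expect_equal(unname(ll), c(0.1, 1 / 3))
  expect_error(estimate_lod_loq(curve, -1), "non-negative")

  # scale consistency with the published GC limit
  gc <- fit_calibration(exact_series("GC", 1815300, 8028, c(2.1, 21, 210)))
  expect_equal(unname(estimate_lod_loq(gc, 1815300 * 0.29 / 3)["lod"]), 0.29)

  # loq/lod = 10/3 and inverse-slope / linear-noise scaling
  set.seed(11)
  for (i in 1:10) {
    slope <- runif(1, 1e5, 1e7)
    noise <- runif(1, 1, 1e4)
    c1 <- fit_calibration(standard_series("X", c(1, 2), slope * c(1, 2)))
    ll1 <- estimate_lod_loq(c1, noise)
    expect_equal(unname(ll1["loq"] / ll1["lod"]), 10 / 3)
    c2 <- fit_calibration(standard_series("X", c(1, 2), 2 * slope * c(1, 2)))
    expect_equal(unname(estimate_lod_loq(c2, noise)["lod"]),
                 unname(ll1["lod"]) / 2)
    expect_equal(unname(estimate_lod_loq(c1, 3 * noise)["lod"]),
                 3 * unname(ll1["lod"]))
  }
})

test_that("relative correction factors reduce to response ratios", {
  conc <- c(1, 2, 5, 10)
  internal <- exact_series("S", 2, 0, conc)
  analyte <- exact_series("K", 4, 0, conc)
  rc <- compute_rcf(internal, analyte)
  expect_equal(rc$per_level_f, rep(0.5, 4))
  expect_equal(rc$mean_f, 0.5)
  expect_equal(rc$rsd_f, 0)

  self <- compute_rcf(internal, internal)
  expect_equal(self$per_level_f, rep(1, 4))
  expect_equal(self$rsd_f, 0)

  expect_error(compute_rcf(internal, exact_series("K", 4, 0, c(1, 2))),
               "pairing error")
})

test_that("noiseless GC-vs-GV factor matches the published value within 1%", {
  std <- noiseless_series()
  rc <- rcf_set(std, internal = "GV")
  f_gc <- rc$mean_f[rc$analyte == "GC"]
  # slope-ratio oracle: intercepts are small, so f ~ slope_GV / slope_GC
  expect_lt(abs(f_gc / (1894482 / 1815300) - 1), 0.005)
  expect_lt(abs(f_gc / 1.047 - 1), 0.01)
  expect_equal(rc$mean_f[rc$analyte == "GV"], 1)
  expect_equal(rc$rsd_f[rc$analyte == "GV"], 0)
  expect_true(all(rc$mean_f > 0))
})

test_that("internal standard factor is identically 1 for any data", {
  set.seed(3)
  for (i in 1:10) {
    conc <- sort(runif(5, 1, 100))
    area <- runif(5, 1e4, 1e7)
    s <- standard_series("S", conc, area)
    rc <- compute_rcf(s, s)
    expect_equal(rc$per_level_f, rep(1, 5))
  }
})

test_that("factor durability flags cross-condition RSD above 5%", {
  base <- fake_rcf_set(c(GC = 1.05, C = 0.65))
  same <- durability_rcf(list(base, base, base))
  expect_equal(same$per_analyte$rsd, c(0, 0))
  expect_true(same$pass)

  wobble <- durability_rcf(list(fake_rcf_set(c(A = 1.00)),
                                fake_rcf_set(c(A = 1.02)),
                                fake_rcf_set(c(A = 0.98))))
  expect_equal(wobble$per_analyte$rsd, 2, tolerance = 1e-6)
  expect_true(wobble$pass)

  wild <- durability_rcf(list(fake_rcf_set(c(A = 1.0)),
                              fake_rcf_set(c(A = 1.2)),
                              fake_rcf_set(c(A = 0.8))))
  expect_equal(wild$per_analyte$rsd, 20, tolerance = 1e-6)
  expect_false(wild$pass)

  expect_error(durability_rcf(list(base)), "at least 2")
  expect_error(durability_rcf(list(base, fake_rcf_set(c(A = 1)))),
               "same analyte panel")
})

test_that("relative retention offsets average correctly across runs", {
  one <- peak_table(c(20, 25.5), c(1e5, 2e5), c("GV", "GH"), "run1")
  rrt <- compute_rrt(list(one), reference = "GV")
  expect_equal(rrt$delta_rt[rrt$analyte == "GH"], 5.5)
  expect_equal(rrt$delta_rt[rrt$analyte == "GV"], 0)
  expect_equal(rrt$rsd[rrt$analyte == "GV"], 0)

  set.seed(5)
  runs <- lapply(1:5, function(i) {
    peak_table(c(20, 20 + 5 * (1 + rnorm(1, 0, 0.01))), c(1e5, 1e5),
               c("GV", "H"), paste0("r", i))
  })
  rr <- compute_rrt(runs, "GV")
  expect_lt(rr$rsd[rr$analyte == "H"], 5)

  bad <- peak_table(c(20, 25), c(1, 1), c(NA, "H"), "norf")
  expect_error(compute_rrt(list(bad), "GV"), "norf")
})

test_that("peak location assigns by nearest offset and flags the absent", {
  panel <- default_panel()
  rrt <- panel_rrt(panel)
  ref_rt <- panel$rt_min[panel$internal_standard]

  complete <- peak_table(panel$rt_min, rep(1e5, 6), sample_id = "full")
  out <- locate_peaks(complete, rrt, ref_rt)
  expect_equal(out$analyte, panel$code[order(panel$rt_min)])
  expect_length(attr(out, "absent"), 0)

  # idempotence and single assignment
  again <- locate_peaks(out, rrt, ref_rt)
  expect_equal(again$analyte, out$analyte)
  expect_false(anyDuplicated(stats::na.omit(out$analyte)) > 0)

  no_h <- peak_table(panel$rt_min[panel$code != "H"], rep(1e5, 5),
                     sample_id = "noH")
  out2 <- locate_peaks(no_h, rrt, ref_rt)
  expect_equal(attr(out2, "absent"), "H")
  expect_equal(sum(!is.na(out2$analyte)), 5)

  # a peak drifted beyond tolerance is not misassigned
  drift <- panel$rt_min
  drift[panel$code == "GH"] <- drift[panel$code == "GH"] + 2
  out3 <- locate_peaks(peak_table(drift, rep(1e5, 6)), rrt, ref_rt)
  expect_true("GH" %in% attr(out3, "absent"))
  expect_false("GH" %in% out3$analyte)

  expect_error(locate_peaks(peak_table(5, 1), rrt, ref_rt),
               "reference peak not found")
})

test_that("competing analytes resolve greedily by smallest deviation", {
  rrt <- panel_rrt(default_panel())
  # one peak sits between the expected GH and H offsets, nearer GH
  tb <- peak_table(c(20.8, 36.0), c(1e5, 1e5))
  out <- locate_peaks(tb, rrt, 20.8, tolerance = 10)
  expect_equal(out$analyte[out$rt_min == 36.0], "GH")
  expect_true("H" %in% attr(out, "absent"))
})

test_that("the dilution ladder of the panel stocks spans the published ranges", {
  panel <- default_panel()
  t1 <- load_fixture("table1")
  m <- match(panel$code, t1$analyte)
  expect_equal(round(panel$stock_mg_ml * 1000 / 100, 2), t1$range_min[m])
  expect_equal(panel$stock_mg_ml * 1000, t1$range_max[m])
})
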