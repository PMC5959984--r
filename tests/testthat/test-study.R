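sweep_cached <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- run_sweep()
    tab
  }
})

test_that("the default factorial sweep covers all 48 configurations", {
  sw <- sweep_cached()
  expect_equal(nrow(sw), 48)
  expect_equal(nrow(unique(sw[c("gtv_diameter_cm", "margin_mm", "beams")])), 48)
  expect_true(all(sw$tcp_fx1 > 0 & sw$tcp_fx1 < 1))
  # a configuration missing from the quality table is skipped with a warning
  tab <- plan_quality_table()
  expect_warning(
    sw47 <- run_sweep(quality_table = tab[-1, ]),
    "skipped")
  expect_equal(nrow(sw47), 47)
})

test_that("the benchmark 4 cm row reproduces the module oracles", {
  sw <- sweep_cached()
  row <- sw[sw$gtv_diameter_cm == 4 & sw$margin_mm == 0 &
              sw$beams == "noncoplanar", ]
  expect_equal(row$nominal_rx_gy, 15)
  expect_equal(row$nominal_v12_cm3, oracle$v12_4cm_0mm_noncop)
  expect_equal(row$idp_gy_fx1, oracle$idp1_4cm_0mm_noncop)
  # the motivating deficit: isotoxic single-fraction dose below the 15 Gy
  # nominal prescription for the largest target
  expect_lt(row$idp_gy_fx1, 15)
})

test_that("V12 exceeds the 10 cm^3 constraint for all targets above 2 cm", {
  sw <- sweep_cached()
  big <- sw[sw$gtv_diameter_cm > 2 & sw$margin_mm >= 1, ]
  expect_true(all(big$nominal_v12_cm3 > 10))
})

test_that("V12 orderings: beams at fixed geometry and margin tendency", {
  sw <- sweep_cached()
  # non-coplanar spares more brain than coplanar for diameters >= 1.5 cm
  sub <- sw[sw$gtv_diameter_cm >= 1.5, ]
  for (key in split(sub, sub[c("gtv_diameter_cm", "margin_mm")])) {
    expect_lt(key$nominal_v12_cm3[key$beams == "noncoplanar"],
              key$nominal_v12_cm3[key$beams == "coplanar"])
  }
  # across the sweep, larger margins irradiate more healthy brain on average
  for (b in c("coplanar", "noncoplanar")) {
    m_mean <- tapply(sw$nominal_v12_cm3[sw$beams == b],
                     sw$margin_mm[sw$beams == b], mean)
    expect_true(all(diff(m_mean) > 0))
  }
})

test_that("fractionated isotoxic schemes dominate single fraction for large targets", {
  sw <- sweep_cached()
  big <- sw[sw$gtv_diameter_cm >= 2.5, ]
  expect_true(all(big$tcp_fx1 <= big$tcp_fx3))
  expect_true(all(big$tcp_fx3 <= big$tcp_fx5))
})

test_that("exponential decay fitting recovers known parameters and degenerates safely", {
  v <- exp(seq(log(0.5), log(60), length.out = 25))
  truth <- c(d_inf = 13, d0 = 20, v0 = 5)
  fit <- fit_exp_decay(v, truth["d_inf"] + truth["d0"] * exp(-v / truth["v0"]))
  expect_equal(fit$coefficients, truth, tolerance = 1e-6)
  # constant data collapse to the mean with no decay amplitude
  flat <- fit_exp_decay(v, rep(17, length(v)))
  expect_equal(unname(flat$coefficients["d_inf"]), 17, tolerance = 1e-6)
  expect_equal(unname(flat$coefficients["d0"]), 0, tolerance = 1e-6)
  expect_error(fit_exp_decay(1:3, 1:3), "at least 4")
})

test_that("the spherical coplanar 2 mm arm is well described by exponential decay", {
  sw <- sweep_cached()
  arm <- sw[sw$beams == "coplanar" & sw$margin_mm == 2, ]
  fit <- fit_exp_decay(arm$ptv_volume_cm3, arm$idp_gy_fx1)
  expect_lt(fit$sigma, 0.05 * mean(arm$idp_gy_fx1))
  expect_gt(fit$coefficients["v0"], 0)
  expect_true(all(diff(predict(fit, seq(0.5, 65, 1))) < 0))
})

test_that("fit comparison is null on identical data and detects a shifted curve", {
  sw <- sweep_cached()
  arm <- sw[sw$beams == "coplanar" & sw$margin_mm == 2, ]
  da <- data.frame(volume = arm$ptv_volume_cm3, dose = arm$idp_gy_fx1)
  fa <- fit_exp_decay(da$volume, da$dose)
  # data generated from the fitted curve itself: statistic 0, p ~ 1
  db0 <- data.frame(volume = exp(seq(log(0.5), log(60), length.out = 46)))
  db0$dose <- predict(fa, db0$volume)
  fb0 <- fit_exp_decay(db0$volume, db0$dose)
  cmp0 <- compare_fits(fa, fb0, da, db0, n_boot = 0)
  expect_equal(cmp0$chisq_stat, 0, tolerance = 1e-10)
  expect_equal(cmp0$chisq_p, 1, tolerance = 1e-6)
  # +5 Gy shifted cohorts are flagged by the bootstrap coefficient test at
  # p < 0.01 in nearly all seeds (the Pearson statistic alone has little
  # power for a uniform shift against dose-sized denominators)
  ps <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(seed = 5000 + s))
    db <- data.frame(volume = co$ptv_volume_cm3, dose = co$idp_gy_fx1 + 5)
    fb <- fit_exp_decay(db$volume, db$dose)
    compare_fits(fa, fb, da, db, n_boot = 150, seed = s)$wald_p
  }, 0)
  expect_gte(mean(ps < 0.01), 0.9)
})

test_that("tuned cohorts are statistically compatible with the spherical curve", {
  sw <- sweep_cached()
  arm <- sw[sw$beams == "coplanar" & sw$margin_mm == 2, ]
  da <- data.frame(volume = arm$ptv_volume_cm3, dose = arm$idp_gy_fx1)
  fa <- fit_exp_decay(da$volume, da$dose)
  ps <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_spec(seed = 8000 + s))
    db <- data.frame(volume = co$ptv_volume_cm3, dose = co$idp_gy_fx1)
    fb <- fit_exp_decay(db$volume, db$dose)
    compare_fits(fa, fb, da, db, n_boot = 0)$chisq_p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("the bootstrap coefficient test agrees with the null on compatible data", {
  sw <- sweep_cached()
  arm <- sw[sw$beams == "coplanar" & sw$margin_mm == 2, ]
  da <- data.frame(volume = arm$ptv_volume_cm3, dose = arm$idp_gy_fx1)
  fa <- fit_exp_decay(da$volume, da$dose)
  co <- generate_cohort(cohort_spec(seed = 314))
  db <- data.frame(volume = co$ptv_volume_cm3, dose = co$idp_gy_fx1)
  fb <- fit_exp_decay(db$volume, db$dose)
  cmp <- compare_fits(fa, fb, da, db, n_boot = 200, seed = 99)
  expect_gt(cmp$n_boot_used, 100)
  expect_gt(cmp$wald_p, 0.05)
  # deterministic given the seed
  cmp2 <- compare_fits(fa, fb, da, db, n_boot = 200, seed = 99)
  expect_equal(cmp$wald_stat, cmp2$wald_stat)
})

test_that("result export is deterministic and round-trips", {
  sw <- sweep_cached()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  arm <- sw[sw$beams == "coplanar" & sw$margin_mm == 2, ]
  fit <- fit_exp_decay(arm$ptv_volume_cm3, arm$idp_gy_fx1)
  export_results(sw, dir1, fits = list(coplanar_2mm = fit))
  export_results(sw, dir2, fits = list(coplanar_2mm = fit))
  f1 <- file.path(dir1, "sweep_results.csv")
  expect_identical(readLines(f1), readLines(file.path(dir2, "sweep_results.csv")))
  back <- utils::read.csv(f1)
  expect_equal(nrow(back), 48)
  expect_equal(back$nominal_v12_cm3, sw$nominal_v12_cm3)
  fits <- jsonlite::read_json(file.path(dir1, "exp_decay_fits.json"))
  expect_equal(fits$coplanar_2mm$coefficients$d_inf,
               unname(fit$coefficients["d_inf"]))
})
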