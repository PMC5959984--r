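test_that("closed-form isotoxic dose matches frozen oracle values", {
  res <- idp_dose_analytic(spherical_target(4, 0), quality_4_0_noncop(),
                           constraint(12, 10, 1), nominal_rx = 15)
  expect_equal(res$idp_dose, oracle$idp1_4cm_0mm_noncop)
  expect_equal(res$scale_factor, oracle$idp1_4cm_0mm_noncop / 15)
  expect_equal(res$achieved_volume, 10, tolerance = 1e-9)
  expect_false(res$constraint_inside_ptv)
  # three-fraction constraint, 1 mm margin, GI 2.5
  res3 <- idp_dose_analytic(spherical_target(4, 1),
                            plan_quality(126, 105, 1.0, 2.5),
                            srs_constraints()$fx3)
  expect_equal(res3$idp_dose, oracle$idp3_4cm_1mm_noncop)
  expect_equal(res3$scheme$n_fractions, 3L)
})

test_that("zero margin and CI 1 put the constraint isodose on the PTV surface", {
  # constraint volume equal to PTV-minus-GTV shell: isotoxic dose equals the
  # constraint level because r_c coincides with r_rx
  tgt <- spherical_target(3, 0)
  q <- plan_quality(113, 97, 1.0, 2.8)
  shell <- 1e-9  # vanishing constraint volume at 0 mm margin
  res <- idp_dose_analytic(spherical_target(3, 0), q,
                           constraint(12, shell, 1))
  expect_equal(res$idp_dose, 12, tolerance = 1e-6)
})

test_that("achieved volume equals the constraint volume on every sweep call", {
  for_each_config(function(d, m, b, q) {
    res <- idp_dose_analytic(spherical_target(d, m), q, constraint(12, 10, 1))
    if (!res$constraint_inside_ptv)
      expect_equal(res$achieved_volume, 10, tolerance = 1e-6)
    else
      expect_lt(res$idp_dose, 12)
  })
})

test_that("isotoxic dose decreases with GTV diameter and margin at fixed quality", {
  q <- plan_quality(120, 100, 1.0, 3.0)
  doses_d <- vapply(seq(0.5, 4, 0.5), function(d)
    idp_dose_analytic(spherical_target(d, 1), q, constraint(12, 10, 1))$idp_dose, 0)
  expect_true(all(diff(doses_d) < 0))
  doses_m <- vapply(c(0, 1, 2), function(m)
    idp_dose_analytic(spherical_target(3, m), q, constraint(12, 10, 1))$idp_dose, 0)
  expect_true(all(diff(doses_m) < 0))
})

test_that("DVH renormalisation reproduces the analytic isotoxic dose within 2%", {
  tgt <- spherical_target(4, 0)
  q <- quality_4_0_noncop()
  mod <- calibrate_radial_model(tgt, q, 15)
  g <- suppressWarnings(render_grid(mod, spacing = 1,
                                    extent = 1.05 * radius_at_dose(mod, 12)))
  dvh <- dvh_from_grid(g, "healthy")
  res <- renormalize_dvh_to_constraint(dvh, 15, constraint(12, 10, 1))
  expect_equal(res$idp_dose, oracle$idp1_4cm_0mm_noncop, tolerance = 0.02)
  expect_equal(res$achieved_volume, 10, tolerance = 1e-6)
  expect_equal(v_at_dose(res$dvh, 12), 10, tolerance = 1e-6)
})

test_that("renormalisation meets its DVH edge cases", {
  # a DVH that already meets the constraint is returned unscaled
  dvh <- cumulative_dvh(seq(0, 30, 0.1), pmax(0, 40 - 2 * seq(0, 30, 0.1)))
  v_at_12 <- v_at_dose(dvh, 12)
  res <- renormalize_dvh_to_constraint(dvh, 20, constraint(12, v_at_12, 1))
  expect_equal(res$scale_factor, 1)
  expect_equal(res$idp_dose, 20)
  # scale equivariance: the same plan delivered at twice the monitor units
  # (doses and nominal prescription doubled) has half the scale factor and
  # an unchanged isotoxic dose
  res2 <- renormalize_dvh_to_constraint(rescale_dvh(dvh, 2), 40,
                                        constraint(12, v_at_12, 1))
  expect_equal(res2$scale_factor, 0.5)
  expect_equal(res2$idp_dose, res$idp_dose)
  expect_error(
    renormalize_dvh_to_constraint(dvh, 20, constraint(12, 100, 1)),
    "exceeds structure volume")
})

test_that("analytic and DVH paths agree within 2% across all configurations", {
  prot <- prescription_protocol()
  for_each_config(function(d, m, b, q) {
    tgt <- spherical_target(d, m)
    rx <- prescribe_by_ptv_size(tgt$ptv_volume, prot)
    mod <- calibrate_radial_model(tgt, q, rx)
    r_need <- max(radius_at_dose(mod, 12),
                  (3 * (10 + tgt$gtv_volume) / (4 * pi))^(1 / 3))
    g <- suppressWarnings(render_grid(mod, spacing = 1,
                                      extent = 1.05 * r_need))
    dvh <- dvh_from_grid(g, "healthy")
    grid_res <- renormalize_dvh_to_constraint(dvh, rx, constraint(12, 10, 1))
    ana_res <- idp_dose_analytic(tgt, q, constraint(12, 10, 1))
    expect_equal(grid_res$idp_dose, ana_res$idp_dose, tolerance = 0.02,
                 info = sprintf("%.1f cm / %g mm / %s", d, m, b))
  })
})
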