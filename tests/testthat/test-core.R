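test_that("total solids percentage follows the gravimetric definition", {
  expect_equal(total_solids_percent(10, 8.4), 16)
  expect_equal(total_solids_percent(5, 5), 0)
  expect_equal(total_solids_percent(12.5, 9.875), 21)
  expect_error(total_solids_percent(10, 10.5), "cannot exceed")
  expect_error(total_solids_percent(0, 0), "strictly positive")
  expect_error(total_solids_percent(10, -1), "non-negative")
})

test_that("fluid constructor derives and cross-checks viscosities", {
  fl <- fluid(1060, 0.0057)
  expect_equal(fl$kinematic_viscosity, 0.0057 / 1060)
  # independently rounded kinematic viscosity within the 2% band is accepted
  expect_silent(fluid(1060, 0.0068, 6.36e-6))
  expect_error(fluid(1060, 0.0057, 7e-6), "disagrees")
  expect_error(fluid(1060, -0.0057), "dynamic_viscosity")
  expect_error(fluid(1060, 0.0057, cell_size_range_um = c(2, 1)),
               "cell_size_range_um")
})

test_that("vessel geometry enforces volume ordering and diameter consistency", {
  v <- vessel_geometry(300, 207, working_height = 11.47, Z_over_T = 2.55,
                       H_over_T = 3, D_over_T = 0.45)
  expect_equal(v$tank_diameter, 11.47 / 2.55)
  expect_equal(v$total_height, 3 * 11.47 / 2.55)
  expect_error(vessel_geometry(100, 207, working_height = 11.47,
                               Z_over_T = 2.55),
               "working_volume")
  expect_error(vessel_geometry(300, 207, working_height = 11.47,
                               tank_diameter = 4.2, Z_over_T = 2.55),
               "disagrees")
})

test_that("geometry derivation reproduces the tabulated vessel dimensions", {
  g <- derive_geometry(11.47, 2.55, 3, 0.45)
  expect_equal(g$tank_diameter, 4.498, tolerance = 1e-3)
  expect_equal(g$impeller_diameter, 2.024, tolerance = 1e-3)
  expect_equal(g$total_height, 13.49, tolerance = 1e-3)
  g2 <- derive_geometry(0.65, 1.61, 3, 0.45)
  expect_equal(g2$tank_diameter, 0.4037, tolerance = 1e-3)
  expect_equal(g2$impeller_diameter, 0.1817, tolerance = 1e-3)
  g3 <- derive_geometry(1, 1, 1, 1)
  expect_equal(unlist(g3, use.names = FALSE), c(1, 1, 1))
  expect_error(derive_geometry(1, 0, 1, 1), "Z_over_T")
})

test_that("geometry derivation is scale-equivariant in the working height", {
  set.seed(42)
  for (i in 1:20) {
    Z0 <- runif(1, 0.1, 20); zt <- runif(1, 1, 3)
    ht <- runif(1, 1.5, 3.5); dt <- runif(1, 0.3, 0.5)
    k <- runif(1, 0.1, 10)
    g1 <- derive_geometry(Z0, zt, ht, dt)
    g2 <- derive_geometry(k * Z0, zt, ht, dt)
    expect_equal(g2$tank_diameter, k * g1$tank_diameter)
    expect_equal(g2$total_height, k * g1$total_height)
    expect_equal(g2$impeller_diameter, k * g1$impeller_diameter)
  }
})

test_that("similarity bookkeeping reproduces the tabulated ratios", {
  expect_equal(calculated_working_height(4.498, 1.33), 5.98, tolerance = 1e-3)
  expect_equal(calculated_working_height(0.4037, 1.32), 0.533,
               tolerance = 1e-3)
  expect_equal(calculated_working_height(1, 2), 2)
  expect_equal(similarity_ratio(0.53, 0.65), 0.815, tolerance = 1e-3)
  expect_equal(similarity_ratio(5.99, 11.47), 0.522, tolerance = 1e-3)
  expect_equal(similarity_ratio(0.18, 0.18), 1)
  expect_equal(apply_similarity_ratio(0.81, 11.47), 9.29, tolerance = 1e-3)
  expect_equal(apply_similarity_ratio(1, 11.47), 11.47)
  expect_error(apply_similarity_ratio(1.2, 11.47), "1.05")
})

test_that("similarity ratio composed with its application is the identity", {
  set.seed(7)
  for (i in 1:20) {
    Z0 <- runif(1, 0.1, 20)
    Z_calc <- runif(1, 0.5, 1.05) * Z0
    expect_equal(apply_similarity_ratio(similarity_ratio(Z_calc, Z0), Z0),
                 Z_calc)
  }
})

test_that("occupancy warns below the 80% working-volume floor", {
  expect_warning(occ <- occupancy_percent(6, 11.47), "80")
  expect_equal(occ, 52.31, tolerance = 1e-3)
  expect_silent(expect_equal(occupancy_percent(11.47, 11.47), 100))
  expect_no_warning(expect_equal(occupancy_percent(9.29, 11.47), 81.0,
                                 tolerance = 1e-2))
})

test_that("cube-root scale factor maps volumes to linear dimensions", {
  expect_equal(geometric_scale_factor(0.003, 0.1), 3.2183, tolerance = 1e-4)
  expect_equal(geometric_scale_factor(1, 1), 1)
  expect_equal(geometric_scale_factor(0.1, 207), 12.744, tolerance = 1e-4)
})

test_that("similarity records tabulate one scale and flag low occupancy", {
  expect_warning(rec <- similarity_record("industrial", 4.498039, 11.47,
                                          1.33), "80")
  expect_equal(rec$Z_calc, 1.33 * 4.498039)
  expect_equal(rec$similarity_ratio, rec$Z_calc / 11.47)
  expect_equal(rec$occupancy_fraction, rec$similarity_ratio)
  lab <- similarity_record("lab", 0.18 / 1.37, 0.18, 1.37)
  expect_equal(lab$similarity_ratio, 1)
})

test_that("case-study impeller diameters imply D/T of 0.449-0.451", {
  for (case in whey) {
    dt <- case$impeller$diameter / case$vessel$tank_diameter
    expect_gt(dt, 0.449)
    expect_lt(dt, 0.452)
    expect_equal(round(dt, 2), 0.45)
  }
})
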