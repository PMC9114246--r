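test_that("Reynolds number matches the tabulated values", {
  expect_equal(reynolds_number(1060, 3.333, 0.1814, 0.0057) / 1e4, 2.04,
               tolerance = 1e-3)
  expect_equal(reynolds_number(1060, 3.333, 2.0295, 0.0057) / 1e6, 2.55,
               tolerance = 1e-2)
  expect_equal(reynolds_number(1, 1, 1, 1), 1)
  expect_error(reynolds_number(1060, 0, 1, 1), "speed")
})

test_that("diameter inversion round-trips through the Reynolds number", {
  expect_equal(diameter_from_reynolds(2.04e4, 1060, 3.333, 0.0057), 0.1814,
               tolerance = 1e-3)
  expect_equal(diameter_from_reynolds(2.55319e6, 1060, 3.333, 0.0057),
               2.0296, tolerance = 1e-3)
  expect_equal(diameter_from_reynolds(1, 1, 1, 1), 1)
  set.seed(11)
  for (i in 1:25) {
    re <- 10^runif(1, 0, 7); rho <- runif(1, 950, 1200)
    n <- runif(1, 0.2, 5); mu <- runif(1, 0.001, 0.02)
    d <- diameter_from_reynolds(re, rho, n, mu)
    expect_equal(reynolds_number(rho, n, d, mu), re, tolerance = 1e-12)
  }
})

test_that("flow regime classification uses the standard thresholds", {
  expect_identical(classify_regime(2.55e6), "turbulent")
  expect_identical(classify_regime(1810), "transition")
  expect_identical(classify_regime(5), "laminar")
  expect_identical(classify_regime(1e4), "transition")  # strictly above
  expect_identical(classify_regime(10), "laminar")      # boundary inclusive
})

test_that("power number switches between laminar, transition and turbulent", {
  expect_equal(power_number("RTB", 2.55e6), 5)
  expect_equal(power_number("PBT", 1e5), 1.64)
  expect_equal(power_number("RTB", 10), 6.4)  # laminar: K_L / Re with K_L 64
  expect_warning(po <- power_number("RTB", 1810), "transition")
  expect_equal(po, 5)  # default policy falls back to the turbulent constant
  expect_silent(po2 <- power_number("RTB", 1810, whey_corr))
  expect_equal(po2, 4.58)
  expect_error(power_number("XYZ", 1e5), "not found")
})

test_that("mixing power reproduces the tabulated draws and is linear in n", {
  expect_equal(mixing_power(5, 3.333, 0.1814, 1060, 2), 77.1,
               tolerance = 1e-3)
  expect_equal(mixing_power(5, 1.33, 2.0295, 1060, 2) / 1000, 858.7,
               tolerance = 1e-3)
  expect_equal(mixing_power(5, 2, 0.5, 1000, 2),
               2 * mixing_power(5, 2, 0.5, 1000, 1))
})

test_that("mixing power is homogeneous of degree 3 in N and 5 in D", {
  set.seed(3)
  for (i in 1:20) {
    po <- runif(1, 0.3, 5); n <- runif(1, 0.2, 5)
    d <- runif(1, 0.05, 2.5); rho <- runif(1, 950, 1200)
    k <- runif(1, 0.5, 3)
    base <- mixing_power(po, n, d, rho)
    expect_equal(mixing_power(po, k * n, d, rho), k^3 * base,
                 tolerance = 1e-12)
    expect_equal(mixing_power(po, n, k * d, rho), k^5 * base,
                 tolerance = 1e-12)
  }
})

test_that("specific power carries its explicit volume basis", {
  pvw <- specific_power(9425.137, 207, "working")
  expect_equal(as.numeric(pvw), 45.53, tolerance = 1e-3)
  expect_identical(attr(pvw, "volume_basis"), "working")
  pvt <- specific_power(862.54, 300, "total")
  expect_equal(as.numeric(pvt), 2.875, tolerance = 1e-3)
  expect_identical(attr(pvt, "volume_basis"), "total")
  expect_equal(as.numeric(specific_power(0, 1, "working")), 0)
})

test_that("energy dissipation rate is power per unit broth mass", {
  expect_equal(energy_dissipation_rate(77.006, 1060, 0.1), 0.7265,
               tolerance = 1e-3)
  expect_equal(energy_dissipation_rate(0.257, 1060, 0.003), 0.0808,
               tolerance = 1e-3)
  expect_equal(energy_dissipation_rate(1060, 1060, 1), 1)
})

test_that("Kolmogorov microscale follows (nu^3/eps)^(1/4) and is monotone", {
  expect_equal(1e6 * kolmogorov_length(0.0430, 5.37e-6), 245.1,
               tolerance = 1e-3)
  expect_equal(1e6 * kolmogorov_length(0.7265, 5.37e-6), 120.9,
               tolerance = 1e-3)
  nu <- 2e-6
  expect_equal(kolmogorov_length(nu^3, nu), 1)
  expect_error(kolmogorov_length(0, 1e-6), "epsilon_t")
  set.seed(5)
  for (i in 1:15) {
    eps <- 10^runif(1, -3, 1); nu <- 10^runif(1, -6.5, -5)
    expect_lt(kolmogorov_length(2 * eps, nu), kolmogorov_length(eps, nu))
    expect_gt(kolmogorov_length(eps, 2 * nu), kolmogorov_length(eps, nu))
  }
})

test_that("shear screen compares the microscale with the cell size", {
  s <- shear_safety(245.12e-6, 1.9)
  expect_equal(s$margin, 129, tolerance = 1e-2)
  expect_true(s$safe)
  expect_false(shear_safety(1.9e-6, 1.9)$safe)  # margin exactly 1
  s3 <- shear_safety(0.95e-6, 1.9)
  expect_equal(s3$margin, 0.5)
  expect_false(s3$safe)
})

test_that("torque conventions: physical definition and hp-formula variant", {
  expect_equal(impeller_torque(2 * pi, 1), 1)
  expect_equal(impeller_torque(862.54e3, 80 / 60, "hp_formula"), 76775,
               tolerance = 1e-3)
  expect_equal(impeller_torque(853.49e3, 150 / 60, "hp_formula"), 40517,
               tolerance = 1e-3)
  set.seed(9)
  for (i in 1:20) {
    p <- 10^runif(1, -1, 6); n <- runif(1, 0.2, 5)
    ratio <- impeller_torque(p, n, "hp_formula") / impeller_torque(p, n)
    expect_lt(abs(ratio - 0.7457), 1e-4)
  }
})

test_that("operating point assembles the full hydrodynamic chain", {
  op <- operating_point(whey$pilot, correlation = whey_corr)
  expect_equal(op$reynolds / 1e4, 2.04, tolerance = 1e-3)
  expect_identical(op$regime, "turbulent")
  expect_equal(op$power, 77.13, tolerance = 1e-3)
  expect_equal(op$rpm, 60 * op$speed)
  expect_equal(as.numeric(op$specific_power_working), op$power / 0.1)
  expect_equal(op$epsilon_t, op$power / (1060 * 0.1))
  expect_equal(op$torque_hp / op$torque_physical, 0.74571,
               tolerance = 1e-4)
  expect_true(op$shear$safe)
  tab <- operating_point_table(op, operating_point(whey$lab,
                                                   correlation = whey_corr))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$power_W[1], op$power)
})

test_that("industrial Reynolds number is exposed at both speeds", {
  ind <- whey$industrial
  expect_equal(operating_point(ind, correlation = whey_corr)$reynolds / 1e6,
               2.553, tolerance = 1e-3)
  op_scaled <- operating_point(ind, speed = 0.295, correlation = whey_corr)
  expect_equal(op_scaled$reynolds / 1e5, 2.26, tolerance = 1e-2)
  expect_identical(op_scaled$regime, "turbulent")
})
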