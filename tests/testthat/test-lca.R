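demo_factors <- impact_factor_table(c(
  AP = 1e-3, EP = 5e-4, FAETP = 2e-2, GWP = 0.3, HTP = 3e-2,
  ODP = 1e-8, POCP = 1e-4, TETP = 1e-3))

test_that("factor tables require all eight CML categories, non-negative", {
  expect_length(cml_categories(), 8)
  expect_error(impact_factor_table(c(GWP = 0.3)), "missing impact")
  bad <- setNames(rep(0.1, 8), cml_categories())
  bad["GWP"] <- -1
  expect_error(impact_factor_table(bad), "non-negative")
})

test_that("energy per functional unit is power x hours over substrate", {
  expect_equal(energy_per_functional_unit(862.54, 20, 207), 83.34,
               tolerance = 1e-3)
  expect_equal(energy_per_functional_unit(7, 11, 77), 1)
  expect_equal(energy_per_functional_unit(100, 10, 500), 2)
})

test_that("characterization is exactly linear in energy", {
  zero <- characterize_impacts(0, demo_factors)
  expect_true(all(zero$impact == 0))
  ten <- characterize_impacts(10, demo_factors)
  expect_equal(ten$impact[ten$category == "GWP"], 3.0)
  twenty <- characterize_impacts(20, demo_factors)
  expect_equal(twenty$impact, 2 * ten$impact)
  expect_equal(ten$impact, 10 * ten$factor)
})

test_that("turbine comparison ranks by energy identically in every category", {
  dm <- build_design_matrix(whey$industrial)
  cand <- filter_by_pv_window(dm[dm$count == 2, ])
  cand$label <- sprintf("%s@%drpm", cand$type, cand$rpm)
  cmp <- compare_turbines(cand[, c("label", "power_kw")], demo_factors)
  rtb <- cmp$table$energy_kwh_m3[cmp$table$label == "RTB@80rpm"]
  cbt <- cmp$table$energy_kwh_m3[cmp$table$label == "CBT@80rpm"]
  # same speed and diameter: the energy gap is the power-number ratio 5/4.4
  expect_equal(rtb / cbt - 1, 5 / 4.4 - 1, tolerance = 1e-12)
  expect_equal(cmp$pairwise_percent["RTB@80rpm", "CBT@80rpm"], 13.64,
               tolerance = 1e-3)
  for (cat in cml_categories()) {
    expect_identical(order(cmp$table[[cat]]), order(cmp$table$energy_kwh_m3))
  }
  # impact ratios equal energy ratios for any factor table
  set.seed(101)
  rnd <- random_impact_factors()
  cmp2 <- compare_turbines(cand[, c("label", "power_kw")], rnd)
  gwp <- cmp2$table$GWP
  expect_equal(gwp / gwp[1], cmp2$table$energy_kwh_m3 /
                 cmp2$table$energy_kwh_m3[1], tolerance = 1e-12)
  expect_error(compare_turbines(cand[1, c("label", "power_kw")],
                                demo_factors), ">= 2")
})

test_that("equal-energy candidates tie with zero pairwise difference", {
  cand <- data.frame(label = c("a", "b"), power_kw = c(100, 100))
  cmp <- compare_turbines(cand, demo_factors)
  expect_equal(cmp$pairwise_percent["a", "b"], 0)
  expect_equal(cmp$table$rank, c(1L, 1L))
})

test_that("working-height sweep averages over feasible counts", {
  sw <- scenario_sweep(whey$industrial, speed = 80 / 60,
                       Z_grid = c(8.6, 9.1), factors = demo_factors)
  expect_equal(sw$counts, c("2,3", "2,3"))
  expect_equal(sw$avg_pv_total[1], sw$avg_pv_total[2])
  expect_equal(sw$avg_pv_total[1], 3.605, tolerance = 1e-3)
  expect_equal(sw$avg_gwp, 0.3 * sw$avg_energy)
  # single feasible count: the average is that cell
  one <- scenario_sweep(whey$industrial, speed = 80 / 60, Z_grid = 5.5)
  dm <- build_design_matrix(whey$industrial)
  cell2 <- dm[dm$type == "RTB" & dm$rpm == 80 & dm$count == 2, "pv_total"]
  cell3 <- dm[dm$type == "RTB" & dm$rpm == 80 & dm$count == 3, "pv_total"]
  expect_equal(one$counts, "1")
  expect_equal(one$avg_pv_total, cell2 / 2, tolerance = 1e-12)
  expect_equal(sw$avg_pv_total[1], mean(c(cell2, cell3)), tolerance = 1e-12)
})

test_that("sweep is piecewise constant in Z, jumping with the count set", {
  sw <- scenario_sweep(whey$industrial, speed = 80 / 60,
                       Z_grid = seq(5, 10, by = 0.5))
  expect_true(all(sw$feasible))
  for (i in 2:nrow(sw)) {
    if (sw$counts[i] == sw$counts[i - 1]) {
      expect_equal(sw$avg_pv_total[i], sw$avg_pv_total[i - 1])
    } else {
      expect_false(sw$avg_pv_total[i] == sw$avg_pv_total[i - 1])
    }
  }
})

test_that("raising H/T slims the tank and lowers power and impacts", {
  sw <- scenario_sweep(whey$industrial, speed = 80 / 60, Z_grid = 8.6,
                       HT_grid = c(2.5, 3, 3.5), factors = demo_factors)
  expect_true(all(diff(sw$tank_diameter) < 0))
  expect_true(all(diff(sw$impeller_diameter) < 0))
  # per-stage power strictly decreases with H/T; the pooled value can only
  # jump where the feasible count set changes
  same_counts <- sw$counts[-1] == sw$counts[-nrow(sw)]
  expect_true(all(diff(sw$avg_pv_total)[same_counts] < 0))
  expect_true(all(diff(sw$avg_gwp)[same_counts] < 0))
})

test_that("infeasible sweep points are recorded as gaps, not failures", {
  sw <- scenario_sweep(whey$industrial, speed = 80 / 60,
                       Z_grid = c(2.1, 8.6))
  expect_false(sw$feasible[1])
  expect_true(is.na(sw$avg_pv_total[1]))
  expect_true(sw$feasible[2])
})
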