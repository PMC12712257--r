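test_that("effective diameter reproduces the published examples", {
  expect_equal(round(effective_diameter(7.0, 5.0), 1), 4.9)
  expect_equal(round(effective_diameter(8.0, 6.0), 1), 5.3)
  expect_equal(round(effective_diameter(9.0, 3.8), 1), 8.2)
  expect_identical(effective_diameter(7.5), 7.5)
})

test_that("effective diameter rejects impossible geometries", {
  expect_error(effective_diameter(6.0, 5.9), NA)  # thin but open lumen
  expect_error(effective_diameter(6.0, 6.0), "lumen")
  expect_error(effective_diameter(5.0, 5.9), "lumen")
  expect_error(effective_diameter(-7, 5), "positive")
  expect_error(effective_diameter(7, 0), "positive")
  expect_error(tube_geometry(d_eff = 5, d_tube = 7), "not both")
  expect_error(tube_geometry(), "required")
})

test_that("the published tube-scope table follows the area formula", {
  tab <- ett_scope_combinations()
  expect_equal(nrow(tab), 18L)
  expect_true(all(tab$d_eff <= tab$d_tube))
  # small and large scope columns agree with the quoted shaft diameters
  sl <- tab[tab$scope_size != "medium", ]
  expect_true(all(abs(sl$d_eff - sl$d_eff_printed) < 0.05))
  # the printed medium column sits up to 0.15 mm above sqrt(d^2 - 5.0^2);
  # it matches a 4.9 mm shaft instead
  med <- tab[tab$scope_size == "medium", ]
  expect_true(all(abs(med$d_eff - med$d_eff_printed) < 0.15))
  expect_true(all(abs(sqrt(med$d_tube^2 - 4.9^2) - med$d_eff_printed) < 0.05))
})

test_that("the Rohrer pressure drop matches its closed form and examples", {
  m <- rohrer_model(k1 = 0.72, k2_insp = 2.88)
  expect_identical(rohrer_dp(m, 0), 0)
  expect_equal(rohrer_dp(m, 1), 3.6)
  expect_equal(rohrer_dp(m, -1), -3.6)
  # separate expiratory coefficient engages only for negative flow
  ma <- rohrer_model(k1 = 1, k2_insp = 2, k2_exp = 5)
  expect_equal(rohrer_dp(ma, 2), 1 * 2 + 2 * 4)
  expect_equal(rohrer_dp(ma, -2), -(1 * 2 + 5 * 4))
})

test_that("the pressure-flow relation is strictly increasing and odd iff symmetric", {
  withr::with_seed(11, {
    for (i in 1:20) {
      m <- random_rohrer()
      f <- seq(-3, 3, by = 0.05)
      expect_true(all(diff(rohrer_dp(m, f)) > 0))
    }
  })
  ms <- rohrer_model(2, 3, 3)
  f <- seq(0.1, 3, by = 0.1)
  expect_equal(rohrer_dp(ms, -f), -rohrer_dp(ms, f))
  masym <- rohrer_model(2, 3, 4)
  expect_false(isTRUE(all.equal(rohrer_dp(masym, -1), -rohrer_dp(masym, 1))))
})

test_that("the scaling law yields the reference resistance and regimes", {
  geom <- tube_geometry(d_eff = 10, has_scope = FALSE)
  m <- scaling_law_model(geom)
  expect_equal(secant_resistance(m, 1), 3.6)
  expect_equal(m$k2_insp, 4 * m$k1)
  # with scope at half the reference diameter: 3.6 * 0.5^-5 = 115.2
  m5 <- scaling_law_model(tube_geometry(d_eff = 5, has_scope = TRUE))
  expect_equal(secant_resistance(m5, 1), 115.2)
  # both exponents coincide at the reference diameter
  m_ref_scope <- scaling_law_model(tube_geometry(d_eff = 10, has_scope = TRUE))
  expect_equal(m_ref_scope$k1, m$k1)
  # halving d_eff multiplies the 1 L/s resistance by 2^5 (scope) / 2^3.6
  r8s <- secant_resistance(tube_at(8), 1)
  r4s <- secant_resistance(tube_at(4), 1)
  expect_equal(r4s / r8s, 2^5)
  r8u <- secant_resistance(tube_at(8, has_scope = FALSE), 1)
  r4u <- secant_resistance(tube_at(4, has_scope = FALSE), 1)
  expect_equal(r4u / r8u, 2^3.6)
  # explicit override beats the has_scope default
  mo <- scaling_law_model(tube_geometry(d_eff = 5), beta = -3.6)
  expect_equal(mo$k1, 0.72 * 0.5^-3.6)
})

test_that("secant resistance follows its definition", {
  m <- rohrer_model(0.72, 2.88)
  expect_equal(secant_resistance(m, 1), 3.6)
  expect_equal(secant_resistance(m, -1), 3.6)
  lin <- rohrer_model(2, 0)
  expect_equal(secant_resistance(lin, 0.3), 2)
  expect_equal(secant_resistance(lin, 2.7), 2)
  expect_error(secant_resistance(m, 0), "zero flow")
})

test_that("driving-pressure inversion is exact and matches bisection", {
  m <- rohrer_model(0.72, 2.88)
  expect_identical(flow_from_driving_pressure(m, 0, 0), 0)
  expect_equal(flow_from_driving_pressure(m, 0, 3.6), 1)
  # linear tube
  expect_equal(flow_from_driving_pressure(rohrer_model(2, 0), 1, 6), 2)
  withr::with_seed(17, {
    for (i in 1:40) {
      mm <- random_rohrer()
      r <- runif(1, 0, 10)
      f <- runif(1, -3, 3)
      dp <- rohrer_dp(mm, f) + r * f
      # round trip through the forward map
      expect_equal(flow_from_driving_pressure(mm, r, dp), f, tolerance = 1e-9)
      # agreement with the independent bisection oracle
      dp2 <- runif(1, -60, 60)
      expect_equal(flow_from_driving_pressure(mm, r, dp2),
                   bisect_flow(mm, r, dp2), tolerance = 1e-9)
    }
  })
})

test_that("model constructors validate their invariants", {
  expect_error(rohrer_model(-1, 2), "non-negative")
  expect_error(rohrer_model(1, 2, v_ref = 0), "v_ref")
  expect_error(scaling_law(k1_ref = 0), "positive")
  expect_error(scaling_law(beta_tube = 1), "negative")
  expect_error(flow_from_driving_pressure(rohrer_model(1, 1), -1, 2),
               "non-negative")
})
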