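p0 <- colony_params()

test_that("Monod fraction: half-saturation, zero, monotonicity, bounds", {
  expect_equal(monod(1, 1), 0.5)
  expect_equal(monod(0, 2), 0)
  expect_equal(monod(3, 1), 0.75)
  C <- seq(0, 50, by = 0.5)
  th <- monod(C, 0.7)
  expect_true(all(th >= 0 & th < 1))
  expect_true(all(diff(th) > 0))
  expect_error(monod(-1, 1), "concentration")
  expect_error(monod(1, 0), "Monod constant")
})

test_that("maintenance threshold solves uptake = maintenance", {
  expect_equal(maintenance_threshold(5, 0, 2), 0)
  # by hand: q_max * C / (C + K) = m with q_max = 2 m gives C = K
  expect_equal(maintenance_threshold(2 * 0.3, 0.3, 1.7), 1.7)
  # monotone divergence as m approaches capacity
  q <- 1
  ms <- q * (1 - 10^-(1:6))
  cs <- vapply(ms, maintenance_threshold, numeric(1), q_max = q, K = 1)
  expect_true(all(diff(cs) > 0))
  expect_gt(cs[6], 1e5)
  expect_error(maintenance_threshold(1, 1, 1), "unreachable")
})

test_that("shifted Monod: zero below threshold, continuity, reductions", {
  lam <- 0.9; K <- 0.4; Cs <- 0.05
  expect_equal(shifted_monod_rate(lam, Cs, K, Cs), 0)
  expect_equal(shifted_monod_rate(lam, Cs / 2, K, Cs), 0)
  # C = C* + K gives half-maximal growth
  expect_equal(shifted_monod_rate(lam, Cs + K, K, Cs), lam / 2)
  # C* = 0 reduces to plain Monod
  C <- c(0, 0.1, 1, 10)
  expect_equal(shifted_monod_rate(lam, C, K, 0), lam * monod(C, K))
  # continuity at the threshold
  lo <- shifted_monod_rate(lam, Cs - 1e-9, K, Cs)
  hi <- shifted_monod_rate(lam, Cs + 1e-9, K, Cs)
  expect_lt(abs(hi - lo), 1e-8)
})

test_that("three-mode growth law recovers its aerobic/anaerobic/acetate limits", {
  sat <- 1e7
  g_aer <- local_growth_rate(sat * p0$K_g, sat * p0$K_o, 0, p0)
  expect_equal(g_aer$lambda_total, p0$lambda_g_aer, tolerance = 1e-3)
  g_ana <- local_growth_rate(sat * p0$K_g, 0, 0, p0)
  expect_equal(g_ana$lambda_total, p0$lambda_g_ana, tolerance = 1e-3)
  g_ace <- local_growth_rate(0, sat * p0$K_o, sat * p0$K_a, p0)
  expect_equal(g_ace$lambda_total, p0$lambda_a_aer, tolerance = 1e-3)
})

test_that("growth components are bounded and glucose suppresses acetate growth", {
  set.seed(42)
  Cg <- runif(300, 0, 30); Co <- runif(300, 0, 0.25); Ca <- runif(300, 0, 20)
  g <- local_growth_rate(Cg, Co, Ca, p0)
  lam_max <- max(p0$lambda_g_aer, p0$lambda_g_ana, p0$lambda_a_aer)
  expect_true(all(g$lambda_total >= 0 & g$lambda_total <= lam_max + 1e-12))
  expect_true(all(g$theta_g >= 0 & g$theta_g <= 1))
  expect_true(all(g$lambda1 >= 0 & g$lambda2 >= 0 & g$lambda3 >= 0))
  # hierarchy: saturating glucose shuts off the acetate contribution
  g_sat <- local_growth_rate(1e7 * p0$K_g, 0.25, 100, p0)
  acetate_part <- g_sat$lambda3 * (1 - g_sat$theta_g) * g_sat$theta_o
  expect_lt(acetate_part, 1e-5)
})

test_that("maintenance allocation: starvation flag and glucose-first priority", {
  # nothing available: starving, no uptake
  m0 <- maintenance_allocation(0, 0, 0, p0)
  expect_true(m0$starving)
  expect_equal(m0$Q_g_maint + m0$Q_a_maint + m0$Q_o_maint + m0$P_a_maint, 0)
  # saturating glucose: maintenance fully covered by glucose
  m1 <- maintenance_allocation(1e7 * p0$K_g, 0.25, 0, p0)
  expect_false(m1$starving)
  expect_equal(6 * m1$Q_g_maint, p0$m_carbon)
  expect_equal(m1$Q_a_maint, 0)
  # acetate at its maintenance threshold with abundant oxygen, no glucose:
  # achievable carbon just covers maintenance, all of it from acetate
  C_star_a <- maintenance_threshold(p0$q_a_aer * p0$lambda_a_aer,
                                    p0$m_carbon / 2, p0$K_a)
  m2 <- maintenance_allocation(0, 1e9 * p0$K_o, C_star_a, p0)
  expect_equal(m2$carbon_flux, p0$m_carbon, tolerance = 1e-6)
  expect_equal(2 * m2$Q_a_maint, p0$m_carbon, tolerance = 1e-6)
  m3 <- maintenance_allocation(0, 1e9 * p0$K_o, C_star_a * 1.01, p0)
  expect_false(m3$starving)
  # anaerobic maintenance glucose is fermented to acetate
  m4 <- maintenance_allocation(1e7 * p0$K_g, 0, 0, p0)
  expect_equal(m4$P_a_maint,
               p0$acetate_per_glucose_maint * m4$Q_g_maint, tolerance = 1e-6)
  expect_true(m4$anaerobic)
})

test_that("source terms follow the displayed uptake/excretion equations", {
  sat <- 1e7
  # anoxic, glucose-replete: oxygen terms vanish, fermentation acetate flows
  g <- local_growth_rate(sat * p0$K_g, 0, 0, p0)
  mn <- maintenance_allocation(sat * p0$K_g, 0, 0, p0)
  s <- source_terms(g, mn, p0)
  expect_equal(s$Q_o, 0)
  expect_equal(s$Q_g, p0$q_g_ana * g$lambda2 + mn$Q_g_maint)
  expect_equal(s$P_a, p0$p_a_ana * g$lambda2 + mn$P_a_maint)
  expect_true(all(s$P_g == 0) && all(s$P_o == 0))
  # fully aerobic growth still excretes overflow acetate
  g2 <- local_growth_rate(sat * p0$K_g, sat * p0$K_o, 0, p0)
  mn2 <- maintenance_allocation(sat * p0$K_g, sat * p0$K_o, 0, p0)
  s2 <- source_terms(g2, mn2, p0)
  expect_gt(s2$P_a, 0)
  # no growth, no maintenance: all terms vanish
  g3 <- local_growth_rate(0, 0, 0, p0)
  mn3 <- maintenance_allocation(0, 0, 0, p0)
  s3 <- source_terms(g3, mn3, p0)
  expect_equal(s3$Q_g + s3$Q_o + s3$Q_a + s3$P_a, 0)
})

test_that("acetate excretion never exceeds twice the glucose uptake", {
  set.seed(7)
  Cg <- runif(500, 0, 30); Co <- runif(500, 0, 0.25); Ca <- runif(500, 0, 40)
  g <- local_growth_rate(Cg, Co, Ca, p0)
  mn <- maintenance_allocation(Cg, Co, Ca, p0)
  s <- source_terms(g, mn, p0)
  expect_true(all(s$P_a <= 2 * s$Q_g + 1e-12))
})

test_that("stoichiometric acetate bound is twice the initial glucose", {
  expect_identical(acetate_yield_bound(20), 40)
  expect_identical(acetate_yield_bound(0), 0)
  expect_identical(acetate_yield_bound(10), 20)
})
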