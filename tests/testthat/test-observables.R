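test_that("cross-sectional profile of simple configurations", {
  # one horizontal cell at the origin: a single bin of radius L/2 + r0
  one <- new_cell_table(x = 0, z = 0.5, angle = 0, length = 4)
  prof <- profile_from_cells(one, dz = 5, r0 = 0.5)
  expect_identical(nrow(prof), 1L)
  expect_equal(prof$r, 2.5)
  # reflection symmetry
  set.seed(4)
  cells <- new_cell_table(x = rnorm(20, 0, 10), z = runif(20, 0.5, 8),
                          angle = runif(20, -1, 1), length = 3)
  mirrored <- cells; mirrored$x <- -mirrored$x; mirrored$angle <- -mirrored$angle
  expect_equal(profile_from_cells(cells, 2)$r, profile_from_cells(mirrored, 2)$r)
  # two stacked cells occupy two bins
  two <- new_cell_table(x = c(0, 0), z = c(0.5, 1.5), angle = 0, length = 3)
  expect_identical(nrow(profile_from_cells(two, dz = 1)), 2L)
  expect_error(profile_from_cells(new_cell_table(x = numeric(0))), "no cells")
})

test_that("radius and height definitions from the profile", {
  rect <- structure(data.frame(z = seq(0, 35, by = 5), r = 100), dz = 5,
                    class = c("cross_section_profile", "data.frame"))
  expect_equal(radius_height(rect), c(radius = 100, height = 40))
  dome <- structure(data.frame(z = seq(0, 20, 5), r = c(50, 40, 30, 20, 10)),
                    dz = 5, class = c("cross_section_profile", "data.frame"))
  rh <- radius_height(dome)
  expect_equal(rh[["radius"]], 50)     # attained at the bottom
  expect_equal(rh[["height"]], 25)
  single <- structure(data.frame(z = 0, r = 7), dz = 5,
                      class = c("cross_section_profile", "data.frame"))
  expect_equal(radius_height(single)[["height"]], 5)
})

test_that("disk-stack volume: single disk, cylinder, cone, scaling", {
  mk <- function(z, r, dz) structure(data.frame(z = z, r = r), dz = dz,
                                     class = c("cross_section_profile",
                                               "data.frame"))
  expect_equal(volume_from_profile(mk(0, 10, 5)), 500 * pi)
  expect_equal(volume_from_profile(mk(seq(0, 15, 5), 10, 5)), 2000 * pi)
  cone <- mk(0:4, c(10, 8, 6, 4, 2), 1)
  expect_equal(volume_from_profile(cone), 220 * pi)
  # scales as r^2 and is reflection-invariant
  expect_equal(volume_from_profile(mk(0:4, 2 * c(10, 8, 6, 4, 2), 1)),
               4 * 220 * pi)
})

test_that("monolayer width on constructed colonies", {
  # entirely one cell thick: half the footprint per side
  mono <- generate_fixtures("monolayer-colony", params = list(width = 100))
  w <- monolayer_width(mono$data)
  expect_equal(as.numeric(w), mono$truth$monolayer_width, tolerance = 0.1)
  # 3-deep block with a single-layer skirt of 25 um
  blk <- generate_fixtures("stacked-block",
                           params = list(inner = 40, outer = 65))
  wb <- monolayer_width(blk$data)
  expect_equal(as.numeric(wb), 25, tolerance = 2.1)
  # adding interior multi-layer cells away from the skirt leaves it unchanged
  extra <- new_cell_table(x = rep(c(-10, 0, 10), each = 2),
                          z = rep(c(4.5, 5.5), 3), angle = 0, length = 3,
                          id = 900 + 1:6)
  aug <- rbind(blk$data, extra)
  class(aug) <- c("cell_table", "data.frame")
  expect_equal(as.numeric(monolayer_width(aug)), as.numeric(wb))
})

test_that("intensity-trace monolayer width finds the sharp rise", {
  pos <- seq(0, 60, by = 1)
  trace <- ifelse(pos < 20, 1.0, 3.0)
  expect_equal(monolayer_width_intensity(pos, trace, 1.5), 20)
  expect_true(is.na(monolayer_width_intensity(pos, rep(1, 61))))
})

test_that("flux partitioning integrates biomass-weighted shares", {
  # anoxia everywhere: all glucose flux is anaerobic
  p <- colony_params(domain_width = 40, agar_depth = 20, air_height = 10,
                     grid_h = 5)
  grid <- make_grid(p)
  cells <- new_cell_table(x = c(-2, 2), z = 0.5, angle = 0, length = 3)
  masks <- build_masks(cells, grid, p)
  fields <- make_fields(grid, p)
  fields$C_o[] <- 0
  fields$C_g[] <- 10
  src <- grid_sources(fields, masks, p)
  fp <- flux_partition(src, masks)
  expect_equal(fp$glucose_anaerobic, 1)
  expect_equal(fp$glucose_aerobic, 0)
  expect_true(is.na(fp$acetate_growth))   # no acetate anywhere
  # hand-built toy: equal aerobic and anaerobic fluxes give 50/50
  toy <- list(idx = c(1L, 2L),
              src = list(Q_g_aer = c(1, 0), Q_g_ana = c(0, 1),
                         Q_a_growth = c(2, 0), Q_a_maint = c(0, 2)))
  toy_masks <- list(rho = matrix(c(3, 3), 1, 2))
  fp2 <- flux_partition(toy, toy_masks)
  expect_equal(fp2$glucose_aerobic, 0.5)
  expect_equal(fp2$acetate_growth + fp2$acetate_maintenance, 1)
})

test_that("growing fraction uses a strict threshold", {
  cells <- new_cell_table(x = 1:3, z = 1)
  cells$lambda_inst <- c(0.005, 0.02, 0.5)
  expect_equal(growing_fraction(cells, 0.01), 2 / 3)
  cells$lambda_inst <- rep(0, 3)
  expect_equal(growing_fraction(cells, 0.01), 0)
  cells$lambda_inst <- rep(1, 3)
  expect_equal(growing_fraction(cells, 0.01), 1)
  cells$lambda_inst <- rep(0.01, 3)   # boundary: not strictly greater
  expect_equal(growing_fraction(cells, 0.01), 0)
  # growing + non-growing partitions the population exactly
  cells$lambda_inst <- runif(3)
  gf <- growing_fraction(cells, 0.01)
  expect_equal(gf + mean(cells$lambda_inst <= 0.01), 1)
})

test_that("expansion kinetics: linear fit, slowdown flag, degenerate cases", {
  t <- seq(0, 10, by = 1)
  lin <- data.frame(time = t, radius = 5 + 3.2 * t,
                    height = 30 * (1 - exp(-t / 4)))
  ek <- expansion_kinetics(lin)
  expect_equal(ek$radial_speed, 3.2, tolerance = 1e-12)
  expect_equal(ek$r_squared, 1)
  expect_true(ek$vertical_slowdown)
  flat <- data.frame(time = t, radius = 50, height = t^2)
  ek2 <- expansion_kinetics(flat)
  expect_equal(ek2$radial_speed, 0)
  expect_false(ek2$vertical_slowdown)   # accelerating height
  expect_error(expansion_kinetics(lin[1:3, ]), "4 samples")
})

test_that("dome fixture volume equals its closed-form disk sum", {
  fx <- generate_fixtures("dome-profile", params = list(R = 80, H = 30, dz = 5))
  expect_equal(volume_from_profile(fx$data), fx$truth$volume)
  expect_equal(radius_height(fx$data)[["radius"]], 80)
  expect_error(generate_fixtures("no-such-kind"), "unknown fixture")
})
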