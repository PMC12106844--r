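p0 <- colony_params()

seg_gap <- function(cells, i, j, r0 = p0$r0) {
  # centre distance minus diameter for two parallel horizontal rods
  sqrt((cells$x[i] - cells$x[j])^2 + (cells$z[i] - cells$z[j])^2) - 2 * r0
}

test_that("elongation follows the exponential law and zero rate is inert", {
  cells <- new_cell_table(length = 1.5)
  out <- elongate_and_divide(cells, 0, 1, p0)
  expect_equal(out$length, 1.5)
  # biomass (spherocylinder extent) exactly doubles over one doubling time
  short <- new_cell_table(length = 1)
  out2 <- elongate_and_divide(short, log(2), 1, p0)
  expect_equal(out2$length + 2 * p0$r0, 2 * (1 + 2 * p0$r0))
  expect_identical(nrow(out2), 1L)
  expect_error(elongate_and_divide(cells, -1, 1, p0), ">= 0")
  expect_error(elongate_and_divide(cells, 1, 0, p0), "dt")
})

test_that("division conserves rod material and assigns lineage", {
  set.seed(11)
  cells <- new_cell_table(length = 3.95, angle = 0.3)
  parent_len <- (3.95 + 2 * p0$r0) * exp(log(2) * 0.5) - 2 * p0$r0
  out <- elongate_and_divide(cells, log(2), 0.5, p0)
  expect_identical(nrow(out), 2L)
  # two fresh caps are inserted at the split: lengths sum to parent - 2 r0
  expect_equal(sum(out$length) + 2 * p0$r0, parent_len)
  expect_true(all(out$lineage == 1L))
  expect_true(all(out$id > 1L))
  # daughters sit end-to-end along the parent axis
  expect_equal(mean(out$x), 0, tolerance = 1e-9)
  # daughters inherit the angle up to a small opposite-signed kick
  expect_true(all(abs(out$angle - 0.3) <= p0$kick_angle + 1e-12))
  expect_equal(sum(out$angle - 0.3), 0, tolerance = 1e-12)
})

test_that("separated rods feel no pairwise force; overlapping rods obey Newton", {
  cells <- new_cell_table(x = c(0, 0), z = c(5, 5 + 2 * p0$r0 + 0.5),
                          angle = c(0, 0), length = c(3, 3))
  f <- compute_forces(cells, p0)
  expect_equal(f$fx_cc, c(0, 0))
  expect_equal(f$fz_cc, c(0, 0))

  over <- new_cell_table(x = c(0, 0.4), z = c(5, 5 + 2 * p0$r0 - 0.3),
                         angle = c(0, 0), length = c(3, 3))
  fo <- compute_forces(over, p0)
  expect_gt(abs(fo$fz_cc[1]), 0)
  expect_equal(fo$fz_cc[1], -fo$fz_cc[2])
  expect_equal(fo$fx_cc[1], -fo$fx_cc[2])
})

test_that("pairwise forces sum to zero over a random crowded population", {
  set.seed(3)
  n <- 60
  cells <- new_cell_table(x = runif(n, -15, 15), z = runif(n, 0.5, 6),
                          angle = runif(n, -pi / 2, pi / 2),
                          length = runif(n, 2, 4))
  f <- compute_forces(cells, p0)
  scale <- max(abs(f$fz_cc), 1)
  expect_lt(abs(sum(f$fx_cc)) / scale, 1e-10)
  expect_lt(abs(sum(f$fz_cc)) / scale, 1e-10)
})

test_that("agar contact force is monotone in the penetration depth", {
  f_at <- function(depth) {
    cells <- new_cell_table(x = 0, z = p0$r0 - depth, angle = 0, length = 3)
    compute_forces(cells, p0)$fz_ext[1]
  }
  f1 <- f_at(0.05); f2 <- f_at(0.1); f3 <- f_at(0.2)
  expect_gt(f1, 0)
  expect_gt(f2, f1)
  expect_gt(f3, f2)
  # Hertz 3/2 power law after removing the constant settling force
  settle <- p0$f_settle * (3 + 2 * p0$r0)
  expect_equal((f3 + settle) / (f2 + settle), 2^1.5, tolerance = 1e-6)
})

test_that("overdamped step: zero force is inert, displacement matches closed form", {
  cells <- new_cell_table(x = 0, z = 5, angle = 0, length = 3)
  f <- compute_forces(cells, p0)
  f$fz_ext <- 0  # cancel settling for the closed-form check
  moved <- step_mechanics(cells, f, 1e-4, p0)
  expect_equal(moved$x, cells$x)
  expect_equal(moved$z, cells$z)
  f$fx_ext <- 7
  moved2 <- step_mechanics(cells, f, 1e-4, p0)
  L <- 3 + 2 * p0$r0
  expect_equal(moved2$x - cells$x, 7 * 1e-4 / (p0$drag * L))
})

test_that("step_mechanics refuses steps above the stability bound", {
  over <- new_cell_table(x = c(0, 0), z = c(2, 2 + 2 * p0$r0 - 0.4),
                         angle = c(0, 0), length = c(3, 3))
  f <- compute_forces(over, p0)
  expect_error(step_mechanics(over, f, 1, p0), "stability bound")
})

test_that("an overlapping pair relaxes monotonically until contact is lost", {
  cells <- new_cell_table(x = c(0, 0), z = c(5, 5 + 2 * p0$r0 - 0.3),
                          angle = c(0, 0), length = c(3, 3))
  p <- colony_params(f_settle = 0, surface_tension = 0)
  gaps <- numeric(20)
  for (k in seq_len(20)) {
    cells <- relax_cells(cells, p, 1e-3)
    gaps[k] <- seg_gap(cells, 1, 2)
  }
  # overlap decays monotonically (Hertz contacts have a power-law tail, so
  # "contact lost" is approached, not crossed, in finite time)
  expect_true(all(diff(gaps) > -1e-12))
  expect_gt(gaps[20], -0.05)
  expect_gt(gaps[20], gaps[1] * 0.2)
})

test_that("cells settle onto the agar without deep penetration", {
  set.seed(5)
  n <- 40
  cells <- new_cell_table(x = runif(n, -20, 20), z = runif(n, 0.5, 4),
                          angle = runif(n, -0.3, 0.3), length = 3)
  cells <- relax_cells(cells, p0, 0.2)
  zmin <- cells$z - (cells$length / 2) * abs(sin(cells$angle))
  expect_true(all(zmin > -0.25 * p0$r0))  # contact-model tolerance
})

test_that("orientation classification uses a strict vertical cutoff", {
  expect_identical(classify_orientation(0), "horizontal")
  expect_identical(classify_orientation(pi / 2), "vertical")
  expect_identical(classify_orientation(pi / 4, pi / 4), "horizontal")
  expect_identical(classify_orientation(c(-1.2, 0.2)),
                   c("vertical", "horizontal"))
})

test_that("cell tables round-trip through CSV", {
  set.seed(9)
  cells <- new_cell_table(x = rnorm(5), z = runif(5, 0.5, 3),
                          angle = runif(5, -1, 1), length = runif(5, 2, 4))
  cells$p_death <- runif(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cells_csv(cells, f)
  back <- read_cells_csv(f)
  expect_equal(back$x, cells$x, tolerance = 1e-5)
  expect_equal(back$p_death, cells$p_death, tolerance = 1e-5)
  expect_identical(back$id, cells$id)
})
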