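p0 <- colony_params()

test_that("empty domain: no colony mask, agar-air surface spans the width", {
  grid <- make_grid(colony_params(domain_width = 60, agar_depth = 30,
                                  air_height = 15, grid_h = 5))
  masks <- build_masks(new_cell_table(x = numeric(0)), grid,
                       colony_params())
  expect_true(all(masks$region != 1L))
  faces <- interface_faces(masks)
  expect_identical(sum(faces$type == "g12"), 0L)
  expect_identical(sum(faces$type == "g02"), grid$nx)
  expect_true(all(masks$rho == 0))
})

test_that("one cell on the agar rasterises to a colony cell with interface below", {
  p <- colony_params(domain_width = 25, agar_depth = 10, air_height = 10,
                     grid_h = 5, closing_radius = 0)
  grid <- make_grid(p)
  cells <- new_cell_table(x = 0, z = 0.5, angle = 0, length = 3)
  masks <- build_masks(cells, grid, p)
  # the cell centre (x = 0, z = 0.5) lies in grid cell (3, 3) of the 5x4 grid
  expect_identical(masks$region[3, 3], 1L)
  expect_true(masks$rho[3, 3] > 0)
  faces <- interface_faces(masks)
  g12 <- faces[faces$type == "g12", ]
  expect_true(nrow(g12) >= 1)
  expect_true(any(g12$ix == 3 & g12$iz == 2))  # directly beneath the cell
})

test_that("a dense block of cells gives a hole-free rectangular mask", {
  p <- colony_params(domain_width = 60, agar_depth = 20, air_height = 20,
                     grid_h = 5)
  grid <- make_grid(p)
  xs <- rep(seq(-15, 15, by = 3), times = 4)
  zs <- rep(c(0.5, 1.5, 2.5, 3.5) * 2, each = 11)
  cells <- new_cell_table(x = xs, z = zs, angle = 0, length = 2.5)
  masks <- build_masks(cells, grid, p)
  block <- masks$region[grid$x > -16 & grid$x < 16, grid$z > 0 & grid$z < 8]
  expect_true(all(block == 1L))
})

test_that("uniform field with zero sources is a diffusion steady state", {
  nx <- 12; nz <- 9
  C0 <- matrix(3.7, nx, nz)
  act <- matrix(TRUE, nx, nz)
  D <- matrix(2e5, nx, nz)
  C1 <- solve_rd_grid(C0, act, D, h = 5, dt = 0.5)
  expect_equal(C1, C0, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("closed no-flux domain conserves mass to 1e-10", {
  set.seed(21)
  nx <- 25; nz <- 18
  C0 <- matrix(runif(nx * nz, 0, 8), nx, nz)
  act <- matrix(TRUE, nx, nz)
  D <- matrix(1e6, nx, nz)
  C <- C0
  for (k in 1:5) C <- solve_rd_grid(C, act, D, h = 4, dt = 0.05)
  expect_lt(abs(sum(C) - sum(C0)) / sum(C0), 1e-10)
  expect_true(all(C >= 0))
})

test_that("1D steady profile with constant uptake matches the parabolic closed form", {
  D <- 500 * 3600; L <- 50; h <- 1; C_bottom <- 10; rhoQ <- 1000
  nzc <- L / h
  C0 <- matrix(C_bottom, 1, nzc + 1)
  act <- matrix(c(FALSE, rep(TRUE, nzc)), 1, nzc + 1)
  dir <- matrix(c(TRUE, rep(FALSE, nzc)), 1, nzc + 1)
  Dm <- matrix(D, 1, nzc + 1)
  sol <- solve_rd_grid(C0, act, Dm, h, Inf,
                       source = matrix(-rhoQ, 1, nzc + 1),
                       dirichlet = dir, dirichlet_value = C_bottom)
  z <- (seq_len(nzc) - 0.5) * h
  exact <- C_bottom - (rhoQ / D) * (L * z - z^2 / 2)
  expect_lt(max(abs(sol[1, -1] - exact) / exact), 0.01)
})

test_that("halving the grid spacing shrinks the discretisation error", {
  run_col <- function(h) {
    D <- 500 * 3600; L <- 48; C_bottom <- 10; rhoQ <- 2000
    nzc <- as.integer(L / h)
    C0 <- matrix(C_bottom, 1, nzc + 1)
    act <- matrix(c(FALSE, rep(TRUE, nzc)), 1, nzc + 1)
    dir <- matrix(c(TRUE, rep(FALSE, nzc)), 1, nzc + 1)
    sol <- solve_rd_grid(C0, act, matrix(D, 1, nzc + 1), h, Inf,
                         source = matrix(-rhoQ, 1, nzc + 1),
                         dirichlet = dir, dirichlet_value = C_bottom)
    z <- (seq_len(nzc) - 0.5) * h
    exact <- C_bottom - (rhoQ / D) * (L * z - z^2 / 2)
    max(abs(sol[1, -1] - exact))
  }
  e_coarse <- run_col(4)
  e_fine <- run_col(2)
  expect_lt(e_fine, e_coarse)
})

test_that("interface continuity: piecewise diffusivity gives the two-slab steady flux", {
  # 1D slab: Dirichlet C = 10 at bottom, C = 0 at top, D jumps mid-column.
  # Steady flux J = (C_bot - C_top) / (L1/D1 + L2/D2); the discrete solution
  # with harmonic-mean faces must reproduce the interface value C_mid.
  D1 <- 1e6; D2 <- 2.5e5; L1 <- 20; L2 <- 20; h <- 1
  n1 <- L1 / h; n2 <- L2 / h; n <- n1 + n2
  act <- matrix(c(FALSE, rep(TRUE, n), FALSE), 1, n + 2)
  dir <- matrix(c(TRUE, rep(FALSE, n), TRUE), 1, n + 2)
  dval <- matrix(0, 1, n + 2); dval[1, 1] <- 10
  D <- matrix(D1, 1, n + 2); D[1, (n1 + 2):(n + 2)] <- D2
  sol <- solve_rd_grid(matrix(5, 1, n + 2), act, D, h, Inf,
                       dirichlet = dir, dirichlet_value = dval)
  J <- (10 - 0) / (L1 / D1 + L2 / D2)
  C_mid_exact <- 10 - J * L1 / D1
  # value at the last cell of slab 1, half a spacing from the interface
  C_near <- sol[1, n1 + 1]
  expect_equal(C_near, C_mid_exact + J * (h / 2) / D1, tolerance = 1e-6)
})

test_that("metabolite step keeps fields nonnegative and feeds back uptake", {
  p <- colony_params(domain_width = 120, agar_depth = 60, air_height = 24,
                     grid_h = 6, C_g_init = 0.05)
  grid <- make_grid(p)
  xs <- seq(-20, 20, by = 4)
  cells <- new_cell_table(x = xs, z = 0.5, angle = 0, length = 3)
  masks <- build_masks(cells, grid, p)
  fields <- make_fields(grid, p)
  total0 <- sum(fields$C_g)
  for (k in 1:5) fields <- metabolite_step(fields, masks, p, dt = 0.1)
  expect_true(all(fields$C_g >= 0))
  expect_true(all(fields$C_o >= 0))
  expect_true(all(fields$C_a >= 0))
  expect_lt(sum(fields$C_g), total0)   # glucose is being consumed
  # oxygen stays at ambient far from the colony
  expect_equal(fields$C_o[1, grid$nz], p$C_o_ambient, tolerance = 1e-6)
})
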