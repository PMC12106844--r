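# Finite-difference reaction-diffusion solver on the cell-centred grid.
#
# Five-point Laplacian with face diffusivities taken as the harmonic mean of
# the two adjacent cells (the standard flux-continuous discretisation for a
# piecewise-constant diffusion coefficient, which enforces C- = C+ and
# D- dC-/dn = D+ dC+/dn across the agar-colony interface). Dirichlet values
# are imposed at faces to designated boundary cells via a ghost value at the
# face midpoint (coefficient 2 D / h^2). Uptake is linearised implicitly as
# kappa * C_new with kappa = rho * Q(C_old) / C_old, which keeps the system an
# M-matrix and guarantees nonnegative concentrations; excretion enters as an
# explicit source.
#
# The discrete operator pattern depends only on the active mask, so the
# assembled triplets and the sparse Cholesky analysis are cached in an
# operator object and reused across subcycles and fixed-point iterations
# within a macro step.

SECONDS_PER_HOUR <- 3600

# Assemble the diffusion operator for one metabolite on the active mask.
rd_operator <- function(active, D, h, dirichlet = NULL, dirichlet_value = 0) {
  nx <- nrow(active); nz <- ncol(active)
  idx <- which(active)
  n <- length(idx)
  eqn <- rep(NA_integer_, nx * nz)
  eqn[idx] <- seq_len(n)
  lin <- seq_len(nx * nz)
  ixv <- ((lin - 1L) %% nx) + 1L
  izv <- ((lin - 1L) %/% nx) + 1L
  xf <- lin[ixv < nx]
  zf <- lin[izv < nz]

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  rhs_dir <- numeric(n)
  add_faces <- function(li, lj) {
    both <- !is.na(eqn[li]) & !is.na(eqn[lj])
    li <- li[both]; lj <- lj[both]
    if (!length(li)) return()
    w <- 2 * D[li] * D[lj] / (D[li] + D[lj]) / h^2
    i <- eqn[li]; j <- eqn[lj]
    ti <<- c(ti, i, j, i, j); tj <<- c(tj, i, j, j, i)
    tv <<- c(tv, w, w, -w, -w)
  }
  add_faces(xf, xf + 1L)
  add_faces(zf, zf + nx)
  if (!is.null(dirichlet)) {
    dval <- if (length(dirichlet_value) == 1L)
      matrix(dirichlet_value, nx, nz) else dirichlet_value
    dir_face <- function(li, lj) { # li active, lj holds the fixed value
      sel <- !is.na(eqn[li]) & dirichlet[lj]
      li <- li[sel]; lj <- lj[sel]
      if (!length(li)) return()
      w <- 2 * D[li] / h^2
      i <- eqn[li]
      ti <<- c(ti, i); tj <<- c(tj, i); tv <<- c(tv, w)
      rhs_dir[i] <<- rhs_dir[i] + w * dval[lj]
    }
    dir_face(xf, xf + 1L); dir_face(xf + 1L, xf)
    dir_face(zf, zf + nx); dir_face(zf + nx, zf)
  }
  # diagonal slots for kappa + 1/dt, appended last so the pattern is stable
  ti <- c(ti, seq_len(n)); tj <- c(tj, seq_len(n))
  structure(list(nx = nx, nz = nz, idx = idx, n = n, ti = ti, tj = tj,
                 lap = tv, rhs_dir = rhs_dir, cache = new.env(parent = emptyenv())),
            class = "rd_operator")
}

# One implicit step (dt finite) or steady solve (dt = Inf) using the cached
# operator. kappa and source are vectors over op$idx (or NULL).
rd_apply <- function(op, C0, dt, kappa = NULL, source = NULL) {
  n <- op$n
  if (!n) return(C0)
  kap <- if (is.null(kappa)) numeric(n) else kappa
  rhs <- op$rhs_dir + (if (is.null(source)) 0 else source)
  diag_x <- kap
  if (is.finite(dt)) {
    diag_x <- diag_x + 1 / dt
    rhs <- rhs + C0[op$idx] / dt
  }
  M <- Matrix::sparseMatrix(i = op$ti, j = op$tj, x = c(op$lap, diag_x),
                            dims = c(n, n))
  Ms <- Matrix::forceSymmetric(M, uplo = "U")
  ch <- op$cache$chol
  ch <- if (is.null(ch)) Matrix::Cholesky(Ms) else Matrix::update(ch, Ms)
  op$cache$chol <- ch
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  out <- C0
  out[op$idx] <- sol
  attr(out, "uptake_vec") <- kap * sol
  out
}

#' Low-level reaction-diffusion solve on a masked grid
#'
#' Advances `dC/dt = div(D grad C) - kappa C + source` on the active cells of
#' a uniform grid by one implicit (backward Euler) step, or directly to steady
#' state. No-flux conditions hold on every face not covered by `dirichlet`.
#'
#' @param C0 matrix of concentrations, mM (values outside `active` ignored).
#' @param active logical matrix: cells on which the equation is solved.
#' @param D matrix of diffusivities, um^2/h.
#' @param h grid spacing, um.
#' @param dt time step in h, or `Inf` for a steady-state solve.
#' @param kappa matrix of linearised uptake coefficients, 1/h (default 0).
#' @param source matrix of explicit volumetric sources, mM/h (default 0).
#' @param dirichlet optional logical matrix of boundary cells that hold a
#'   fixed value; faces between an active cell and a `dirichlet` cell impose it.
#' @param dirichlet_value the fixed value (scalar or matrix), mM.
#' @return matrix like `C0` with updated values on `active`, with attribute
#'   `uptake` (matrix of kappa * C_new, mM/h, the uptake actually applied).
#' @export
solve_rd_grid <- function(C0, active, D, h, dt, kappa = NULL, source = NULL,
                          dirichlet = NULL, dirichlet_value = 0) {
  op <- rd_operator(active, D, h, dirichlet, dirichlet_value)
  out <- rd_apply(op, C0, dt,
                  kappa = if (is.null(kappa)) NULL else kappa[op$idx],
                  source = if (is.null(source)) NULL else source[op$idx])
  upt <- matrix(0, nrow(C0), ncol(C0))
  if (op$n) upt[op$idx] <- attr(out, "uptake_vec")
  attr(out, "uptake_vec") <- NULL
  attr(out, "uptake") <- upt
  out
}

#' Initialise metabolite fields
#'
#' Glucose starts uniform at `C_g_init` in the agar, acetate at `C_a_init`,
#' oxygen at ambient everywhere.
#'
#' @param grid a [make_grid()] grid.
#' @param p a [colony_params()] set.
#' @return object of class `metabolite_fields`: list of matrices `C_g`, `C_o`,
#'   `C_a` (mM) plus the `grid`.
#' @export
make_fields <- function(grid, p) {
  agar <- matrix(rep(grid$z < 0, each = grid$nx), grid$nx, grid$nz)
  C_g <- matrix(0, grid$nx, grid$nz); C_g[agar] <- p$C_g_init
  C_a <- matrix(0, grid$nx, grid$nz); C_a[agar] <- p$C_a_init
  C_o <- matrix(p$C_o_ambient, grid$nx, grid$nz)
  structure(list(C_g = C_g, C_o = C_o, C_a = C_a, grid = grid),
            class = "metabolite_fields")
}

# Give grid cells that newly joined the colony region a concentration equal to
# the mean of their already-active neighbours (fallback value if none).
fill_new_active <- function(C, new_active, old_active, fallback) {
  idx <- which(new_active & !old_active)
  if (!length(idx)) return(C)
  nx <- nrow(C); nz <- ncol(C)
  for (li in idx) {
    ix <- ((li - 1L) %% nx) + 1L; iz <- ((li - 1L) %/% nx) + 1L
    nb <- c(if (ix > 1) li - 1L, if (ix < nx) li + 1L,
            if (iz > 1) li - nx, if (iz < nz) li + nx)
    nb <- nb[old_active[nb]]
    C[li] <- if (length(nb)) mean(C[nb]) else fallback
  }
  C
}

#' Per-grid-cell metabolic source terms
#'
#' Evaluates growth rates, maintenance allocation and uptake/excretion rates
#' on every colony grid cell at the current local concentrations.
#'
#' @param fields a [make_fields()] object.
#' @param masks a [build_masks()] object.
#' @param p a [colony_params()] set.
#' @return list with the `growth_rates`, `maintenance` and `source_terms`
#'   components evaluated on the colony cells (index vector `idx`).
#' @export
grid_sources <- function(fields, masks, p) {
  idx <- which(masks$region == REGION_COLONY)
  if (!length(idx))
    return(list(idx = integer(0)))
  g <- local_growth_rate(fields$C_g[idx], fields$C_o[idx], fields$C_a[idx], p)
  maint <- maintenance_allocation(fields$C_g[idx], fields$C_o[idx],
                                  fields$C_a[idx], p)
  src <- source_terms(g, maint, p)
  list(idx = idx, growth = g, maint = maint, src = src)
}

#' Advance the metabolite fields over one macro step
#'
#' Glucose and acetate obey closed no-flux boundaries and are integrated in
#' time with subcycled implicit steps (uptake linearised, excretion explicit),
#' re-evaluating the metabolic source terms each subcycle. Oxygen, supplied at
#' fixed ambient concentration on every air-facing surface and consumed with
#' fast kinetics, is relaxed to its quasi-steady profile by fixed-point
#' iteration at each call (its transient lasts seconds, far below the macro
#' step).
#'
#' @param fields a `metabolite_fields` object.
#' @param masks a `domain_masks` object on the same grid.
#' @param p a [colony_params()] set.
#' @param dt macro time step, h (default `p$dt_macro`).
#' @param sources optional precomputed [grid_sources()] list for the first
#'   subcycle (recomputed afterwards).
#' @return updated `metabolite_fields`, with attributes `uptake_g`, `uptake_a`
#'   (time-integrated glucose/acetate uptake over the step, mM * h per grid
#'   cell) and `oxygen_iterations`.
#' @export
metabolite_step <- function(fields, masks, p, dt = p$dt_macro, sources = NULL) {
  grid <- fields$grid
  region <- masks$region
  act_ga <- region != REGION_AIR        # glucose/acetate: colony + agar
  air <- region == REGION_AIR
  h <- grid$h
  D_of <- function(agar_val, colony_val) {
    D <- matrix(agar_val, grid$nx, grid$nz)
    D[region == REGION_COLONY] <- colony_val
    D * SECONDS_PER_HOUR
  }
  op_g <- rd_operator(act_ga, D_of(p$D_g_agar, p$D_g_colony), h)
  op_a <- rd_operator(act_ga, D_of(p$D_a_agar, p$D_a_colony), h)
  op_o <- rd_operator(act_ga, D_of(p$D_o_agar, p$D_o_colony), h,
                      dirichlet = air, dirichlet_value = p$C_o_ambient)

  upt_g_total <- matrix(0, grid$nx, grid$nz)
  upt_a_total <- matrix(0, grid$nx, grid$nz)
  n_sub <- max(1L, as.integer(p$n_subcycle))
  dts <- dt / n_sub
  o_iter <- 0L
  eps <- 1e-12
  cidx <- which(region == REGION_COLONY)
  pos_c <- match(cidx, op_g$idx)   # colony cells within the active ordering

  for (s in seq_len(n_sub)) {
    sc <- if (s == 1L && !is.null(sources)) sources
          else grid_sources(fields, masks, p)
    kap_g <- kap_a <- src_a <- numeric(op_g$n)
    if (length(sc$idx)) {
      rho <- masks$rho[sc$idx]
      kap_g[pos_c] <- rho * sc$src$Q_g / pmax(fields$C_g[sc$idx], eps)
      kap_a[pos_c] <- rho * sc$src$Q_a / pmax(fields$C_a[sc$idx], eps)
      src_a[pos_c] <- rho * sc$src$P_a
    }
    Cg <- rd_apply(op_g, fields$C_g, dts, kappa = kap_g)
    upt_g_total[op_g$idx] <- upt_g_total[op_g$idx] +
      attr(Cg, "uptake_vec") * dts
    Ca <- rd_apply(op_a, fields$C_a, dts, kappa = kap_a, source = src_a)
    upt_a_total[op_a$idx] <- upt_a_total[op_a$idx] +
      attr(Ca, "uptake_vec") * dts
    attr(Cg, "uptake_vec") <- NULL; attr(Ca, "uptake_vec") <- NULL
    fields$C_g <- Cg
    fields$C_a <- Ca
  }

  # oxygen: quasi-steady fixed point on the Monod-linearised uptake
  for (it in seq_len(50L)) {
    sc_o <- grid_sources(fields, masks, p)
    kap_o <- numeric(op_o$n)
    if (length(sc_o$idx))
      kap_o[pos_c] <- masks$rho[sc_o$idx] * sc_o$src$Q_o /
        pmax(fields$C_o[sc_o$idx], eps)
    Co <- rd_apply(op_o, fields$C_o, Inf, kappa = kap_o)
    attr(Co, "uptake_vec") <- NULL
    delta <- max(abs(Co - fields$C_o)) / max(p$C_o_ambient, eps)
    fields$C_o <- Co
    o_iter <- o_iter + 1L
    if (delta < p$pde_tol * 100) break
  }
  attr(fields, "uptake_g") <- upt_g_total
  attr(fields, "uptake_a") <- upt_a_total
  attr(fields, "oxygen_iterations") <- o_iter
  fields
}
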