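# Simulation driver: the four-step macro iteration (colony mask -> metabolite
# fields -> local growth rates -> agent growth/division/mechanics), snapshot
# collection and the classed result object.

# Bilinear interpolation of a grid field at arbitrary points, restricted to
# active (colony/agar) cells: inactive corners are dropped from the weights.
sample_field <- function(C, active, grid, x, z, fallback = 0) {
  gx <- (x - grid$x[1]) / grid$h + 1
  gz <- (z - grid$z[1]) / grid$h + 1
  i0 <- pmin(pmax(floor(gx), 1), grid$nx - 1)
  k0 <- pmin(pmax(floor(gz), 1), grid$nz - 1)
  wx <- pmin(pmax(gx - i0, 0), 1)
  wz <- pmin(pmax(gz - k0, 0), 1)
  val <- numeric(length(x)); wtot <- numeric(length(x))
  for (di in 0:1) for (dk in 0:1) {
    ii <- i0 + di; kk <- k0 + dk
    w <- (if (di == 1) wx else 1 - wx) * (if (dk == 1) wz else 1 - wz)
    li <- ii + (kk - 1) * grid$nx
    w <- w * active[li]
    val <- val + w * C[li]
    wtot <- wtot + w
  }
  out <- ifelse(wtot > 0, val / pmax(wtot, 1e-300), fallback)
  out
}

#' Run a colony development simulation
#'
#' Starts from a single horizontal cell at the centre of the agar-air
#' interface and iterates the hybrid model: (1) rasterise cells into a
#' smoothed colony mask, (2) advance the glucose/oxygen/acetate
#' reaction-diffusion fields, (3) evaluate local growth rates and maintenance
#' state at each cell position (bilinear sampling of the fields), (4) grow,
#' divide, accumulate starvation and death probability, and relax the contact
#' mechanics with adaptive substeps. Fully deterministic for a given seed.
#'
#' @param p a validated [colony_params()] set.
#' @param t_end simulated duration, h.
#' @param snapshot_every snapshot cadence, h.
#' @param seed RNG seed (default `p$seed`); all stochastic draws (division
#'   noise, daughter angle kicks) flow from it.
#' @param pde if `FALSE`, the metabolite fields are frozen at saturating
#'   values and every cell grows at the maximal aerobic rate — the
#'   nutrient-replete control mode used for growth-law checks.
#' @param quiet suppress the per-step log line.
#' @return object of class `colony_sim`: list with `params`, `kinetics` (one
#'   row per macro step: time, cell count, radius, height, volume, growing
#'   fraction, flux shares, monolayer width, oxygen minimum, glucose pool),
#'   `snapshots` (list of time-stamped cells + fields + masks + death-zone
#'   grids), `final` state and the termination reason.
#' @export
run_simulation <- function(p, t_end = p$t_end, snapshot_every = p$snapshot_every,
                           seed = p$seed, pde = TRUE, quiet = TRUE) {
  stopifnot(t_end > 0)
  v <- validate_params(p)
  if (nrow(v)) stop("invalid parameter set; see validate_params()")
  set.seed(as.integer(seed))
  grid <- make_grid(p)
  fields <- make_fields(grid, p)
  dmodel <- death_model(p$delta_aer, p$delta_ana)
  cells <- new_cell_table(x = 0, z = p$r0, angle = 0, length = p$l_div / 2)
  prev_active <- matrix(rep(grid$z < 0, each = grid$nx), grid$nx, grid$nz)

  n_steps <- ceiling(t_end / p$dt_macro)
  snapshots <- list()
  kin <- vector("list", n_steps)
  next_snap <- 0
  glucose_consumed <- 0
  termination <- "t_end"
  wall_margin <- 2 * grid$h
  half_w <- p$domain_width / 2
  initial_glucose <- sum(fields$C_g[, grid$z < 0]) * grid$h^2

  t <- 0
  for (step in seq_len(n_steps)) {
    dt <- min(p$dt_macro, t_end - t)
    if (dt <= 1e-9) break
    masks <- build_masks(cells, grid, p)
    active <- masks$region != REGION_AIR
    fields$C_g <- fill_new_active(fields$C_g, active, prev_active, 0)
    fields$C_a <- fill_new_active(fields$C_a, active, prev_active, 0)
    fields$C_o <- fill_new_active(fields$C_o, active, prev_active, p$C_o_ambient)
    prev_active <- active

    if (pde) {
      fields <- metabolite_step(fields, masks, p, dt)
      glucose_consumed <- glucose_consumed +
        sum(attr(fields, "uptake_g")) * grid$h^2
      Cg_c <- sample_field(fields$C_g, active, grid, cells$x, cells$z)
      Co_c <- sample_field(fields$C_o, active, grid, cells$x, cells$z,
                           fallback = p$C_o_ambient)
      Ca_c <- sample_field(fields$C_a, active, grid, cells$x, cells$z)
      lam <- local_growth_rate(Cg_c, Co_c, Ca_c, p)$lambda_total
      maint <- maintenance_allocation(Cg_c, Co_c, Ca_c, p)
      starving <- maint$starving
      anaerobic <- maint$anaerobic
    } else {
      lam <- rep(p$lambda_g_aer, nrow(cells))
      starving <- rep(FALSE, nrow(cells))
      anaerobic <- rep(FALSE, nrow(cells))
    }

    cells <- elongate_and_divide(cells, lam, dt, p)
    # flags are re-evaluated at the (possibly new) cell positions so daughters
    # get their own starvation state
    if (pde) {
      Co_c <- sample_field(fields$C_o, active, grid, cells$x, cells$z,
                           fallback = p$C_o_ambient)
      Cg_c <- sample_field(fields$C_g, active, grid, cells$x, cells$z)
      Ca_c <- sample_field(fields$C_a, active, grid, cells$x, cells$z)
      maint <- maintenance_allocation(Cg_c, Co_c, Ca_c, p)
      starving <- maint$starving
      anaerobic <- maint$anaerobic
    } else {
      starving <- rep(FALSE, nrow(cells))
      anaerobic <- rep(FALSE, nrow(cells))
    }
    cells <- update_starvation(cells, starving, anaerobic, dt)
    cells$p_death <- death_probability(cells$tau_aer, cells$tau_ana, dmodel)
    cells <- relax_cells(cells, p, dt)
    t <- t + dt

    colony_idx <- masks$region == REGION_COLONY
    min_o <- if (pde && any(colony_idx)) min(fields$C_o[colony_idx]) else NA_real_
    prof <- profile_from_cells(cells, dz = 5, r0 = p$r0)
    rh <- radius_height(prof)
    mw <- tryCatch(as.numeric(monolayer_width(cells, r0 = p$r0)),
                   error = function(e) NA_real_)
    fp <- if (pde) flux_partition(grid_sources(fields, masks, p), masks)
          else list(glucose_aerobic = NA_real_, glucose_anaerobic = NA_real_,
                    acetate_growth = NA_real_, acetate_maintenance = NA_real_)
    kin[[step]] <- data.frame(
      time = t, n_cells = nrow(cells), radius = rh[["radius"]],
      height = rh[["height"]], volume = volume_from_profile(prof),
      growing_fraction = growing_fraction(cells, p$growth_threshold),
      monolayer_width = mw,
      glucose_aerobic_share = fp$glucose_aerobic,
      glucose_anaerobic_share = fp$glucose_anaerobic,
      acetate_growth_share = fp$acetate_growth,
      acetate_maintenance_share = fp$acetate_maintenance,
      min_oxygen_colony = min_o,
      glucose_remaining = sum(fields$C_g[active]) * grid$h^2,
      mean_abs_angle = mean(abs(cells$angle)),
      expected_dead = attr(death_zone_grid(cells), "total")
    )
    if (!quiet)
      message(sprintf("t=%6.2f h  N=%6d  R=%7.1f  H=%6.1f  minO2=%s",
                      t, nrow(cells), rh[["radius"]], rh[["height"]],
                      format(min_o, digits = 3)))
    if (t >= next_snap - 1e-9 || t >= t_end - 1e-9) {
      # masks are rebuilt so the stored snapshot is self-consistent with the
      # post-relaxation cell positions
      snapshots[[length(snapshots) + 1L]] <- list(
        time = t, cells = cells, fields = fields,
        masks = build_masks(cells, grid, p),
        death_zone = death_zone_grid(cells), kinetics = kin[[step]])
      next_snap <- next_snap + snapshot_every
    }
    ext <- max(abs(cells$x)) + max(cells$length) / 2 + p$r0
    if (ext > half_w - wall_margin) {
      termination <- "wall_contact"
      warning("colony reached the lateral wall at t = ", round(t, 2),
              " h; stopping", call. = FALSE)
      break
    }
    top <- max(cells$z) + max(cells$length) / 2 + p$r0
    if (top > p$air_height - wall_margin) {
      termination <- "top_contact"
      warning("colony reached the top of the air region at t = ",
              round(t, 2), " h; stopping", call. = FALSE)
      break
    }
  }
  kinetics <- do.call(rbind, kin[!vapply(kin, is.null, logical(1))])
  structure(list(params = p, kinetics = kinetics, snapshots = snapshots,
                 final = list(cells = cells, fields = fields, time = t),
                 glucose_consumed = glucose_consumed,
                 initial_glucose = initial_glucose,
                 termination = termination, seed = seed),
            class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  k <- x$kinetics
  last <- k[nrow(k), ]
  cat("Colony simulation (", nrow(k), " macro steps, ",
      length(x$snapshots), " snapshots, seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  t = %.2f h | %d cells | radius %.1f um | height %.1f um\n",
              last$time, last$n_cells, last$radius, last$height))
  cat(sprintf("  growing fraction %.3f | monolayer width %s um\n",
              last$growing_fraction, format(last$monolayer_width, digits = 3)))
  cat("  termination:", x$termination, "\n")
  invisible(x)
}

#' @export
summary.colony_sim <- function(object, window = NULL, ...) {
  k <- object$kinetics
  if (is.null(window))
    window <- c(min(k$time) + diff(range(k$time)) / 3, max(k$time))
  ek <- tryCatch(expansion_kinetics(k[, c("time", "radius", "height")],
                                    window = window),
                 error = function(e) NULL)
  out <- list(kinetics = k, expansion = ek, window = window,
              params = object$params, termination = object$termination)
  class(out) <- "summary.colony_sim"
  out
}

#' @export
print.summary.colony_sim <- function(x, ...) {
  k <- x$kinetics
  cat("Colony simulation summary (", nrow(k), " steps to t = ",
      round(max(k$time), 2), " h)\n", sep = "")
  if (!is.null(x$expansion)) {
    cat(sprintf("  radial speed %.2f um/h (R^2 = %.4f) on window [%.1f, %.1f] h\n",
                x$expansion$radial_speed, x$expansion$r_squared,
                x$window[1], x$window[2]))
    cat("  vertical slowdown:", x$expansion$vertical_slowdown, "\n")
  }
  last <- k[nrow(k), ]
  cat(sprintf("  final: %d cells, radius %.1f um, height %.1f um, growing fraction %.3f\n",
              last$n_cells, last$radius, last$height, last$growing_fraction))
  invisible(x)
}

#' Plot a colony simulation snapshot
#'
#' Draws the rods of the last (or chosen) snapshot coloured by orientation
#' (blue horizontal to yellow vertical), the agar surface, and optionally the
#' radius/height kinetics.
#'
#' @param x a `colony_sim` object.
#' @param which `"cells"` or `"kinetics"`.
#' @param snapshot snapshot index (default last).
#' @param ... passed to the underlying plot.
#' @export
plot.colony_sim <- function(x, which = c("cells", "kinetics"),
                            snapshot = length(x$snapshots), ...) {
  which <- match.arg(which)
  if (which == "kinetics") {
    k <- x$kinetics
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    plot(k$time, k$radius, type = "l", xlab = "time (h)",
         ylab = "radius (um)", ...)
    plot(k$time, k$height, type = "l", xlab = "time (h)",
         ylab = "height (um)", ...)
    return(invisible(x))
  }
  sn <- x$snapshots[[snapshot]]
  cells <- sn$cells
  frac <- abs(cells$angle) / (pi / 2)
  cols <- grDevices::rgb(frac, frac * 0.8, 1 - frac)
  hx <- cells$length / 2 * cos(cells$angle)
  hz <- cells$length / 2 * sin(cells$angle)
  plot(NA, xlim = range(cells$x) + c(-5, 5), ylim = c(-2, max(cells$z) + 3),
       xlab = "x (um)", ylab = "z (um)", asp = 1,
       main = sprintf("t = %.1f h, %d cells", sn$time, nrow(cells)), ...)
  graphics::abline(h = 0, col = "tan4", lwd = 2)
  graphics::segments(cells$x - hx, cells$z - hz, cells$x + hx, cells$z + hz,
                     col = cols, lwd = 3, lend = 1)
  invisible(x)
}

#' Extract the kinetics table of a simulation
#' @param sim a `colony_sim`.
#' @return data.frame, one row per macro step.
#' @export
kinetics <- function(sim) sim$kinetics

#' Write snapshots of a simulation to CSV files
#'
#' Writes per-snapshot cell tables (`cells_<t>.csv`), field tables
#' (`fields_<t>.csv`: one row per active grid cell with region, rho and the
#' three concentrations) and the kinetics series (`kinetics.csv`).
#'
#' @param sim a `colony_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_snapshots <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sn in sim$snapshots) {
    tag <- sprintf("%07.2fh", sn$time)
    write_cells_csv(sn$cells, file.path(dir, paste0("cells_", tag, ".csv")))
    grid <- sn$fields$grid
    act <- which(sn$masks$region != REGION_AIR)
    ix <- ((act - 1L) %% grid$nx) + 1L
    iz <- ((act - 1L) %/% grid$nx) + 1L
    fd <- data.frame(x = grid$x[ix], z = grid$z[iz],
                     region = sn$masks$region[act], rho = sn$masks$rho[act],
                     C_g = sn$fields$C_g[act], C_o = sn$fields$C_o[act],
                     C_a = sn$fields$C_a[act])
    write.csv(fd, file.path(dir, paste0("fields_", tag, ".csv")),
              row.names = FALSE)
  }
  write.csv(sim$kinetics, file.path(dir, "kinetics.csv"), row.names = FALSE)
  invisible(dir)
}
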