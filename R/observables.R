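# Colony morphometry: cross-sectional profiles, disk-stack volume, monolayer
# width, flux partitioning, growing fractions and expansion kinetics.

#' Cross-sectional profile of a colony
#'
#' For each z-bin of width `dz` above the agar surface, the bounding radial
#' extent is the maximum over all cells intersecting the bin of
#' `|x| + (L/2)|cos(angle)| + r0` (cap-inclusive). Bins above the topmost cell
#' are dropped.
#'
#' @param cells a nonempty `cell_table`.
#' @param dz z-step, um (default 5, the conventional disk thickness).
#' @param r0 cell radius, um.
#' @return data.frame of class `cross_section_profile` with columns `z` (bin
#'   lower edge, starting at 0) and `r` (bounding radius, um); attribute `dz`.
#' @export
profile_from_cells <- function(cells, dz = 5, r0 = 0.5) {
  if (dz <= 0) stop("dz must be > 0")
  if (!nrow(cells)) stop("no cells")
  zlo <- cells$z - (cells$length / 2) * abs(sin(cells$angle)) - r0
  zhi <- cells$z + (cells$length / 2) * abs(sin(cells$angle)) + r0
  xext <- abs(cells$x) + (cells$length / 2) * abs(cos(cells$angle)) + r0
  nbin <- max(1L, ceiling(max(zhi) / dz))
  r <- numeric(nbin)
  for (i in seq_len(nbin)) {
    lo <- (i - 1) * dz; hi <- i * dz
    hit <- zhi > lo & zlo < hi
    r[i] <- if (any(hit)) max(xext[hit]) else 0
  }
  while (nbin > 1L && r[nbin] == 0) { r <- r[-nbin]; nbin <- nbin - 1L }
  structure(data.frame(z = (seq_len(nbin) - 1L) * dz, r = r),
            dz = dz, class = c("cross_section_profile", "data.frame"))
}

#' Colony radius and height from a cross-sectional profile
#'
#' Radius is the maximum bounding radius over the profile (attained at the
#' colony bottom for dome-shaped colonies); height is the largest z at which
#' the bounding radius is still non-zero (the top edge of the last occupied
#' bin).
#'
#' @param profile a [profile_from_cells()] data.frame (or any data.frame with
#'   `z`, `r` and a `dz` attribute / uniform spacing).
#' @return named numeric vector `c(radius =, height =)`, um.
#' @export
radius_height <- function(profile) {
  if (!nrow(profile)) stop("empty profile")
  dz <- attr(profile, "dz")
  if (is.null(dz)) dz <- if (nrow(profile) > 1) diff(profile$z[1:2]) else
    profile$z[2] - profile$z[1]
  if (is.null(dz) || !is.finite(dz)) stop("cannot determine dz")
  nz <- which(profile$r > 0)
  height <- if (length(nz)) max(profile$z[nz]) + dz else 0
  c(radius = max(profile$r), height = height)
}

#' Colony volume by the stack-of-disks estimate
#'
#' Treats the colony as a stack of disks, one per z-bin: each bin of thickness
#' `dz` and bounding radius `r` contributes `pi * r^2 * dz`.
#'
#' @param profile a [profile_from_cells()] profile with uniform `dz`.
#' @return volume, um^3.
#' @export
volume_from_profile <- function(profile) {
  if (!nrow(profile)) stop("empty profile")
  dz <- attr(profile, "dz")
  if (is.null(dz)) {
    steps <- diff(profile$z)
    if (length(steps) && max(abs(steps - steps[1])) > 1e-9 * steps[1])
      stop("profile z-steps are not uniform")
    dz <- if (length(steps)) steps[1] else stop("cannot determine dz")
  }
  sum(pi * profile$r^2 * dz)
}

# Per-column stack heights: the union length of cell z-extents over each
# x-column, in units of the cell diameter 2*r0.
column_layers <- function(cells, dx, r0) {
  zlo <- cells$z - (cells$length / 2) * abs(sin(cells$angle)) - r0
  zhi <- cells$z + (cells$length / 2) * abs(sin(cells$angle)) + r0
  xlo <- cells$x - (cells$length / 2) * abs(cos(cells$angle)) - r0
  xhi <- cells$x + (cells$length / 2) * abs(cos(cells$angle)) + r0
  x0 <- floor(min(xlo) / dx) * dx
  ncol_ <- max(1L, ceiling((max(xhi) - x0) / dx))
  centers <- x0 + (seq_len(ncol_) - 0.5) * dx
  layers <- integer(ncol_)
  for (j in seq_len(ncol_)) {
    hit <- which(xlo <= centers[j] & xhi >= centers[j])
    if (!length(hit)) next
    # union length of the z-intervals
    o <- order(zlo[hit])
    lo <- zlo[hit][o]; hi <- zhi[hit][o]
    tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
    for (k in seq_along(lo)[-1]) {
      if (lo[k] <= cur_hi) cur_hi <- max(cur_hi, hi[k])
      else { tot <- tot + (cur_hi - cur_lo); cur_lo <- lo[k]; cur_hi <- hi[k] }
    }
    tot <- tot + (cur_hi - cur_lo)
    layers[j] <- as.integer(round(tot / (2 * r0)))
  }
  list(centers = centers, layers = layers, dx = dx)
}

#' Peripheral monolayer width of a colony
#'
#' Simulation-mode definition: per x-column (width `grid_dx`), the local stack
#' height is the union length of cell z-extents in units of the cell diameter;
#' the monolayer on each peripheral side is the outermost contiguous run of
#' columns of stack height exactly one, and the reported width is the average
#' of the two sides. A colony that is a monolayer throughout returns half the
#' footprint per side (the two runs meet at the centre).
#'
#' @param cells a nonempty `cell_table` with a contiguous footprint.
#' @param grid_dx column width, um (default 2).
#' @param r0 cell radius, um.
#' @return monolayer width, um, with attribute `sides = c(left =, right =)`.
#' @export
monolayer_width <- function(cells, grid_dx = 2, r0 = 0.5) {
  if (!nrow(cells)) stop("empty colony")
  cl <- column_layers(cells, grid_dx, r0)
  occ <- which(cl$layers > 0)
  if (!length(occ)) stop("empty colony footprint")
  footprint <- length(occ) * cl$dx
  run_from <- function(idx_seq) {
    w <- 0L
    for (j in idx_seq) {
      if (cl$layers[j] == 1L) w <- w + 1L else break
    }
    w
  }
  left <- run_from(seq(min(occ), max(occ)))
  right <- run_from(seq(max(occ), min(occ)))
  n_occ <- max(occ) - min(occ) + 1L
  lw <- if (left >= n_occ) footprint / 2 else left * cl$dx
  rw <- if (right >= n_occ) footprint / 2 else right * cl$dx
  structure(mean(c(lw, rw)), sides = c(left = lw, right = rw))
}

#' Monolayer width from a projected-intensity trace
#'
#' Experimental-mode analogue: given a 1D projected fluorescence intensity
#' trace starting at the outer colony edge, the monolayer plateau is the
#' intensity at the edge and the monolayer ends at the first position whose
#' intensity exceeds `threshold_factor` times the plateau (the sharp rise
#' where cells start stacking).
#'
#' @param position positions from the outer edge, um (increasing inward).
#' @param intensity projected intensities (same length).
#' @param threshold_factor multiple of the plateau marking the rise
#'   (default 1.5).
#' @return monolayer width, um (`NA` if the intensity never rises).
#' @export
monolayer_width_intensity <- function(position, intensity,
                                      threshold_factor = 1.5) {
  if (length(position) != length(intensity)) stop("length mismatch")
  plateau <- intensity[1]
  idx <- which(intensity > threshold_factor * plateau)
  if (!length(idx)) return(NA_real_)
  position[min(idx)] - position[1]
}

#' Colony-integrated flux partitioning
#'
#' Integrates the biomass-weighted uptake fluxes over the colony region and
#' returns the aerobic/anaerobic shares of glucose uptake and the
#' growth/maintenance shares of acetate uptake. A pair whose total flux is
#' zero is returned as `NA` (undefined).
#'
#' @param sources a [grid_sources()] list.
#' @param masks the matching [build_masks()] object.
#' @return list with `glucose_aerobic`, `glucose_anaerobic`, `acetate_growth`,
#'   `acetate_maintenance` (fractions in `[0, 1]`, each pair summing to 1 when
#'   defined).
#' @export
flux_partition <- function(sources, masks) {
  if (!length(sources$idx))
    return(list(glucose_aerobic = NA_real_, glucose_anaerobic = NA_real_,
                acetate_growth = NA_real_, acetate_maintenance = NA_real_))
  rho <- masks$rho[sources$idx]
  g_aer <- sum(rho * sources$src$Q_g_aer)
  g_ana <- sum(rho * sources$src$Q_g_ana)
  a_gro <- sum(rho * sources$src$Q_a_growth)
  a_mnt <- sum(rho * sources$src$Q_a_maint)
  g_tot <- g_aer + g_ana
  a_tot <- a_gro + a_mnt
  list(
    glucose_aerobic = if (g_tot > 0) g_aer / g_tot else NA_real_,
    glucose_anaerobic = if (g_tot > 0) g_ana / g_tot else NA_real_,
    acetate_growth = if (a_tot > 0) a_gro / a_tot else NA_real_,
    acetate_maintenance = if (a_tot > 0) a_mnt / a_tot else NA_real_
  )
}

#' Fraction of growing cells
#'
#' A cell counts as growing iff its instantaneous growth rate strictly
#' exceeds the threshold (default 0.01 1/h).
#'
#' @param cells a `cell_table` with populated `lambda_inst`.
#' @param threshold classification rate, 1/h.
#' @return fraction in `[0, 1]` (0 for an empty table).
#' @export
growing_fraction <- function(cells, threshold = 0.01) {
  if (!nrow(cells)) return(0)
  mean(cells$lambda_inst > threshold)
}

#' Radial and vertical expansion kinetics
#'
#' Fits a least-squares line to radius versus time inside a window (linear
#' radial expansion gives slope = radial speed with R^2 near 1) and examines
#' the height increments over the successive sampling intervals for a
#' monotone slowdown.
#'
#' @param series data.frame with columns `time` (h), `radius`, `height` (um).
#' @param window `c(t1, t2)` in h; defaults to the full series.
#' @param slowdown_tol relative tolerance when comparing successive height
#'   increments (default 0.05).
#' @return list with `radial_speed` (um/h), `r_squared`,
#'   `height_increments` and logical `vertical_slowdown`.
#' @export
expansion_kinetics <- function(series, window = range(series$time),
                               slowdown_tol = 0.05) {
  sel <- series$time >= window[1] & series$time <= window[2]
  d <- series[sel, , drop = FALSE]
  if (nrow(d) < 4) stop("need at least 4 samples in the window")
  fit <- lm(radius ~ time, data = d)
  sst <- sum((d$radius - mean(d$radius))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  dh <- diff(d$height)
  tol <- slowdown_tol * max(abs(dh), 1e-12)
  slow <- all(diff(dh) <= tol)
  list(radial_speed = unname(coef(fit)[2]), r_squared = r2,
       height_increments = dh, vertical_slowdown = slow)
}
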