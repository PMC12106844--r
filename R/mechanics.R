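# R-facing surface over the compiled contact-mechanics core.

#' Compute forces and torques on every cell
#'
#' Four contributions: (i) Hertz-like elastic repulsion `F = k_cc * d^(3/2)`
#' at the minimum-distance points of overlapping rod pairs (`d` = overlap),
#' applied equal-and-opposite along the mutual normal; (ii) the same law
#' against the agar half-space `z < 0` for penetrating poles/centres
#' (`k_wall`); (iii) a surface-tension spring pulling cell tops that protrude
#' above the smoothed colony outline back towards it; (iv) a small settling
#' force proportional to cell length. Pairwise contributions sum to zero over
#' the population (Newton's third law); the external contributions do not.
#'
#' @param cells a `cell_table`.
#' @param p a [colony_params()] set.
#' @return data.frame with per-cell columns `fx_cc, fz_cc, torque_cc` (pairwise
#'   cell-cell part) and `fx_ext, fz_ext, torque_ext` (agar + surface tension +
#'   settling), plus attributes `max_overlap` (um) and `max_stiffness`
#'   (the steepest local force gradient, used for the stability bound).
#' @export
compute_forces <- function(cells, p) {
  if (!nrow(cells)) {
    out <- data.frame(fx_cc = numeric(), fz_cc = numeric(),
                      torque_cc = numeric(), fx_ext = numeric(),
                      fz_ext = numeric(), torque_ext = numeric())
    attr(out, "max_overlap") <- 0
    attr(out, "max_stiffness") <- 0
    return(out)
  }
  m <- .forces_cpp(as_state_matrix(cells), p$r0, p$k_cc, p$k_wall,
                   p$surface_tension, p$f_settle)
  out <- as.data.frame(m)
  attr(out, "max_overlap") <- attr(m, "max_overlap")
  attr(out, "max_stiffness") <- attr(m, "max_stiffness")
  out
}

# Largest stable explicit step for the stiffest active contact.
mech_stability_bound <- function(cells, forces, p) {
  ks <- attr(forces, "max_stiffness")
  if (is.null(ks) || ks <= 0) return(Inf)
  lmin <- min(cells$length + 2 * p$r0)
  p$mech_safety * p$drag * lmin / ks
}

#' Advance cell positions one overdamped step
#'
#' Explicit overdamped update: `velocity = force / (drag * L)` and
#' `angular velocity = torque / (drag * L^3 / 12)` with `L` the full
#' spherocylinder length; angles are re-wrapped to `[-pi/2, pi/2]`. The step
#' refuses to run above the contact-stiffness stability bound and suggests a
#' stable step instead.
#'
#' @param cells a `cell_table`.
#' @param forces output of [compute_forces()] for `cells`.
#' @param dt_mech step, h.
#' @param p a [colony_params()] set.
#' @return updated `cell_table`.
#' @export
step_mechanics <- function(cells, forces, dt_mech, p) {
  if (dt_mech <= 0) stop("dt_mech must be > 0")
  bound <- mech_stability_bound(cells, forces, p)
  if (dt_mech > bound)
    stop(sprintf("dt_mech = %g h exceeds the stability bound for the stiffest contact; use dt_mech <= %g h",
                 dt_mech, bound))
  L <- cells$length + 2 * p$r0
  zeta <- p$drag * L
  fx <- forces$fx_cc + forces$fx_ext
  fz <- forces$fz_cc + forces$fz_ext
  tq <- forces$torque_cc + forces$torque_ext
  cells$x <- cells$x + dt_mech * fx / zeta
  cells$z <- cells$z + dt_mech * fz / zeta
  cells$angle <- wrap_angle(cells$angle + dt_mech * tq / (p$drag * L^3 / 12))
  cells
}

#' Relax a configuration mechanically for a time interval
#'
#' Runs the compiled nested mechanics loop: adaptive explicit substeps, each
#' bounded by the stability limit of the currently stiffest contact, until
#' `total_time` is covered (or the step cap is hit).
#'
#' @param cells a `cell_table`.
#' @param p a [colony_params()] set.
#' @param total_time interval to integrate, h.
#' @param max_steps substep cap (default 50000).
#' @return updated `cell_table` with attributes `n_steps` and `max_overlap`.
#' @export
relax_cells <- function(cells, p, total_time, max_steps = 50000L) {
  if (!nrow(cells) || total_time <= 0) return(cells)
  res <- .relax_cpp(as_state_matrix(cells), p$r0, p$k_cc, p$k_wall,
                    p$surface_tension, p$f_settle, p$drag,
                    total_time, p$dt_mech, p$mech_safety,
                    as.integer(max_steps))
  st <- res$state
  cells$x <- st[, 1]; cells$z <- st[, 2]
  cells$angle <- st[, 3]; cells$length <- st[, 4]
  attr(cells, "n_steps") <- res$n_steps
  attr(cells, "max_overlap") <- res$max_overlap
  cells
}
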