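# Rod-shaped cell agents. A population is a plain data.frame ("cell table")
# with one row per cell; positions in micrometres, angles in radians measured
# from the horizontal agar axis and wrapped to [-pi/2, pi/2].

CELL_COLUMNS <- c("id", "x", "z", "angle", "length", "lambda_inst",
                  "tau_aer", "tau_ana", "p_death", "lineage")

#' Create a cell table
#'
#' @param x,z centre coordinates, um.
#' @param angle orientation from the horizontal axis, rad, in `[-pi/2, pi/2]`.
#' @param length pole-to-pole rod length (hemispherical caps excluded), um.
#' @param id integer ids (default sequential).
#' @param lineage parent id (`NA` for founders).
#' @return data.frame of class `cell_table` with columns `id, x, z, angle,
#'   length, lambda_inst, tau_aer, tau_ana, p_death, lineage`.
#' @export
new_cell_table <- function(x = 0, z = 0.5, angle = 0, length = 2,
                           id = seq_along(x), lineage = NA_integer_) {
  n <- if (length(x)) max(length(x), length(z), length(angle), length(length))
       else 0L
  d <- data.frame(id = as.integer(rep_len(id, n)),
                  x = rep_len(as.numeric(x), n),
                  z = rep_len(as.numeric(z), n),
                  angle = rep_len(as.numeric(angle), n),
                  length = rep_len(as.numeric(length), n),
                  lambda_inst = rep(0, n), tau_aer = rep(0, n),
                  tau_ana = rep(0, n), p_death = rep(0, n),
                  lineage = rep_len(as.integer(lineage), n))
  class(d) <- c("cell_table", "data.frame")
  d
}

as_state_matrix <- function(cells)
  cbind(x = cells$x, z = cells$z, angle = cells$angle, length = cells$length)

#' Grow cells exponentially and divide those past the division length
#'
#' Each cell's spherocylinder extent (`length + 2 r0`, proportional to its
#' biomass) is multiplied by `exp(lambda * dt)` — exponential single-cell
#' elongation. Because a daughter's extent is exactly half its parent's, the
#' total population extent then grows as `exp(lambda * t)` through divisions,
#' and so does the cell count. A cell whose length exceeds its division
#' threshold — `l_div` perturbed by a uniform noise fraction drawn per
#' division — is replaced by two daughters that split the spherocylinder at
#' its midpoint: each daughter has length `L/2 - r0`, so the two daughters
#' placed pole-to-pole occupy exactly the parent's extent (total rod material
#' is conserved up to the two newly inserted caps, `2 * r0`). Daughters
#' inherit the parent's angle with a tiny opposite-signed random kick to break
#' collinearity, inherit the starvation clocks and death probability, and get
#' fresh ids with `lineage` set to the parent id.
#'
#' @param cells a `cell_table`.
#' @param lambda instantaneous growth rate(s), 1/h (recycled; must be >= 0).
#' @param dt time step, h (> 0).
#' @param p a [colony_params()] set (for `l_div`, `div_noise`, `kick_angle`, `r0`).
#' @return updated `cell_table` (row count grows by the number of divisions).
#' @export
elongate_and_divide <- function(cells, lambda, dt, p) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(lambda < 0)) stop("growth rate must be >= 0")
  lambda <- rep_len(lambda, nrow(cells))
  cells$lambda_inst <- lambda
  cells$length <- (cells$length + 2 * p$r0) * exp(lambda * dt) - 2 * p$r0
  if (!nrow(cells)) return(cells)
  thresh <- p$l_div * (1 + runif(nrow(cells), -p$div_noise, p$div_noise))
  divide <- cells$length > thresh & cells$length > 2 * p$r0 + 1e-9
  if (!any(divide)) return(cells)
  parents <- cells[divide, , drop = FALSE]
  nd <- nrow(parents)
  ld <- parents$length / 2 - p$r0
  off <- ld / 2 + p$r0              # daughter centre offset along the axis
  ux <- cos(parents$angle); uz <- sin(parents$angle)
  kick <- runif(nd, 0, p$kick_angle)
  mk <- function(sgn, ids) {
    d <- parents
    d$id <- ids
    d$x <- parents$x + sgn * off * ux
    d$z <- parents$z + sgn * off * uz
    d$angle <- wrap_angle(parents$angle + sgn * kick)
    d$length <- ld
    d$lineage <- parents$id
    d
  }
  next_id <- max(cells$id) + 1L
  d1 <- mk(-1, next_id + seq_len(nd) - 1L)
  d2 <- mk(+1, next_id + nd + seq_len(nd) - 1L)
  out <- rbind(cells[!divide, , drop = FALSE], d1, d2)
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

wrap_angle <- function(a) {
  a <- (a + pi / 2) %% pi - pi / 2
  # map the boundary case -pi/2 consistently into the closed interval
  a[a < -pi / 2] <- a[a < -pi / 2] + pi
  a
}

#' Classify cell orientation as horizontal or vertical
#'
#' A cell is vertical iff `|angle|` strictly exceeds the cutoff; a cell at
#' exactly the cutoff counts as horizontal.
#'
#' @param angle orientation(s), rad.
#' @param vertical_cutoff cutoff angle, rad (default `pi/4`).
#' @return character vector, `"horizontal"` or `"vertical"`.
#' @export
classify_orientation <- function(angle, vertical_cutoff = pi / 4) {
  ifelse(abs(angle) > vertical_cutoff, "vertical", "horizontal")
}

#' Write a cell table to CSV
#'
#' Positions with 6 significant digits, one row per cell.
#' @param cells a `cell_table`.
#' @param path output path.
#' @export
write_cells_csv <- function(cells, path) {
  out <- cells
  for (nm in c("x", "z", "angle", "length", "lambda_inst", "tau_aer",
               "tau_ana", "p_death"))
    out[[nm]] <- signif(out[[nm]], 6)
  write.csv(out[, CELL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#' @param path CSV written by [write_cells_csv()] (or matching its header).
#' @return a `cell_table`.
#' @export
read_cells_csv <- function(path) {
  d <- read.csv(path)
  missing <- setdiff(CELL_COLUMNS, names(d))
  if (length(missing))
    stop("cell CSV lacks column(s): ", paste(missing, collapse = ", "))
  class(d) <- c("cell_table", "data.frame")
  d
}
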