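# Starvation clocks, the exponential death model, and viability-decay fitting.
#
# A cell is starving when its achievable carbon uptake flux is below the
# maintenance flux. Starvation time accumulates on one of two clocks according
# to the local oxygen state (anoxia: C_o below the cutoff, by default K_o);
# accumulated exposure converts to a death probability through mode-specific
# exponential death rates measured in days^-1.

#' Construct a death model
#'
#' @param delta_aer aerobic starvation death rate, 1/day (default 0.2).
#' @param delta_ana anaerobic starvation death rate, 1/day (default 2).
#' @param a amplitude for viability curves, CFU/mL (default 1).
#' @return object of class `death_model`.
#' @export
death_model <- function(delta_aer = 0.2, delta_ana = 2, a = 1) {
  if (delta_aer <= 0 || delta_ana <= 0) stop("death rates must be > 0")
  structure(list(delta_aer = delta_aer, delta_ana = delta_ana, a = a),
            class = "death_model")
}

#' Accumulate starvation time on a cell's clocks
#'
#' Starving cells add `dt` to the anaerobic clock when the local environment
#' is anoxic, otherwise to the aerobic clock. Clocks are cumulative by
#' default: renewed nutrient access pauses but does not reset them (death
#' hazard is modelled on total accumulated exposure); `reset_on_feed = TRUE`
#' selects the alternative semantics in which any non-starving step zeroes
#' both clocks.
#'
#' @param cells a `cell_table`.
#' @param starving logical vector (one per cell).
#' @param anaerobic logical vector (one per cell).
#' @param dt elapsed time, h (> 0).
#' @param reset_on_feed reset clocks when not starving (default `FALSE`).
#' @return updated `cell_table`.
#' @export
update_starvation <- function(cells, starving, anaerobic, dt,
                              reset_on_feed = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  starving <- rep_len(starving, nrow(cells))
  anaerobic <- rep_len(anaerobic, nrow(cells))
  cells$tau_ana <- cells$tau_ana + dt * (starving & anaerobic)
  cells$tau_aer <- cells$tau_aer + dt * (starving & !anaerobic)
  if (reset_on_feed) {
    cells$tau_ana[!starving] <- 0
    cells$tau_aer[!starving] <- 0
  }
  cells
}

#' Death probability from accumulated starvation
#'
#' Exponential survival under the two starvation modes:
#' `p = 1 - exp(-(delta_aer * tau_aer + delta_ana * tau_ana))` with clocks
#' converted from hours to days. Monotone non-decreasing in both clocks, and
#' multiplicative over consecutive exposures.
#'
#' @param tau_aer,tau_ana accumulated starvation durations, h (>= 0).
#' @param model a [death_model()].
#' @return probability in `[0, 1]`.
#' @export
death_probability <- function(tau_aer, tau_ana, model = death_model()) {
  if (any(tau_aer < 0) || any(tau_ana < 0)) stop("clocks must be >= 0")
  1 - exp(-(model$delta_aer * tau_aer + model$delta_ana * tau_ana) / 24)
}

#' Expected dead-cell counts on a spatial grid
#'
#' Bins cells into `box` x `box` squares; the expected number of dead cells
#' in a box is the number of cells there times their mean death probability.
#'
#' @param cells a `cell_table` with populated `p_death`.
#' @param box bin side, um (default 4).
#' @return matrix of expected dead-cell counts with attributes `x_breaks`,
#'   `z_breaks` and `total` (the summed expected dead count).
#' @export
death_zone_grid <- function(cells, box = 4) {
  if (box <= 0) stop("box must be > 0")
  if (!nrow(cells)) {
    out <- matrix(0, 0, 0)
    attr(out, "total") <- 0
    return(out)
  }
  xb <- seq(floor(min(cells$x) / box) * box,
            ceiling(max(cells$x) / box) * box + box, by = box)
  zb <- seq(floor(min(cells$z) / box) * box,
            ceiling(max(cells$z) / box) * box + box, by = box)
  ix <- findInterval(cells$x, xb, rightmost.closed = TRUE)
  iz <- findInterval(cells$z, zb, rightmost.closed = TRUE)
  n <- tapply(rep(1, nrow(cells)), list(factor(ix, seq_len(length(xb) - 1)),
                                        factor(iz, seq_len(length(zb) - 1))),
              sum, default = 0)
  pm <- tapply(cells$p_death, list(factor(ix, seq_len(length(xb) - 1)),
                                   factor(iz, seq_len(length(zb) - 1))),
               mean, default = 0)
  out <- n * pm
  attr(out, "x_breaks") <- xb
  attr(out, "z_breaks") <- zb
  attr(out, "total") <- sum(out)
  out
}

#' Fit an exponential viability decay a * exp(-delta * t)
#'
#' Least squares on `log(counts)` versus time, the standard way viable-count
#' decay curves are fitted.
#'
#' @param times time since starvation onset, days.
#' @param counts viable counts, CFU/mL (all > 0; at least 3 points).
#' @return object of class `decay_fit` with elements `a`, `delta`, their
#'   standard errors, `r_squared` and the underlying `lm` fit. Methods:
#'   `print`, `coef`, `summary`, `predict`.
#' @examples
#' t <- 0:3
#' fit <- fit_exponential_decay(t, 1e9 * exp(-2 * t))
#' coef(fit)
#' @export
fit_exponential_decay <- function(times, counts) {
  if (length(times) != length(counts)) stop("times and counts differ in length")
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(counts <= 0)) stop("counts must be positive")
  fit <- lm(log(counts) ~ times)
  # summary.lm warns on exact (residual-free) data; the SEs are still valid
  sm <- suppressWarnings(summary(fit))
  a <- exp(coef(fit)[[1]])
  delta <- -coef(fit)[[2]]
  structure(list(a = a, delta = delta,
                 se_log_a = sm$coefficients[1, 2],
                 se_delta = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 residuals = stats::residuals(fit), lm = fit,
                 times = times, counts = counts),
            class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) c(a = object$a, delta = object$delta)

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential viability decay fit: a * exp(-delta * t)\n")
  cat(sprintf("  a     = %.4g CFU/mL\n", x$a))
  cat(sprintf("  delta = %.4g /day (SE %.3g)\n", x$delta, x$se_delta))
  cat(sprintf("  R^2 on log counts = %.4f (n = %d)\n", x$r_squared,
              length(x$times)))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), se_delta = object$se_delta,
              se_log_a = object$se_log_a, r_squared = object$r_squared,
              n = length(object$times))
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("Decay fit: delta =", signif(x$coefficients[["delta"]], 4),
      "/day (SE", signif(x$se_delta, 3), "), a =",
      signif(x$coefficients[["a"]], 4), ", R^2 =", round(x$r_squared, 4),
      ", n =", x$n, "\n")
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, times = object$times, ...) {
  object$a * exp(-object$delta * times)
}
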