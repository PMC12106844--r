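# Synthetic fixture generator: small cell tables, colony profiles and
# viability decay series with analytically known ground truth, used by the
# observable and fitting tests (and available to users for sanity checks).

#' Generate a synthetic fixture with known ground truth
#'
#' Kinds:
#' \describe{
#'   \item{`"monolayer-colony"`}{a single layer of horizontal rods spanning a
#'     footprint of `width` um; truth: monolayer width = width / 2 per side.}
#'   \item{`"stacked-block"`}{a `depth`-deep block of horizontal rods for
#'     `|x| < inner` plus a single-layer skirt out to `outer`; truth:
#'     monolayer width = `outer - inner`.}
#'   \item{`"dome-profile"`}{a cross-sectional profile `r(z) = R *
#'     sqrt(1 - z/H)` sampled at steps `dz`; truth: the closed-form disk sum
#'     `sum(pi * r_i^2 * dz)`.}
#'   \item{`"decay-series"`}{viable counts `a * exp(-delta * t)` at `n` times,
#'     optionally with lognormal noise of standard deviation `noise`.}
#' }
#'
#' @param kind one of the fixture kinds above.
#' @param params named list overriding the fixture's defaults.
#' @param seed RNG seed for the stochastic fixtures.
#' @param dir optional directory; when given, the fixture is also written as
#'   CSV.
#' @return list with `data` (a `cell_table`, profile data.frame or series
#'   data.frame) and `truth` (named list of ground-truth values).
#' @export
generate_fixtures <- function(kind, params = list(), seed = 1, dir = NULL) {
  set.seed(seed)
  pick <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  r0 <- pick("r0", 0.5)
  out <- switch(
    kind,
    "monolayer-colony" = {
      width <- pick("width", 100)
      l <- pick("cell_length", 3)
      pitch <- l + 2 * r0
      n <- max(1L, floor(width / pitch))
      xc <- (seq_len(n) - (n + 1) / 2) * pitch
      cells <- new_cell_table(x = xc, z = r0, angle = 0, length = l)
      list(data = cells,
           truth = list(monolayer_width = n * pitch / 2, footprint = n * pitch))
    },
    "stacked-block" = {
      inner <- pick("inner", 40)
      outer <- pick("outer", 65)
      depth <- pick("depth", 3L)
      l <- pick("cell_length", 3)
      pitch <- l + 2 * r0
      xc_in <- seq(-inner + pitch / 2, inner - pitch / 2, by = pitch)
      cells <- do.call(rbind, lapply(seq_len(depth), function(k)
        new_cell_table(x = xc_in, z = r0 + (k - 1) * 2 * r0, angle = 0,
                       length = l)))
      xr <- seq(inner + pitch / 2, outer - pitch / 2 + 1e-9, by = pitch)
      skirt <- rbind(new_cell_table(x = xr, z = r0, angle = 0, length = l),
                     new_cell_table(x = -xr, z = r0, angle = 0, length = l))
      cells <- rbind(cells, skirt)
      cells$id <- seq_len(nrow(cells))
      class(cells) <- c("cell_table", "data.frame")
      list(data = cells,
           truth = list(monolayer_width = outer - inner, inner = inner,
                        outer = outer))
    },
    "dome-profile" = {
      R <- pick("R", 100)
      H <- pick("H", 40)
      dz <- pick("dz", 5)
      z <- seq(0, H - dz, by = dz)
      r <- R * sqrt(1 - z / H)
      prof <- structure(data.frame(z = z, r = r), dz = dz,
                        class = c("cross_section_profile", "data.frame"))
      list(data = prof,
           truth = list(volume = sum(pi * r^2 * dz), radius = R,
                        height = max(z) + dz))
    },
    "decay-series" = {
      a <- pick("a", 1e9)
      delta <- pick("delta", 2)
      n <- pick("n", 8L)
      tmax <- pick("tmax", 3)
      noise <- pick("noise", 0)
      times <- seq(0, tmax, length.out = n)
      counts <- a * exp(-delta * times)
      if (noise > 0) counts <- counts * exp(rnorm(n, 0, noise))
      list(data = data.frame(time_days = times, cfu_per_ml = counts),
           truth = list(a = a, delta = delta, noise = noise))
    },
    stop("unknown fixture kind: ", kind)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(dir, paste0(gsub("-", "_", kind), ".csv"))
    if (inherits(out$data, "cell_table")) write_cells_csv(out$data, path)
    else write.csv(out$data, path, row.names = FALSE)
    out$path <- path
  }
  out
}
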