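# Computational grid and domain masks. Matrices are indexed [ix, iz]; x runs
# horizontally along the agar surface (centred on 0), z vertically with z = 0
# at the agar-air interface (negative into the agar, positive into colony/air).

REGION_AIR <- 0L
REGION_COLONY <- 1L
REGION_AGAR <- 2L

#' Build the uniform computational grid
#'
#' @param p a [colony_params()] set (`domain_width`, `agar_depth`,
#'   `air_height`, `grid_h`).
#' @return object of class `colony_grid`: list with `nx`, `nz`, `h` (um) and
#'   cell-centre coordinate vectors `x`, `z`.
#' @export
make_grid <- function(p) {
  h <- p$grid_h
  nx <- max(3L, as.integer(round(p$domain_width / h)))
  nz_ag <- as.integer(round(p$agar_depth / h))
  nz_air <- as.integer(round(p$air_height / h))
  nz <- nz_ag + nz_air
  structure(list(nx = nx, nz = nz, h = h,
                 x = (seq_len(nx) - (nx + 1) / 2) * h,
                 z = (seq_len(nz) - nz_ag - 0.5) * h),
            class = "colony_grid")
}

# 3x3 binary dilation/erosion iterated `r` times (morphological closing).
binary_dilate <- function(m) {
  out <- m
  out[-1, ] <- out[-1, ] | m[-nrow(m), ]
  out[-nrow(m), ] <- out[-nrow(m), ] | m[-1, ]
  out2 <- out
  out2[, -1] <- out2[, -1] | out[, -ncol(out)]
  out2[, -ncol(out)] <- out2[, -ncol(out)] | out[, -1]
  out2
}
binary_erode <- function(m) !binary_dilate(!m)
binary_close <- function(m, r = 1L) {
  if (r < 1L) return(m)
  for (i in seq_len(r)) m <- binary_dilate(m)
  for (i in seq_len(r)) m <- binary_erode(m)
  m
}

#' Rasterise cells into domain masks and a biomass density field
#'
#' Marks every above-agar grid cell touched by a rod (sampled along its
#' segment at half-grid resolution), applies a morphological closing to yield
#' a coarse-grained smoothed colony region, and converts occupied cell area to
#' a biomass density `rho = rho_cell * min(1, occupied fraction)` (gdw/L,
#' nonzero only in the colony region). Grid cells below z = 0 are agar; the
#' rest is air.
#'
#' @param cells a `cell_table` (may be empty).
#' @param grid a [make_grid()] grid.
#' @param p a [colony_params()] set.
#' @return object of class `domain_masks`: list with integer matrix `region`
#'   (0 = air, 1 = colony, 2 = agar), numeric matrix `rho`, and the `grid`.
#' @export
build_masks <- function(cells, grid, p) {
  region <- matrix(REGION_AIR, grid$nx, grid$nz)
  region[, grid$z < 0] <- REGION_AGAR
  occ <- matrix(FALSE, grid$nx, grid$nz)
  area <- matrix(0, grid$nx, grid$nz)
  if (nrow(cells)) {
    half_w <- grid$nx * grid$h / 2
    if (any(abs(cells$x) > half_w) || any(cells$z > max(grid$z) + grid$h / 2))
      stop("cell outside computational domain")
    # sample every rod at half-grid resolution (plus its exact centre),
    # all cells at once
    npt <- pmax(2L, as.integer(ceiling(cells$length / (grid$h / 2))) + 1L)
    cid <- c(rep.int(seq_len(nrow(cells)), npt), seq_len(nrow(cells)))
    frac <- c(unlist(lapply(npt, function(k) seq(-0.5, 0.5, length.out = k)),
                     use.names = FALSE), rep(0, nrow(cells)))
    px <- cells$x[cid] + frac * cells$length[cid] * cos(cells$angle[cid])
    pz <- cells$z[cid] + frac * cells$length[cid] * sin(cells$angle[cid])
    keep <- pz > 0                         # colony lives above the agar surface
    cid <- cid[keep]; px <- px[keep]; pz <- pz[keep]
    if (length(cid)) {
      ix <- pmin(grid$nx, pmax(1L, as.integer(floor((px + half_w) / grid$h)) + 1L))
      iz <- pmin(grid$nz, pmax(1L, as.integer(floor(pz / grid$h)) +
                                 sum(grid$z < 0) + 1L))
      li <- ix + (iz - 1L) * grid$nx
      occ[unique(li)] <- TRUE
      cell_area <- 2 * p$r0 * cells$length + pi * p$r0^2
      wt <- (cell_area / tabulate(cid, nbins = nrow(cells)))[cid]
      acc <- rowsum(wt, li)
      area[as.integer(rownames(acc))] <- acc[, 1]
    }
  }
  colony <- binary_close(occ, as.integer(p$closing_radius))
  colony[, grid$z < 0] <- FALSE
  region[colony] <- REGION_COLONY
  rho <- matrix(0, grid$nx, grid$nz)
  rho[colony] <- p$rho_cell * pmin(1, area[colony] / grid$h^2)
  structure(list(region = region, rho = rho, grid = grid),
            class = "domain_masks")
}

#' Enumerate interface and boundary faces of the domain masks
#'
#' Classifies every face separating two grid cells (or a grid cell and the
#' domain edge): `g12` agar-colony interface, `g01` colony-air surface, `g02`
#' agar-air surface, `gs` side walls, `gb` agar bottom.
#'
#' @param masks a [build_masks()] object.
#' @return data.frame with columns `ix`, `iz` (the colony/agar cell adjacent
#'   to the face), `side` (`"x-", "x+", "z-", "z+"`) and `type`.
#' @export
interface_faces <- function(masks) {
  r <- masks$region
  nx <- nrow(r); nz <- ncol(r)
  out <- list()
  add <- function(ix, iz, side, type) {
    if (length(type) && length(ix) && length(iz))
      out[[length(out) + 1L]] <<- data.frame(ix = ix, iz = iz, side = side,
                                             type = type)
  }
  pair_type <- function(a, b) {
    t <- rep(NA_character_, length(a))
    t[a == REGION_AGAR & b == REGION_COLONY] <- "g12"
    t[a == REGION_COLONY & b == REGION_AGAR] <- "g12"
    t[a == REGION_COLONY & b == REGION_AIR] <- "g01"
    t[a == REGION_AGAR & b == REGION_AIR] <- "g02"
    t
  }
  # z-direction faces between (ix, iz) and (ix, iz + 1)
  for (iz in seq_len(nz - 1L)) {
    a <- r[, iz]; b <- r[, iz + 1L]
    t <- pair_type(a, b)
    add(which(!is.na(t)), iz, "z+", t[!is.na(t)])
  }
  # x-direction faces
  for (ix in seq_len(nx - 1L)) {
    a <- r[ix, ]; b <- r[ix + 1L, ]
    t <- pair_type(a, b)
    add(ix, which(!is.na(t)), "x+", t[!is.na(t)])
  }
  # domain edges
  add(which(r[, 1L] != REGION_AIR), 1L, "z-", "gb")
  act <- r[1L, ] != REGION_AIR
  add(1L, which(act), "x-", "gs")
  act <- r[nx, ] != REGION_AIR
  add(nx, which(act), "x+", "gs")
  if (length(out)) do.call(rbind, out)
  else data.frame(ix = integer(), iz = integer(), side = character(),
                  type = character())
}
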