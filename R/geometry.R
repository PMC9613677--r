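# Monolayer cell-array geometry: construction, boron assignment, region
# lookup and boundary distances.
#
# Coordinate convention: the beam travels along -z. z = 0 is the interface
# between the buffer medium and the cell layer; cells occupy z in
# [-tcell, 0), the buffer z in [0, tbuffer), both over the square array
# footprint [-L/2, L/2) x [-L/2, L/2) with L = n * lcell. Everything else
# inside the ambient sphere of radius airad is air. All boxes are half-open
# [min, max) on every axis so each face has a unique owner.
#
# Region ids: 0 escaped (outside the ambient sphere), 1 ambient air,
# 2 buffer, 2 + k cytoplasm of cell k, 2 + n^2 + k nucleus of cell k, with
# k = iy * n + ix + 1 (row-major, 0-based column ix along x, row iy along
# y).

#' Assign per-cell boron flags
#'
#' Draws one uniform(0,1) number per cell in row-major order from the
#' current R random stream and, in mode `cytob = 2`, flags the cell as
#' boron-filled when the draw is below `bthresh` (default 0.5). Modes 0 and
#' 1 return all-zero / all-one flags; the draws are consumed in every mode
#' so that runs differing only in the boron mode keep their downstream
#' random streams aligned (common random numbers).
#'
#' @param config a `pbft_config`.
#' @return integer vector of `n^2` borcheck flags (0/1), row-major.
#' @export
assign_boron <- function(config) {
  stopifnot(inherits(config, "pbft_config"))
  u <- runif(config$n^2)
  switch(as.character(config$cytob),
         "0" = integer(config$n^2),
         "1" = rep(1L, config$n^2),
         "2" = as.integer(u < config$bthresh))
}

#' Build the cell-array geometry
#'
#' Constructs the `n x n` monolayer of rectangular-parallelepiped cells at
#' 100% confluence (shared faces, no gaps), each holding a centred cubic
#' nucleus, below the buffer slab and inside the ambient air sphere. The
#' array is centred on the beam axis (x = y = 0). Boron flags follow the
#' configured cytoplasm mode; a nucleus is boron-loaded only when
#' `nuclb = 1` and its own cell's cytoplasm carries boron.
#'
#' @param config a `pbft_config`.
#' @param borcheck optional pre-drawn flags from [assign_boron()]; when
#'   `NULL` the generator seeds the R stream with `config$seed` and draws
#'   them itself, so a standalone call reproduces the layout used inside
#'   [run_simulation()].
#' @return an object of class `pbft_geometry`.
#' @export
build_geometry <- function(config, borcheck = NULL) {
  validate_config(config)
  n <- config$n
  if (is.null(borcheck)) {
    set.seed(config$seed)
    borcheck <- assign_boron(config)
  }
  if (length(borcheck) != n^2 || !all(borcheck %in% 0:1)) {
    stop("borcheck must hold n^2 flags in {0, 1}")
  }
  borcheck <- as.integer(borcheck)
  structure(list(
    config = config,
    n = n, lcell = config$lcell, tcell = config$tcell, lnuc = config$lnuc,
    L = n * config$lcell, tbuffer = config$tbuffer,
    airad_um = config$airad * 1e4,
    borcheck = borcheck,
    nucb = as.integer(borcheck & config$nuclb)
  ), class = "pbft_geometry")
}

#' @export
print.pbft_geometry <- function(x, ...) {
  cat(sprintf(
    "<pbft_geometry> %d x %d cells (%d regions), %g um cells / %g um nuclei\n",
    x$n, x$n, 2 * x$n^2, x$lcell, x$lnuc))
  cat(sprintf("  footprint [%g, %g) um, buffer %g um, ambient %g cm\n",
              -x$L / 2, x$L / 2, x$tbuffer, x$airad_um / 1e4))
  cat(sprintf("  boron cells: %d of %d\n", sum(x$borcheck), x$n^2))
  invisible(x)
}

#' Region table of a geometry
#'
#' One row per region: the ambient sphere, the buffer slab and the
#' cytoplasm and nucleus of every cell with its half-open box bounds (um)
#' and boron flag.
#'
#' @param geometry a `pbft_geometry`.
#' @return data frame with columns `id`, `domain`, `ix`, `iy`, `xmin`,
#'   `xmax`, `ymin`, `ymax`, `zmin`, `zmax`, `borcheck`, `material`.
#' @export
region_table <- function(geometry) {
  g <- geometry
  n <- g$n
  k <- seq_len(n^2)
  ix <- (k - 1) %% n
  iy <- (k - 1) %/% n
  xc <- -g$L / 2 + (ix + 0.5) * g$lcell
  yc <- -g$L / 2 + (iy + 0.5) * g$lcell
  zc <- -g$tcell / 2
  cyto <- data.frame(
    id = 2L + k, domain = "cytoplasm", ix = ix, iy = iy,
    xmin = xc - g$lcell / 2, xmax = xc + g$lcell / 2,
    ymin = yc - g$lcell / 2, ymax = yc + g$lcell / 2,
    zmin = -g$tcell, zmax = 0,
    borcheck = g$borcheck,
    material = ifelse(g$borcheck == 1, "cytoplasm+boron", "cytoplasm")
  )
  nuc <- data.frame(
    id = 2L + n^2 + k, domain = "nucleus", ix = ix, iy = iy,
    xmin = xc - g$lnuc / 2, xmax = xc + g$lnuc / 2,
    ymin = yc - g$lnuc / 2, ymax = yc + g$lnuc / 2,
    zmin = zc - g$lnuc / 2, zmax = zc + g$lnuc / 2,
    borcheck = g$nucb,
    material = ifelse(g$nucb == 1, "nucleus+boron", "nucleus")
  )
  head <- data.frame(
    id = c(1L, 2L), domain = c("ambient", "buffer"),
    ix = NA_integer_, iy = NA_integer_,
    xmin = c(-g$airad_um, -g$L / 2), xmax = c(g$airad_um, g$L / 2),
    ymin = c(-g$airad_um, -g$L / 2), ymax = c(g$airad_um, g$L / 2),
    zmin = c(-g$airad_um, 0), zmax = c(g$airad_um, g$tbuffer),
    borcheck = c(0L, as.integer(g$config$watb)),
    material = c("air",
                 if (g$config$watb == 1) "buffer+boron" else "buffer")
  )
  rbind(head, cyto, nuc)
}

# Fast vectorized locator. Returns list(id, mat, cell) where mat indexes the
# run-time material set: 1 air, 2 buffer, 3 normal cytoplasm, 4 boron
# cytoplasm, 5 normal nucleus, 6 boron nucleus; cell is the cell index k (0
# outside the cell layer). id 0 marks points outside the ambient sphere.
.geo_locate <- function(g, x, y, z) {
  m <- length(x)
  id <- integer(m)
  mat <- integer(m)
  cell <- integer(m)
  inside <- (x * x + y * y + z * z) < g$airad_um^2
  id[inside] <- 1L
  mat[inside] <- 1L
  half <- g$L / 2
  foot <- inside & x >= -half & x < half & y >= -half & y < half
  buf <- foot & z >= 0 & z < g$tbuffer
  id[buf] <- 2L
  mat[buf] <- 2L
  lay <- foot & z >= -g$tcell & z < 0
  if (any(lay)) {
    xi <- x[lay]; yi <- y[lay]; zi <- z[lay]
    ix <- pmin.int(floor((xi + half) / g$lcell), g$n - 1)
    iy <- pmin.int(floor((yi + half) / g$lcell), g$n - 1)
    k <- as.integer(iy * g$n + ix + 1)
    dx <- xi - (-half + (ix + 0.5) * g$lcell)
    dy <- yi - (-half + (iy + 0.5) * g$lcell)
    dz <- zi + g$tcell / 2
    h <- g$lnuc / 2
    nuc <- dx >= -h & dx < h & dy >= -h & dy < h & dz >= -h & dz < h
    idl <- ifelse(nuc, 2L + g$n^2 + k, 2L + k)
    matl <- ifelse(nuc, 5L + g$nucb[k], 3L + g$borcheck[k])
    id[lay] <- idl
    mat[lay] <- as.integer(matl)
    cell[lay] <- k
  }
  list(id = id, mat = mat, cell = cell)
}

#' Locate points in the geometry
#'
#' Maps points (um) to the unique region owning them under the half-open
#' box convention (each box owns its lower-coordinate faces). Points
#' outside the ambient sphere get the `"escaped"` sentinel (id 0).
#'
#' @param geometry a `pbft_geometry`.
#' @param point numeric length-3 vector or an m x 3 matrix of coordinates
#'   in um.
#' @return data frame with columns `id`, `domain`, `cell` (cell index, NA
#'   outside the cell layer).
#' @export
locate_region <- function(geometry, point) {
  stopifnot(inherits(geometry, "pbft_geometry"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (ncol(p) != 3) stop("point must have 3 columns (x, y, z in um)")
  loc <- .geo_locate(geometry, p[, 1], p[, 2], p[, 3])
  domain <- c("escaped", "ambient", "buffer")[pmin.int(loc$id, 2L) + 1L]
  domain[loc$id > 2L + geometry$n^2] <- "nucleus"
  domain[loc$id > 2L & loc$id <= 2L + geometry$n^2] <- "cytoplasm"
  data.frame(id = loc$id, domain = domain,
             cell = ifelse(loc$cell > 0L, loc$cell, NA_integer_))
}

# -- ray helpers (vectorized; distances in um, directions unit) -----------

# exit distance from an axis-aligned box for points inside it
.ray_box_exit <- function(px, py, pz, dx, dy, dz, x0, x1, y0, y1, z0, z1) {
  tx <- ifelse(dx > 0, (x1 - px) / dx, ifelse(dx < 0, (x0 - px) / dx, Inf))
  ty <- ifelse(dy > 0, (y1 - py) / dy, ifelse(dy < 0, (y0 - py) / dy, Inf))
  tz <- ifelse(dz > 0, (z1 - pz) / dz, ifelse(dz < 0, (z0 - pz) / dz, Inf))
  pmax(pmin(tx, ty, tz), 0)
}

# entry distance into an axis-aligned box for points outside it (Inf: miss)
.ray_box_entry <- function(px, py, pz, dx, dy, dz, x0, x1, y0, y1, z0, z1) {
  slab <- function(p, d, lo, hi) {
    t1 <- (lo - p) / d
    t2 <- (hi - p) / d
    tlo <- pmin(t1, t2)
    thi <- pmax(t1, t2)
    par <- d == 0
    ins <- p >= lo & p < hi
    tlo[par] <- ifelse(ins[par], -Inf, Inf)
    thi[par] <- ifelse(ins[par], Inf, -Inf)
    list(lo = tlo, hi = thi)
  }
  sx <- slab(px, dx, x0, x1)
  sy <- slab(py, dy, y0, y1)
  sz <- slab(pz, dz, z0, z1)
  tin <- pmax(sx$lo, sy$lo, sz$lo)
  tout <- pmin(sx$hi, sy$hi, sz$hi)
  ifelse(tout > tin & tin > 0, tin, Inf)
}

# exit distance from the ambient sphere (points inside)
.ray_sphere_exit <- function(px, py, pz, dx, dy, dz, R) {
  b <- px * dx + py * dy + pz * dz
  cc <- px * px + py * py + pz * pz - R * R
  disc <- pmax(b * b - cc, 0)
  pmax(-b + sqrt(disc), 0)
}

# Distance to the next region boundary along the flight direction, given
# the locator output. Vectorized companion of .geo_locate.
.geo_boundary_distance <- function(g, px, py, pz, dx, dy, dz, loc) {
  m <- length(px)
  t_out <- numeric(m)
  half <- g$L / 2
  id <- loc$id
  amb <- id == 1L
  if (any(amb)) {
    ts <- .ray_sphere_exit(px[amb], py[amb], pz[amb], dx[amb], dy[amb],
                           dz[amb], g$airad_um)
    tb <- .ray_box_entry(px[amb], py[amb], pz[amb], dx[amb], dy[amb],
                         dz[amb], -half, half, -half, half, -g$tcell,
                         g$tbuffer)
    t_out[amb] <- pmin(ts, tb)
  }
  buf <- id == 2L
  if (any(buf)) {
    t_out[buf] <- .ray_box_exit(px[buf], py[buf], pz[buf], dx[buf], dy[buf],
                                dz[buf], -half, half, -half, half, 0,
                                g$tbuffer)
  }
  cel <- id > 2L
  if (any(cel)) {
    k <- loc$cell[cel]
    ix <- (k - 1) %% g$n
    iy <- (k - 1) %/% g$n
    xc <- -half + (ix + 0.5) * g$lcell
    yc <- -half + (iy + 0.5) * g$lcell
    zc <- -g$tcell / 2
    h <- g$lnuc / 2
    in_nuc <- id[cel] > 2L + g$n^2
    tt <- numeric(sum(cel))
    pxc <- px[cel]; pyc <- py[cel]; pzc <- pz[cel]
    dxc <- dx[cel]; dyc <- dy[cel]; dzc <- dz[cel]
    if (any(in_nuc)) {
      i <- in_nuc
      tt[i] <- .ray_box_exit(pxc[i], pyc[i], pzc[i], dxc[i], dyc[i], dzc[i],
                             xc[i] - h, xc[i] + h, yc[i] - h, yc[i] + h,
                             zc - h, zc + h)
    }
    if (any(!in_nuc)) {
      i <- !in_nuc
      t_cell <- .ray_box_exit(pxc[i], pyc[i], pzc[i], dxc[i], dyc[i], dzc[i],
                              xc[i] - g$lcell / 2, xc[i] + g$lcell / 2,
                              yc[i] - g$lcell / 2, yc[i] + g$lcell / 2,
                              -g$tcell, 0)
      t_nuc <- .ray_box_entry(pxc[i], pyc[i], pzc[i], dxc[i], dyc[i], dzc[i],
                              xc[i] - h, xc[i] + h, yc[i] - h, yc[i] + h,
                              zc - h, zc + h)
      tt[i] <- pmin(t_cell, t_nuc)
    }
    t_out[cel] <- tt
  }
  t_out
}

#' Render the boron layout as a character grid
#'
#' One glyph per cell: `.` normal cytoplasm, `B` boron-filled cytoplasm
#' with boron-filled nucleus, `b` boron-filled cytoplasm with normal
#' nucleus (i.e. `nuclb = 0`). Rows run from high y (top) to low y,
#' matching a beam's-eye view.
#'
#' @param geometry a `pbft_geometry`.
#' @return an `n x n` character matrix of class `pbft_boron_grid`.
#' @export
render_boron_grid <- function(geometry) {
  stopifnot(inherits(geometry, "pbft_geometry"))
  g <- geometry
  glyph <- ifelse(g$borcheck == 1, ifelse(g$nucb == 1, "B", "b"), ".")
  m <- matrix(glyph, nrow = g$n, ncol = g$n, byrow = TRUE)  # rows = iy
  m <- m[rev(seq_len(g$n)), , drop = FALSE]                 # top row = max y
  structure(m, class = c("pbft_boron_grid", "matrix"))
}

#' @export
print.pbft_boron_grid <- function(x, ...) {
  apply(unclass(x), 1, function(r) cat(paste(r, collapse = " "), "\n"))
  invisible(x)
}

#' Plot the boron layout
#'
#' Image view of the boron grid (base graphics): normal cells light, boron
#' cells dark.
#'
#' @param x a `pbft_geometry`.
#' @param ... passed to [graphics::image()].
#' @export
plot.pbft_geometry <- function(x, ...) {
  z <- matrix(x$borcheck, nrow = x$n)  # ix rows (x), iy cols (y)
  graphics::image(seq_len(x$n), seq_len(x$n), z, zlim = c(0, 1),
                  col = c("#7799dd", "#ffcc55"), xlab = "cell column (x)",
                  ylab = "cell row (y)", ...)
}

#' Export the geometry region list as JSON
#'
#' @param geometry a `pbft_geometry`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @export
geometry_to_json <- function(geometry, path = NULL) {
  tab <- region_table(geometry)
  js <- jsonlite::toJSON(tab, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
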