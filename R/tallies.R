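# Derived statistics: axial profiles, total alpha dose, enhancement
# factors, energy-deposition fractions, hit counts and track maps.
# Everything is normalized per primary source particle, so no explicit
# fluence determination is needed; uncertainties are standard errors over
# batches.

.cell_region_ids <- function(res) {
  seq(3L, res$n_regions)
}

.nucleus_region_ids <- function(res) {
  n2 <- res$config$n^2
  seq(3L + n2, res$n_regions)
}

# per-batch total deposition (MeV per source particle) for a species over
# a set of regions
.batch_totals <- function(res, species, regions) {
  colSums(res$dep[regions, species, , drop = FALSE], dims = 2) /
    res$config$maxcas
}

#' Total alpha energy deposition in the cell array
#'
#' @param res a `pbft_result`.
#' @param domain `"cells"` (default), `"nucleus"`, `"cytoplasm"` or
#'   `"buffer"`.
#' @return list with `mean`, `se` (MeV per source particle) and the
#'   per-batch vector `batches`.
#' @export
total_alpha_dose <- function(res, domain = c("cells", "nucleus",
                                             "cytoplasm", "buffer")) {
  stopifnot(inherits(res, "pbft_result"))
  domain <- match.arg(domain)
  regions <- switch(domain,
                    cells = .cell_region_ids(res),
                    nucleus = .nucleus_region_ids(res),
                    cytoplasm = setdiff(.cell_region_ids(res),
                                        .nucleus_region_ids(res)),
                    buffer = 2L)
  b <- .batch_totals(res, "alpha", regions)
  list(mean = mean(b), se = stats::sd(b) / sqrt(length(b)), batches = b)
}

#' Axial alpha energy-deposition profile across the cell layer
#'
#' Depth runs from 0 (top surface of the cell array, under the buffer) to
#' `-tcell` (bottom). The per-bin standard error comes from the batch
#' scatter; with a single batch the profile is returned with `se = NA` and
#' a warning.
#'
#' @param res a `pbft_result`.
#' @return data frame with columns `depth_um` (bin midpoints, negative
#'   into the layer), `dose` (MeV per source particle per bin), `se`.
#' @export
axial_profile <- function(res) {
  stopifnot(inherits(res, "pbft_result"))
  m <- res$axial_cell / res$config$maxcas  # nbins x nbatch
  nb <- ncol(m)
  mean_d <- rowMeans(m)
  if (nb < 2) {
    warning("single batch: axial profile has no uncertainty estimate")
    se <- rep(NA_real_, nrow(m))
  } else {
    se <- apply(m, 1, stats::sd) / sqrt(nb)
  }
  bw <- res$opts$bw_cell
  data.frame(depth_um = -(seq_len(nrow(m)) - 0.5) * bw,
             dose = mean_d, se = se)
}

#' Depth-dose profile in the buffer medium
#'
#' @param res a `pbft_result`.
#' @param species `"proton"` or `"alpha"`.
#' @return data frame with `depth_um` (measured downward from the buffer
#'   top, where the beam enters), `dose`, `se`.
#' @export
buffer_depth_dose <- function(res, species = c("proton", "alpha")) {
  stopifnot(inherits(res, "pbft_result"))
  species <- match.arg(species)
  m <- res$axial_buffer[, species, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = res$config$maxbch)
  m <- m / res$config$maxcas
  nb <- ncol(m)
  bw <- res$opts$bw_buffer
  # bin i covers z in [(i-1) bw, i bw); depth from top = tbuffer - z
  data.frame(depth_um = res$config$tbuffer -
               (seq_len(nrow(m)) - 0.5) * bw,
             dose = rowMeans(m),
             se = if (nb > 1) apply(m, 1, stats::sd) / sqrt(nb) else
               NA_real_)
}

#' Alpha hit counts
#'
#' A hit is one (alpha track, subdomain) pair: a track scores one hit in
#' every cell nucleus or cytoplasm it enters or is born in, regardless of
#' how many segments it leaves there. Counts are aggregated over all cells
#' into nucleus and cytoplasm totals.
#'
#' @param x a `pbft_result`, or a data frame of track segments with
#'   columns `x0..z1` and `track` (then `geometry` is required and hits are
#'   recomputed by walking the segments through the geometry).
#' @param geometry a `pbft_geometry` (segment-input form only).
#' @param step sampling step along segments, um (segment-input form).
#' @return data frame with one row per batch (or a single row for segment
#'   input): `nucleus`, `cytoplasm` (raw counts) and `nucleus_per_source`,
#'   `cytoplasm_per_source` where the source count is known.
#' @export
count_hits <- function(x, geometry = NULL, step = 0.5) {
  if (inherits(x, "pbft_result")) {
    out <- data.frame(batch = seq_len(ncol(x$hits)),
                      nucleus = x$hits["nucleus", ],
                      cytoplasm = x$hits["cytoplasm", ])
    out$nucleus_per_source <- out$nucleus / x$config$maxcas
    out$cytoplasm_per_source <- out$cytoplasm / x$config$maxcas
    return(out)
  }
  if (is.null(geometry)) {
    stop("segment input needs the geometry")
  }
  segs <- x
  n2 <- geometry$n^2
  pairs <- list()
  for (i in seq_len(nrow(segs))) {
    p0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
    p1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
    len <- sqrt(sum((p1 - p0)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                 p0[2] + tt * (p1[2] - p0[2]),
                 p0[3] + tt * (p1[3] - p0[3]))
    loc <- .geo_locate(geometry, pts[, 1], pts[, 2], pts[, 3])
    ids <- unique(loc$id[loc$id > 2L])
    if (length(ids)) {
      pairs[[length(pairs) + 1L]] <- data.frame(track = segs$track[i],
                                                region = ids)
    }
  }
  if (!length(pairs)) {
    return(data.frame(batch = 1L, nucleus = 0L, cytoplasm = 0L))
  }
  pr <- unique(do.call(rbind, pairs))
  data.frame(batch = 1L,
             nucleus = sum(pr$region > 2L + n2),
             cytoplasm = sum(pr$region <= 2L + n2))
}

#' Summarize hit counts over repeated runs
#'
#' Mirrors the (lower bound, average, upper bound) presentation over k
#' independent runs.
#'
#' @param results list of `pbft_result` objects (independent seeds).
#' @return data frame with rows `nucleus`, `cytoplasm` and columns
#'   `lower`, `average`, `upper` (raw counts summed over batches per run)
#'   plus the per-source-particle equivalents.
#' @export
hit_count_summary <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "pbft_result")))
  per_run <- vapply(results, function(r) {
    c(nucleus = sum(r$hits["nucleus", ]),
      cytoplasm = sum(r$hits["cytoplasm", ]))
  }, c(nucleus = 0, cytoplasm = 0))
  n_src <- vapply(results, function(r) r$config$maxcas * r$config$maxbch, 0)
  out <- data.frame(
    subdomain = c("nucleus", "cytoplasm"),
    lower = apply(per_run, 1, min),
    average = apply(per_run, 1, mean),
    upper = apply(per_run, 1, max))
  out$lower_per_source <- apply(sweep(per_run, 2, n_src, "/"), 1, min)
  out$average_per_source <- apply(sweep(per_run, 2, n_src, "/"), 1, mean)
  out$upper_per_source <- apply(sweep(per_run, 2, n_src, "/"), 1, max)
  out
}

#' Alpha-dose enhancement factor
#'
#' Ratio of total alpha energy deposition in the cell array with boron to
#' the matched run without. `method = "pooled"` (default) divides the
#' batch-mean totals and propagates the batch scatter; `"batchwise"`
#' averages the per-batch ratios (batches with zero denominator are
#' dropped with a flag). Paired seeds make the two runs share common
#' random numbers, so the estimate is stable even at modest statistics.
#'
#' @param boron_res,normal_res `pbft_result`s from paired runs (same
#'   geometry, source and seed; boron on/off).
#' @param method `"pooled"` or `"batchwise"`.
#' @param domain passed to [total_alpha_dose()].
#' @return list with `ef`, `se`, `method` and `flagged` (TRUE when the
#'   denominator vanished somewhere).
#' @export
enhancement_factor <- function(boron_res, normal_res,
                               method = c("pooled", "batchwise"),
                               domain = "cells") {
  method <- match.arg(method)
  b <- total_alpha_dose(boron_res, domain)$batches
  a <- total_alpha_dose(normal_res, domain)$batches
  if (length(b) != length(a)) {
    stop("paired runs must use the same number of batches")
  }
  if (method == "pooled") {
    if (mean(a) == 0) {
      return(list(ef = NA_real_, se = NA_real_, method = method,
                  flagged = TRUE))
    }
    ef <- mean(b) / mean(a)
    # delta-method SE from the batch covariance of the paired totals
    nb <- length(a)
    if (nb > 1) {
      va <- stats::var(a) / nb
      vb <- stats::var(b) / nb
      cab <- stats::cov(a, b) / nb
      se <- abs(ef) * sqrt(max(vb / mean(b)^2 + va / mean(a)^2 -
                                 2 * cab / (mean(a) * mean(b)), 0))
    } else {
      se <- NA_real_
    }
    list(ef = ef, se = se, method = method, flagged = FALSE)
  } else {
    ok <- a > 0
    if (!any(ok)) {
      return(list(ef = NA_real_, se = NA_real_, method = method,
                  flagged = TRUE))
    }
    r <- b[ok] / a[ok]
    list(ef = mean(r),
         se = if (sum(ok) > 1) stats::sd(r) / sqrt(sum(ok)) else NA_real_,
         method = method, flagged = !all(ok))
  }
}

#' Fraction of energy deposition carried by alpha particles
#'
#' `f = D_alpha / (D_alpha + D_proton)` over the cell array and per
#' subdomain. Residual-recoil deposition is excluded from both terms.
#'
#' @param res a `pbft_result`.
#' @return data frame with rows `cells`, `nucleus`, `cytoplasm`: columns
#'   `d_alpha`, `d_proton` (MeV per source particle) and `fraction`
#'   (NA-flagged when the total vanishes).
#' @export
energy_fraction <- function(res) {
  stopifnot(inherits(res, "pbft_result"))
  rows <- list(cells = .cell_region_ids(res),
               nucleus = .nucleus_region_ids(res),
               cytoplasm = setdiff(.cell_region_ids(res),
                                   .nucleus_region_ids(res)))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    da <- mean(.batch_totals(res, "alpha", rows[[nm]]))
    dp <- mean(.batch_totals(res, "proton", rows[[nm]]))
    data.frame(domain = nm, d_alpha = da, d_proton = dp,
               fraction = if (da + dp > 0) da / (da + dp) else NA_real_)
  }))
  out
}

#' Beam's-eye track density map
#'
#' Rasterizes the stored track segments into an x-y (beam's-eye) density
#' grid per species. Requires `store_tracks = TRUE` in
#' [run_simulation()].
#'
#' @param res a `pbft_result` with stored segments, or a segment data
#'   frame.
#' @param resolution pixel size, um.
#' @param half_width half-width of the map, um (default: the array
#'   half-side plus one cell).
#' @return list of matrices (one per species present) with attributes
#'   `resolution` and `extent`; pixel value = summed track length in the
#'   pixel, um.
#' @export
track_map <- function(res, resolution = 5, half_width = NULL) {
  segs <- if (inherits(res, "pbft_result")) {
    if (is.null(res$segments)) {
      stop("no stored segments: rerun with store_tracks = TRUE")
    }
    res$segments
  } else {
    res
  }
  if (is.null(half_width)) {
    half_width <- if (inherits(res, "pbft_result")) {
      res$geometry$L / 2 + res$geometry$lcell
    } else {
      max(abs(c(segs$x0, segs$x1, segs$y0, segs$y1)))
    }
  }
  npix <- max(1L, ceiling(2 * half_width / resolution))
  out <- list()
  for (sp in unique(segs$species)) {
    s <- segs[segs$species == sp, ]
    len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 + (s$z1 - s$z0)^2)
    # subdivide along the transverse projection only: the raster is a
    # beam's-eye (x-y) view, so an axial segment is a single pixel however
    # long it is
    len_xy <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
    nsub <- pmin(pmax(1L, ceiling(len_xy / (resolution / 2))), 20000L)
    idx <- rep(seq_len(nrow(s)), nsub)
    tt <- (sequence(nsub) - 0.5) / rep(nsub, nsub)
    xs <- s$x0[idx] + tt * (s$x1[idx] - s$x0[idx])
    ys <- s$y0[idx] + tt * (s$y1[idx] - s$y0[idx])
    w <- (len / nsub)[idx]
    ix <- floor((xs + half_width) / resolution) + 1L
    iy <- floor((ys + half_width) / resolution) + 1L
    keep <- ix >= 1L & ix <= npix & iy >= 1L & iy <= npix
    m <- matrix(0, npix, npix)
    if (any(keep)) {
      key <- ix[keep] + (iy[keep] - 1L) * npix
      tabw <- rowsum(w[keep], key)
      m[as.integer(rownames(tabw))] <- tabw
    }
    attr(m, "resolution") <- resolution
    attr(m, "extent") <- c(-half_width, half_width)
    out[[sp]] <- m
  }
  out
}
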