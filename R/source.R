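# Proton source models: monoenergetic disk beam and spread-out Bragg peak.

#' Create a monoenergetic disk source
#'
#' Protons start uniformly over a disk of radius `r0` at the top of the
#' buffer, travelling along -z.
#'
#' @param e0 kinetic energy, MeV.
#' @param r0 disk radius, mm (default 0.30 mm, half the default array side).
#' @return an object of class `pbft_source`.
#' @export
source_model <- function(e0, r0 = 0.3) {
  stopifnot(is.numeric(e0), length(e0) == 1L, e0 > 0, r0 > 0)
  structure(list(kind = "mono", energies = e0, weights = 1, r0_mm = r0),
            class = "pbft_source")
}

#' Build a spread-out Bragg peak source
#'
#' Chooses `nsobp` beam energies whose CSDA ranges in `medium` are equally
#' spaced over the modulation interval `[prox_frac * R(E_max), R(E_max)]`
#' and solves a non-negative least-squares problem for the weights that
#' flatten the summed depth-dose over that interval. The per-beam
#' depth-dose model is the CSDA deposition profile smeared by a Gaussian
#' range-straggling kernel of width `straggling * R` (default 1.2% of the
#' range, the usual magnitude for protons in water); without the smearing a
#' superposition of straggling-free peaks cannot form a plateau.
#'
#' @param e_max maximum (distal) beam energy, MeV.
#' @param nsobp number of energy points (>= 1; 1 degenerates to the
#'   pristine peak).
#' @param medium a `pbft_material` (typically the buffer) in which the SOBP
#'   is shaped.
#' @param r0 disk radius, mm.
#' @param prox_frac proximal edge of the modulated region as a fraction of
#'   the distal range (default 0.75).
#' @param straggling range-straggling width as a fraction of range.
#' @return a `pbft_source` with fields `energies`, `weights`, `depth_cm`,
#'   `dose` (summed normalized depth-dose), `modulation_cm` and `flatness`
#'   (max relative deviation from the plateau mean). A warning is issued
#'   when the plateau cannot be flattened to 5%.
#' @export
build_sobp <- function(e_max, nsobp, medium, r0 = 0.3, prox_frac = 0.75,
                       straggling = 0.012) {
  stopifnot(inherits(medium, "pbft_material"), e_max > 0, nsobp >= 1)
  rho <- medium$density
  r_max <- csda_range(medium, "proton", e_max)   # g/cm^2
  if (nsobp == 1) {
    src <- source_model(e_max, r0)
    src$kind <- "sobp"
    src$modulation_cm <- rep(r_max / rho, 2)
    return(src)
  }
  r_prox <- prox_frac * r_max
  ranges <- seq(r_prox, r_max, length.out = nsobp)
  energies <- .energy_from_range(medium, "proton", ranges)
  energies[nsobp] <- e_max
  # depth grid (g/cm^2) fine enough to resolve the straggling width
  dz <- straggling * r_prox / 4
  z <- seq(0, r_max * 1.08, by = dz)
  nb <- length(z) - 1
  zmid <- (z[-1] + z[-length(z)]) / 2
  # per-beam binned CSDA deposit, then Gaussian range smearing
  curves <- sapply(seq_len(nsobp), function(k) {
    e_res <- .energy_from_range(medium, "proton", pmax(ranges[k] - z, 0))
    dep <- pmax(e_res[-length(e_res)] - e_res[-1], 0)  # MeV per bin
    sd_k <- straggling * ranges[k]
    kern_half <- ceiling(4 * sd_k / dz)
    kern <- stats::dnorm(seq(-kern_half, kern_half) * dz, sd = sd_k)
    kern <- kern / sum(kern)
    stats::filter(c(numeric(kern_half), dep, numeric(kern_half)), kern,
                  sides = 2)[kern_half + seq_len(nb)]
  })
  curves[is.na(curves)] <- 0
  # flatten over the interior of the modulated region
  sel <- zmid >= r_prox & zmid <= r_max - 2 * straggling * r_max
  a <- curves[sel, , drop = FALSE]
  target <- rep(mean(a) * nsobp, sum(sel))
  w <- pracma::lsqnonneg(a, target)$x
  if (sum(w) <= 0) stop("SOBP weight optimization failed")
  dose <- as.numeric(curves %*% w)
  plateau <- dose[sel]
  flatness <- max(abs(plateau - mean(plateau))) / mean(plateau)
  if (flatness > 0.05) {
    warning(sprintf(
      "SOBP plateau variation %.1f%% exceeds 5%%; increase nsobp",
      100 * flatness))
  }
  w <- w / sum(w)
  structure(list(kind = "sobp", energies = energies, weights = w,
                 r0_mm = r0, depth_cm = zmid / rho, dose = dose,
                 modulation_cm = c(r_prox, r_max) / rho,
                 flatness = flatness),
            class = "pbft_source")
}

#' @export
print.pbft_source <- function(x, ...) {
  if (x$kind == "mono") {
    cat(sprintf("<pbft_source> monoenergetic %g MeV, disk r0 = %g mm\n",
                x$energies, x$r0_mm))
  } else {
    cat(sprintf(
      "<pbft_source> SOBP: %d beams %.2f-%.2f MeV, modulation %.2f-%.2f cm, plateau within %.1f%%\n",
      length(x$energies), min(x$energies), max(x$energies),
      x$modulation_cm[1], x$modulation_cm[2],
      100 * (x$flatness %||% 0)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample source protons
#'
#' Draws `n` protons: positions uniform over the source disk at the top of
#' the buffer, direction (0, 0, -1), energies from the (possibly weighted
#' SOBP) spectrum. Consumes exactly 3 uniforms per particle from the
#' current R stream regardless of source kind, keeping paired runs
#' stream-aligned.
#'
#' @param source a `pbft_source`.
#' @param n number of protons.
#' @param z_top starting z, um (top of the buffer).
#' @return data frame with columns `x`, `y`, `z` (um), `dx`, `dy`, `dz`,
#'   `E` (MeV).
#' @export
sample_source <- function(source, n, z_top) {
  stopifnot(inherits(source, "pbft_source"))
  r_um <- source$r0_mm * 1e3 * sqrt(runif(n))
  th <- 2 * pi * runif(n)
  ue <- runif(n)
  e <- if (length(source$energies) == 1L) {
    rep(source$energies, n)
  } else {
    cw <- cumsum(source$weights) / sum(source$weights)
    source$energies[findInterval(ue, cw, rightmost.closed = TRUE) + 1L]
  }
  data.frame(x = r_um * cos(th), y = r_um * sin(th),
             z = rep(z_top, n), dx = 0, dy = 0, dz = -1, E = e)
}

#' Plot an SOBP depth-dose profile
#'
#' @param x a `pbft_source` built by [build_sobp()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.pbft_source <- function(x, ...) {
  if (x$kind != "sobp" || is.null(x$dose)) {
    stop("plot is available for SOBP sources built by build_sobp()")
  }
  graphics::plot(x$depth_cm, x$dose / max(x$dose), type = "l",
                 xlab = "depth in buffer (cm)", ylab = "relative dose", ...)
  graphics::abline(v = x$modulation_cm, lty = 3)
}
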