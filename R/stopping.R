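# Electronic stopping powers and CSDA ranges for protons and alphas.
#
# Model: first-order Bethe formula without shell or density-effect
# corrections, combined over elements by Bragg additivity on the mass
# stopping power. Below 1 MeV per nucleon each elemental term is continued
# by a power law matched in value and logarithmic slope at 1 MeV/u, which
# keeps S(E) positive, continuous and monotone down to the transport
# cutoffs. Ranges are continuous-slowing-down path integrals of 1/S,
# tabulated once per (material, particle) on a dense log grid and inverted
# by interpolation.

.SPECIES <- list(
  proton = list(mass_mev = 938.27208816, z = 1, nucleons = 1),
  alpha  = list(mass_mev = 3727.3794066, z = 2, nucleons = 4)
)

# energy grid bounds (MeV); calls outside are clamped with a warning
.E_DOMAIN <- c(0.005, 300)

# Bethe mass stopping power for one element, no low-energy continuation.
.bethe_element <- function(E, mass_mev, z2, Z, A, I_eV) {
  b2g2 <- E * (E + 2 * mass_mev) / mass_mev^2
  beta2 <- b2g2 / (1 + b2g2)
  L <- log(2 * .MEC2_MEV * 1e6 * b2g2 / I_eV) - beta2
  .K_BETHE * z2 * (Z / A) / beta2 * L
}

# Elemental mass stopping power with matched power-law continuation below
# 1 MeV/u. Vectorized over E.
.stopping_element <- function(E, species, Z, A, I_eV) {
  sp <- .SPECIES[[species]]
  z2 <- sp$z^2
  e_lo <- sp$nucleons * 1.0  # 1 MeV per nucleon
  s <- numeric(length(E))
  hi <- E >= e_lo
  if (any(hi)) {
    s[hi] <- .bethe_element(E[hi], sp$mass_mev, z2, Z, A, I_eV)
  }
  if (any(!hi)) {
    s_lo <- .bethe_element(e_lo, sp$mass_mev, z2, Z, A, I_eV)
    # log-slope at the matching point by central difference
    h <- 1e-4
    slope <- (log(.bethe_element(e_lo * (1 + h), sp$mass_mev, z2, Z, A, I_eV)) -
              log(.bethe_element(e_lo * (1 - h), sp$mass_mev, z2, Z, A, I_eV))) /
             (2 * h)
    s[!hi] <- s_lo * (E[!hi] / e_lo)^slope
  }
  s
}

.clamp_energy <- function(E, what) {
  if (any(E < .E_DOMAIN[1] * (1 - 1e-12) | E > .E_DOMAIN[2] * (1 + 1e-12))) {
    warning(what, ": energy outside [", .E_DOMAIN[1], ", ", .E_DOMAIN[2],
            "] MeV clamped to the model domain")
    E <- pmin(pmax(E, .E_DOMAIN[1]), .E_DOMAIN[2])
  }
  E
}

#' Mass stopping power of a material
#'
#' Bragg-additive electronic mass stopping power, MeV cm^2/g. A table
#' attached with [set_stopping_table()] overrides the analytic model for
#' that species (log-log interpolation, clamped at the table ends).
#'
#' @param material a `pbft_material`.
#' @param particle `"proton"` or `"alpha"`.
#' @param E kinetic energy in MeV (vectorized). Values outside the model
#'   domain 0.005--300 MeV are clamped with a warning.
#' @return mass stopping power(s), MeV cm^2/g.
#' @export
stopping_power <- function(material, particle, E) {
  stopifnot(inherits(material, "pbft_material"))
  particle <- match.arg(particle, c("proton", "alpha"))
  E <- .clamp_energy(E, "stopping_power")
  tab <- material$stopping_table[[particle]]
  if (!is.null(tab)) {
    le <- log(pmin(pmax(E, tab$E[1]), tab$E[nrow(tab)]))
    return(exp(stats::approx(log(tab$E), log(tab$S), xout = le,
                             rule = 2)$y))
  }
  s <- numeric(length(E))
  for (el in names(material$fractions)) {
    w <- material$fractions[[el]]
    if (w <= 0) next
    row <- .ELEMENTS[el, ]
    s <- s + w * .stopping_element(E, particle, row$Z, row$A, row$I_eV)
  }
  s
}

# Build (and cache) the range-energy table for a material/particle pair.
# Returns list(E, R, e_of_r, r_of_e) with R in g/cm^2.
.range_table <- function(material, particle) {
  key <- paste(particle, material$density,
               paste(names(material$fractions), material$fractions,
                     collapse = ";"),
               if (!is.null(material$stopping_table[[particle]]))
                 digest_table(material$stopping_table[[particle]]) else "",
               sep = "|")
  hit <- .pbft_cache[[key]]
  if (!is.null(hit)) return(hit)
  E <- exp(seq(log(.E_DOMAIN[1]), log(.E_DOMAIN[2]), length.out = 800))
  S <- stopping_power(material, particle, E)
  # cumulative trapezoid of dE/S; start segment approximated as E_min/S_min
  R <- c(E[1] / S[1] + pracma::cumtrapz(E, 1 / S))
  tab <- list(
    E = E, R = R,
    r_of_e = stats::approxfun(log(E), log(R), rule = 2),
    e_of_r = stats::approxfun(log(R), log(E), rule = 2)
  )
  .pbft_cache[[key]] <- tab
  tab
}

# cheap stable fingerprint for a small numeric table
digest_table <- function(tab) {
  paste(format(unlist(tab), digits = 10), collapse = ",")
}

#' Continuous-slowing-down (CSDA) range
#'
#' Path length `R(E) = integral dE'/S(E')`, in g/cm^2, from a dense
#' tabulation of the stopping power. Divide by the density for a geometric
#' length.
#'
#' @inheritParams stopping_power
#' @return CSDA range(s), g/cm^2.
#' @export
csda_range <- function(material, particle, E) {
  particle <- match.arg(particle, c("proton", "alpha"))
  E <- .clamp_energy(E, "csda_range")
  tab <- .range_table(material, particle)
  exp(tab$r_of_e(log(E)))
}

# Inverse: energy that has residual range r (g/cm^2); r below the table
# start maps to the domain floor (treated as stopped by the caller).
.energy_from_range <- function(material, particle, r) {
  tab <- .range_table(material, particle)
  out <- numeric(length(r))
  pos <- r > tab$R[1]
  out[pos] <- exp(tab$e_of_r(log(r[pos])))
  out[!pos] <- 0
  out
}
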