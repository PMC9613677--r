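# Material compositions, ppm-boron mixing and nuclide number densities.

.BUILTIN_MATERIALS <- list(
  cytoplasm = list(
    density = 1.27,
    fractions = c(H = 0.1064, O = 0.745, C = 0.0904, N = 0.0321, P = 0.0261)
  ),
  nucleus = list(
    density = 1.27,
    fractions = c(H = 0.1064, O = 0.745, C = 0.0904, N = 0.0321, P = 0.0261)
  ),
  buffer = list(
    density = 1.00,
    fractions = c(H = 0.111, O = 0.889)
  ),
  # standard dry air near sea level
  air = list(
    density = 1.205e-3,
    fractions = c(N = 0.7553, O = 0.2318, Ar = 0.0129)
  ),
  # hypothetical pure-hydrogen medium: the null control in which no
  # alpha-producing target nuclide is present
  hydrogen_only = list(
    density = 1.00,
    fractions = c(H = 1.0)
  )
)

#' Create a material composition
#'
#' A material is a set of elemental weight fractions plus a mass density.
#' Fractions are normalized checks only: they must sum to 1 within 1e-9.
#'
#' @param name character label.
#' @param density mass density in g/cm^3 (> 0).
#' @param fractions named numeric vector of elemental weight fractions
#'   (names from `H`, `B`, `C`, `N`, `O`, `P`, `Ar`), summing to 1.
#' @return an object of class `pbft_material`.
#' @export
material <- function(name, density, fractions) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("material '", name, "': density must be a single positive number")
  }
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("material '", name, "': fractions must be a named vector")
  }
  unknown <- setdiff(names(fractions), .ELEMENTS$symbol)
  if (length(unknown)) {
    stop("material '", name, "': unknown element(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(fractions < 0)) {
    stop("material '", name, "': negative weight fraction")
  }
  if (abs(sum(fractions) - 1) >= 1e-9) {
    stop("material '", name, "': weight fractions sum to ",
         format(sum(fractions), digits = 12), ", not 1")
  }
  structure(list(name = name, density = density,
                 fractions = fractions, stopping_table = NULL),
            class = "pbft_material")
}

#' Built-in material compositions
#'
#' Returns one of the embedded compositions: cell `cytoplasm` and `nucleus`
#' (identical: 1.27 g/cm^3; H 10.64%, O 74.5%, C 9.04%, N 3.21%, P 2.61% by
#' weight), the water-like `buffer` medium (1.00 g/cm^3; H 11.1%, O 88.9%),
#' ambient dry `air` (1.205e-3 g/cm^3), and the `hydrogen_only` null-control
#' medium in which protons cannot produce alpha particles.
#'
#' @param name one of `"cytoplasm"`, `"nucleus"`, `"buffer"`, `"air"`,
#'   `"hydrogen_only"`.
#' @return a `pbft_material`.
#' @export
builtin_material <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.BUILTIN_MATERIALS)) {
    stop("unknown material name; choose one of: ",
         paste(names(.BUILTIN_MATERIALS), collapse = ", "))
  }
  m <- .BUILTIN_MATERIALS[[name]]
  material(name, m$density, m$fractions)
}

#' Mix boron into a material at fixed density
#'
#' Adds natural boron at a mass concentration of `ppm` parts per million.
#' The boron weight fraction becomes `ppm * 1e-6`, all base fractions are
#' rescaled by `1 - ppm * 1e-6`, and the density is left unchanged (100 ppm
#' loaded and unloaded cell media share the fixed 1.27 g/cm^3 density; the
#' buffer keeps 1.00 g/cm^3).
#'
#' @param base a `pbft_material`.
#' @param ppm mass parts-per-million of natural boron (>= 0).
#' @return a `pbft_material`; `base` itself when `ppm == 0`.
#' @export
mix_boron <- function(base, ppm) {
  stopifnot(inherits(base, "pbft_material"))
  if (!is.numeric(ppm) || length(ppm) != 1L || !is.finite(ppm) || ppm < 0) {
    stop("ppm must be a single non-negative number")
  }
  if (ppm == 0) return(base)
  wb <- ppm * 1e-6
  if (wb > 1) stop("ppm exceeds 1e6 (pure boron)")
  fr <- base$fractions * (1 - wb)
  fr <- fr[fr > 0 | names(fr) == "B"]
  if (wb == 1) {
    fr <- c(B = 1.0)
  } else if ("B" %in% names(fr)) {
    fr[["B"]] <- fr[["B"]] + wb
  } else {
    fr <- c(fr, B = wb)
  }
  out <- material(paste0(base$name, "+", format(ppm), "ppmB"),
                  base$density, fr)
  out$stopping_table <- base$stopping_table
  out
}

#' Nuclide number densities of a material
#'
#' Converts weight fractions to atom number densities,
#' `N_i = rho * w_i * N_A / A_i` (atoms/cm^3). Natural boron is split
#' 19.9% 10B / 80.1% 11B by atom; only 11B feeds the fusion channel.
#'
#' @param comp a `pbft_material`.
#' @return named numeric vector over nuclides `H1`, `B10`, `B11`, `C12`,
#'   `N14`, `O16`, `P31`, `Ar40` (atoms/cm^3).
#' @export
number_densities <- function(comp) {
  stopifnot(inherits(comp, "pbft_material"))
  out <- setNames(numeric(length(.INVENTORY_NUCLIDES)), .INVENTORY_NUCLIDES)
  for (el in names(comp$fractions)) {
    w <- comp$fractions[[el]]
    if (w <= 0) next
    n_el <- comp$density * w * .AVOGADRO / .ELEMENTS[el, "A"]
    if (el == "B") {
      out[["B10"]] <- out[["B10"]] + n_el * .B10_ATOM_FRACTION
      out[["B11"]] <- out[["B11"]] + n_el * .B11_ATOM_FRACTION
    } else {
      nm <- .ELEMENT_NUCLIDE[[el]]
      out[[nm]] <- out[[nm]] + n_el
    }
  }
  out
}

#' @export
print.pbft_material <- function(x, ...) {
  cat("<pbft_material> ", x$name, "  (", format(x$density), " g/cm^3)\n",
      sep = "")
  fr <- x$fractions[order(-x$fractions)]
  cat(paste0("  ", names(fr), ": ", formatC(100 * fr, format = "g"), "%",
             collapse = "\n"), "\n")
  invisible(x)
}

#' Export a material to JSON
#'
#' Writes `{name, density, fractions}` so users can edit compositions and
#' densities to match their own cell lines and media.
#'
#' @param comp a `pbft_material`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @export
material_to_json <- function(comp, path = NULL) {
  stopifnot(inherits(comp, "pbft_material"))
  obj <- list(name = comp$name, density = comp$density,
              fractions = as.list(comp$fractions))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a material from JSON
#'
#' @param path path to a JSON file produced by [material_to_json()] (or
#'   hand-written in the same `{name, density, fractions}` layout).
#' @return a `pbft_material`.
#' @export
material_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  material(obj$name, obj$density, unlist(obj$fractions))
}

#' Attach a user-supplied stopping-power table to a material
#'
#' Overrides the analytic Bethe model for one particle species with a
#' two-column table, interpolated log-log and integrated for ranges exactly
#' like the built-in model.
#'
#' @param comp a `pbft_material`.
#' @param particle `"proton"` or `"alpha"`.
#' @param table data frame with columns `E` (MeV) and `S` (mass stopping
#'   power, MeV cm^2/g), strictly increasing in `E`, all `S > 0`.
#' @return the material with the override attached.
#' @export
set_stopping_table <- function(comp, particle, table) {
  stopifnot(inherits(comp, "pbft_material"))
  particle <- match.arg(particle, c("proton", "alpha"))
  if (!all(c("E", "S") %in% names(table))) {
    stop("stopping table needs columns 'E' and 'S'")
  }
  if (any(diff(table$E) <= 0) || any(table$S <= 0) || any(table$E <= 0)) {
    stop("stopping table must have strictly increasing E > 0 and S > 0")
  }
  if (is.null(comp$stopping_table)) comp$stopping_table <- list()
  comp$stopping_table[[particle]] <- table[c("E", "S")]
  comp
}
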