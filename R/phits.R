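# PHITS-style input-deck export: the cell-array generator role.
#
# The deck follows PHITS structural conventions (sections, RPP/SPH surface
# cards, MCNP-style negative mass fractions, e-type energy tables) but
# bit-exact parity with any particular generator's formatting is not
# promised; decks are validated structurally.

.PHITS_SECTIONS <- c("Title", "Parameters", "Source", "Material",
                     "Surface", "Cell", "T-Track", "T-Deposit", "T-Gshow")

.mat_card <- function(idx, m) {
  line <- sprintf("mat[%d] $ %s, %.4g g/cm^3", idx, m$name, m$density)
  body <- vapply(names(m$fractions), function(el) {
    sprintf("  %-2s %.6e", el, -m$fractions[[el]])
  }, "")
  c(line, body)
}

#' Export a PHITS-style input deck
#'
#' Emits one RPP surface and one cell card per cytoplasm and nucleus,
#' plus the buffer slab, the ambient sphere and the outer void; materials
#' reflect the per-cell boron flags and ppm loading; the source section
#' carries the disk beam (with an e-type table for SOBP spectra); tally
#' sections cover the cell array. The deck is a pure function of the
#' configuration and seed.
#'
#' @param config a `pbft_config`.
#' @param geometry optional pre-built `pbft_geometry` (rebuilt from the
#'   config seed when `NULL`).
#' @param mset optional `pbft_material_set`.
#' @return a character vector of deck lines, class `pbft_phits_deck`.
#' @export
export_phits_deck <- function(config, geometry = NULL, mset = NULL) {
  validate_config(config)
  if (is.null(geometry)) geometry <- build_geometry(config)
  if (is.null(mset)) mset <- build_material_set(config)
  g <- geometry
  n2 <- g$n^2
  tab <- region_table(g)
  cyto <- tab[tab$domain == "cytoplasm", ]
  nuc <- tab[tab$domain == "nucleus", ]
  src <- if (config$sobp == 1) {
    s <- build_sobp(config$e0, config$nsobp,
                    mset$materials[["buffer"]], r0 = config$r0)
    c("  s-type = 1", "  proj = proton",
      sprintf("  r0 = %.4f", config$r0 / 10),  # cm
      sprintf("  z0 = %.6e", config$tbuffer * 1e-4),
      sprintf("  z1 = %.6e", config$tbuffer * 1e-4),
      "  dir = -1", "  e-type = 1",
      sprintf("  ne = %d", length(s$energies)),
      sprintf("  %.6f %.6e", s$energies, s$weights))
  } else {
    c("  s-type = 1", "  proj = proton",
      sprintf("  r0 = %.4f", config$r0 / 10),
      sprintf("  z0 = %.6e", config$tbuffer * 1e-4),
      sprintf("  z1 = %.6e", config$tbuffer * 1e-4),
      "  dir = -1",
      sprintf("  e0 = %.4f", config$e0))
  }
  # surfaces: 1..n2 cell boxes, n2+1..2n2 nucleus boxes, then buffer, sphere
  um <- 1e-4  # cm per um
  surf <- c(
    sprintf("  %d rpp %.6e %.6e %.6e %.6e %.6e %.6e",
            seq_len(n2), cyto$xmin * um, cyto$xmax * um, cyto$ymin * um,
            cyto$ymax * um, cyto$zmin * um, cyto$zmax * um),
    sprintf("  %d rpp %.6e %.6e %.6e %.6e %.6e %.6e",
            n2 + seq_len(n2), nuc$xmin * um, nuc$xmax * um, nuc$ymin * um,
            nuc$ymax * um, nuc$zmin * um, nuc$zmax * um),
    sprintf("  %d rpp %.6e %.6e %.6e %.6e %.6e %.6e", 2L * n2 + 1L,
            -g$L / 2 * um, g$L / 2 * um, -g$L / 2 * um, g$L / 2 * um,
            0, g$tbuffer * um),
    sprintf("  %d so %.6e", 2L * n2 + 2L, g$airad_um * um)
  )
  # material ids: 1 air, 2 buffer, 3 cyto, 4 cyto+B, 5 nuc, 6 nuc+B
  cyto_mat <- 3L + g$borcheck
  nuc_mat <- 5L + g$nucb
  dens <- mset$density
  cells <- c(
    sprintf("  %d %d -%.6e -%d #%d", seq_len(n2), cyto_mat,
            dens[cyto_mat], seq_len(n2), n2 + seq_len(n2)),
    sprintf("  %d %d -%.6e -%d", n2 + seq_len(n2), nuc_mat,
            dens[nuc_mat], n2 + seq_len(n2)),
    sprintf("  %d 2 -%.6e -%d", 2L * n2 + 1L, dens[2], 2L * n2 + 1L),
    sprintf("  %d 1 -%.6e -%d %s #%d", 2L * n2 + 2L, dens[1],
            2L * n2 + 2L,
            paste0("#", seq_len(n2), collapse = " "), 2L * n2 + 1L),
    sprintf("  %d -1 %d", 2L * n2 + 3L, 2L * n2 + 2L)
  )
  mats <- unlist(lapply(seq_along(mset$materials),
                        function(i) .mat_card(i, mset$materials[[i]])))
  half_cm <- g$L / 2 * um
  tally_mesh <- c(
    "  mesh = xyz",
    sprintf("  x-type = 2 / nx = %d / xmin = %.6e / xmax = %.6e", g$n,
            -half_cm, half_cm),
    sprintf("  y-type = 2 / ny = %d / ymin = %.6e / ymax = %.6e", g$n,
            -half_cm, half_cm),
    sprintf("  z-type = 2 / nz = 30 / zmin = %.6e / zmax = 0",
            -g$tcell * um))
  deck <- c(
    "[Title]",
    sprintf("  PBFT cell array %d x %d, %g MeV, seed %d", g$n, g$n,
            config$e0, config$seed),
    "",
    "[Parameters]",
    "  icntl = 0",
    sprintf("  maxcas = %d", config$maxcas),
    sprintf("  maxbch = %d", config$maxbch),
    sprintf("  $ omp = %d (parallelization metadata)", config$omp),
    "  file(6) = phits.out",
    "",
    "[Source]", src, "",
    "[Material]", mats, "",
    "[Surface]", surf, "",
    "[Cell]", cells, "",
    "[T-Track]", tally_mesh, "  part = proton neutron alpha",
    "  e-type = 2 / ne = 1 / emin = 0 / emax = 1000",
    "  unit = 1", "  file = track.out", "",
    "[T-Deposit]", tally_mesh, "  part = proton neutron alpha",
    "  output = dose", "  unit = 1", "  file = deposit.out", "",
    "[T-Gshow]",
    "  mesh = xyz",
    sprintf("  x-type = 2 / nx = 200 / xmin = %.6e / xmax = %.6e",
            -half_cm, half_cm),
    "  y-type = 1 / ny = 1 / 0 0",
    sprintf("  z-type = 2 / nz = 200 / zmin = %.6e / zmax = %.6e",
            -g$tcell * um, g$tbuffer * um),
    "  file = gshow.out"
  )
  structure(deck, class = "pbft_phits_deck")
}

#' @export
print.pbft_phits_deck <- function(x, n = 40, ...) {
  cat(sprintf("<pbft_phits_deck> %d lines\n", length(x)))
  cat(head(unclass(x), n), sep = "\n")
  if (length(x) > n) cat("  ... (", length(x) - n, " more lines)\n")
  invisible(x)
}

#' Write a deck to file
#'
#' @param deck a `pbft_phits_deck`.
#' @param path output path.
#' @export
write_phits_deck <- function(deck, path) {
  writeLines(unclass(deck), path)
  invisible(path)
}

#' Split a deck into its sections
#'
#' @param deck a `pbft_phits_deck`.
#' @return named list of character vectors, one per section header found.
#' @export
phits_deck_sections <- function(deck) {
  x <- unclass(deck)
  hdr <- grep("^\\[", x)
  nm <- gsub("^\\[|\\]$", "", x[hdr])
  ends <- c(hdr[-1] - 1L, length(x))
  stats::setNames(lapply(seq_along(hdr), function(i)
    x[(hdr[i] + 1L):ends[i]]), nm)
}
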