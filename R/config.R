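# Simulation configuration: the 18 cell-generator user inputs plus the RNG
# seed and the random-boron threshold.

.CONFIG_FIELDS <- c("n", "lcell", "tcell", "lnuc", "tbuffer", "airad",
                    "maxcas", "maxbch", "e0", "sobp", "nsobp", "r0", "ppm",
                    "cytob", "nuclb", "watb", "ppmw", "omp", "seed",
                    "bthresh")

#' Create a simulation configuration
#'
#' Collects the user inputs of the cell-array generator. All lengths follow
#' the generator's units: cell dimensions in micrometres, the ambient air
#' radius in centimetres, the beam radius in millimetres, energies in MeV.
#'
#' @param e0 incident proton kinetic energy, MeV (> 0). Required: the beam
#'   energy defines the irradiation scenario and has no universal default.
#' @param n array edge count; the monolayer holds `n^2` cells.
#' @param lcell cell side length, um.
#' @param tcell cell thickness, um.
#' @param lnuc nucleus side length, um (`lnuc < lcell`, `lnuc <= tcell`);
#'   the cubic nucleus sits at the cell centre.
#' @param tbuffer buffer-medium thickness above the cell layer, um.
#' @param airad ambient air radius, cm (sphere enclosing the whole model).
#' @param maxcas histories per batch (>= 1).
#' @param maxbch number of batches (>= 1).
#' @param sobp SOBP beam option: 0 monoenergetic, 1 spread-out Bragg peak.
#' @param nsobp number of SOBP energy points (>= 2 when `sobp = 1`).
#' @param r0 beam (disk source) radius, mm.
#' @param ppm boron mass concentration in boron-flagged cells, ppm.
#' @param cytob cytoplasm boron mode: 0 normal, 1 all boron, 2 random boron.
#' @param nuclb nucleus boron option (0/1); a nucleus is boron-loaded only
#'   when its own cell's cytoplasm is.
#' @param watb buffer boron option (0/1).
#' @param ppmw boron concentration in the buffer medium, ppm.
#' @param omp parallelization flag; carried as metadata only.
#' @param seed RNG seed making runs and boron layouts reproducible.
#' @param bthresh random-boron acceptance threshold: in mode `cytob = 2` a
#'   cell is boron-filled when its uniform(0,1) draw is below `bthresh`
#'   (default 0.5).
#' @return an object of class `pbft_config`.
#' @export
simulation_config <- function(e0, n = 20, lcell = 30, tcell = 30, lnuc = 10,
                              tbuffer = 1000, airad = 10, maxcas = 10000,
                              maxbch = 10, sobp = 0, nsobp = 25, r0 = 0.3,
                              ppm = 100, cytob = 0, nuclb = 1, watb = 0,
                              ppmw = 100, omp = 0, seed = 1, bthresh = 0.5) {
  cfg <- list(n = n, lcell = lcell, tcell = tcell, lnuc = lnuc,
              tbuffer = tbuffer, airad = airad, maxcas = maxcas,
              maxbch = maxbch, e0 = e0, sobp = sobp, nsobp = nsobp, r0 = r0,
              ppm = ppm, cytob = cytob, nuclb = nuclb, watb = watb,
              ppmw = ppmw, omp = omp, seed = seed, bthresh = bthresh)
  validate_config(cfg)
  structure(cfg, class = "pbft_config")
}

.cfg_fail <- function(field, why) {
  stop("invalid configuration: field '", field, "' ", why, call. = FALSE)
}

#' Validate a configuration
#'
#' Checks every invariant of the configuration contract and raises an error
#' naming the offending field.
#'
#' @param cfg a list or `pbft_config`.
#' @return the configuration, invisibly, when valid.
#' @export
validate_config <- function(cfg) {
  missing <- setdiff(.CONFIG_FIELDS, names(cfg))
  if (length(missing)) {
    .cfg_fail(missing[1], "is missing")
  }
  num1 <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      .cfg_fail(f, "must be a single finite number")
    }
    v
  }
  intlike <- function(f) {
    v <- num1(f)
    if (v != round(v)) .cfg_fail(f, "must be an integer")
    v
  }
  if (intlike("n") < 1) .cfg_fail("n", "must be >= 1")
  for (f in c("lcell", "tcell", "lnuc", "tbuffer", "airad", "r0")) {
    if (num1(f) <= 0) .cfg_fail(f, "must be > 0")
  }
  if (cfg$lnuc >= cfg$lcell) .cfg_fail("lnuc", "must be < lcell")
  if (cfg$lnuc > cfg$tcell) .cfg_fail("lnuc", "must be <= tcell")
  if (num1("e0") <= 0) .cfg_fail("e0", "must be > 0")
  for (f in c("ppm", "ppmw")) {
    if (num1(f) < 0) .cfg_fail(f, "must be >= 0")
  }
  if (!intlike("cytob") %in% 0:2) .cfg_fail("cytob", "must be 0, 1 or 2")
  for (f in c("sobp", "nuclb", "watb", "omp")) {
    if (!intlike(f) %in% 0:1) .cfg_fail(f, "must be 0 or 1")
  }
  for (f in c("maxcas", "maxbch")) {
    if (intlike(f) < 1) .cfg_fail(f, "must be >= 1")
  }
  if (cfg$sobp == 1 && intlike("nsobp") < 2) {
    .cfg_fail("nsobp", "must be >= 2 when sobp = 1")
  }
  intlike("seed")
  bt <- num1("bthresh")
  if (bt < 0 || bt > 1) .cfg_fail("bthresh", "must be in [0, 1]")
  # the geometry must fit inside the ambient sphere
  half_um <- sqrt(2 * (cfg$n * cfg$lcell / 2)^2 +
                  max(cfg$tbuffer, cfg$tcell)^2)
  if (half_um >= cfg$airad * 1e4) {
    .cfg_fail("airad", "is too small to enclose the cell array and buffer")
  }
  invisible(cfg)
}

#' @export
print.pbft_config <- function(x, ...) {
  cat("<pbft_config>\n")
  cat(sprintf("  array: %d x %d cells, %g x %g x %g um, nucleus %g um\n",
              x$n, x$n, x$lcell, x$lcell, x$tcell, x$lnuc))
  cat(sprintf("  buffer %g um, ambient radius %g cm\n", x$tbuffer, x$airad))
  src <- if (x$sobp == 1) {
    sprintf("SOBP, %g MeV max, %d points", x$e0, x$nsobp)
  } else {
    sprintf("monoenergetic %g MeV", x$e0)
  }
  cat(sprintf("  beam: %s, disk r0 = %g mm\n", src, x$r0))
  cat(sprintf("  boron: cytob=%d (%g ppm), nuclb=%d, watb=%d (%g ppm)\n",
              x$cytob, x$ppm, x$nuclb, x$watb, x$ppmw))
  cat(sprintf("  run: %d histories x %d batches, seed %d, omp=%d\n",
              x$maxcas, x$maxbch, x$seed, x$omp))
  invisible(x)
}

#' Read a configuration from a YAML key-value file
#'
#' Keys are named exactly as the generator inputs (`n`, `lcell`, ...,
#' `omp`) plus `seed` and `bthresh`; missing keys fall back to the
#' [simulation_config()] defaults and `...` overrides the file.
#'
#' @param path YAML (flat key-value) file.
#' @param ... overriding fields, e.g. `e0 = 35`.
#' @return a `pbft_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a key-value mapping")
  unknown <- setdiff(names(vals), .CONFIG_FIELDS)
  if (length(unknown)) {
    stop("config file has unknown key(s): ", paste(unknown, collapse = ", "))
  }
  vals <- utils::modifyList(vals, list(...))
  if (!"e0" %in% names(vals)) .cfg_fail("e0", "is missing")
  do.call(simulation_config, vals)
}

#' Write a configuration to YAML
#'
#' @param cfg a `pbft_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pbft_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
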