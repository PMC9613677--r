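# Shared fixtures: small, fast configurations built in code.

small_config <- function(...) {
  args <- utils::modifyList(
    list(e0 = 25, n = 4, maxcas = 200, maxbch = 2, tbuffer = 500,
         airad = 2, seed = 11),
    list(...))
  do.call(simulation_config, args)
}

# default computational-scheme array (20 x 20, 30 um cells, 10 um nuclei)
scheme_config <- function(...) {
  args <- utils::modifyList(list(e0 = 25, seed = 1), list(...))
  do.call(simulation_config, args)
}

hydrogen_world <- function() {
  h <- builtin_material("hydrogen_only")
  list(cytoplasm = h, nucleus = h, buffer = h, air = h)
}

# independent fine-step Euler slowing-down oracle: path length to go from
# e0 down to e1 (um), and energy after path s_um (MeV)
euler_path_um <- function(material, particle, e0, e1, de = 1e-3) {
  e <- seq(e0, max(e1, de), by = -de)
  emid <- (e[-1] + e[-length(e)]) / 2
  s <- stopping_power(material, particle, emid)
  sum(de / (s * material$density)) * 1e4
}

euler_energy_after <- function(material, particle, e0, s_um, ds = 0.01) {
  e <- e0
  rho <- material$density
  travelled <- 0
  while (travelled < s_um && e > 0.01) {
    step <- min(ds, s_um - travelled)
    e <- e - stopping_power(material, particle, e) * rho * step * 1e-4
    travelled <- travelled + step
    if (e <= 0) return(0)
  }
  max(e, 0)
}
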