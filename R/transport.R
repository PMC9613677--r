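# Condensed-history Monte Carlo transport of protons and secondary alphas.
#
# Protons step through the geometry with steps limited by (i) the distance
# to the next region boundary, (ii) a maximum fractional energy loss
# (default 5%), and (iii) the axial tally bin width inside the buffer.
# Continuous energy loss uses range-energy inversion (exact within CSDA);
# discrete alpha-producing reactions fire with probability
# 1 - exp(-Sigma_tot * ds), with cross sections evaluated at the step
# midpoint energy and the reaction placed at the step midpoint. Every
# (p,alpha)-type channel and the fusion channel absorb the proton. Alphas
# travel in straight lines, depositing energy by the same range inversion,
# until stopped or escaped. Neutrons from the effective (p,n) channel are
# counted at birth and their energy booked as escaping; residual nuclei
# (13N, 11C, 9B) are counted and their recoil energy deposited locally.

.X0_ELEM <- c(H = 63.04, B = 52.69, C = 42.70, N = 37.99, O = 34.24,
              P = 21.21, Ar = 19.55)  # radiation lengths, g/cm^2

# material-set indices used by the locator
.MAT_NAMES <- c("air", "buffer", "cytoplasm", "cytoplasm+boron",
                "nucleus", "nucleus+boron")

#' Build the run-time material set
#'
#' Assembles the six transport media (ambient air, buffer with optional
#' `ppmw` boron, normal and boron cytoplasm, normal and boron nucleus) with
#' their nuclide inventories and per-channel target densities.
#'
#' @param config a `pbft_config`.
#' @param materials optional named list overriding the base compositions
#'   before boron mixing; names among `"cytoplasm"`, `"nucleus"`,
#'   `"buffer"`, `"air"` and values `pbft_material`s. Pass
#'   `builtin_material("hydrogen_only")` for the null-control media.
#' @param channels list of `pbft_channel`s (default [default_channels()]).
#' @return an object of class `pbft_material_set`.
#' @export
build_material_set <- function(config, materials = NULL, channels = NULL) {
  base <- list(air = builtin_material("air"),
               buffer = builtin_material("buffer"),
               cytoplasm = builtin_material("cytoplasm"),
               nucleus = builtin_material("nucleus"))
  if (!is.null(materials)) {
    for (nm in names(materials)) {
      if (!nm %in% names(base)) stop("unknown material slot: ", nm)
      stopifnot(inherits(materials[[nm]], "pbft_material"))
      base[[nm]] <- materials[[nm]]
    }
  }
  if (is.null(channels)) channels <- default_channels()
  mats <- list(
    base$air,
    if (config$watb == 1) mix_boron(base$buffer, config$ppmw) else
      base$buffer,
    base$cytoplasm,
    mix_boron(base$cytoplasm, config$ppm),
    base$nucleus,
    mix_boron(base$nucleus, config$ppm)
  )
  names(mats) <- .MAT_NAMES
  inv <- t(vapply(mats, number_densities,
                  setNames(numeric(length(.INVENTORY_NUCLIDES)),
                           .INVENTORY_NUCLIDES)))
  ntarget <- vapply(channels, function(ch) inv[, ch$target],
                    numeric(length(mats)))
  if (is.null(dim(ntarget))) ntarget <- matrix(ntarget, nrow = length(mats))
  structure(list(materials = mats, density = vapply(mats, `[[`, 0,
                 "density"), inventory = inv, channels = channels,
                 ntarget = ntarget),
            class = "pbft_material_set")
}

# per-material/species range machinery: r_of_e, e_of_r (log-log funs),
# residual range at the cutoff
.range_funs <- function(mset, species, e_cut) {
  lapply(mset$materials, function(m) {
    tab <- .range_table(m, species)
    list(r_of_e = tab$r_of_e, e_of_r = tab$e_of_r,
         r_cut = exp(tab$r_of_e(log(max(e_cut, .E_DOMAIN[1])))))
  })
}

# radiation length of a material, g/cm^2 (Bragg-additive inverse)
.rad_length <- function(m) {
  1 / sum(m$fractions / .X0_ELEM[names(m$fractions)])
}

.default_opts <- function(config,
                          e_cut_proton = 0.1, e_cut_alpha = 0.05,
                          max_frac_eloss = 0.05, nbins_cell = 30,
                          nbins_buffer = NULL, store_tracks = FALSE,
                          scattering = FALSE, max_iter = 50000) {
  if (is.null(nbins_buffer)) {
    bw <- max(config$tbuffer / 100, 25)
    nbins_buffer <- max(1L, ceiling(config$tbuffer / bw))
  }
  list(e_cut_proton = e_cut_proton, e_cut_alpha = e_cut_alpha,
       max_frac_eloss = max_frac_eloss, nbins_cell = nbins_cell,
       nbins_buffer = nbins_buffer,
       bw_cell = config$tcell / nbins_cell,
       bw_buffer = config$tbuffer / nbins_buffer,
       store_tracks = store_tracks, scattering = scattering,
       max_iter = max_iter)
}

# accumulator for one batch
.new_acc <- function(nreg, maxcas, opts) {
  env <- new.env(parent = emptyenv())
  env$reg <- list(); env$spec <- list(); env$dep <- list()
  env$axc_bin <- list(); env$axc_dep <- list()
  env$axb_bin <- list(); env$axb_spec <- list(); env$axb_dep <- list()
  env$hit_track <- list(); env$hit_reg <- list()
  env$seg <- list()
  env$dep_hist <- numeric(maxcas)
  env$esc_hist <- numeric(maxcas)
  env$q_hist <- numeric(maxcas)
  env$counters <- c(n_reactions = 0, fusion = 0, N13 = 0, C11 = 0, B9 = 0,
                    neutron = 0)
  env$i <- 0L
  env
}

.acc_dep <- function(acc, reg, spec, dep, hist) {
  i <- acc$i + 1L
  acc$reg[[i]] <- reg; acc$spec[[i]] <- spec; acc$dep[[i]] <- dep
  acc$i <- i
  acc$dep_hist <- acc$dep_hist + .by_hist(dep, hist, length(acc$dep_hist))
}

.by_hist <- function(v, hist, n) {
  out <- numeric(n)
  s <- rowsum(v, hist)
  out[as.integer(rownames(s))] <- s
  out
}

# ---- proton transport for one batch -------------------------------------

.transport_protons <- function(geom, mset, pfuns, src, seed, batch, opts,
                               acc) {
  n_p <- nrow(src)
  px <- src$x; py <- src$y; pz <- src$z
  dx <- src$dx; dy <- src$dy; dz <- src$dz
  E <- src$E
  hist <- seq_len(n_p)
  stepk <- rep(1L, n_p)
  alive <- rep(TRUE, n_p)
  nchan <- length(mset$channels)
  bank <- list(E = list(), x = list(), y = list(), z = list(),
               dx = list(), dy = list(), dz = list(), hist = list(), j = 0L)
  rho <- mset$density
  it <- 0L
  while (any(alive)) {
    it <- it + 1L
    if (it > opts$max_iter) {
      warning("proton transport iteration cap reached; killing stragglers")
      break
    }
    idx <- which(alive)
    loc <- .geo_locate(geom, px[idx], py[idx], pz[idx])
    esc <- loc$id == 0L
    if (any(esc)) {
      ei <- idx[esc]
      acc$esc_hist <- acc$esc_hist + .by_hist(E[ei], hist[ei], n_p)
      alive[ei] <- FALSE
    }
    idx <- idx[!esc]
    if (!length(idx)) next
    id <- loc$id[!esc]; mat <- loc$mat[!esc]
    e_i <- E[idx]
    m <- length(idx)
    rcur <- numeric(m); rcut <- numeric(m); ds_e <- numeric(m)
    for (u in unique(mat)) {
      f <- pfuns[[u]]
      sel <- mat == u
      r1 <- exp(f$r_of_e(log(e_i[sel])))
      r2 <- exp(f$r_of_e(log(e_i[sel] * (1 - opts$max_frac_eloss))))
      rcur[sel] <- r1
      rcut[sel] <- f$r_cut
      ds_e[sel] <- (r1 - r2) / rho[u] * 1e4
    }
    ds_geom <- .geo_boundary_distance(geom, px[idx], py[idx], pz[idx],
                                      dx[idx], dy[idx], dz[idx],
                                      list(id = id, cell = loc$cell[!esc]))
    ds_cap <- ifelse(id == 2L, opts$bw_buffer, Inf)
    ds <- pmax(pmin(ds_geom, ds_e, ds_cap), 1e-6)
    rrem_um <- (rcur - rcut) / rho[mat] * 1e4
    stopped <- rrem_um <= ds
    ds[stopped] <- pmax(rrem_um[stopped], 1e-9)
    e_new <- numeric(m)
    live <- !stopped
    if (any(live)) {
      for (u in unique(mat[live])) {
        f <- pfuns[[u]]
        sel <- live & mat == u
        e_new[sel] <- exp(f$e_of_r(log(rcur[sel] -
                                       ds[sel] * rho[u] * 1e-4)))
      }
    }
    e_mid <- (e_i + e_new) / 2
    # --- reactions -------------------------------------------------------
    sig <- matrix(0, m, nchan)
    for (c_i in seq_len(nchan)) {
      nt <- mset$ntarget[mat, c_i]
      has <- nt > 0
      if (any(has)) {
        sig[has, c_i] <- nt[has] * 1e-24 *
          channel_cross_section(mset$channels[[c_i]], e_mid[has])
      }
    }
    sig_tot <- rowSums(sig)
    react <- logical(m)
    hot <- sig_tot > 0
    if (any(hot)) {
      p_reac <- 1 - exp(-sig_tot[hot] * ds[hot] * 1e-4)
      u1 <- .hash_u01(seed, batch, hist[idx[hot]], stepk[idx[hot]], 1)
      react[hot] <- u1 < p_reac
    }
    dep_cont <- ifelse(react, e_i - e_mid, ifelse(stopped, e_i,
                                                  e_i - e_new))
    travel <- ifelse(react, ds / 2, ds)
    zdep <- pz[idx] + dz[idx] * travel / 2
    .acc_dep(acc, id, rep(1L, m), dep_cont, hist[idx])
    inb <- id == 2L
    if (any(inb)) {
      ib <- pmin.int(pmax.int(floor(zdep[inb] / opts$bw_buffer), 0),
                     opts$nbins_buffer - 1) + 1L
      j <- length(acc$axb_bin) + 1L
      acc$axb_bin[[j]] <- ib
      acc$axb_spec[[j]] <- rep(1L, sum(inb))
      acc$axb_dep[[j]] <- dep_cont[inb]
    }
    if (opts$store_tracks) {
      acc$seg[[length(acc$seg) + 1L]] <- cbind(
        px[idx], py[idx], pz[idx],
        px[idx] + dx[idx] * travel, py[idx] + dy[idx] * travel,
        pz[idx] + dz[idx] * travel, 1, hist[idx], e_i, dep_cont)
    }
    if (any(react)) {
      ri <- which(react)
      u2 <- .hash_u01(seed, batch, hist[idx[ri]], stepk[idx[ri]], 2)
      cum <- sig[ri, 1, drop = TRUE]
      pick <- rep(1L, length(ri))
      if (nchan > 1) {
        tot <- sig_tot[ri]
        acc_p <- cum
        for (c_i in 2:nchan) {
          undecided <- u2 >= acc_p / tot
          pick[undecided] <- c_i
          acc_p <- acc_p + sig[ri, c_i]
        }
      }
      rxp <- cbind(px[idx[ri]] + dx[idx[ri]] * ds[ri] / 2,
                   py[idx[ri]] + dy[idx[ri]] * ds[ri] / 2,
                   pz[idx[ri]] + dz[idx[ri]] * ds[ri] / 2)
      e_rx <- e_mid[ri]
      h_rx <- hist[idx[ri]]
      k_rx <- stepk[idx[ri]]
      acc$counters[["n_reactions"]] <- acc$counters[["n_reactions"]] +
        length(ri)
      for (c_i in unique(pick)) {
        ch <- mset$channels[[c_i]]
        s <- which(pick == c_i)
        e_p <- e_rx[s]
        prod_e_sum <- numeric(length(s))
        if (ch$product == "fusion_3a") {
          acc$counters[["fusion"]] <- acc$counters[["fusion"]] + length(s)
          for (jj in 1:3) {
            ea <- c(3.76, 2.46, 2.46)[jj]
            uc <- .hash_u01(seed, batch, h_rx[s], k_rx[s], 1 + 2 * jj)
            up <- .hash_u01(seed, batch, h_rx[s], k_rx[s], 2 + 2 * jj)
            d3 <- .iso_direction(uc, up)
            bank <- .bank_push(bank, rep(ea, length(s)), rxp[s, 1],
                               rxp[s, 2], rxp[s, 3], d3, h_rx[s])
          }
          prod_e_sum <- prod_e_sum + 8.68
        } else if (ch$product == "two_body_alpha") {
          m_a <- .NUCLIDE_MASS[["alpha"]]
          e_avail <- pmax(e_p + ch$q_value, 0)
          e_a <- e_avail * ch$m_residual / (m_a + ch$m_residual)
          uc <- .hash_u01(seed, batch, h_rx[s], k_rx[s], 3)
          up <- .hash_u01(seed, batch, h_rx[s], k_rx[s], 4)
          d3 <- .iso_direction(uc, up)
          bank <- .bank_push(bank, e_a, rxp[s, 1], rxp[s, 2], rxp[s, 3],
                             d3, h_rx[s])
          # residual recoil deposited locally
          e_res <- e_avail - e_a
          .acc_dep(acc, id[ri[s]], rep(3L, length(s)), e_res, h_rx[s])
          if (!is.na(ch$residual) && ch$residual %in% names(acc$counters)) {
            acc$counters[[ch$residual]] <- acc$counters[[ch$residual]] +
              length(s)
          }
          prod_e_sum <- prod_e_sum + e_avail
        } else if (ch$product == "neutron") {
          m_n <- .NUCLIDE_MASS[["n"]]
          e_avail <- pmax(e_p + ch$q_value, 0)
          e_n <- e_avail * ch$m_residual / (m_n + ch$m_residual)
          e_res <- e_avail - e_n
          acc$counters[["neutron"]] <- acc$counters[["neutron"]] +
            length(s)
          acc$esc_hist <- acc$esc_hist + .by_hist(e_n, h_rx[s],
                                                  length(acc$esc_hist))
          .acc_dep(acc, id[ri[s]], rep(3L, length(s)), e_res, h_rx[s])
          prod_e_sum <- prod_e_sum + e_avail
        }
        acc$q_hist <- acc$q_hist + .by_hist(prod_e_sum - e_p, h_rx[s],
                                            length(acc$q_hist))
      }
    }
    # --- update ----------------------------------------------------------
    adv <- ds + 1e-6
    px[idx] <- px[idx] + dx[idx] * adv
    py[idx] <- py[idx] + dy[idx] * adv
    pz[idx] <- pz[idx] + dz[idx] * adv
    E[idx] <- e_new
    stepk[idx] <- stepk[idx] + 1L
    if (opts$scattering) {
      keep <- !(react | stopped)
      if (any(keep)) {
        ki <- idx[keep]
        t_gcm2 <- ds[keep] * rho[mat[keep]] * 1e-4
        x0 <- vapply(mset$materials[mat[keep]], .rad_length, 0)
        tn <- pmax(t_gcm2 / x0, 1e-12)
        pc <- sqrt(e_new[keep] * (e_new[keep] + 2 * .M_PROTON))
        beta <- pc / (e_new[keep] + .M_PROTON)
        th0 <- 13.6 / (beta * pc) * sqrt(tn) * (1 + 0.038 * log(tn))
        u1 <- .hash_u01(seed, batch, hist[ki], stepk[ki], 9)
        u2 <- .hash_u01(seed, batch, hist[ki], stepk[ki], 10)
        r <- sqrt(-2 * log(pmax(u1, 1e-12)))
        thx <- th0 * r * cos(2 * pi * u2)
        thy <- th0 * r * sin(2 * pi * u2)
        new_d <- .deflect(dx[ki], dy[ki], dz[ki], thx, thy)
        dx[ki] <- new_d[, 1]; dy[ki] <- new_d[, 2]; dz[ki] <- new_d[, 3]
      }
    }
    alive[idx[react | stopped]] <- FALSE
  }
  bank
}

.bank_push <- function(bank, E, x, y, z, d3, hist) {
  j <- bank$j + 1L
  bank$E[[j]] <- E; bank$x[[j]] <- x; bank$y[[j]] <- y; bank$z[[j]] <- z
  bank$dx[[j]] <- d3[, 1]; bank$dy[[j]] <- d3[, 2]; bank$dz[[j]] <- d3[, 3]
  bank$hist[[j]] <- hist
  bank$j <- j
  bank
}

# rotate unit vectors by small projected angles (thx, thy) in a transverse
# basis; exact renormalization keeps |d| = 1
.deflect <- function(dx, dy, dz, thx, thy) {
  # transverse basis (u, v) for each direction
  swap <- abs(dz) > 0.99
  ux <- ifelse(swap, 1, -dy); uy <- ifelse(swap, 0, dx)
  uz <- numeric(length(dx))
  un <- sqrt(ux^2 + uy^2 + uz^2)
  ux <- ux / un; uy <- uy / un
  vx <- dy * uz - dz * uy; vy <- dz * ux - dx * uz; vz <- dx * uy - dy * ux
  nx <- dx + thx * ux + thy * vx
  ny <- dy + thx * uy + thy * vy
  nz <- dz + thx * uz + thy * vz
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  cbind(nx / nn, ny / nn, nz / nn)
}

# ---- alpha transport for one batch --------------------------------------

.transport_alphas <- function(geom, mset, afuns, bank, opts, acc) {
  if (bank$j == 0L) return(invisible(NULL))
  E <- unlist(bank$E); px <- unlist(bank$x); py <- unlist(bank$y)
  pz <- unlist(bank$z)
  dx <- unlist(bank$dx); dy <- unlist(bank$dy); dz <- unlist(bank$dz)
  hist <- unlist(bank$hist)
  n_a <- length(E)
  track <- seq_len(n_a)
  alive <- rep(TRUE, n_a)
  rho <- mset$density
  it <- 0L
  while (any(alive)) {
    it <- it + 1L
    if (it > opts$max_iter) {
      warning("alpha transport iteration cap reached; killing stragglers")
      break
    }
    idx <- which(alive)
    loc <- .geo_locate(geom, px[idx], py[idx], pz[idx])
    esc <- loc$id == 0L
    if (any(esc)) {
      ei <- idx[esc]
      acc$esc_hist <- acc$esc_hist + .by_hist(E[ei], hist[ei],
                                              length(acc$esc_hist))
      alive[ei] <- FALSE
    }
    idx <- idx[!esc]
    if (!length(idx)) next
    id <- loc$id[!esc]; mat <- loc$mat[!esc]
    e_i <- E[idx]
    m <- length(idx)
    # hit bookkeeping: any presence of the track in a cell subdomain
    incell <- id > 2L
    if (any(incell)) {
      j <- length(acc$hit_track) + 1L
      acc$hit_track[[j]] <- track[idx[incell]]
      acc$hit_reg[[j]] <- id[incell]
    }
    low <- e_i <= opts$e_cut_alpha
    if (any(low)) {
      li <- low
      .acc_dep(acc, id[li], rep(2L, sum(li)), e_i[li], hist[idx[li]])
      alive[idx[li]] <- FALSE
    }
    idx <- idx[!low]; id <- id[!low]; mat <- mat[!low]; e_i <- e_i[!low]
    m <- length(idx)
    if (!m) next
    rcur <- numeric(m); rcut <- numeric(m)
    for (u in unique(mat)) {
      f <- afuns[[u]]
      sel <- mat == u
      rcur[sel] <- exp(f$r_of_e(log(e_i[sel])))
      rcut[sel] <- f$r_cut
    }
    ds_geom <- .geo_boundary_distance(geom, px[idx], py[idx], pz[idx],
                                      dx[idx], dy[idx], dz[idx],
                                      list(id = id, cell = loc$cell[!esc][!low]))
    ds_cap <- ifelse(id == 2L, opts$bw_buffer,
                     ifelse(id > 2L, opts$bw_cell, Inf))
    ds <- pmax(pmin(ds_geom, ds_cap), 1e-6)
    rrem_um <- (rcur - rcut) / rho[mat] * 1e4
    stopped <- rrem_um <= ds
    ds[stopped] <- pmax(rrem_um[stopped], 1e-9)
    e_new <- numeric(m)
    live <- !stopped
    if (any(live)) {
      for (u in unique(mat[live])) {
        f <- afuns[[u]]
        sel <- live & mat == u
        e_new[sel] <- exp(f$e_of_r(log(rcur[sel] -
                                       ds[sel] * rho[u] * 1e-4)))
      }
    }
    dep <- ifelse(stopped, e_i, e_i - e_new)
    zmid <- pz[idx] + dz[idx] * ds / 2
    .acc_dep(acc, id, rep(2L, m), dep, hist[idx])
    inb <- id == 2L
    if (any(inb)) {
      ib <- pmin.int(pmax.int(floor(zmid[inb] / opts$bw_buffer), 0),
                     opts$nbins_buffer - 1) + 1L
      j <- length(acc$axb_bin) + 1L
      acc$axb_bin[[j]] <- ib
      acc$axb_spec[[j]] <- rep(2L, sum(inb))
      acc$axb_dep[[j]] <- dep[inb]
    }
    incell <- id > 2L
    if (any(incell)) {
      ib <- pmin.int(pmax.int(floor(-zmid[incell] / opts$bw_cell), 0),
                     opts$nbins_cell - 1) + 1L
      j <- length(acc$axc_bin) + 1L
      acc$axc_bin[[j]] <- ib
      acc$axc_dep[[j]] <- dep[incell]
    }
    if (opts$store_tracks) {
      acc$seg[[length(acc$seg) + 1L]] <- cbind(
        px[idx], py[idx], pz[idx],
        px[idx] + dx[idx] * ds, py[idx] + dy[idx] * ds,
        pz[idx] + dz[idx] * ds, 2, track[idx], e_i, dep)
    }
    adv <- ds + 1e-6
    px[idx] <- px[idx] + dx[idx] * adv
    py[idx] <- py[idx] + dy[idx] * adv
    pz[idx] <- pz[idx] + dz[idx] * adv
    E[idx] <- e_new
    alive[idx[stopped]] <- FALSE
  }
  invisible(NULL)
}

# collapse a batch accumulator into dense tallies
.collapse_acc <- function(acc, nreg, opts) {
  dep <- matrix(0, nreg, 3,
                dimnames = list(NULL, c("proton", "alpha", "residual")))
  if (acc$i > 0L) {
    reg <- unlist(acc$reg); spec <- unlist(acc$spec); dv <- unlist(acc$dep)
    key <- reg + nreg * (spec - 1L)
    s <- rowsum(dv, key)
    dep[as.integer(rownames(s))] <- s
  }
  axc <- numeric(opts$nbins_cell)
  if (length(acc$axc_bin)) {
    s <- rowsum(unlist(acc$axc_dep), unlist(acc$axc_bin))
    axc[as.integer(rownames(s))] <- s
  }
  axb <- matrix(0, opts$nbins_buffer, 2,
                dimnames = list(NULL, c("proton", "alpha")))
  if (length(acc$axb_bin)) {
    key <- unlist(acc$axb_bin) + opts$nbins_buffer *
      (unlist(acc$axb_spec) - 1L)
    s <- rowsum(unlist(acc$axb_dep), key)
    axb[as.integer(rownames(s))] <- s
  }
  hits <- c(nucleus = 0L, cytoplasm = 0L)
  pairs <- NULL
  if (length(acc$hit_track)) {
    pairs <- unique(data.frame(track = unlist(acc$hit_track),
                               region = unlist(acc$hit_reg)))
  }
  segments <- NULL
  if (length(acc$seg)) {
    sm <- do.call(rbind, acc$seg)
    segments <- data.frame(x0 = sm[, 1], y0 = sm[, 2], z0 = sm[, 3],
                           x1 = sm[, 4], y1 = sm[, 5], z1 = sm[, 6],
                           species = c("proton", "alpha")[sm[, 7]],
                           track = sm[, 8], E0 = sm[, 9], dep = sm[, 10])
  }
  list(dep = dep, axial_cell = axc, axial_buffer = axb, pairs = pairs,
       counters = acc$counters, dep_hist = acc$dep_hist,
       esc_hist = acc$esc_hist, q_hist = acc$q_hist,
       segments = segments)
}

#' Run the full simulation
#'
#' Seeds the R stream with `config$seed`, assigns boron, then runs
#' `maxbch` batches of `maxcas` proton histories each (with secondary alpha
#' transport), scoring per-region and axial energy deposition, alpha hit
#' counts, reaction counters and per-history energy balance. All tallies
#' are stored per batch; accessors normalize per source particle. Two runs
#' with the same configuration are identical bit for bit.
#'
#' @param config a `pbft_config`.
#' @param materials,channels optional overrides, see
#'   [build_material_set()].
#' @param scattering enable small-angle (Highland) multiple scattering of
#'   protons; off by default so depth-dose checks stay analytic.
#' @param store_tracks retain track segments for [track_map()].
#' @param nbins_cell axial bins across the cell layer (default 30, i.e.
#'   1 um bins for the 30 um default thickness).
#' @param nbins_buffer axial bins across the buffer (default: 25 um bins,
#'   at most 100 bins).
#' @param e_cut_proton,e_cut_alpha transport cutoffs, MeV; residual energy
#'   is deposited locally.
#' @param max_frac_eloss condensed-history step limiter (maximum fractional
#'   energy loss per step).
#' @return an object of class `pbft_result`.
#' @export
run_simulation <- function(config, materials = NULL, channels = NULL,
                           scattering = FALSE, store_tracks = FALSE,
                           nbins_cell = 30, nbins_buffer = NULL,
                           e_cut_proton = 0.1, e_cut_alpha = 0.05,
                           max_frac_eloss = 0.05) {
  validate_config(config)
  if (config$maxcas < 1) stop("maxcas must be >= 1")
  opts <- .default_opts(config, e_cut_proton = e_cut_proton,
                        e_cut_alpha = e_cut_alpha,
                        max_frac_eloss = max_frac_eloss,
                        nbins_cell = nbins_cell,
                        nbins_buffer = nbins_buffer,
                        store_tracks = store_tracks,
                        scattering = scattering)
  set.seed(config$seed)
  borcheck <- assign_boron(config)
  geom <- build_geometry(config, borcheck = borcheck)
  mset <- build_material_set(config, materials = materials,
                             channels = channels)
  src_model <- if (config$sobp == 1) {
    build_sobp(config$e0, config$nsobp, mset$materials[["buffer"]],
               r0 = config$r0)
  } else {
    source_model(config$e0, r0 = config$r0)
  }
  pfuns <- .range_funs(mset, "proton", opts$e_cut_proton)
  afuns <- .range_funs(mset, "alpha", opts$e_cut_alpha)
  nreg <- 2L + 2L * config$n^2
  batches <- vector("list", config$maxbch)
  for (b in seq_len(config$maxbch)) {
    src <- sample_source(src_model, config$maxcas,
                         z_top = config$tbuffer * (1 - 1e-9))
    acc <- .new_acc(nreg, config$maxcas, opts)
    bank <- .transport_protons(geom, mset, pfuns, src, config$seed, b,
                               opts, acc)
    .transport_alphas(geom, mset, afuns, bank, opts, acc)
    out <- .collapse_acc(acc, nreg, opts)
    out$e_source <- sum(src$E)
    out$e_source_hist <- src$E
    batches[[b]] <- out
  }
  dep <- array(unlist(lapply(batches, `[[`, "dep")),
               dim = c(nreg, 3, config$maxbch),
               dimnames = list(NULL, c("proton", "alpha", "residual"),
                               NULL))
  counters <- vapply(batches, `[[`, batches[[1]]$counters, "counters")
  hits <- vapply(batches, function(b) {
    if (is.null(b$pairs)) return(c(nucleus = 0, cytoplasm = 0))
    nuc <- sum(b$pairs$region > 2L + config$n^2)
    c(nucleus = nuc, cytoplasm = nrow(b$pairs) - nuc)
  }, c(nucleus = 0, cytoplasm = 0))
  balance_err <- vapply(batches, function(b) {
    max(abs(b$e_source_hist + b$q_hist - b$dep_hist - b$esc_hist))
  }, 0)
  structure(list(
    config = config, geometry = geom, source = src_model, opts = opts,
    n_regions = nreg,
    dep = dep,
    axial_cell = vapply(batches, `[[`, numeric(opts$nbins_cell),
                        "axial_cell"),
    axial_buffer = array(unlist(lapply(batches, `[[`, "axial_buffer")),
                         dim = c(opts$nbins_buffer, 2, config$maxbch),
                         dimnames = list(NULL, c("proton", "alpha"), NULL)),
    counters = counters,
    hits = hits,
    hit_pairs = lapply(batches, `[[`, "pairs"),
    balance = list(
      max_error = balance_err,
      per_history = lapply(batches, function(b)
        data.frame(e_source = b$e_source_hist, deposited = b$dep_hist,
                   escaped = b$esc_hist, q_released = b$q_hist))),
    segments = if (store_tracks)
      do.call(rbind, lapply(batches, `[[`, "segments")) else NULL,
    e_source = vapply(batches, `[[`, 0, "e_source")
  ), class = "pbft_result")
}

#' @export
print.pbft_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pbft_result> %d x %d histories, %g MeV%s, seed %d\n",
              cfg$maxbch, cfg$maxcas, cfg$e0,
              if (cfg$sobp == 1) " SOBP" else "", cfg$seed))
  ad <- total_alpha_dose(x)
  cat(sprintf("  alpha dose in cell array: %.4g MeV/source (se %.2g)\n",
              ad$mean, ad$se))
  cat(sprintf("  reactions: %d (fusion %d, N13 %d, C11 %d, B9 %d, n %d)\n",
              sum(x$counters["n_reactions", ]), sum(x$counters["fusion", ]),
              sum(x$counters["N13", ]), sum(x$counters["C11", ]),
              sum(x$counters["B9", ]), sum(x$counters["neutron", ])))
  cat(sprintf("  max per-history energy-balance error: %.2g MeV\n",
              max(x$balance$max_error)))
  invisible(x)
}

# ---- single-particle module surface -------------------------------------

#' Advance a proton by one condensed-history step
#'
#' Single-particle wrapper around the batch engine's step logic, useful for
#' inspecting the stepping rules. Randomness is drawn from the current R
#' stream.
#'
#' @param state list/one-row data frame with `x`, `y`, `z` (um), `dx`,
#'   `dy`, `dz`, `E` (MeV).
#' @param geometry a `pbft_geometry`.
#' @param mset a `pbft_material_set`.
#' @param max_frac_eloss,e_cut step limiter and cutoff, MeV.
#' @return list with `state` (updated; `alive = FALSE` when terminated) and
#'   `events` (data frame of deposits/reaction products for the step).
#' @export
step_proton <- function(state, geometry, mset, max_frac_eloss = 0.05,
                        e_cut = 0.1) {
  cfg <- geometry$config
  opts <- .default_opts(cfg, max_frac_eloss = max_frac_eloss,
                        e_cut_proton = e_cut)
  pfuns <- .range_funs(mset, "proton", e_cut)
  loc <- .geo_locate(geometry, state$x, state$y, state$z)
  if (loc$id == 0L) {
    return(list(state = c(state, alive = FALSE),
                events = data.frame(type = "escape", E = state$E)))
  }
  f <- pfuns[[loc$mat]]
  rho <- mset$density[loc$mat]
  rcur <- exp(f$r_of_e(log(state$E)))
  ds_e <- (rcur - exp(f$r_of_e(log(state$E * (1 - max_frac_eloss))))) /
    rho * 1e4
  ds_geom <- .geo_boundary_distance(geometry, state$x, state$y, state$z,
                                    state$dx, state$dy, state$dz, loc)
  ds <- max(min(ds_geom, ds_e), 1e-6)
  rrem <- (rcur - f$r_cut) / rho * 1e4
  stopped <- rrem <= ds
  if (stopped) ds <- max(rrem, 1e-9)
  e_new <- if (stopped) 0 else
    exp(f$e_of_r(log(rcur - ds * rho * 1e-4)))
  e_mid <- (state$E + e_new) / 2
  sig <- vapply(seq_along(mset$channels), function(ci)
    mset$ntarget[loc$mat, ci] * 1e-24 *
      channel_cross_section(mset$channels[[ci]], e_mid), 0)
  p_reac <- 1 - exp(-sum(sig) * ds * 1e-4)
  react <- sum(sig) > 0 && runif(1) < p_reac
  events <- data.frame(type = "deposit", E = if (react) state$E - e_mid
                       else if (stopped) state$E else state$E - e_new)
  if (react) {
    ci <- which(runif(1) < cumsum(sig) / sum(sig))[1]
    events <- rbind(events,
                    data.frame(type = paste0("reaction:",
                                             mset$channels[[ci]]$label),
                               E = e_mid))
  }
  adv <- ds + 1e-6
  new_state <- list(x = state$x + state$dx * adv,
                    y = state$y + state$dy * adv,
                    z = state$z + state$dz * adv,
                    dx = state$dx, dy = state$dy, dz = state$dz,
                    E = e_new, alive = !(react || stopped))
  list(state = new_state, events = events)
}

#' Transport one alpha particle to rest
#'
#' Straight-line transport with continuous slowing; returns the per-region
#' track segments. Energy is conserved exactly: the segment depositions sum
#' to the initial energy minus any energy carried out of the ambient
#' sphere.
#'
#' @param state list with `x`, `y`, `z` (um), `dx`, `dy`, `dz` (unit), `E`
#'   (MeV).
#' @param geometry a `pbft_geometry`.
#' @param mset a `pbft_material_set`.
#' @param e_cut transport cutoff, MeV.
#' @return data frame of segments: `x0..z1`, `region`, `E_start`, `dep`,
#'   plus attribute `escaped` (energy leaving the sphere, MeV).
#' @export
transport_alpha <- function(state, geometry, mset, e_cut = 0.05) {
  afuns <- .range_funs(mset, "alpha", e_cut)
  rho <- mset$density
  segs <- list()
  x <- state$x; y <- state$y; z <- state$z
  dx <- state$dx; dy <- state$dy; dz <- state$dz
  e <- state$E
  escaped <- 0
  for (it in seq_len(100000)) {
    loc <- .geo_locate(geometry, x, y, z)
    if (loc$id == 0L) {
      escaped <- e
      break
    }
    if (e <= e_cut) {
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = x, y0 = y, z0 = z, x1 = x, y1 = y, z1 = z,
        region = loc$id, E_start = e, dep = e)
      break
    }
    f <- afuns[[loc$mat]]
    rcur <- exp(f$r_of_e(log(e)))
    ds_geom <- .geo_boundary_distance(geometry, x, y, z, dx, dy, dz, loc)
    ds <- max(ds_geom, 1e-6)
    rrem <- (rcur - f$r_cut) / rho[loc$mat] * 1e4
    stopped <- rrem <= ds
    if (stopped) ds <- max(rrem, 1e-9)
    e_new <- if (stopped) 0 else
      exp(f$e_of_r(log(rcur - ds * rho[loc$mat] * 1e-4)))
    dep <- if (stopped) e else e - e_new
    segs[[length(segs) + 1L]] <- data.frame(
      x0 = x, y0 = y, z0 = z,
      x1 = x + dx * ds, y1 = y + dy * ds, z1 = z + dz * ds,
      region = loc$id, E_start = e, dep = dep)
    if (stopped) break
    adv <- ds + 1e-6
    x <- x + dx * adv; y <- y + dy * adv; z <- z + dz * adv
    e <- e_new
  }
  out <- do.call(rbind, segs)
  attr(out, "escaped") <- escaped
  out
}
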