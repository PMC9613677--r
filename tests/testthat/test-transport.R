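test_that("a hydrogen-only world produces no alpha particles", {
  cfg <- small_config(e0 = 25, maxcas = 300, tbuffer = 1000)
  res <- run_simulation(cfg, materials = hydrogen_world())
  expect_equal(sum(res$counters["n_reactions", ]), 0)
  expect_equal(sum(res$dep[, "alpha", ]), 0)
  expect_equal(sum(res$hits), 0)
})

test_that("with no open reaction channel the beam energy is fully deposited", {
  # hydrogen everywhere and a buffer much thicker than the 10 MeV range:
  # every history deposits exactly its source energy
  cfg <- small_config(e0 = 10, maxcas = 100, maxbch = 1, tbuffer = 2000)
  res <- run_simulation(cfg, materials = hydrogen_world())
  ph <- res$balance$per_history[[1]]
  expect_equal(ph$deposited, ph$e_source, tolerance = 1e-9)
  expect_true(all(ph$escaped == 0))
})

test_that("energy is conserved per history through reactions", {
  cfg <- scheme_config(e0 = 25, maxcas = 1500, maxbch = 2, tbuffer = 1000,
                       airad = 2, cytob = 1, seed = 21)
  res <- run_simulation(cfg)
  expect_gt(sum(res$counters["n_reactions", ]), 0)
  expect_lt(max(res$balance$max_error), 1e-4)
  for (ph in res$balance$per_history) {
    expect_lt(max(abs(ph$e_source + ph$q_released - ph$deposited -
                        ph$escaped)), 1e-4)
  }
})

test_that("equal seeds reproduce tallies bit for bit", {
  cfg <- scheme_config(e0 = 25, maxcas = 400, maxbch = 2, cytob = 2,
                       airad = 2, seed = 33)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$dep, r2$dep)
  expect_identical(r1$axial_cell, r2$axial_cell)
  expect_identical(r1$counters, r2$counters)
  expect_identical(r1$hits, r2$hits)
})

test_that("the Bragg peak sits at the CSDA range", {
  w <- builtin_material("buffer")
  # narrow beam so every proton traverses the buffer slab of the small array
  cfg <- simulation_config(e0 = 25, n = 2, maxcas = 40, maxbch = 1,
                           tbuffer = 7000, airad = 2, seed = 2, r0 = 0.02)
  res <- run_simulation(cfg)
  bd <- buffer_depth_dose(res, "proton")
  peak <- bd$depth_um[which.max(bd$dose)]
  r_um <- csda_range(w, "proton", 25) / w$density * 1e4
  expect_lt(abs(peak - r_um) / r_um, 0.02)
})

test_that("thin-target reaction counts match the analytic expectation", {
  # one artificial flat 50 b channel on oxygen, hydrogen cells/air so only
  # the 100 um buffer slab reacts: P = 1 - exp(-N_O sigma t)
  flat <- reaction_channel(
    "flat50", "O16", threshold = 0.1,
    grid = data.frame(E = c(0.1, 100), sigma = c(50, 50)),
    q_value = 0, product = "two_body_alpha", m_residual = 16)
  h <- builtin_material("hydrogen_only")
  cfg <- simulation_config(e0 = 30, n = 2, maxcas = 10000, maxbch = 2,
                           tbuffer = 100, airad = 2, seed = 17, r0 = 0.02)
  res <- run_simulation(cfg, materials = list(cytoplasm = h, nucleus = h,
                                              air = h),
                        channels = list(flat50 = flat))
  n_o <- number_densities(builtin_material("buffer"))[["O16"]]
  p_exp <- 1 - exp(-n_o * 50e-24 * 100e-4)
  n_hist <- 20000
  n_obs <- sum(res$counters["n_reactions", ])
  expect_lt(abs(n_obs - n_hist * p_exp),
            3 * sqrt(n_hist * p_exp * (1 - p_exp)))
})

test_that("alpha transport conserves energy and matches the Euler oracle", {
  cfg <- scheme_config()
  geom <- build_geometry(cfg)
  mset <- build_material_set(cfg)
  cy <- mset$materials[["cytoplasm"]]
  # downward 3.76 MeV alpha from a cytoplasm point above the nucleus
  segs <- transport_alpha(list(x = 15, y = 15, z = -1, dx = 0, dy = 0,
                               dz = -1, E = 3.76), geom, mset)
  expect_equal(sum(segs$dep) + attr(segs, "escaped"), 3.76,
               tolerance = 1e-6)
  expect_true(all(segs$dep >= 0))
  # first-segment deposition against fine-step Euler slowing
  s1 <- segs[1, ]
  len1 <- sqrt((s1$x1 - s1$x0)^2 + (s1$y1 - s1$y0)^2 + (s1$z1 - s1$z0)^2)
  e_after <- euler_energy_after(cy, "alpha", 3.76, len1, ds = 0.002)
  expect_equal(s1$dep, 3.76 - e_after, tolerance = 0.01 * s1$dep)
})

test_that("a low-energy alpha born mid-nucleus never leaves it", {
  cfg <- scheme_config()
  geom <- build_geometry(cfg)
  mset <- build_material_set(cfg)
  r_um <- csda_range(mset$materials[["nucleus"]], "alpha", 0.5) /
    1.27 * 1e4
  expect_lt(r_um, 5)  # well under the 10 um nucleus
  segs <- transport_alpha(list(x = 15, y = 15, z = -15, dx = 1, dy = 0,
                               dz = 0, E = 0.5), geom, mset)
  nuc_ids <- unique(segs$region)
  expect_length(nuc_ids, 1)
  expect_gt(nuc_ids, 2 + cfg$n^2)  # a nucleus region
  expect_equal(sum(segs$dep), 0.5, tolerance = 1e-9)
})

test_that("single-step proton logic respects limiters and boundaries", {
  cfg <- scheme_config(tbuffer = 1000)
  geom <- build_geometry(cfg)
  mset <- build_material_set(cfg)
  set.seed(1)
  st <- list(x = 15, y = 15, z = 999.9, dx = 0, dy = 0, dz = -1, E = 25)
  out <- step_proton(st, geom, mset)
  # 5% max fractional energy loss per step
  expect_gte(out$state$E, 25 * 0.95 - 1e-9)
  expect_lt(out$state$z, st$z)
  expect_true(out$state$alive)
  # stepping from the buffer crosses into the cell layer, not past it
  st2 <- list(x = 15, y = 15, z = 0.5, dx = 0, dy = 0, dz = -1, E = 25)
  out2 <- step_proton(st2, geom, mset)
  expect_gte(out2$state$z, -30)
})

test_that("total alpha dose orders all-boron >= random >= normal at matched seeds", {
  base <- list(e0 = 25, maxcas = 2500, maxbch = 2, tbuffer = 1000,
               airad = 2, seed = 77, nuclb = 1)
  run_mode <- function(mode) {
    run_simulation(do.call(scheme_config, c(base, list(cytob = mode))))
  }
  r0 <- run_mode(0); r2 <- run_mode(2); r1 <- run_mode(1)
  d0 <- total_alpha_dose(r0)$mean
  d2 <- total_alpha_dose(r2)$mean
  d1 <- total_alpha_dose(r1)$mean
  slack <- 1e-3 * max(d1, 1e-12)
  expect_gte(d1, d2 - slack)
  expect_gte(d2, d0 - slack)
  # hit counts inherit the ordering (common random numbers)
  expect_gte(sum(r1$hits), sum(r0$hits))
})

test_that("no alpha energy reaches cells when protons arrive below the oxygen threshold", {
  # 5900 um of buffer degrades 25 MeV protons to ~5.3 MeV (< 5.66) at the
  # cell layer; with no boron anywhere, alpha deposition in cells is zero
  cfg <- scheme_config(e0 = 25, maxcas = 800, maxbch = 2, tbuffer = 5900,
                       airad = 2, cytob = 0, watb = 0, seed = 5)
  res <- run_simulation(cfg)
  expect_equal(total_alpha_dose(res)$mean, 0)
})

test_that("scattering spreads the beam laterally when enabled", {
  cfg <- simulation_config(e0 = 25, n = 2, maxcas = 150, maxbch = 1,
                           tbuffer = 5000, airad = 2, seed = 3, r0 = 0.01)
  res_s <- run_simulation(cfg, scattering = TRUE, store_tracks = TRUE)
  segs <- res_s$segments
  spread <- max(sqrt(segs$x1^2 + segs$y1^2))
  expect_gt(spread, 50)  # a pencil beam acquires visible lateral spread
})
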