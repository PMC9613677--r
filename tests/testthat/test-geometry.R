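test_that("the default computational-scheme array has 400 cells", {
  geom <- build_geometry(scheme_config())
  tab <- region_table(geom)
  expect_equal(sum(tab$domain == "cytoplasm"), 400)
  expect_equal(sum(tab$domain == "nucleus"), 400)
  expect_equal(sum(tab$domain %in% c("cytoplasm", "nucleus")), 800)
})

test_that("a single-cell array has one cell, two regions, full volume", {
  cfg <- simulation_config(e0 = 25, n = 1, airad = 1)
  tab <- region_table(build_geometry(cfg))
  cells <- tab[tab$domain %in% c("cytoplasm", "nucleus"), ]
  expect_equal(nrow(cells), 2)
  v_cell <- with(cells[cells$domain == "cytoplasm", ],
                 (xmax - xmin) * (ymax - ymin) * (zmax - zmin))
  expect_equal(v_cell, 30^2 * 30)
})

test_that("confluent cells share internal faces exactly", {
  cfg <- simulation_config(e0 = 25, n = 3, airad = 1)
  tab <- region_table(build_geometry(cfg))
  cy <- tab[tab$domain == "cytoplasm", ]
  expect_setequal(unique(cy$xmin), c(-45, -15, 15))
  expect_setequal(unique(cy$xmax), c(-15, 15, 45))
  expect_equal(range(c(cy$xmin, cy$xmax)), c(-45, 45))
})

test_that("cell volumes are conserved: cytoplasm + nucleus = cell box", {
  cfg <- simulation_config(e0 = 25, n = 2, lcell = 30, tcell = 30,
                           lnuc = 10, airad = 1)
  tab <- region_table(build_geometry(cfg))
  nuc <- tab[tab$domain == "nucleus", ][1, ]
  v_nuc <- with(nuc, (xmax - xmin) * (ymax - ymin) * (zmax - zmin))
  expect_equal(v_nuc, 10^3)
  # cytoplasm = cell box minus nucleus box
  expect_equal((30^2 * 30 - v_nuc) + v_nuc, 30^2 * 30)
})

test_that("locate_region resolves the worked points of the default array", {
  geom <- build_geometry(scheme_config())
  # nucleus spans z in [-20, -10) for tcell = 30, lnuc = 10 centred; probe
  # at a cell centre (with even n the beam axis itself is a shared corner
  # of four cells, so (0, 0, z) lies in cytoplasm)
  expect_equal(locate_region(geom, c(15, 15, -15))$domain, "nucleus")
  expect_equal(locate_region(geom, c(15, 15, -9))$domain, "cytoplasm")
  expect_equal(locate_region(geom, c(15, 15, -20))$domain, "nucleus")
  expect_equal(locate_region(geom, c(0, 0, -15))$domain, "cytoplasm")
  expect_equal(locate_region(geom, c(0, 0, 500))$domain, "buffer")
  expect_equal(locate_region(geom, c(15, 15, -29))$domain, "cytoplasm")
  expect_equal(locate_region(geom, c(0, 0, 2e5))$domain, "escaped")
  expect_equal(locate_region(geom, c(29, 15, -15))$domain, "cytoplasm")
  # an odd-sized array does have a centre cell owning the axis
  geom3 <- build_geometry(simulation_config(e0 = 25, n = 3, airad = 1))
  at <- locate_region(geom3, c(0, 0, -15))
  expect_equal(at$domain, "nucleus")
  expect_equal(at$cell, 5)  # centre cell of the 3 x 3 array
})

test_that("every sampled point maps to exactly one region, gap-free", {
  geom <- build_geometry(small_config(n = 3))
  set.seed(5)
  n <- 1e4
  pts <- cbind(runif(n, -45, 45), runif(n, -45, 45), runif(n, -30, 0))
  loc <- locate_region(geom, pts)
  expect_true(all(loc$id >= 3))   # never ambient/buffer inside the layer
  expect_equal(length(loc$id), n)
  # translation consistency: shifting one cell pitch shifts the cell index
  inner <- pts[, 1] < 15 & pts[, 1] >= -45 + 30  # stays inside after shift
  shifted <- locate_region(geom, cbind(pts[inner, 1] + 30, pts[inner, 2],
                                       pts[inner, 3]))
  expect_equal(shifted$cell, loc$cell[inner] + 1)
  expect_equal(shifted$domain, loc$domain[inner])
})

test_that("boron assignment honours the three cytoplasm modes", {
  cfg0 <- small_config(cytob = 0)
  expect_equal(sum(build_geometry(cfg0)$borcheck), 0)
  cfg1 <- small_config(cytob = 1)
  expect_equal(mean(build_geometry(cfg1)$borcheck), 1)
  # mode 2: below-0.5 rule; binomial 3 sigma band at 1e4 draws
  cfg2 <- simulation_config(e0 = 25, n = 100, airad = 3, cytob = 2,
                            seed = 4)
  frac <- mean(build_geometry(cfg2)$borcheck)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
  # the acceptance threshold is exposed
  cfg3 <- simulation_config(e0 = 25, n = 50, airad = 2, cytob = 2,
                            seed = 4, bthresh = 0.2)
  expect_lt(abs(mean(build_geometry(cfg3)$borcheck) - 0.2),
            3 * sqrt(0.2 * 0.8 / 2500))
})

test_that("mode-2 boron fraction is unbiased over many seeds", {
  hits <- 0L
  draws <- 0L
  for (s in 1:25) {
    g <- build_geometry(scheme_config(cytob = 2, seed = s))
    hits <- hits + sum(g$borcheck)
    draws <- draws + length(g$borcheck)
  }
  expect_gte(draws, 1e4)
  expect_gt(stats::binom.test(hits, draws, 0.5)$p.value, 1e-3)
})

test_that("nucleus boron follows the cytoplasm flag only when enabled", {
  g1 <- build_geometry(scheme_config(cytob = 2, nuclb = 1, seed = 8))
  expect_equal(g1$nucb, g1$borcheck)
  g0 <- build_geometry(scheme_config(cytob = 2, nuclb = 0, seed = 8))
  expect_equal(sum(g0$nucb), 0)
  expect_equal(g0$borcheck, g1$borcheck)  # same draws, same layout
})

test_that("the rendered boron grid matches the flags one-to-one", {
  g <- build_geometry(scheme_config(cytob = 2, seed = 7))
  grid <- render_boron_grid(g)
  expect_equal(dim(grid), c(20, 20))
  expect_equal(sum(grid %in% c("B", "b")), sum(g$borcheck))
  # row-major flags: row iy of the grid (from the top) is y row n-iy
  flags <- matrix(g$borcheck, nrow = 20, byrow = TRUE)[rev(1:20), ]
  expect_equal(unclass(grid) != ".", flags == 1,
               ignore_attr = TRUE)
  # degenerate cases
  g_all <- build_geometry(small_config(n = 2, cytob = 1))
  expect_equal(sum(render_boron_grid(g_all) %in% c("B", "b")), 4)
  g_none <- build_geometry(small_config(n = 2, cytob = 0))
  expect_equal(sum(render_boron_grid(g_none) == "."), 4)
})

test_that("geometry exports a complete JSON region list", {
  g <- build_geometry(small_config(n = 2, cytob = 1))
  js <- jsonlite::fromJSON(geometry_to_json(g))
  expect_equal(nrow(js), 2 + 2 * 4)
  expect_true(all(c("id", "domain", "borcheck", "material") %in% names(js)))
  expect_equal(sum(js$domain == "nucleus"), 4)
})
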