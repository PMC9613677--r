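test_that("a small deck carries all nine sections with complete cards", {
  cfg <- simulation_config(e0 = 25, n = 2, airad = 1, cytob = 1)
  deck <- export_phits_deck(cfg)
  sec <- phits_deck_sections(deck)
  expect_setequal(names(sec),
                  c("Title", "Parameters", "Source", "Material", "Surface",
                    "Cell", "T-Track", "T-Deposit", "T-Gshow"))
  n2 <- 4
  # one RPP per cell box and per nucleus, plus buffer RPP and sphere
  expect_equal(sum(grepl(" rpp ", sec$Surface)), 2 * n2 + 1)
  expect_equal(sum(grepl(" so ", sec$Surface)), 1)
  # one cell card per region: cytoplasm, nucleus, buffer, ambient, void
  cell_cards <- grep("^  \\d+ ", sec$Cell, value = TRUE)
  expect_equal(length(cell_cards), 2 * n2 + 3)
  # every material id referenced by a cell card is defined
  mat_ids <- as.integer(sub("^mat\\[(\\d+)\\].*", "\\1",
                            grep("^mat\\[", sec$Material, value = TRUE)))
  used <- as.integer(vapply(strsplit(trimws(cell_cards), " +"),
                            `[[`, "", 2))
  expect_true(all(setdiff(used, -1) %in% mat_ids))
})

test_that("the default 20 x 20 deck has the expected scale", {
  deck <- export_phits_deck(scheme_config())
  expect_gt(length(deck), 1812 / 2)
  expect_lt(length(deck), 1812 * 2)
})

test_that("boron loading only changes material assignments in the deck", {
  d_norm <- export_phits_deck(scheme_config(cytob = 0))
  d_bor <- export_phits_deck(scheme_config(cytob = 1))
  s_norm <- phits_deck_sections(d_norm)
  s_bor <- phits_deck_sections(d_bor)
  expect_identical(s_norm$Surface, s_bor$Surface)
  expect_identical(s_norm$Source, s_bor$Source)
  expect_identical(s_norm$Parameters, s_bor$Parameters)
  expect_identical(s_norm$`T-Track`, s_bor$`T-Track`)
  expect_false(identical(s_norm$Cell, s_bor$Cell))
})

test_that("deck export is a pure function of config and seed", {
  cfg <- scheme_config(cytob = 2, seed = 31)
  expect_identical(export_phits_deck(cfg), export_phits_deck(cfg))
  # a different seed reshuffles the random boron layout
  expect_false(identical(export_phits_deck(cfg),
                         export_phits_deck(scheme_config(cytob = 2,
                                                         seed = 32))))
})

test_that("results survive a save/load round trip", {
  res <- run_simulation(small_config(cytob = 1, maxcas = 300))
  dir <- withr::local_tempdir()
  save_results(res, dir)
  back <- load_results(dir)
  expect_equal(back$dep, res$dep, tolerance = 1e-12)
  expect_equal(back$hits, res$hits)
  expect_equal(unclass(back$config), unclass(res$config))
  expect_equal(back$counters, res$counters)
  expect_equal(total_alpha_dose(back)$mean, total_alpha_dose(res)$mean,
               tolerance = 1e-12)
})

test_that("the CLI runs reproducibly and matches library calls", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  args <- c("generate", "--e0", "25", "--n", "6", "--cytob", "2",
            "--seed", "7", "--airad", "2")
  capture.output(st1 <- suppressMessages(cli(c(args, "--out", out1))))
  capture.output(st2 <- suppressMessages(cli(c(args, "--out", out2))))
  expect_equal(st1, 0L)
  expect_equal(st2, 0L)
  expect_identical(readLines(file.path(out1, "geometry.json")),
                   readLines(file.path(out2, "geometry.json")))
  # the CLI grid equals the library-level geometry at the same seed
  cfg <- simulation_config(e0 = 25, n = 6, cytob = 2, seed = 7, airad = 2)
  expect_identical(readLines(file.path(out1, "geometry.json")),
                   as.character(geometry_to_json(build_geometry(cfg))))
})

test_that("CLI run output files are byte-identical across equal seeds", {
  outs <- replicate(2, withr::local_tempdir(.local_envir = parent.frame()))
  for (o in outs) {
    capture.output(
      st <- suppressMessages(cli(c("run", "--e0", "25", "--n", "4",
                                   "--maxcas", "150", "--maxbch", "2",
                                   "--tbuffer", "300", "--airad", "2",
                                   "--seed", "5", "--out", o))))
    expect_equal(st, 0L)
  }
  for (f in c("deposition.csv", "hits.csv", "counters.csv")) {
    expect_identical(readLines(file.path(outs[1], f)),
                     readLines(file.path(outs[2], f)))
  }
})

test_that("the CLI rejects a missing beam energy, naming the field", {
  msgs <- capture.output(st <- cli(c("run", "--n", "4")),
                         type = "message")
  expect_equal(st, 1L)
  expect_true(any(grepl("e0", msgs)))
  expect_equal(suppressMessages(cli(c("frobnicate"))), 1L)
})

test_that("config file plus flag overrides drive the CLI", {
  dir <- withr::local_tempdir()
  cfgfile <- file.path(dir, "c.yaml")
  write_config(simulation_config(e0 = 35, n = 5, airad = 2, seed = 2),
               cfgfile)
  st <- suppressMessages(cli(c("export-phits", "--config", cfgfile,
                               "--n", "3", "--out", dir)))
  expect_equal(st, 0L)
  deck <- readLines(file.path(dir, "cellarray.inp"))
  expect_true(any(grepl("3 x 3", deck)))
  expect_true(any(grepl("e0 = 35", deck)))
})
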