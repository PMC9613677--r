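# Plain-text persistence of simulation results (CSV + YAML), enough to
# recompute profiles, enhancement factors and hit summaries offline.

.num <- function(x) formatC(x, format = "g", digits = 15)

#' Save simulation results to a directory of CSV files
#'
#' Writes `config.yaml`, `deposition.csv` (region x species x batch, long
#' form), `axial_cell.csv`, `axial_buffer.csv`, `hits.csv` and
#' `counters.csv`. Output is deterministic for a fixed configuration.
#'
#' @param res a `pbft_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_results <- function(res, dir) {
  stopifnot(inherits(res, "pbft_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(res$config, file.path(dir, "config.yaml"))
  d <- res$dep
  nz <- which(d != 0, arr.ind = TRUE)
  dep <- data.frame(region = nz[, 1],
                    species = dimnames(d)[[2]][nz[, 2]],
                    batch = nz[, 3],
                    dep_mev = .num(d[nz]))
  dep <- dep[order(dep$batch, dep$region, dep$species), ]
  utils::write.csv(dep, file.path(dir, "deposition.csv"),
                   row.names = FALSE, quote = FALSE)
  ac <- res$axial_cell
  utils::write.csv(
    data.frame(bin = rep(seq_len(nrow(ac)), ncol(ac)),
               batch = rep(seq_len(ncol(ac)), each = nrow(ac)),
               dep_mev = .num(as.numeric(ac))),
    file.path(dir, "axial_cell.csv"), row.names = FALSE, quote = FALSE)
  ab <- res$axial_buffer
  utils::write.csv(
    data.frame(bin = rep(seq_len(dim(ab)[1]), 2 * dim(ab)[3]),
               species = rep(rep(c("proton", "alpha"),
                                 each = dim(ab)[1]), dim(ab)[3]),
               batch = rep(seq_len(dim(ab)[3]), each = 2 * dim(ab)[1]),
               dep_mev = .num(as.numeric(ab))),
    file.path(dir, "axial_buffer.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(batch = seq_len(ncol(res$hits)),
               nucleus = res$hits["nucleus", ],
               cytoplasm = res$hits["cytoplasm", ]),
    file.path(dir, "hits.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(counter = rownames(res$counters),
               res$counters,
               row.names = NULL),
    file.path(dir, "counters.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load saved results
#'
#' Rebuilds a lightweight `pbft_result` (tallies and counters; no track
#' segments or per-history balance) from a [save_results()] directory.
#'
#' @param dir directory written by [save_results()].
#' @return a `pbft_result`.
#' @export
load_results <- function(dir) {
  cfg <- read_config(file.path(dir, "config.yaml"))
  nreg <- 2L + 2L * cfg$n^2
  opts <- .default_opts(cfg)
  dep <- array(0, dim = c(nreg, 3, cfg$maxbch),
               dimnames = list(NULL, c("proton", "alpha", "residual"),
                               NULL))
  dd <- utils::read.csv(file.path(dir, "deposition.csv"))
  if (nrow(dd)) {
    sp <- match(dd$species, c("proton", "alpha", "residual"))
    dep[cbind(dd$region, sp, dd$batch)] <- dd$dep_mev
  }
  ac_raw <- utils::read.csv(file.path(dir, "axial_cell.csv"))
  nbc <- max(ac_raw$bin)
  ac <- matrix(0, nbc, cfg$maxbch)
  ac[cbind(ac_raw$bin, ac_raw$batch)] <- ac_raw$dep_mev
  ab_raw <- utils::read.csv(file.path(dir, "axial_buffer.csv"))
  nbb <- max(ab_raw$bin)
  ab <- array(0, dim = c(nbb, 2, cfg$maxbch),
              dimnames = list(NULL, c("proton", "alpha"), NULL))
  ab[cbind(ab_raw$bin, match(ab_raw$species, c("proton", "alpha")),
           ab_raw$batch)] <- ab_raw$dep_mev
  hits_raw <- utils::read.csv(file.path(dir, "hits.csv"))
  hits <- rbind(nucleus = hits_raw$nucleus, cytoplasm = hits_raw$cytoplasm)
  cnt_raw <- utils::read.csv(file.path(dir, "counters.csv"))
  counters <- as.matrix(cnt_raw[, -1, drop = FALSE])
  dimnames(counters) <- list(cnt_raw$counter, NULL)
  opts$nbins_cell <- nbc
  opts$bw_cell <- cfg$tcell / nbc
  opts$nbins_buffer <- nbb
  opts$bw_buffer <- cfg$tbuffer / nbb
  structure(list(config = cfg, geometry = build_geometry(cfg),
                 source = NULL, opts = opts, n_regions = nreg, dep = dep,
                 axial_cell = ac, axial_buffer = ab, counters = counters,
                 hits = hits, hit_pairs = NULL,
                 balance = list(max_error = NA_real_, per_history = NULL),
                 segments = NULL,
                 e_source = rep(NA_real_, cfg$maxbch)),
            class = "pbft_result")
}
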