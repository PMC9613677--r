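# Counter-based uniform generator for transport decisions.
#
# Every in-flight random decision (reaction firing, channel choice, product
# emission angles, optional scattering deflections) is a pure function of
# (seed, batch, history, step, purpose) through a 32-bit integer hash. This
# gives bit-reproducible runs, makes each history an independent substream,
# and lets paired scenarios (e.g. boron vs normal at the same seed) share
# common random numbers exactly, which is what stabilizes paired
# enhancement-factor estimates. Arithmetic is done on doubles holding
# unsigned 32-bit values (products split into 16-bit halves stay exact in
# double precision).

.mod32 <- function(x) x %% 4294967296

.mul32 <- function(a, b) {
  al <- a %% 65536; ah <- a %/% 65536
  bl <- b %% 65536; bh <- b %/% 65536
  (al * bl + ((al * bh + ah * bl) %% 65536) * 65536) %% 4294967296
}

.xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

.rsh32 <- function(x, k) x %/% 2^k

# murmur3-style finalizer
.fmix32 <- function(h) {
  h <- .xor32(h, .rsh32(h, 16))
  h <- .mul32(h, 2246822507)
  h <- .xor32(h, .rsh32(h, 13))
  h <- .mul32(h, 3266489909)
  .xor32(h, .rsh32(h, 16))
}

# Uniform(0,1) draws keyed by (seed, batch, hist, step, purpose); hist and
# step may be vectors (recycled together), seed/batch/purpose scalars.
.hash_u01 <- function(seed, batch, hist, step, purpose) {
  key <- .mod32(.mul32(.mod32(seed), 2654435761) +
                .mul32(.mod32(batch), 1013904223) +
                .mul32(.mod32(purpose), 374761393))
  h <- .xor32(key, .mul32(.mod32(hist), 2246822519))
  h <- .fmix32(h)
  h <- .xor32(h, .mul32(.mod32(step), 2654435761))
  h <- .fmix32(h)
  (h + 0.5) / 4294967296
}
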