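## Shared, lazily-built fixtures. Everything is generated in code from
## fixed seeds; expensive objects are memoised for the whole test run.

.fix_env <- new.env(parent = emptyenv())

## Small 64x64 fixture set (speckle references, known-shift pair, star
## pair, tiny training set).
fixtures <- function() {
  if (is.null(.fix_env$fx)) .fix_env$fx <- make_fixtures(seed = 101L)
  .fix_env$fx
}

## One medium 128x128 speckle reference (default geometry/diffuser).
ref128 <- function() {
  if (is.null(.fix_env$r128)) {
    .fix_env$r128 <- simulate_pair(imaging_geometry(),
                                   diffuser_spec(seed = 201L),
                                   shape = c(128L, 128L),
                                   seed = 201L)$reference$data
  }
  .fix_env$r128
}

## The acceptance-scale reference set: n 256x256 references, simulated
## once and shared by the acceptance tests.
refs256 <- function(n = 10L) {
  key <- paste0("refs256_", n)
  if (is.null(.fix_env[[key]])) {
    geom <- imaging_geometry()
    .fix_env[[key]] <- lapply(seq_len(n), function(i) {
      simulate_pair(geom, diffuser_spec(seed = 300L + i),
                    shape = c(256L, 256L), seed = 300L + i)$reference$data
    })
  }
  .fix_env[[key]]
}
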