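## Deterministic small fixtures for tests and demonstrations: built from
## the full simulation chain at reduced grid sizes (fast, byte-stable).

#' Generate the standard fixture set
#'
#' Small deterministic objects used throughout the test suite: two 64 x 64
#' speckle reference images, known-shift warped pairs, a star-pattern
#' pair, and a tiny 8-item training set. All randomness derives from the
#' given seed; the same seed reproduces the set bit-identically.
#'
#' @param seed Integer seed.
#' @param shape Fixture image shape.
#' @return A list of class `fixture_set` with elements `references`,
#'   `known_shift` (list with `reference`, `sample`, `shift`), `star`
#'   (list with `reference`, `sample`, `pattern`), `train_items` (8 items
#'   for [cade_train()]), `visibility` (per reference), `seed`.
#' @export
make_fixtures <- function(seed = 1L, shape = c(64L, 64L)) {
  geom <- imaging_geometry()
  refs <- lapply(1:2, function(i) {
    simulate_pair(geom, diffuser_spec(seed = derive_seed(seed, i)),
                  shape = shape, seed = derive_seed(seed, i))$reference$data
  })
  shift <- c(0.4, -0.25)
  ks_field <- constant_field(shape, shift[1], shift[2])
  known_shift <- list(reference = refs[[1]],
                      sample = warp(refs[[1]], ks_field),
                      shift = shift, field = ks_field)
  star <- make_star_pattern(shape, wavelength_range = c(4, 60))
  star_pair <- list(reference = refs[[2]],
                    sample = warp(refs[[2]], star$field),
                    pattern = star)
  shifts <- list(c(0.3, -0.2), c(-0.5, 0.1), c(0.15, 0.15), c(0.7, -0.6))
  train_items <- list()
  for (r in 1:2) {
    for (k in seq_along(shifts)) {
      f <- constant_field(shape, shifts[[k]][1], shifts[[k]][2])
      train_items[[length(train_items) + 1L]] <-
        list(reference = refs[[r]], sample = warp(refs[[r]], f), truth = f)
    }
  }
  structure(list(references = refs, known_shift = known_shift,
                 star = star_pair, train_items = train_items,
                 visibility = vapply(refs, visibility, numeric(1)),
                 seed = seed),
            class = "fixture_set")
}
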