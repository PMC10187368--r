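## Dataset assembly: reference images x random deformations -> persisted
## (reference, sample, ground truth) triplets with a reproducible manifest.

#' Dataset manifest
#'
#' Describes a training/testing dataset: how many deformations to draw per
#' reference, the share of special (identity / constant) deformation maps,
#' the attenuation range and the photon fluence. The full-fidelity
#' configuration of record is 364 references with 60 training and 10
#' testing deformations each (21840 / 3640 image sets); scaled-down runs
#' use the same composition at smaller counts.
#'
#' @param n_references Number of reference images.
#' @param deformations_per_reference Named vector `c(train = , test = )`.
#' @param special_fraction Total fraction of special deformation maps,
#'   split evenly over the four kinds (identity, constant x, constant y,
#'   constant xy); default 0.02 (0.5% each).
#' @param small_constant_range Constant displacements are drawn within this
#'   half-range (pixels), the small-displacement augmentation.
#' @param patch_sizes Candidate deformation patch sizes.
#' @param transmission_range Patchwise attenuation range.
#' @param fluence Mean photons per pixel for the Poisson noise.
#' @param seed Global dataset seed; every item derives its own stream.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(n_references,
                             deformations_per_reference = c(train = 60L,
                                                            test = 10L),
                             special_fraction = 0.02,
                             small_constant_range = 0.15,
                             patch_sizes = c(4L, 8L, 16L, 32L, 64L, 128L),
                             transmission_range = c(0.5, 1.0),
                             fluence = default_fluence(),
                             seed = 1L) {
  stopifnot(n_references >= 1, all(deformations_per_reference >= 0),
            special_fraction >= 0, special_fraction < 1,
            transmission_range[1] > 0, transmission_range[2] <= 1)
  structure(list(n_references = as.integer(n_references),
                 deformations_per_reference = deformations_per_reference,
                 special_fraction = special_fraction,
                 small_constant_range = small_constant_range,
                 patch_sizes = as.integer(patch_sizes),
                 transmission_range = transmission_range,
                 fluence = fluence, seed = as.integer(seed)),
            class = "dataset_manifest")
}

## Draw the per-item deformation spec (kind, patch size, seeds) for item i
## of a dataset; deterministic given the manifest seed.
item_spec <- function(manifest, i, image_shape) {
  with_seed(derive_seed(manifest$seed, i), {
    u <- stats::runif(1)
    specials <- c("identity", "constant_x", "constant_y", "constant_xy")
    if (u < manifest$special_fraction) {
      kind <- specials[1L + (floor(u / (manifest$special_fraction / 4)) %% 4)]
      ps <- manifest$patch_sizes[1]
      rng <- c(-1, 1) * manifest$small_constant_range
    } else {
      kind <- "random_patches"
      ok <- manifest$patch_sizes[image_shape[1] %% manifest$patch_sizes == 0 &
                                 image_shape[2] %% manifest$patch_sizes == 0]
      ps <- sample(ok, 1L)
      rng <- c(-1, 1)
    }
    list(kind = kind, patch_size = ps, amplitude_range = rng,
         deform_seed = sample.int(2^31 - 2, 1L),
         trans_seed = sample.int(2^31 - 2, 1L),
         noise_seed_ref = sample.int(2^31 - 2, 1L),
         noise_seed_sam = sample.int(2^31 - 2, 1L))
  })
}

## Build one (reference, sample, truth) triplet from its item spec.
make_triplet <- function(reference, ispec, manifest) {
  refm <- as_image_matrix(reference)
  dspec <- deformation_spec(ispec$kind, ispec$patch_size,
                            ispec$amplitude_range, seed = ispec$deform_seed)
  field <- generate_deformation(dspec, dim(refm))
  sam <- warp(refm, field)
  sam <- apply_transmission(sam, patch_size = ispec$patch_size,
                            range = manifest$transmission_range,
                            seed = ispec$trans_seed)$image
  ref_n <- add_poisson_noise(refm, manifest$fluence, seed = ispec$noise_seed_ref)
  sam_n <- add_poisson_noise(sam, manifest$fluence, seed = ispec$noise_seed_sam)
  list(reference = ref_n, sample = sam_n, truth = field, spec = ispec)
}

#' Build a speckle-deformation dataset
#'
#' Emits `(reference, sample, ground truth)` triplets for every reference
#' and every train/test deformation index: about 98% random piecewise
#' patch deformations, the rest split evenly across identity and constant
#' maps; the sample image is patchwise attenuated and both images receive
#' independent Poisson noise. Fully reproducible: each item's seeds derive
#' from the manifest seed and are recorded.
#'
#' @param manifest A [dataset_manifest()].
#' @param references List of reference images (matrices or
#'   [speckle_image()]s), length `n_references`.
#' @param dir Optional output directory: triplets are written as float
#'   TIFFs (`*_ref.tif`, `*_sam.tif`, `*_ux.tif`, `*_uy.tif`) plus a
#'   `manifest.yaml`; if `NULL` the triplets are returned in memory.
#' @param split `"train"`, `"test"` or `"both"`.
#' @return A list with `items` (in-memory triplets or file stems),
#'   `manifest`, and `counts` (named train/test totals).
#' @export
build_dataset <- function(manifest, references, dir = NULL, split = "both") {
  stopifnot(inherits(manifest, "dataset_manifest"),
            length(references) == manifest$n_references)
  split <- match.arg(split, c("both", "train", "test"))
  shape <- dim(as_image_matrix(references[[1]]))
  dpr <- manifest$deformations_per_reference
  want <- c(train = unname(dpr["train"]), test = unname(dpr["test"]))
  if (split == "train") want["test"] <- 0L
  if (split == "test") want["train"] <- 0L
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  items <- list()
  parts <- character()
  idx <- 0L
  global_item <- 0L
  for (r in seq_len(manifest$n_references)) {
    for (part in c("train", "test")) {
      n_it <- if (part == "train") dpr["train"] else dpr["test"]
      for (j in seq_len(n_it)) {
        global_item <- global_item + 1L
        if (want[part] == 0L) next
        if (j > want[part]) next
        ispec <- item_spec(manifest, global_item, shape)
        ispec$reference_index <- r
        ispec$part <- part
        trip <- make_triplet(references[[r]], ispec, manifest)
        idx <- idx + 1L
        parts[idx] <- part
        if (is.null(dir)) {
          items[[idx]] <- trip
        } else {
          stem <- sprintf("%s_r%03d_d%03d", part, r, j)
          write_image(as_image_matrix(trip$reference),
                      file.path(dir, paste0(stem, "_ref.tif")))
          write_image(as_image_matrix(trip$sample),
                      file.path(dir, paste0(stem, "_sam.tif")))
          write_image(trip$truth$ux, file.path(dir, paste0(stem, "_ux.tif")))
          write_image(trip$truth$uy, file.path(dir, paste0(stem, "_uy.tif")))
          items[[idx]] <- c(list(stem = stem), ispec)
        }
      }
    }
  }
  counts <- c(train = sum(parts == "train"), test = sum(parts == "test"))
  out <- list(items = items, manifest = manifest, counts = counts)
  if (!is.null(dir)) {
    yaml::write_yaml(list(manifest = unclass(manifest),
                          items = lapply(items, function(it)
                            lapply(it, function(v) if (is.numeric(v)) unname(v) else v))),
                     file.path(dir, "manifest.yaml"))
    out$dir <- dir
  }
  out
}
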