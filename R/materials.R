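## Embedded optical-constants table (30 keV). Kept as a plain CSV under
## inst/extdata so the literature provenance can be recorded next to the
## numbers; loaded once per session.

.materials_env <- new.env(parent = emptyenv())

#' Optical constants at 30 keV
#'
#' Returns the embedded table of refractive index decrement delta and linear
#' attenuation coefficient mu (1/um) for the materials used by the simulator
#' (Al2O3 sandpaper grains, C6H10O5 backing, PMMA phantom).
#'
#' @param material Optional material name; if given, returns a single-row
#'   list with elements `delta`, `mu`, `density_g_cm3`.
#' @return A data.frame (all materials) or a list (one material).
#' @export
optical_constants <- function(material = NULL) {
  if (is.null(.materials_env$tab)) {
    path <- system.file("extdata", "optical_constants_30kev.csv",
                        package = "speckletrack")
    if (!nzchar(path)) path <- file.path("inst", "extdata",
                                         "optical_constants_30kev.csv")
    .materials_env$tab <- utils::read.csv(path, comment.char = "#",
                                          stringsAsFactors = FALSE)
  }
  tab <- .materials_env$tab
  if (is.null(material)) return(tab)
  i <- match(material, tab$material)
  if (is.na(i)) stop("unknown material: ", material)
  list(material = tab$material[i], delta = tab$delta[i],
       mu = tab$mu_per_um[i], density_g_cm3 = tab$density_g_cm3[i])
}
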