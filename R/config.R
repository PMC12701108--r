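# Pipeline configuration: one nested list of defaults, overridable from a
# YAML file. Defaults follow the reference acquisition (654.762 um/px,
# phases 2 and 3, 10-px crop margin, 15-px / 0.95 rules).

#' Default CAD pipeline configuration
#'
#' @param ... named overrides of top-level entries (nested lists are
#'   replaced wholesale; use [load_cad_config()] for deep merges).
#' @return named list of configuration entries: segmentation (`phases`,
#'   `background_level`, `margin_px`, `clahe`, `asf_radii`,
#'   `n_thresholds`), rules (`connectivity`, `min_area`, `max_ecc`,
#'   `min_max_dimension`), features (`dilate_radius`, `grow_radius`,
#'   `glcm_levels`, `glcm_distances`, `feature_extras`), classification
#'   (`relieff_k`, `folds`, `repeats`, `hidden`).
#' @export
cad_config <- function(...) {
  cfg <- list(
    phases = c(2L, 3L),
    background_level = 0,
    margin_px = 10L,
    clahe = list(tiles = c(8L, 8L), clip_limit = 0.01, alpha = 0.4),
    asf_radii = c(1L, 2L),
    n_thresholds = 4L,
    connectivity = 8L,
    min_area = 15L,
    max_ecc = 0.95,
    min_max_dimension = NULL,
    dilate_radius = 1L,
    grow_radius = 4L,
    glcm_levels = 8L,
    glcm_distances = c(1L, 2L),
    feature_extras = FALSE,
    relieff_k = 10L,
    folds = 5L,
    repeats = 5L,
    hidden = c(6L, 10L))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Load configuration overrides from YAML
#'
#' Reads a YAML file and deep-merges it over [cad_config()] defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_cad_config <- function(path) {
  over <- yaml::read_yaml(path)
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge2(cad_config(), over)
}
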