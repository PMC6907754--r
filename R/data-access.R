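#' Per-plant survey summary of the Garraf scrubland study
#'
#' The published per-plant summary table of the Garraf Natural Park
#' (Barcelona, NE Spain) pollination survey: for each of the 19 surveyed
#' plant species, its code, the number of pollinator species recorded on it,
#' the mean and SD of visits per encounter (mean over pollinator species),
#' and the floral display (mean open flowers per individual at peak bloom).
#'
#' These 19 rows are the input of the display-to-visits regression: plants
#' with larger floral displays receive more visits per encounter.
#'
#' @return data frame with columns `code`, `plant_species`,
#'   `n_pollinator_species`, `visits_per_encounter`, `visits_sd`,
#'   `floral_display`.
#' @examples
#' tab <- garraf_plants()
#' fit_regression(tab$floral_display, tab$visits_per_encounter,
#'                transform_x = "log", transform_y = "log",
#'                labels = tab$code)
#' @export
garraf_plants <- function() {
  path <- system.file("extdata", "garraf_table1.csv", package = "visitnet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Path to the deposited long-format interaction-strength dataset of the
# Garraf study, if the user has placed it in the package's extdata (it is
# distributed as journal supplementary material, not with this package).
garraf_s1_path <- function() {
  system.file("extdata", "s1_interactions.csv", package = "visitnet")
}
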