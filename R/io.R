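#' Read the three survey tables
#'
#' Reads and validates the long-format field survey files:
#' \describe{
#'   \item{encounters}{CSV `week,plant,pollinator` — one row per encounter
#'     (an individual pollinator observed on an individual plant).}
#'   \item{flowers}{CSV `week,plant,flowers_surveyed,flower_abundance` — at
#'     most one row per (week, plant): open flowers counted on the observed
#'     (tagged) individuals, and the weekly flower density from transects.}
#'   \item{visits}{CSV `plant,pollinator,n_visits` — one row per 4-minute
#'     pollinator follow, recording the number of flowers (inflorescences in
#'     Asteraceae) visited; a recorded encounter involves at least one.}
#' }
#' Unknown columns are ignored with a warning. Column names can be remapped
#' via the `*_cols` arguments, since deposited datasets vary in layout.
#'
#' @param encounters_path,flowers_path,visits_path file paths
#' @param encounter_cols,flower_cols,visit_cols named character vectors
#'   mapping the canonical names above to the column names in the file,
#'   e.g. `c(week = "wk", plant = "plant_sp", pollinator = "poll_sp")`.
#' @return list with data frames `encounters`, `flowers`, `visits`.
#' @export
read_survey_tables <- function(encounters_path, flowers_path, visits_path,
                               encounter_cols = NULL, flower_cols = NULL,
                               visit_cols = NULL) {
  enc <- read_mapped_csv(encounters_path, c("week", "plant", "pollinator"),
                         encounter_cols)
  flw <- read_mapped_csv(flowers_path,
                         c("week", "plant", "flowers_surveyed", "flower_abundance"),
                         flower_cols)
  vis <- read_mapped_csv(visits_path, c("plant", "pollinator", "n_visits"),
                         visit_cols)

  check_week(enc$week, encounters_path)
  check_labels(enc, c("plant", "pollinator"), encounters_path)

  check_week(flw$week, flowers_path)
  check_labels(flw, "plant", flowers_path)
  check_nonneg(flw$flowers_surveyed, "flowers_surveyed", flowers_path)
  check_nonneg(flw$flower_abundance, "flower_abundance", flowers_path)
  dup <- duplicated(flw[c("week", "plant")])
  if (any(dup)) {
    d <- flw[which(dup)[1L], ]
    stop(sprintf("duplicate flower-survey row for (week %d, plant %s) in %s",
                 d$week, d$plant, flowers_path), call. = FALSE)
  }

  check_labels(vis, c("plant", "pollinator"), visits_path)
  if (any(!is.finite(vis$n_visits)) || any(vis$n_visits < 1)) {
    bad <- which(!is.finite(vis$n_visits) | vis$n_visits < 1)[1L]
    stop(sprintf("row %d of %s violates n_visits >= 1 (a recorded encounter involves at least one flower visit)",
                 bad, visits_path), call. = FALSE)
  }

  list(encounters = enc, flowers = flw, visits = vis)
}

read_mapped_csv <- function(path, required, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canonical in names(mapping)) {
      pos <- match(mapping[[canonical]], names(df))
      if (!is.na(pos)) names(df)[pos] <- canonical
    }
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0L) {
    warning(sprintf("%s: ignoring unknown column(s): %s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

check_week <- function(week, path) {
  if (any(!is.finite(week)) || any(week < 1) || any(week != floor(week))) {
    bad <- which(!is.finite(week) | week < 1 | week != floor(week))[1L]
    stop(sprintf("row %d of %s: week must be an integer >= 1", bad, path),
         call. = FALSE)
  }
}

check_labels <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (any(is.na(v)) || any(!nzchar(as.character(v)))) {
      bad <- which(is.na(v) | !nzchar(as.character(v)))[1L]
      stop(sprintf("row %d of %s: empty %s label", bad, path, cl), call. = FALSE)
    }
  }
}

check_nonneg <- function(v, name, path) {
  if (any(!is.finite(v)) || any(v < 0)) {
    bad <- which(!is.finite(v) | v < 0)[1L]
    stop(sprintf("row %d of %s: %s must be a nonnegative number", bad, path, name),
         call. = FALSE)
  }
}

#' Read a pre-aggregated interaction-strength matrix
#'
#' Reads a long-format strength file (one row per link) such as the deposited
#' network dataset, with columns `plant`, `pollinator` and one strength
#' column per measure (`strength_encounter`, `strength_visit`, or a single
#' `strength`). Zero-strength rows are treated as absent links; species left
#' without links are dropped.
#'
#' @param path file path
#' @param measure which measure to read, `"encounter"` or `"visit"`
#' @param plant_col,pollinator_col,strength_col column names in the file;
#'   `strength_col = NULL` tries `strength_<measure>` then `strength`.
#' @return a [bipartite_network()]
#' @export
read_strength_matrix <- function(path, measure = c("encounter", "visit"),
                                 plant_col = "plant",
                                 pollinator_col = "pollinator",
                                 strength_col = NULL) {
  measure <- match.arg(measure)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty strength file: ", path, call. = FALSE)
  if (is.null(strength_col)) {
    candidates <- c(paste0("strength_", measure), "strength")
    strength_col <- candidates[candidates %in% names(df)][1L]
    if (is.na(strength_col)) {
      stop(sprintf("%s has no strength column for measure '%s' (looked for %s)",
                   path, measure, paste(candidates, collapse = ", ")),
           call. = FALSE)
    }
  }
  for (cl in c(plant_col, pollinator_col, strength_col)) {
    if (!cl %in% names(df)) {
      stop(sprintf("%s is missing required column: %s", path, cl), call. = FALSE)
    }
  }
  cells <- data.frame(plant = df[[plant_col]],
                      pollinator = df[[pollinator_col]],
                      strength = df[[strength_col]],
                      stringsAsFactors = FALSE)
  bipartite_network(cells, measure)
}

#' Write a network as a long-format strength file
#'
#' Writes the positive cells of a network to CSV with header
#' `plant,pollinator,strength_<measure>`. Values are written with 17
#' significant digits so that [read_strength_matrix()] round-trips the
#' network exactly.
#'
#' @param network a `bipartite_network`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "bipartite_network"))
  cells <- network_cells(network)
  if (nrow(cells) == 0L) stop("refusing to write an empty network", call. = FALSE)
  out <- data.frame(plant = cells$plant, pollinator = cells$pollinator,
                    strength = sprintf("%.17g", cells$strength),
                    stringsAsFactors = FALSE)
  names(out)[3] <- paste0("strength_", network$measure)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write network to ", path, call. = FALSE)
  invisible(path)
}

#' Read plant trait table (floral display)
#'
#' CSV with header `plant,floral_display`: the mean number of open flowers
#' per individual at peak bloom, one row per plant species.
#'
#' @param path file path
#' @return data frame with columns `plant`, `floral_display`.
#' @export
read_plant_traits <- function(path) {
  df <- read_mapped_csv(path, c("plant", "floral_display"))
  if (any(!is.finite(df$floral_display)) || any(df$floral_display <= 0)) {
    bad <- which(!is.finite(df$floral_display) | df$floral_display <= 0)[1L]
    stop(sprintf("row %d of %s: floral_display must be positive", bad, path),
         call. = FALSE)
  }
  df
}

#' Read the donor/expert imputation configuration
#'
#' YAML file with two optional sections:
#' \preformatted{
#' donors:
#'   - {plant: CAL, pollinator: "Andrena sp2", donor_pollinator: "Andrena sp1"}
#' expert_defaults:
#'   - {plant: ILU, pollinator: "Oedemera sp", mean_visits: 1}
#' }
#' Donors express "use the visits-per-encounter of a functionally similar
#' pollinator on the same plant"; expert defaults are judgement-call values
#' for interactions with neither own nor donor observations.
#'
#' @param path YAML file path
#' @return list with data frames `donors` (plant, pollinator,
#'   donor_pollinator) and `expert_defaults` (plant, pollinator, mean_visits),
#'   either possibly empty.
#' @export
read_imputation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  donors <- bind_config_rows(cfg$donors,
                             c("plant", "pollinator", "donor_pollinator"))
  expert <- bind_config_rows(cfg$expert_defaults,
                             c("plant", "pollinator", "mean_visits"))
  if (nrow(expert) > 0L) {
    expert$mean_visits <- as.numeric(expert$mean_visits)
    if (any(!is.finite(expert$mean_visits)) || any(expert$mean_visits < 1)) {
      stop("expert_defaults mean_visits must be >= 1", call. = FALSE)
    }
  }
  list(donors = donors, expert_defaults = expert)
}

bind_config_rows <- function(entries, fields) {
  if (is.null(entries) || length(entries) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(fields)),
                                         fields), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(entries, function(e) {
    if (!all(fields %in% names(e))) {
      stop("imputation config entry missing field(s): ",
           paste(setdiff(fields, names(e)), collapse = ", "), call. = FALSE)
    }
    as.data.frame(e[fields], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
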