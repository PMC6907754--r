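#' Scenario configuration for the synthetic survey generator
#'
#' Bundles, with validation, every knob of the synthetic community and
#' survey generator. The defaults emulate the structure of a Mediterranean
#' scrubland pollination survey: 19 plant species and 122 pollinator
#' morphotypes in eight functional groups (39 bees, 27 Coleoptera, 20
#' Diptera, 15 Lepidoptera, 9 wasps, 8 ants, 3 Heteroptera, 1 Orthoptera), a
#' 14-week March-June season, on the order of 4249 encounter events,
#' log-normal floral displays, a positive log-log relation between floral
#' display and visits per encounter, and heavy-tailed (Dirichlet,
#' low-concentration) pollinator preferences producing a few strong and many
#' weak interactions.
#'
#' @param n_plants,n_pollinators,n_weeks community and season size (all >= 2)
#' @param group_sizes named integer vector of pollinator functional-group
#'   sizes; rescaled to sum to `n_pollinators`
#' @param group_visit_effect named numeric vector, log-scale additive effect
#'   of each group on visits per encounter
#' @param display_meanlog,display_sdlog log-normal floral display parameters
#'   (mean open flowers per individual at peak bloom)
#' @param visits_slope,visits_intercept,visits_sd the log-log
#'   display-to-visits relation: `log E[visits] = intercept + slope *
#'   log(display) + group effect + N(0, sd)`
#' @param concentration Dirichlet concentration of pollinator preferences
#'   over plants; smaller is heavier-tailed
#' @param encounter_total target expected number of encounter events
#' @param survey_fraction expected fraction of open flowers on surveyed
#'   (tagged) individuals
#' @param nb_size negative-binomial size (overdispersion) for encounter
#'   counts; smaller is more overdispersed
#' @param samples_per_interaction mean number of 4-minute follows per
#'   interaction
#' @param zero_sample_fraction fraction of interactions deliberately given
#'   no follow observations, to exercise the imputation hierarchy
#' @param min_bloom_weeks,max_bloom_weeks bounds of the contiguous per-plant
#'   bloom window
#' @param seed integer; one global seed governs all draws (the community,
#'   encounter and visit-sample stages use `seed`, `seed + 1`, `seed + 2`)
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_plants = 19, n_pollinators = 122, n_weeks = 14,
                            group_sizes = c(bee = 39, coleoptera = 27,
                                            diptera = 20, lepidoptera = 15,
                                            wasp = 9, ant = 8,
                                            heteroptera = 3, orthoptera = 1),
                            group_visit_effect = c(bee = 0.4,
                                                   coleoptera = -0.4,
                                                   diptera = 0,
                                                   lepidoptera = 0.1,
                                                   wasp = 0, ant = -0.2,
                                                   heteroptera = -0.1,
                                                   orthoptera = 0),
                            display_meanlog = 3, display_sdlog = 1.7,
                            visits_slope = 0.285, visits_intercept = 0.26,
                            visits_sd = 0.66,
                            concentration = 0.3,
                            encounter_total = 4249,
                            survey_fraction = 0.2,
                            nb_size = 0.8,
                            samples_per_interaction = 5,
                            zero_sample_fraction = 0.1,
                            min_bloom_weeks = 4, max_bloom_weeks = 10,
                            seed = 1) {
  cfg <- list(n_plants = n_plants, n_pollinators = n_pollinators,
              n_weeks = n_weeks, group_sizes = group_sizes,
              group_visit_effect = group_visit_effect,
              display_meanlog = display_meanlog,
              display_sdlog = display_sdlog,
              visits_slope = visits_slope,
              visits_intercept = visits_intercept, visits_sd = visits_sd,
              concentration = concentration,
              encounter_total = encounter_total,
              survey_fraction = survey_fraction, nb_size = nb_size,
              samples_per_interaction = samples_per_interaction,
              zero_sample_fraction = zero_sample_fraction,
              min_bloom_weeks = min_bloom_weeks,
              max_bloom_weeks = max_bloom_weeks, seed = seed)
  with(cfg, {
    stopifnot(n_plants >= 2, n_pollinators >= 2, n_weeks >= 2,
              all(group_sizes >= 0), sum(group_sizes) > 0,
              all(names(group_sizes) %in% names(group_visit_effect)),
              is.finite(display_sdlog), display_sdlog > 0,
              is.finite(visits_slope), is.finite(visits_sd), visits_sd >= 0,
              concentration > 0, encounter_total >= 1,
              survey_fraction > 0, survey_fraction <= 1, nb_size > 0,
              samples_per_interaction > 0,
              zero_sample_fraction >= 0, zero_sample_fraction < 1,
              min_bloom_weeks >= 1, max_bloom_weeks >= min_bloom_weeks,
              max_bloom_weeks <= n_weeks)
  })
  structure(cfg, class = "scenario_config")
}

#' Generate a synthetic plant-pollinator community
#'
#' Draws floral displays from the configured log-normal, assigns pollinators
#' to functional groups with heavy-tailed activity levels, draws each
#' pollinator's preference distribution over plants from a Dirichlet (rows
#' summing to 1), and gives each plant a contiguous bloom window.
#'
#' @param config a [scenario_config()]
#' @return list of class `pollination_community` with elements `traits`
#'   (plant, floral_display), `pollinators` (pollinator, group, activity),
#'   `preference` (pollinators x plants matrix, rows summing to 1),
#'   `phenology` (plant, start_week, end_week) and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  plant_ids <- sprintf("P%02d", seq_len(config$n_plants))
  display <- stats::rlnorm(config$n_plants, config$display_meanlog,
                           config$display_sdlog)
  traits <- data.frame(plant = plant_ids, floral_display = display,
                       stringsAsFactors = FALSE)

  # allocate pollinators to groups proportionally to the configured sizes
  share <- config$group_sizes / sum(config$group_sizes)
  counts <- floor(share * config$n_pollinators)
  rem <- config$n_pollinators - sum(counts)
  if (rem > 0) {
    top_up <- order(share * config$n_pollinators - counts, decreasing = TRUE)
    counts[top_up[seq_len(rem)]] <- counts[top_up[seq_len(rem)]] + 1L
  }
  group <- rep(names(counts), counts)
  poll_ids <- sprintf("%s_%03d", group, unlist(lapply(counts, seq_len)))
  activity <- stats::rlnorm(config$n_pollinators, 0, 1.2)
  pollinators <- data.frame(pollinator = poll_ids, group = group,
                            activity = activity, stringsAsFactors = FALSE)

  # Dirichlet preferences: low concentration gives near-one-hot rows
  g <- matrix(stats::rgamma(config$n_pollinators * config$n_plants,
                            shape = config$concentration),
              nrow = config$n_pollinators,
              dimnames = list(poll_ids, plant_ids))
  g[rowSums(g) == 0, 1] <- 1  # guard against all-zero gamma draws
  preference <- g / rowSums(g)

  len <- sample(config$min_bloom_weeks:config$max_bloom_weeks,
                config$n_plants, replace = TRUE)
  start <- vapply(len, function(l) sample.int(config$n_weeks - l + 1L, 1L),
                  integer(1))
  phenology <- data.frame(plant = plant_ids, start_week = start,
                          end_week = start + len - 1L,
                          stringsAsFactors = FALSE)
  structure(list(traits = traits, pollinators = pollinators,
                 preference = preference, phenology = phenology,
                 config = config),
            class = "pollination_community")
}

#' Generate encounter events and weekly flower surveys
#'
#' Weekly flower abundance follows each plant's bloom window with a
#' triangular within-window profile scaled by floral display; the number of
#' flowers surveyed on tagged plants is a noisy fraction of abundance (at
#' least 1 in bloom weeks). Encounter counts per (week, plant, pollinator)
#' are negative-binomial with mean proportional to abundance x preference x
#' pollinator activity, scaled so the expected total matches
#' `encounter_total`.
#'
#' @param community a [generate_community()] result
#' @param config a [scenario_config()]; defaults to the community's own
#' @return list with `encounters` (week, plant, pollinator; one row per
#'   event) and `flowers` (week, plant, flowers_surveyed, flower_abundance).
#' @export
generate_encounters <- function(community, config = community$config) {
  stopifnot(inherits(community, "pollination_community"))
  set.seed(config$seed + 1L)
  ph <- community$phenology
  traits <- community$traits
  weeks <- seq_len(config$n_weeks)

  grid <- expand.grid(week = weeks, plant = traits$plant,
                      stringsAsFactors = FALSE)
  i <- match(grid$plant, ph$plant)
  in_bloom <- grid$week >= ph$start_week[i] & grid$week <= ph$end_week[i]
  mid <- (ph$start_week[i] + ph$end_week[i]) / 2
  half <- pmax((ph$end_week[i] - ph$start_week[i]) / 2 + 0.5, 0.5)
  profile <- pmax(1 - abs(grid$week - mid) / half, 0) * in_bloom
  display <- traits$floral_display[match(grid$plant, traits$plant)]
  abundance <- display * profile * 5  # flowers per m^2 scale factor
  flowers <- grid[abundance > 0, , drop = FALSE]
  abundance <- abundance[abundance > 0]
  surveyed <- pmax(1L, as.integer(round(
    config$survey_fraction * abundance *
      stats::rlnorm(length(abundance), 0, 0.3))))
  flowers$flowers_surveyed <- surveyed
  flowers$flower_abundance <- abundance
  rownames(flowers) <- NULL

  # expected encounters: abundance share x preference x activity, rescaled
  pref <- t(community$preference)  # plants x pollinators
  act <- community$pollinators$activity
  pi <- match(flowers$plant, rownames(pref))
  mu <- flowers$flower_abundance * pref[pi, , drop = FALSE] *
    rep(act, each = nrow(flowers))
  total_mu <- sum(mu)
  if (total_mu <= 0) stop("degenerate scenario: zero expected encounters",
                          call. = FALSE)
  mu <- mu * (config$encounter_total / total_mu)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  idx <- which(counts > 0, arr.ind = TRUE)
  encounters <- data.frame(
    week = rep(flowers$week[idx[, 1]], counts[idx]),
    plant = rep(flowers$plant[idx[, 1]], counts[idx]),
    pollinator = rep(colnames(counts)[idx[, 2]], counts[idx]),
    stringsAsFactors = FALSE)
  rownames(encounters) <- NULL
  list(encounters = encounters,
       flowers = flowers[c("week", "plant", "flowers_surveyed",
                           "flower_abundance")])
}

#' Generate 4-minute follow observations of visits per encounter
#'
#' For each (plant, pollinator) pair the expected visits per encounter is
#' \eqn{\mu_{ij} = \exp(\alpha + b \ln display_i + \gamma_{g(j)} +
#' \varepsilon_{ij})} with pair-level noise
#' \eqn{\varepsilon_{ij} \sim N(0, sd)}. Samples are drawn from a shifted
#' negative binomial supported on \{1, 2, ...\} with mean \eqn{\mu_{ij}}.
#' A configurable fraction of pairs receives zero samples, to exercise the
#' donor/expert imputation downstream.
#'
#' @inheritParams generate_encounters
#' @param pairs data frame `plant, pollinator` giving the interactions to
#'   sample; defaults to every plant x pollinator combination
#' @return data frame `plant, pollinator, n_visits`, one row per follow.
#' @export
generate_visit_samples <- function(community, config = community$config,
                                   pairs = NULL) {
  stopifnot(inherits(community, "pollination_community"))
  set.seed(config$seed + 2L)
  if (is.null(pairs)) {
    pairs <- expand.grid(plant = community$traits$plant,
                         pollinator = community$pollinators$pollinator,
                         stringsAsFactors = FALSE)
  }
  pairs <- unique(pairs[c("plant", "pollinator")])
  display <- community$traits$floral_display[
    match(pairs$plant, community$traits$plant)]
  grp <- community$pollinators$group[
    match(pairs$pollinator, community$pollinators$pollinator)]
  eff <- config$group_visit_effect[grp]
  eff[is.na(eff)] <- 0
  mu <- exp(config$visits_intercept + config$visits_slope * log(display) +
              eff + stats::rnorm(nrow(pairs), 0, config$visits_sd))
  n_samples <- ifelse(stats::runif(nrow(pairs)) < config$zero_sample_fraction,
                      0L,
                      1L + stats::rpois(nrow(pairs),
                                        max(config$samples_per_interaction - 1, 0)))
  keep <- n_samples > 0
  out <- data.frame(
    plant = rep(pairs$plant[keep], n_samples[keep]),
    pollinator = rep(pairs$pollinator[keep], n_samples[keep]),
    stringsAsFactors = FALSE)
  mu_rep <- rep(mu[keep], n_samples[keep])
  out$n_visits <- 1L + stats::rnbinom(nrow(out),
                                      mu = pmax(mu_rep - 1, 0.02), size = 1)
  rownames(out) <- NULL
  out
}

#' Run the whole synthetic survey
#'
#' Generates a community, its encounter events and flower surveys, and
#' visit-per-encounter follows for the pairs actually observed, i.e. the
#' three tables the analysis pipeline ingests, together with the generating
#' parameters for recovery tests.
#'
#' @param config a [scenario_config()]
#' @return list with `encounters`, `flowers`, `visits`, `community` and
#'   `truth` (the generating display-visits parameters).
#' @export
simulate_survey <- function(config = scenario_config()) {
  community <- generate_community(config)
  surveys <- generate_encounters(community, config)
  observed <- unique(surveys$encounters[c("plant", "pollinator")])
  visits <- generate_visit_samples(community, config, pairs = observed)
  list(encounters = surveys$encounters, flowers = surveys$flowers,
       visits = visits, community = community,
       truth = list(visits_slope = config$visits_slope,
                    visits_intercept = config$visits_intercept,
                    visits_sd = config$visits_sd))
}
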