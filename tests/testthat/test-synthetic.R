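test_that("generation is deterministic under a seed and varies across seeds", {
  cfg <- scenario_config(n_plants = 19, n_pollinators = 122, seed = 5)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$traits, b$traits)
  expect_identical(a$preference, b$preference)
  c2 <- generate_community(scenario_config(n_plants = 19, n_pollinators = 122,
                                           seed = 6))
  expect_false(identical(a$traits$floral_display, c2$traits$floral_display))

  expect_equal(nrow(a$traits), 19)
  expect_equal(nrow(a$pollinators), 122)
  expect_equal(unname(table(a$pollinators$group)["bee"]), 39)
  # preference rows are distributions; bloom windows are contiguous and valid
  expect_equal(unname(rowSums(a$preference)), rep(1, 122))
  expect_true(all(a$phenology$start_week >= 1 &
                    a$phenology$end_week <= cfg$n_weeks &
                    a$phenology$start_week <= a$phenology$end_week))
})

test_that("low concentration produces near-one-hot specialist preferences", {
  cfg <- scenario_config(n_plants = 10, n_pollinators = 40,
                         concentration = 0.01, seed = 9)
  com <- generate_community(cfg)
  expect_gt(mean(apply(com$preference, 1, max)), 0.9)
})

test_that("encounter totals scale with the intensity knob", {
  totals <- vapply(1:20, function(s) {
    base <- generate_encounters(generate_community(
      scenario_config(n_plants = 6, n_pollinators = 12,
                      encounter_total = 300, seed = s)))
    nrow(base$encounters)
  }, numeric(1))
  doubled <- vapply(1:20, function(s) {
    d <- generate_encounters(generate_community(
      scenario_config(n_plants = 6, n_pollinators = 12,
                      encounter_total = 600, seed = s)))
    nrow(d$encounters)
  }, numeric(1))
  expect_equal(mean(doubled) / mean(totals), 2, tolerance = 0.15)
  # and the default configuration lands at the field-study scale (~4e3)
  def <- generate_encounters(generate_community(scenario_config(seed = 3)))
  expect_gt(nrow(def$encounters), 2000)
  expect_lt(nrow(def$encounters), 9000)
})

test_that("a plant with an empty bloom window gets no encounters", {
  com <- generate_community(scenario_config(n_plants = 5, n_pollinators = 10,
                                            seed = 13))
  com$phenology$start_week[2] <- 5
  com$phenology$end_week[2] <- 4  # empty window
  out <- generate_encounters(com)
  expect_false(com$phenology$plant[2] %in% out$encounters$plant)
  expect_false(com$phenology$plant[2] %in% out$flowers$plant)
})

test_that("flower surveys support the weighting pipeline preconditions", {
  out <- generate_encounters(generate_community(
    scenario_config(n_plants = 8, n_pollinators = 16, seed = 17)))
  expect_false(any(duplicated(out$flowers[c("week", "plant")])))
  expect_true(all(out$flowers$flowers_surveyed >= 1))
  expect_true(all(out$flowers$flower_abundance > 0))
  # every encounter's (week, plant) has a survey row
  key <- function(w, p) paste(w, p)
  expect_true(all(key(out$encounters$week, out$encounters$plant) %in%
                    key(out$flowers$week, out$flowers$plant)))
})

test_that("interactions given zero follow samples surface as non-observed", {
  cfg <- scenario_config(n_plants = 8, n_pollinators = 16,
                         zero_sample_fraction = 0.3, seed = 23)
  com <- generate_community(cfg)
  pairs <- expand.grid(plant = com$traits$plant[1:5],
                       pollinator = com$pollinators$pollinator[1:10],
                       stringsAsFactors = FALSE)
  vs <- generate_visit_samples(com, cfg, pairs = pairs)
  sampled <- unique(paste(vs$plant, vs$pollinator))
  n_unsampled <- sum(!paste(pairs$plant, pairs$pollinator) %in% sampled)
  est <- estimate_visits(vs, pairs)
  expect_equal(sum(est$provenance == "excluded"), n_unsampled)
  expect_true(all(vs$n_visits >= 1))
})

test_that("the display-visits slope is recovered from the synthetic survey", {
  cfg <- scenario_config(n_plants = 19, n_pollinators = 122, seed = 29)
  sim <- simulate_survey(cfg)
  est <- estimate_visits(sim$visits, unique(sim$encounters[c("plant", "pollinator")]))
  obs <- est[est$provenance == "observed", ]
  per_plant <- aggregate(mean_visits ~ plant, data = obs, FUN = mean)
  per_plant$display <- sim$community$traits$floral_display[
    match(per_plant$plant, sim$community$traits$plant)]
  fit <- fit_regression(per_plant$display, per_plant$mean_visits,
                        transform_x = "log", transform_y = "log")
  expect_lt(abs(fit$slope - cfg$visits_slope), 3 * fit$slope_se)
})

test_that("the noise-free limit puts plant means on the log-log line", {
  cfg <- scenario_config(n_plants = 12, n_pollinators = 20, visits_sd = 0,
                         visits_slope = 1, visits_intercept = 0,
                         group_visit_effect = c(bee = 0, coleoptera = 0,
                                                diptera = 0, lepidoptera = 0,
                                                wasp = 0, ant = 0,
                                                heteroptera = 0, orthoptera = 0),
                         samples_per_interaction = 60,
                         zero_sample_fraction = 0, seed = 37)
  com <- generate_community(cfg)
  vs <- generate_visit_samples(com, cfg)
  per_plant <- aggregate(n_visits ~ plant, data = vs, FUN = mean)
  display <- com$traits$floral_display[match(per_plant$plant, com$traits$plant)]
  fit <- fit_regression(display, per_plant$n_visits,
                        transform_x = "log", transform_y = "log")
  expect_lt(abs(fit$slope - 1), 3 * fit$slope_se)
  expect_gt(fit$r2, 0.9)
})

test_that("random small scenarios run the whole pipeline without error", {
  set.seed(71)
  for (i in 1:100) {
    cfg <- scenario_config(
      n_plants = sample(3:8, 1), n_pollinators = sample(4:15, 1),
      n_weeks = sample(4:10, 1),
      concentration = runif(1, 0.05, 1.5),
      encounter_total = sample(100:500, 1),
      zero_sample_fraction = runif(1, 0, 0.3),
      min_bloom_weeks = 2, max_bloom_weeks = 4,
      seed = sample.int(1e6, 1))
    sim <- simulate_survey(cfg)
    nets <- try(build_networks(sim$encounters, sim$flowers, sim$visits),
                silent = TRUE)
    expect_false(inherits(nets, "try-error"))
    if (nrow(nets$encounter$W) >= 2 && ncol(nets$encounter$W) >= 2) {
      expect_no_error(network_metrics(nets$encounter))
      expect_no_error(species_metrics(nets$visit))
    }
  }
})

test_that("positive display-visits slope induces display-correlated strength change", {
  sim <- simulate_survey(scenario_config(n_plants = 19, n_pollinators = 60,
                                         visits_sd = 0.3, seed = 43))
  nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
  sm_e <- species_metrics(nets$encounter)
  sm_v <- species_metrics(nets$visit)
  pl_e <- sm_e[sm_e$level == "plant", ]
  pl_v <- sm_v[sm_v$level == "plant", ]
  common <- intersect(pl_e$species, pl_v$species)
  ratio <- pl_v$strength[match(common, pl_v$species)] /
    pl_e$strength[match(common, pl_e$species)]
  display <- sim$community$traits$floral_display[
    match(common, sim$community$traits$plant)]
  expect_gt(cor(log(display), log(ratio)), 0)
})
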