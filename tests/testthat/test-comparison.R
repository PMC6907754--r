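test_that("fit_regression agrees with the closed-form least-squares solution", {
  x <- c(1, 2, 3); y <- c(1, 3, 4)
  # closed form computed here, independently of lm
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  sse <- sum(res^2); sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  se_b <- sqrt(sse / 1 / sum((x - mean(x))^2))  # n - 2 = 1 df
  Fstat <- (sst - sse) / (sse / 1)

  fit <- fit_regression(x, y)
  expect_equal(fit$slope, b)
  expect_equal(fit$intercept, a)
  expect_equal(fit$slope_se, se_b)
  expect_equal(fit$r2, r2)
  expect_equal(fit$F, Fstat)
  expect_equal(fit$df, c(1, 1))
  expect_equal(fit$p_slope_vs_1, 2 * pt(-abs((b - 1) / se_b), 1))
})

test_that("a perfect identity fit gives slope 1 with p(slope=1) = 1", {
  fit <- fit_regression(1:5, 1:5)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$p_slope_vs_1, 1)
})

test_that("transformations validate their domains and name offenders", {
  expect_error(fit_regression(c(1, 0, 2), c(1, 2, 3), transform_x = "log",
                              labels = c("TVU", "ROF", "CAL")),
               "ROF")
  expect_error(fit_regression(c(0.5, 1.2, 0.3), c(1, 2, 3),
                              transform_x = "arcsin_sqrt",
                              labels = c("a", "b", "c")),
               "b")
  expect_error(fit_regression(1:2, 1:2), "at least 3")
})

test_that("a known slope is recovered from noisy simulated pairs", {
  set.seed(88)
  x <- runif(40, 1, 5)
  y <- 2 * x + rnorm(40, 0, 0.05)
  fit <- fit_regression(x, y)
  expect_lt(abs(fit$slope - 2), 3 * fit$slope_se)
})

test_that("identical networks give unit slopes and unit change ratios", {
  sim <- simulate_survey(scenario_config(n_plants = 8, n_pollinators = 15,
                                         encounter_total = 500, seed = 21))
  nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
  sm <- species_metrics(nets$encounter)
  res <- descriptor_change_analysis(sm, sm, sim$community$traits)
  expect_equal(res$measure_comparison$slope,
               rep(1, nrow(res$measure_comparison)))
  expect_equal(res$measure_comparison$r2,
               rep(1, nrow(res$measure_comparison)))
  # all ratios are exactly 1 so every display regression is flat
  expect_equal(res$display_regressions$slope,
               rep(0, nrow(res$display_regressions)))
})

test_that("descriptor comparison applies the stated transformations", {
  sim <- simulate_survey(scenario_config(n_plants = 10, n_pollinators = 20,
                                         encounter_total = 800, seed = 31))
  nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
  sm_e <- species_metrics(nets$encounter)
  sm_v <- species_metrics(nets$visit)
  res <- descriptor_change_analysis(sm_e, sm_v, sim$community$traits)
  mc <- res$measure_comparison
  expect_setequal(mc$descriptor, c("strength", "push_pull", "d_prime"))
  expect_setequal(mc$level, c("plant", "pollinator"))
  # log-log for strength on both levels, arcsin-sqrt for plant d'
  expect_equal(unname(res$fits[["plant.strength"]]$transforms), c("log", "log"))
  expect_equal(unname(res$fits[["plant.d_prime"]]$transforms),
               c("arcsin_sqrt", "arcsin_sqrt"))
  expect_equal(unname(res$fits[["pollinator.d_prime"]]$transforms),
               c("identity", "identity"))
  # ratio regressions: log display predictor throughout, sqrt for d' ratios
  expect_equal(unname(res$fits[["ratio.d_prime"]]$transforms),
               c("log", "sqrt"))
  expect_equal(unname(res$fits[["ratio.strength"]]$transforms), c("log", "log"))
})

test_that("plants with zero encounter-based values are dropped from ratios with a warning", {
  base <- rbind(
    data.frame(species = c("a", "b", "c", "d"), level = "plant",
               degree = 2, strength = c(1, 2, 3, 4),
               push_pull = c(0.5, 0.4, 0.3, 0.2),
               d_prime = c(0, 0.2, 0.4, 0.6)),
    data.frame(species = c("x", "y", "z"), level = "pollinator",
               degree = 2, strength = c(1, 2, 3),
               push_pull = c(-0.5, -0.4, -0.3),
               d_prime = c(0.1, 0.2, 0.3)))
  vis <- base
  vis$d_prime[vis$level == "plant"] <- c(0.1, 0.3, 0.5, 0.7)
  traits <- data.frame(plant = c("a", "b", "c", "d"),
                       floral_display = c(5, 50, 500, 20))
  expect_warning(res <- descriptor_change_analysis(base, vis, traits),
                 "zero encounter-based d_prime.*a")
  expect_equal(res$display_regressions$n[
    res$display_regressions$descriptor == "d_prime"], 3)
})

test_that("bootstrap at fraction 1 degenerates to the original network", {
  sim <- simulate_survey(scenario_config(n_plants = 6, n_pollinators = 12,
                                         encounter_total = 400, seed = 41))
  nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
  est <- nets$estimates
  bc <- bootstrap_compare(sim$encounters, sim$flowers, est,
                          fractions = 1, n_reps = 5, seed = 1)
  orig_e <- network_metrics(nets$encounter)
  orig_v <- network_metrics(nets$visit)
  for (d in c("wnodf", "h2_prime", "interaction_evenness",
              "plant_generality", "pollinator_generality")) {
    row <- bc[bc$descriptor == d, ]
    expect_equal(row$encounter_mean, orig_e[[d]])
    expect_equal(row$visit_mean, orig_v[[d]])
    expect_equal(row$encounter_sd, 0)
    # identical paired differences across replicates: t test undefined
    expect_true(is.na(row$paired_t))
  }
})

test_that("bootstrap output is bit-reproducible under a fixed seed", {
  sim <- simulate_survey(scenario_config(n_plants = 6, n_pollinators = 12,
                                         encounter_total = 400, seed = 51))
  nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
  a <- bootstrap_compare(sim$encounters, sim$flowers, nets$estimates,
                         fractions = c(0.5), n_reps = 8, seed = 99)
  b <- bootstrap_compare(sim$encounters, sim$flowers, nets$estimates,
                         fractions = c(0.5), n_reps = 8, seed = 99)
  attr(a, "replicates") <- attr(b, "replicates") <- NULL
  expect_identical(a, b)
  c2 <- bootstrap_compare(sim$encounters, sim$flowers, nets$estimates,
                          fractions = c(0.5), n_reps = 8, seed = 100)
  expect_false(identical(a$encounter_mean, c2$encounter_mean))
})

test_that("bootstrap means approach the original value as the fraction grows", {
  sim <- simulate_survey(scenario_config(n_plants = 10, n_pollinators = 25,
                                         encounter_total = 1500, seed = 61))
  nets <- build_networks(sim$encounters, sim$flowers, sim$visits)
  bc <- bootstrap_compare(sim$encounters, sim$flowers, nets$estimates,
                          fractions = c(0.25, 0.75), n_reps = 30, seed = 7)
  orig <- network_metrics(nets$encounter)
  # size-sensitive descriptors: richness-driven bias shrinks with fraction
  for (d in c("wnodf", "plant_generality", "pollinator_generality")) {
    dev25 <- abs(bc$encounter_mean[bc$descriptor == d & bc$fraction == 0.25] -
                   orig[[d]])
    dev75 <- abs(bc$encounter_mean[bc$descriptor == d & bc$fraction == 0.75] -
                   orig[[d]])
    expect_lt(dev75, dev25)
  }
  expect_true(all(bc$encounter_sd > 0))
})
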