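test_that("a null configuration yields ~50% return in both groups", {
  cfg <- sim_config(
    taxa = data.frame(taxon = "SYN1", n_sites = 5L, n_years = 2L,
                      n_birds_per_site_year = 500L, p_geolocator = 0.5),
    fixed_effects = c("(Intercept)" = 0, geolocator = 0),
    random_sd = list(site_intercept = 0, site_geo_slope = 0,
                     year_intercept = 0),
    seed = 11L)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$records), 5 * 2 * 500)  # conservation of events
  rate <- tapply(sim$records$returned, sim$records$group, mean)
  expect_lt(abs(rate[["control"]] - 0.5), 0.03)
  expect_lt(abs(rate[["geolocator"]] - 0.5), 0.03)
  expect_lt(abs(rate[["control"]] - rate[["geolocator"]]), 0.03)
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- sim_config(seed = 99L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$ranef, b$ranef)
  c <- simulate_study(sim_config(seed = 100L))
  expect_false(identical(a$records, c$records))
})

test_that("increasing the tag effect increases the tagged-group return rate", {
  base <- list(taxa = data.frame(taxon = "SYN1", n_sites = 4L, n_years = 2L,
                                 n_birds_per_site_year = 400L,
                                 p_geolocator = 0.5),
               random_sd = list(site_intercept = 0.3, site_geo_slope = 0.2,
                                year_intercept = 0.2),
               seed = 21L)
  rates <- sapply(c(-1, 0, 1), function(bg) {
    cfg <- do.call(sim_config, c(base, list(
      fixed_effects = c("(Intercept)" = -0.4, geolocator = bg))))
    r <- simulate_study(cfg)$records
    mean(r$returned[r$group == "geolocator"])
  })
  expect_true(all(diff(rates) > 0))
})

test_that("covariates come out on their raw field scales", {
  sim <- simulate_study(sim_config(seed = 5L))
  r <- sim$records
  expect_true(mean(r$capture_day) > 100)           # Julian days, not z-scores
  expect_true(mean(r$body_mass_g) > 10)            # grams
  expect_equal(nrow(validate_records(r, "capture_event")), 0)
})

test_that("simulated effect tables honour their degenerate limits", {
  # no between-taxon spread, no sampling noise: pooled mean is exact
  eff <- simulate_effect_table(k_taxa = 10, true_mean = -0.4, tau = 0,
                               moderator_slope = 0, se_scale = 0, seed = 3L)
  pm <- pooled_mean_mom(eff)
  expect_equal(pm$M, -0.4, tolerance = 1e-12)
  expect_equal(pm$tau2, 0, tolerance = 1e-12)
  expect_equal(pm$I2, 0)

  expect_error(simulate_effect_table(k_taxa = 1), "k_taxa")
  expect_error(simulate_effect_table(k_taxa = 5, tau = -1), "tau")
})

test_that("the WLS stage recovers a planted moderator slope", {
  slopes <- vapply(seq_len(200), function(i) {
    eff <- simulate_effect_table(k_taxa = 23, true_mean = 0, tau = 0.2,
                                 moderator_slope = -0.5, seed = 7000 + i)
    wls_threshold(eff, eff$moderator)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.5)), 0.1)
})

test_that("response families produce matching record types", {
  taxa <- data.frame(taxon = "SYN1", n_sites = 3L, n_years = 2L,
                     n_birds_per_site_year = 20L, p_geolocator = 0.5)
  nest <- simulate_study(sim_config(taxa = taxa,
                                    response_family = "binomial_nest",
                                    seed = 8L))
  expect_equal(attr(nest$records, "schema"), "nest_record")
  expect_equal(nrow(validate_records(nest$records)), 0)

  mov <- simulate_study(sim_config(taxa = taxa,
                                   fixed_effects = c("(Intercept)" = 4,
                                                     geolocator = 0),
                                   response_family = "gaussian_log_movement",
                                   seed = 8L))
  expect_equal(attr(mov$records, "schema"), "movement_record")
  expect_true(all(mov$records$distance_m >= 0))
})
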