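test_that("effect-size transforms behave at their anchors", {
  for (m in c("identity", "borenstein_chain", "clipped_arctanh")) {
    expect_equal(as.numeric(fisher_z_effect(0, m)), 0, info = m)
  }
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # hand-computed chain for beta = -1.10:
  # d = -1.10 * sqrt(3)/pi = -0.60646; r = d/sqrt(d^2+4) = -0.29018;
  # z = arctanh(r) = -0.29877
  z <- as.numeric(fisher_z_effect(-1.10, "borenstein_chain"))
  d <- -1.10 * sqrt(3) / pi
  expect_equal(z, atanh(d / sqrt(d^2 + 4)), tolerance = 1e-12)
  expect_equal(z, -0.29877, tolerance = 1e-4)
  # the clip keeps arctanh finite beyond |beta| = 1
  expect_true(is.finite(fisher_z_effect(1.51, "clipped_arctanh")))
})

test_that("identical effects pool to themselves with zero heterogeneity", {
  eff <- data.frame(beta_geo = rep(-0.4, 5), N_i = c(50, 100, 200, 400, 800),
                    se_geo = rep(0.2, 5))
  pm <- pooled_mean_mom(eff)
  expect_equal(pm$M, -0.4)
  expect_equal(pm$tau2, 0)
  expect_equal(pm$I2, 0)
  expect_error(pooled_mean_mom(eff[1, , drop = FALSE]), "at least 2")
})

test_that("the inverse-variance option reproduces DerSimonian-Laird (metafor)", {
  skip_if_not_installed("metafor")
  eff <- simulate_effect_table(k_taxa = 15, true_mean = -0.2, tau = 0.4,
                               seed = 77L)
  pm <- pooled_mean_mom(eff, weights = "inverse_variance")
  rma <- metafor::rma(yi = eff$beta_geo, sei = eff$se_geo, method = "DL")
  expect_equal(pm$M, as.numeric(rma$beta), tolerance = 1e-6)
  expect_equal(pm$SE_M, rma$se, tolerance = 1e-6)
  expect_equal(pm$tau2, rma$tau2, tolerance = 1e-6)
  expect_equal(100 * pm$I2, rma$I2, tolerance = 1e-4)
})

test_that("missing SEs are imputed (flagged) or trigger the fallback", {
  eff <- simulate_effect_table(k_taxa = 8, seed = 5L)
  eff$se_geo[c(2, 5)] <- NA
  pm <- pooled_mean_mom(eff, weights = "inverse_variance")
  expect_equal(pm$n_se_imputed, 2L)
  eff$se_geo <- NA
  expect_warning(pm2 <- pooled_mean_mom(eff, weights = "inverse_variance"),
                 "falling back")
  expect_equal(pm2$weights, "n_captures")
})

test_that("pooled SE shrinks as taxa accumulate", {
  ses <- vapply(c(5, 15, 45), function(k) {
    mean(vapply(1:20, function(r) {
      pooled_mean_mom(simulate_effect_table(k_taxa = k, tau = 0.3,
                                            seed = 1200 + r))$SE_M
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("contrast test is centred, scale-stable and guards its domain", {
  eff <- simulate_effect_table(k_taxa = 12, tau = 0.3, moderator_slope = -0.4,
                               seed = 9L)
  a <- contrast_test(eff, eff$moderator)
  b <- contrast_test(eff, eff$moderator + 7)       # shift invariance
  expect_equal(a$X, b$X, tolerance = 1e-12)

  same <- eff; same$beta_geo <- rep(0.3, 12)       # all z equal -> X = 0
  expect_equal(contrast_test(same, same$moderator)$X, 0, tolerance = 1e-10)

  expect_error(contrast_test(eff, rep(1, 12)), "constant moderator")
  expect_error(contrast_test(eff, eff$moderator[-1]), "every taxon")
})

test_that("weighted least squares interpolates two points exactly", {
  eff <- data.frame(beta_geo = c(1, -1), N_i = c(100, 100))
  expect_error(wls_threshold(eff, c(0, 2)), "at least 3")
  eff3 <- data.frame(beta_geo = c(1, 0, -1), N_i = c(100, 100, 100))
  w <- wls_threshold(eff3, c(0, 1, 2))
  expect_equal(w$intercept, 1, tolerance = 1e-10)
  expect_equal(w$slope, -1, tolerance = 1e-10)
  expect_equal(w$threshold, 1, tolerance = 1e-10)
  flat <- data.frame(beta_geo = c(0.2, 0.2, 0.2), N_i = c(10, 10, 10))
  # a perfectly flat line has no zero crossing (lm warns about the exact fit)
  suppressWarnings(expect_true(is.na(wls_threshold(flat, c(0, 1, 2))$threshold)))
})

test_that("meta results on the packaged tables are internally coherent", {
  st <- load_study_tables()
  m <- meta_analysis(st$effects,
                     moderators = list(pct_mass = st$effects$geo_pct_body_mass,
                                       migration = st$effects$migration_deg_lat))
  expect_equal(m$pooled$k, 23)
  expect_true(m$pooled$I2 >= 0 && m$pooled$I2 < 1)
  expect_true(m$pooled$tau2 >= 0)
  expect_equal(m$config$alpha_per_moderator, 0.025)
  # taxa outside the final model enter with beta 0 and weight N_i - 3
  expect_true(all(st$effects$N_i > 3))
  # contrast direction: heavier relative tag loads go with more negative
  # effects, longer migrations with less negative effects
  expect_lt(m$contrasts$pct_mass$X, 0)
  expect_gt(m$contrasts$migration$X, 0)
  expect_lt(m$wls$pct_mass$slope, 0)
  # the %-mass zero crossing sits in the observed moderator range
  expect_gt(m$wls$pct_mass$threshold, min(st$effects$geo_pct_body_mass))
  expect_lt(m$wls$pct_mass$threshold, max(st$effects$geo_pct_body_mass))
})
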