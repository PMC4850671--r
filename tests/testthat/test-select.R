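test_that("standardization centres binaries and rescales continuous to SD 0.5", {
  d <- data.frame(y = 1:4, b = c(0, 0, 1, 1), x = c(1, 2, 3, 4))
  attr(d, "response") <- "y"
  std <- standardize_table(d)
  expect_equal(std$table$b, c(-0.5, -0.5, 0.5, 0.5))
  expect_lt(abs(mean(std$table$x)), 1e-10)
  expect_equal(sd(std$table$x), 0.5)
  expect_equal(std$map$x$rule, "two_sd")
  expect_equal(std$map$b$rule, "centered_binary")

  d5 <- data.frame(y = 1:5, x = 1:5)
  attr(d5, "response") <- "y"
  s5 <- standardize_table(d5)
  expect_lt(abs(mean(s5$table$x)), 1e-10)
  expect_equal(sd(s5$table$x), 0.5)

  dc <- data.frame(y = 1:4, k = rep(2, 4))
  attr(dc, "response") <- "y"
  expect_warning(sc <- standardize_table(dc), "zero-variance")
  expect_false("k" %in% names(sc$table))

  # full rule also divides binaries by 2 SD
  sf <- standardize_table(d, binary_rule = "full")
  expect_equal(sd(sf$table$b), 0.5)

  # multi-level factors expand to centred indicators
  df <- data.frame(y = 1:6, f = rep(c("a", "b", "c"), 2))
  attr(df, "response") <- "y"
  sfa <- standardize_table(df)
  expect_true(all(c("f_b", "f_c") %in% names(sfa$table)))
  expect_lt(abs(mean(sfa$table$f_b)), 1e-10)
})

test_that("submodel enumeration covers all subsets with grouped units", {
  expect_length(enumerate_submodels(c("a", "b", "c")), 8)
  expect_equal(enumerate_submodels(character()), list(character()))
  subs <- enumerate_submodels(c("geo", "nf_h", "nf_u"),
                              units = list(nf = c("nf_h", "nf_u")))
  expect_length(subs, 4)  # two units toggle: {}, {geo}, {nf}, {geo, nf}
  expect_true(any(vapply(subs, function(s) setequal(s, c("nf_h", "nf_u")),
                         logical(1))))
  expect_error(enumerate_submodels(letters[1:13]), "8,192")
})

test_that("AICc follows its closed form and guards its domain", {
  expect_equal(aicc(-10, k = 2, n = 10), 24 + 12 / 7)
  expect_error(aicc(-10, k = 0, n = 10), "intercept")
  expect_error(aicc(-10, k = 9, n = 10), "undefined")
  # same k and n: AICc difference is -2 * (logLik difference)
  expect_equal(aicc(-10, k = 2, n = 50) - aicc(-12, k = 2, n = 50),
               -2 * (-10 - (-12)))
})

test_that("Akaike weights renormalize correctly", {
  expect_equal(round(akaike_weights(c(0, 2)), 3), c(0.731, 0.269))
  expect_equal(akaike_weights(0), 1)
  expect_equal(round(akaike_weights(c(0, 19.36)), 3), c(1, 0))
  expect_equal(sum(akaike_weights(c(0, 0.7, 1.9))), 1)
  expect_error(akaike_weights(numeric()), "empty")
  expect_error(akaike_weights(c(1, 2)), "minimum 0")
})

test_that("natural averaging matches its defining toy examples", {
  models <- as_top_set_input(list(
    list(est = list("(Intercept)" = 0.1, X = 1.0),
         se = list("(Intercept)" = 0.1, X = 0.2), aicc = 100),
    list(est = list("(Intercept)" = 0.2),
         se = list("(Intercept)" = 0.1), aicc = 100 - 2 * log(0.4 / 0.6))))
  # weights are 0.6 / 0.4 by construction
  ts <- top_model_set(models, cutoff = 5)
  avg <- natural_average(ts)
  co <- avg$coefficients
  expect_equal(co$estimate[co$term == "X"], 1.0)   # averaged only where present
  expect_equal(co$ri[co$term == "X"], 0.6, tolerance = 1e-10)
  expect_equal(co$ri[co$term == "(Intercept)"], 1)

  models2 <- as_top_set_input(list(
    list(est = list("(Intercept)" = 0, X = 1.0),
         se = list("(Intercept)" = 0.1, X = 0.2), aicc = 50),
    list(est = list("(Intercept)" = 0, X = 2.0),
         se = list("(Intercept)" = 0.1, X = 0.2), aicc = 50)))
  avg2 <- natural_average(top_model_set(models2))
  co2 <- avg2$coefficients
  expect_equal(co2$estimate[co2$term == "X"], 1.5)
  expect_equal(co2$ri[co2$term == "X"], 1)
})

test_that("averaging a single-model top set is the identity", {
  models <- as_top_set_input(list(
    list(est = list("(Intercept)" = -0.3, X = 0.7),
         se = list("(Intercept)" = 0.05, X = 0.11), aicc = 10),
    list(est = list("(Intercept)" = -0.1),
         se = list("(Intercept)" = 0.05), aicc = 30)))
  avg <- natural_average(top_model_set(models))
  co <- avg$coefficients
  expect_equal(co$estimate[co$term == "X"], 0.7)
  expect_equal(co$se[co$term == "X"], 0.11)
  expect_equal(co$ri[co$term == "X"], 1)
})

test_that("natural averaging agrees with a brute-force oracle on random problems", {
  for (seed in 1:25) {
    set.seed(seed)
    p <- sample(1:4, 1)
    terms <- paste0("t", seq_len(p))
    subsets <- enumerate_submodels(terms)
    models <- lapply(subsets, function(s) {
      nm <- c("(Intercept)", s)
      list(est = as.list(stats::setNames(round(rnorm(length(nm)), 2), nm)),
           se = as.list(stats::setNames(round(runif(length(nm), 0.05, 0.5), 2), nm)),
           aicc = round(runif(1, 100, 106), 2))
    })
    oracle <- naive_average(models)
    avg <- natural_average(top_model_set(as_top_set_input(models)),
                           all_terms = c("(Intercept)", terms))
    co <- avg$coefficients
    for (tm in names(oracle)) {
      i <- match(tm, co$term)
      expect_equal(co$estimate[i], unname(oracle[[tm]]["estimate"]),
                   tolerance = 1e-10, info = paste(seed, tm))
      expect_equal(co$se[i], unname(oracle[[tm]]["se"]),
                   tolerance = 1e-10, info = paste(seed, tm))
      if (tm != "(Intercept)") {
        expect_equal(co$ri[i], unname(oracle[[tm]]["ri"]),
                     tolerance = 1e-10, info = paste(seed, tm))
      }
    }
    # terms absent from every top model have RI 0 and no estimate
    absent <- setdiff(terms, names(oracle))
    for (tm in absent) {
      i <- match(tm, co$term)
      expect_equal(co$ri[i], 0)
      expect_true(is.na(co$estimate[i]))
    }
    expect_true(all(co$ri >= 0 & co$ri <= 1))
  }
})

test_that("dredging ranks submodels and averaging flags the planted effect", {
  cfg <- sim_config(
    taxa = data.frame(taxon = "SYN1", n_sites = 8L, n_years = 3L,
                      n_birds_per_site_year = 60L, p_geolocator = 0.5),
    fixed_effects = c("(Intercept)" = -0.3, geolocator = -1.2),
    random_sd = list(site_intercept = 0.4, site_geo_slope = 0.2,
                     year_intercept = 0.2),
    seed = 314L)
  tab <- build_return_table(simulate_study(cfg)$records)
  std <- standardize_table(tab)
  spec <- model_spec("binomial_logit",
                     fixed = c("geolocator", "sex_male", "previously_marked"),
                     random = c(site = "intercept_plus_geo_slope",
                                year = "intercept_only"))
  ts <- dredge_glmm(spec, std$table)
  expect_equal(min(ts$table$delta), 0)
  expect_equal(sum(ts$weights), 1)
  avg <- natural_average(ts, all_terms = c("(Intercept)", spec$fixed))
  co <- avg$coefficients
  i <- match("geolocator", co$term)
  expect_gte(co$ri[i], 0.8)                     # strong planted effect found
  expect_lt(abs(co$estimate[i] - (-1.2)), 3 * co$se[i])
})

test_that("two-pass refit restores rows lost to unimportant covariates", {
  cfg <- sim_config(
    taxa = data.frame(taxon = "SYN1", n_sites = 8L, n_years = 2L,
                      n_birds_per_site_year = 50L, p_geolocator = 0.5),
    fixed_effects = c("(Intercept)" = 0, geolocator = -1.5),
    random_sd = list(site_intercept = 0.3, site_geo_slope = 0,
                     year_intercept = 0.2),
    seed = 2718L)
  tab <- build_return_table(simulate_study(cfg)$records)
  std <- standardize_table(tab)
  d <- std$table
  set.seed(1)
  d$body_mass[runif(nrow(d)) < 0.3] <- NA   # unrelated covariate, 30% missing
  attr(d, "response") <- "returned"
  spec <- model_spec("binomial_logit",
                     fixed = c("geolocator", "body_mass"),
                     random = c(site = "intercept_plus_geo_slope",
                                year = "intercept_only"))
  res <- two_pass_refit(spec, d)
  if ("body_mass" %in% res$dropped_terms) {
    expect_equal(res$pass2$top$models[[1]]$fit$n, sum(!is.na(d$returned)))
    expect_gt(res$pass2$top$models[[1]]$fit$n,
              res$pass1$top$models[[1]]$fit$n)
  }
  # with no missing data the two passes coincide
  d2 <- std$table
  res2 <- two_pass_refit(spec, d2)
  expect_equal(res2$pass1$averaged$coefficients,
               res2$final$coefficients)
})
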