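# Shared fixtures, all built in code.

# minimal well-formed capture events
make_events <- function(n = 6) {
  if (n == 0) return(make_events(1)[0, , drop = FALSE])
  data.frame(
    individual_id = sprintf("B%03d", seq_len(n)),
    taxon = "SYN1", site = "B01", year = 2010L,
    group = factor(rep(c("control", "geolocator"), length.out = n),
                   levels = c("control", "geolocator")),
    attachment = factor(rep(c("none", "PEF"), length.out = n),
                        levels = c("PAB", "PEF", "PAF", "LLH", "none")),
    sex = factor("female", levels = c("female", "male", "unknown")),
    capture_day = 160L, body_mass_g = 28, marker_mass_g = 0.5,
    blood_sample = FALSE, previously_marked = FALSE,
    nest_fate_final = factor("hatched",
                             levels = c("hatched", "failed", "unknown", "none")),
    returned = rep(c(TRUE, FALSE), length.out = n),
    returned_without_tag = FALSE,
    age_class = factor("adult", levels = c("adult", "juvenile")),
    stringsAsFactors = FALSE)
}

make_nests <- function(n = 6) {
  data.frame(
    nest_id = sprintf("N%03d", seq_len(n)),
    taxon = "SESA", site = "B01", year = 2010L,
    n_geo_parents = rep(c(0L, 1L), length.out = n),
    fate = factor(rep(c("successful", "failed"), length.out = n),
                  levels = c("successful", "failed", "unknown")),
    cause_of_failure = factor(rep(c("none", "predation"), length.out = n),
                              levels = c("predation", "abandonment",
                                         "failure_to_hatch", "egg_damage",
                                         "unknown", "none")),
    unhatched_egg_present = FALSE, research_damage = FALSE,
    found_stage = 0.2, stringsAsFactors = FALSE)
}

# a fixed, seeded grouped binomial dataset for engine cross-checks
make_grouped_binomial <- function(seed = 101, n_groups = 12, n_per = 25,
                                  beta = c(-0.4, 0.8), sd_group = 0.7) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = n_per)
  b <- stats::rnorm(n_groups, 0, sd_group)
  x <- stats::rnorm(n_groups * n_per)
  eta <- beta[1] + beta[2] * x + b[as.integer(factor(g))]
  data.frame(y = stats::rbinom(length(g), 1, stats::plogis(eta)),
             x = x, site = g, stringsAsFactors = FALSE)
}

# independent brute-force natural averaging: plain loops over a list of
# models given as (terms, estimates, ses, aicc); deliberately naive
naive_average <- function(models, cutoff = 2) {
  a <- sapply(models, function(mm) mm$aicc)
  delta <- a - min(a)
  keep <- which(delta < cutoff)
  w <- exp(-delta[keep] / 2)
  w <- w / sum(w)
  terms <- unique(unlist(lapply(models[keep], function(mm) names(mm$est))))
  out <- list()
  for (tm in terms) {
    num <- 0; den <- 0
    for (j in seq_along(keep)) {
      mm <- models[[keep[j]]]
      if (tm %in% names(mm$est)) {
        num <- num + w[j] * mm$est[[tm]]
        den <- den + w[j]
      }
    }
    est <- num / den
    s2 <- 0
    for (j in seq_along(keep)) {
      mm <- models[[keep[j]]]
      if (tm %in% names(mm$est)) {
        s2 <- s2 + (w[j] / den) * (mm$se[[tm]]^2 + (mm$est[[tm]] - est)^2)
      }
    }
    out[[tm]] <- c(estimate = est, se = sqrt(s2), ri = den / sum(w))
  }
  out
}

# wrap plain (terms, est, se, aicc) models into the package structure
as_top_set_input <- function(models) {
  lapply(models, function(mm) {
    list(terms = setdiff(names(mm$est), "(Intercept)"),
         coefficients = data.frame(term = names(mm$est),
                                   estimate = unname(unlist(mm$est)),
                                   se = unname(unlist(mm$se)),
                                   stringsAsFactors = FALSE),
         aicc = mm$aicc)
  })
}
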