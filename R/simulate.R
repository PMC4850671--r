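## Synthetic multi-taxon tagging-study generator ----------------------------

#' Configuration for a synthetic tagging study
#'
#' Builds the configuration object consumed by [simulate_study()]. Defaults
#' describe a single mid-sized sandpiper-like taxon studied at several sites
#' over several years, with a geolocator applied at a fixed fraction of
#' capture events.
#'
#' Covariates are generated on their raw field scales (Julian capture day,
#' grams of body mass) so that the pipeline's own standardization step is
#' exercised downstream; inside the generator, continuous covariates enter
#' the linear predictor standardized by their generating moments
#' (`(x - mean) / (2 sd)`) and binary covariates are centred, matching the
#' scale on which fitted coefficients are reported. The tag indicator itself
#' enters as 0/1, so `beta_geo` is the logit-scale difference between the
#' tagged and control groups and the intercept is the control-group logit.
#'
#' @param taxa Data frame with columns `taxon`, `n_sites`, `n_years`,
#'   `n_birds_per_site_year`, `p_geolocator`, and optionally
#'   `mean_body_mass_g`.
#' @param fixed_effects Named numeric vector of logit- (binomial) or
#'   identity-scale (Gaussian) coefficients. Must include `"(Intercept)"` and
#'   `"geolocator"`; other recognised names are `sex_male`,
#'   `previously_marked`, `capture_day`, `body_mass`, `marker_mass`,
#'   `blood_sample`, `attachment_PEF`, `nest_hatched`, `nest_unknown`.
#' @param random_sd Named list/vector of random-effect standard deviations:
#'   `site_intercept`, `site_geo_slope`, `year_intercept`,
#'   `individual_intercept`, `species_intercept` (all >= 0).
#' @param covariates Named list of covariate-model parameters; see defaults.
#' @param response_family One of `"binomial_return"`, `"binomial_nest"`,
#'   `"binomial_partial_hatch"`, `"gaussian_log_movement"`,
#'   `"gaussian_mass_change"`.
#' @param residual_sd Residual standard deviation for Gaussian families.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(taxa = data.frame(taxon = "SYN1", n_sites = 5L,
                                         n_years = 3L,
                                         n_birds_per_site_year = 40L,
                                         p_geolocator = 0.25),
                       fixed_effects = c("(Intercept)" = -0.62,
                                         geolocator = -0.66),
                       random_sd = list(site_intercept = 0.5,
                                        site_geo_slope = 0.3,
                                        year_intercept = 0.3,
                                        individual_intercept = 0,
                                        species_intercept = 0),
                       covariates = list(sex_ratio = 0.5,
                                         p_attachment_pef = 1,
                                         capture_day_mean = 160,
                                         capture_day_sd = 10,
                                         body_mass_cv = 0.08,
                                         marker_mass_mean = 0.6,
                                         marker_mass_sd = 0.15,
                                         p_previously_marked = 0.2,
                                         p_blood_sample = 0.5,
                                         nest_fate_probs = c(hatched = 0.5,
                                                             failed = 0.35,
                                                             unknown = 0.15)),
                       response_family = c("binomial_return", "binomial_nest",
                                           "binomial_partial_hatch",
                                           "gaussian_log_movement",
                                           "gaussian_mass_change"),
                       residual_sd = 1,
                       seed = 1L) {
  response_family <- match.arg(response_family)
  covariates <- utils::modifyList(
    list(sex_ratio = 0.5, p_attachment_pef = 1, capture_day_mean = 160,
         capture_day_sd = 10, body_mass_cv = 0.08, marker_mass_mean = 0.6,
         marker_mass_sd = 0.15, p_previously_marked = 0.2,
         p_blood_sample = 0.5,
         nest_fate_probs = c(hatched = 0.5, failed = 0.35, unknown = 0.15)),
    as.list(covariates))
  random_sd <- utils::modifyList(
    list(site_intercept = 0, site_geo_slope = 0, year_intercept = 0,
         individual_intercept = 0, species_intercept = 0), as.list(random_sd))
  if (any(unlist(random_sd) < 0)) stop("random-effect SDs must be >= 0", call. = FALSE)
  if (!all(c("(Intercept)", "geolocator") %in% names(fixed_effects))) {
    stop("fixed_effects must include '(Intercept)' and 'geolocator'", call. = FALSE)
  }
  if (any(taxa$p_geolocator < 0 | taxa$p_geolocator > 1)) {
    stop("p_geolocator must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(taxa$mean_body_mass_g)) taxa$mean_body_mass_g <- 50
  structure(list(taxa = taxa, fixed_effects = fixed_effects,
                 random_sd = random_sd, covariates = covariates,
                 response_family = response_family,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic sub-stream seeds: one stream per record type derived from the
# master seed, so adding nest simulation does not perturb return outcomes.
.substream <- function(seed, stream) {
  offs <- c(ranef = 11L, covariates = 23L, response = 37L, nests = 53L,
            sublethal = 71L)
  (seed * 101L + offs[[stream]]) %% .Machine$integer.max
}

.sim_ranef <- function(config) {
  set.seed(.substream(config$seed, "ranef"))
  sd <- config$random_sd
  out <- list()
  for (i in seq_len(nrow(config$taxa))) {
    tx <- config$taxa[i, ]
    sites <- sprintf("%s_B%02d", tx$taxon, seq_len(tx$n_sites))
    years <- 2007L + seq_len(tx$n_years) - 1L
    out[[tx$taxon]] <- list(
      site_intercept = stats::setNames(stats::rnorm(tx$n_sites, 0, sd$site_intercept), sites),
      site_geo_slope = stats::setNames(stats::rnorm(tx$n_sites, 0, sd$site_geo_slope), sites),
      year_intercept = stats::setNames(stats::rnorm(tx$n_years, 0, sd$year_intercept), years),
      species_intercept = stats::rnorm(1, 0, sd$species_intercept)
    )
  }
  out
}

#' Simulate a multi-taxon tagging study
#'
#' Draws a complete synthetic dataset under the hierarchical model the
#' analysis pipeline assumes: a linear predictor built from configured fixed
#' effects plus site intercepts, site-level tag-effect slopes, year intercepts
#' and (optionally) individual and species intercepts; binomial outcomes are
#' drawn with probability `plogis(eta)` and Gaussian outcomes with the
#' configured residual SD. The realised random effects and the generating
#' configuration are stored alongside the records.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_dataset`: list with `records` (a
#'   typed record data frame matching the response family), `truth` (the
#'   config) and `ranef` (realised random effects per taxon).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fam <- config$response_family
  ranef <- .sim_ranef(config)
  cov <- config$covariates
  be <- config$fixed_effects

  set.seed(.substream(config$seed, "covariates"))
  recs <- list()
  for (i in seq_len(nrow(config$taxa))) {
    tx <- config$taxa[i, ]
    sites <- names(ranef[[tx$taxon]]$site_intercept)
    years <- as.integer(names(ranef[[tx$taxon]]$year_intercept))
    g <- expand.grid(site = sites, year = years, stringsAsFactors = FALSE)
    n <- tx$n_birds_per_site_year
    df <- g[rep(seq_len(nrow(g)), each = n), ]
    m <- nrow(df)
    df$taxon <- tx$taxon
    df$individual_id <- sprintf("%s_%05d", tx$taxon, seq_len(m))
    df$group <- ifelse(stats::runif(m) < tx$p_geolocator, "geolocator", "control")
    df$attachment <- ifelse(df$group == "geolocator",
                            ifelse(stats::runif(m) < cov$p_attachment_pef,
                                   "PEF", "PAB"), "none")
    df$sex <- ifelse(stats::runif(m) < cov$sex_ratio, "male", "female")
    df$capture_day <- as.integer(round(stats::rnorm(m, cov$capture_day_mean,
                                                    cov$capture_day_sd)))
    df$body_mass_g <- stats::rnorm(m, tx$mean_body_mass_g,
                                   cov$body_mass_cv * tx$mean_body_mass_g)
    df$marker_mass_g <- pmax(0, stats::rnorm(m, cov$marker_mass_mean,
                                             cov$marker_mass_sd))
    df$blood_sample <- stats::runif(m) < cov$p_blood_sample
    df$previously_marked <- stats::runif(m) < cov$p_previously_marked
    nf <- cov$nest_fate_probs
    df$nest_fate_final <- sample(names(nf), m, replace = TRUE, prob = nf)
    df$age_class <- "adult"
    recs[[tx$taxon]] <- df
  }
  df <- do.call(rbind, recs)
  rownames(df) <- NULL

  # linear predictor on the reporting scale: continuous terms standardized by
  # generating moments, binaries centred, tag indicator raw 0/1
  geo <- as.numeric(df$group == "geolocator")
  term <- function(nm, x) if (nm %in% names(be)) be[[nm]] * x else 0
  mass_mu <- config$taxa$mean_body_mass_g[match(df$taxon, config$taxa$taxon)]
  eta <- be[["(Intercept)"]] + be[["geolocator"]] * geo +
    term("sex_male", as.numeric(df$sex == "male") - cov$sex_ratio) +
    term("previously_marked",
         as.numeric(df$previously_marked) - cov$p_previously_marked) +
    term("capture_day",
         (df$capture_day - cov$capture_day_mean) / (2 * cov$capture_day_sd)) +
    term("body_mass",
         (df$body_mass_g - mass_mu) / (2 * cov$body_mass_cv * mass_mu)) +
    term("marker_mass",
         (df$marker_mass_g - cov$marker_mass_mean) / (2 * cov$marker_mass_sd)) +
    term("attachment_PEF", as.numeric(df$attachment == "PEF")) +
    term("blood_sample", as.numeric(df$blood_sample) - cov$p_blood_sample) +
    term("nest_hatched", as.numeric(df$nest_fate_final == "hatched")) +
    term("nest_unknown", as.numeric(df$nest_fate_final == "unknown"))
  for (tx in names(ranef)) {
    sel <- df$taxon == tx
    re <- ranef[[tx]]
    eta[sel] <- eta[sel] + re$species_intercept +
      re$site_intercept[df$site[sel]] +
      geo[sel] * re$site_geo_slope[df$site[sel]] +
      re$year_intercept[as.character(df$year[sel])]
  }
  if (config$random_sd$individual_intercept > 0) {
    set.seed(.substream(config$seed, "response") + 1L)
    bind <- stats::rnorm(nrow(df), 0, config$random_sd$individual_intercept)
    eta <- eta + bind
  }

  set.seed(.substream(config$seed, "response"))
  records <- switch(fam,
    binomial_return = {
      df$returned <- stats::rbinom(nrow(df), 1, stats::plogis(eta)) == 1
      df$returned_without_tag <- FALSE
      out <- df[, names(.schemas$capture_event)]
      attr(out, "schema") <- "capture_event"
      out
    },
    binomial_nest = {
      ok <- stats::rbinom(nrow(df), 1, stats::plogis(eta)) == 1
      out <- data.frame(
        nest_id = sprintf("N%05d", seq_len(nrow(df))), taxon = df$taxon,
        site = df$site, year = df$year,
        n_geo_parents = as.integer(geo), fate = ifelse(ok, "successful", "failed"),
        cause_of_failure = ifelse(ok, "none", "predation"),
        unhatched_egg_present = NA, research_damage = FALSE,
        found_stage = stats::runif(nrow(df), 0, 0.5),
        stringsAsFactors = FALSE)
      attr(out, "schema") <- "nest_record"
      out
    },
    binomial_partial_hatch = {
      unh <- stats::rbinom(nrow(df), 1, stats::plogis(eta)) == 1
      out <- data.frame(
        nest_id = sprintf("N%05d", seq_len(nrow(df))), taxon = df$taxon,
        site = df$site, year = df$year,
        n_geo_parents = as.integer(geo), fate = "successful",
        cause_of_failure = "none", unhatched_egg_present = unh,
        research_damage = FALSE, found_stage = stats::runif(nrow(df), 0, 0.5),
        stringsAsFactors = FALSE)
      attr(out, "schema") <- "nest_record"
      out
    },
    gaussian_log_movement = {
      logd <- eta + stats::rnorm(nrow(df), 0, config$residual_sd)
      out <- data.frame(
        individual_id = df$individual_id, taxon = df$taxon, site = df$site,
        year_t = df$year, year_t1 = df$year + 1L,
        distance_m = exp(logd) - 1, sex = df$sex,
        nest_fate_year_t = df$nest_fate_final,
        previously_marked = df$previously_marked, group = df$group,
        on_plot_both_years = TRUE, stringsAsFactors = FALSE)
      out$distance_m <- pmax(out$distance_m, 0)
      out$nest_fate_year_t[out$nest_fate_year_t == "none"] <- "unknown"
      attr(out, "schema") <- "movement_record"
      out
    },
    gaussian_mass_change = {
      out <- data.frame(
        individual_id = df$individual_id, taxon = df$taxon, site = df$site,
        year_t = df$year, year_t1 = df$year + 1L,
        pct_mass_change = eta + stats::rnorm(nrow(df), 0, config$residual_sd),
        delta_capture_day = as.integer(round(stats::rnorm(nrow(df), 0, 5))),
        delta_nest_age = stats::rnorm(nrow(df), 0, 3), group = df$group,
        stringsAsFactors = FALSE)
      attr(out, "schema") <- "mass_change_record"
      out
    })

  structure(list(records = records, truth = config, ranef = ranef),
            class = "synthetic_dataset")
}

#' Simulate a table of taxon-specific tag effects
#'
#' Draws `k_taxa` taxon-level tag effects for exercising the meta-analysis
#' stage with known truth. True effects follow
#' `Normal(true_mean + moderator_slope * (moderator - midrange), tau^2)`;
#' observed effects add within-taxon sampling noise with
#' `SE_i = se_scale / sqrt(N_i)`, and capture counts `N_i` are drawn uniformly
#' over `N_range`.
#'
#' @param k_taxa Number of taxa (>= 2).
#' @param true_mean True mean tag effect (logit-coefficient scale).
#' @param tau Between-taxon SD (>= 0).
#' @param moderator_slope True linear effect of the moderator.
#' @param N_range Integer range for per-taxon capture counts.
#' @param moderator_range Range over which the moderator is drawn uniformly.
#' @param se_scale Scale constant for within-taxon SEs (default 8: about 0.8
#'   at N = 100, 0.25 at N = 1000, matching typical reported SEs).
#' @param seed Integer seed.
#' @return Effect-record data frame with columns `taxon`, `beta_geo`,
#'   `se_geo`, `ri_geo`, `in_final_model`, `N_i`, `moderator`, plus the true
#'   effects in attribute `truth`.
#' @export
simulate_effect_table <- function(k_taxa, true_mean = 0, tau = 0.5,
                                  moderator_slope = 0,
                                  N_range = c(30L, 1200L),
                                  moderator_range = c(0.1, 3.9),
                                  se_scale = 8, seed = 1L) {
  if (k_taxa < 2) stop("k_taxa must be >= 2", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  N <- as.integer(round(stats::runif(k_taxa, N_range[1], N_range[2])))
  mod <- stats::runif(k_taxa, moderator_range[1], moderator_range[2])
  theta <- stats::rnorm(k_taxa,
                        true_mean + moderator_slope * (mod - mean(moderator_range)),
                        tau)
  se <- se_scale / sqrt(N)
  beta <- stats::rnorm(k_taxa, theta, se)
  out <- data.frame(taxon = sprintf("T%02d", seq_len(k_taxa)),
                    beta_geo = beta, se_geo = se, ri_geo = NA_real_,
                    in_final_model = TRUE, N_i = N, moderator = mod,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(theta = theta, true_mean = true_mean, tau = tau,
                             moderator_slope = moderator_slope)
  attr(out, "schema") <- "effect_record"
  out
}
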