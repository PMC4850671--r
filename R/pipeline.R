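## Pipeline orchestration ----------------------------------------------------

.stage_designs <- list(
  return_rate = list(
    fixed = c("geolocator", "sex_male", "sex_unknown", "nest_fate_hatched",
              "nest_fate_unknown", "previously_marked", "body_mass",
              "capture_day", "blood_sample", "marker_mass"),
    random = c(site = "intercept_plus_geo_slope", year = "intercept_only",
               individual = "intercept_only"),
    family = "binomial_logit"),
  nest_success = list(
    fixed = "geolocator",
    random = c(site = "intercept_plus_geo_slope", year = "intercept_only"),
    family = "binomial_logit"),
  cause_of_failure = list(
    fixed = "geolocator",
    random = c(site = "intercept_only", year = "intercept_only"),
    family = "binomial_logit"),
  partial_hatch = list(
    fixed = "geolocator",
    random = c(species = "intercept_only", site = "intercept_plus_geo_slope",
               year = "intercept_only"),
    family = "binomial_logit"),
  movement = list(
    fixed = c("geolocator", "sex_male", "sex_unknown", "nest_fate_hatched",
              "nest_fate_unknown", "previously_marked"),
    random = c(species = "intercept_only", site = "intercept_plus_geo_slope",
               year = "intercept_only"),
    family = "gaussian_identity"),
  mass_change = list(
    fixed = c("geolocator", "delta_capture_day", "delta_nest_age"),
    random = c(species = "intercept_only", site = "intercept_plus_geo_slope",
               year = "intercept_only"),
    family = "gaussian_identity"),
  attachment_contrast = list(
    fixed = c("attachment_PEF", "nest_fate_hatched", "nest_fate_unknown"),
    random = c(year = "intercept_only"),
    family = "binomial_logit")
)

#' Stage designs used by the pipeline
#'
#' Returns, per analysis stage, the candidate fixed terms (as standardized
#' column names), the random-effect structure and the response family.
#'
#' @return Named list of stage designs.
#' @export
stage_designs <- function() .stage_designs

.fit_stage <- function(table, design, binary_rule = "center",
                       two_pass = TRUE) {
  std <- standardize_table(table, binary_rule = binary_rule)
  fixed <- intersect(design$fixed, names(std$table))
  random <- design$random[names(design$random) %in% names(std$table)]
  spec <- model_spec(design$family, fixed = fixed, random = random)
  units <- list()
  for (pfx in c("sex", "nest_fate")) {
    cols <- grep(paste0("^", pfx, "_"), fixed, value = TRUE)
    if (length(cols) > 1) units[[pfx]] <- cols
  }
  if (!length(units)) units <- NULL
  res <- if (two_pass) {
    two_pass_refit(spec, std$table, units = units)
  } else {
    ts <- dredge_glmm(spec, std$table, units = units)
    list(pass1 = list(top = ts, averaged = natural_average(
      ts, all_terms = c("(Intercept)", fixed))),
      dropped_terms = character(),
      final = natural_average(ts, all_terms = c("(Intercept)", fixed)))
  }
  list(top = res$pass2$top %||% res$pass1$top, averaged = res$final,
       dropped_terms = res$dropped_terms, standardization = std$map,
       n = nrow(std$table))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one per-taxon analysis stage
#'
#' Builds the stage's model table, standardizes it, runs all-subsets AICc
#' selection with the stage's random structure, and returns the natural-
#' average model per taxon (return-rate stage) or pooled across taxa (other
#' stages).
#'
#' @param stage Stage name (see [stage_designs()]).
#' @param records The stage's input record data frame.
#' @param per_taxon Fit separately per taxon (default `TRUE` for the
#'   return-rate stage, `FALSE` otherwise).
#' @param eligible Optional eligibility screen for the nest-success stage.
#' @param terms Optional subset of the stage's candidate fixed terms (the tag
#'   indicator is always retained); useful to bound the 2^m submodel count
#'   when few covariates were recorded.
#' @param binary_rule Passed to [standardize_table()].
#' @param two_pass Use the two-pass missing-data refit (default `TRUE`).
#' @return A list of per-taxon stage results (`averaged`, `top`, `n`), or a
#'   single pooled result.
#' @export
run_stage <- function(stage, records, per_taxon = stage == "return_rate",
                      eligible = NULL, terms = NULL, binary_rule = "center",
                      two_pass = TRUE) {
  design <- .stage_designs[[match.arg(stage, names(.stage_designs))]]
  if (!is.null(terms)) {
    design$fixed <- union("geolocator", intersect(design$fixed, terms))
  }
  table <- switch(stage,
    return_rate = build_return_table(records),
    nest_success = build_nest_table(records, eligible = eligible),
    partial_hatch = build_partial_hatch_table(records),
    movement = build_movement_table(records),
    mass_change = build_mass_change_table(records),
    attachment_contrast = build_attachment_table(records),
    stop("use cause_of_failure_stage() for the failure-cause analysis"))
  if (!nrow(table)) {
    message("stage '", stage, "' skipped: no rows after filtering")
    return(NULL)
  }
  if (!per_taxon) return(.fit_stage(table, design, binary_rule, two_pass))
  out <- list()
  for (tx in unique(table$taxon)) {
    sub <- table[table$taxon == tx, , drop = FALSE]
    attributes(sub)[c("response", "grouping")] <-
      attributes(table)[c("response", "grouping")]
    out[[tx]] <- tryCatch(.fit_stage(sub, design, binary_rule, two_pass),
                          error = function(e) {
                            message("stage '", stage, "' skipped for ", tx,
                                    ": ", conditionMessage(e))
                            NULL
                          })
  }
  out
}

#' Model the cause of nest failure for tagged versus control nests
#'
#' For taxa flagged by a tag effect on nest success, tests whether the tag
#' changed the distribution of failure causes. The response is binarized as
#' predation versus all other causes (configurable); the model is a logit
#' GLMM with a tag fixed effect and site and year random intercepts.
#'
#' @param nests Nest records; only failed nests with known cause are used.
#' @param predation_vs Baseline coding: causes grouped against predation.
#' @return List with the fitted top set and averaged model, or `NULL` (with
#'   a message) when fewer than 2 failure categories are present.
#' @export
cause_of_failure_stage <- function(nests,
                                   predation_vs = c("abandonment",
                                                    "failure_to_hatch",
                                                    "egg_damage", "unknown")) {
  ff <- nests[nests$fate == "failed" & nests$cause_of_failure != "none", ,
              drop = FALSE]
  if (length(unique(ff$cause_of_failure[!is.na(ff$cause_of_failure)])) < 2) {
    message("cause-of-failure stage skipped: fewer than 2 failure categories")
    return(NULL)
  }
  tab <- data.frame(
    depredated = as.integer(ff$cause_of_failure == "predation"),
    geolocator = as.integer(ff$n_geo_parents >= 1),
    site = ff$site, year = ff$year, taxon = ff$taxon,
    stringsAsFactors = FALSE)
  tab <- .model_table(tab, response = "depredated",
                      grouping = c("site", "year"),
                      stage = "cause_of_failure",
                      exclusions = .exclusion_log(
                        not_failed_or_no_cause = nrow(nests) - nrow(ff)))
  .fit_stage(tab, .stage_designs$cause_of_failure, two_pass = FALSE)
}

#' Extract per-taxon tag-effect records from stage results
#'
#' Collects the tag coefficient, its unconditional SE and RI from each
#' taxon's averaged model into an effect-record table ready for
#' [meta_analysis()]. Taxa whose top set never contained the tag term enter
#' with a zero effect and `in_final_model = FALSE`.
#'
#' @param stage_results Per-taxon list from [run_stage()].
#' @param n_captures Optional named vector of capture counts per taxon.
#' @return Effect-record data frame.
#' @export
effects_from_stage <- function(stage_results, n_captures = NULL) {
  rows <- lapply(names(stage_results), function(tx) {
    sr <- stage_results[[tx]]
    if (is.null(sr)) return(NULL)
    co <- sr$averaged$coefficients
    i <- match("geolocator", co$term)
    inmod <- !is.na(i) && !is.na(co$estimate[i]) && co$ri[i] > 0
    data.frame(taxon = tx,
               beta_geo = if (inmod) co$estimate[i] else 0,
               se_geo = if (inmod) co$se[i] else NA_real_,
               ri_geo = if (inmod) co$ri[i] else NA_real_,
               in_final_model = inmod,
               N_i = if (!is.null(n_captures)) n_captures[[tx]] else sr$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "schema") <- "effect_record"
  out
}

#' Run the full pipeline from a configuration
#'
#' Executes the configured stages end to end: simulate (or read) records,
#' build and standardize stage tables, run all-subsets selection and
#' averaging, collect per-taxon tag effects, and run the cross-taxon
#' meta-analysis. Every artifact is written under `out_dir` together with
#' the configuration and seed, and the run is deterministic given both.
#'
#' @param config Either a list or a path to a YAML file with entries
#'   `seed`, `stages` (character vector), `simulate` (arguments for
#'   [sim_config()]) or `data` (named CSV paths per record type), and
#'   optional `options` (`binary_rule`, `z_transform`, `mom_weights`).
#' @param out_dir Output directory (created if needed); `NULL` suppresses
#'   file output.
#' @return A report bundle: list with per-stage results, effect table, meta
#'   results and the echoed config.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  opts <- utils::modifyList(list(binary_rule = "center",
                                 z_transform = "identity",
                                 mom_weights = "n_captures"),
                            config$options %||% list())
  stages <- config$stages %||% "return_rate"

  records <- if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$taxa)) sim_args$taxa <- as.data.frame(sim_args$taxa)
    if (!is.null(sim_args$fixed_effects)) {
      sim_args$fixed_effects <- unlist(sim_args$fixed_effects)
    }
    sim <- simulate_study(do.call(sim_config, sim_args))
    sim$records
  } else if (!is.null(config$data)) {
    read_records(config$data$path, config$data$schema)
  } else stop("config must provide either 'simulate' or 'data'", call. = FALSE)

  bundle <- list(config = config, options = opts, stages = list())
  for (st in stages) {
    bundle$stages[[st]] <- run_stage(st, records, terms = config$terms,
                                     binary_rule = opts$binary_rule)
  }
  if ("return_rate" %in% stages && length(bundle$stages$return_rate) >= 2) {
    eff <- effects_from_stage(bundle$stages$return_rate)
    bundle$effects <- eff
    if (nrow(eff) >= 2) {
      bundle$meta <- meta_analysis(eff, z_transform = opts$z_transform,
                                   weights = opts$mom_weights)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bundle$effects)) {
      write_records(bundle$effects, file.path(out_dir, "effects.csv"))
    }
    for (st in names(bundle$stages)) {
      res <- bundle$stages[[st]]
      if (is.null(res)) next
      per_taxon <- !("averaged" %in% names(res))
      items <- if (per_taxon) res else list(pooled = res)
      for (nm in names(items)) {
        if (is.null(items[[nm]])) next
        utils::write.csv(items[[nm]]$averaged$coefficients,
                         file.path(out_dir, sprintf("%s_%s_averaged.csv", st, nm)),
                         row.names = FALSE)
        utils::write.csv(items[[nm]]$top$table,
                         file.path(out_dir, sprintf("%s_%s_topset.csv", st, nm)),
                         row.names = FALSE)
      }
    }
    report <- list(seed = config$seed, options = opts,
                   stages = names(bundle$stages))
    if (!is.null(bundle$meta)) {
      p <- bundle$meta$pooled
      report$meta <- list(M = p$M, SE_M = p$SE_M, tau2 = p$tau2, Q = p$Q,
                          I2 = p$I2, k = p$k)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
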