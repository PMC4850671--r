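## Inclusion/exclusion rules and model-table construction --------------------

.model_table <- function(df, response, grouping, stage, exclusions) {
  rownames(df) <- NULL
  attr(df, "response") <- response
  attr(df, "grouping") <- grouping
  attr(df, "stage") <- stage
  attr(df, "exclusions") <- exclusions
  class(df) <- c("model_table", "data.frame")
  df
}

.exclusion_log <- function(...) {
  rules <- list(...)
  data.frame(rule = names(rules), n_excluded = unlist(rules, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Exclusion log of a model table
#'
#' @param table A model table built by one of the `build_*_table` functions.
#' @return Data frame of exclusion rules and counts; the input row count
#'   always equals the output row count plus the sum of exclusions.
#' @export
exclusions <- function(table) attr(table, "exclusions")

#' Classify nest fate from monitoring evidence
#'
#' A nest is `successful` if at least one newly hatched chick was observed,
#' or if eggshells indicative of hatching were found within 4 days of the
#' expected hatch date. It is `failed` if all eggs disappeared with no
#' evidence of hatching while monitoring covered the loss. Anything else —
#' conflicting evidence, or monitoring that ended before the expected hatch
#' date without resolution — is `unknown`.
#'
#' @param chick_observed Logical: newly hatched chick seen in the nest.
#' @param eggshell_day_offset Days between finding hatch-indicative eggshells
#'   and the expected hatch date (`NA` when no shells were found or the hatch
#'   date is unknown).
#' @param eggs_disappeared Logical: all eggs gone with no hatching evidence.
#' @param monitored_to_expected_hatch Logical: monitoring continued until the
#'   expected hatch date (or the nest's earlier loss).
#' @return Factor with levels `successful`, `failed`, `unknown`.
#' @export
classify_nest_fate <- function(chick_observed, eggshell_day_offset,
                               eggs_disappeared,
                               monitored_to_expected_hatch) {
  n <- max(length(chick_observed), length(eggshell_day_offset),
           length(eggs_disappeared), length(monitored_to_expected_hatch))
  chick_observed <- rep_len(chick_observed, n)
  eggshell_day_offset <- rep_len(eggshell_day_offset, n)
  eggs_disappeared <- rep_len(eggs_disappeared, n)
  monitored_to_expected_hatch <- rep_len(monitored_to_expected_hatch, n)
  hatched_evidence <- (!is.na(chick_observed) & chick_observed) |
    (!is.na(eggshell_day_offset) & abs(eggshell_day_offset) <= 4)
  failed_evidence <- !is.na(eggs_disappeared) & eggs_disappeared &
    !hatched_evidence & !is.na(monitored_to_expected_hatch) &
    monitored_to_expected_hatch
  out <- rep("unknown", n)
  out[hatched_evidence] <- "successful"
  out[failed_evidence] <- "failed"
  factor(out, levels = c("successful", "failed", "unknown"))
}

#' Screen site-by-taxon combinations for capture-timing balance
#'
#' A site-taxon combination is eligible for the nest-success stage only when
#' Welch two-sample t-tests detect no difference between tagged and control
#' groups in capture date nor in nest age at capture (both `p >= 0.05`).
#' Combinations where either group has fewer than 2 usable observations are
#' flagged ineligible with a warning.
#'
#' @param events Data frame with columns `site`, `taxon`, `group`,
#'   `capture_day` and `nest_age_at_capture` (days).
#' @param p_cutoff Eligibility threshold (default 0.05).
#' @return Data frame with one row per site-taxon: the two p-values,
#'   `eligible`, and a `reason` for ineligible combinations.
#' @export
screen_sites_capture_timing <- function(events, p_cutoff = 0.05) {
  needed <- c("site", "taxon", "group", "capture_day", "nest_age_at_capture")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    stop("events lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- unique(events[, c("site", "taxon")])
  res <- lapply(seq_len(nrow(key)), function(i) {
    sub <- events[events$site == key$site[i] & events$taxon == key$taxon[i], ]
    ctl <- sub[sub$group == "control", ]
    geo <- sub[sub$group == "geolocator", ]
    small <- function(x) sum(!is.na(x)) < 2
    if (small(ctl$capture_day) || small(geo$capture_day) ||
        small(ctl$nest_age_at_capture) || small(geo$nest_age_at_capture)) {
      warning(sprintf("site %s / %s: fewer than 2 observations in a group",
                      key$site[i], key$taxon[i]))
      return(data.frame(site = key$site[i], taxon = key$taxon[i],
                        p_capture_day = NA_real_, p_nest_age = NA_real_,
                        eligible = FALSE, reason = "group with < 2 observations",
                        stringsAsFactors = FALSE))
    }
    p1 <- stats::t.test(ctl$capture_day, geo$capture_day)$p.value
    p2 <- stats::t.test(ctl$nest_age_at_capture, geo$nest_age_at_capture)$p.value
    ok <- p1 >= p_cutoff && p2 >= p_cutoff
    data.frame(site = key$site[i], taxon = key$taxon[i],
               p_capture_day = p1, p_nest_age = p2, eligible = ok,
               reason = if (ok) "" else "group difference in capture timing",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build the return-rate model table
#'
#' Applies the return-rate inclusion rules to validated capture events:
#' juveniles are excluded; tagged birds that returned without their tag are
#' excluded; once an individual has been in the tagged group it no longer
#' contributes control events in later years (avoiding carry-over bias after
#' tag removal); rows lacking group or year are rejected. Multiple capture
#' events per individual are retained, with individual available as a
#' grouping factor.
#'
#' @param events Capture-event data frame.
#' @return A model table with binary response `returned`, the tag indicator
#'   `geolocator` plus candidate covariates, and grouping columns
#'   `site`, `year`, `individual`. The exclusion log is in
#'   [exclusions()].
#' @export
build_return_table <- function(events) {
  bad <- is.na(events$group) | is.na(events$year)
  ev <- events[!bad, , drop = FALSE]
  # tagging history is taken from the full record before other exclusions
  first_geo <- tapply(ifelse(ev$group == "geolocator", ev$year, NA_integer_),
                      ev$individual_id,
                      function(y) suppressWarnings(min(y, na.rm = TRUE)))
  juv <- ev$age_class == "juvenile"
  ev <- ev[!juv, , drop = FALSE]
  wot <- ev$group == "geolocator" & !is.na(ev$returned_without_tag) &
    ev$returned_without_tag
  ev <- ev[!wot, , drop = FALSE]
  fg <- first_geo[ev$individual_id]
  post_removal <- ev$group == "control" & is.finite(fg) & ev$year > fg
  ev <- ev[!post_removal, , drop = FALSE]

  tab <- data.frame(
    returned = as.integer(ev$returned),
    geolocator = as.integer(ev$group == "geolocator"),
    sex = factor(ev$sex, levels = c("female", "male", "unknown")),
    nest_fate = factor(ev$nest_fate_final,
                       levels = c("failed", "hatched", "unknown", "none")),
    previously_marked = as.integer(ev$previously_marked),
    body_mass = ev$body_mass_g,
    capture_day = ev$capture_day,
    blood_sample = as.integer(ev$blood_sample),
    marker_mass = ev$marker_mass_g,
    site = ev$site, year = ev$year, individual = ev$individual_id,
    taxon = ev$taxon, stringsAsFactors = FALSE)
  .model_table(tab, response = "returned",
               grouping = c("site", "year", "individual"),
               stage = "return_rate",
               exclusions = .exclusion_log(
                 missing_group_or_year = sum(bad),
                 juvenile = sum(juv),
                 returned_without_tag = sum(wot),
                 control_after_tagging = sum(post_removal)))
}

#' Build the nest-success model table
#'
#' Excludes nests of unknown fate and restricts to eligible site-taxon
#' combinations (see [screen_sites_capture_timing()]). Nests with one or two
#' tagged parents are pooled into a single tagged group.
#'
#' @param nests Nest-record data frame.
#' @param eligible Optional data frame with columns `site`, `taxon`,
#'   `eligible`; when omitted all sites are eligible.
#' @return Model table with binary response `success`.
#' @export
build_nest_table <- function(nests, eligible = NULL) {
  unknown <- nests$fate == "unknown"
  nn <- nests[!unknown, , drop = FALSE]
  n_inel <- 0L
  if (!is.null(eligible)) {
    ok <- eligible[eligible$eligible, c("site", "taxon")]
    keep <- paste(nn$site, nn$taxon) %in% paste(ok$site, ok$taxon)
    n_inel <- sum(!keep)
    nn <- nn[keep, , drop = FALSE]
  }
  tab <- data.frame(
    success = as.integer(nn$fate == "successful"),
    geolocator = as.integer(nn$n_geo_parents >= 1),
    site = nn$site, year = nn$year, taxon = nn$taxon,
    stringsAsFactors = FALSE)
  .model_table(tab, response = "success", grouping = c("site", "year"),
               stage = "nest_success",
               exclusions = .exclusion_log(unknown_fate = sum(unknown),
                                           ineligible_site = n_inel))
}

#' Build the partial-hatching model table
#'
#' Restricts to successful nests (at least one egg hatched) of the pooled
#' small-bodied taxa, with unhatched-egg presence recorded and no research
#' damage to the clutch.
#'
#' @param nests Nest-record data frame.
#' @param taxa Taxa pooled for this stage (default the two smallest-bodied
#'   sandpipers, `SESA` and `WESA`).
#' @return Model table with binary response `unhatched_egg`.
#' @export
build_partial_hatch_table <- function(nests, taxa = c("SESA", "WESA")) {
  not_success <- nests$fate != "successful"
  nn <- nests[!not_success, , drop = FALSE]
  off_taxa <- !(nn$taxon %in% taxa)
  nn <- nn[!off_taxa, , drop = FALSE]
  damaged <- !is.na(nn$research_damage) & nn$research_damage
  nn <- nn[!damaged, , drop = FALSE]
  unrecorded <- is.na(nn$unhatched_egg_present)
  nn <- nn[!unrecorded, , drop = FALSE]
  tab <- data.frame(
    unhatched_egg = as.integer(nn$unhatched_egg_present),
    geolocator = as.integer(nn$n_geo_parents >= 1),
    site = nn$site, year = nn$year, species = substr(nn$taxon, 1, 4),
    taxon = nn$taxon, stringsAsFactors = FALSE)
  .model_table(tab, response = "unhatched_egg",
               grouping = c("species", "site", "year"),
               stage = "partial_hatch",
               exclusions = .exclusion_log(
                 not_successful = sum(not_success), other_taxon = sum(off_taxa),
                 research_damage = sum(damaged),
                 unhatched_not_recorded = sum(unrecorded)))
}

#' Build the attachment-contrast model table
#'
#' Compares the two leg-mounted attachment configurations (parallel-band
#' versus perpendicular-flag) within the tagged group: adult tagged birds
#' carrying either attachment, with the return outcome as response,
#' a perpendicular-flag indicator (parallel-band baseline) and nest fate as
#' a covariate, and year as the grouping factor.
#'
#' @param events Capture-event data frame.
#' @return Model table with binary response `returned`.
#' @export
build_attachment_table <- function(events) {
  not_geo <- events$group != "geolocator"
  ev <- events[!not_geo, , drop = FALSE]
  juv <- ev$age_class == "juvenile"
  ev <- ev[!juv, , drop = FALSE]
  other <- !(ev$attachment %in% c("PAB", "PEF"))
  ev <- ev[!other, , drop = FALSE]
  tab <- data.frame(
    returned = as.integer(ev$returned),
    attachment_PEF = as.integer(ev$attachment == "PEF"),
    nest_fate = factor(ev$nest_fate_final,
                       levels = c("failed", "hatched", "unknown", "none")),
    site = ev$site, year = ev$year, taxon = ev$taxon,
    stringsAsFactors = FALSE)
  .model_table(tab, response = "returned", grouping = c("year"),
               stage = "attachment_contrast",
               exclusions = .exclusion_log(control_group = sum(not_geo),
                                           juvenile = sum(juv),
                                           other_attachment = sum(other)))
}

#' Build the breeding-movement model table
#'
#' Movements are included only when the nest was on an established study plot
#' in both the capture and the return year, keeping recorded movements on the
#' same spatial scale for tagged and control birds. The response is the
#' natural log of `distance_m + 1`, admitting reuse of the same nest cup.
#'
#' @param movements Movement-record data frame.
#' @return Model table with Gaussian response `log_distance`.
#' @export
build_movement_table <- function(movements) {
  off <- !movements$on_plot_both_years
  mv <- movements[!off, , drop = FALSE]
  tab <- data.frame(
    log_distance = log(mv$distance_m + 1),
    geolocator = as.integer(mv$group == "geolocator"),
    sex = factor(mv$sex, levels = c("female", "male", "unknown")),
    nest_fate = factor(mv$nest_fate_year_t,
                       levels = c("failed", "hatched", "unknown")),
    previously_marked = as.integer(mv$previously_marked),
    site = mv$site, year = mv$year_t, species = substr(mv$taxon, 1, 4),
    taxon = mv$taxon, stringsAsFactors = FALSE)
  .model_table(tab, response = "log_distance",
               grouping = c("species", "site", "year"),
               stage = "movement",
               exclusions = .exclusion_log(off_plot = sum(off)))
}

#' Build the body-mass-change model table
#'
#' @param masses Mass-change record data frame.
#' @return Model table with Gaussian response `pct_mass_change` and the
#'   capture-interval covariates.
#' @export
build_mass_change_table <- function(masses) {
  miss <- is.na(masses$pct_mass_change)
  mm <- masses[!miss, , drop = FALSE]
  tab <- data.frame(
    pct_mass_change = mm$pct_mass_change,
    geolocator = as.integer(mm$group == "geolocator"),
    delta_capture_day = mm$delta_capture_day,
    delta_nest_age = mm$delta_nest_age,
    site = mm$site, year = mm$year_t, species = substr(mm$taxon, 1, 4),
    taxon = mm$taxon, stringsAsFactors = FALSE)
  .model_table(tab, response = "pct_mass_change",
               grouping = c("species", "site", "year"),
               stage = "mass_change",
               exclusions = .exclusion_log(missing_response = sum(miss)))
}
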