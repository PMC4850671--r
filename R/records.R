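#' @keywords internal
"_PACKAGE"

## Record schemas ------------------------------------------------------------

# Column definitions for the five tabular record types used throughout the
# package. Each entry is a named character vector: field name -> storage type.
# Enum levels are enforced at read/validation time.
.schemas <- list(
  capture_event = c(
    individual_id = "character", taxon = "character", site = "character",
    year = "integer", group = "enum", attachment = "enum", sex = "enum",
    capture_day = "integer", body_mass_g = "numeric", marker_mass_g = "numeric",
    blood_sample = "logical", previously_marked = "logical",
    nest_fate_final = "enum", returned = "logical",
    returned_without_tag = "logical", age_class = "enum"
  ),
  nest_record = c(
    nest_id = "character", taxon = "character", site = "character",
    year = "integer", n_geo_parents = "integer", fate = "enum",
    cause_of_failure = "enum", unhatched_egg_present = "logical",
    research_damage = "logical", found_stage = "numeric"
  ),
  movement_record = c(
    individual_id = "character", taxon = "character", site = "character",
    year_t = "integer", year_t1 = "integer", distance_m = "numeric",
    sex = "enum", nest_fate_year_t = "enum", previously_marked = "logical",
    group = "enum", on_plot_both_years = "logical"
  ),
  mass_change_record = c(
    individual_id = "character", taxon = "character", site = "character",
    year_t = "integer", year_t1 = "integer", pct_mass_change = "numeric",
    delta_capture_day = "integer", delta_nest_age = "numeric", group = "enum"
  ),
  taxon_summary = c(
    taxon = "character", common_name = "character", n_sites = "integer",
    n_control_captures = "integer", n_geo_captures = "integer",
    mean_body_mass_g = "numeric", migration_deg_lat = "numeric",
    attachment = "character", geo_total_mass_g = "numeric",
    geo_pct_body_mass = "numeric", max_pct_all_tags = "numeric"
  ),
  effect_record = c(
    taxon = "character", beta_geo = "numeric", se_geo = "numeric",
    ri_geo = "numeric", in_final_model = "logical"
  )
)

.enum_levels <- list(
  group = c("control", "geolocator"),
  attachment = c("PAB", "PEF", "PAF", "LLH", "none"),
  sex = c("female", "male", "unknown"),
  nest_fate_final = c("hatched", "failed", "unknown", "none"),
  fate = c("successful", "failed", "unknown"),
  cause_of_failure = c("predation", "abandonment", "failure_to_hatch",
                       "egg_damage", "unknown", "none"),
  nest_fate_year_t = c("hatched", "failed", "unknown"),
  age_class = c("adult", "juvenile")
)

.study_years <- c(2007L, 2015L)

#' Record schemas used by the package
#'
#' Returns the named list of column schemas for the tabular record types:
#' `capture_event`, `nest_record`, `movement_record`, `mass_change_record`,
#' `taxon_summary` and `effect_record`.
#'
#' @return Named list; each element maps field names to storage types.
#' @export
tagdem_schemas <- function() .schemas

.coerce_column <- function(x, name, type, path = "<data>") {
  x[x %in% c("", "NA")] <- NA
  out <- switch(type,
    character = as.character(x),
    integer   = suppressWarnings(as.integer(x)),
    numeric   = suppressWarnings(as.numeric(x)),
    logical   = {
      v <- rep(NA, length(x))
      v[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
      v[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
      as.logical(v)
    },
    enum = {
      lev <- .enum_levels[[name]]
      bad <- !is.na(x) & !(x %in% lev)
      if (any(bad)) {
        stop(sprintf("%s: invalid value '%s' for '%s' at row %d",
                     path, x[which(bad)[1]], name, which(bad)[1]), call. = FALSE)
      }
      factor(x, levels = lev)
    },
    stop("unknown storage type: ", type)
  )
  if (type %in% c("integer", "numeric")) {
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop(sprintf("%s: cannot parse '%s' as %s in column '%s' at row %d",
                   path, x[which(bad)[1]], type, name, which(bad)[1]),
           call. = FALSE)
    }
  }
  out
}

#' Read a typed record table from CSV
#'
#' Parses a comma-delimited UTF-8 file with a mandatory header row into one of
#' the package's record types. Empty cells and the literal token `NA` are both
#' read as missing. Columns must match the schema exactly (order-free);
#' unknown or absent columns raise an error naming the column.
#'
#' @param path Path to a CSV file.
#' @param schema Schema name, one of `names(tagdem_schemas())`.
#' @return A `data.frame` with one typed column per schema field and as many
#'   rows as the file has data rows.
#' @export
read_records <- function(path, schema) {
  schema <- match.arg(schema, names(.schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sch <- .schemas[[schema]]
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  unknown <- setdiff(names(raw), names(sch))
  if (length(unknown)) {
    stop(sprintf("%s: unknown column(s) for schema '%s': %s",
                 path, schema, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(names(sch), names(raw))
  if (length(absent)) {
    stop(sprintf("%s: missing column(s) for schema '%s': %s",
                 path, schema, paste(absent, collapse = ", ")), call. = FALSE)
  }
  out <- as.data.frame(
    lapply(names(sch), function(nm) .coerce_column(raw[[nm]], nm, sch[[nm]], path)),
    col.names = names(sch), stringsAsFactors = FALSE, optional = TRUE
  )
  names(out) <- names(sch)
  if (schema == "capture_event" && nrow(out)) {
    key <- paste(out$individual_id, out$year, out$group, sep = "\r")
    if (anyDuplicated(key)) {
      d <- out[duplicated(key), , drop = FALSE]
      stop(sprintf("%s: duplicate capture event (individual_id=%s, year=%s, group=%s)",
                   path, d$individual_id[1], d$year[1], d$group[1]), call. = FALSE)
    }
  }
  attr(out, "schema") <- schema
  out
}

#' Write a typed record table to CSV
#'
#' Inverse of [read_records()]: missing values are written as empty cells so
#' that a write/read round trip reproduces the records field-for-field.
#'
#' @param records Data frame of records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

## Validation ----------------------------------------------------------------

.violation <- function(id, field, problem) {
  data.frame(record_id = as.character(id), field = field, problem = problem,
             stringsAsFactors = FALSE)
}

#' Validate a record table against its domain invariants
#'
#' Checks cross-field invariants (group/attachment consistency, study-year
#' window, fate/cause consistency, non-negative distances, and so on).
#' Violations are reported, never raised: clean data yields a zero-row report.
#'
#' @param records Data frame as returned by [read_records()] or the synthetic
#'   generator.
#' @param schema Schema name; defaults to the `schema` attribute of `records`.
#' @return Data frame with columns `record_id`, `field`, `problem`; zero rows
#'   when all invariants hold.
#' @export
validate_records <- function(records, schema = attr(records, "schema")) {
  schema <- match.arg(schema, names(.schemas))
  rep <- list()
  add <- function(mask, id, field, problem) {
    if (any(mask, na.rm = TRUE)) {
      rep[[length(rep) + 1]] <<- .violation(id[which(mask)], field, problem)
    }
  }
  r <- records
  if (schema == "capture_event") {
    id <- paste(r$individual_id, r$year, sep = "/")
    add(r$year < .study_years[1] | r$year > .study_years[2], id, "year",
        "year outside study window 2007-2015")
    add(r$group == "control" & r$attachment != "none", id, "attachment",
        "control event with a tag attachment")
    add(r$returned_without_tag & r$group != "geolocator", id,
        "returned_without_tag", "returned_without_tag on a control event")
    add(!is.na(r$body_mass_g) & r$body_mass_g < 0, id, "body_mass_g",
        "negative body mass")
    add(!is.na(r$marker_mass_g) & r$marker_mass_g < 0, id, "marker_mass_g",
        "negative marker mass")
    add(!is.na(r$capture_day) & (r$capture_day < 1 | r$capture_day > 366), id,
        "capture_day", "capture day outside 1-366")
  } else if (schema == "nest_record") {
    id <- r$nest_id
    add(r$fate != "failed" & r$cause_of_failure != "none", id,
        "cause_of_failure", "cause of failure recorded for a non-failed nest")
    add(r$fate == "failed" & r$cause_of_failure == "none", id,
        "cause_of_failure", "failed nest without a cause of failure")
    add(r$n_geo_parents < 0 | r$n_geo_parents > 2, id, "n_geo_parents",
        "number of tagged parents outside 0-2")
    add(!is.na(r$found_stage) & (r$found_stage < 0 | r$found_stage > 1), id,
        "found_stage", "found stage outside [0, 1]")
  } else if (schema == "movement_record") {
    id <- paste(r$individual_id, r$year_t, sep = "/")
    add(r$distance_m < 0, id, "distance_m", "negative movement distance")
    add(r$year_t1 != r$year_t + 1L, id, "year_t1",
        "year pair is not consecutive")
  } else if (schema == "mass_change_record") {
    id <- paste(r$individual_id, r$year_t, sep = "/")
    add(r$year_t1 != r$year_t + 1L, id, "year_t1",
        "year pair is not consecutive")
  } else if (schema == "taxon_summary") {
    id <- r$taxon
    add(r$n_control_captures + r$n_geo_captures <= 0, id, "n_geo_captures",
        "taxon without capture events")
    add(!is.na(r$geo_pct_body_mass) & r$geo_pct_body_mass <= 0, id,
        "geo_pct_body_mass", "non-positive tag percent body mass")
  } else if (schema == "effect_record") {
    id <- r$taxon
    add(!r$in_final_model & r$beta_geo != 0, id, "beta_geo",
        "taxon outside final model must carry a zero effect")
    add(!r$in_final_model & !is.na(r$se_geo), id, "se_geo",
        "taxon outside final model must carry no SE")
    add(r$in_final_model & !is.na(r$se_geo) & r$se_geo <= 0, id, "se_geo",
        "non-positive SE")
  }
  if (!length(rep)) {
    return(data.frame(record_id = character(), field = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rep)
}

## Packaged study fixtures ---------------------------------------------------

#' Load the packaged 23-taxon study tables
#'
#' Loads the per-taxon summary table (capture counts, tag percent of mean body
#' mass, migration distance in degrees latitude) and the table of
#' model-averaged geolocator coefficients on annual return rate, transcribed
#' at printed precision from a 23-taxon shorebird geolocator study. Where the
#' source table prints a range for tag mass or percent body mass, the midpoint
#' is stored. Taxa whose geolocator term was absent from the final averaged
#' model carry `beta_geo = 0`, no SE, and `in_final_model = FALSE`.
#'
#' @return A list with elements `taxa` (23 taxon summaries) and `effects`
#'   (23 effect records joined with capture counts `N_i` and the moderators
#'   `geo_pct_body_mass` and `migration_deg_lat`).
#' @export
load_study_tables <- function() {
  p1 <- system.file("extdata", "table1_taxa.csv", package = "tagdem")
  p3 <- system.file("extdata", "table3_effects.csv", package = "tagdem")
  if (p1 == "" || p3 == "") stop("packaged study tables not found", call. = FALSE)
  taxa <- read_records(p1, "taxon_summary")
  eff <- read_records(p3, "effect_record")
  if (nrow(taxa) != 23L || nrow(eff) != 23L) {
    stop("study tables must each contain 23 taxa", call. = FALSE)
  }
  if (!setequal(taxa$taxon, eff$taxon)) {
    stop("taxon codes differ between the summary and effect tables: ",
         paste(union(setdiff(taxa$taxon, eff$taxon),
                     setdiff(eff$taxon, taxa$taxon)), collapse = ", "),
         call. = FALSE)
  }
  m <- match(eff$taxon, taxa$taxon)
  eff$N_i <- taxa$n_control_captures[m] + taxa$n_geo_captures[m]
  eff$n_geo_captures <- taxa$n_geo_captures[m]
  eff$geo_pct_body_mass <- taxa$geo_pct_body_mass[m]
  eff$migration_deg_lat <- taxa$migration_deg_lat[m]
  attr(eff, "schema") <- "effect_record"
  list(taxa = taxa, effects = eff)
}
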