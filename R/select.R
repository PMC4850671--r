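## Standardization, all-subsets selection, averaging ------------------------

#' Standardize predictor columns
#'
#' Rescales predictors so that coefficients are comparable across terms:
#' continuous columns are centred and divided by twice their standard
#' deviation (so a 2-SD change corresponds to one unit, commensurate with a
#' binary contrast); binary columns are centred only under the default rule,
#' or fully rescaled under `binary_rule = "full"`; multi-level factors are
#' expanded to centred indicator contrasts. Zero-variance columns are dropped
#' with a warning. Grouping and response columns are left untouched.
#'
#' @param data Model table.
#' @param columns Columns to standardize; defaults to every numeric, logical
#'   or factor column not listed in `exclude`.
#' @param exclude Columns never transformed (response, grouping and taxon
#'   label columns by default, read from attributes when present).
#' @param binary_rule `"center"` (default) or `"full"` (divide binaries by
#'   2 SD as well; changes the coefficient scale of binary terms).
#' @return List with `table` (transformed data) and `map` (per-column mean,
#'   SD and the rule applied, for back-transformation).
#' @export
standardize_table <- function(data, columns = NULL,
                              exclude = c(attr(data, "response"),
                                          attr(data, "grouping"),
                                          "taxon", "species", "site", "year",
                                          "individual"),
                              binary_rule = c("center", "full")) {
  binary_rule <- match.arg(binary_rule)
  exclude <- exclude[!is.null(exclude)]
  if (is.null(columns)) {
    columns <- setdiff(names(data), exclude)
    columns <- columns[vapply(data[columns], function(x)
      is.numeric(x) || is.logical(x) || is.factor(x) || is.character(x),
      logical(1))]
  }
  map <- list()
  out <- data
  for (cl in columns) {
    x <- out[[cl]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      lev <- levels(droplevels(x))
      if (length(lev) < 2) {
        warning("dropping zero-variance column '", cl, "'")
        out[[cl]] <- NULL
        map[[cl]] <- list(rule = "dropped")
        next
      }
      for (lv in lev[-1]) {
        ind <- as.numeric(x == lv)
        nm <- paste0(cl, "_", lv)
        out[[nm]] <- ind - mean(ind, na.rm = TRUE)
        map[[nm]] <- list(mean = mean(ind, na.rm = TRUE), sd = NA_real_,
                          rule = "centered_indicator", parent = cl)
      }
      out[[cl]] <- NULL
      next
    }
    x <- as.numeric(x)
    ux <- unique(x[!is.na(x)])
    if (length(ux) < 2) {
      warning("dropping zero-variance column '", cl, "'")
      out[[cl]] <- NULL
      map[[cl]] <- list(rule = "dropped")
      next
    }
    is_binary <- all(ux %in% c(0, 1))
    mu <- mean(x, na.rm = TRUE)
    if (is_binary && binary_rule == "center") {
      out[[cl]] <- x - mu
      map[[cl]] <- list(mean = mu, sd = NA_real_, rule = "centered_binary")
    } else {
      s <- stats::sd(x, na.rm = TRUE)
      out[[cl]] <- (x - mu) / (2 * s)
      map[[cl]] <- list(mean = mu, sd = s, rule = "two_sd")
    }
  }
  attr(out, "response") <- attr(data, "response")
  attr(out, "grouping") <- attr(data, "grouping")
  list(table = out, map = map)
}

#' Enumerate all fixed-effect submodels
#'
#' Generates every subset of the supplied fixed terms (the intercept and the
#' full random structure are retained in every submodel). Indicator columns
#' that expand one categorical predictor can be grouped so that they toggle
#' as a unit.
#'
#' @param fixed Character vector of fixed-term (column) names.
#' @param units Optional named list grouping columns into single selection
#'   units, e.g. `list(nest_fate = c("nest_fate_hatched", "nest_fate_unknown"))`.
#' @param max_terms Combinatorial guard: refuse more than this many units
#'   (default 12).
#' @return List of character vectors, one per submodel (possibly empty for
#'   the intercept-only model).
#' @export
enumerate_submodels <- function(fixed, units = NULL, max_terms = 12L) {
  unit_names <- fixed
  unit_cols <- as.list(fixed)
  if (!is.null(units)) {
    grouped <- unlist(units, use.names = FALSE)
    unit_names <- c(setdiff(fixed, grouped), names(units))
    unit_cols <- c(as.list(setdiff(fixed, grouped)), units)
  }
  m <- length(unit_names)
  if (m > max_terms) {
    stop(sprintf(paste0("%d candidate terms would require %s submodels; ",
                        "reduce the term list or raise max_terms"),
                 m, format(2^m, big.mark = ",")), call. = FALSE)
  }
  if (m == 0) return(list(character()))
  idx <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  lapply(seq_len(nrow(idx)), function(i) {
    unlist(unit_cols[unlist(idx[i, ])], use.names = FALSE)
  })
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param object A `fitted_glmm`, or a numeric log-likelihood.
#' @param k,n Parameter count and sample size (required when `object` is
#'   numeric).
#' @return AICc value. Undefined (error) when `n <= k + 1`.
#' @export
aicc <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "fitted_glmm")) {
    ll <- object$logLik; k <- object$k; n <- object$n
  } else {
    ll <- as.numeric(object)
    if (is.null(k) || is.null(n)) stop("k and n are required", call. = FALSE)
  }
  if (k < 1) stop("k must count at least the intercept", call. = FALSE)
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' @param delta Numeric vector of AICc differences (minimum must be 0).
#' @return Weights `exp(-delta/2) / sum(exp(-delta/2))`, summing to 1.
#' @export
akaike_weights <- function(delta) {
  if (!length(delta)) stop("empty delta vector", call. = FALSE)
  if (any(delta < 0) || abs(min(delta)) > 1e-8) {
    stop("delta values must be >= 0 with minimum 0", call. = FALSE)
  }
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Construct a top model set
#'
#' Assembles ranked models into the structure consumed by
#' [natural_average()]. Normally produced by [dredge_glmm()], but can be
#' built directly from term lists, coefficient estimates and AICc values
#' (useful for worked examples and cross-checks).
#'
#' @param models List of models; each a list with elements `terms`
#'   (character), `coefficients` (data frame `term`/`estimate`/`se`) and
#'   `aicc` (numeric). `fitted_glmm` objects are also accepted.
#' @param cutoff Retain models with `delta < cutoff` (strictly; default 2).
#' @param family Response family label propagated to the averaged model.
#' @return Object of class `top_model_set`: ranked table and retained models
#'   with renormalized Akaike weights (summing to 1 over the top set).
#' @export
top_model_set <- function(models, cutoff = 2, family = "binomial_logit") {
  models <- lapply(models, function(mm) {
    if (inherits(mm, "fitted_glmm")) {
      list(terms = mm$spec$fixed, coefficients = mm$coefficients,
           aicc = aicc(mm), fit = mm)
    } else mm
  })
  a <- vapply(models, function(mm) mm$aicc, numeric(1))
  ord <- order(a)
  models <- models[ord]
  a <- a[ord]
  delta <- a - a[1]
  keep <- delta < cutoff
  w <- akaike_weights(delta[keep])
  tab <- data.frame(
    rank = seq_along(a),
    terms = vapply(models, function(mm)
      if (length(mm$terms)) paste(mm$terms, collapse = " + ") else "(intercept only)",
      character(1)),
    aicc = a, delta = delta, in_top_set = keep,
    weight = { z <- rep(NA_real_, length(a)); z[keep] <- w; z },
    stringsAsFactors = FALSE)
  structure(list(table = tab, models = models[keep], weights = w,
                 cutoff = cutoff, family = family), class = "top_model_set")
}

#' @export
print.top_model_set <- function(x, ...) {
  cat(sprintf("<top_model_set> %d model(s) at delta-AICc < %g\n",
              length(x$models), x$cutoff))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' All-subsets AICc model selection for a mixed-model design
#'
#' Fits every fixed-effect subset of the full specification (same random
#' structure throughout), ranks converged, non-singular fits by AICc and
#' retains the top set (`delta < cutoff`). Non-converged and singular
#' submodels are excluded from ranking and counted.
#'
#' @param spec Full [model_spec()].
#' @param data Model table (already standardized).
#' @param response Response column; defaults to the table's attribute.
#' @param units Categorical indicator groupings passed to
#'   [enumerate_submodels()].
#' @param cutoff Top-set cutoff on delta-AICc (default 2, strict).
#' @return A [top_model_set()] with extra fields `n_dropped_nonconverged`
#'   and `n_dropped_singular`.
#' @export
dredge_glmm <- function(spec, data, response = attr(data, "response"),
                        units = NULL, cutoff = 2) {
  subsets <- enumerate_submodels(spec$fixed, units = units)
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- model_spec(spec$family, fixed = subsets[[i]], random = spec$random,
                      geo_term = spec$geo_term)
    fits[[i]] <- tryCatch(fit_glmm(sub, data, response = response),
                          error = function(e) NULL)
  }
  failed <- vapply(fits, is.null, logical(1))
  fits <- fits[!failed]
  ok <- vapply(fits, function(f) f$converged, logical(1))
  sing <- vapply(fits, function(f) f$singular, logical(1))
  kept <- fits[ok & !sing]
  singular_ranked <- FALSE
  if (!length(kept) && any(ok)) {
    # every converged fit sits on a variance boundary (common with few
    # grouping levels); rank them rather than abandoning the stage
    kept <- fits[ok]
    singular_ranked <- TRUE
  }
  if (!length(kept)) {
    stop("no converged submodels to rank", call. = FALSE)
  }
  ts <- top_model_set(kept, cutoff = cutoff, family = spec$family)
  ts$n_dropped_nonconverged <- sum(!ok) + sum(failed)
  ts$n_dropped_singular <- if (singular_ranked) 0L else sum(ok & sing)
  ts$singular_ranked <- singular_ranked
  ts
}

#' Natural-average model averaging with relative importance
#'
#' Averages each term only over the top models that contain it, with Akaike
#' weights renormalized within that subset (the natural average). The
#' unconditional SE combines within-model variance and between-model spread
#' (revised squared-deviation estimator):
#' `SE_j = sqrt( sum_m w~_m (se_jm^2 + (b_jm - b_j)^2) )`.
#' Relative importance of a term is the summed weight of top models
#' containing it divided by the total top-set weight; RI = 1 for terms in
#' every top model and 0 for terms in none.
#'
#' @param top A [top_model_set()].
#' @param all_terms Terms to report; defaults to the union of terms across
#'   the top set (terms absent everywhere get RI 0 and no estimate).
#' @param ri_threshold Flag terms at or above this RI as high-importance
#'   (default 0.80).
#' @return Object of class `averaged_model` with a coefficient table
#'   (`term`, `estimate`, `se`, `ri`, `high_ri`).
#' @export
natural_average <- function(top, all_terms = NULL, ri_threshold = 0.80) {
  stopifnot(inherits(top, "top_model_set"))
  w <- top$weights
  terms_by_model <- lapply(top$models, function(mm) c("(Intercept)", mm$terms))
  union_terms <- unique(unlist(terms_by_model))
  if (is.null(all_terms)) all_terms <- union_terms
  all_terms <- union(union_terms, all_terms)
  rows <- lapply(all_terms, function(tm) {
    has <- vapply(terms_by_model, function(tt) tm %in% tt, logical(1))
    ri <- sum(w[has]) / sum(w)
    if (!any(has)) {
      return(data.frame(term = tm, estimate = NA_real_, se = NA_real_,
                        ri = 0, stringsAsFactors = FALSE))
    }
    wt <- w[has] / sum(w[has])
    est <- vapply(top$models[has], function(mm) {
      mm$coefficients$estimate[match(tm, mm$coefficients$term)]
    }, numeric(1))
    ses <- vapply(top$models[has], function(mm) {
      mm$coefficients$se[match(tm, mm$coefficients$term)]
    }, numeric(1))
    avg <- sum(wt * est)
    use <- sqrt(sum(wt * (ses^2 + (est - avg)^2)))
    data.frame(term = tm, estimate = avg, se = use,
               ri = if (tm == "(Intercept)") 1 else ri,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$high_ri <- !is.na(tab$ri) & tab$ri >= ri_threshold
  structure(list(coefficients = tab, family = top$family,
                 n_models = length(top$models),
                 ri_threshold = ri_threshold), class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> natural average over %d top model(s)\n",
              x$n_models))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Two-pass model selection with missing-covariate recovery
#'
#' Pass 1 runs all-subsets selection and averaging on rows complete for every
#' candidate term. Terms absent from every pass-1 top model are dropped, rows
#' that were missing data only for dropped terms are restored, and the full
#' selection procedure is re-run on the enlarged data with the reduced term
#' list. This maximizes the sample size behind the terms that matter (the tag
#' effect in particular) without biasing selection.
#'
#' @inheritParams dredge_glmm
#' @return List with `pass1`, `pass2` (each: top set + averaged model),
#'   `dropped_terms` and `final` (the pass-2 averaged model).
#' @export
two_pass_refit <- function(spec, data, response = attr(data, "response"),
                           units = NULL, cutoff = 2) {
  cc <- stats::complete.cases(data[, c(response, spec$fixed), drop = FALSE])
  if (!any(cc)) stop("no complete cases for pass 1", call. = FALSE)
  d1 <- data[cc, , drop = FALSE]
  attr(d1, "response") <- response; attr(d1, "grouping") <- attr(data, "grouping")
  ts1 <- dredge_glmm(spec, d1, response = response, units = units, cutoff = cutoff)
  avg1 <- natural_average(ts1, all_terms = c("(Intercept)", spec$fixed))
  present <- unique(unlist(lapply(ts1$models, `[[`, "terms")))
  dropped <- setdiff(spec$fixed, present)
  keep_terms <- setdiff(spec$fixed, dropped)
  if (!length(dropped)) {
    return(list(pass1 = list(top = ts1, averaged = avg1),
                pass2 = list(top = ts1, averaged = avg1),
                dropped_terms = character(), final = avg1))
  }
  cc2 <- stats::complete.cases(data[, c(response, keep_terms), drop = FALSE])
  d2 <- data[cc2, , drop = FALSE]
  attr(d2, "response") <- response; attr(d2, "grouping") <- attr(data, "grouping")
  spec2 <- model_spec(spec$family, fixed = keep_terms, random = spec$random,
                      geo_term = spec$geo_term)
  units2 <- if (!is.null(units)) units[vapply(units, function(u) all(u %in% keep_terms), logical(1))]
  ts2 <- dredge_glmm(spec2, d2, response = response, units = units2, cutoff = cutoff)
  avg2 <- natural_average(ts2, all_terms = c("(Intercept)", keep_terms))
  list(pass1 = list(top = ts1, averaged = avg1),
       pass2 = list(top = ts2, averaged = avg2),
       dropped_terms = dropped, final = avg2)
}
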