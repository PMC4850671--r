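## Mixed-model engine --------------------------------------------------------

#' Specify a mixed model
#'
#' Defines a model design for [fit_glmm()]: the response family, the fixed
#' terms (intercept always included) and the random-effect structure. The
#' tag-effect slope may vary only across sites; all other grouping factors
#' carry random intercepts, mirroring the design in which site-level
#' conditions can modulate the tag effect while years, individuals and
#' species shift only the baseline.
#'
#' @param family `"binomial_logit"` or `"gaussian_identity"`.
#' @param fixed Character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param random Named character vector: names are grouping factors (subset of
#'   `site`, `year`, `individual`, `species`), values are `"intercept_only"`
#'   or `"intercept_plus_geo_slope"`.
#' @param geo_term Name of the tag indicator column used for the random
#'   slope (default `"geolocator"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("binomial_logit", "gaussian_identity"),
                       fixed = character(),
                       random = c(site = "intercept_plus_geo_slope",
                                  year = "intercept_only"),
                       geo_term = "geolocator") {
  family <- match.arg(family)
  if (length(random)) {
    bad_g <- setdiff(names(random), c("site", "year", "individual", "species"))
    if (length(bad_g)) stop("unknown grouping factor(s): ",
                            paste(bad_g, collapse = ", "), call. = FALSE)
    bad_s <- setdiff(random, c("intercept_only", "intercept_plus_geo_slope"))
    if (length(bad_s)) stop("unknown random scope: ",
                            paste(bad_s, collapse = ", "), call. = FALSE)
    slope_on <- names(random)[random == "intercept_plus_geo_slope"]
    if (length(setdiff(slope_on, "site"))) {
      stop("the tag-effect random slope is only supported on 'site'",
           call. = FALSE)
    }
  }
  structure(list(family = family, fixed = unique(fixed), random = random,
                 geo_term = geo_term), class = "model_spec")
}

.spec_formula <- function(spec, response, diagonal_cov = FALSE) {
  fx <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  re <- character()
  for (g in names(spec$random)) {
    re <- c(re, if (spec$random[[g]] == "intercept_plus_geo_slope") {
      sprintf("(1 + %s %s %s)", spec$geo_term,
              if (diagonal_cov) "||" else "|", g)
    } else sprintf("(1 | %s)", g))
  }
  stats::as.formula(paste(response, "~", paste(c(fx, re), collapse = " + ")))
}

.n_vc_params <- function(spec, diagonal_cov = FALSE) {
  k <- 0L
  for (g in names(spec$random)) {
    k <- k + if (spec$random[[g]] == "intercept_plus_geo_slope") {
      if (diagonal_cov) 2L else 3L
    } else 1L
  }
  k
}

#' Fit a mixed model by maximum likelihood
#'
#' Fits the design in `spec` to a model table. Binomial (logit) models are
#' fitted by maximum likelihood with the Laplace approximation to the
#' integrated likelihood; Gaussian models by ML (not REML) so that AICc is
#' comparable across fixed-effect structures. When a random intercept-plus-
#' slope term is singular or its correlation estimate is pinned at +-1, the
#' fit automatically falls back to a diagonal (uncorrelated) covariance and
#' records the fallback.
#'
#' With no random terms the model reduces to an ordinary GLM/LM fit.
#'
#' @param spec A [model_spec()].
#' @param data Model table containing the response, fixed-term columns and
#'   grouping columns.
#' @param response Response column name; defaults to the `response` attribute
#'   of `data`.
#' @return An object of class `fitted_glmm`: coefficients (estimate, SE),
#'   variance components, log-likelihood, parameter count `k` (fixed effects
#'   + variance/covariance parameters + residual variance for Gaussian),
#'   `n`, and `converged`/`singular`/`separation`/`fallback` flags.
#' @export
fit_glmm <- function(spec, data, response = attr(data, "response")) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(response)) stop("response column not specified", call. = FALSE)
  missing_cols <- setdiff(c(response, spec$fixed, names(spec$random)),
                          names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  use <- stats::complete.cases(data[, c(response, spec$fixed), drop = FALSE])
  dat <- data[use, , drop = FALSE]

  # grouping factors need >= 2 observed levels; drop degenerate random terms
  # (mirrors including random effects only "where necessary")
  dropped_random <- character()
  if (length(spec$random)) {
    nlev <- vapply(names(spec$random),
                   function(g) length(unique(dat[[g]][!is.na(dat[[g]])])),
                   integer(1))
    degenerate <- nlev < 2
    # a Bernoulli observation-level intercept (one row per level) is not
    # identifiable; include such factors only when birds repeat
    if (spec$family == "binomial_logit") {
      degenerate <- degenerate | nlev >= nrow(dat)
    }
    dropped_random <- names(spec$random)[degenerate]
    if (length(dropped_random)) {
      spec$random <- spec$random[!degenerate]
    }
  }

  fit_once <- function(diagonal_cov) {
    f <- .spec_formula(spec, response, diagonal_cov)
    warned <- character()
    fit <- withCallingHandlers({
      if (!length(spec$random)) {
        if (spec$family == "binomial_logit") {
          stats::glm(f, data = dat, family = stats::binomial())
        } else {
          stats::lm(f, data = dat)
        }
      } else if (spec$family == "binomial_logit") {
        lme4::glmer(f, data = dat, family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = TRUE,
                                                 check.conv.singular = "ignore"))
      } else {
        lme4::lmer(f, data = dat, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      }
    }, warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    list(fit = fit, warned = warned)
  }

  diagonal <- FALSE
  res <- fit_once(diagonal)
  is_mermod <- inherits(res$fit, "merMod")
  needs_fallback <- FALSE
  if (is_mermod && any(spec$random == "intercept_plus_geo_slope")) {
    vc <- lme4::VarCorr(res$fit)
    corr_pinned <- any(vapply(vc, function(v) {
      cr <- attr(v, "correlation")
      !is.null(cr) && nrow(cr) > 1 && any(abs(cr[lower.tri(cr)]) > 0.999)
    }, logical(1)))
    needs_fallback <- corr_pinned || lme4::isSingular(res$fit, tol = 1e-5)
  }
  if (needs_fallback) {
    diagonal <- TRUE
    res <- fit_once(diagonal)
    is_mermod <- inherits(res$fit, "merMod")
  }
  fit <- res$fit

  if (is_mermod) {
    co <- stats::coef(summary(fit))
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    nobs_ <- stats::nobs(fit)
    singular <- lme4::isSingular(fit, tol = 1e-5)
    conv_ok <- length(res$warned) == 0 &&
      (is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code == 0)
    vc <- as.data.frame(lme4::VarCorr(fit))
  } else {
    co <- stats::coef(summary(fit))
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    nobs_ <- stats::nobs(fit)
    singular <- FALSE
    conv_ok <- if (inherits(fit, "glm")) fit$converged else TRUE
    vc <- NULL
  }
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  separation <- spec$family == "binomial_logit" && any(abs(est) > 15)

  structure(list(
    spec = spec, response = response,
    coefficients = data.frame(term = rownames(co), estimate = unname(est),
                              se = unname(se), stringsAsFactors = FALSE),
    varcomp = vc, logLik = ll, k = as.integer(k), n = as.integer(nobs_),
    converged = conv_ok, singular = singular, separation = separation,
    fallback_diagonal = diagonal, dropped_random = dropped_random, fit = fit
  ), class = "fitted_glmm")
}

#' @export
print.fitted_glmm <- function(x, ...) {
  cat(sprintf("<fitted_glmm> %s, n = %d, k = %d, logLik = %.2f%s%s\n",
              x$spec$family, x$n, x$k, x$logLik,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$singular) ", singular" else ""))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict the expected rate for a covariate scenario
#'
#' Computes the expected response with all random effects set to zero and
#' fixed terms at the supplied scenario values (on the same, typically
#' standardized, scale used for fitting). For binomial models the inverse-
#' logit of the linear predictor is returned; for Gaussian models the linear
#' predictor itself.
#'
#' @param model A `fitted_glmm` or `averaged_model`.
#' @param scenario Named list/vector covering every non-intercept fixed term.
#' @return Expected probability (binomial) or mean response (Gaussian).
#' @export
predict_expected_rate <- function(model, scenario = list()) {
  if (inherits(model, "fitted_glmm")) {
    coefs <- model$coefficients
    fam <- model$spec$family
  } else if (inherits(model, "averaged_model")) {
    coefs <- model$coefficients[!is.na(model$coefficients$estimate), ]
    fam <- model$family
  } else stop("model must be a fitted_glmm or averaged_model", call. = FALSE)
  scenario <- as.list(scenario)
  eta <- 0
  for (i in seq_len(nrow(coefs))) {
    tm <- coefs$term[i]
    if (tm == "(Intercept)") { eta <- eta + coefs$estimate[i]; next }
    if (is.null(scenario[[tm]])) {
      stop("scenario is missing term '", tm, "'", call. = FALSE)
    }
    eta <- eta + coefs$estimate[i] * scenario[[tm]]
  }
  if (fam == "binomial_logit") stats::plogis(eta) else eta
}
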