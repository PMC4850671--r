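## Cross-taxon meta-analysis -------------------------------------------------

#' Transform a logit-scale coefficient to an effect-size z value
#'
#' Places taxon-specific tag coefficients on the scale used by the focused
#' contrast test. Three strategies are available:
#' \describe{
#'   \item{`identity`}{uses the coefficient itself (the default: the pooled
#'     coefficients are already standardized, mutually comparable effect
#'     sizes, and this strategy reproduces the reference study's contrast
#'     statistics).}
#'   \item{`borenstein_chain`}{log-odds to standardized difference
#'     (`d = beta * sqrt(3) / pi`), to correlation (`r = d / sqrt(d^2 + 4)`),
#'     to Fisher's z (`arctanh(r)`).}
#'   \item{`clipped_arctanh`}{`arctanh` of the coefficient clipped to
#'     (-0.99, 0.99).}
#' }
#'
#' @param beta Numeric vector of coefficients.
#' @param method Transform strategy.
#' @return Numeric vector of z values with attribute `strategy`.
#' @export
fisher_z_effect <- function(beta,
                            method = c("identity", "borenstein_chain",
                                       "clipped_arctanh")) {
  method <- match.arg(method)
  z <- switch(method,
    identity = beta,
    borenstein_chain = {
      d <- beta * sqrt(3) / pi
      atanh(d / sqrt(d^2 + 4))
    },
    clipped_arctanh = atanh(pmin(pmax(beta, -0.99), 0.99))
  )
  attr(z, "strategy") <- method
  z
}

#' Pooled mean tag effect with method-of-moments heterogeneity
#'
#' Pools taxon-specific tag coefficients into an overall mean `M` under a
#' random-effects model, with the between-taxon variance `tau^2` estimated by
#' the method of moments from the heterogeneity statistic `Q`.
#'
#' Under the default `weights = "n_captures"` each taxon is weighted by its
#' total number of capture events `N_i` (the weights play the role of
#' inverse within-taxon variances, `v_i = 1/N_i`): `M` is the
#' capture-count-weighted mean, `Q = sum(N_i (b_i - M)^2)`,
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and `SE_M`
#' is the random-effects standard error of the weighted mean,
#' `sqrt(sum(w^2 (tau^2 + v))) / sum(w)`. `I^2 = max(0, (Q - (k-1))/Q)` is
#' the proportion of total variance attributable to real between-taxon
#' differences.
#'
#' `weights = "inverse_variance"` instead runs the classic DerSimonian-Laird
#' estimator on the reported SEs (missing SEs are imputed as the median
#' squared SE of reported taxa and flagged), recombining with
#' `w* = 1/(tau^2 + se^2)`.
#'
#' @param effects Effect-record data frame with columns `beta_geo`, `N_i`
#'   and (for the inverse-variance option) `se_geo`.
#' @param weights Weighting scheme (see Details).
#' @return Object of class `meta_pooled`: `M`, `SE_M`, `tau2`, `Q`, `I2`,
#'   `k`, `weights`, and `n_se_imputed`.
#' @export
pooled_mean_mom <- function(effects, weights = c("n_captures",
                                                 "inverse_variance")) {
  weights <- match.arg(weights)
  b <- effects$beta_geo
  N <- effects$N_i
  k <- length(b)
  if (k < 2) stop("at least 2 effects are required", call. = FALSE)
  if (any(is.na(N)) || any(N <= 0)) stop("N_i must be positive", call. = FALSE)
  df <- k - 1
  n_imputed <- 0L
  if (weights == "n_captures") {
    w <- N
    v <- 1 / N
    M_fix <- sum(w * b) / sum(w)
    Q <- sum(w * (b - M_fix)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    M <- M_fix
    SE <- sqrt(sum(w^2 * (tau2 + v))) / sum(w)
  } else {
    v <- effects$se_geo^2
    if (all(is.na(v))) {
      warning("all SEs missing; falling back to capture-count weighting")
      return(pooled_mean_mom(effects, weights = "n_captures"))
    }
    n_imputed <- sum(is.na(v))
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    w <- 1 / v
    M_fix <- sum(w * b) / sum(w)
    Q <- sum(w * (b - M_fix)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    wre <- 1 / (tau2 + v)
    M <- sum(wre * b) / sum(wre)
    SE <- 1 / sqrt(sum(wre))
  }
  I2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  structure(list(M = M, SE_M = SE, tau2 = tau2, Q = Q, I2 = I2, k = k,
                 weights = weights, n_se_imputed = n_imputed),
            class = "meta_pooled")
}

#' @export
print.meta_pooled <- function(x, ...) {
  cat(sprintf(paste0("<meta_pooled> k = %d (%s weights)\n",
                     "  M = %.3f (SE %.3f), tau2 = %.3f, Q = %.1f, ",
                     "I2 = %.1f%%\n"),
              x$k, x$weights, x$M, x$SE_M, x$tau2, x$Q, 100 * x$I2))
  invisible(x)
}

#' Focused contrast test for a meta-analytic moderator
#'
#' Tests whether taxon-specific tag effects vary linearly with a moderator
#' using zero-sum contrast weights. Effects are placed on the z scale by
#' [fisher_z_effect()]; the contrast weight for taxon `i` is the centred
#' moderator `lambda_i = x_i - mean(x)`; the within-taxon weight is
#' `w_i = N_i - 3`; and the statistic
#' `X = sum(lambda_i z_i) / sqrt(sum(lambda_i^2 / w_i))`
#' is referred to a standard normal distribution. Because the contrasts are
#' centred, adding a constant to the moderator leaves `X` unchanged.
#'
#' @param effects Effect-record data frame (`beta_geo`, `N_i`).
#' @param moderator Numeric moderator, one value per taxon.
#' @param z_transform Strategy passed to [fisher_z_effect()].
#' @param center `"unweighted"` (default) or `"weighted"` (centre the
#'   moderator at its `N_i - 3`-weighted mean).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param alpha Significance level after Bonferroni correction for testing
#'   two moderators (default 0.025).
#' @return Object of class `meta_contrast`: `X`, `p`, `significant`,
#'   `strategy`, `alternative`, `k`.
#' @export
contrast_test <- function(effects, moderator,
                          z_transform = c("identity", "borenstein_chain",
                                          "clipped_arctanh"),
                          center = c("unweighted", "weighted"),
                          alternative = c("two.sided", "less", "greater"),
                          alpha = 0.025) {
  z_transform <- match.arg(z_transform)
  center <- match.arg(center)
  alternative <- match.arg(alternative)
  if (length(moderator) != nrow(effects) || any(is.na(moderator))) {
    stop("moderator must be known for every taxon", call. = FALSE)
  }
  z <- fisher_z_effect(effects$beta_geo, method = z_transform)
  w <- effects$N_i - 3
  if (any(w <= 0)) stop("N_i must exceed 3 for the contrast test", call. = FALSE)
  ctr <- if (center == "unweighted") mean(moderator) else
    sum(w * moderator) / sum(w)
  lam <- moderator - ctr
  if (all(abs(lam) < 1e-12)) {
    stop("constant moderator: contrast weights are all zero", call. = FALSE)
  }
  X <- sum(lam * z) / sqrt(sum(lam^2 / w))
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(X)),
    less = stats::pnorm(X),
    greater = stats::pnorm(X, lower.tail = FALSE))
  structure(list(X = X, p = p, significant = p < alpha, alpha = alpha,
                 strategy = z_transform, alternative = alternative,
                 k = nrow(effects)), class = "meta_contrast")
}

#' @export
print.meta_contrast <- function(x, ...) {
  cat(sprintf("<meta_contrast> X = %.2f, p = %.3g (%s, z: %s)%s\n",
              x$X, x$p, x$alternative, x$strategy,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Weighted least-squares moderator regression and zero-crossing threshold
#'
#' Regresses raw taxon coefficients on a moderator, weighting each taxon by
#' its total captures `N_i`, and reports where the fitted line crosses zero
#' (the moderator value beyond which tag effects are expected to turn
#' negative), on the moderator's native scale.
#'
#' @param effects Effect-record data frame (`beta_geo`, `N_i`).
#' @param moderator Numeric moderator, one value per taxon.
#' @return Object of class `meta_wls`: `intercept`, `se_intercept`, `slope`,
#'   `se_slope`, `p_slope`, `threshold` (`-intercept/slope`, `NA` when the
#'   slope is numerically zero), `k`.
#' @export
wls_threshold <- function(effects, moderator) {
  if (nrow(effects) < 3) stop("at least 3 taxa are required", call. = FALSE)
  if (length(moderator) != nrow(effects) || any(is.na(moderator))) {
    stop("moderator must be known for every taxon", call. = FALSE)
  }
  fit <- stats::lm(effects$beta_geo ~ moderator, weights = effects$N_i)
  sm <- stats::coef(summary(fit))
  b0 <- sm[1, 1]; b1 <- sm[2, 1]
  thr <- if (abs(b1) < 1e-12) NA_real_ else -b0 / b1
  structure(list(intercept = b0, se_intercept = sm[1, 2],
                 slope = b1, se_slope = sm[2, 2], p_slope = sm[2, 4],
                 threshold = thr, k = nrow(effects), fit = fit),
            class = "meta_wls")
}

#' @export
print.meta_wls <- function(x, ...) {
  cat(sprintf(paste0("<meta_wls> intercept = %.3f (SE %.3f), slope = %.3f ",
                     "(SE %.3f, p = %.3g), zero crossing at %.2f\n"),
              x$intercept, x$se_intercept, x$slope, x$se_slope, x$p_slope,
              x$threshold))
  invisible(x)
}

#' Full cross-taxon meta-analysis of tag effects
#'
#' Convenience wrapper running [pooled_mean_mom()] plus, for each supplied
#' moderator, [contrast_test()] and [wls_threshold()], with a Bonferroni-
#' corrected significance level shared across moderators.
#'
#' @param effects Effect-record data frame with `beta_geo`, `N_i` (e.g. from
#'   [load_study_tables()] or [simulate_effect_table()]).
#' @param moderators Named list of numeric moderator vectors.
#' @param z_transform,weights Passed through to the component functions.
#' @param alpha Family significance level (default 0.05, split across
#'   moderators).
#' @return Object of class `meta_result` with elements `pooled`, `contrasts`,
#'   `wls`, `config`.
#' @export
meta_analysis <- function(effects, moderators = list(),
                          z_transform = "identity",
                          weights = "n_captures", alpha = 0.05) {
  pooled <- pooled_mean_mom(effects, weights = weights)
  a <- if (length(moderators)) alpha / length(moderators) else alpha
  contrasts <- lapply(moderators, function(m) {
    contrast_test(effects, m, z_transform = z_transform, alpha = a)
  })
  wls <- lapply(moderators, function(m) wls_threshold(effects, m))
  structure(list(pooled = pooled, contrasts = contrasts, wls = wls,
                 config = list(z_transform = z_transform, weights = weights,
                               alpha_per_moderator = a)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  print(x$pooled)
  for (nm in names(x$contrasts)) {
    cat(nm, ": ")
    print(x$contrasts[[nm]])
    cat(nm, ": ")
    print(x$wls[[nm]])
  }
  invisible(x)
}
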