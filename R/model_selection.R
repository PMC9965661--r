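#' Extra-sum-of-squares F-test between nested kinetic fits
#'
#' Compares a simpler and a more complex nested model fitted to the same
#' data: `F = ((rss_s - rss_c) / (df_s - df_c)) / (rss_c / df_c)`, with the
#' p-value from the F distribution on `(df_s - df_c, df_c)` degrees of
#' freedom. A low p-value favours the complex model. When the complex model
#' fits no better (within numerical tolerance of the optimiser), F is
#' clamped to 0 and p to 1.
#'
#' @param simple,complex [fit_kinetics()] results on the same data, with
#'   `simple` having fewer parameters.
#' @return One-row tibble: `f_stat`, `df1`, `df2`, `p_value`.
#' @export
f_test <- function(simple, complex) {
  check_nested(simple, complex)
  if (complex$df < 1) abort_validation("complex model has no residual degrees of freedom")
  rss_s <- simple$rss
  rss_c <- effective_rss_c(rss_s, complex$rss)
  df1 <- simple$df - complex$df
  df2 <- complex$df
  f_stat <- ((rss_s - rss_c) / df1) / (rss_c / df2)
  tibble(f_stat = f_stat, df1 = df1, df2 = df2,
         p_value = pf(f_stat, df1, df2, lower.tail = FALSE))
}

check_nested <- function(simple, complex) {
  stopifnot(inherits(simple, "kinetic_fit"), inherits(complex, "kinetic_fit"))
  if (simple$refused || complex$refused) {
    abort_validation("cannot compare refused fits")
  }
  if (simple$model$n_params >= complex$model$n_params) {
    abort_validation("`simple` must have fewer parameters than `complex`")
  }
  if (simple$n_obs != complex$n_obs) {
    abort_validation("fits being compared must use the same data")
  }
}

# complex RSS used in comparisons: improvements smaller than numerical
# tolerance (or negative, from optimizer noise) count as no improvement
effective_rss_c <- function(rss_s, rss_c) {
  if (rss_s - rss_c < 1e-10 * max(1, rss_s)) rss_s else rss_c
}

#' Small-sample Akaike information criterion of a kinetic fit
#'
#' `AICc = n log(rss/n) + 2K + 2K(K+1)/(n-K-1)` with `K = n_params + 1`
#' (the error variance counts as a parameter). `variant = "aic"` drops the
#' small-sample correction term. The RSS is floored at 1e-12 so that
#' noiseless (machine-zero residual) fits remain comparable.
#'
#' @param fit A [fit_kinetics()] result.
#' @param variant `"aicc"` (default) or `"aic"`.
#' @return Scalar criterion value (lower is better).
#' @export
aicc <- function(fit, variant = c("aicc", "aic")) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "kinetic_fit"))
  if (fit$refused) abort_validation("no information criterion for a refused fit")
  aicc_value(fit$rss, fit$n_obs, fit$model$n_params, variant)
}

aicc_value <- function(rss, n, n_params, variant) {
  k <- n_params + 1
  if (variant == "aicc" && n - k - 1 <= 0) {
    abort_validation("too few observations for the small-sample AIC correction")
  }
  out <- n * log(max(rss, 1e-12) / n) + 2 * k
  if (variant == "aicc") out <- out + 2 * k * (k + 1) / (n - k - 1)
  out
}

#' AICc difference between nested kinetic fits
#'
#' `delta = AICc(simple) - AICc(complex)`: a positive value prefers the
#' complex model, a negative one the simpler model (the sign convention of
#' the information-criterion comparison in nested curve fitting). The same
#' numerical-tolerance rule as [f_test()] applies: a complex RSS that is
#' not meaningfully smaller is treated as equal to the simple RSS, so only
#' the parameter penalty differs.
#'
#' @inheritParams f_test
#' @param variant `"aicc"` (default) or `"aic"`.
#' @return Scalar `delta_aicc`.
#' @export
aicc_compare <- function(simple, complex, variant = c("aicc", "aic")) {
  variant <- match.arg(variant)
  check_nested(simple, complex)
  rss_c <- effective_rss_c(simple$rss, complex$rss)
  aicc_value(simple$rss, simple$n_obs, simple$model$n_params, variant) -
    aicc_value(rss_c, complex$n_obs, complex$model$n_params, variant)
}

#' Compare two nested kinetic fits
#'
#' Runs both the extra-sum-of-squares F-test and the (small-sample) AIC
#' comparison. The complex model is preferred only when both agree: the
#' F-test p-value is below `alpha` and the AICc difference is positive.
#'
#' @inheritParams f_test
#' @param alpha Significance level for the F-test (default 0.05).
#' @param variant Information-criterion variant, see [aicc()].
#' @return One-row tibble with the fit forms, `f_stat`, `p_value`,
#'   `delta_aicc` and `preferred` (`"simple"` or `"complex"`).
#' @export
compare_models <- function(simple, complex, alpha = 0.05,
                           variant = c("aicc", "aic")) {
  variant <- match.arg(variant)
  ft <- f_test(simple, complex)
  delta <- aicc_compare(simple, complex, variant)
  tibble(
    simple = simple$model$form, complex = complex$model$form,
    f_stat = ft$f_stat, df1 = ft$df1, df2 = ft$df2, p_value = ft$p_value,
    delta_aicc = delta,
    preferred = ifelse(ft$p_value < alpha & delta > 0, "complex", "simple")
  )
}

#' Fit and select among the nested kinetic models
#'
#' Fits the fixed-slope, variable-slope and asymmetric logistic models and
#' steps up from simple to complex only when the F-test is significant
#' (`p < alpha`), the AICc difference favours the complex model, *and*
#' every parameter the complex model adds has a calculable, finite
#' confidence interval. The identifiability clause matters in practice: the
#' asymmetry parameter often improves the residual sum of squares
#' significantly while its own confidence interval is unbounded, in which
#' case the asymmetric model is rejected and the variable-slope model kept.
#'
#' @inheritParams fit_kinetics
#' @param alpha F-test significance level (default 0.05).
#' @param variant Information-criterion variant, see [aicc()].
#' @return The selected `kinetic_fit`, with attributes `selection` (tibble
#'   of pairwise comparisons) and `candidates` (named list of all fits).
#'   If only the fixed-slope model converges it is returned with a warning.
#'   If the series has no signal, the refused variable-slope fit is
#'   returned.
#' @export
select_model <- function(data, alpha = 0.05, variant = c("aicc", "aic"),
                         bod = NULL) {
  variant <- match.arg(variant)
  fits <- list(
    fixed_slope = try_fit(data, "fixed_slope", bod),
    variable_slope = try_fit(data, "variable_slope", bod),
    asymmetric = try_fit(data, "asymmetric", bod)
  )
  usable <- function(f) !is.null(f) && !f$refused
  if (!usable(fits$fixed_slope)) {
    # no signal at all: return the (refused) variable-slope fit so callers
    # still get a BOD_L point estimate and n.c. flags
    ref <- fits$variable_slope %||% fits$fixed_slope
    if (is.null(ref)) abort_validation("series cannot be fitted by any model form")
    attr(ref, "selection") <- tibble()
    attr(ref, "candidates") <- fits
    return(ref)
  }

  comparisons <- list()
  current <- fits$fixed_slope
  step_up <- function(current, candidate, new_pars) {
    if (!usable(candidate)) return(list(fit = current, cmp = NULL))
    cmp <- compare_models(current, candidate, alpha, variant)
    identifiable <- all(candidate$ci_calculable[new_pars])
    cmp$new_params_identifiable <- identifiable
    cmp$stepped <- cmp$preferred == "complex" && identifiable
    list(fit = if (cmp$stepped) candidate else current, cmp = cmp)
  }

  st <- step_up(current, fits$variable_slope, "b")
  comparisons <- c(comparisons, list(st$cmp))
  current <- st$fit
  st <- step_up(current, fits$asymmetric, "s")
  comparisons <- c(comparisons, list(st$cmp))
  current <- st$fit

  if (identical(current$model$form, "fixed_slope") &&
      !usable(fits$variable_slope)) {
    warn("only the fixed-slope model converged; returning it")
  }
  attr(current, "selection") <- dplyr::bind_rows(purrr::compact(comparisons))
  attr(current, "candidates") <- fits
  current
}

try_fit <- function(data, form, bod) {
  tryCatch(fit_kinetics(data, form, bod = bod), error = function(e) NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
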