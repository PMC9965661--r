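#' The logistic biodegradation-kinetics model family
#'
#' Three nested forms describe cumulative BOD `Y` (mg O2/L) as a function
#' of incubation time `X` (days):
#'
#' * `variable_slope` (3 parameters):
#'   `Y = BOD_L / (1 + (a/X)^b)` — equivalently
#'   `BOD_L / (1 + 10^((log10 a - log10 X) * b))`.
#' * `fixed_slope` (2 parameters): the same with slope `b = 1`.
#' * `asymmetric` (4 parameters):
#'   `Y = BOD_L / (1 + (2^(1/S) - 1) * (a/X)^b)^S`, which reduces to the
#'   variable-slope form at `S = 1`.
#'
#' `BOD_L` is the ultimate BOD (the asymptote, a time-independent measure
#' of ultimate biodegradability), `a` the half-degradation time (every form
#' passes through `BOD_L/2` at `X = a`), `b` the slope (biodegradation-rate
#' proxy) and `S` the degree of asymmetry. All parameters are positive.
#'
#' @param form One of `"variable_slope"`, `"fixed_slope"`, `"asymmetric"`.
#' @return A list with `form`, `n_params` and `par_names`.
#' @export
kinetic_model <- function(form = c("variable_slope", "fixed_slope", "asymmetric")) {
  form <- match.arg(form)
  par_names <- switch(form,
    fixed_slope = c("bod_l", "a"),
    variable_slope = c("bod_l", "a", "b"),
    asymmetric = c("bod_l", "a", "b", "s")
  )
  structure(list(form = form, n_params = length(par_names),
                 par_names = par_names),
            class = "kinetic_model")
}

#' Evaluate a kinetic model curve
#'
#' Vectorised in `x`. The value at `x = 0` is 0, the continuous limit of
#' every form for `b > 0`.
#'
#' @param x Days, non-negative.
#' @param bod_l Ultimate BOD (mg O2/L), positive.
#' @param a Half-degradation time (days), positive.
#' @param b Slope, positive (forced to 1 for `form = "fixed_slope"`).
#' @param s Asymmetry, positive (used only for `form = "asymmetric"`).
#' @param form Model form, see [kinetic_model()].
#' @return BOD values (mg O2/L), same length as `x`.
#' @export
#' @examples
#' model_value(10, bod_l = 22.2, a = 10, b = 1.4) # half of 22.2
model_value <- function(x, bod_l, a, b = 1, s = 1,
                        form = c("variable_slope", "fixed_slope", "asymmetric")) {
  form <- match.arg(form)
  if (form == "fixed_slope") b <- 1
  if (any(x < 0)) abort_validation("time must be non-negative")
  if (bod_l <= 0 || a <= 0 || b <= 0 || (form == "asymmetric" && s <= 0)) {
    abort_validation("kinetic parameters must be positive")
  }
  y <- numeric(length(x))
  pos <- x > 0
  r <- (a / x[pos])^b
  y[pos] <- if (form == "asymmetric") {
    bod_l / (1 + (2^(1 / s) - 1) * r)^s
  } else {
    bod_l / (1 + r)
  }
  y
}

model_fun <- function(form) {
  switch(form,
    fixed_slope = function(x, p) model_value(x, p[["bod_l"]], p[["a"]], form = "fixed_slope"),
    variable_slope = function(x, p) model_value(x, p[["bod_l"]], p[["a"]], p[["b"]]),
    asymmetric = function(x, p) model_value(x, p[["bod_l"]], p[["a"]], p[["b"]], p[["s"]],
                                            form = "asymmetric")
  )
}

# deterministic data-driven starts: asymptote a bit above the observed
# maximum; half-degradation time where the series first crosses half max
# (linear interpolation); b and s at their nesting-neutral values
start_values <- function(day, bod, model) {
  ord <- order(day)
  d <- day[ord]; y <- bod[ord]
  ymax <- max(y)
  bod_l0 <- 1.1 * ymax
  half <- ymax / 2
  above <- which(y >= half & d > 0)
  if (length(above) == 0) {
    a0 <- max(d)
  } else {
    i <- above[1]
    if (i == 1 || y[i] == half || y[i] == y[i - 1]) {
      a0 <- d[i]
    } else {
      a0 <- d[i - 1] + (half - y[i - 1]) * (d[i] - d[i - 1]) / (y[i] - y[i - 1])
    }
    a0 <- max(a0, min(d[d > 0]))
  }
  p <- c(bod_l = bod_l0, a = a0, b = 1, s = 1)
  p[model$par_names]
}

param_bounds <- function(day, bod, model) {
  upper <- c(bod_l = 10 * max(bod), a = 10 * max(day), b = 20, s = 100)
  lower <- c(bod_l = 1e-8, a = 1e-8, b = 1e-8, s = 0.01)
  list(lower = lower[model$par_names], upper = upper[model$par_names])
}

pick_bod_column <- function(data, bod) {
  if (!is.null(bod)) return(bod)
  cand <- intersect(c("bod", "bod_corrected", "bod_mg_l"), names(data))
  if (length(cand) == 0) {
    abort_format("no BOD column found (expected one of bod, bod_corrected, bod_mg_l)")
  }
  cand[1]
}

#' Fit a kinetic model to a corrected BOD series
#'
#' Bound-constrained nonlinear least squares (Levenberg-Marquardt) over all
#' per-replicate points, unweighted. Confidence intervals are asymptotic
#' (Wald): `estimate +/- t(0.975, df) * SE` with `SE` from
#' `s^2 (J'J)^-1`; a parameter whose covariance entry is singular or
#' non-finite is flagged not calculable.
#'
#' A series whose corrected BOD never rises above zero carries no kinetic
#' signal: the fit is refused and a not-calculable result is returned whose
#' `bod_l` point estimate is the mean of the observations at the last three
#' time points (the conventional fallback for flat negative controls).
#'
#' @param data Data frame with a `day` column and a BOD column (`bod`,
#'   `bod_corrected` or `bod_mg_l`; pass per-replicate corrected values,
#'   e.g. one material's rows from [blank_correct()]).
#' @param form Model form, see [kinetic_model()].
#' @param bod Optional name of the BOD column, overriding auto-detection.
#' @return An object of class `kinetic_fit` with methods [tidy()],
#'   [glance()], [predict()][predict.kinetic_fit], [autoplot()] and
#'   [half_degradation_time()].
#' @export
fit_kinetics <- function(data, form = c("variable_slope", "fixed_slope", "asymmetric"),
                         bod = NULL) {
  model <- kinetic_model(match.arg(form))
  data <- as_tibble(data)
  if (!"day" %in% names(data)) abort_format("no `day` column in data")
  bod_col <- pick_bod_column(data, bod)
  day <- as.numeric(data[["day"]])
  y <- as.numeric(data[[bod_col]])
  keep <- is.finite(day) & is.finite(y)
  day <- day[keep]; y <- y[keep]
  n <- length(y)
  if (sum(day > 0) < model$n_params + 1) {
    abort_validation(paste0("need at least ", model$n_params + 1,
                            " observations at positive time to fit ", model$form))
  }

  if (max(y) <= 0) {
    return(refused_fit(model, day, y, bod_col))
  }

  f <- model_fun(model$form)
  start <- start_values(day, y, model)
  bounds <- param_bounds(day, y, model)
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = bounds$lower, upper = bounds$upper,
      fn = function(p) y - f(day, setNames(p, model$par_names)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(res)) return(refused_fit(model, day, y, bod_col))

  est <- setNames(as.numeric(res$par), model$par_names)
  rss <- sum(res$fvec^2)
  df <- n - model$n_params
  sigma2 <- rss / df
  # asymptotic covariance from the final-iterate J'J
  vcov_ok <- FALSE
  se <- setNames(rep(NA_real_, model$n_params), model$par_names)
  jtj <- as.matrix(res$hessian)  # Gauss-Newton J'J at the optimum
  cv <- tryCatch(solve(jtj) * sigma2, error = function(e) NULL)
  if (!is.null(cv)) {
    dg <- diag(cv)
    se <- setNames(ifelse(is.finite(dg) & dg >= 0, sqrt(pmax(dg, 0)), NA_real_),
                   model$par_names)
    vcov_ok <- TRUE
  }
  tq <- qt(0.975, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  ci_calc <- is.finite(se) & is.finite(ci[, 1]) & is.finite(ci[, 2])

  structure(
    list(model = model, coef = est, se = se, ci = ci,
         ci_calculable = setNames(as.logical(ci_calc), model$par_names),
         rss = rss, sigma = sqrt(sigma2), n_obs = n, df = df,
         converged = res$info %in% 1:4, refused = FALSE,
         data = tibble(day = day, bod = y), bod_col = bod_col),
    class = "kinetic_fit"
  )
}

refused_fit <- function(model, day, y, bod_col) {
  last3 <- sort(unique(day), decreasing = TRUE)[1:min(3, length(unique(day)))]
  bod_l_pt <- mean(y[day %in% last3])
  est <- setNames(rep(NA_real_, model$n_params), model$par_names)
  est["bod_l"] <- bod_l_pt
  ci <- cbind(lower = rep(NA_real_, model$n_params),
              upper = rep(NA_real_, model$n_params))
  rownames(ci) <- model$par_names
  structure(
    list(model = model, coef = est,
         se = setNames(rep(NA_real_, model$n_params), model$par_names),
         ci = ci,
         ci_calculable = setNames(rep(FALSE, model$n_params), model$par_names),
         rss = NA_real_, sigma = NA_real_, n_obs = length(y),
         df = length(y) - model$n_params,
         converged = FALSE, refused = TRUE,
         data = tibble(day = day, bod = y), bod_col = bod_col),
    class = "kinetic_fit"
  )
}

#' Half-degradation time of a fitted curve
#'
#' The time at which the fitted curve reaches half its asymptote; for every
#' form in the family this is the `a` parameter itself.
#'
#' @param fit A [fit_kinetics()] result.
#' @return Days (scalar); `NA` for a refused fit.
#' @export
half_degradation_time <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  unname(fit$coef["a"])
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  if (object$refused) {
    abort_validation("cannot predict from a refused (not calculable) fit")
  }
  day <- if (is.null(newdata)) object$data$day else {
    if (is.data.frame(newdata)) as.numeric(newdata$day) else as.numeric(newdata)
  }
  model_fun(object$model$form)(day, object$coef)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", x$model$form, "\n")
  if (x$refused) {
    cat("  fit refused (no signal above zero); BOD_L point estimate",
        format(x$coef[["bod_l"]], digits = 3), "(n.c.)\n")
    return(invisible(x))
  }
  for (p in x$model$par_names) {
    ci_txt <- if (x$ci_calculable[[p]]) {
      sprintf("(%.3g, %.3g)", x$ci[p, "lower"], x$ci[p, "upper"])
    } else "(n.c.)"
    cat(sprintf("  %-6s %8.4g %s\n", p, x$coef[[p]], ci_txt))
  }
  cat(sprintf("  rss %.4g on %d df (n = %d)\n", x$rss, x$df, x$n_obs))
  invisible(x)
}

#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    term = x$model$par_names,
    estimate = unname(x$coef),
    std.error = unname(x$se),
    conf.low = unname(x$ci[, "lower"]),
    conf.high = unname(x$ci[, "upper"]),
    ci_calculable = unname(x$ci_calculable)
  )
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    form = x$model$form, n_params = x$model$n_params,
    rss = x$rss, sigma = x$sigma, n_obs = x$n_obs, df = x$df,
    converged = x$converged, refused = x$refused
  )
}
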