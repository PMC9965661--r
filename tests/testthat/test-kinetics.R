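test_that("all model forms pass through half the asymptote at x = a", {
  set.seed(11)
  for (i in 1:20) {
    bod_l <- runif(1, 1, 200); a <- runif(1, 1, 25)
    b <- runif(1, 0.2, 5); s <- runif(1, 0.2, 5)
    expect_equal(model_value(a, bod_l, a, form = "fixed_slope"), bod_l / 2)
    expect_equal(model_value(a, bod_l, a, b), bod_l / 2)
    expect_equal(model_value(a, bod_l, a, b, s, form = "asymmetric"), bod_l / 2)
  }
})

test_that("model nesting identities hold at b = 1 and S = 1", {
  x <- c(0, 0.5, 1, 5, 10, 28, 100)
  expect_equal(model_value(x, 50, 8, b = 1),
               model_value(x, 50, 8, form = "fixed_slope"))
  expect_equal(model_value(x, 50, 8, b = 1.7, s = 1, form = "asymmetric"),
               model_value(x, 50, 8, b = 1.7))
})

test_that("curves start at zero, increase monotonically, approach the asymptote", {
  expect_equal(model_value(0, 22.2, 10, 1.4), 0)
  set.seed(22)
  for (i in 1:20) {
    bod_l <- runif(1, 1, 100); a <- runif(1, 1, 20); b <- runif(1, 0.2, 6)
    x <- sort(runif(50, 0.01, 50))
    y <- model_value(x, bod_l, a, b)
    expect_true(all(diff(y) > 0))
    expect_true(all(y < bod_l))
  }
  # asymptote: published curve parameters approach BOD_L at large time
  expect_equal(model_value(1e4, 22.2, 10, 1.4), 22.2, tolerance = 1e-3)
})

test_that("invalid model inputs are rejected", {
  expect_error(model_value(-1, 10, 5, 1), class = "marbod_validation_error")
  expect_error(model_value(1, -10, 5, 1), class = "marbod_validation_error")
  expect_error(model_value(1, 10, 5, 0), class = "marbod_validation_error")
})

test_that("noiseless data are recovered exactly by their own model form", {
  cases <- list(
    list(form = "fixed_slope", bod_l = 30, a = 8, b = 1, s = NA),
    list(form = "variable_slope", bod_l = 22.2, a = 10, b = 1.4, s = NA),
    list(form = "asymmetric", bod_l = 60, a = 12, b = 1.8, s = 2.5)
  )
  for (cs in cases) {
    d <- noiseless_series(cs$bod_l, cs$a, cs$b, cs$s)
    fit <- fit_kinetics(d, cs$form)
    expect_lt(fit$rss, 1e-8)
    expect_rel_error(fit$coef[["bod_l"]], cs$bod_l, 1e-4)
    expect_rel_error(fit$coef[["a"]], cs$a, 1e-4)
    if (cs$form != "fixed_slope") expect_rel_error(fit$coef[["b"]], cs$b, 1e-4)
    if (cs$form == "asymmetric") expect_rel_error(fit$coef[["s"]], cs$s, 1e-3)
  }
})

test_that("half-degradation time is where the curve crosses half the asymptote", {
  d <- noiseless_series(22.2, 10, 1.4)
  fit <- fit_kinetics(d)
  a_hat <- half_degradation_time(fit)
  expect_equal(predict(fit, a_hat), fit$coef[["bod_l"]] / 2, tolerance = 1e-8)
})

test_that("rescaling time doubles a and leaves b unchanged", {
  d <- noiseless_series(22.2, 10, 1.4)
  d2 <- dplyr::mutate(d, day = 2 * day)
  f1 <- fit_kinetics(d)
  f2 <- fit_kinetics(d2)
  expect_equal(half_degradation_time(f2), 2 * half_degradation_time(f1),
               tolerance = 1e-4)
  expect_equal(f2$coef[["b"]], f1$coef[["b"]], tolerance = 1e-4)
})

test_that("a signal-free series is refused with a last-readings BOD_L estimate", {
  d <- tibble::tibble(day = 1:28, bod = rep(0, 28))
  fit <- fit_kinetics(d)
  expect_true(fit$refused)
  expect_equal(fit$coef[["bod_l"]], 0)
  expect_false(any(fit$ci_calculable))
  neg <- tibble::tibble(day = 1:28, bod = seq(-0.1, -2.8, length.out = 28))
  fit2 <- fit_kinetics(neg)
  expect_true(fit2$refused)
  expect_equal(fit2$coef[["bod_l"]], mean(neg$bod[26:28]))
  expect_error(predict(fit2, 10), class = "marbod_validation_error")
})

test_that("too-short series are rejected", {
  d <- tibble::tibble(day = 1:3, bod = model_value(1:3, 20, 10, 1.4))
  expect_error(fit_kinetics(d, "variable_slope"),
               class = "marbod_validation_error")
})

test_that("optimizer matches a grid-search oracle on a five-point dataset", {
  set.seed(33)
  d <- tibble::tibble(day = c(3, 7, 14, 21, 28))
  d$bod <- model_value(d$day, 40, 9, 1.6) + c(0.8, -0.5, 0.3, -0.7, 0.4)
  fit <- fit_kinetics(d, "variable_slope")
  grid <- expand.grid(bod_l = seq(30, 60, length.out = 60),
                      a = seq(4, 16, length.out = 60),
                      b = seq(0.5, 3, length.out = 60))
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    sum((d$bod - model_value(d$day, grid$bod_l[i], grid$a[i], grid$b[i]))^2)
  }, numeric(1))
  best <- min(rss_grid)
  expect_lte(fit$rss, best + 1e-9)          # optimizer at least as good
  expect_lt(best - fit$rss, 0.05 * max(fit$rss, 0.1))  # lattice confirms optimum
})

test_that("parameter recovery: median BOD_L error under 5% noise is below 5%", {
  truth <- list(bod_l = 22.2, a = 10, b = 1.4)
  sd <- 0.05 * truth$bod_l
  set.seed(101)
  errs <- replicate(200, {
    d <- tibble::tibble(
      day = rep(1:28, 2),
      bod = model_value(rep(1:28, 2), truth$bod_l, truth$a, truth$b) +
        rnorm(56, 0, sd)
    )
    fit <- fit_kinetics(d)
    abs(fit$coef[["bod_l"]] - truth$bod_l) / truth$bod_l
  })
  expect_lt(median(errs), 0.05)
})

test_that("Wald intervals bracket the estimate and SEs match an independent fit", {
  set.seed(55)
  d <- tibble::tibble(day = rep(1:28, 2),
                      bod = model_value(rep(1:28, 2), 22.2, 10, 1.4) +
                        rnorm(56, 0, 1))
  fit <- fit_kinetics(d)
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  # independent route: nls() with the port algorithm on the same data
  ref <- nls(bod ~ bl / (1 + (a / day)^b), data = d,
             start = list(bl = 25, a = 8, b = 1), algorithm = "port",
             lower = c(1e-8, 1e-8, 1e-8))
  expect_equal(unname(fit$coef), unname(coef(ref)[c("bl", "a", "b")]),
               tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[c("bl", "a", "b"), "Std. Error"]),
               tolerance = 1e-3)
})

test_that("tidy and glance expose the fit in rectangular form", {
  fit <- fit_kinetics(noiseless_series(22.2, 10, 1.4))
  td <- tidy(fit)
  expect_equal(td$term, c("bod_l", "a", "b"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 28)
  expect_equal(gl$df, 25)
  expect_false(gl$refused)
})
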