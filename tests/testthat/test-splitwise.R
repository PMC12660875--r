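test_that("partial residuals follow the leave-one-term-out definition", {
  d <- make_toy(n = 50, seed = 61)
  m <- splitwise(y ~ ., d, mode = "iterative", direction = "both",
                 min_improvement = Inf)
  # in-model predictor: residuals + fitted contribution == residuals of the
  # refit on the remaining terms' column space is not required, but the
  # additive identity is
  sel <- selected_predictors(m)
  expect_true("x1" %in% sel)
  pr <- partial_residuals(m, "x1")
  expect_equal(pr, residuals(m) + coef(m)[["x1"]] * d$x1)
  # predictor absent from the model: equal to plain residuals
  out <- setdiff(names(m$encodings), sel)
  if (length(out)) {
    expect_equal(partial_residuals(m, out[1]), residuals(m))
  }
  expect_error(partial_residuals(m, "nope"), "unknown predictor")
})

test_that("intercept-only models give centered response as partial residuals", {
  set.seed(62)
  n <- 40
  y <- rnorm(n)
  d <- data.frame(y = y, a = stats::resid(stats::lm(rnorm(n) ~ y)))
  m <- splitwise(y ~ a, d, mode = "iterative", direction = "forward",
                 criterion = "BIC", min_improvement = Inf)
  expect_identical(m$selected, character(0))
  expect_equal(partial_residuals(m, "a"), y - mean(y))
})

test_that("univariate screening discards noise, keeps linear truth linear, finds step thresholds", {
  set.seed(63)
  n <- 500
  x <- rnorm(n)
  # pure noise with exactly zero sample correlation to the response
  y0 <- rnorm(n)
  noise <- stats::resid(stats::lm(rnorm(n) ~ y0))
  ds <- sw_dataset(y0, data.frame(a = noise))
  enc <- univariate_transform(ds, splitwise_config(mode = "univariate",
                                                   min_improvement = 5))
  expect_identical(enc$a$kind, "excluded")

  # linear truth: split forms cannot beat the linear term by min_improvement
  y_lin <- 2 * x + rnorm(n)
  enc <- univariate_transform(sw_dataset(y_lin, data.frame(x = x)),
                              splitwise_config(mode = "univariate", min_improvement = 5))
  expect_identical(enc$x$kind, "linear")

  # step truth: single split recovered near the generating threshold
  y_step <- as.numeric(x > 0.2) + rnorm(n, 0, 0.3)
  enc <- univariate_transform(sw_dataset(y_step, data.frame(x = x)),
                              splitwise_config(mode = "univariate", min_improvement = 5))
  expect_identical(enc$x$kind, "single_split")
  expect_lt(abs(enc$x$cutpoints - 0.2), 0.1)
})

test_that("min_improvement = Inf collapses both modes to plain stepwise", {
  gen <- generate_scenario(scenario_spec("step", seed = 7))
  d <- gen$data
  ds <- sw_dataset(d$y, d[setdiff(names(d), "y")])
  for (dir in c("forward", "both")) {
    plain <- stepwise_select(splitwise:::build_groups(ds, splitwise:::linear_map(ds)),
                             d$y, dir, "AIC")
    m <- splitwise(y ~ ., d, mode = "iterative", direction = dir,
                   min_improvement = Inf)
    expect_setequal(selected_predictors(m), plain$selected)
    expect_equal(m$criterion_value, information_criterion(plain$fit, "AIC"))
    # univariate mode still screens marginally, but no split encoding can
    # ever be accepted
    for (mode in c("iterative", "univariate")) {
      mu <- splitwise(y ~ ., d, mode = mode, direction = dir,
                      min_improvement = Inf)
      expect_true(all(vapply(mu$encodings, function(e)
        e$kind %in% c("linear", "excluded"), logical(1))))
    }
  }
})

test_that("iterative mode dummy-encodes the step predictor near the true threshold", {
  gen <- generate_scenario(scenario_spec("step", seed = 11))
  m <- splitwise(y ~ ., gen$data, mode = "iterative", direction = "forward",
                 min_improvement = 5, min_support = 0.2)
  expect_true(all(c("X1", "X2") %in% selected_predictors(m)))
  expect_identical(m$encodings$X1$kind, "linear")
  expect_identical(m$encodings$X2$kind, "single_split")
  expect_lt(abs(m$encodings$X2$cutpoints[1] - 0.2), 0.15)
})

test_that("every accepted transformation in the trace meets min_improvement", {
  gen <- generate_scenario(scenario_spec("complete", seed = 5))
  mi <- 5
  m <- splitwise(y ~ ., gen$data, mode = "iterative", direction = "forward",
                 min_improvement = mi)
  tr <- m$trace[m$trace$action == "transform", ]
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$crit_before - tr$crit_after >= mi))
})

test_that("prediction on training data equals fitted values; thresholds apply as stored", {
  gen <- generate_scenario(scenario_spec("step", seed = 13))
  m <- splitwise(y ~ ., gen$data, mode = "iterative", direction = "forward",
                 min_improvement = 5)
  expect_equal(predict(m, gen$data), fitted(m))
  expect_equal(predict(m), fitted(m))
  # single-dummy model on newdata straddling the threshold: exactly two
  # distinct predictions per side once other predictors are held fixed
  cut <- m$encodings$X2$cutpoints[1]
  nd <- gen$data[rep(1, 6), ]
  nd$X2 <- cut + c(-1, -0.5, -0.1, 0.1, 0.5, 1)
  pr <- predict(m, nd)
  expect_identical(length(unique(round(pr, 10))), 2L)
  # manual arithmetic on a hand-built row
  beta <- coef(m)
  nd1 <- gen$data[3, ]
  manual <- beta[["(Intercept)"]] +
    sum(vapply(selected_predictors(m), function(p) {
      e <- m$encodings[[p]]
      xv <- nd1[[p]]
      if (e$kind == "linear") beta[[p]] * xv
      else if (e$kind == "single_split")
        beta[[grep(paste0("^", p, "_dummy"), names(beta), value = TRUE)]] * (xv > e$cutpoints)
      else stop("unexpected kind in fixture")
    }, numeric(1)))
  expect_equal(unname(predict(m, nd1)), manual, tolerance = 1e-10)
  expect_error(predict(m, nd1[setdiff(names(nd1), "X2")]), "missing column")
})

test_that("summary reports consistent diagnostics and plain-language thresholds", {
  gen <- generate_scenario(scenario_spec("step", seed = 17))
  m <- splitwise(y ~ ., gen$data, mode = "iterative", direction = "forward",
                 min_improvement = 5)
  s <- summary(m)
  n <- m$fit$n; k <- m$fit$k
  expect_equal(s$adj.r.squared,
               1 - (1 - s$r.squared) * (n - 1) / (n - k), tolerance = 1e-12)
  # coefficient table matches stats::lm on the same design
  ref <- stats::lm(m$y ~ m$X - 1)
  expect_equal(unname(s$coefficients[, "Std. Error"]),
               unname(summary(ref)$coefficients[, "Std. Error"]), tolerance = 1e-8)
  expect_match(s$dummy_lines["X2"], "X2 > ")
  txt <- utils::capture.output(print(s))
  expect_true(any(grepl("Dummy transformations", txt)))
  # intercept-only model has an empty dummy section
  set.seed(3)
  y <- rnorm(30)
  d0 <- data.frame(y = y, a = stats::resid(stats::lm(rnorm(30) ~ y)))
  m0 <- splitwise(y ~ a, d0, direction = "forward", criterion = "BIC")
  expect_identical(length(summary(m0)$dummy_lines), 0L)
})

test_that("the full pipeline is deterministic: identical data and config give identical traces", {
  gen <- generate_scenario(scenario_spec("complete", seed = 23))
  m1 <- splitwise(y ~ ., gen$data, mode = "iterative", direction = "forward",
                  min_improvement = 5)
  m2 <- splitwise(y ~ ., gen$data, mode = "iterative", direction = "forward",
                  min_improvement = 5)
  expect_identical(m1$trace, m2$trace)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$encodings, m2$encodings)
})

test_that("an empty predictor set yields the intercept-only model", {
  d <- data.frame(y = c(1, 2, 3, 4, 6))
  m <- splitwise(y ~ 1, d, mode = "univariate")
  expect_identical(m$selected, character(0))
  expect_equal(unname(coef(m)), mean(d$y))
})
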