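test_that("noise calibration divides the realized signal variance by the SNR", {
  sig <- c(1, 3, 5, 7, 9)
  expect_equal(calibrate_noise(sig, 5), stats::var(sig) / 5)
  expect_warning(s2 <- calibrate_noise(rep(2, 10), 5), "constant signal")
  expect_identical(s2, 0)
})

test_that("generated scenarios satisfy their construction identities", {
  spec <- scenario_spec("linear", seed = 3)
  gen <- generate_scenario(spec)
  expect_identical(gen$truth, "X1")
  expect_equal(dim(gen$data), c(500L, 21L))
  # scenario A: the signal is exactly X1
  expect_equal(gen$signal, gen$data$X1)
  # SNR holds exactly by construction
  expect_equal(stats::var(gen$signal) / gen$sigma2, 5)

  spec_d <- scenario_spec("complete", seed = 4)
  gen_d <- generate_scenario(spec_d)
  expect_setequal(gen_d$truth, c("X1", "X2", "X3"))
  x3 <- gen_d$data$X3
  x3s <- (x3 - min(x3)) / (max(x3) - min(x3))
  quad <- -8 * (x3s - 0.5)^2 + 2
  # vertex form: values in [0, 2], 0 attained at both endpoints
  expect_true(all(quad >= 0 - 1e-12 & quad <= 2 + 1e-12))
  expect_equal(min(quad), 0)
  expect_equal(gen_d$signal,
               gen_d$data$X1 + as.numeric(gen_d$data$X2 > 0.2) + quad)
  # step indicator frequency matches the standard-normal tail P(X > 0.2)
  fr <- vapply(1:40, function(i) {
    mean(generate_scenario(scenario_spec("step", seed = 100 + i))$data$X2 > 0.2)
  }, numeric(1))
  expect_equal(mean(fr), stats::pnorm(-0.2), tolerance = 0.01)
})

test_that("regenerated datasets re-estimate the target SNR within sampling error", {
  est <- vapply(1:30, function(i) {
    g <- generate_scenario(scenario_spec("complete", seed = 500 + i))
    eps <- g$data$y - g$signal
    stats::var(g$signal) / stats::var(eps)
  }, numeric(1))
  expect_equal(mean(est), 5, tolerance = 0.25)
})

test_that("MCC matches direct evaluation and its boundary conventions", {
  expect_identical(mcc(3, 17, 0, 0), 1)
  expect_identical(mcc(0, 18, 0, 2), 0) # tp + fp = 0 factor
  expect_equal(mcc(2, 16, 1, 1), 31 / 51)
  set.seed(77)
  for (i in 1:50) {
    cts <- as.list(sample(0:12, 4, replace = TRUE))
    names(cts) <- c("tp", "tn", "fp", "fn")
    v <- mcc(cts$tp, cts$tn, cts$fp, cts$fn)
    den <- sqrt(prod(c(cts$tp + cts$fp, cts$tp + cts$fn,
                       cts$tn + cts$fp, cts$tn + cts$fn)))
    direct <- if (den == 0) 0 else (cts$tp * cts$tn - cts$fp * cts$fn) / den
    expect_equal(v, direct)
    expect_true(v >= -1 && v <= 1)
    # symmetric under simultaneous swap tp<->tn, fp<->fn
    expect_equal(v, mcc(cts$tn, cts$tp, cts$fn, cts$fp))
  }
})

test_that("selection confusion counts predictors by source, once each", {
  cf <- selection_confusion(c("X1", "X2"), c("X1", "X2"), 20)
  expect_identical(unclass(cf)[c("tp", "tn", "fp", "fn")],
                   list(tp = 2L, tn = 18L, fp = 0L, fn = 0L))
  cf0 <- selection_confusion(character(0), c("X1", "X2"), 20)
  expect_identical(cf0$fn, 2L)
  expect_identical(cf0$tn, 18L)
  # a double-split term still counts its source once
  cf1 <- selection_confusion(c("X3", "X3"), "X3", 20)
  expect_identical(cf1$tp, 1L)
  expect_identical(cf1$fp, 0L)
  expect_identical(cf$tp + cf$tn + cf$fp + cf$fn, 20L)
})

test_that("single-replication benchmarks equal their summaries and reruns are identical", {
  spec <- scenario_spec("step", n = 120, p = 5, seed = 1)
  methods <- list(sw = adapter_splitwise(mode = "univariate", direction = "forward"))
  b1 <- run_benchmark(spec, methods, reps = 1, seed = 9)
  expect_identical(b1$summary$rmse_median, b1$replications$rmse[1])
  expect_identical(b1$summary$mae_median, b1$replications$mae[1])
  b2 <- run_benchmark(spec, methods, reps = 1, seed = 9)
  expect_identical(b1$replications, b2$replications)
  b3 <- run_benchmark(spec, methods, reps = 3, seed = 9)
  expect_identical(nrow(b3$replications), 3L)
  # medians are invariant to replication order
  expect_equal(b3$summary$rmse_median, stats::median(b3$replications$rmse))
})

test_that("adapter failures are recorded per replication and excluded from summaries", {
  spec <- scenario_spec("linear", n = 60, p = 4, seed = 2)
  methods <- list(
    ok = adapter_splitwise(mode = "univariate", direction = "forward"),
    broken = function(train, response) stop("deliberate failure"))
  b <- run_benchmark(spec, methods, reps = 2, seed = 1)
  expect_identical(b$n_failures, 2L)
  expect_true(all(is.na(b$replications$rmse[b$replications$method == "broken"])))
  expect_identical(nrow(b$summary), 1L)
  expect_identical(b$summary$method, "ok")
})

test_that("fixed datasets are resampled rather than regenerated", {
  d <- make_toy(n = 80, seed = 5)
  b <- run_benchmark(d, list(sw = adapter_splitwise(mode = "univariate",
                                                    direction = "forward")),
                     reps = 2, seed = 3, response = "y")
  expect_identical(b$n_failures, 0L)
  expect_true(all(is.na(b$replications$mcc)))
  expect_true(all(b$replications$rmse > 0))
})

test_that("mode pre-selection is deterministic and uses only training error", {
  spec <- scenario_spec("step", n = 200, p = 5, seed = 1)
  m1 <- select_mode(spec, seed = 4)
  m2 <- select_mode(spec, seed = 4)
  expect_identical(m1, m2)
  expect_true(m1 %in% c("univariate", "iterative"))
  # with transformations unreachable both modes coincide: tie goes univariate
  m3 <- select_mode(spec, min_improvement = Inf, seed = 4)
  expect_identical(m3, "univariate")
})
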