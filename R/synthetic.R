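#' Scenario specification for the synthetic benchmark
#'
#' Defines one of four simulation designs on `p` i.i.d. standard-normal
#' predictors: the response is a sum of a linear term in `X1`, a step term
#' `I(X2 > tau)`, a rescaled-quadratic (U-shaped) term in `X3`, and
#' Gaussian noise calibrated to a fixed signal-to-noise ratio. The
#' scenario activates subsets of the three signal components:
#' `"linear"` (X1 only), `"step"` (X1 + step), `"u_shape"` (X1 +
#' quadratic), `"complete"` (all three). All active coefficients equal 1.
#'
#' @param scenario one of `"linear"`, `"step"`, `"u_shape"`, `"complete"`.
#' @param n observations (default 500).
#' @param p predictors (default 20).
#' @param tau step threshold on `X2` (default 0.2).
#' @param snr signal-to-noise ratio (default 5).
#' @param seed integer seed used by [generate_scenario()].
#' @return A list of class `sw_scenario` with the resolved coefficients
#'   `beta = c(beta1, beta2, beta3)`.
#' @export
scenario_spec <- function(scenario = c("linear", "step", "u_shape", "complete"),
                          n = 500L, p = 20L, tau = 0.2, snr = 5, seed = 1L) {
  scenario <- match.arg(scenario)
  beta <- switch(scenario,
    linear   = c(1, 0, 0),
    step     = c(1, 1, 0),
    u_shape  = c(1, 0, 1),
    complete = c(1, 1, 1))
  stopifnot(n >= 10, p >= 3, snr > 0)
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 tau = tau, snr = snr, seed = as.integer(seed), beta = beta),
            class = "sw_scenario")
}

#' Calibrate the noise variance to a target signal-to-noise ratio
#'
#' Returns `sigma^2 = Var(signal) / snr`, with `Var` the sample variance of
#' the realized signal vector, so the generated dataset's
#' `Var(signal) / sigma^2` equals `snr` exactly by construction.
#'
#' @param signal numeric vector of realized systematic response values.
#' @param snr target signal-to-noise ratio (> 0).
#' @return The noise variance (0, with a warning, for a constant signal).
#' @export
calibrate_noise <- function(signal, snr) {
  stopifnot(snr > 0)
  v <- stats::var(signal)
  if (v == 0) {
    warning("calibrate_noise: constant signal; sigma^2 = 0", call. = FALSE)
    return(0)
  }
  v / snr
}

#' Generate one synthetic dataset
#'
#' Draws `X` as an `n x p` matrix of i.i.d. standard normals and builds
#' `y = beta1*X1 + beta2*I(X2 > tau) + beta3*(-8*(X3s - 0.5)^2 + 2) + eps`,
#' where `X3s` is `X3` min-max rescaled to `[0, 1]` using the realized
#' sample minimum and maximum, and `eps ~ N(0, sigma^2)` with `sigma^2`
#' from [calibrate_noise()] applied to the realized signal.
#'
#' @param spec an [scenario_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return A list with `data` (data frame: `y`, `X1` ... `Xp`), `truth`
#'   (names of the predictors carrying signal), `sigma2`, and `signal`.
#' @export
generate_scenario <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sw_scenario"))
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))
  n <- spec$n
  p <- spec$p
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("X", seq_len(p))))
  b <- spec$beta
  x3s <- (X[, 3L] - min(X[, 3L])) / (max(X[, 3L]) - min(X[, 3L]))
  signal <- b[1L] * X[, 1L] +
    b[2L] * as.numeric(X[, 2L] > spec$tau) +
    b[3L] * (-8 * (x3s - 0.5)^2 + 2)
  sigma2 <- calibrate_noise(signal, spec$snr)
  y <- signal + stats::rnorm(n, 0, sqrt(sigma2))
  truth <- c("X1", if (b[2L] != 0) "X2", if (b[3L] != 0) "X3")
  list(data = data.frame(y = y, X), truth = truth, sigma2 = sigma2,
       signal = signal)
}

#' Variable-selection confusion counts
#'
#' A predictor counts as selected if any of its encodings (linear or
#' dummy) appears in the final model; counts are computed against the
#' truth set over all `p` predictors.
#'
#' @param selected character vector of selected source predictors.
#' @param truth character vector of truly relevant predictors.
#' @param predictors character vector of all predictor names (or a count
#'   `p`, in which case names `X1..Xp` are assumed).
#' @return A list of class `sw_confusion` with `tp`, `tn`, `fp`, `fn`.
#' @export
selection_confusion <- function(selected, truth, predictors) {
  if (is.numeric(predictors)) predictors <- paste0("X", seq_len(predictors))
  selected <- unique(selected)
  stopifnot(all(truth %in% predictors), all(selected %in% predictors))
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  tn <- length(predictors) - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "sw_confusion")
}

#' Matthews correlation coefficient of a selection confusion
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the value
#' defined as 0 whenever any factor of the denominator is zero. Bounded in
#' `[-1, 1]`.
#'
#' @param tp an `sw_confusion` object, or the true-positive count.
#' @param tn,fp,fn remaining counts when `tp` is numeric.
#' @return A single numeric value.
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(tp, "sw_confusion")) {
    c_ <- tp
  } else {
    c_ <- list(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  stopifnot(all(vapply(c_, function(v) v >= 0, logical(1))))
  den <- prod(c(c_$tp + c_$fp, c_$tp + c_$fn, c_$tn + c_$fp, c_$tn + c_$fn))
  if (den == 0) return(0)
  (c_$tp * c_$tn - c_$fp * c_$fn) / sqrt(den)
}

#' Method adapter: SplitWise
#'
#' Returns a fitting function usable by [run_benchmark()]: it takes a
#' training data frame and the response column name, fits [splitwise()],
#' and exposes `predict` and the selected source predictors.
#'
#' @inheritParams splitwise_config
#' @return A function `(train, response) -> list(predict, selected, model)`.
#' @export
adapter_splitwise <- function(mode = "iterative", direction = "forward",
                              criterion = "AIC", min_support = 0.2,
                              min_improvement = 5, cp = 0.01,
                              max_iterations = 20L, transformable = NULL) {
  function(train, response) {
    m <- splitwise(stats::reformulate(".", response), train, mode = mode,
                   direction = direction, criterion = criterion,
                   min_support = min_support, min_improvement = min_improvement,
                   cp = cp, max_iterations = max_iterations,
                   transformable = transformable)
    list(predict = function(newdata) stats::predict(m, newdata),
         selected = selected_predictors(m), model = m)
  }
}

#' Method adapter: plain stepwise regression on linear terms
#'
#' Classic criterion-driven stepwise selection with every predictor kept
#' in linear form (no threshold transformation), as the baseline the
#' threshold-encoding search is compared against.
#'
#' @param direction,criterion see [splitwise_config()].
#' @return A function `(train, response) -> list(predict, selected, model)`.
#' @export
adapter_stepwise <- function(direction = "forward", criterion = "AIC") {
  function(train, response) {
    m <- splitwise(stats::reformulate(".", response), train, mode = "iterative",
                   direction = direction, criterion = criterion,
                   transformable = character(0))
    list(predict = function(newdata) stats::predict(m, newdata),
         selected = selected_predictors(m), model = m)
  }
}

#' Repeated train/test benchmark
#'
#' Runs each method adapter over `reps` replications. For a scenario
#' specification a fresh dataset is generated per replication (seed =
#' `seed + replication index`) before the 70/30 split; for a fixed data
#' frame the same rows are re-split per replication. Per replication and
#' method the test RMSE and MAE, the number of selected predictors and —
#' when ground truth is known — the selection MCC are recorded; summaries
#' report medians and standard deviations. Adapter failures are recorded
#' and excluded from the summaries.
#'
#' @param x an [scenario_spec()] or a data frame.
#' @param methods named list of adapters (see [adapter_splitwise()]).
#' @param reps number of replications.
#' @param train_frac fraction of rows used for training.
#' @param seed master seed; replication `i` uses `seed + i`.
#' @param response response column name (fixed-dataset path; default
#'   `"y"`).
#' @param truth optional character vector of relevant predictors for a
#'   fixed dataset.
#' @return An object of class `sw_benchmark`: list with `replications`
#'   (one row per replication x method), `summary` (medians and SDs per
#'   method), `n_failures` and the echoed configuration.
#' @export
run_benchmark <- function(x, methods, reps = 100L, train_frac = 0.7,
                          seed = 1L, response = "y", truth = NULL) {
  stopifnot(is.list(methods), length(methods) > 0, !is.null(names(methods)))
  synthetic <- inherits(x, "sw_scenario")
  rows <- list()
  for (i in seq_len(reps)) {
    rep_seed <- seed + i
    if (synthetic) {
      gen <- generate_scenario(x, seed = rep_seed)
      df <- gen$data
      truth_i <- gen$truth
    } else {
      set.seed(rep_seed)
      df <- as.data.frame(x)
      truth_i <- truth
    }
    n <- nrow(df)
    train_idx <- sample(n, round(train_frac * n))
    train <- df[train_idx, , drop = FALSE]
    test <- df[-train_idx, , drop = FALSE]
    pnames <- setdiff(names(df), response)
    for (mn in names(methods)) {
      res <- tryCatch({
        fitobj <- methods[[mn]](train, response)
        pred <- fitobj$predict(test)
        err <- test[[response]] - pred
        m_mcc <- if (!is.null(truth_i)) {
          mcc(selection_confusion(fitobj$selected, truth_i, pnames))
        } else NA_real_
        data.frame(rep = i, seed = rep_seed, method = mn,
                   rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                   mcc = m_mcc, n_selected = length(fitobj$selected),
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(rep = i, seed = rep_seed, method = mn, rmse = NA_real_,
                   mae = NA_real_, mcc = NA_real_, n_selected = NA_integer_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  replications <- do.call(rbind, rows)
  ok <- is.na(replications$error)
  summ <- do.call(rbind, lapply(split(replications[ok, ], replications$method[ok]),
    function(d) {
      data.frame(
        method = d$method[1L], n_ok = nrow(d),
        rmse_median = stats::median(d$rmse), rmse_sd = stats::sd(d$rmse),
        mae_median = stats::median(d$mae), mae_sd = stats::sd(d$mae),
        mcc_median = stats::median(d$mcc), mcc_sd = stats::sd(d$mcc),
        n_selected_median = stats::median(d$n_selected),
        stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  structure(list(replications = replications, summary = summ,
                 n_failures = sum(!ok), reps = reps, train_frac = train_frac,
                 seed = seed,
                 scenario = if (synthetic) x else NULL),
            class = "sw_benchmark")
}

#' @export
print.sw_benchmark <- function(x, ...) {
  cat("sw_benchmark:", x$reps, "replications",
      if (!is.null(x$scenario)) paste0("(scenario ", x$scenario$scenario, ")"),
      "\n")
  print(x$summary, digits = 4)
  if (x$n_failures > 0) cat(x$n_failures, "failed replication fits\n")
  invisible(x)
}

#' Pre-select the SplitWise transformation mode for a scenario
#'
#' Runs both modes once on a single preliminary training draw and returns
#' the mode with the lower *training* RMSE (ties go to the cheaper
#' univariate mode); no test-set information is used. The chosen mode is
#' then held fixed across benchmark replications.
#'
#' @param spec an [scenario_spec()].
#' @param direction,criterion,min_support,min_improvement see
#'   [splitwise_config()].
#' @param train_frac training fraction for the preliminary draw.
#' @param seed seed of the preliminary draw.
#' @return `"univariate"` or `"iterative"`.
#' @export
select_mode <- function(spec, direction = "forward", criterion = "AIC",
                        min_support = 0.2, min_improvement = 5,
                        train_frac = 0.7, seed = 1L) {
  gen <- generate_scenario(spec, seed = seed)
  n <- nrow(gen$data)
  train_idx <- sample(n, round(train_frac * n))
  train <- gen$data[train_idx, , drop = FALSE]
  rmse_of <- function(mode) {
    m <- splitwise(y ~ ., train, mode = mode, direction = direction,
                   criterion = criterion, min_support = min_support,
                   min_improvement = min_improvement)
    sqrt(mean(residuals(m)^2))
  }
  r_uni <- rmse_of("univariate")
  r_it <- rmse_of("iterative")
  if (r_it < r_uni) "iterative" else "univariate"
}
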