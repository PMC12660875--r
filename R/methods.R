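#' Predict from a SplitWise model
#'
#' Rebuilds the design columns on `newdata` using the stored encodings
#' (thresholds are applied as stored, never re-estimated; values outside
#' the training range still encode deterministically) and returns the
#' linear combination with the fitted coefficients.
#'
#' @param object a `splitwise_lm` object.
#' @param newdata data frame containing every source predictor of the
#'   final model. If missing, the training fitted values are returned.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.splitwise_lm <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fit$fitted)
  newdata <- as.data.frame(newdata)
  X <- cbind(`(Intercept)` = rep(1, nrow(newdata)))
  for (nm in object$selected) {
    g <- object$groups[[nm]]
    src <- g$source
    if (!src %in% names(newdata)) stop("predict: missing column '", src, "'")
    xv <- newdata[[src]]
    enc <- object$encodings[[src]]
    if (enc$kind != "linear" || object$kinds[[src]] == "numeric") {
      if (!is.numeric(xv)) stop("predict: column '", src, "' must be numeric")
    }
    cols <- switch(enc$kind,
      linear = if (object$kinds[[src]] == "categorical") {
        f <- factor(xv, levels = object$xlevels[[src]])
        if (anyNA(f)) stop("predict: unknown level in '", src, "'")
        m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(m) <- colnames(g$cols)
        m
      } else {
        matrix(xv, ncol = 1L, dimnames = list(NULL, src))
      },
      single_split = matrix(as.integer(xv > enc$cutpoints), ncol = 1L,
                            dimnames = list(NULL, colnames(g$cols))),
      double_split = {
        m <- cbind(as.integer(xv > enc$cutpoints[1L] & xv <= enc$cutpoints[2L]),
                   as.integer(xv > enc$cutpoints[2L]))
        colnames(m) <- colnames(g$cols)
        m
      })
    X <- cbind(X, cols)
  }
  beta <- object$fit$coefficients
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' @export
coef.splitwise_lm <- function(object, ...) object$fit$coefficients

#' @export
fitted.splitwise_lm <- function(object, ...) object$fit$fitted

#' @export
residuals.splitwise_lm <- function(object, ...) object$fit$residuals

#' @export
model.matrix.splitwise_lm <- function(object, ...) object$X

# encodings of predictors present in the final model, split kinds only
model_dummies <- function(object) {
  Filter(function(e) e$kind %in% c("single_split", "double_split"),
         object$encodings)
}

#' Source predictors selected by the final model
#'
#' A predictor counts as selected when any of its encodings (linear,
#' categorical block or threshold dummy) appears in the final model.
#'
#' @param object a `splitwise_lm` object.
#' @return Character vector of predictor names.
#' @export
selected_predictors <- function(object) {
  stopifnot(inherits(object, "splitwise_lm"))
  unique(vapply(object$groups[object$selected], `[[`, character(1), "source"))
}

#' Summarize a SplitWise model
#'
#' @param object a `splitwise_lm` object.
#' @param ... unused.
#' @return An object of class `summary.splitwise_lm` holding the
#'   coefficient table (estimate, standard error, t and p value), residual
#'   standard error, (adjusted) R squared, AIC and BIC under both the
#'   full-likelihood and the RSS-based (`extractAIC`) conventions, and the
#'   dummy-transformation details in plain language.
#' @export
summary.splitwise_lm <- function(object, ...) {
  fit <- object$fit
  X <- object$X
  n <- fit$n
  k <- fit$k
  sigma2 <- fit$rss / (n - k)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(sigma2 * xtx_inv))[order(fit$qr$pivot)]
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  coef_table <- cbind(Estimate = est, `Std. Error` = se,
                      `t value` = tval, `Pr(>|t|)` = pval)
  tss <- sum((object$y - mean(object$y))^2)
  r2 <- 1 - fit$rss / tss
  dummies <- model_dummies(object)
  out <- list(
    call = object$call,
    coefficients = coef_table,
    sigma = sqrt(sigma2),
    df = c(k, n - k),
    r.squared = r2,
    adj.r.squared = 1 - (1 - r2) * (n - 1) / (n - k),
    aic = fit$aic, bic = fit$bic,
    aic_rss = extract_criterion(fit, "AIC"),
    bic_rss = extract_criterion(fit, "BIC"),
    dummy_lines = vapply(dummies, function(e) {
      if (e$kind == "single_split") {
        sprintf("%s > %g", e$source, e$cutpoints)
      } else {
        sprintf("%s in (%g, %g] / %s > %g (reference: %s <= %g)",
                e$source, e$cutpoints[1L], e$cutpoints[2L],
                e$source, e$cutpoints[2L], e$source, e$cutpoints[1L])
      }
    }, character(1)),
    n = n, response_name = object$response_name,
    criterion = object$config$criterion
  )
  class(out) <- "summary.splitwise_lm"
  out
}

#' @export
print.summary.splitwise_lm <- function(x, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat("Coefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
              x$sigma, x$df[2L]))
  cat(sprintf("Multiple R-squared: %.4g, Adjusted R-squared: %.4g\n",
              x$r.squared, x$adj.r.squared))
  cat(sprintf("AIC: %.2f  BIC: %.2f  (RSS-convention: %.2f / %.2f)\n",
              x$aic, x$bic, x$aic_rss, x$bic_rss))
  cat("\nDummy transformations:\n")
  if (length(x$dummy_lines)) {
    for (ln in x$dummy_lines) cat("  ", ln, "\n", sep = "")
  } else {
    cat("  (none)\n")
  }
  invisible(x)
}

#' @export
print.splitwise_lm <- function(x, ...) {
  cat("SplitWise linear model (", x$config$mode, " mode, direction ",
      x$config$direction, ", ", x$config$criterion, ")\n", sep = "")
  cat("Response:", x$response_name, "\n\nCoefficients:\n")
  print(x$fit$coefficients)
  dm <- model_dummies(x)
  if (length(dm)) {
    cat("\nDummy-encoded predictors:\n")
    for (e in dm) cat("  ", dummy_label(e$source, e$cutpoints), "\n", sep = "")
  }
  invisible(x)
}

#' Machine-readable report of a fitted SplitWise model
#'
#' @param object a `splitwise_lm` object.
#' @return A list (convertible to JSON) with the coefficient table,
#'   per-predictor encodings and thresholds, criterion values under both
#'   conventions, fit diagnostics and the full search trace.
#' @export
as_report <- function(object) {
  stopifnot(inherits(object, "splitwise_lm"))
  s <- summary(object)
  list(
    response = object$response_name,
    config = unclass(object$config),
    coefficients = as.data.frame(s$coefficients),
    encodings = lapply(object$encodings, function(e) {
      list(kind = e$kind, cutpoints = e$cutpoints)
    }),
    diagnostics = list(
      n = s$n, sigma = s$sigma, r_squared = s$r.squared,
      adj_r_squared = s$adj.r.squared,
      aic = s$aic, bic = s$bic,
      aic_rss_convention = s$aic_rss, bic_rss_convention = s$bic_rss
    ),
    selected_predictors = selected_predictors(object),
    trace = object$trace
  )
}
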