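#' Configuration for a SplitWise fit
#'
#' @param mode `"iterative"` (model-aware search: thresholds proposed from
#'   partial residuals as the model evolves) or `"univariate"` (each
#'   predictor's representation chosen once from its marginal relationship
#'   with the response, then a single global stepwise pass).
#' @param direction stepwise direction: `"both"`, `"backward"` or
#'   `"forward"`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param min_support minimum fraction of observations required in every
#'   segment induced by an accepted split, in (0, 0.5]. Enforced as a
#'   minimum segment size of `round(min_support * n)` observations against
#'   the full sample size.
#' @param min_improvement minimum decrease of the criterion required to
#'   accept a dummy transformation (plain additions/removals of terms only
#'   need any strict improvement). Default 3; larger values make the model
#'   more conservative about thresholds.
#' @param cp complexity parameter of the threshold-proposing trees.
#' @param max_iterations cap on iterative-mode outer loops.
#' @param transformable optional character vector naming the predictors
#'   eligible for threshold encoding (default: all numeric predictors).
#' @return A list of class `sw_config`.
#' @export
splitwise_config <- function(mode = c("iterative", "univariate"),
                             direction = c("both", "backward", "forward"),
                             criterion = c("AIC", "BIC"),
                             min_support = 0.2, min_improvement = 3,
                             cp = 0.01, max_iterations = 20L,
                             transformable = NULL) {
  stopifnot(min_support > 0, min_support <= 0.5, min_improvement >= 0, cp >= 0,
            max_iterations >= 1)
  structure(list(mode = match.arg(mode), direction = match.arg(direction),
                 criterion = match.arg(criterion), min_support = min_support,
                 min_improvement = min_improvement, cp = cp,
                 max_iterations = as.integer(max_iterations),
                 transformable = transformable),
            class = "sw_config")
}

# predictors eligible for threshold transformation
transformable_predictors <- function(data, config) {
  num <- names(data$kinds)[data$kinds == "numeric"]
  if (is.null(config$transformable)) num else intersect(num, config$transformable)
}

group_name_for <- function(enc) {
  if (enc$kind == "linear") enc$source else dummy_label(enc$source, enc$cutpoints)
}

# ---- univariate mode ------------------------------------------------------

#' Choose each predictor's representation from its marginal fit
#'
#' For every transformable numeric predictor four single-predictor models
#' are scored by the configured criterion: intercept-only (null), linear,
#' single-split and double-split (cutpoints proposed by a shallow tree of
#' the predictor against the response). A split form is eligible only when
#' it beats the *linear* form by at least `min_improvement` and respects
#' `min_support`; predictors whose best representation is the null model
#' are excluded. Non-transformable numeric and categorical predictors keep
#' their linear (reference-coded) representation.
#'
#' @param data an [sw_dataset()].
#' @param config an [splitwise_config()].
#' @return Named list of [encoding()] objects, one per predictor, plus a
#'   `"trace"` attribute recording the per-predictor criterion comparison.
#' @export
univariate_transform <- function(data, config = splitwise_config(mode = "univariate")) {
  y <- data$y
  null_fit <- suppressWarnings(fit_ols(cbind(`(Intercept)` = rep(1, data$n)), y))
  crit_null <- information_criterion(null_fit, config$criterion)
  eligible <- transformable_predictors(data, config)
  enc_map <- list()
  rows <- list()
  for (nm in names(data$x)) {
    if (!nm %in% eligible) {
      enc_map[[nm]] <- encoding("linear", nm)
      next
    }
    x <- data$x[[nm]]
    cand_encs <- list(linear = encoding("linear", nm))
    crit_of <- function(enc) {
      g <- tryCatch(encoding_group(data, enc), sw_degenerate_encoding = function(e) NULL)
      if (is.null(g)) return(NA_real_)
      f <- fit_groups(stats::setNames(list(g), g$name), y, g$name)
      if (is.null(f)) return(NA_real_)
      information_criterion(f, config$criterion)
    }
    crit_lin <- crit_of(cand_encs$linear)
    crits <- c(null = crit_null, linear = crit_lin)
    if (length(unique(x)) >= 2L && data$n >= ceiling(1 / config$min_support)) {
      tree <- grow_tree(x, y, config$min_support, config$cp)
      cands <- extract_candidates(tree, x, config$min_support)
      if (!is.null(cands$single)) {
        cand_encs$single <- encoding("single_split", nm, cands$single)
        crits["single"] <- crit_of(cand_encs$single)
      }
      if (!is.null(cands$double)) {
        cand_encs$double <- encoding("double_split", nm, cands$double)
        crits["double"] <- crit_of(cand_encs$double)
      }
    }
    # split forms must beat the linear form by min_improvement
    for (form in c("single", "double")) {
      if (!is.na(crits[form] %||% NA_real_) && !is.na(crit_lin) &&
          !(crits[[form]] <= crit_lin - config$min_improvement)) {
        crits[form] <- NA_real_
      }
    }
    ok <- !is.na(crits)
    # tie-break toward the simpler form (null < linear < single < double)
    pick <- names(crits)[ok][which.min(crits[ok])]
    enc_map[[nm]] <- switch(pick,
      null = encoding("excluded", nm),
      linear = cand_encs$linear,
      single = cand_encs$single,
      double = cand_encs$double)
    rows[[nm]] <- trace_row("univariate", paste0("encode_", pick), nm,
                            crit_lin, crits[[pick]])
  }
  attr(enc_map, "trace") <- do.call(rbind, unname(rows))
  enc_map
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# ---- iterative mode -------------------------------------------------------

# Partial residuals of the current state with respect to `predictor`:
# residuals plus the fitted contribution of every in-model term of that
# predictor (equals plain residuals when the predictor is absent).
state_partial_residuals <- function(fit, groups, selected, predictor) {
  pres <- fit$residuals
  for (nm in selected) {
    g <- groups[[nm]]
    if (g$source == predictor) {
      beta <- fit$coefficients[colnames(g$cols)]
      pres <- pres + drop(g$cols %*% beta)
    }
  }
  pres
}

#' Model-aware iterative transformation search
#'
#' Alternates (a) a classic stepwise pass (additions/removals per the
#' configured direction, any strict criterion improvement) with (b) a
#' transformation scan: for every transformable numeric predictor still in
#' linear representation, a shallow tree grown on its partial residuals
#' proposes single- and double-split encodings; the best proposal replaces
#' the predictor's linear term (or enters the model, if the predictor is
#' absent) iff it lowers the criterion by at least `min_improvement` and
#' satisfies `min_support`. The loop ends when a full pass changes nothing
#' or `max_iterations` is reached, after which a final global stepwise
#' selection runs over the frozen transformed candidate set.
#'
#' @inheritParams univariate_transform
#' @return List with `enc_map`, `fit`, `selected`, `groups` and `trace`.
#' @export
iterative_search <- function(data, config = splitwise_config(mode = "iterative")) {
  y <- data$y
  enc_map <- linear_map(data)
  groups <- build_groups(data, enc_map)
  eligible <- transformable_predictors(data, config)
  start <- if (config$direction == "forward") character(0) else names(groups)
  trace <- list()
  current <- start
  sw <- stepwise_select(groups, y, config$direction, config$criterion,
                        start = current, trace_label = "pass1")
  trace[[length(trace) + 1L]] <- sw$trace
  current <- sw$selected
  fit <- sw$fit
  crit <- information_criterion(fit, config$criterion)
  iter <- 1L
  repeat {
    changed <- FALSE
    # (b) transformation scan in fixed input column order. A transformation
    # modifies the representation of a predictor currently in the model in
    # linear form: its linear term is replaced by the dummy encoding
    # proposed from its partial residuals, and the replacement is accepted
    # iff it lowers the criterion by at least min_improvement. Entering or
    # leaving the model remains the stepwise passes' decision; a predictor
    # must first earn a place linearly before it can be threshold-encoded.
    for (nm in eligible) {
      if (enc_map[[nm]]$kind != "linear" || !nm %in% current) next
      x <- data$x[[nm]]
      if (length(unique(x)) < 2L) next
      pres <- state_partial_residuals(fit, groups, current, nm)
      tree <- grow_tree(x, pres, config$min_support, config$cp)
      cands <- extract_candidates(tree, x, config$min_support)
      ref_sel <- current
      ref_crit <- crit
      best <- NULL
      for (cuts in Filter(Negate(is.null), list(cands$single, cands$double))) {
        enc <- encoding(if (length(cuts) == 1L) "single_split" else "double_split",
                        nm, cuts)
        g <- tryCatch(encoding_group(data, enc),
                      sw_degenerate_encoding = function(e) NULL)
        if (is.null(g)) next
        trial_groups <- groups
        trial_groups[[nm]] <- NULL
        trial_groups[[g$name]] <- g
        trial_sel <- c(setdiff(ref_sel, nm), g$name)
        cand_fit <- fit_groups(trial_groups, y, trial_sel)
        if (is.null(cand_fit)) next
        cc <- information_criterion(cand_fit, config$criterion)
        if (ref_crit - cc >= config$min_improvement &&
            (is.null(best) || cc < best$crit)) {
          best <- list(enc = enc, groups = trial_groups, fit = cand_fit,
                       crit = cc, gname = g$name)
        }
      }
      if (!is.null(best)) {
        trace[[length(trace) + 1L]] <- trace_row(
          paste0("pass", iter), "transform", group_name_for(best$enc),
          ref_crit, best$crit)
        enc_map[[nm]] <- best$enc
        groups <- best$groups
        current <- c(setdiff(current, nm), best$gname)
        fit <- best$fit
        crit <- best$crit
        changed <- TRUE
      }
    }
    # (a) stepwise pass over the updated candidate set
    sw <- stepwise_select(groups, y, config$direction, config$criterion,
                          start = current, trace_label = paste0("pass", iter + 1L))
    if (!setequal(sw$selected, current) ||
        information_criterion(sw$fit, config$criterion) < crit) {
      changed <- TRUE
    }
    if (nrow(sw$trace) > 1L) trace[[length(trace) + 1L]] <- sw$trace[-1L, ]
    current <- sw$selected
    fit <- sw$fit
    crit <- information_criterion(fit, config$criterion)
    iter <- iter + 1L
    if (!changed) break
    if (iter > config$max_iterations) {
      warning("iterative_search: max_iterations reached before convergence",
              call. = FALSE)
      trace[[length(trace) + 1L]] <-
        trace_row("warning", "max_iterations", "", crit, crit)
      break
    }
  }
  # final global stepwise selection over the frozen transformed candidate set
  final <- stepwise_select(groups, y, config$direction, config$criterion,
                           trace_label = "final")
  trace[[length(trace) + 1L]] <- final$trace
  list(enc_map = enc_map, fit = final$fit, selected = final$selected,
       groups = groups, trace = do.call(rbind, trace))
}

# ---- main entry point -----------------------------------------------------

#' Fit a SplitWise regression model
#'
#' Stepwise linear-model selection in which each numeric predictor may
#' enter as a plain linear term or as data-driven threshold indicators
#' (single or double split) proposed by shallow regression trees. A
#' threshold encoding is accepted only when it improves the AIC/BIC by at
#' least `min_improvement` and every induced segment keeps at least a
#' `min_support` fraction of the observations, so the final model remains a
#' sparse, auditable linear equation.
#'
#' @param formula model formula; predictors are taken at face value (e.g.
#'   `y ~ .`). Numeric right-hand-side variables are eligible for threshold
#'   transformation, factors/characters enter via reference coding.
#' @param data data frame containing the variables.
#' @param mode,direction,criterion,min_support,min_improvement,cp,max_iterations,transformable
#'   see [splitwise_config()].
#' @return An object of class `splitwise_lm` with components `fit` (the
#'   final OLS fit), `encodings` (per-predictor final encoding; predictors
#'   not in the final model are `"excluded"`), `selected` (names of the
#'   in-model term groups), `trace` (search trace with criterion values
#'   before/after every accepted action), `config`, `X`/`y` (final design
#'   and response) and `xlevels`. Methods: [predict.splitwise_lm()],
#'   [summary.splitwise_lm()], `print()`, `coef()`, `fitted()`,
#'   `residuals()`, `model.matrix()`.
#' @examples
#' d <- datasets::mtcars
#' m <- splitwise(mpg ~ ., d, mode = "iterative", direction = "backward")
#' summary(m)
#' @export
splitwise <- function(formula, data,
                      mode = c("iterative", "univariate"),
                      direction = c("both", "backward", "forward"),
                      criterion = c("AIC", "BIC"),
                      min_support = 0.2, min_improvement = 3,
                      cp = 0.01, max_iterations = 20L, transformable = NULL) {
  config <- splitwise_config(mode, direction, criterion, min_support,
                             min_improvement, cp, max_iterations, transformable)
  mf <- stats::model.frame(formula, as.data.frame(data))
  y <- stats::model.response(mf)
  resp_name <- deparse(formula[[2L]])
  ds <- sw_dataset(y, mf[setdiff(names(mf), resp_name)], response_name = resp_name)
  out <- splitwise_fit(ds, config)
  out$call <- match.call()
  out
}

#' Fit a SplitWise model on a prepared dataset
#'
#' Lower-level entry point taking an [sw_dataset()] and an
#' [splitwise_config()]; [splitwise()] is the formula-interface wrapper.
#'
#' @param data an [sw_dataset()].
#' @param config an [splitwise_config()].
#' @return A `splitwise_lm` object; see [splitwise()].
#' @export
splitwise_fit <- function(data, config = splitwise_config()) {
  stopifnot(inherits(data, "sw_dataset"), inherits(config, "sw_config"))
  if (round(config$min_support * data$n) < 1) {
    stop("min_support * n must be at least 1")
  }
  if (config$mode == "univariate") {
    enc_map <- univariate_transform(data, config)
    trace <- attr(enc_map, "trace")
    attr(enc_map, "trace") <- NULL
    groups <- build_groups(data, enc_map)
    final <- stepwise_select(groups, data$y, config$direction, config$criterion,
                             trace_label = "final")
    res <- list(enc_map = enc_map, fit = final$fit, selected = final$selected,
                groups = groups, trace = rbind(trace, final$trace))
  } else {
    res <- iterative_search(data, config)
  }
  # predictors absent from the final model are recorded as excluded
  enc_map <- res$enc_map
  in_model <- unique(vapply(res$groups[res$selected], `[[`, character(1), "source"))
  for (nm in names(enc_map)) {
    if (!nm %in% in_model) enc_map[[nm]] <- encoding("excluded", nm)
  }
  X <- cbind(`(Intercept)` = rep(1, data$n))
  for (nm in res$selected) X <- cbind(X, res$groups[[nm]]$cols)
  xlevels <- lapply(data$x[data$kinds == "categorical"], levels)
  structure(list(
    fit = res$fit, encodings = enc_map, selected = res$selected,
    groups = res$groups[res$selected], trace = res$trace, config = config,
    X = X, y = data$y, kinds = data$kinds, xlevels = xlevels,
    response_name = data$response_name,
    criterion_value = information_criterion(res$fit, config$criterion)
  ), class = "splitwise_lm")
}

#' Partial residuals of a fitted SplitWise model
#'
#' Residuals plus the fitted contribution of every in-model term derived
#' from `predictor`; equals the ordinary residuals when no term of that
#' predictor is in the model. This is the target against which new
#' thresholds are proposed in iterative mode.
#'
#' @param model a `splitwise_lm` object.
#' @param predictor predictor name.
#' @return Numeric vector of length `n`.
#' @export
partial_residuals <- function(model, predictor) {
  stopifnot(inherits(model, "splitwise_lm"))
  if (!predictor %in% names(model$encodings)) {
    stop("unknown predictor '", predictor, "'")
  }
  state_partial_residuals(model$fit, model$groups, model$selected, predictor)
}
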