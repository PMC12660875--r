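#' Greedy criterion-driven stepwise selection over term groups
#'
#' Classic stepwise search in which the unit of addition/removal is a *term
#' group*: a linear column, a single threshold indicator, a double-split
#' indicator pair, or a categorical indicator block (groups always enter
#' and leave jointly). At each step every legal single-group addition
#' (forward/both) and removal (backward/both) is scored by the criterion;
#' the best move is taken iff it is strictly better than the incumbent
#' model, so the incumbent criterion is strictly decreasing and termination
#' is guaranteed. Ties are broken toward removals, then by term name.
#'
#' @param groups named list of term groups as produced internally by the
#'   encoding module; each element has `name`, `source` and `cols`.
#' @param y numeric response.
#' @param direction `"forward"` (start empty, additions only),
#'   `"backward"` (start full, removals only) or `"both"` (start full,
#'   additions and removals).
#' @param criterion `"AIC"` or `"BIC"`.
#' @param start optional character vector of group names forming the
#'   starting model (overrides the per-direction default start).
#' @param trace_label prefix used in trace rows.
#' @return List with `fit` (`sw_ols` of the final model), `selected`
#'   (character vector of in-model group names), and `trace` (data frame of
#'   evaluated/accepted moves with criterion before/after).
#' @details Candidate moves that produce a rank-deficient design are
#'   rejected (never silently aliased). If the *starting* model itself is
#'   rank-deficient, aliased groups are dropped with a warning before the
#'   search begins.
#' @export
stepwise_select <- function(groups, y,
                            direction = c("both", "backward", "forward"),
                            criterion = c("AIC", "BIC"),
                            start = NULL, trace_label = "stepwise") {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  stopifnot(is.list(groups))
  if (is.null(start)) {
    start <- if (direction == "forward") character(0) else names(groups)
  }
  current <- as.character(start)
  fit <- fit_groups(groups, y, current)
  if (is.null(fit)) {
    # rank-deficient start: locate aliased columns via pivoted QR and drop
    # the groups that own them, one at a time
    repeat {
      X <- cbind(`(Intercept)` = rep(1, length(y)))
      for (nm in current) X <- cbind(X, groups[[nm]]$cols)
      qx <- qr(X)
      if (qx$rank == ncol(X)) break
      bad_col <- colnames(X)[qx$pivot[qx$rank + 1L]]
      owner <- NULL
      for (nm in current) {
        if (bad_col %in% colnames(groups[[nm]]$cols)) { owner <- nm; break }
      }
      if (is.null(owner)) stop("stepwise_select: could not resolve rank deficiency")
      warning("stepwise_select: dropping aliased term '", owner,
              "' from the starting model", call. = FALSE)
      current <- setdiff(current, owner)
    }
    fit <- fit_groups(groups, y, current)
  }
  crit <- information_criterion(fit, criterion)
  trace <- list(trace_row(trace_label, "start", "", NA, crit))
  repeat {
    moves <- list()
    if (direction %in% c("backward", "both")) {
      for (nm in current) moves[[length(moves) + 1L]] <- list(action = "remove", term = nm)
    }
    if (direction %in% c("forward", "both")) {
      for (nm in setdiff(names(groups), current)) {
        moves[[length(moves) + 1L]] <- list(action = "add", term = nm)
      }
    }
    if (!length(moves)) break
    # deterministic evaluation order: removals first, then name
    ord <- order(vapply(moves, function(m) m$action != "remove", logical(1)),
                 vapply(moves, `[[`, character(1), "term"))
    moves <- moves[ord]
    best <- NULL
    for (m in moves) {
      sel <- if (m$action == "remove") setdiff(current, m$term) else c(current, m$term)
      cand <- fit_groups(groups, y, sel)
      if (is.null(cand)) next
      cc <- information_criterion(cand, criterion)
      if (cc < crit && (is.null(best) || cc < best$crit)) {
        best <- list(move = m, fit = cand, crit = cc, sel = sel)
      }
    }
    if (is.null(best)) break
    trace[[length(trace) + 1L]] <-
      trace_row(trace_label, best$move$action, best$move$term, crit, best$crit)
    current <- best$sel
    fit <- best$fit
    crit <- best$crit
  }
  list(fit = fit, selected = current, trace = do.call(rbind, trace))
}

# Assemble intercept + selected group columns and fit; NULL on degeneracy.
fit_groups <- function(groups, y, selected) {
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  for (nm in selected) X <- cbind(X, groups[[nm]]$cols)
  tryCatch(suppressWarnings(fit_ols(X, y)),
           sw_degenerate_design = function(e) NULL)
}

trace_row <- function(stage, action, term, before, after) {
  data.frame(stage = stage, action = action, term = term,
             crit_before = before, crit_after = after,
             stringsAsFactors = FALSE)
}
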