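#' Grow a shallow regression tree on one predictor
#'
#' Deterministic depth-2 CART-style split search used to propose candidate
#' cutpoints for threshold encodings. At each node the SSE-minimizing
#' binary partition by a threshold on `x` is found by an exact scan over
#' all midpoints between consecutive distinct values. A split is retained
#' only if
#' * its SSE improvement is at least `cp` times the root-node SSE
#'   (cost-complexity pruning, relative to the root as in rpart), and
#' * both resulting leaves contain at least `round(min_support * n)`
#'   observations, with `n` the full sample size.
#'
#' The procedure involves no randomness; ties between equally good
#' thresholds are broken toward the smallest cutpoint.
#'
#' @param x numeric predictor vector.
#' @param target numeric target vector (response or partial residuals).
#' @param min_support minimum segment fraction in (0, 0.5].
#' @param cp complexity parameter: minimum relative SSE improvement
#'   (default 0.01, the rpart default).
#' @return An object of class `sw_tree`: list with `root`, `left`, `right`
#'   (each `NULL` or `list(cut, improvement)`), `n` and `sse_root`. A
#'   constant `x` or constant `target` yields an empty tree (`root = NULL`).
#' @export
grow_tree <- function(x, target, min_support = 0.2, cp = 0.01) {
  n <- length(x)
  stopifnot(length(target) == n, min_support > 0, min_support <= 0.5)
  if (n < ceiling(1 / min_support)) {
    stop("grow_tree: need at least ceiling(1/min_support) observations")
  }
  minbucket <- max(1L, as.integer(round(min_support * n)))
  sse_root <- sum((target - mean(target))^2)
  tree <- structure(list(root = NULL, left = NULL, right = NULL,
                         n = n, sse_root = sse_root),
                    class = "sw_tree")
  if (sse_root <= 0 || length(unique(x)) < 2L) return(tree)
  thresh <- cp * sse_root
  root <- best_split(x, target, minbucket)
  if (is.null(root) || root$improvement < thresh) return(tree)
  tree$root <- root
  lo <- x <= root$cut
  for (side in c("left", "right")) {
    idx <- if (side == "left") lo else !lo
    if (sum(idx) >= 2L * minbucket) {
      child <- best_split(x[idx], target[idx], minbucket)
      if (!is.null(child) && child$improvement >= thresh) tree[[side]] <- child
    }
  }
  tree
}

# Exact SSE-minimizing threshold on x for a numeric target; both sides must
# hold >= minbucket observations. Returns NULL when no admissible split
# exists. Ties go to the smallest cutpoint.
best_split <- function(x, target, minbucket) {
  n <- length(x)
  o <- order(x, method = "radix")
  xs <- x[o]
  ts <- target[o]
  i <- seq_len(n - 1L)
  ok <- (xs[i] < xs[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
  if (!any(ok)) return(NULL)
  cs <- cumsum(ts)
  css <- cumsum(ts^2)
  tot <- cs[n]
  totss <- css[n]
  i <- i[ok]
  sse_l <- css[i] - cs[i]^2 / i
  sse_r <- (totss - css[i]) - (tot - cs[i])^2 / (n - i)
  sse0 <- totss - tot^2 / n
  impr <- sse0 - (sse_l + sse_r)
  j <- which.max(impr) # first maximum = smallest cutpoint (xs ascending)
  list(cut = (xs[i[j]] + xs[i[j] + 1L]) / 2, improvement = impr[[j]])
}

#' Extract single- and double-split cutpoint candidates from a tree
#'
#' The single-split candidate is the root cutpoint. The double-split
#' candidate combines the root cutpoint with the child cutpoint of larger
#' SSE improvement (ties toward the smaller cutpoint), provided all three
#' resulting segments hold at least `round(min_support * length(x))`
#' observations; otherwise it is absent.
#'
#' @param tree an [grow_tree()] result.
#' @param x the predictor vector the tree was grown on.
#' @param min_support minimum segment fraction.
#' @return List with `single` (numeric or `NULL`) and `double` (sorted
#'   numeric pair or `NULL`).
#' @export
extract_candidates <- function(tree, x, min_support = 0.2) {
  out <- list(single = NULL, double = NULL)
  if (is.null(tree$root)) return(out)
  out$single <- tree$root$cut
  kids <- Filter(Negate(is.null), list(tree$left, tree$right))
  if (length(kids)) {
    impr <- vapply(kids, `[[`, numeric(1), "improvement")
    cuts <- vapply(kids, `[[`, numeric(1), "cut")
    best <- order(-impr, cuts)[1L]
    cand <- sort(c(tree$root$cut, cuts[best]))
    minbucket <- max(1L, as.integer(round(min_support * length(x))))
    sizes <- segment_support(x, cand) * length(x)
    if (all(sizes >= minbucket)) out$double <- cand
  }
  out
}

#' @export
print.sw_tree <- function(x, ...) {
  if (is.null(x$root)) {
    cat("sw_tree: no splits (n =", x$n, ")\n")
  } else {
    cat(sprintf("sw_tree: root cut %g (improvement %.4g), n = %d\n",
                x$root$cut, x$root$improvement, x$n))
    for (side in c("left", "right")) {
      if (!is.null(x[[side]])) {
        cat(sprintf("  %s child cut %g (improvement %.4g)\n",
                    side, x[[side]]$cut, x[[side]]$improvement))
      }
    }
  }
  invisible(x)
}
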