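# Independent brute-force oracles used across tests. These deliberately use
# naive enumeration, never the package's own code paths.

# SSE of a constant fit
sse0 <- function(v) sum((v - mean(v))^2)

# Exhaustive best single threshold: scan every midpoint between consecutive
# distinct sorted values; both sides must hold >= minbucket observations.
# Ties resolved toward the smallest cutpoint.
bf_best_split <- function(x, target, minbucket) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (head(ux, -1) + tail(ux, -1)) / 2
  best <- NULL
  for (cc in cuts) {
    l <- target[x <= cc]; r <- target[x > cc]
    if (length(l) < minbucket || length(r) < minbucket) next
    sse <- sse0(l) + sse0(r)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(cut = cc, sse = sse)
  }
  if (is.null(best)) return(NULL)
  best$improvement <- sse0(target) - best$sse
  best
}

# Exhaustive best pair of thresholds (three segments), each >= minbucket.
bf_best_two_cuts <- function(x, target, minbucket) {
  ux <- sort(unique(x))
  if (length(ux) < 3L) return(NULL)
  cuts <- (head(ux, -1) + tail(ux, -1)) / 2
  best <- NULL
  for (i in seq_along(cuts)) for (j in seq_along(cuts)) {
    if (j <= i) next
    c1 <- cuts[i]; c2 <- cuts[j]
    s1 <- target[x <= c1]; s2 <- target[x > c1 & x <= c2]; s3 <- target[x > c2]
    if (min(length(s1), length(s2), length(s3)) < minbucket) next
    sse <- sse0(s1) + sse0(s2) + sse0(s3)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(cuts = c(c1, c2), sse = sse)
    }
  }
  best
}

# Gaussian AIC/BIC of an lm-style fit by direct density evaluation.
bf_gaussian_aic <- function(y, fitted, k_coefs, penalty = 2) {
  n <- length(y)
  rss <- sum((y - fitted)^2)
  ll <- sum(stats::dnorm(y, mean = fitted, sd = sqrt(rss / n), log = TRUE))
  -2 * ll + penalty * (k_coefs + 1)
}

# Independent greedy stepwise reference: enumerates every add/remove move
# with lm() fits and full-likelihood AIC/BIC, removals preferred on ties,
# then lexicographic term name.
bf_stepwise <- function(cols, y, direction, criterion = "AIC", start = NULL) {
  crit_of <- function(sel) {
    X <- cbind(rep(1, length(y)))
    for (nm in sel) X <- cbind(X, cols[[nm]])
    f <- stats::lm.fit(X, y)
    if (f$rank < ncol(X)) return(Inf)
    rss <- sum(f$residuals^2)
    n <- length(y)
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    pen <- if (criterion == "AIC") 2 else log(n)
    -2 * ll + pen * (ncol(X) + 1)
  }
  current <- if (!is.null(start)) start
    else if (direction == "forward") character(0) else names(cols)
  crit <- crit_of(current)
  path <- list(current)
  repeat {
    cand <- list()
    if (direction %in% c("backward", "both")) {
      for (nm in sort(current)) {
        cand[[length(cand) + 1L]] <- list(sel = setdiff(current, nm),
                                          key = c(0, match(nm, sort(names(cols)))))
      }
    }
    if (direction %in% c("forward", "both")) {
      for (nm in sort(setdiff(names(cols), current))) {
        cand[[length(cand) + 1L]] <- list(sel = c(current, nm),
                                          key = c(1, match(nm, sort(names(cols)))))
      }
    }
    if (!length(cand)) break
    vals <- vapply(cand, function(m) crit_of(m$sel), numeric(1))
    if (min(vals) >= crit) break
    keys <- sapply(cand, function(m) m$key)
    ord <- order(vals, keys[1, ], keys[2, ])
    pick <- cand[[ord[1L]]]
    current <- pick$sel
    crit <- min(vals)
    path[[length(path) + 1L]] <- current
  }
  list(selected = current, criterion = crit, path = path)
}

# small regression fixture with mixed signal
make_toy <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    y = NA, x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n)
  ) -> d
  d$y <- 1.5 * d$x1 - 0.8 * d$x2 + rnorm(n, 0, 0.5)
  d
}
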