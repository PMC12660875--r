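#' Predictor encodings
#'
#' An encoding records how one predictor enters the design matrix:
#' `"excluded"` (absent), `"linear"` (raw column; for categorical
#' predictors this means reference-coded indicators), `"single_split"`
#' (one indicator `I(x > c)`) or `"double_split"` (two cutpoints
#' `c1 < c2` yielding three segments, with the lowest segment as the
#' reference category).
#'
#' @param kind one of `"excluded"`, `"linear"`, `"single_split"`,
#'   `"double_split"`.
#' @param source name of the source predictor.
#' @param cutpoints numeric vector of length 0, 1 or 2 (strictly
#'   increasing), matching `kind`.
#' @return An object of class `sw_encoding`.
#' @export
encoding <- function(kind = c("excluded", "linear", "single_split", "double_split"),
                     source, cutpoints = numeric(0)) {
  kind <- match.arg(kind)
  cutpoints <- as.numeric(cutpoints)
  need <- c(excluded = 0L, linear = 0L, single_split = 1L, double_split = 2L)[[kind]]
  if (length(cutpoints) != need) {
    stop("encoding '", kind, "' needs ", need, " cutpoint(s), got ",
         length(cutpoints))
  }
  if (length(cutpoints) == 2L && !(cutpoints[1L] < cutpoints[2L])) {
    stop("cutpoints must be strictly increasing")
  }
  structure(list(kind = kind, source = source, cutpoints = cutpoints),
            class = "sw_encoding")
}

#' Single-split indicator column
#'
#' Codes `I(x > c)` (strict: the boundary value falls in the lower
#' segment). The threshold must lie strictly inside the observed range,
#' otherwise the column is constant and an error of class
#' `"sw_degenerate_encoding"` is raised.
#'
#' @param x numeric vector.
#' @param c threshold.
#' @return Integer 0/1 vector of `length(x)`.
#' @export
encode_single <- function(x, c) {
  col <- as.integer(x > c)
  if (all(col == 0L) || all(col == 1L)) {
    stop(errorCondition(
      sprintf("degenerate encoding: I(x > %g) is constant", c),
      class = c("sw_degenerate_encoding", "error")))
  }
  col
}

#' Double-split indicator columns
#'
#' Two cutpoints `c1 < c2` partition `x` into segments
#' `S1 = {x <= c1}`, `S2 = {c1 < x <= c2}`, `S3 = {x > c2}`. Indicators
#' are returned for S2 and S3; S1 is the reference category, so the two
#' columns are mutually exclusive and never both 1. Any empty segment
#' raises a `"sw_degenerate_encoding"` error.
#'
#' @param x numeric vector.
#' @param c1,c2 cutpoints, `c1 < c2`.
#' @return Integer matrix with two columns (`mid`, `high`).
#' @export
encode_double <- function(x, c1, c2) {
  if (!(c1 < c2)) stop("encode_double: c1 must be < c2")
  s2 <- as.integer(x > c1 & x <= c2)
  s3 <- as.integer(x > c2)
  sizes <- c(sum(x <= c1), sum(s2), sum(s3))
  if (any(sizes == 0L)) {
    stop(errorCondition(
      sprintf("degenerate encoding: empty segment for cutpoints (%g, %g)", c1, c2),
      class = c("sw_degenerate_encoding", "error")))
  }
  cbind(mid = s2, high = s3)
}

#' Segment occupancy fractions induced by cutpoints
#'
#' Splits `x` at the given (sorted) cutpoints and returns the fraction of
#' observations per segment; used for the minimum-support test on candidate
#' splits. Fractions always sum to 1.
#'
#' @param x numeric vector.
#' @param cutpoints sorted numeric vector (possibly empty).
#' @return Numeric vector of `length(cutpoints) + 1` fractions.
#' @export
segment_support <- function(x, cutpoints) {
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be sorted strictly increasing")
  }
  # boundary values belong to the lower segment (x > c semantics)
  seg <- if (length(cutpoints)) rowSums(outer(x, cutpoints, `>`)) else rep(0L, length(x))
  tabulate(seg + 1L, nbins = length(cutpoints) + 1L) / length(x)
}

# --- term groups -----------------------------------------------------------

# A term group is the unit the stepwise engine adds/removes atomically:
# list(name, source, cols = numeric matrix). Double-split pairs and factor
# indicator blocks are single groups.
term_group <- function(name, source, cols) {
  cols <- as.matrix(cols)
  list(name = name, source = source, cols = cols)
}

dummy_label <- function(source, cutpoints) {
  if (length(cutpoints) == 1L) {
    sprintf("%s_dummy: %s > %g", source, source, cutpoints)
  } else {
    sprintf("%s_dummy: %g < %s <= %g | %s > %g",
            source, cutpoints[1L], source, cutpoints[2L], source, cutpoints[2L])
  }
}

# Build the term group for one predictor under an encoding (NULL if excluded).
encoding_group <- function(data, enc) {
  src <- enc$source
  x <- data$x[[src]]
  switch(enc$kind,
    excluded = NULL,
    linear = {
      if (data$kinds[[src]] == "categorical") {
        m <- stats::model.matrix(~x)[, -1L, drop = FALSE]
        colnames(m) <- paste0(src, sub("^x", "", colnames(m)))
        term_group(src, src, m)
      } else {
        m <- matrix(x, ncol = 1L, dimnames = list(NULL, src))
        term_group(src, src, m)
      }
    },
    single_split = {
      col <- encode_single(x, enc$cutpoints)
      m <- matrix(col, ncol = 1L,
                  dimnames = list(NULL, sprintf("%s_dummy(>%g)", src, enc$cutpoints)))
      term_group(dummy_label(src, enc$cutpoints), src, m)
    },
    double_split = {
      m <- encode_double(x, enc$cutpoints[1L], enc$cutpoints[2L])
      colnames(m) <- c(
        sprintf("%s_dummy(%g,%g]", src, enc$cutpoints[1L], enc$cutpoints[2L]),
        sprintf("%s_dummy(>%g)", src, enc$cutpoints[2L]))
      term_group(dummy_label(src, enc$cutpoints), src, m)
    }
  )
}

# All term groups for a dataset under an encoding map (excluded dropped).
build_groups <- function(data, enc_map) {
  groups <- list()
  for (enc in enc_map) {
    g <- encoding_group(data, enc)
    if (!is.null(g)) groups[[g$name]] <- g
  }
  groups
}

#' Build a design matrix from an encoding map
#'
#' Assembles the intercept plus, per predictor, the columns implied by its
#' encoding: the raw column for `"linear"` numeric predictors,
#' reference-coded indicators for categorical ones, threshold indicators
#' for split encodings; `"excluded"` predictors contribute nothing.
#'
#' @param data an [sw_dataset()].
#' @param enc_map named list of [encoding()] objects, one per predictor of
#'   `data` (every predictor must appear exactly once).
#' @return A list with `X` (the numeric design matrix, intercept first) and
#'   `term_map` (data frame mapping each column to its source predictor and
#'   encoding kind).
#' @export
build_design <- function(data, enc_map) {
  if (!setequal(names(enc_map), names(data$x))) {
    stop("encoding map must cover every predictor exactly once")
  }
  groups <- build_groups(data, enc_map[names(data$x)])
  X <- cbind(`(Intercept)` = rep(1, data$n))
  term_map <- data.frame(column = "(Intercept)", source = "(Intercept)",
                         kind = "intercept", stringsAsFactors = FALSE)
  for (g in groups) {
    X <- cbind(X, g$cols)
    kind <- enc_map[[g$source]]$kind
    term_map <- rbind(term_map, data.frame(
      column = colnames(g$cols), source = g$source, kind = kind,
      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(colnames(X))) stop("duplicated design column names")
  list(X = X, term_map = term_map)
}

# Default all-linear encoding map for a dataset.
linear_map <- function(data) {
  out <- lapply(names(data$x), function(nm) encoding("linear", nm))
  names(out) <- names(data$x)
  out
}
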