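#' Construct a modeling dataset
#'
#' Bundles a numeric response with a predictor table and records, per
#' column, whether the predictor is numeric (and hence eligible for
#' threshold encoding) or categorical (entered via reference coding only,
#' never transformed).
#'
#' @param response numeric vector without missing values.
#' @param predictors data frame of predictor columns (numeric, factor or
#'   character; character columns are converted to factors). May have zero
#'   columns.
#' @param response_name name used for the response in reports.
#' @return An object of class `sw_dataset` with elements `y`, `x`, `kinds`
#'   (named character vector, `"numeric"` or `"categorical"`), `n` and
#'   `response_name`.
#' @export
sw_dataset <- function(response, predictors, response_name = "y") {
  if (!is.numeric(response)) stop("response must be numeric")
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) == 0L && ncol(predictors) > 0L) {
    stop("empty predictor table")
  }
  if (ncol(predictors) > 0L && nrow(predictors) != length(response)) {
    stop("response length (", length(response), ") != predictor rows (",
         nrow(predictors), ")")
  }
  if (anyNA(response)) stop("missing values in response")
  kinds <- character(ncol(predictors))
  names(kinds) <- names(predictors)
  for (nm in names(predictors)) {
    col <- predictors[[nm]]
    if (anyNA(col)) stop("missing values in predictor '", nm, "'")
    if (is.numeric(col)) {
      kinds[nm] <- "numeric"
    } else {
      predictors[[nm]] <- factor(col)
      kinds[nm] <- "categorical"
    }
  }
  if (anyDuplicated(names(predictors))) stop("duplicated predictor names")
  structure(
    list(y = as.numeric(response), x = predictors, kinds = kinds,
         n = length(response), response_name = response_name),
    class = "sw_dataset"
  )
}

#' Read a CSV/TSV file into a modeling dataset
#'
#' The separator is inferred from the file extension (`.tsv`/`.tab` are
#' tab-separated, everything else comma-separated). Missing values are
#' rejected with a diagnostic naming the first offending cell.
#'
#' @param path path to a delimited text file with a header row.
#' @param response name of the response column.
#' @return An [sw_dataset()].
#' @export
read_table <- function(path, response) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found in ", path)
  }
  na_idx <- which(is.na(df), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) {
    stop("missing value at row ", na_idx[1L, 1L], ", column '",
         names(df)[na_idx[1L, 2L]], "' of ", path)
  }
  if (!is.numeric(df[[response]])) {
    stop("response column '", response, "' is not numeric")
  }
  sw_dataset(df[[response]], df[setdiff(names(df), response)],
             response_name = response)
}

#' @export
print.sw_dataset <- function(x, ...) {
  cat("sw_dataset: n =", x$n, ", p =", ncol(x$x),
      sprintf("(%d numeric, %d categorical)",
              sum(x$kinds == "numeric"), sum(x$kinds == "categorical")),
      "\nresponse:", x$response_name, "\n")
  invisible(x)
}
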