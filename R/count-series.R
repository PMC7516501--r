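#' Count time series with an autoregressive order
#'
#' Bundles an observed series of non-negative integer counts
#' \eqn{y_1, \dots, y_T} with the model order \eqn{p}.  All modelling
#' functions in the package take a `count_series`; plain integer vectors are
#' coerced with the default order `p = 1`.
#'
#' @param y vector of non-negative integer counts.
#' @param order model order `p` (number of thinned lags), a positive integer
#'   strictly smaller than `length(y)`.
#' @return An object of class `count_series`: an integer vector with an
#'   `order` attribute.
#' @examples
#' y <- count_series(c(3, 1, 4, 1, 5), order = 1)
#' length(y)
#' series_order(y)
#' @export
count_series <- function(y, order = 1L) {
  y <- as.vector(y, mode = "numeric")
  if (length(y) == 0L) stop("empty series")
  if (anyNA(y)) stop("series contains missing values")
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers")
  }
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L) {
    stop("'order' must be a positive integer")
  }
  if (length(y) <= order) {
    stop("series length T must exceed the model order p")
  }
  structure(as.integer(y), order = order, class = "count_series")
}

#' @rdname count_series
#' @param x a `count_series` (or something coercible to one).
#' @export
series_order <- function(x) {
  if (inherits(x, "count_series")) attr(x, "order") else 1L
}

as_count_series <- function(x, order = NULL) {
  if (inherits(x, "count_series")) {
    if (!is.null(order) && order != series_order(x)) {
      x <- count_series(unclass(x), order = order)
    }
    return(x)
  }
  count_series(x, order = if (is.null(order)) 1L else order)
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("count_series: T = %d observations, order p = %d\n",
              length(x), series_order(x)))
  cat(sprintf("  range [%d, %d], mean %.3f\n",
              min(x), max(x), mean(unclass(x))))
  invisible(x)
}

#' Read or write a count series as CSV
#'
#' The on-disk dialect is a two-column UTF-8 CSV with header `t,y`: an
#' integer time index `t = 1, ..., T` without gaps and a non-negative
#' integer count `y` per row.
#'
#' @param path file path.
#' @param order model order attached to the series on reading.
#' @return `read_count_series()` returns a [count_series()];
#'   `write_count_series()` invisibly returns `path`.
#' @export
read_count_series <- function(path, order = 1L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "y") %in% names(df))) {
    stop("count-series CSV must have columns 't' and 'y'")
  }
  if (anyNA(df$t) || anyNA(df$y)) stop("missing values in count-series CSV")
  if (any(df$y != round(df$y)) || any(df$y < 0)) {
    stop("column 'y' must hold non-negative integer counts")
  }
  o <- order(df$t)
  df <- df[o, , drop = FALSE]
  if (!isTRUE(all.equal(as.numeric(df$t), seq_len(nrow(df))))) {
    stop("column 't' must be the gap-free index 1..T")
  }
  count_series(df$y, order = order)
}

#' @rdname read_count_series
#' @param x a [count_series()] (or integer vector) to write.
#' @export
write_count_series <- function(x, path) {
  x <- as_count_series(x)
  write.csv(data.frame(t = seq_along(x), y = as.integer(x)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
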