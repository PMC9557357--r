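# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

#' Weighted quintile assignment
#'
#' Assigns each observation to a weighted quintile (1 = lowest) of `x`:
#' cut points are the weighted 20/40/60/80th percentiles, so each quintile
#' holds roughly 20% of the total weight.
#'
#' @param x numeric vector to rank.
#' @param w positive weights, same length as `x`.
#' @return integer vector in 1..5.
#' @keywords internal
weighted_quintile <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  q <- pmin(5L, findInterval(cw, c(0.2, 0.4, 0.6, 0.8), left.open = TRUE) + 1L)
  out <- integer(length(x))
  out[ord] <- q
  out
}

# Weighted mean of x over the band of the weighted cumulative distribution
# [lo, hi]: observation i (sorted by x) occupies the weight interval
# (cw_{i-1}, cw_i]; it is included iff cw_i > lo and cw_{i-1} < hi.
weighted_band_mean <- function(x, w, lo, hi) {
  stopifnot(length(x) == length(w), lo < hi)
  ord <- order(x)
  xs <- x[ord]
  ws <- w[ord]
  cw <- cumsum(ws) / sum(ws)
  cw0 <- c(0, cw[-length(cw)])
  keep <- cw > lo & cw0 < hi
  if (!any(keep)) keep[which.min(abs(cw - (lo + hi) / 2))] <- TRUE
  sum(xs[keep] * ws[keep]) / sum(ws[keep])
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
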