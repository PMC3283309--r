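#' Insert-size library statistics
#'
#' Cutoffs separating concordant from discordant paired-end mappings. A
#' mapping with proper orientation is concordant when its span length
#' (outer distance, reads included) lies in `[min_len, max_len]`;
#' deletion-indicating when the span exceeds `max_len`.
#'
#' @param min_len Lower insert-size cutoff in bases (span length including
#'   both reads).
#' @param max_len Upper insert-size cutoff in bases.
#' @param quality_min Minimum mapping quality for a pair to be used at all.
#' @param q_low,q_high Quantile levels the cutoffs were (or would be)
#'   derived from; recorded for provenance.
#' @return An object of class `library_stats`.
#' @examples
#' library_stats(126, 263)
#' @export
library_stats <- function(min_len, max_len, quality_min = 20,
                          q_low = 0.001, q_high = 0.999) {
  stopifnot(is.numeric(min_len), is.numeric(max_len),
            min_len > 0, min_len <= max_len,
            q_low >= 0, q_low < q_high, q_high <= 1,
            quality_min >= 0)
  structure(
    list(min_len = as.numeric(min_len), max_len = as.numeric(max_len),
         quality_min = as.numeric(quality_min),
         q_low = q_low, q_high = q_high),
    class = "library_stats"
  )
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(
    "library_stats: min_len=%g max_len=%g (quantiles %g/%g), quality_min=%g\n",
    x$min_len, x$max_len, x$q_low, x$q_high, x$quality_min))
  invisible(x)
}

#' Estimate insert-size cutoffs from observed insert lengths
#'
#' Computes `min_len` and `max_len` as nearest-rank quantiles of the insert
#' (span) lengths of properly oriented pairs. The nearest-rank estimator is
#' used so that the cutoffs are always observed, integer-valued lengths:
#' the q-quantile of n sorted values is the value at rank `ceiling(q * n)`
#' (clamped to at least 1).
#'
#' @param inserts Numeric vector of insert lengths (bases) from
#'   proper-orientation pairs.
#' @param q_low,q_high Quantile levels for the lower/upper cutoff.
#' @param quality_min Quality threshold to record in the result (the inserts
#'   are assumed to be pre-filtered).
#' @return A [library_stats] object.
#' @examples
#' estimate_insert_bounds(1:1000)  # min_len = 1, max_len = 999
#' @export
estimate_insert_bounds <- function(inserts, q_low = 0.001, q_high = 0.999,
                                   quality_min = 20) {
  if (!length(inserts)) stop("cannot estimate insert bounds from zero inserts")
  stopifnot(is.numeric(inserts), q_low >= 0, q_low < q_high, q_high <= 1)
  x <- sort(as.numeric(inserts))
  n <- length(x)
  rank_of <- function(q) min(n, max(1L, as.integer(ceiling(q * n))))
  library_stats(x[rank_of(q_low)], x[rank_of(q_high)],
                quality_min = quality_min, q_low = q_low, q_high = q_high)
}
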