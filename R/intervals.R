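# Interval arithmetic on 0-based, half-open [start, end) genomic intervals.
# All coordinates in the package use this convention; SAM input (1-based,
# closed) is converted at the reader boundary.

#' Length of half-open intervals
#'
#' @param start,end Numeric vectors of interval bounds, `[start, end)`.
#' @return `pmax(end - start, 0)`.
#' @keywords internal
interval_length <- function(start, end) pmax(end - start, 0)

#' Merge possibly overlapping intervals into a disjoint sorted set
#'
#' @param start,end Numeric vectors of interval bounds.
#' @return Two-column matrix (`start`, `end`) of disjoint intervals sorted by
#'   start; empty intervals are dropped.
#' @keywords internal
merge_intervals <- function(start, end) {
  keep <- end > start
  start <- start[keep]
  end <- end[keep]
  if (!length(start)) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Subtract a set of blocking intervals from one interval
#'
#' Returns the maximal sub-intervals of `[start, end)` not covered by the
#' union of the blockers. This is the primitive behind free-space
#' computation for deletion consistency.
#'
#' @param start,end Bounds of the target interval.
#' @param block_start,block_end Numeric vectors of blocking intervals.
#' @return Two-column matrix (`start`, `end`) of the free sub-intervals,
#'   sorted by position; zero rows if the target is fully covered or empty.
#' @examples
#' subtract_intervals(20, 400, 100, 520)   # [20, 100)
#' subtract_intervals(200, 800, c(0, 650), c(350, 1000))  # [350, 650)
#' @export
subtract_intervals <- function(start, end, block_start = numeric(0),
                               block_end = numeric(0)) {
  stopifnot(length(start) == 1L, length(end) == 1L,
            length(block_start) == length(block_end))
  empty <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (end <= start) return(empty)
  blk <- merge_intervals(pmax(block_start, start), pmin(block_end, end))
  if (!nrow(blk)) return(cbind(start = start, end = end))
  gaps_s <- c(start, blk[, "end"])
  gaps_e <- c(blk[, "start"], end)
  keep <- gaps_e > gaps_s
  out <- cbind(start = gaps_s[keep], end = gaps_e[keep])
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Longest free sub-interval after subtraction
#'
#' @inheritParams subtract_intervals
#' @return Length of the longest maximal sub-interval of `[start, end)` not
#'   covered by the blockers; 0 if none remains.
#' @keywords internal
max_free_length <- function(start, end, block_start = numeric(0),
                            block_end = numeric(0)) {
  free <- subtract_intervals(start, end, block_start, block_end)
  if (!nrow(free)) 0 else max(free[, "end"] - free[, "start"])
}

# TRUE iff the two half-open intervals intersect.
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}
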