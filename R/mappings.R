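#' Construct a table of paired-end mappings
#'
#' One row per read pair mapped to the reference. Coordinates are 0-based,
#' half-open. The left read must lie at or before the right read
#' (`left_start <= right_start`); orientation is recorded per read as
#' `"+"`/`"-"`.
#'
#' @param id Character vector of unique pair identifiers.
#' @param chrom Chromosome name per pair.
#' @param left_start,left_end Left read interval `[left_start, left_end)`.
#' @param left_orient,right_orient Strand of each read, `"+"` or `"-"`.
#' @param right_start,right_end Right read interval.
#' @param quality Mapping quality of the pair.
#' @param source Sample label, typically `"normal"` or `"tumor"`.
#' @return A `data.frame` with one row per mapping and the given columns.
#' @export
paired_mappings <- function(id, chrom, left_start, left_end, left_orient,
                            right_start, right_end, right_orient,
                            quality = NA_real_, source = NA_character_) {
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    left_start = as.numeric(left_start), left_end = as.numeric(left_end),
    left_orient = as.character(left_orient),
    right_start = as.numeric(right_start), right_end = as.numeric(right_end),
    right_orient = as.character(right_orient),
    quality = as.numeric(quality), source = as.character(source),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$id)) stop("mapping ids must be unique")
  with(df, {
    if (any(left_end < left_start) || any(right_end < right_start))
      stop("read intervals must satisfy start <= end")
    if (any(!left_orient %in% c("+", "-")) || any(!right_orient %in% c("+", "-")))
      stop("orientations must be '+' or '-'")
    if (any(left_start < 0)) stop("coordinates must be non-negative")
  })
  df
}

empty_mappings <- function() {
  paired_mappings(character(0), character(0), numeric(0), numeric(0),
                  character(0), numeric(0), numeric(0), character(0),
                  numeric(0), character(0))
}

#' Deletion-size bounds implied by a discordant mapping
#'
#' A read pair spanning a deletion breakpoint maps with its span stretched
#' by the deletion size. Given fragment-length cutoffs `min_len`/`max_len`,
#' the deletion indicated by a mapping of span length `|span|` must measure
#' at least `|span| - max_len` and at most `|span| - min_len` bases.
#'
#' @param span_len Numeric vector of span lengths (outer distance, reads
#'   included) of deletion-indicating mappings.
#' @param lib A [library_stats] object.
#' @return A two-column matrix (`del_min`, `del_max`), one row per input.
#' @examples
#' deletion_bounds(420, library_stats(100, 200))  # 220, 320
#' @export
deletion_bounds <- function(span_len, lib) {
  stopifnot(inherits(lib, "library_stats"))
  if (any(span_len <= lib$max_len)) {
    stop("span length <= max_len: mapping is not deletion-indicating")
  }
  cbind(del_min = span_len - lib$max_len, del_max = span_len - lib$min_len)
}

#' Classify mappings as concordant, deletion-indicating, or other
#'
#' A mapping is *concordant* if its orientation is proper (left read on
#' `+`, right read on `-`, left at or before right) and its span length
#' lies within `[min_len, max_len]`. It indicates a *deletion* if the
#' orientation is proper, the span exceeds `max_len`, and the reads do not
#' overlap (non-empty breakpoint region). Everything else — wrong
#' orientation, span below `min_len` (possible insertion), overlapping
#' reads — is `other` and excluded from deletion analysis.
#'
#' @param m Mapping `data.frame` from [paired_mappings()] or [read_mappings()].
#' @param lib A [library_stats] object.
#' @return Character vector over `{"concordant", "deletion", "other"}`.
#' @export
classify_mappings <- function(m, lib) {
  stopifnot(inherits(lib, "library_stats"))
  span_len <- m$right_end - m$left_start
  proper <- m$left_orient == "+" & m$right_orient == "-" &
    m$left_start <= m$right_start & !is.na(m$chrom)
  cls <- rep("other", nrow(m))
  cls[proper & span_len >= lib$min_len & span_len <= lib$max_len] <- "concordant"
  cls[proper & span_len > lib$max_len & m$left_end < m$right_start] <- "deletion"
  cls
}

#' Annotate mappings with derived geometry and classification
#'
#' Adds the derived columns used throughout the package: `span_start`,
#' `span_end`, `span_len` (the insert length), the breakpoint region
#' `br_start`/`br_end` (between the inner read ends, where a deleted
#' segment must lie), the classification (`class`), and, for
#' deletion-indicating mappings, the per-mapping deletion-size bounds
#' `del_min`/`del_max`.
#'
#' @inheritParams classify_mappings
#' @return The input `data.frame` with derived columns appended.
#' @export
annotate_mappings <- function(m, lib) {
  stopifnot(inherits(lib, "library_stats"))
  m$span_start <- m$left_start
  m$span_end <- m$right_end
  m$span_len <- m$right_end - m$left_start
  m$br_start <- m$left_end
  m$br_end <- m$right_start
  m$class <- classify_mappings(m, lib)
  m$del_min <- rep(NA_real_, nrow(m))
  m$del_max <- rep(NA_real_, nrow(m))
  is_del <- m$class == "deletion"
  if (any(is_del)) {
    b <- deletion_bounds(m$span_len[is_del], lib)
    m$del_min[is_del] <- b[, "del_min"]
    m$del_max[is_del] <- b[, "del_max"]
  }
  m
}
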