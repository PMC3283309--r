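# Deletion clusters: sets of deletion-indicating mappings that can be
# explained by one common deletion. Cluster statistics are derived from the
# per-mapping annotation, so mappings from samples with different
# insert-size cutoffs can be combined in one cluster.

# Internal: cluster statistics from annotated deletion rows.
# Returns list(br_start, br_end, del_min, del_max, hull_start, hull_end).
cluster_stats_rows <- function(rows) {
  list(
    br_start = max(rows$br_start),
    br_end = min(rows$br_end),
    del_min = max(rows$del_min),
    del_max = min(rows$del_max),
    hull_start = min(rows$span_start),
    hull_end = max(rows$span_end)
  )
}

valid_stats <- function(st) {
  br_len <- st$br_end - st$br_start
  br_len > 0 && st$del_min <= st$del_max && st$del_min <= br_len
}

check_deletion_rows <- function(rows) {
  if (!nrow(rows)) stop("cluster must contain at least one mapping")
  if (is.null(rows$class)) stop("mappings must be annotated (see annotate_mappings)")
  if (any(rows$class != "deletion"))
    stop("all cluster members must be deletion-indicating mappings")
  if (length(unique(rows$chrom)) != 1L)
    stop("all cluster members must map to the same chromosome")
  invisible(rows)
}

#' Is a set of deletion mappings a valid cluster?
#'
#' A set of deletion-indicating mappings is a *valid cluster* if a single
#' deletion length is compatible with all of them: the intersection of
#' their breakpoint regions is non-empty, `max(del_min) <= min(del_max)`,
#' and `max(del_min)` fits inside the intersected breakpoint region.
#'
#' @param rows Annotated mapping rows (class `"deletion"`, one chromosome).
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_cluster <- function(rows) {
  check_deletion_rows(rows)
  valid_stats(cluster_stats_rows(rows))
}

#' Build a deletion cluster from mapping rows
#'
#' @param rows Annotated deletion-indicating mapping rows (same chromosome).
#' @param id Cluster identifier; autogenerated if `NULL`.
#' @return An object of class `deletion_cluster` with fields `id`,
#'   `members` (mapping ids), `chrom`, `br` (intersected breakpoint region,
#'   `c(start, end)`), `del_min`/`del_max` (deletion-size range),
#'   `span_hull` (leftmost read start to rightmost read end),
#'   `source_mix` (member counts by sample label), and `valid`.
#' @export
deletion_cluster <- function(rows, id = NULL) {
  check_deletion_rows(rows)
  st <- cluster_stats_rows(rows)
  src <- table(factor(ifelse(is.na(rows$source), "unknown", rows$source)))
  structure(
    list(
      id = if (is.null(id)) paste0("c_", rows$chrom[1], "_", st$br_start) else id,
      members = sort(rows$id),
      chrom = rows$chrom[1],
      br = c(st$br_start, st$br_end),
      del_min = st$del_min,
      del_max = st$del_max,
      span_hull = c(st$hull_start, st$hull_end),
      support = nrow(rows),
      source_mix = as.list(src),
      valid = valid_stats(st)
    ),
    class = "deletion_cluster"
  )
}

#' @export
print.deletion_cluster <- function(x, ...) {
  cat(sprintf(
    "deletion_cluster %s: %s br=[%g,%g) del=[%g,%g] support=%d%s\n",
    x$id, x$chrom, x$br[1], x$br[2], x$del_min, x$del_max, x$support,
    if (x$valid) "" else " (INVALID)"))
  invisible(x)
}

#' Summarize a list of clusters as a data frame
#'
#' @param clusters List of [deletion_cluster] objects.
#' @return A `data.frame` with one row per cluster (id, chrom, breakpoint
#'   region, deletion-size range, span hull, support, source mix).
#' @export
clusters_to_df <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      br_start = numeric(0), br_end = numeric(0),
                      del_min = numeric(0), del_max = numeric(0),
                      hull_start = numeric(0), hull_end = numeric(0),
                      support = integer(0), source_mix = character(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(
      cluster_id = cl$id, chrom = cl$chrom,
      br_start = cl$br[1], br_end = cl$br[2],
      del_min = cl$del_min, del_max = cl$del_max,
      hull_start = cl$span_hull[1], hull_end = cl$span_hull[2],
      support = cl$support,
      source_mix = paste(sprintf("%s:%d", names(cl$source_mix),
                                 unlist(cl$source_mix)), collapse = ","),
      members = paste(cl$members, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}
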