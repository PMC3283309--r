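# Enumeration of maximal valid deletion clusters.
#
# Validity is hereditary (every subset of a valid cluster is valid), so the
# valid clusters form an independence system and the inclusion-maximal ones
# can be enumerated by a Bron-Kerbosch-style branch enumeration in which a
# candidate survives only if the *full* current set plus that candidate is
# still valid. Pairwise compatibility alone is not enough: the deletion
# length of a cluster is checked against the multi-way breakpoint-region
# intersection, so a pairwise-compatible triple can be jointly invalid.

#' Are two deletion mappings compatible?
#'
#' @param rows1,rows2 Single annotated deletion mapping rows.
#' @return `TRUE` iff the pair forms a valid cluster.
#' @export
pairwise_compatible <- function(rows1, rows2) {
  is_valid_cluster(rbind(rows1, rows2))
}

# Fast validity on index sets over precomputed vectors.
.valid_idx <- function(idx, brs, bre, dmin, dmax) {
  b_s <- max(brs[idx])
  b_e <- min(bre[idx])
  d_lo <- max(dmin[idx])
  b_e > b_s && d_lo <= min(dmax[idx]) && d_lo <= b_e - b_s
}

# Connected components of the span-overlap graph over mappings (one
# chromosome): clusters cannot span disjoint components. Returns an integer
# component label per row. Sweep over spans sorted by start.
.span_components <- function(span_start, span_end) {
  n <- length(span_start)
  o <- order(span_start, span_end)
  comp <- integer(n)
  cur <- 0L
  cur_end <- -Inf
  for (i in o) {
    if (span_start[i] >= cur_end) cur <- cur + 1L
    comp[i] <- cur
    cur_end <- max(cur_end, span_end[i])
  }
  comp
}

# Bron-Kerbosch-style enumeration of maximal valid subsets within one
# overlap component. `collect` is called with each maximal index set.
.enumerate_maximal <- function(idx_all, brs, bre, dmin, dmax, limit) {
  out <- vector("list", 64L)
  n_out <- 0L
  overflow <- FALSE

  emit <- function(R) {
    n_out <<- n_out + 1L
    if (n_out > limit) {
      overflow <<- TRUE
      return()
    }
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- R
  }

  recurse <- function(R, P, X) {
    if (overflow) return()
    if (!length(P) && !length(X)) {
      emit(R)
      return()
    }
    # Domination shortcut: if R with all remaining candidates is jointly
    # valid, the only possible maximal set below this branch is R + P
    # (validity is hereditary, so any proper sub-leaf could still be
    # extended by a leftover candidate). It is maximal iff no excluded
    # node can be added on top.
    RP <- c(R, P)
    if (.valid_idx(RP, brs, bre, dmin, dmax)) {
      extendable <- any(vapply(X, function(x)
        .valid_idx(c(RP, x), brs, bre, dmin, dmax), logical(1)))
      if (!extendable) emit(RP)
      return()
    }
    while (length(P)) {
      v <- P[1L]
      Rv <- c(R, v)
      keep_p <- P[-1L]
      keep_p <- keep_p[vapply(keep_p, function(p)
        .valid_idx(c(Rv, p), brs, bre, dmin, dmax), logical(1))]
      keep_x <- X[vapply(X, function(x)
        .valid_idx(c(Rv, x), brs, bre, dmin, dmax), logical(1))]
      recurse(Rv, keep_p, keep_x)
      if (overflow) return()
      P <- P[-1L]
      X <- c(X, v)
    }
  }

  recurse(integer(0), idx_all, integer(0))
  if (overflow) return(NULL)
  out[seq_len(n_out)]
}

#' Enumerate all maximal valid deletion clusters
#'
#' Finds exactly the inclusion-maximal valid clusters among the given
#' deletion-indicating mappings, per chromosome. Mappings are first split
#' into connected components of span overlap (clusters cannot cross
#' components); within each component a branch enumeration with
#' full-validity pruning is used. Every input mapping appears in at least
#' one cluster (a single deletion mapping is always a valid cluster), and
#' no reported cluster is a subset of another.
#'
#' If a chromosome would produce more than `max_clusters` clusters the
#' chromosome is abandoned with a diagnostic and the remaining chromosomes
#' are still processed.
#'
#' @param m Annotated mapping `data.frame`; only rows with
#'   `class == "deletion"` are used.
#' @param max_clusters Per-chromosome cap on the number of maximal clusters.
#' @param id_prefix Prefix for generated cluster ids.
#' @return A list with `clusters` (list of [deletion_cluster], sorted by
#'   chromosome, breakpoint start/end and support) and `skipped`
#'   (`data.frame` of abandoned chromosomes and the reason).
#' @export
enumerate_maximal_valid_clusters <- function(m, max_clusters = 1e6,
                                             id_prefix = "c") {
  del <- m[!is.na(m$class) & m$class == "deletion", , drop = FALSE]
  skipped <- data.frame(chrom = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  clusters <- list()
  if (!nrow(del)) return(list(clusters = clusters, skipped = skipped))

  for (chrom in sort(unique(del$chrom))) {
    rows <- del[del$chrom == chrom, , drop = FALSE]
    comp <- .span_components(rows$span_start, rows$span_end)
    chrom_sets <- list()
    aborted <- FALSE
    budget <- max_clusters
    for (k in sort(unique(comp))) {
      ridx <- which(comp == k)
      sets <- .enumerate_maximal(
        seq_along(ridx),
        brs = rows$br_start[ridx], bre = rows$br_end[ridx],
        dmin = rows$del_min[ridx], dmax = rows$del_max[ridx],
        limit = budget
      )
      if (is.null(sets)) {
        aborted <- TRUE
        break
      }
      budget <- budget - length(sets)
      chrom_sets <- c(chrom_sets, lapply(sets, function(s) ridx[s]))
    }
    if (aborted) {
      warning(sprintf("chromosome %s: more than %g maximal clusters; skipped",
                      chrom, max_clusters))
      skipped <- rbind(skipped, data.frame(
        chrom = chrom,
        reason = sprintf("more than %g maximal clusters", max_clusters),
        stringsAsFactors = FALSE))
      next
    }
    chrom_clusters <- lapply(chrom_sets, function(s)
      deletion_cluster(rows[s, , drop = FALSE]))
    clusters <- c(clusters, chrom_clusters)
  }

  if (length(clusters)) {
    key <- order(
      vapply(clusters, function(cl) cl$chrom, character(1)),
      vapply(clusters, function(cl) cl$br[1], numeric(1)),
      vapply(clusters, function(cl) cl$br[2], numeric(1)),
      vapply(clusters, function(cl) cl$support, numeric(1))
    )
    clusters <- clusters[key]
    for (i in seq_along(clusters)) {
      clusters[[i]]$id <- sprintf("%s%04d", id_prefix, i)
    }
  }
  list(clusters = clusters, skipped = skipped)
}
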