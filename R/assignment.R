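# Assignment of tumor-sample mappings to four chromosome copies.
#
# The tumor sample is assumed to be a mixture of tumor and normal cells, so
# its read pairs originate from four chromosome copies: two normal, two
# tumor. All deletions are treated as heterozygous; a normal deletion
# occupies one normal copy and, because tumor cells inherit the patient's
# germline deletions, one tumor copy. For each overlapping component built
# around a normal deletion cluster we: (1) explain every concordant tumor
# mapping by the non-deleted normal copy, (2) add a maximum supporting
# subset of the discordant mappings to the normal deletion (refining it),
# and (3) partition the remaining discordant mappings into valid
# tumor-specific clusters on the two tumor copies, discarding as few
# mappings as possible, by branch-and-bound.

# -- cluster stat helpers (plain lists; cheap to copy in the search) -------

.stats_of_cluster <- function(cl) {
  list(br_start = cl$br[1], br_end = cl$br[2],
       del_min = cl$del_min, del_max = cl$del_max,
       hull_start = cl$span_hull[1], hull_end = cl$span_hull[2])
}

.stats_add_row <- function(st, brs, bre, dmin, dmax, ss, se) {
  list(br_start = max(st$br_start, brs), br_end = min(st$br_end, bre),
       del_min = max(st$del_min, dmin), del_max = min(st$del_max, dmax),
       hull_start = min(st$hull_start, ss), hull_end = max(st$hull_end, se))
}

.stats_valid <- function(st) {
  br_len <- st$br_end - st$br_start
  br_len > 0 && st$del_min <= st$del_max && st$del_min <= br_len
}

# Haploid consistency of one chromosome copy holding the given cluster
# stats plus demand-zero blockers (two-column matrix or NULL).
.copy_consistent <- function(stats_list, blockers = NULL) {
  k <- length(stats_list)
  if (!k) return(TRUE)
  hs <- vapply(stats_list, `[[`, numeric(1), "hull_start")
  he <- vapply(stats_list, `[[`, numeric(1), "hull_end")
  if (!is.null(blockers) && nrow(blockers)) {
    hs <- c(hs, blockers[, 1])
    he <- c(he, blockers[, 2])
  }
  for (i in seq_len(k)) {
    st <- stats_list[[i]]
    if (max_free_length(st$br_start, st$br_end, hs[-i], he[-i]) < st$del_min)
      return(FALSE)
  }
  TRUE
}

# -- overlapping components ------------------------------------------------

#' Build overlapping components around normal deletion clusters
#'
#' For each normal deletion cluster, collects the tumor deletion mappings
#' whose span overlaps the cluster's breakpoint region, then transitively
#' adds tumor deletion mappings whose spans overlap mappings already
#' collected. Components that share a tumor mapping, and components whose
#' normal clusters' breakpoint regions overlap, cannot be treated
#' independently and are dropped (and reported).
#'
#' @param normal_clusters List of valid [deletion_cluster] objects from the
#'   normal sample.
#' @param tumor_m Annotated tumor mapping `data.frame`.
#' @param overlap_on Whether the seeding test compares the mapping `span`
#'   (default, more inclusive) or its breakpoint region `br` against the
#'   normal cluster's breakpoint region.
#' @return List with `components` (each a list with `id`,
#'   `normal_cluster_id`, `deletion_ids`, `concordant_ids`, `footprint`)
#'   and `dropped` (`data.frame` of dropped normal cluster ids + reason).
#' @export
build_components <- function(normal_clusters, tumor_m,
                             overlap_on = c("span", "br")) {
  overlap_on <- match.arg(overlap_on)
  stopifnot(all(vapply(normal_clusters, inherits, logical(1), "deletion_cluster")))
  tdel <- tumor_m[!is.na(tumor_m$class) & tumor_m$class == "deletion", , drop = FALSE]
  tcon <- tumor_m[!is.na(tumor_m$class) & tumor_m$class == "concordant", , drop = FALSE]

  # Span-overlap connected components of the tumor deletion mappings.
  tdel$comp <- NA_character_
  for (chrom in unique(tdel$chrom)) {
    ix <- which(tdel$chrom == chrom)
    tdel$comp[ix] <- paste0(chrom, ".",
      .span_components(tdel$span_start[ix], tdel$span_end[ix]))
  }

  member_ids <- vector("list", length(normal_clusters))
  for (ci in seq_along(normal_clusters)) {
    cl <- normal_clusters[[ci]]
    on_chrom <- tdel$chrom == cl$chrom
    seed <- if (overlap_on == "span") {
      on_chrom & intervals_overlap(tdel$span_start, tdel$span_end, cl$br[1], cl$br[2])
    } else {
      on_chrom & intervals_overlap(tdel$br_start, tdel$br_end, cl$br[1], cl$br[2])
    }
    labs <- unique(tdel$comp[seed])
    member_ids[[ci]] <- tdel$id[tdel$comp %in% labs]
  }

  # Drop components sharing tumor mappings or with overlapping normal brs.
  drop <- rep(FALSE, length(normal_clusters))
  reason <- rep(NA_character_, length(normal_clusters))
  if (length(normal_clusters) > 1) {
    for (i in seq_len(length(normal_clusters) - 1)) {
      for (j in (i + 1):length(normal_clusters)) {
        ci <- normal_clusters[[i]]; cj <- normal_clusters[[j]]
        shared <- length(intersect(member_ids[[i]], member_ids[[j]])) > 0
        br_olap <- ci$chrom == cj$chrom &&
          intervals_overlap(ci$br[1], ci$br[2], cj$br[1], cj$br[2])
        if (shared || br_olap) {
          drop[c(i, j)] <- TRUE
          why <- if (shared) "shares tumor mappings" else "overlapping normal clusters"
          reason[i] <- if (is.na(reason[i])) why else reason[i]
          reason[j] <- if (is.na(reason[j])) why else reason[j]
        }
      }
    }
  }

  components <- list()
  for (ci in which(!drop)) {
    cl <- normal_clusters[[ci]]
    mem <- tdel[tdel$id %in% member_ids[[ci]], , drop = FALSE]
    fp_start <- min(cl$span_hull[1], if (nrow(mem)) min(mem$span_start) else Inf)
    fp_end <- max(cl$span_hull[2], if (nrow(mem)) max(mem$span_end) else -Inf)
    con_ids <- tcon$id[tcon$chrom == cl$chrom &
                         intervals_overlap(tcon$span_start, tcon$span_end,
                                           fp_start, fp_end)]
    components[[length(components) + 1L]] <- list(
      id = paste0("comp_", cl$id),
      normal_cluster_id = cl$id,
      deletion_ids = sort(mem$id),
      concordant_ids = sort(con_ids),
      footprint = c(fp_start, fp_end)
    )
  }
  dropped <- data.frame(
    normal_cluster_id = vapply(normal_clusters[drop], function(cl) cl$id,
                               character(1)),
    reason = reason[drop], stringsAsFactors = FALSE)
  list(components = components, dropped = dropped)
}

# -- maximum supporting subset (Problem: largest S with c + S valid) -------

# Max cardinality of a subset of candidates (index vector, in order) that
# keeps `st` valid; used both to find the optimum and to certify prefixes.
.max_extension <- function(st, cand, brs, bre, dmin, dmax, ss, se) {
  best <- 0L
  rec <- function(st, pos, count) {
    if (count + (length(cand) - pos + 1L) <= best) return()
    if (pos > length(cand)) {
      if (count > best) best <<- count
      return()
    }
    m <- cand[pos]
    st2 <- .stats_add_row(st, brs[m], bre[m], dmin[m], dmax[m], ss[m], se[m])
    if (.stats_valid(st2)) rec(st2, pos + 1L, count + 1L)
    rec(st, pos + 1L, count)
  }
  rec(st, 1L, 0L)
  best
}

#' Maximum subset of mappings supporting a deletion cluster
#'
#' Finds a maximum-cardinality subset `S` of the given deletion mappings
#' such that the cluster together with `S` is still a valid cluster, i.e.
#' all of them call for one single deletion. Ties are broken towards the
#' lexicographically smallest set of mapping ids.
#'
#' @param cluster A valid [deletion_cluster].
#' @param rows Annotated deletion mapping rows (candidates), same
#'   chromosome as the cluster.
#' @return Character vector of the supporting mapping ids (possibly empty).
#' @export
max_supporting_subset <- function(cluster, rows) {
  stopifnot(inherits(cluster, "deletion_cluster"), isTRUE(cluster$valid))
  if (!nrow(rows)) return(character(0))
  check_deletion_rows(rows)
  if (any(rows$chrom != cluster$chrom))
    stop("candidate mappings must be on the cluster's chromosome")
  st0 <- .stats_of_cluster(cluster)
  o <- order(rows$id)
  rows <- rows[o, , drop = FALSE]
  brs <- rows$br_start; bre <- rows$br_end
  dmin <- rows$del_min; dmax <- rows$del_max
  ss <- rows$span_start; se <- rows$span_end

  # Only individually compatible candidates can ever contribute.
  single_ok <- vapply(seq_len(nrow(rows)), function(i)
    .stats_valid(.stats_add_row(st0, brs[i], bre[i], dmin[i], dmax[i],
                                ss[i], se[i])), logical(1))
  cand <- which(single_ok)
  if (!length(cand)) return(character(0))

  k <- .max_extension(st0, cand, brs, bre, dmin, dmax, ss, se)
  if (k == 0L) return(character(0))

  # Lexicographically smallest id set of size k: fix candidates greedily in
  # ascending id order, keeping each one only if the target size is still
  # attainable from the later candidates.
  chosen <- integer(0)
  st <- st0
  need <- k
  pool <- cand
  while (need > 0L) {
    took <- FALSE
    for (pi in seq_along(pool)) {
      m <- pool[pi]
      st2 <- .stats_add_row(st, brs[m], bre[m], dmin[m], dmax[m], ss[m], se[m])
      if (!.stats_valid(st2)) next
      rest <- pool[-seq_len(pi)]
      if (1L + .max_extension(st2, rest, brs, bre, dmin, dmax, ss, se) >= need) {
        chosen <- c(chosen, m)
        st <- st2
        pool <- rest
        need <- need - 1L
        took <- TRUE
        break
      }
    }
    if (!took) stop("internal error: supporting subset extension failed")
  }
  sort(rows$id[chosen])
}

# -- Problem: consistent assignment to four chromosome copies --------------

#' Assign an overlapping component's tumor mappings to four copies
#'
#' Solves, for one overlapping component, the consistent-assignment
#' problem: concordant mappings are explained by the non-deleted normal
#' copy; a maximum supporting subset `S` of the discordant mappings refines
#' the normal deletion (`c' = c + S`, placed on one normal and one tumor
#' copy); the remaining discordant mappings are partitioned by
#' branch-and-bound into valid tumor-specific clusters on the two tumor
#' copies plus a minimal set of discarded mappings, such that each tumor
#' copy is haploid-consistent. The search is exact; if it exceeds
#' `time_limit` seconds the best solution found so far is returned and
#' flagged `"time_limited"`.
#'
#' @param component One component from [build_components()].
#' @param normal_cluster The valid [deletion_cluster] the component was
#'   built around.
#' @param tumor_m Annotated tumor mapping `data.frame` (resolves the
#'   component's mapping ids).
#' @param time_limit Wall-clock budget in seconds for the branch-and-bound.
#' @param concordant_constrain If `TRUE`, the component's concordant tumor
#'   mappings additionally block both tumor copies (stricter analysis); by
#'   default they are explained by the non-deleted normal copy and do not
#'   constrain the tumor side.
#' @return An `assignment_result`: list with `component_id`,
#'   `normal_cluster_id`, `refined_normal` (the cluster `c'`),
#'   `support_ids` (`S`), `tumor_clusters` (list of [deletion_cluster]),
#'   `copy_of` (named vector over tumor cluster ids, values 1/2),
#'   `normal_concordant_ids`, `tumor_concordant_ids`, `discarded_ids`,
#'   `n_discarded`, and `status` (`"optimal"` or `"time_limited"`).
#' @export
assign_component <- function(component, normal_cluster, tumor_m,
                             time_limit = 600, concordant_constrain = FALSE) {
  stopifnot(inherits(normal_cluster, "deletion_cluster"))
  if (!isTRUE(normal_cluster$valid)) stop("normal cluster must be valid")
  if (time_limit <= 0) stop("time_limit must be positive")

  rows <- tumor_m[match(component$deletion_ids, tumor_m$id), , drop = FALSE]
  if (anyNA(rows$id)) stop("component references unknown tumor mapping ids")
  if (nrow(rows)) check_deletion_rows(rows)

  support <- max_supporting_subset(normal_cluster, rows)
  s_rows <- rows[rows$id %in% support, , drop = FALSE]
  st_cp <- .stats_of_cluster(normal_cluster)
  for (i in seq_len(nrow(s_rows))) {
    st_cp <- .stats_add_row(st_cp, s_rows$br_start[i], s_rows$br_end[i],
                            s_rows$del_min[i], s_rows$del_max[i],
                            s_rows$span_start[i], s_rows$span_end[i])
  }
  cprime <- structure(list(
    id = normal_cluster$id,
    members = sort(c(normal_cluster$members, support)),
    chrom = normal_cluster$chrom,
    br = c(st_cp$br_start, st_cp$br_end),
    del_min = st_cp$del_min, del_max = st_cp$del_max,
    span_hull = c(st_cp$hull_start, st_cp$hull_end),
    support = normal_cluster$support + length(support),
    source_mix = normal_cluster$source_mix,
    valid = .stats_valid(st_cp)
  ), class = "deletion_cluster")

  blockers <- NULL
  if (concordant_constrain && length(component$concordant_ids)) {
    crows <- tumor_m[match(component$concordant_ids, tumor_m$id), , drop = FALSE]
    blockers <- cbind(crows$span_start, crows$span_end)
  }
  if (!.copy_consistent(list(st_cp), blockers)) {
    stop("refined normal cluster is inconsistent with the concordant blockers")
  }

  rem <- rows[!rows$id %in% support, , drop = FALSE]
  rem <- rem[order(rem$br_start, rem$id), , drop = FALSE]
  n <- nrow(rem)
  brs <- rem$br_start; bre <- rem$br_end
  dmin <- rem$del_min; dmax <- rem$del_max
  ss <- rem$span_start; se <- rem$span_end

  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE
  best_d <- Inf
  best_lab <- NULL     # per-mapping group index (0 = discarded)
  best_copy <- NULL    # copy per group
  lab <- integer(n)

  # groups: list of list(idx, st, copy); copy 1 also carries c'.
  rec <- function(i, groups, discards) {
    if (timed_out) return()
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      timed_out <<- TRUE
      return()
    }
    if (discards >= best_d) return()
    if (i > n) {
      best_d <<- discards
      best_lab <<- lab
      best_copy <<- vapply(groups, `[[`, numeric(1), "copy")
      return()
    }
    # join an existing group
    for (g in seq_along(groups)) {
      grp <- groups[[g]]
      st2 <- .stats_add_row(grp$st, brs[i], bre[i], dmin[i], dmax[i],
                            ss[i], se[i])
      if (!.stats_valid(st2)) next
      groups2 <- groups
      groups2[[g]]$st <- st2
      groups2[[g]]$idx <- c(grp$idx, i)
      copy_sts <- lapply(groups2[vapply(groups2, `[[`, numeric(1), "copy") ==
                                   grp$copy], `[[`, "st")
      if (grp$copy == 1) copy_sts <- c(list(st_cp), copy_sts)
      if (!.copy_consistent(copy_sts, blockers)) next
      lab[i] <<- g
      rec(i + 1L, groups2, discards)
    }
    # open a new group on copy 1 or copy 2
    st_new <- list(br_start = brs[i], br_end = bre[i], del_min = dmin[i],
                   del_max = dmax[i], hull_start = ss[i], hull_end = se[i])
    for (cp in 1:2) {
      groups2 <- c(groups, list(list(idx = i, st = st_new, copy = cp)))
      copy_sts <- lapply(groups2[vapply(groups2, `[[`, numeric(1), "copy") == cp],
                         `[[`, "st")
      if (cp == 1) copy_sts <- c(list(st_cp), copy_sts)
      if (!.copy_consistent(copy_sts, blockers)) next
      lab[i] <<- length(groups) + 1L
      rec(i + 1L, groups2, discards)
    }
    # discard
    lab[i] <<- 0L
    rec(i + 1L, groups, discards + 1L)
  }

  if (n > 0) rec(1L, list(), 0L) else {
    best_d <- 0L
    best_lab <- integer(0)
    best_copy <- numeric(0)
  }
  if (is.null(best_lab)) {
    stop("branch-and-bound found no solution within the time limit")
  }

  # Post-pass: merge tumor clusters whose union is still a valid cluster
  # and keeps both copies consistent. The search minimizes |D| only, so its
  # first optimum may split one deletion's mappings over the two copies;
  # merging never discards anything and calls one cluster per deletion.
  groups <- list()
  for (g in seq_along(best_copy)) {
    members <- which(best_lab == g)
    st <- NULL
    for (i in members) {
      st <- if (is.null(st)) {
        list(br_start = brs[i], br_end = bre[i], del_min = dmin[i],
             del_max = dmax[i], hull_start = ss[i], hull_end = se[i])
      } else {
        .stats_add_row(st, brs[i], bre[i], dmin[i], dmax[i], ss[i], se[i])
      }
    }
    groups[[g]] <- list(idx = members, st = st, copy = best_copy[g])
  }
  arrangement_ok <- function(groups) {
    for (cp in 1:2) {
      copy_sts <- lapply(groups[vapply(groups, `[[`, numeric(1), "copy") == cp],
                         `[[`, "st")
      if (cp == 1) copy_sts <- c(list(st_cp), copy_sts)
      if (!.copy_consistent(copy_sts, blockers)) return(FALSE)
    }
    TRUE
  }
  repeat {
    merged <- FALSE
    ng <- length(groups)
    if (ng < 2) break
    for (i in seq_len(ng - 1)) {
      for (j in (i + 1):ng) {
        st_u <- groups[[i]]$st
        for (k in groups[[j]]$idx) {
          st_u <- .stats_add_row(st_u, brs[k], bre[k], dmin[k], dmax[k],
                                 ss[k], se[k])
        }
        if (!.stats_valid(st_u)) next
        for (cp in unique(c(groups[[i]]$copy, groups[[j]]$copy))) {
          cand <- groups
          cand[[i]] <- list(idx = sort(c(groups[[i]]$idx, groups[[j]]$idx)),
                            st = st_u, copy = cp)
          cand[[j]] <- NULL
          if (arrangement_ok(cand)) {
            groups <- cand
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }

  tumor_clusters <- list()
  copy_of <- numeric(0)
  if (length(groups)) {
    ord <- order(vapply(groups, function(g) g$st$br_start, numeric(1)),
                 vapply(groups, function(g) g$st$br_end, numeric(1)))
    groups <- groups[ord]
    for (g in seq_along(groups)) {
      cl <- deletion_cluster(rem[groups[[g]]$idx, , drop = FALSE],
                             id = sprintf("%s_t%d", component$id, g))
      tumor_clusters[[length(tumor_clusters) + 1L]] <- cl
      copy_of[cl$id] <- groups[[g]]$copy
    }
  }
  discarded <- sort(rem$id[best_lab == 0L])

  structure(list(
    component_id = component$id,
    normal_cluster_id = normal_cluster$id,
    refined_normal = cprime,
    support_ids = support,
    tumor_clusters = tumor_clusters,
    copy_of = copy_of,
    normal_concordant_ids = component$concordant_ids,
    tumor_concordant_ids = character(0),
    discarded_ids = discarded,
    n_discarded = length(discarded),
    status = if (timed_out) "time_limited" else "optimal"
  ), class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf(
    "assignment_result %s: |S|=%d, %d tumor cluster(s), |D|=%d (%s)\n",
    x$component_id, length(x$support_ids), length(x$tumor_clusters),
    x$n_discarded, x$status))
  invisible(x)
}

#' Refinement ratios of a normal deletion cluster
#'
#' Compares a normal cluster before and after supporting tumor mappings
#' were added: the ratio of the deletion-size range widths
#' (`del_max - del_min`) and the ratio of the breakpoint-region lengths,
#' both after/before. Member addition can only shrink both, so the ratios
#' lie in `(0, 1]`; a degenerate zero-width range before refinement yields
#' a ratio of 1.
#'
#' @param cluster Cluster before refinement.
#' @param refined Cluster after refinement (superset of members).
#' @return Named numeric vector `c(del_ratio, br_ratio)`.
#' @export
refinement_ratios <- function(cluster, refined) {
  stopifnot(inherits(cluster, "deletion_cluster"),
            inherits(refined, "deletion_cluster"))
  if (!all(cluster$members %in% refined$members))
    stop("`refined` must contain all members of `cluster`")
  w0 <- cluster$del_max - cluster$del_min
  w1 <- refined$del_max - refined$del_min
  b0 <- cluster$br[2] - cluster$br[1]
  b1 <- refined$br[2] - refined$br[1]
  c(del_ratio = if (w0 == 0) 1 else w1 / w0,
    br_ratio = if (b0 == 0) 1 else b1 / b0)
}
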