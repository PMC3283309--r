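# Independent oracles: brute-force enumerations and a direct placement
# check, kept deliberately naive and separate from the package internals.

# Validity of a mapping subset, recomputed directly from the definition.
oracle_valid <- function(rows) {
  br_s <- max(rows$left_end)
  br_e <- min(rows$right_start)
  d_lo <- max(rows$span_len) - attr(rows, "max_len")
  d_hi <- min(rows$span_len) - attr(rows, "min_len")
  br_e > br_s && d_lo <= d_hi && d_lo <= br_e - br_s
}

with_lib <- function(rows, lib) {
  attr(rows, "max_len") <- lib$max_len
  attr(rows, "min_len") <- lib$min_len
  rows
}

# All inclusion-maximal valid subsets by exhaustive enumeration (n <= ~14).
oracle_maximal_clusters <- function(rows, lib) {
  n <- nrow(rows)
  rows <- with_lib(rows, lib)
  valid_mask <- logical(2^n)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
    valid_mask[mask + 1] <- oracle_valid(rows[idx, , drop = FALSE])
  }
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    if (!valid_mask[mask + 1]) next
    maximal <- TRUE
    for (b in 0:(n - 1)) {
      if (bitwAnd(mask, bitwShiftL(1L, b)) == 0 &&
          valid_mask[bitwOr(mask, bitwShiftL(1L, b)) + 1]) {
        maximal <- FALSE
        break
      }
    }
    if (maximal) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
      out[[length(out) + 1L]] <- sort(rows$id[idx])
    }
  }
  out
}

# Direct placement check: a node set is consistent iff every cluster can
# place an interval of its demand inside its breakpoint region avoiding
# every other node's blocked positions (position-by-position occupancy).
oracle_consistent_placement <- function(nodes, idx = seq_len(nrow(nodes))) {
  for (i in idx) {
    if (nodes$demand[i] <= 0) next
    s <- nodes$br_start[i]
    e <- nodes$br_end[i]
    d <- nodes$demand[i]
    if (e - s < d) return(FALSE)
    occ <- rep(FALSE, e - s)
    for (j in setdiff(idx, i)) {
      if (nodes$chrom[j] != nodes$chrom[i]) next
      a <- max(nodes$blocked_start[j], s) - s
      b <- min(nodes$blocked_end[j], e) - s
      if (b > a) occ[(a + 1):b] <- TRUE
    }
    runs <- rle(occ)
    if (!any(!runs$values & runs$lengths >= d)) return(FALSE)
  }
  TRUE
}

# All minimal conflicting subsets (any size) by exhaustive enumeration,
# using conflict monotonicity to skip supersets of known conflicts.
oracle_minimal_conflicts <- function(nodes,
                                     consist = function(idx)
                                       is_consistent_haploid(nodes, idx)) {
  n <- nrow(nodes)
  bits <- bitwShiftL(1L, 0:(n - 1))
  conflicted <- logical(2^n)
  masks <- order(vapply(0:(2^n - 1), function(m) sum(bitwAnd(m, bits) > 0),
                        numeric(1)))
  minimal <- list()
  for (mask in (masks - 1L)) {
    if (mask == 0) next
    idx <- which(bitwAnd(mask, bits) > 0)
    sub_confl <- FALSE
    for (b in idx) {
      if (conflicted[bitwAnd(mask, bitwNot(bits[b])) + 1]) {
        sub_confl <- TRUE
        break
      }
    }
    if (sub_confl) {
      conflicted[mask + 1] <- TRUE
    } else if (!consist(idx)) {
      conflicted[mask + 1] <- TRUE
      minimal[[length(minimal) + 1L]] <- idx
    }
  }
  minimal
}

# Exhaustive two-copy assignment: TRUE iff some bipartition of the nodes
# is haploid-consistent on both sides.
oracle_diploid_consistent <- function(nodes) {
  n <- nrow(nodes)
  if (n == 0) return(TRUE)
  for (mask in 0:(2^(n - 1) - 1)) {  # node 1 fixed on side A
    side_a <- c(1L, which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2))) > 0) + 1L)
    side_b <- setdiff(seq_len(n), side_a)
    if (is_consistent_haploid(nodes, side_a) &&
        is_consistent_haploid(nodes, side_b)) {
      return(TRUE)
    }
  }
  FALSE
}

# --- exhaustive four-copy assignment oracle -------------------------------
# Minimal number of discarded mappings over all partitions of the
# remaining tumor mappings into labelled clusters on two tumor copies
# (copy 1 also carries the refined normal cluster). Group validity is
# enforced at insertion (exact, since validity is hereditary); per-copy
# consistency is checked at complete assignments with its own gap scan.

oracle_max_gap <- function(s, e, bs, be) {
  if (e <= s) return(0)
  keep <- be > s & bs < e
  bs <- pmax(bs[keep], s)
  be <- pmin(be[keep], e)
  if (!length(bs)) return(e - s)
  o <- order(bs)
  bs <- bs[o]
  be <- be[o]
  gap <- bs[1] - s
  reach <- be[1]
  for (i in seq_along(bs)[-1]) {
    if (bs[i] > reach) gap <- max(gap, bs[i] - reach)
    reach <- max(reach, be[i])
  }
  max(gap, e - reach)
}

oracle_min_discards <- function(cprime, rem_rows) {
  n <- nrow(rem_rows)
  if (n == 0) return(0L)
  brs <- rem_rows$br_start; bre <- rem_rows$br_end
  dmin <- rem_rows$del_min; dmax <- rem_rows$del_max
  ss <- rem_rows$span_start; se <- rem_rows$span_end
  cp <- list(brs = cprime$br[1], bre = cprime$br[2], dmin = cprime$del_min,
             hs = cprime$span_hull[1], he = cprime$span_hull[2])
  best <- n

  copy_ok <- function(groups, copy) {
    sel <- Filter(function(g) g$copy == copy, groups)
    demands <- vapply(sel, function(g) max(dmin[g$idx]), numeric(1))
    br_s <- vapply(sel, function(g) max(brs[g$idx]), numeric(1))
    br_e <- vapply(sel, function(g) min(bre[g$idx]), numeric(1))
    h_s <- vapply(sel, function(g) min(ss[g$idx]), numeric(1))
    h_e <- vapply(sel, function(g) max(se[g$idx]), numeric(1))
    if (copy == 1) {
      demands <- c(cp$dmin, demands)
      br_s <- c(cp$brs, br_s)
      br_e <- c(cp$bre, br_e)
      h_s <- c(cp$hs, h_s)
      h_e <- c(cp$he, h_e)
    }
    for (i in seq_along(demands)) {
      if (oracle_max_gap(br_s[i], br_e[i], h_s[-i], h_e[-i]) < demands[i])
        return(FALSE)
    }
    TRUE
  }
  group_valid <- function(idx) {
    b_s <- max(brs[idx]); b_e <- min(bre[idx]); d <- max(dmin[idx])
    b_e > b_s && d <= min(dmax[idx]) && d <= b_e - b_s
  }

  rec <- function(i, groups, discards) {
    if (discards >= best) return()
    if (i > n) {
      if (copy_ok(groups, 1) && copy_ok(groups, 2)) best <<- discards
      return()
    }
    for (g in seq_along(groups)) {
      idx2 <- c(groups[[g]]$idx, i)
      if (!group_valid(idx2)) next
      g2 <- groups
      g2[[g]]$idx <- idx2
      rec(i + 1L, g2, discards)
    }
    for (copy in 1:2) {
      rec(i + 1L, c(groups, list(list(idx = i, copy = copy))), discards)
    }
    rec(i + 1L, groups, discards + 1L)
  }
  rec(1L, list(), 0L)
  best
}
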