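# Simulator of matched normal/tumor paired-end mapping data.
#
# The generator implements the generative assumptions of the analysis
# model: a diploid normal genome with heterozygous germline deletions on
# one copy, a diploid tumor genome derived from the normal copies plus
# heterozygous tumor-specific deletions, and a tumor *sample* that is a
# mixture of tumor and normal cells (four chromosome copies). Fragments
# are drawn per copy; a fragment whose reads map contiguously but whose
# inner gap spans a deletion yields a deletion-indicating mapping with its
# span stretched by the deleted bases. Mapping itself is simulated
# (coordinates computed from the ground truth), not re-aligned.

#' Simulation parameters
#'
#' Defaults describe a desk-scale matched pair: a 1 Mb reference, ten
#' germline (normal) deletions and five tumor-specific deletions of a few
#' hundred bases, an Illumina-like fragment library (mean 200 bp, sd
#' 20 bp, 50 bp reads), 15-fold physical coverage per sample, and a tumor
#' sample contaminated with 30% normal cells.
#'
#' @param ref_length Reference chromosome length (bases).
#' @param n_normal_deletions,n_tumor_deletions Number of germline /
#'   tumor-specific heterozygous deletions to plant.
#' @param deletion_size_range Min/max deletion size (bases).
#' @param frag_mean,frag_sd Fragment (insert) length distribution, bases;
#'   lengths are Normal draws truncated below at `2 * read_len`.
#' @param read_len Read length (bases).
#' @param coverage_normal,coverage_tumor Physical coverage (fold) of each
#'   sample.
#' @param contamination Fraction of normal cells in the tumor sample, in
#'   `[0, 1]`.
#' @param proximity_bias Probability that a tumor-specific deletion is
#'   planted next to a (still unpaired) normal deletion rather than in an
#'   empty region. The analysis targets exactly such nearby deletions, so
#'   the default is 1.
#' @param min_separation Minimum distance between planted deletions not
#'   deliberately paired (bases); keeps overlapping components disjoint.
#' @param chrom Chromosome name used in the output.
#' @param quality Mapping quality attached to every simulated pair.
#' @param seed RNG seed; the whole data set is reproducible from it.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(ref_length = 1e6,
                              n_normal_deletions = 10,
                              n_tumor_deletions = 5,
                              deletion_size_range = c(200, 1000),
                              frag_mean = 200, frag_sd = 20, read_len = 50,
                              coverage_normal = 15, coverage_tumor = 15,
                              contamination = 0.3,
                              proximity_bias = 1,
                              min_separation = 4000,
                              chrom = "chr1",
                              quality = 37,
                              seed = 1) {
  p <- list(ref_length = ref_length,
            n_normal_deletions = as.integer(n_normal_deletions),
            n_tumor_deletions = as.integer(n_tumor_deletions),
            deletion_size_range = deletion_size_range,
            frag_mean = frag_mean, frag_sd = frag_sd, read_len = read_len,
            coverage_normal = coverage_normal, coverage_tumor = coverage_tumor,
            contamination = contamination, proximity_bias = proximity_bias,
            min_separation = min_separation, chrom = chrom,
            quality = quality, seed = as.integer(seed))
  with(p, {
    stopifnot(ref_length > 0, n_normal_deletions >= 0, n_tumor_deletions >= 0,
              length(deletion_size_range) == 2,
              deletion_size_range[1] > 0,
              deletion_size_range[1] <= deletion_size_range[2],
              frag_mean > 2 * read_len, frag_sd >= 0, read_len > 0,
              coverage_normal > 0, coverage_tumor > 0,
              contamination >= 0, contamination <= 1,
              proximity_bias >= 0, proximity_bias <= 1,
              min_separation > 0)
  })
  structure(p, class = "simulation_params")
}

# Plant `n` non-overlapping deletions with the given minimum separation in
# [margin, ref_length - margin). Returns data.frame(start, end, size).
.plant_deletions <- function(n, sizes, ref_length, min_separation, margin) {
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0),
                                size = numeric(0)))
  usable <- ref_length - 2 * margin
  slack <- usable - sum(sizes) - (n - 1) * min_separation
  if (slack < 0) stop("infeasible packing: deletions do not fit the reference")
  cuts <- sort(stats::runif(n))
  extra <- floor(slack * diff(c(0, cuts)))
  start <- numeric(n)
  pos <- margin
  for (i in seq_len(n)) {
    pos <- pos + extra[i]
    start[i] <- pos
    pos <- pos + sizes[i] + min_separation
  }
  data.frame(start = start, end = start + sizes, size = sizes)
}

# Fragments from one chromosome copy carrying `dels` (sorted, disjoint).
# Returns a data.frame of mappings in reference coordinates; fragments with
# a read straddling a breakpoint are dropped (they would not map).
.copy_fragments <- function(n, dels, p) {
  if (n == 0) return(NULL)
  del_sizes <- dels$size
  copy_len <- p$ref_length - sum(del_sizes)
  fl <- pmax(round(stats::rnorm(n, p$frag_mean, p$frag_sd)), 2 * p$read_len)
  s <- floor(stats::runif(n, 0, pmax(copy_len - fl, 1)))
  # donor coordinates of the deletion breakpoints and cumulative shifts
  if (nrow(dels)) {
    csum <- cumsum(del_sizes)
    dp <- dels$start - c(0, csum[-length(csum)])
    shift <- function(x) c(0, csum)[findInterval(x, dp) + 1L]
    count_le <- function(x) findInterval(x, dp)
  } else {
    shift <- function(x) numeric(length(x))
    count_le <- function(x) integer(length(x))
  }
  rl <- p$read_len
  rs <- s + fl - rl
  split_left <- count_le(s + rl - 1) - count_le(s) > 0
  split_right <- count_le(s + fl - 1) - count_le(rs) > 0
  keep <- !(split_left | split_right)
  s <- s[keep]; fl <- fl[keep]; rs <- rs[keep]
  if (!length(s)) return(NULL)
  data.frame(
    left_start = s + shift(s), left_end = s + shift(s) + rl,
    right_start = rs + shift(rs), right_end = rs + shift(rs) + rl,
    spanned = shift(rs) - shift(s),
    frag_len = fl
  )
}

#' Simulate a matched normal/tumor mapping data set with ground truth
#'
#' Plants heterozygous germline deletions on one normal chromosome copy and
#' heterozygous tumor-specific deletions on the tumor copies (next to a
#' germline deletion with probability `proximity_bias`, on the tumor copy
#' derived from the deletion-free normal copy so the local configuration
#' stays consistent by construction). Draws fragments per copy at the
#' requested physical coverages; the tumor sample mixes tumor- and
#' normal-cell fragments according to `contamination`. Fully reproducible
#' from `params$seed`.
#'
#' @param params A [simulation_params] object.
#' @return List with `normal` and `tumor` (mapping `data.frame`s as from
#'   [paired_mappings()], with an extra `origin` column naming the source
#'   genome copy) and `truth`: per-copy deletion tables (`normal_copy1`,
#'   `normal_copy2`, `tumor_copy1`, `tumor_copy2`), the `normal_deletions`
#'   and `tumor_specific` tables (the latter with its copy), and the
#'   parameters.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)
  szr <- p$deletion_size_range
  # keep every deletion (and its proximal neighbour) clear of the ends
  margin <- 5 * p$frag_mean + szr[2] + 100

  nd <- .plant_deletions(
    p$n_normal_deletions,
    sizes = floor(stats::runif(p$n_normal_deletions, szr[1], szr[2] + 1)),
    ref_length = p$ref_length, min_separation = p$min_separation,
    margin = margin)

  # Tumor-specific deletions: proximal ones sit next to an unpaired normal
  # deletion at a gap small enough that their discordant mappings overlap
  # the normal cluster, on tumor copy 1 (derived from the deletion-free
  # normal copy). Distal ones go to a random copy, far from everything.
  td <- data.frame(start = numeric(0), end = numeric(0), size = numeric(0),
                   copy = integer(0), proximal = logical(0))
  unused <- seq_len(nrow(nd))
  inner_gap <- p$frag_mean - 2 * p$read_len
  all_dels <- nd
  for (i in seq_len(p$n_tumor_deletions)) {
    size <- floor(stats::runif(1, szr[1], szr[2] + 1))
    proximal <- length(unused) > 0 && stats::runif(1) < p$proximity_bias
    placed <- FALSE
    if (proximal) {
      pick <- if (length(unused) == 1) unused else sample(unused, 1)
      unused <- setdiff(unused, pick)
      gap_lo <- max(10, round(inner_gap / 4))
      gap_hi <- max(gap_lo + 5, round(0.8 * inner_gap))
      gap <- sample(seq(gap_lo, gap_hi), 1)
      side <- sample(c("left", "right"), 1)
      start <- if (side == "right") nd$end[pick] + gap else nd$start[pick] - gap - size
      td <- rbind(td, data.frame(start = start, end = start + size, size = size,
                                 copy = 1L, proximal = TRUE))
      placed <- TRUE
    }
    if (!placed) {
      for (try in seq_len(1000)) {
        start <- floor(stats::runif(1, margin, p$ref_length - margin - size))
        ok <- !any(start - p$min_separation < all_dels$end &
                     all_dels$start < start + size + p$min_separation)
        if (ok) {
          td <- rbind(td, data.frame(start = start, end = start + size,
                                     size = size,
                                     copy = sample(1:2, 1), proximal = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible packing: could not place tumor deletion")
    }
    all_dels <- rbind(all_dels[, c("start", "end", "size")],
                      td[nrow(td), c("start", "end", "size")])
  }

  sort_dels <- function(d) d[order(d$start), , drop = FALSE]
  copies <- list(
    normal_copy1 = sort_dels(nd[0, c("start", "end", "size")]),
    normal_copy2 = sort_dels(nd[, c("start", "end", "size")]),
    tumor_copy1 = sort_dels(td[td$copy == 1L, c("start", "end", "size")]),
    tumor_copy2 = sort_dels(rbind(nd[, c("start", "end", "size")],
                                  td[td$copy == 2L, c("start", "end", "size")]))
  )

  make_sample <- function(counts, copy_names, prefix) {
    parts <- list()
    for (k in seq_along(copy_names)) {
      frag <- .copy_fragments(counts[k], copies[[copy_names[k]]], p)
      if (!is.null(frag)) {
        frag$origin <- copy_names[k]
        parts[[length(parts) + 1L]] <- frag
      }
    }
    if (!length(parts)) {
      m <- empty_mappings()
      m$origin <- character(0)
      return(list(mappings = m, frag_range = c(NA_real_, NA_real_)))
    }
    df <- do.call(rbind, parts)
    df <- df[order(df$left_start, df$right_start), , drop = FALSE]
    m <- paired_mappings(
      id = sprintf("%s%06d", prefix, seq_len(nrow(df))),
      chrom = p$chrom,
      left_start = df$left_start, left_end = df$left_end, left_orient = "+",
      right_start = df$right_start, right_end = df$right_end,
      right_orient = "-",
      quality = p$quality)
    m$origin <- df$origin
    list(mappings = m, frag_range = range(df$frag_len))
  }

  n_frag_normal <- round(p$coverage_normal * p$ref_length / p$frag_mean)
  n_frag_tumor <- round(p$coverage_tumor * p$ref_length / p$frag_mean)
  from_copy1 <- stats::rbinom(1, n_frag_normal, 0.5)
  normal_counts <- c(from_copy1, n_frag_normal - from_copy1)
  from_normal <- stats::rbinom(1, n_frag_tumor, p$contamination)
  t_n1 <- stats::rbinom(1, from_normal, 0.5)
  t_t1 <- stats::rbinom(1, n_frag_tumor - from_normal, 0.5)
  tumor_counts <- c(t_n1, from_normal - t_n1,
                    t_t1, n_frag_tumor - from_normal - t_t1)

  normal <- make_sample(normal_counts, c("normal_copy1", "normal_copy2"), "n")
  tumor <- make_sample(tumor_counts,
                       c("normal_copy1", "normal_copy2",
                         "tumor_copy1", "tumor_copy2"), "t")

  list(
    normal = normal$mappings,
    tumor = tumor$mappings,
    truth = c(copies, list(
      normal_deletions = sort_dels(nd),
      tumor_specific = sort_dels(td),
      # true fragment-length extremes per sample; using them as cutoffs
      # classifies every simulated mapping exactly (noise-free analysis)
      frag_range_normal = normal$frag_range,
      frag_range_tumor = tumor$frag_range,
      params = p
    ))
  )
}

#' Evaluate recovery of planted deletions from assignment results
#'
#' A planted tumor-specific deletion counts as recovered when some called
#' tumor-specific cluster has a breakpoint region overlapping the truth
#' interval and a deletion-size range covering the truth size.
#'
#' @param truth Truth list from [simulate_dataset()].
#' @param results List of `assignment_result` objects from
#'   [assign_component()] (or `pipeline$assignments`).
#' @return List with `recovery` (fraction of planted tumor-specific
#'   deletions recovered), `discarded_fraction` (discarded mappings over
#'   all component deletion mappings), `refined_fraction` (components
#'   whose normal cluster gained supporting tumor mappings),
#'   `n_tumor_specific_called`, and `n_components`.
#' @export
evaluate_recovery <- function(truth, results) {
  called <- unlist(lapply(results, function(r) r$tumor_clusters),
                   recursive = FALSE)
  ts <- truth$tumor_specific
  recovered <- if (nrow(ts)) {
    vapply(seq_len(nrow(ts)), function(i) {
      any(vapply(called, function(cl) {
        intervals_overlap(cl$br[1], cl$br[2], ts$start[i], ts$end[i]) &&
          cl$del_min <= ts$size[i] && ts$size[i] <= cl$del_max
      }, logical(1)))
    }, logical(1))
  } else {
    logical(0)
  }
  n_del <- sum(vapply(results, function(r) {
    length(r$support_ids) + length(r$discarded_ids) +
      sum(vapply(r$tumor_clusters, function(cl)
        length(setdiff(cl$members, r$support_ids)), numeric(1)))
  }, numeric(1)))
  n_disc <- sum(vapply(results, function(r) r$n_discarded, numeric(1)))
  list(
    recovery = if (length(recovered)) mean(recovered) else NA_real_,
    discarded_fraction = if (n_del > 0) n_disc / n_del else 0,
    refined_fraction = if (length(results)) {
      mean(vapply(results, function(r) length(r$support_ids) > 0, logical(1)))
    } else {
      NA_real_
    },
    n_tumor_specific_called = length(called),
    n_components = length(results)
  )
}
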