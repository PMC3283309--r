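# Fixture builders. All coordinates 0-based half-open; default library
# cutoffs lib(100, 200) keep the arithmetic easy to check by hand.

lib100 <- library_stats(100, 200)

# One mapping from its span and read length(s).
mk_map <- function(id, span_start, span_end, read_len = 20, chrom = "chr1",
                   quality = 37, left_orient = "+", right_orient = "-",
                   source = NA_character_) {
  paired_mappings(id, chrom,
                  left_start = span_start, left_end = span_start + read_len,
                  left_orient = left_orient,
                  right_start = span_end - read_len, right_end = span_end,
                  right_orient = right_orient,
                  quality = quality, source = source)
}

# Several mappings from a spans matrix/list; annotated.
mk_maps <- function(spans, lib = lib100, read_len = 20, ...) {
  rows <- do.call(rbind, lapply(seq_along(spans), function(i) {
    mk_map(sprintf("m%02d", i), spans[[i]][1], spans[[i]][2],
           read_len = read_len, ...)
  }))
  annotate_mappings(rows, lib)
}

# Mapping with explicit breakpoint region and deletion-size minimum:
# br = [br_start, br_start + br_len), span extends read_len both sides,
# span length = br_len + 2 * read_len, so del_min = br_len + 2*read_len -
# max_len under `lib`.
mk_map_br <- function(id, br_start, br_len, read_len = 30, lib = lib100,
                      chrom = "chr1") {
  mk_map(id, br_start - read_len, br_start + br_len + read_len,
         read_len = read_len, chrom = chrom)
}

# Random deletion-indicating mappings packed into a window, annotated.
rand_del_rows <- function(n, lib = lib100, window = 2000, origin = 0,
                          span_extra_max = 400, read_len_max = 40,
                          chrom = "chr1") {
  span_len <- lib$max_len + sample.int(span_extra_max, n, replace = TRUE)
  start <- origin + sample.int(max(window - max(span_len), 1), n, replace = TRUE)
  rl <- pmin(sample.int(read_len_max, n, replace = TRUE) + 5,
             floor((span_len - 1) / 2))
  m <- paired_mappings(
    id = sprintf("r%03d", seq_len(n)), chrom = chrom,
    left_start = start, left_end = start + rl, left_orient = "+",
    right_start = start + span_len - rl, right_end = start + span_len,
    right_orient = "-", quality = 37)
  annotate_mappings(m, lib)
}

# Random set of valid deletion clusters (1-3 member mappings each) in a
# shared window, as cluster objects. Wide spans relative to the window
# make pair- and chain-squeezes (minimal conflicts of both sizes) common.
rand_clusters <- function(k, lib = lib100, window = 2500, span_extra_max = 500,
                          chrom = "chr1") {
  clusters <- list()
  for (i in seq_len(k)) {
    repeat {
      n_mem <- sample(1:3, 1)
      rows <- rand_del_rows(n_mem, lib = lib, window = window,
                            span_extra_max = span_extra_max, chrom = chrom)
      rows$id <- sprintf("c%02d_%s", i, rows$id)
      if (is_valid_cluster(rows)) break
    }
    clusters[[i]] <- deletion_cluster(rows, id = sprintf("cl%02d", i))
  }
  clusters
}

# Random concordant mappings in a window, annotated.
rand_conc_rows <- function(n, lib = lib100, window = 2500, chrom = "chr1") {
  if (n == 0) {
    return(annotate_mappings(mk_map("q000", 0, 150)[0, , drop = FALSE], lib))
  }
  span_len <- lib$min_len +
    sample.int(lib$max_len - lib$min_len + 1, n, replace = TRUE) - 1L
  start <- sample.int(max(window - max(span_len), 1), n, replace = TRUE)
  rl <- pmin(20L, floor(span_len / 2))
  m <- paired_mappings(
    id = sprintf("q%03d", seq_len(n)), chrom = chrom,
    left_start = start, left_end = start + rl, left_orient = "+",
    right_start = start + span_len - rl, right_end = start + span_len,
    right_orient = "-", quality = 37)
  annotate_mappings(m, lib)
}

# Mappings that all span one common deletion; retried until jointly valid.
rand_valid_cluster_rows <- function(n, lib = lib100, chrom = "chr1") {
  repeat {
    nd_s <- 1000
    nd_e <- nd_s + sample(210:500, 1)
    rl <- 30
    rows <- do.call(rbind, lapply(seq_len(n), function(i) {
      le <- nd_s - sample(10:120, 1)
      rs <- nd_e + sample(10:120, 1)
      mk_map(sprintf("v%02d", i), le - rl, rs + rl, read_len = rl,
             chrom = chrom)
    }))
    rows <- annotate_mappings(rows, lib)
    if (all(rows$class == "deletion") && is_valid_cluster(rows)) return(rows)
  }
}

# Three mappings that are pairwise compatible but jointly invalid: the
# widest mapping's deletion minimum exceeds the narrow breakpoint-region
# intersection contributed by the other two.
triple_pairwise_only <- function(lib = lib100) {
  m1 <- mk_map("m1", 55, 465, read_len = 5)    # del [210, 310], br [60, 460)
  m2 <- mk_map("m2", 0, 320, read_len = 10)    # del [120, 220], br [10, 310)
  m3 <- mk_map("m3", 150, 470, read_len = 10)  # del [120, 220], br [160, 460)
  annotate_mappings(rbind(m1, m2, m3), lib)
}

# Random tumor component around one normal deletion cluster for the
# four-copy assignment: a mixture of supporting mappings, nearby
# tumor-deletion mappings, and adversarial wide mappings.
rand_component <- function(n_tumor, lib = lib100, chrom = "chr1") {
  rl <- 30
  nd_s <- 2500
  nd_len <- sample(150:500, 1)
  nd_e <- nd_s + nd_len
  span_nd <- function(id) {
    le <- nd_s - sample(10:120, 1)   # left read end
    rs <- nd_e + sample(10:120, 1)   # right read start
    mk_map(id, le - rl, rs + rl, read_len = rl, chrom = chrom)
  }
  normal_rows <- annotate_mappings(
    rbind(span_nd("nm1"), span_nd("nm2")), lib)
  if (!is_valid_cluster(normal_rows)) {
    normal_rows <- normal_rows[1, , drop = FALSE]
  }
  cl <- deletion_cluster(normal_rows, id = "cN")

  tumor <- list()
  for (i in seq_len(n_tumor)) {
    id <- sprintf("t%02d", i)
    kind <- sample(c("support", "nearby", "adversarial"), 1,
                   prob = c(0.35, 0.45, 0.2))
    tumor[[i]] <- switch(kind,
      support = span_nd(id),
      nearby = {
        off <- sample(c(-1, 1), 1) * sample(50:400, 1)
        sz <- sample(150:500, 1)
        ds <- if (off > 0) nd_e + off else nd_s + off - sz
        le <- ds - sample(10:120, 1)
        rs <- ds + sz + sample(10:120, 1)
        mk_map(id, le - rl, rs + rl, read_len = rl, chrom = chrom)
      },
      adversarial = {
        br_len <- sample(200:900, 1)
        bs <- nd_s + sample(-700:700, 1)
        mk_map(id, bs - rl, bs + br_len + rl, read_len = rl, chrom = chrom)
      })
  }
  trows <- annotate_mappings(do.call(rbind, tumor), lib)
  trows <- trows[trows$class == "deletion", , drop = FALSE]
  comp <- list(id = "compX", normal_cluster_id = cl$id,
               deletion_ids = sort(trows$id), concordant_ids = character(0),
               footprint = c(min(trows$span_start, cl$span_hull[1]),
                             max(trows$span_end, cl$span_hull[2])))
  list(cluster = cl, tumor = trows, component = comp)
}
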