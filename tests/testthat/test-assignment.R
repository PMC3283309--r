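test_that("overlapping components grow transitively and drop collisions", {
  # normal cluster around a deletion at [1070, 1380)
  nrows <- mk_maps(list(c(1000, 1420), c(1050, 1400)), chrom = "chr1")
  for (i in seq_len(nrow(nrows))) nrows$source[i] <- "normal"
  cl <- deletion_cluster(nrows, id = "cN")

  tumor <- mk_maps(list(
    c(1100, 1500),   # span overlaps br directly
    c(1350, 1800),   # overlaps br directly
    c(1650, 2100),   # overlaps the previous mapping only (indirect)
    c(9000, 9400)    # far away: in no component
  ), chrom = "chr1")
  tumor$source <- "tumor"

  res <- build_components(list(cl), tumor)
  expect_length(res$components, 1)
  expect_equal(res$components[[1]]$deletion_ids, c("m01", "m02", "m03"))

  # two normal clusters whose growing components share a mapping: dropped
  cl2 <- deletion_cluster(mk_maps(list(c(1900, 2350)), chrom = "chr1"),
                          id = "cN2")
  res2 <- build_components(list(cl, cl2), tumor)
  expect_length(res2$components, 0)
  expect_setequal(res2$dropped$normal_cluster_id, c("cN", "cN2"))
})

test_that("maximum supporting subset is maximal and tie-broken by id", {
  c0 <- deletion_cluster(mk_maps(list(c(1000, 1420), c(1050, 1400))), id = "c")
  # m_a compatible; m_b's del_min (480) exceeds c's del_max (250)
  cand <- mk_maps(list(c(1020, 1430), c(1010, 1690)))
  cand$id <- c("m_a", "m_b")
  expect_equal(max_supporting_subset(c0, cand), "m_a")
  expect_equal(max_supporting_subset(c0, cand[0, , drop = FALSE]), character(0))
  # all jointly compatible: everything supports
  all_ok <- mk_maps(list(c(1020, 1430), c(1030, 1440), c(990, 1410)))
  expect_equal(max_supporting_subset(c0, all_ok), c("m01", "m02", "m03"))

  set.seed(1009)
  joint_valid_with <- function(cl, rows) {
    br_s <- max(cl$br[1], rows$br_start)
    br_e <- min(cl$br[2], rows$br_end)
    d_lo <- max(cl$del_min, rows$del_min)
    d_hi <- min(cl$del_max, rows$del_max)
    br_e > br_s && d_lo <= d_hi && d_lo <= br_e - br_s
  }
  for (rep in 1:20) {
    inst <- rand_component(sample(2:6, 1))
    s <- max_supporting_subset(inst$cluster, inst$tumor)
    if (length(s)) {
      expect_true(joint_valid_with(
        inst$cluster, inst$tumor[inst$tumor$id %in% s, , drop = FALSE]))
    }
    # cardinality equals the brute-force maximum over all subsets
    n <- nrow(inst$tumor)
    best <- 0
    for (mask in seq_len(2^n) - 1) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
      if (length(idx) <= best) next
      if (joint_valid_with(inst$cluster, inst$tumor[idx, , drop = FALSE]))
        best <- length(idx)
    }
    expect_equal(length(s), best)
  }
})

test_that("assignment: full support, split over copies, forced discard", {
  c0 <- deletion_cluster(mk_maps(list(c(1000, 1420), c(1050, 1400))), id = "cN")

  # every tumor mapping supports the normal deletion: no tumor-specific
  # clusters, nothing discarded, the refinement shrinks the ranges
  tumor1 <- mk_maps(list(c(1020, 1430), c(1030, 1440)))
  tumor1$source <- "tumor"
  comp1 <- list(id = "k1", normal_cluster_id = "cN",
                deletion_ids = tumor1$id, concordant_ids = character(0),
                footprint = c(0, 2000))
  r1 <- assign_component(comp1, c0, tumor1)
  expect_length(r1$tumor_clusters, 0)
  expect_equal(r1$n_discarded, 0)
  expect_setequal(r1$support_ids, tumor1$id)
  rr <- refinement_ratios(c0, r1$refined_normal)
  expect_true(all(rr <= 1))
  expect_equal(r1$status, "optimal")

  # two wide mappings near each other but clear of c: mutually conflicting
  # (each blocks the other's breakpoint region) and mutually incompatible
  # (del_min 1200 > del_max 1150), yet each fits beside c'. One lands on
  # each tumor copy, nothing discarded.
  tumor2 <- annotate_mappings(rbind(
    mk_map("w1", 2000, 3400, read_len = 30),   # del [1200, 1300]
    mk_map("w2", 2040, 3290, read_len = 30)),  # del [1050, 1150]
    lib100)
  expect_false(pairwise_compatible(tumor2[1, ], tumor2[2, ]))
  comp2 <- list(id = "k2", normal_cluster_id = "cN",
                deletion_ids = c("w1", "w2"), concordant_ids = character(0),
                footprint = c(0, 3500))
  r2 <- assign_component(comp2, c0, tumor2)
  expect_length(r2$tumor_clusters, 2)
  expect_equal(r2$n_discarded, 0)
  expect_setequal(unname(r2$copy_of), c(1, 2))
  rem2 <- tumor2[!tumor2$id %in% r2$support_ids, , drop = FALSE]
  expect_equal(r2$n_discarded, oracle_min_discards(r2$refined_normal, rem2))

  # a third wide mapping conflicting with and incompatible to both leaves
  # no copy free: exactly one mapping is discarded, the exhaustive minimum
  tumor3 <- annotate_mappings(rbind(
    mk_map("w1", 2000, 3400, read_len = 30),
    mk_map("w2", 2040, 3290, read_len = 30),
    mk_map("w3", 2080, 3630, read_len = 30)),  # del [1350, 1450]
    lib100)
  comp3 <- list(id = "k3", normal_cluster_id = "cN",
                deletion_ids = c("w1", "w2", "w3"),
                concordant_ids = character(0), footprint = c(0, 3700))
  r3 <- assign_component(comp3, c0, tumor3)
  expect_equal(r3$n_discarded, 1)
  rem3 <- tumor3[!tumor3$id %in% r3$support_ids, , drop = FALSE]
  expect_equal(oracle_min_discards(r3$refined_normal, rem3), 1)

  expect_error(assign_component(comp1, c0, tumor1, time_limit = 0),
               "time_limit")
})

test_that("assignment result is sound and deterministic", {
  set.seed(2203)
  for (rep in 1:15) {
    inst <- rand_component(sample(2:6, 1))
    r <- assign_component(inst$component, inst$cluster, inst$tumor)
    # partition: support + cluster members + discarded = all deletion ids
    members <- unlist(lapply(r$tumor_clusters, function(cl)
      setdiff(cl$members, r$support_ids)))
    expect_setequal(c(r$support_ids, members, r$discarded_ids),
                    inst$component$deletion_ids)
    expect_equal(anyDuplicated(c(r$support_ids, members, r$discarded_ids)), 0)
    # every tumor cluster and the refined normal cluster are valid
    expect_true(r$refined_normal$valid)
    for (cl in r$tumor_clusters) expect_true(cl$valid)
    # per-copy haploid consistency including the refined normal on copy 1
    for (copy in 1:2) {
      on_copy <- r$tumor_clusters[
        vapply(r$tumor_clusters, function(cl)
          r$copy_of[[cl$id]] == copy, logical(1))]
      if (copy == 1) on_copy <- c(list(r$refined_normal), on_copy)
      nodes <- conflict_nodes(on_copy)
      expect_true(is_consistent_haploid(nodes))
    }
    # determinism
    r_again <- assign_component(inst$component, inst$cluster, inst$tumor)
    expect_identical(r, r_again)
  }
})

test_that("refinement ratios compare range widths after/before", {
  df <- data.frame(
    cluster_id = c("c", "cp"), chrom = "chr1",
    br_start = c(1020, 1060), br_end = c(1400, 1360),
    del_min = c(220, 237), del_max = c(320, 280),
    hull_start = 1000, hull_end = 1420, support = c(1, 3),
    source_mix = "", members = c("m1", "m1,m4,m5"),
    stringsAsFactors = FALSE)
  cls <- clusters_from_df(df)
  rr <- refinement_ratios(cls[[1]], cls[[2]])
  expect_equal(unname(rr["del_ratio"]), 43 / 100)
  expect_equal(unname(rr["br_ratio"]), 300 / 380)
  # identity refinement
  expect_equal(unname(refinement_ratios(cls[[1]], cls[[1]])), c(1, 1))
  expect_error(refinement_ratios(cls[[2]], cls[[1]]), "members")
})
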