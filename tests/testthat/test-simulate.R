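# Small parameter sets keep the simulator tests fast; coverage and
# reference length are scaled down from the defaults.
small_params <- function(...) {
  args <- list(ref_length = 2e5, n_normal_deletions = 3,
               n_tumor_deletions = 2, coverage_normal = 8,
               coverage_tumor = 8, min_separation = 3000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_params, args)
}

test_that("the same seed reproduces the data set byte for byte", {
  s1 <- simulate_dataset(small_params(seed = 5))
  s2 <- simulate_dataset(small_params(seed = 5))
  f1 <- withr::local_tempfile(fileext = ".esp")
  f2 <- withr::local_tempfile(fileext = ".esp")
  write_mappings(s1$tumor, f1)
  write_mappings(s2$tumor, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth$tumor_specific, s2$truth$tumor_specific)
  s3 <- simulate_dataset(small_params(seed = 6))
  expect_false(identical(s1$tumor, s3$tumor))
})

test_that("deletion-spanning pairs have span about fragment + deletion", {
  p <- simulation_params(ref_length = 3e5, n_normal_deletions = 1,
                         n_tumor_deletions = 0,
                         deletion_size_range = c(500, 500),
                         frag_mean = 300, frag_sd = 30, read_len = 50,
                         coverage_normal = 120, coverage_tumor = 1,
                         contamination = 0, seed = 8)
  sim <- simulate_dataset(p)
  spanning <- sim$normal[sim$normal$origin == "normal_copy2" &
                           sim$normal$right_end - sim$normal$left_start > 500, ]
  expect_gt(nrow(spanning), 20)
  spans <- spanning$right_end - spanning$left_start
  # longer fragments are more likely to span the breakpoint, so the mean
  # sits slightly above frag_mean + deletion; allow 3 SE plus that bias
  se <- sd(spans) / sqrt(length(spans))
  expect_lt(abs(mean(spans) - (300 + 500)), 3 * se + 6)
})

test_that("tumor-sample contamination mixes normal-cell fragments", {
  p <- simulation_params(ref_length = 4e5, n_normal_deletions = 2,
                         n_tumor_deletions = 1, coverage_tumor = 20,
                         coverage_normal = 5, contamination = 0.3, seed = 9)
  sim <- simulate_dataset(p)
  frac <- mean(startsWith(sim$tumor$origin, "normal"))
  n <- nrow(sim$tumor)
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / n) + 0.005)
})

test_that("degenerate mixtures and packing errors behave", {
  # contamination 0, no tumor deletions: tumor sample is structurally a
  # normal sample (all fragments from copies carrying only normal deletions)
  p <- small_params(seed = 10)
  p$contamination <- 0
  p$n_tumor_deletions <- 0L
  sim <- simulate_dataset(p)
  expect_equal(nrow(sim$truth$tumor_specific), 0)
  expect_true(all(sim$tumor$origin %in% c("tumor_copy1", "tumor_copy2")))
  expect_equal(sim$truth$tumor_copy2, sim$truth$normal_copy2,
               ignore_attr = TRUE)

  expect_error(
    simulate_dataset(simulation_params(ref_length = 2e4,
                                       n_normal_deletions = 30, seed = 1)),
    "infeasible packing")
})

test_that("planted deletions respect the inferred size bounds", {
  sim <- simulate_dataset(small_params(seed = 11, coverage_normal = 20))
  lib <- library_stats(sim$truth$frag_range_normal[1],
                       sim$truth$frag_range_normal[2])
  nm <- annotate_mappings(sim$normal, lib)
  res <- enumerate_maximal_valid_clusters(nm)
  nd <- sim$truth$normal_deletions
  matched <- 0
  for (i in seq_len(nrow(nd))) {
    for (cl in res$clusters) {
      if (cl$br[1] < nd$end[i] && nd$start[i] < cl$br[2]) {
        expect_lte(cl$del_min, nd$size[i])
        expect_gte(cl$del_max, nd$size[i])
        matched <- matched + 1
      }
    }
  }
  expect_gte(matched, nrow(nd))
})

test_that("recovery report flags planted deletions and negative controls", {
  # with no tumor-specific deletions the pipeline must call none
  p <- small_params(seed = 12, coverage_normal = 20, coverage_tumor = 20)
  p$n_tumor_deletions <- 0L
  sim <- simulate_dataset(p)
  libn <- library_stats(sim$truth$frag_range_normal[1],
                        sim$truth$frag_range_normal[2])
  libt <- library_stats(sim$truth$frag_range_tumor[1],
                        sim$truth$frag_range_tumor[2])
  res <- run_pipeline(sim$normal, sim$tumor,
                      lib_normal = libn, lib_tumor = libt)
  rep <- evaluate_recovery(sim$truth, res$assignments)
  expect_equal(rep$n_tumor_specific_called, 0)
  expect_true(is.na(rep$recovery))
  expect_equal(rep$discarded_fraction, 0)
})
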