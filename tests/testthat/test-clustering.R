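test_that("pairwise compatibility delegates to cluster validity", {
  m <- mk_maps(list(c(1000, 1420), c(1050, 1400), c(3000, 3420)))
  expect_true(pairwise_compatible(m[1, ], m[2, ]))
  # disjoint breakpoint regions
  expect_false(pairwise_compatible(m[1, ], m[3, ]))
  # idempotence
  expect_true(pairwise_compatible(m[1, ], m[1, ]))
})

test_that("maximal clusters on small crafted instances", {
  # two mutually compatible mappings: one cluster
  m <- mk_maps(list(c(1000, 1420), c(1050, 1400)))
  res <- enumerate_maximal_valid_clusters(m)
  expect_length(res$clusters, 1)
  expect_equal(res$clusters[[1]]$members, c("m01", "m02"))

  # three pairwise-incompatible mappings: three singletons
  m3 <- mk_maps(list(c(0, 300), c(5000, 5300), c(9000, 9300)))
  res3 <- enumerate_maximal_valid_clusters(m3)
  expect_length(res3$clusters, 3)
  expect_true(all(vapply(res3$clusters, function(cl) cl$support, numeric(1)) == 1))
})

test_that("a pairwise-compatible triple can be jointly invalid", {
  m <- triple_pairwise_only()
  expect_true(pairwise_compatible(m[1, ], m[2, ]))
  expect_true(pairwise_compatible(m[1, ], m[3, ]))
  expect_true(pairwise_compatible(m[2, ], m[3, ]))
  expect_false(is_valid_cluster(m))
  res <- enumerate_maximal_valid_clusters(m)
  got <- lapply(res$clusters, function(cl) cl$members)
  expect_equal(sort(vapply(got, paste, character(1), collapse = "+")),
               c("m1+m2", "m1+m3", "m2+m3"))
  # matches the exhaustive oracle
  expect_setequal(vapply(got, paste, character(1), collapse = "+"),
                  vapply(oracle_maximal_clusters(m, lib100),
                         paste, character(1), collapse = "+"))
})

test_that("enumeration equals exhaustive subset enumeration on random input", {
  set.seed(20121)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    rows <- rand_del_rows(n, window = sample(c(800, 1500, 2500), 1))
    res <- enumerate_maximal_valid_clusters(rows)
    got <- sort(vapply(res$clusters, function(cl)
      paste(cl$members, collapse = "+"), character(1)))
    want <- sort(vapply(oracle_maximal_clusters(rows, lib100),
                        paste, character(1), collapse = "+"))
    expect_equal(got, want)
    # every mapping appears in at least one cluster
    expect_setequal(unique(unlist(lapply(res$clusters, `[[`, "members"))),
                    rows$id)
  }
})

test_that("cluster output is invariant to input row order", {
  set.seed(77)
  rows <- rand_del_rows(8, window = 1200)
  a <- enumerate_maximal_valid_clusters(rows)
  b <- enumerate_maximal_valid_clusters(rows[sample(nrow(rows)), ])
  key <- function(res) sort(vapply(res$clusters, function(cl)
    paste(cl$members, collapse = "+"), character(1)))
  expect_equal(key(a), key(b))
})

test_that("per-chromosome cluster cap aborts only that chromosome", {
  set.seed(5)
  crowded <- rand_del_rows(14, window = 600, chrom = "chrA")
  lonely <- mk_maps(list(c(1000, 1420)), chrom = "chrB")
  rows <- rbind(crowded, lonely)
  expect_warning(res <- enumerate_maximal_valid_clusters(rows, max_clusters = 2),
                 "skipped")
  expect_equal(res$skipped$chrom, "chrA")
  expect_match(res$skipped$reason, "maximal clusters")
  expect_equal(vapply(res$clusters, function(cl) cl$chrom, character(1)), "chrB")
})
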