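chain3 <- function() {
  neighbor_set(data.frame(i = c(1, 2), j = c(2, 3),
                          distance = c(0.01, 0.02)), 3, 0.1)
}

test_that("MCC follows the formula with its zero-denominator conventions", {
  expect_equal(mcc(c(TP = 10, TN = 90, FP = 0, FN = 0)), 1)
  expect_equal(mcc(c(TP = 2, TN = 2, FP = 1, FN = 1)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(mcc(c(TP = 0, TN = 5, FP = 0, FN = 5)), 0)
  expect_equal(mcc(c(TP = 3, TN = 4, FP = 1, FN = 2)),
               (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6), tolerance = 1e-12)
})

test_that("a 3-item chain is optimally split into a pair and a singleton", {
  nb <- chain3()
  opt <- opticlust_partition(nb, 0.03)
  expect_equal(opt$mcc, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(opt$otu_of)), 2)
  bf <- brute_force_optimal(nb, 0.03)
  expect_equal(bf$mcc, 0.5, tolerance = 1e-12)
  # furthest-neighbor merges the closest pair first, leaving C alone
  cl <- complete_linkage_partition(nb, 0.03)
  expect_equal(cl$otu_of, c(1L, 1L, 2L))
})

test_that("degenerate instances cluster as expected", {
  all_in <- neighbor_set(data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                    distance = 0.01), 3, 0.1)
  p <- opticlust_partition(all_in, 0.03)
  expect_equal(length(unique(p$otu_of)), 1)
  expect_equal(p$mcc, 1)
  expect_equal(length(unique(complete_linkage_partition(all_in, 0.03)$otu_of)), 1)

  none <- neighbor_set(data.frame(i = integer(), j = integer(),
                                  distance = numeric()), 4, 0.1)
  p0 <- opticlust_partition(none, 0.03)
  expect_equal(p0$otu_of, 1:4)
  expect_equal(unname(p0$confusion[c("FP", "FN")]), c(0, 0))
  expect_equal(p0$mcc, 1)
  expect_equal(complete_linkage_partition(none, 0.03)$otu_of, 1:4)
  expect_equal(brute_force_optimal(none, 0.03)$otu_of, 1:4)

  two_pairs <- neighbor_set(data.frame(i = c(1, 3), j = c(2, 4),
                                       distance = 0.01), 4, 0.1)
  bf <- brute_force_optimal(two_pairs, 0.03)
  expect_equal(bf$otu_of, c(1L, 1L, 2L, 2L))
  expect_equal(bf$mcc, 1)
})

test_that("pairs exactly at the threshold are merged", {
  nb <- neighbor_set(data.frame(i = 1, j = 2, distance = 0.03), 2, 0.1)
  expect_equal(length(unique(opticlust_partition(nb, 0.03)$otu_of)), 1)
  expect_equal(length(unique(complete_linkage_partition(nb, 0.03)$otu_of)), 1)
})

test_that("thresholds above the neighbor set's cutoff are refused", {
  expect_error(opticlust_partition(chain3(), 0.2), "configuration error")
})

test_that("the iterative clusterer never beats the exhaustive optimum", {
  worse <- 0L
  for (seed in 1:40) {
    nb <- random_instance(6, 0.03, seed)
    opt <- opticlust_partition(nb, 0.03, seed = seed, restarts = 2)
    bf <- brute_force_optimal(nb, 0.03)
    expect_lte(opt$mcc, bf$mcc + 1e-9)
    if (opt$mcc < bf$mcc - 1e-9) worse <- worse + 1L
  }
  expect_lte(worse, 4)  # near-always optimal on 6-item instances
})

test_that("the objective is non-decreasing across accepted moves", {
  for (seed in 1:20) {
    nb <- random_instance(7, 0.03, seed + 100)
    opt <- opticlust_partition(nb, 0.03, seed = seed)
    for (trace in opt$mcc_trace) {
      expect_true(all(diff(trace) >= -1e-12))
    }
  }
})

test_that("confusion counts match a from-scratch recount", {
  for (seed in 1:15) {
    nb <- random_instance(8, 0.03, seed + 200)
    opt <- opticlust_partition(nb, 0.03, seed = seed)
    expect_equal(opt$confusion, partition_confusion(opt$otu_of, nb, 0.03))
    expect_equal(sum(opt$confusion), 8 * 7 / 2)
    expect_equal(opt$mcc, mcc(opt$confusion), tolerance = 1e-12)
    cl <- complete_linkage_partition(nb, 0.03)
    expect_equal(sum(cl$confusion), 8 * 7 / 2)
  }
})

test_that("clustering is deterministic for a fixed seed and restarts", {
  nb <- random_instance(10, 0.03, 999)
  a <- opticlust_partition(nb, 0.03, seed = 7, restarts = 3)
  b <- opticlust_partition(nb, 0.03, seed = 7, restarts = 3)
  expect_identical(a$otu_of, b$otu_of)
  expect_identical(a$mcc, b$mcc)
})

test_that("complete-linkage partitions are nested across thresholds", {
  nb <- random_instance(12, 0.05, 31)
  parts <- lapply(c(0.01, 0.02, 0.04, 0.05) / 1,
                  function(t) complete_linkage_partition(nb, t)$otu_of)
  for (k in seq_len(length(parts) - 1)) {
    finer <- parts[[k]]; coarser <- parts[[k + 1]]
    # every finer cluster sits inside one coarser cluster
    expect_true(all(tapply(coarser, finer,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("list-format output holds every item exactly once", {
  nb <- chain3()
  p <- opticlust_partition(nb, 0.03)
  path <- tempfile()
  write_list_format(p, path, ids = c("A", "B", "C"))
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(fields[2]), 2L)
  members <- sort(unlist(strsplit(fields[-(1:2)], ",")))
  expect_equal(members, c("A", "B", "C"))
})
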