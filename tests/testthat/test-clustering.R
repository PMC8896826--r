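test_that("threshold clustering honors the diameter limit cases", {
  tr <- simulate_yule_tree(12, seed = 2)
  m <- patristic_matrix(tr)
  diam <- max(m)
  for (mode in c("max_clade", "max")) {
    one <- threshold_clusters(tr, diam + 1, mode)
    expect_equal(unique(one$cluster), 1L)
    sing <- threshold_clusters(tr, min(m[m > 0]) / 2, mode)
    expect_equal(dplyr::n_distinct(sing$cluster), ape::Ntip(tr))
  }
  expect_error(threshold_clusters(tr, -1), "positive")
  expect_error(threshold_clusters(tr, 1, mode = "nope"), "max_clade")
})

test_that("mode max finds the minimal diameter-constrained partition", {
  tr <- read_newick("((A:1,B:1):5,(C:1,D:1):5);")
  cl <- threshold_clusters(tr, 3, "max")
  expect_equal(canonical_partition(cl), list(c("A", "B"), c("C", "D")))

  # exhaustive oracles on random trees: edge-cut enumeration, and for the
  # smallest trees the global partition minimum
  for (seed in 1:5) {
    tr <- simulate_yule_tree(sample(5:8, 1), seed = seed + 20)
    m <- patristic_matrix(tr)
    for (thr in mid_thresholds(m, c(0.2, 0.5, 0.8))) {
      cl <- threshold_clusters(tr, thr, "max", matrix = m)
      k <- dplyr::n_distinct(cl$cluster)
      expect_equal(k, oracle_min_edge_cut(tr, m, thr))
      ok <- all(vapply(split(cl$leaf, cl$cluster), function(b) {
        length(b) < 2 || max(m[b, b]) <= thr
      }, logical(1)))
      expect_true(ok)
    }
  }
  tr <- simulate_yule_tree(6, seed = 31)
  m <- patristic_matrix(tr)
  for (thr in mid_thresholds(m, c(0.3, 0.7))) {
    expect_equal(dplyr::n_distinct(threshold_clusters(tr, thr, "max")$cluster),
                 oracle_min_partition(m, thr))
  }
})

test_that("mode max_clade matches the maximal-fitting-ancestor characterization", {
  for (seed in 1:6) {
    tr <- simulate_yule_tree(sample(5:10, 1), seed = seed + 40)
    m <- patristic_matrix(tr)
    for (thr in mid_thresholds(m, c(0.25, 0.6, 0.9))) {
      cl <- threshold_clusters(tr, thr, "max_clade", matrix = m)
      expect_equal(canonical_partition(cl),
                   canonical_blocks(oracle_max_clade(tr, m, thr)))
    }
  }
})

test_that("raising the threshold never increases max_clade cluster count", {
  tr <- simulate_yule_tree(40, seed = 7)
  m <- patristic_matrix(tr)
  thresholds <- seq(0.1, max(m) * 1.05, length.out = 15)
  ks <- vapply(thresholds, function(t) {
    dplyr::n_distinct(threshold_clusters(tr, t, "max_clade", matrix = m)$cluster)
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("cluster assignments are partitions with contiguous ids", {
  for (seed in 1:4) {
    tr <- simulate_yule_tree(30, seed = seed + 60)
    for (mode in c("max_clade", "max")) {
      cl <- threshold_clusters(tr, 1.5, mode)
      expect_setequal(cl$leaf, tr$tip.label)
      expect_equal(anyDuplicated(cl$leaf), 0L)
      expect_equal(sort(unique(cl$cluster)),
                   seq_len(dplyr::n_distinct(cl$cluster)))
    }
  }
})

test_that("subcluster planning applies the 20% rule and linkage correctly", {
  tr <- simulate_yule_tree(12, seed = 9)
  m <- patristic_matrix(tr)
  one <- plan_subclusters(tr$tip.label[1], m, fraction = 0.2)
  expect_equal(nrow(one), 1L)
  expect_equal(one$subcluster, 1L)

  ten <- plan_subclusters(tr$tip.label[1:10], m, fraction = 0.2)
  expect_equal(dplyr::n_distinct(ten$subcluster), 2L)

  # average-linkage worked example: the far singleton splits off
  m3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p3 <- plan_subclusters(c("A", "B", "C"), m3, fraction = 0.6) # k = ceil(1.8) = 2
  expect_equal(dplyr::n_distinct(p3$subcluster), 2L)
  expect_equal(p3$subcluster[p3$leaf == "A"], p3$subcluster[p3$leaf == "B"])
  expect_false(p3$subcluster[p3$leaf == "C"] == p3$subcluster[p3$leaf == "A"])

  expect_error(plan_subclusters(character(0), m), "empty")
  expect_error(plan_subclusters(tr$tip.label[1:3], m, fraction = 0), "0, 1")
  expect_error(plan_subclusters(tr$tip.label[1:3], m, fraction = 1.2), "0, 1")
})

test_that("subcluster counts follow k = min(max(1, ceil(f n)), n) across sizes", {
  tr <- simulate_yule_tree(60, seed = 10)
  m <- patristic_matrix(tr)
  for (n_c in c(1, 2, 4, 5, 10, 23, 60)) {
    for (f in c(0.2, 0.5, 1)) {
      p <- plan_subclusters(tr$tip.label[seq_len(n_c)], m, fraction = f)
      expect_equal(dplyr::n_distinct(p$subcluster),
                   min(max(1, ceiling(f * n_c)), n_c))
      expect_setequal(p$leaf, tr$tip.label[seq_len(n_c)])
    }
  }
})

test_that("representative selection applies priority, then medoid, then label", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  plan <- tibble::tibble(leaf = c("A", "B", "C"), subcluster = 1L)

  # priority wins
  r1 <- pick_representatives(plan, m, priorities = c(B = 2))
  expect_equal(r1$leaf, "B")
  expect_equal(r1$selection_reason, "priority")

  # all rank 0: medoid (min summed distance: A = 3, B = 4, C = 5)
  r2 <- pick_representatives(plan, m)
  expect_equal(r2$leaf, "A")
  expect_equal(r2$selection_reason, "medoid")

  # symmetric pair: lexicographic
  m2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("Q", "P"), c("Q", "P")))
  r3 <- pick_representatives(tibble::tibble(leaf = c("Q", "P"), subcluster = 1L), m2)
  expect_equal(r3$leaf, "P")
  expect_equal(r3$selection_reason, "lexicographic")

  # priorities as a data frame, tie on rank falls through to medoid
  r4 <- pick_representatives(plan, m,
                             priorities = data.frame(leaf = c("A", "B", "C"),
                                                     rank = c(1, 1, 1)))
  expect_equal(r4$leaf, "A")
  expect_equal(r4$selection_reason, "medoid")
})

test_that("sample_tree composes the stages deterministically", {
  # single-leaf tree: that leaf
  tr1 <- suppressWarnings(read_newick("(A:1);"))
  r1 <- sample_tree(tr1, threshold = 1, fraction = 0.2)
  expect_equal(r1$leaf, "A")

  # threshold >= diameter, f = 1: every leaf its own subcluster
  tr <- simulate_yule_tree(15, seed = 12)
  m <- patristic_matrix(tr)
  rall <- sample_tree(tr, threshold = max(m) + 1, fraction = 1)
  expect_setequal(rall$leaf, tr$tip.label)

  # equals the independently scripted stage composition
  tr12 <- simulate_yule_tree(12, seed = 13)
  m12 <- patristic_matrix(tr12)
  reps <- sample_tree(tr12, threshold = 1.2, fraction = 0.4)
  cl <- threshold_clusters(tr12, 1.2, "max_clade", matrix = m12)
  manual <- dplyr::bind_rows(lapply(split(cl$leaf, cl$cluster), function(lv) {
    p <- plan_subclusters(lv, m12, fraction = 0.4)
    pick_representatives(p, m12)
  }))
  expect_setequal(reps$leaf, manual$leaf)

  # total count = sum over clusters of min(k_c, n_c); one rep per subcluster
  pv <- attr(reps, "provenance")
  expected_n <- sum(pmin(pmax(1, ceiling(0.4 * pv$clusters$n_leaves)),
                         pv$clusters$n_leaves))
  expect_equal(nrow(reps), expected_n)
  expect_equal(anyDuplicated(reps[c("cluster", "subcluster")]), 0L)

  # byte-identical TSV on rerun
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_representatives_tsv(sample_tree(tr12, 1.2, 0.4), f1)
  write_representatives_tsv(sample_tree(tr12, 1.2, 0.4), f2)
  expect_identical(readLines(f1), readLines(f2))
})
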