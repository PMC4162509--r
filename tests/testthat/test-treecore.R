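test_that("merge tables build trees and round-trip exactly", {
  # smallest case
  t2 <- from_merge_table(data.frame(child_a = 0, child_b = 1, height = 1.0),
                         labels = c("A", "B"))
  expect_equal(t2$n, 2L)
  expect_equal(t2$height, 1.0)
  expect_identical(leaf_order(t2), c("A", "B"))

  # hand-built ((A,B):1,(C,D):2):5
  tb <- data.frame(child_a = c(0, 2, 4), child_b = c(1, 3, 5),
                   height = c(1, 2, 5))
  tr <- from_merge_table(tb, labels = c("A", "B", "C", "D"))
  expect_identical(leaf_order(tr), c("A", "B", "C", "D"))
  back <- to_merge_table(tr)
  expect_equal(back$child_a, tb$child_a)
  expect_equal(back$child_b, tb$child_b)
  expect_equal(back$height, tb$height)
  expect_identical(attr(back, "labels"), c("A", "B", "C", "D"))

  # round trip on a random 50-leaf tree
  big <- random_merge_tree(50, seed = 7)
  rt <- from_merge_table(to_merge_table(big))
  expect_identical(leaf_order(rt), leaf_order(big))
  expect_equal(rt$height, big$height)

  # tied heights keep their relative merge order (stable)
  tied <- data.frame(child_a = c(0, 2, 4), child_b = c(1, 3, 5),
                     height = c(1, 1, 2))
  tt <- from_merge_table(tied, labels = c("A", "B", "C", "D"))
  bk <- to_merge_table(tt)
  expect_equal(bk$child_a, tied$child_a)
  expect_equal(bk$height, tied$height)
})

test_that("malformed merge tables are rejected with the offending row", {
  expect_error(
    from_merge_table(data.frame(child_a = 0, child_b = 0, height = 1),
                     labels = c("A", "B")),
    "duplicate child"
  )
  expect_error(
    from_merge_table(data.frame(child_a = c(0, 0), child_b = c(1, 2),
                                height = c(1, 2)),
                     labels = c("A", "B", "C")),
    "duplicate child"
  )
  expect_error(
    from_merge_table(data.frame(child_a = c(0, 2, 4), child_b = c(5, 3, 1),
                                height = c(1, 2, 3)),
                     labels = c("A", "B", "C", "D")),
    "later or same merge"
  )
  expect_error(
    from_merge_table(data.frame(child_a = 0, child_b = 1, height = -1),
                     labels = c("A", "B")),
    "row 1"
  )
})

test_that("leaf order reflects orientation and handles a single leaf", {
  tb <- data.frame(child_a = c(0, 2, 4), child_b = c(1, 3, 5),
                   height = c(1, 2, 5))
  tr <- from_merge_table(tb, labels = c("A", "B", "C", "D"))
  expect_identical(leaf_order(tr), c("A", "B", "C", "D"))
  flipped <- from_merge_table(
    data.frame(child_a = c(0, 2, 5), child_b = c(1, 3, 4),
               height = c(1, 2, 5)),
    labels = c("A", "B", "C", "D"))
  expect_identical(leaf_order(flipped), c("C", "D", "A", "B"))
  single <- structure(list(n = 1L, labels = "A", left = integer(0),
                           right = integer(0), height = numeric(0)),
                      class = "merge_tree")
  expect_identical(leaf_order(single), "A")
})

test_that("leaf order is always a permutation and subtrees nest", {
  set.seed(114)
  for (seed in 1:10) {
    n <- sample(2:40, 1)
    tr <- random_merge_tree(n, seed = seed)
    expect_setequal(leaf_order(tr), tr$labels)
    expect_equal(anyDuplicated(leaf_order(tr)), 0L)
    # every internal node's leaf set is the union of its children's
    seqs <- leaf_sequences_oracle(tr)
    tb <- to_merge_table(tr)
    for (m in seq_len(n - 1L)) {
      kids <- c(tb$child_a[m], tb$child_b[m]) + 1L
      expect_setequal(seqs[[n + m]], unlist(seqs[kids]))
    }
  }
})

test_that("newick serialization preserves branch lengths and orientation", {
  t2 <- from_merge_table(data.frame(child_a = 0, child_b = 1, height = 1.0),
                         labels = c("A", "B"))
  expect_identical(to_newick(t2), "(A:1,B:1);")

  tb <- data.frame(child_a = c(0, 2, 4), child_b = c(1, 3, 5),
                   height = c(1, 2, 5))
  tr <- from_merge_table(tb, labels = c("A", "B", "C", "D"))
  # branch = parent height - child height: 5-1=4 and 5-2=3
  expect_identical(to_newick(tr), "((A:1,B:1):4,(C:2,D:2):3);")

  big <- random_merge_tree(30, seed = 3)
  rt <- from_newick(to_newick(big))
  expect_identical(leaf_order(rt), leaf_order(big))
  expect_equal(sort(rt$height), sort(big$height), tolerance = 1e-10)

  expect_error(from_newick("((A:1,B:1):4"), "parse")
  expect_error(from_newick("(A:1,B:1,C:1);"), "non-binary")
})

test_that("validation reports monotonicity violations and duplicates", {
  d <- random_distance_matrix(paste0("L", 1:12), seed = 5)
  ct <- agglomerate(d, "complete")
  expect_equal(validate_merge_tree(ct)$monotonicity_violations, 0L)

  # parent at height 1 below a child at height 2
  bad <- from_merge_table(
    data.frame(child_a = c(0, 1, 3), child_b = c(2, 4, 5),
               height = c(2, 1, 3)),
    labels = c("A", "B", "C", "D"))
  expect_equal(validate_merge_tree(bad)$monotonicity_violations, 1L)
  expect_false(validate_merge_tree(bad)$ok)

  dup <- from_merge_table(data.frame(child_a = 0, child_b = 1, height = 1),
                          labels = c("A", "A"))
  expect_identical(validate_merge_tree(dup)$duplicate_labels, "A")
})

test_that("hclust conversion preserves merge order, heights, orientation", {
  set.seed(11)
  x <- matrix(rnorm(20 * 3), 20)
  rownames(x) <- paste0("s", 1:20)
  hc <- hclust(dist(x), method = "complete")
  tr <- as_merge_tree(hc)
  expect_equal(tr$height, hc$height)
  # hclust's drawn order and ours agree up to per-merge orientation: the
  # same merge leaf sets must appear
  expect_setequal(leaf_order(tr), hc$labels)
  naive <- naive_linkage(as.matrix(dist(x)), "complete")
  expect_equal(merge_leaf_sets(tr), naive$merge_sets)
})
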