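# 4-leaf caterpillar/balanced trees used across blocks
balanced4 <- function(heights = c(1, 2, 5), labs = c("A", "B", "C", "D")) {
  from_merge_table(
    data.frame(child_a = c(0, 2, 4), child_b = c(1, 3, 5), height = heights),
    labels = labs)
}

test_that("default orientation applies the three merge rules", {
  # leaf-leaf: smaller input index left (input indices 4 vs 2, 1-based)
  leafleaf <- from_merge_table(
    data.frame(child_a = c(3, 0, 4), child_b = c(1, 2, 5), height = 1:3),
    labels = paste0("L", 1:4))
  od <- order_default(leafleaf)
  expect_identical(od$left[1], 2L)   # leaf index 2 left of leaf index 4
  expect_identical(od$right[1], 4L)

  # leaf-subtree: the leaf goes left
  ls <- from_merge_table(
    data.frame(child_a = c(0, 3), child_b = c(1, 2), height = c(1, 2)),
    labels = c("L1", "L2", "L5"))
  odl <- order_default(ls)
  expect_identical(leaf_order(odl), c("L5", "L1", "L2"))

  # subtree-subtree: previous-merge heights 2.0 vs 1.0 -> 1.0 left
  ss <- from_merge_table(
    data.frame(child_a = c(2, 0, 4), child_b = c(3, 1, 5),
               height = c(2, 1, 5)),
    labels = c("A", "B", "C", "D"))
  ods <- order_default(ss)
  expect_identical(leaf_order(ods), c("A", "B", "C", "D"))
})

test_that("modular ordering puts the smaller-key subtree left", {
  # ((C,D):2,(A,B):1):5 with min keys 1 < 2 -> [A,B,C,D]
  tr <- from_merge_table(
    data.frame(child_a = c(2, 0, 4), child_b = c(3, 1, 5),
               height = c(2, 1, 5)),
    labels = c("A", "B", "C", "D"))
  mo <- order_molo(tr, "min")
  expect_identical(leaf_order(mo), c("A", "B", "C", "D"))
  # cross-check against exhaustive enumeration: among all flip orders,
  # the modular one is the one whose every node satisfies key(l) <= key(r)
  key <- subtree_keys(mo, "min")
  expect_true(all(key[mo$left] <= key[mo$right] |
                    (is.infinite(key[mo$left]) & is.infinite(key[mo$right]))))

  # leaf merging with a subtree goes right
  ls <- from_merge_table(
    data.frame(child_a = c(0, 3), child_b = c(1, 2), height = c(1, 2)),
    labels = c("A", "B", "E"))
  # subtree (A,B) left, leaf E right
  expect_identical(leaf_order(order_molo(ls, "min")), c("A", "B", "E"))

  # min and avg criteria diverge: S1 heights {1,4} (avg 2.5) vs S2 {2}
  tr2 <- from_merge_table(
    data.frame(child_a = c(0, 3, 5, 7), child_b = c(1, 4, 2, 6),
               height = c(1, 2, 4, 6)),
    labels = c("a1", "a2", "a3", "b1", "b2"))
  # S1 = ((a1,a2):1,a3):4 ; S2 = (b1,b2):2
  omin <- order_molo(tr2, "min")
  oavg <- order_molo(tr2, "avg")
  expect_identical(leaf_order(omin)[1], "a1")  # S1 left under min (key 1)
  expect_identical(leaf_order(oavg)[1], "b1")  # S2 left under avg (2 < 2.5)
})

test_that("modular ordering is idempotent and key-sorted at every node", {
  set.seed(109)
  for (seed in 1:12) {
    n <- sample(3:60, 1)
    tr <- random_merge_tree(n, seed = 300 + seed)
    for (crit in c("min", "avg")) {
      o1 <- order_molo(tr, crit)
      o2 <- order_molo(o1, crit)
      expect_identical(leaf_order(o1), leaf_order(o2))
      key <- subtree_keys(o1, crit)
      ok <- key[o1$left] <= key[o1$right] |
        (is.infinite(key[o1$left]) & is.infinite(key[o1$right]))
      expect_true(all(ok))
    }
  }
})

test_that("after min-ordering the leftmost-descent chain holds the global minimum merge", {
  # the tightest merge is reachable from the root by always descending left
  set.seed(110)
  for (seed in 1:8) {
    n <- sample(4:50, 1)
    tr <- order_molo(random_merge_tree(n, seed = 400 + seed), "min")
    target <- which.min(tr$height) + tr$n
    id <- 2L * tr$n - 1L
    found <- FALSE
    while (id > tr$n) {
      if (id == target) { found <- TRUE; break }
      id <- tr$left[id - tr$n]
    }
    expect_true(found)
  }
})

test_that("endpoint-greedy ordering picks the closest inner pair", {
  tr <- balanced4()
  d <- random_distance_matrix(c("A", "B", "C", "D"), seed = 1)
  d["B", "C"] <- d["C", "B"] <- 3
  d["B", "D"] <- d["D", "B"] <- 4
  d["A", "C"] <- d["C", "A"] <- 4
  d["A", "D"] <- d["D", "A"] <- 5
  expect_identical(leaf_order(order_gw(tr, d)), c("A", "B", "C", "D"))

  tri <- from_merge_table(
    data.frame(child_a = c(0, 3), child_b = c(1, 2), height = c(1, 2)),
    labels = c("A", "B", "C"))
  d3 <- matrix(c(0, 1, 4, 1, 0, 3, 4, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(leaf_order(order_gw(tri, d3)), c("A", "B", "C"))

  # 2-leaf tree: all orientations tie, keep input
  t2 <- from_merge_table(data.frame(child_a = 1, child_b = 0, height = 1),
                         labels = c("A", "B"))
  expect_identical(leaf_order(order_gw(t2, d3[1:2, 1:2])), c("B", "A"))
})

test_that("endpoint-greedy inner pairs are minimal among the four combinations", {
  set.seed(111)
  for (seed in 1:10) {
    n <- sample(3:10, 1)
    tr <- random_merge_tree(n, seed = 500 + seed)
    d <- random_distance_matrix(tr$labels, seed = 600 + seed)
    gt <- order_gw(tr, d)
    seqs <- leaf_sequences_oracle(gt)
    idx <- match(gt$labels, rownames(d))
    for (m in seq_len(n - 1L)) {
      A <- seqs[[gt$left[m]]]; B <- seqs[[gt$right[m]]]
      chosen <- d[idx[A[length(A)]], idx[B[1]]]
      alts <- c(d[idx[A[1]], idx[B[1]]],
                d[idx[A[length(A)]], idx[B[length(B)]]],
                d[idx[A[1]], idx[B[length(B)]]])
      expect_lte(chosen, min(alts))
    }
  }
})

test_that("optimal leaf ordering achieves the exhaustive flip minimum", {
  # fixed worked example
  tr <- balanced4()
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 1; d["A", "C"] <- 4; d["A", "D"] <- 5
  d["B", "C"] <- 3; d["B", "D"] <- 4; d["C", "D"] <- 2
  d <- d + t(d)
  ot <- order_olo(tr, d)
  expect_identical(leaf_order(ot), c("A", "B", "C", "D"))
  expect_equal(attr(ot, "path_length"), 6)
  expect_equal(path_length(d, leaf_order(ot)), 6)

  # 2-leaf tree unchanged
  t2 <- from_merge_table(data.frame(child_a = 1, child_b = 0, height = 1),
                         labels = c("A", "B"))
  o2 <- order_olo(t2, d[1:2, 1:2])
  expect_identical(leaf_order(o2), c("B", "A"))
  expect_equal(attr(o2, "path_length"), d["A", "B"])

  # random trees: equal to brute force over all 2^(n-1) orders
  set.seed(112)
  for (seed in 1:10) {
    n <- sample(3:10, 1)
    tr <- random_merge_tree(n, seed = 700 + seed)
    dd <- random_distance_matrix(tr$labels, seed = 800 + seed)
    ot <- order_olo(tr, dd)
    all_orders <- enumerate_flip_orders(tr)
    brute <- min(vapply(all_orders, function(o) path_length_oracle(dd, o),
                        numeric(1)))
    expect_equal(attr(ot, "path_length"), brute, tolerance = 1e-12)
    expect_equal(path_length(dd, leaf_order(ot)), brute, tolerance = 1e-12)
  }

  expect_error(order_olo(random_merge_tree(12, 1),
                         random_distance_matrix(paste0("L", 1:12), 1),
                         max_leaves = 10), "cap")
})

test_that("flip enumeration covers exactly 2^(n-1) orders", {
  t2 <- from_merge_table(data.frame(child_a = 0, child_b = 1, height = 1),
                         labels = c("A", "B"))
  expect_length(enumerate_flip_orders(t2), 2L)
  expect_length(enumerate_flip_orders(random_merge_tree(4, 1)), 8L)
  orders10 <- enumerate_flip_orders(random_merge_tree(10, 2))
  expect_length(orders10, 512L)
  expect_equal(anyDuplicated(vapply(orders10, paste, "", collapse = "|")), 0L)
  expect_error(enumerate_flip_orders(random_merge_tree(17, 1)), "cap")
})

test_that("every ordering method only changes orientation", {
  set.seed(113)
  for (seed in 1:6) {
    n <- sample(3:40, 1)
    tr <- random_merge_tree(n, seed = 900 + seed)
    d <- random_distance_matrix(tr$labels, seed = 950 + seed)
    sig <- tree_signature(tr)
    for (meth in c("default", "molo-min", "molo-avg", "gw", "olo")) {
      out <- apply_ordering(tr, meth, d = d)
      expect_identical(tree_signature(out), sig)
      expect_equal(out$height, tr$height)
    }
  }
})

test_that("reorient_to_order realizes exactly the achievable orders", {
  tr <- random_merge_tree(8, seed = 33)
  target <- enumerate_flip_orders(tr)[[100]]
  rt <- reorient_to_order(tr, target)
  expect_identical(leaf_order(rt), target)
  expect_error(reorient_to_order(tr, leaf_order(tr)[c(1, 2)]),
               "permutation")
  # an order crossing a subtree boundary is not achievable
  b4 <- balanced4()
  expect_error(reorient_to_order(b4, c("A", "C", "B", "D")),
               "not achievable")
})

test_that("method dispatch validates inputs", {
  tr <- random_merge_tree(5, seed = 1)
  expect_error(apply_ordering(tr, "olo"), "needs a distance matrix")
  d <- random_distance_matrix(paste0("X", 1:5), seed = 1)
  expect_error(order_gw(tr, d), "missing from distance matrix")
})
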