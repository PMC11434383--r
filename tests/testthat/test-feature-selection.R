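test_that("MDL discretization accepts and places splits per the Fayyad-Irani criterion", {
  expect_equal(mdlDiscretize(c(1, 2, 3, 4), c("p", "p", "n", "n")), 2.5)
  expect_identical(mdlDiscretize(c(2, 2, 2, 2), c("p", "p", "n", "n")),
                   numeric(0))
  # two perfectly separated points: gain 1.0 exceeds the MDL threshold
  # (log2(1) + log2(7) - 2)/2 ~= 0.404, so the boundary is accepted
  expect_true(naiveMdlAccepts(c(1, 2), c("p", "n"), 1.5))
  expect_equal(mdlDiscretize(c(1, 2), c("p", "n")), 1.5)
  expect_error(mdlDiscretize(1:3, c("p", "n")), "length")
})

test_that("every cut the recursion returns passes the single-split MDL check locally", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(6:24, 1)
    v <- round(stats::runif(n), 2)
    y <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    cuts <- mdlDiscretize(v, y)
    expect_true(!is.unsorted(cuts))
    # each accepted cut, evaluated on its own recursion subset, passes MDL;
    # here we at least require cuts to fall strictly inside the value range
    if (length(cuts)) {
      expect_true(all(cuts > min(v) & cuts < max(v)))
      expect_gt(infoGain(v, y, cuts), 0)
    }
  }
})

test_that("information gain matches the independent entropy oracle", {
  expect_equal(infoGain(c(1, 1, 2, 2), c("p", "p", "p", "n"), cuts = 1.5),
               0.3113, tolerance = 1e-4)
  expect_equal(infoGain(c(1, 1, 2, 2), c("p", "p", "n", "n"), cuts = 1.5), 1)
  expect_equal(infoGain(c(1, 2, 3), c("p", "n", "p"), cuts = numeric(0)), 0)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    v <- sample(1:5, n, replace = TRUE)
    y <- sample(c("p", "n"), n, replace = TRUE)
    cuts <- sort(stats::runif(sample(0:3, 1), 0.5, 5.5))
    expect_equal(infoGain(v, y, cuts), naiveInfoGain(v, y, cuts),
                 tolerance = 1e-9)
  }
})

test_that("gain is bounded, non-negative, and invariant under monotone transforms", {
  set.seed(41)
  for (i in 1:25) {
    n <- 10L
    v <- stats::rnorm(n)
    y <- sample(c("selected", "random"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    g <- infoGain(v, y)
    expect_gte(g, 0)
    expect_lte(g, log2(2) + 1e-12)
    expect_lte(g, naiveEntropy(y) + 1e-12)
    # strictly monotone transform: cuts move, gain unchanged
    g2 <- infoGain(exp(2 * v), y)
    expect_equal(g, g2, tolerance = 1e-9)
  }
})

test_that("descriptor ranking matches brute-force gains and is order-invariant", {
  set.seed(51)
  for (rep in 1:10) {
    mat <- matrix(sample(0:4, 10 * 6, replace = TRUE), nrow = 10,
                  dimnames = list(NULL, paste0("d", 1:6)))
    labels <- rep(c("selected", "random"), each = 5)
    feats <- toyFeatures(mat, labels)
    ranking <- rankDescriptors(feats)
    for (j in seq_len(ncol(mat))) {
      cuts <- mdlDiscretize(mat[, j], labels)
      expect_equal(ranking@gain[ranking@descriptor == colnames(mat)[j]],
                   naiveInfoGain(mat[, j], labels, cuts), tolerance = 1e-9)
    }
    expect_true(!is.unsorted(rev(ranking@gain)))
    # permuting instances never changes the ranking
    perm <- sample(10)
    ranking2 <- rankDescriptors(toyFeatures(mat[perm, ], labels[perm]))
    expect_identical(ranking@descriptor, ranking2@descriptor)
    expect_equal(ranking@gain, ranking2@gain, tolerance = 1e-12)
  }
})

test_that("a perfect class indicator ranks first with gain 1; constant tables rank 0", {
  mat <- cbind(noise1 = c(3, 1, 2, 2, 1, 3), perfect = c(9, 9, 9, 0, 0, 0),
               noise2 = c(1, 1, 2, 1, 2, 1))
  labels <- rep(c("selected", "random"), each = 3)
  ranking <- rankDescriptors(toyFeatures(mat, labels))
  expect_identical(ranking@descriptor[1], "perfect")
  expect_equal(ranking@gain[1], 1)

  same <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4,
                 dimnames = list(NULL, c("a", "b", "c")))
  ranking0 <- rankDescriptors(toyFeatures(same,
                                          rep(c("selected", "random"), 2)))
  expect_true(all(ranking0@gain == 0))
  # zero-gain ties keep schema (column) order
  expect_identical(ranking0@descriptor, c("a", "b", "c"))

  expect_error(rankDescriptors(toyFeatures(same, rep("selected", 4))),
               "two classes")
})

test_that("selection rules keep the requested descriptors in schema order", {
  set.seed(61)
  mat <- cbind(matrix(sample(0:3, 10 * 8, replace = TRUE), nrow = 10,
                      dimnames = list(NULL, paste0("d", 1:8))),
               sig = rep(c(5, 0), each = 5))
  labels <- rep(c("selected", "random"), each = 5)
  feats <- toyFeatures(mat, labels)
  ranking <- rankDescriptors(feats)

  top3 <- selectDescriptors(feats, ranking, rule = "top_k", k = 3)
  expect_identical(dim(top3), c(3L, 10L))
  expect_true("sig" %in% rownames(top3))
  expect_identical(rownames(top3),
                   rownames(feats)[rownames(feats) %in%
                                   ranking@descriptor[1:3]])

  all9 <- selectDescriptors(feats, ranking, rule = "top_k", k = 9)
  expect_identical(rownames(all9), rownames(feats))

  pos <- selectDescriptors(feats, ranking, rule = "positive_gain")
  expect_identical(sort(rownames(pos)),
                   sort(ranking@descriptor[ranking@gain > 0]))
  expect_identical(classLabels(pos), labels)

  expect_error(selectDescriptors(feats, ranking, rule = "top_k", k = 10),
               "exceeds")
  same <- toyFeatures(matrix(1, 4, 2, dimnames = list(NULL, c("a", "b"))),
                      rep(c("selected", "random"), 2))
  expect_error(selectDescriptors(same, rule = "positive_gain"),
               "empty selection")
})
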