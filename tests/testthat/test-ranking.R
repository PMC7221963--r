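test_that("standard scores have mean zero and unit sample SD", {
  expect_equal(standard_scores(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standard_scores(c(5, 5, 5)), "constant")
  set.seed(3)
  for (k in 1:25) {
    z <- standard_scores(rnorm(sample(3:30, 1), sd = runif(1, 0.1, 50)))
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
})

test_that("RACI averages oriented z-scores and sums to zero", {
  vals <- cbind(a = c(1, 4, 2, 6), b = c(10, 2, 5, 1))
  rownames(vals) <- paste0("s", 1:4)
  m1 <- activity_matrix(vals[, "a", drop = FALSE], "higher-better")
  r1 <- raci(m1)
  expect_equal(unname(r1$raci), unname(standard_scores(vals[, "a"])))
  # strictly best in every metric gets the strictly largest index
  best <- cbind(c(1, 5, 9), c(20, 10, 4))  # sample 1 lowest id50, highest orac
  best[, 2] <- rev(best[, 2])
  m2 <- activity_matrix(best, c("lower-better", "higher-better"))
  r2 <- raci(m2)
  expect_equal(which.max(r2$raci), 1L)
  expect_lt(abs(sum(r2$raci)), 1e-12)
  expect_error(raci(activity_matrix(cbind(c(1, 1, 1)), "higher-better")),
               "constant")
})

test_that("RACI is invariant under affine rescaling of a metric", {
  set.seed(9)
  vals <- matrix(rnorm(24), 6, 4)
  ori <- c("lower-better", "lower-better", "lower-better", "higher-better")
  r <- raci(activity_matrix(vals, ori))
  vals2 <- vals
  vals2[, 2] <- 100 * vals2[, 2] - 7
  r2 <- raci(activity_matrix(vals2, ori))
  expect_equal(r$raci, r2$raci, tolerance = 1e-12)
})

test_that("correlation distance spans [0, 2] with hand-checked values", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1), c(1, 3, 2))
  d <- correlation_distance(m)
  expect_equal(d[1, 2], 0)          # identical profile shape
  expect_equal(d[1, 3], 2)          # exact anti-correlation
  expect_equal(d[1, 4], 0.5)        # r = 0.5 by hand
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 4))
  expect_error(correlation_distance(rbind(c(1, 1, 1), c(1, 2, 3))),
               "constant")
})

test_that("average linkage reproduces hand-computed UPGMA merges", {
  D <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3)
  hc <- average_linkage(D)
  expect_equal(hc$height, c(1, 4))
  sets <- hclust_member_sets(hc)
  expect_equal(sets[[1]], c(1, 2))
  expect_equal(sets[[2]], c(1, 2, 3))
  # identical profiles merge at height zero
  D0 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3, 3)
  expect_equal(average_linkage(D0)$height[1], 0)
  expect_error(average_linkage(matrix(1:6, 2, 3)), "square")
})

test_that("average linkage agrees with the brute-force UPGMA oracle", {
  set.seed(17)
  for (k in 1:40) {
    D <- random_distance_matrix(6)
    hc <- average_linkage(D)
    oracle <- upgma_oracle(D)
    expect_equal(hc$height,
                 vapply(oracle, `[[`, numeric(1), "height"),
                 tolerance = 1e-12)
    expect_equal(hclust_member_sets(hc),
                 lapply(oracle, `[[`, "members"))
    expect_equal(length(hc$height), 5L)
    expect_true(!is.unsorted(hc$height))
  }
})

test_that("dendrograms serialize to newick with height-difference branches", {
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  nwk <- dendrogram_newick(average_linkage(D))
  expect_match(nwk, "^\\(")
  expect_match(nwk, "a:")
  tf <- tempfile(fileext = ".nwk")
  dendrogram_newick(average_linkage(D), tf)
  expect_true(file.exists(tf))
  phy <- ape::read.tree(tf)
  expect_setequal(phy$tip.label, letters[1:3])
})

test_that("heatmap preparation scales rows and groups planted blocks", {
  set.seed(21)
  block1 <- matrix(rnorm(4 * 6, mean = rep(c(2, -2, 1, -1, 0, 0), each = 4),
                         sd = 0.1), 4, 6)
  block2 <- -block1 + matrix(rnorm(24, sd = 0.1), 4, 6)
  m <- rbind(block1, block2)
  rownames(m) <- paste0("f", 1:8)
  hm <- heatmap_matrix(m)
  expect_equal(apply(hm$scaled, 1, sd), setNames(rep(1, 8), rownames(hm$scaled)),
               tolerance = 1e-12)
  # the two planted blocks come out adjacent in leaf order
  groups <- (hm$row_order - 1) %/% 4
  expect_equal(length(rle(groups)$lengths), 2L)
})
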