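test_that("a noise-free planted partition is recovered exactly", {
  set.seed(31)
  a <- sin(seq(0, 2 * pi, length.out = 40))
  b <- c(rep(0, 20), seq(0, 1, length.out = 20))   # uncorrelated with a
  w <- rbind(matrix(rep(a, 60), 60, byrow = TRUE),
             matrix(rep(b, 60), 60, byrow = TRUE))
  res <- clusterTraces(w, threshold = 0.75, minSize = 50)
  expect_equal(length(res$clusters), 2L)
  sizes <- vapply(res$clusters, function(cl) length(members(cl)), integer(1))
  expect_equal(sizes, c(60L, 60L))
  expect_equal(sort(unique(res$assignment[1:60])),
               res$assignment[1L])
  expect_false(res$assignment[1L] == res$assignment[120L])
})

test_that("clusters below the minimum size are discarded", {
  a <- sin(seq(0, 2 * pi, length.out = 30))
  w <- matrix(rep(a, 10), 10, byrow = TRUE)
  res <- clusterTraces(w, threshold = 0.75, minSize = 50)
  expect_equal(length(res$clusters), 0L)
  expect_true(all(is.na(res$assignment)))
})

test_that("a single waveform forms a singleton cluster when allowed", {
  a <- cos(seq(0, 4 * pi, length.out = 25))
  res <- clusterTraces(matrix(a, 1L), minSize = 1L)
  expect_equal(length(res$clusters), 1L)
  z <- (a - mean(a)) / sd(a)
  expect_equal(centroid(res$clusters[[1L]]), z)
  expect_equal(centroidSem(res$clusters[[1L]]), rep(0, 25))
})

test_that("all-constant waveforms yield no clusters", {
  res <- clusterTraces(matrix(5, 8, 20), minSize = 2L)
  expect_equal(length(res$clusters), 0L)
})

test_that("reported clusters satisfy their own membership invariants", {
  set.seed(32)
  tpl <- list(sin(seq(0, 2 * pi, length.out = 50)),
              cos(seq(0, 6 * pi, length.out = 50)),
              seq(-1, 1, length.out = 50))
  w <- do.call(rbind, lapply(tpl, function(f)
    t(replicate(15, f + rnorm(50, 0, 0.15)))))
  res <- clusterTraces(w, threshold = 0.75, minSize = 5L)
  expect_gte(length(res$clusters), 3L)
  z <- t(apply(w, 1L, function(x) (x - mean(x)) / sd(x)))
  for (cl in res$clusters) {
    expect_gte(length(members(cl)), 5L)
    for (m in members(cl))
      expect_gte(cor(z[m, ], centroid(cl)), 0.75)
  }
  # membership disjoint across clusters
  all_m <- unlist(lapply(res$clusters, members))
  expect_equal(anyDuplicated(all_m), 0L)
})

test_that("input order changes labels at most, not the partition", {
  set.seed(33)
  tpl <- list(sin(seq(0, 2 * pi, length.out = 40)),
              cos(seq(0, 2 * pi, length.out = 40)))
  w <- do.call(rbind, lapply(tpl, function(f)
    t(replicate(20, f + rnorm(40, 0, 0.05)))))
  res1 <- clusterTraces(w, minSize = 5L)
  p <- sample(nrow(w))
  res2 <- clusterTraces(w[p, ], minSize = 5L)
  part1 <- res1$assignment
  part2 <- res2$assignment[order(p)]
  # same co-membership structure
  expect_equal(outer(part1, part1, "=="), outer(part2, part2, "=="))
})

test_that("a noisy centroid stays within 3 SEM of its template", {
  set.seed(34)
  tpl <- sin(seq(0, 2 * pi, length.out = 30))
  w <- t(replicate(50, 5 + 2 * tpl + rnorm(30, 0, 0.2)))
  cs <- waveformCentroid(w)
  expect_true(all(abs(cs$centroid - (5 + 2 * tpl)) <= 3 * cs$sem + 1e-9))
  # identical members: centroid equals any member, SEM zero
  w2 <- matrix(rep(tpl, 4), 4, byrow = TRUE)
  cs2 <- waveformCentroid(w2)
  expect_equal(cs2$centroid, tpl)
  expect_equal(cs2$sem, rep(0, 30))
  expect_equal(waveformCentroid(rbind(tpl, -tpl))$centroid, rep(0, 30))
})
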