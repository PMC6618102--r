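test_that("diagonally adjacent bins form one cluster under 8-way adjacency", {
  nf <- 5; nt <- 5
  idx <- c(2 + (2 - 1) * nf, 3 + (3 - 1) * nf)  # (2,2) and (3,3)
  lab8 <- oscrep:::label_components(idx, nf, nt, 8)
  expect_equal(length(unique(lab8)), 1)
  lab4 <- oscrep:::label_components(idx, nf, nt, 4)
  expect_equal(length(unique(lab4)), 2)
  # an L-shaped component under 4-way adjacency stays connected
  idx2 <- c(2, 3, 3 + nf)
  expect_equal(length(unique(oscrep:::label_components(idx2, nf, nt, 4))), 1)
})

test_that("cluster masses sum member statistics and cover all supra bins", {
  set.seed(30)
  a <- null_maps(12, 12, 16)
  b <- null_maps(12, 12, 16)
  cl <- cluster_permutation(a, b, "paired_t", n_permutations = 120, seed = 1)
  tmap <- as.vector(cl$stat_map)
  if (nrow(cl$clusters)) {
    for (i in seq_len(nrow(cl$clusters))) {
      expect_equal(cl$clusters$mass[i], sum(tmap[cl$members[[i]]]),
                   tolerance = 1e-9)
    }
    expect_equal(sum(cl$clusters$n_bins), length(unlist(cl$members)))
    expect_true(all(cl$clusters$p >= 1 / 121 & cl$clusters$p <= 1))
  }
  expect_length(cl$null_max, 120)
})

test_that("mismatched grids are rejected", {
  a <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  b <- array(rnorm(5 * 4 * 7), c(5, 4, 7))
  expect_error(cluster_permutation(a, b), "grid mismatch")
})

test_that("an injected rectangular effect is recovered with high overlap", {
  set.seed(31)
  nf <- 30; nt <- 40
  inj_rows <- 10:17; inj_cols <- 5:15
  injected <- as.vector(outer(seq_len(nf) %in% inj_rows,
                              seq_len(nt) %in% inj_cols) * 1)
  overlaps <- replicate(8, {
    a <- null_maps(20, nf, nt)
    b <- null_maps(20, nf, nt)
    for (p in 1:20) a[p, inj_rows, inj_cols] <- a[p, inj_rows, inj_cols] + 1.2
    cl <- cluster_permutation(a, b, "paired_t", n_permutations = 250)
    sig <- which(cl$clusters$p <= 0.05)
    hit <- unique(unlist(cl$members[sig]))
    sum(injected[hit]) / sum(injected)
  })
  expect_gte(median(overlaps), 0.8)
})

test_that("the Watson U2 statistic path finds phase-angle separation", {
  set.seed(32)
  nf <- 12; nt <- 14
  a <- array(runif(16 * nf * nt, -pi, pi), c(16, nf, nt))
  b <- array(runif(16 * nf * nt, -pi, pi), c(16, nf, nt))
  # strong angular separation in a block
  for (p in 1:16) {
    a[p, 4:8, 4:9] <- oscrep:::rvm(30, pi / 2, 6)
    b[p, 4:8, 4:9] <- oscrep:::rvm(30, -pi / 2, 6)
  }
  cl <- cluster_permutation(a, b, "watson_u2", n_permutations = 200, seed = 5,
                            freqs = 1:nf, times = 1:nt)
  expect_true(nrow(cl$clusters) > 0)
  top <- cl$clusters[1, ]
  expect_lte(top$p, 0.05)
  expect_true(top$freq_min >= 3 && top$freq_max <= 9)
})

test_that("cluster results are reproducible under a fixed seed", {
  set.seed(33)
  a <- null_maps(10, 10, 12)
  b <- null_maps(10, 10, 12)
  c1 <- cluster_permutation(a, b, "paired_t", n_permutations = 80, seed = 9)
  c2 <- cluster_permutation(a, b, "paired_t", n_permutations = 80, seed = 9)
  expect_identical(c1$null_max, c2$null_max)
  expect_identical(c1$clusters, c2$clusters)
})
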