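test_that("circular mean and resultant length follow vector arithmetic", {
  cm <- circ_mean(rep(pi / 4, 10))
  expect_equal(cm$mean, pi / 4)
  expect_equal(cm$r, 1)
  # antipodal pair cancels; mean direction is flagged undefined
  cm2 <- circ_mean(c(0, pi))
  expect_equal(cm2$r, 0, tolerance = 1e-12)
  expect_true(is.na(cm2$mean))
  cm3 <- circ_mean(c(0, pi / 2))
  expect_equal(cm3$mean, pi / 4)
  expect_equal(cm3$r, cos(pi / 4))
  expect_error(circ_mean(numeric(0)), "empty")
})

test_that("PLV is 1 for aligned phases, 0 for antipodal pairs, small under uniformity", {
  expect_equal(plv(rep(0.73, 50)), 1)
  expect_equal(plv(c(0, pi)), 0, tolerance = 1e-12)
  set.seed(11)
  expect_lt(plv(runif(10000, -pi, pi)), 0.03)
  # matrix input gives one PLV per column
  m <- cbind(rep(1, 8), seq(-pi, pi, length.out = 8))
  v <- plv(m)
  expect_length(v, 2)
  expect_equal(v[1], 1)
  expect_error(plv(numeric(0)), "empty")
})

test_that("PLV is trial-order invariant and decreases with phase noise", {
  set.seed(12)
  ang <- runif(30, -pi, pi)
  expect_equal(plv(ang), plv(sample(ang)))
  mean_plv <- vapply(c(8, 2, 0.5), function(k) {
    mean(replicate(40, plv(oscrep:::rvm(20, 0, k))))
  }, numeric(1))
  expect_true(all(diff(mean_plv) < 0))
})

test_that("Rayleigh test matches its closed forms at the extremes", {
  r <- rayleigh_test(rep(1.2, 20))
  expect_equal(unname(r$statistic), 20)
  expect_lt(r$p.value, 1e-6)
  grid <- seq(-pi, pi - 2 * pi / 20, length.out = 20)
  r0 <- rayleigh_test(grid)
  expect_equal(unname(r0$statistic), 0, tolerance = 1e-20)
  expect_equal(r0$p.value, 1, tolerance = 1e-6)
  expect_warning(rayleigh_test(c(0.1, 0.2, 0.3)), "n < 4")
})

test_that("angle tests are invariant to a constant rotation", {
  set.seed(13)
  ang <- oscrep:::rvm(25, 0.4, 2)
  r1 <- rayleigh_test(ang)
  r2 <- rayleigh_test(oscrep:::wrap_angle(ang + 1.1))
  expect_equal(unname(r1$statistic), unname(r2$statistic), tolerance = 1e-9)
  expect_equal(plv(ang), plv(ang + 1.1))
  u1 <- watson_u2(ang, ang + 0.5, n_permutations = 99, seed = 1)
  u2r <- watson_u2(oscrep:::wrap_angle(ang + 1.1),
                   oscrep:::wrap_angle(ang + 0.5 + 1.1),
                   n_permutations = 99, seed = 1)
  expect_equal(unname(u1$statistic), unname(u2r$statistic), tolerance = 1e-9)
})

test_that("Watson-Williams behaves on identical, separated, and diffuse groups", {
  set.seed(14)
  g <- oscrep:::rvm(50, 0, 8)
  ww_same <- watson_williams(list(g, g))
  expect_equal(unname(ww_same$statistic), 0, tolerance = 1e-9)
  expect_gt(ww_same$p.value, 0.99)
  ww_sep <- watson_williams(list(oscrep:::rvm(50, 0, 8), oscrep:::rvm(50, pi / 2, 8)))
  expect_lt(ww_sep$p.value, 0.001)
  ww_unif <- watson_williams(list(runif(30, -pi, pi), runif(30, -pi, pi)))
  expect_true("low_concentration" %in% ww_unif$flags)
  expect_true("recommend_watson_u2" %in% ww_unif$flags)
  expect_error(watson_williams(list(c(1, 2, 3), g)), "at least 5")
})

test_that("Watson's U2 permutation test detects separation and bounds p", {
  set.seed(15)
  a <- oscrep:::rvm(20, 0, 8)
  u_same <- watson_u2(a, a, n_permutations = 199, seed = 2)
  expect_equal(unname(u_same$statistic), 0, tolerance = 1e-12)
  expect_equal(u_same$p.value, 1)
  u_sep <- watson_u2(oscrep:::rvm(20, 0, 20), oscrep:::rvm(20, pi, 20),
                     n_permutations = 5000, seed = 3)
  expect_lte(u_sep$p.value, 0.001)
  # permutation p can never fall below 1 / (n_permutations + 1)
  for (i in 1:5) {
    u <- watson_u2(runif(12, -pi, pi), runif(12, -pi, pi),
                   n_permutations = 59, seed = i)
    expect_gte(u$p.value, 1 / 60)
    expect_lte(u$p.value, 1)
  }
  expect_error(watson_u2(numeric(0), a), "nonempty")
})
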