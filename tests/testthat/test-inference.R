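test_that("JZS Bayes factors agree with an independent quadrature oracle", {
  for (case in list(c(0, 20), c(1.5, 20), c(-0.22, 20), c(3.2, 19), c(6, 12))) {
    got <- jzs_bf_from_t(case[1], case[2])$bf10
    expect_equal(got, bf10_oracle(case[1], case[2]), tolerance = 1e-4)
  }
  expect_error(jzs_bf_from_t(NaN, 20), "finite")
})

test_that("JZS Bayes factor is symmetric in t and monotone in |t|", {
  expect_equal(jzs_bf_from_t(1.3, 20)$bf10, jzs_bf_from_t(-1.3, 20)$bf10,
               tolerance = 1e-9)
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(t) jzs_bf_from_t(t, 20)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_lt(bfs[1], 1)  # t = 0 favours the null
})

test_that("Chauvenet's criterion excludes the expected points", {
  mask <- chauvenet(c(rep(0, 9), 10))
  expect_identical(which(!mask), 10L)
  expect_true(all(chauvenet(c(1, 1.5, 2))))
  expect_true(all(chauvenet(rep(4, 6))))
  expect_error(chauvenet(c(1, 2)), "at least 3")
})

test_that("within-subject ANCOVA reports the paper's df arithmetic", {
  set.seed(20)
  id <- rep(1:20, each = 12)
  x <- runif(240)
  y <- 0.5 * x + rnorm(240, 0, 0.1)
  a <- within_subject_ancova(x, y, id)
  expect_equal(a$slope_df, c(1, 219))
  expect_equal(a$participant_df, c(19, 219))
  expect_equal(a$intercept_df, 19)
  expect_equal(a$slope, 0.5, tolerance = 0.1)
})

test_that("a perfect identity relation is recovered exactly", {
  set.seed(19)
  id <- rep(1:5, each = 12)
  x <- runif(60)
  a <- suppressWarnings(within_subject_ancova(x, x, id))
  expect_equal(a$slope, 1, tolerance = 1e-9)
  expect_equal(a$r, 1, tolerance = 1e-6)
  expect_true(all(abs(a$intercepts) < 1e-9))
})

test_that("a single participant degrades to ordinary regression", {
  set.seed(21)
  x <- runif(12); y <- x + rnorm(12, 0, 0.05)
  a <- within_subject_ancova(x, y, rep(1, 12))
  expect_equal(a$slope_df, c(1, 10))
  b <- lm(y ~ x)
  expect_equal(a$slope, unname(coef(b)[2]), tolerance = 1e-9)
})

test_that("ANCOVA slope p-values are uniform under independence", {
  set.seed(22)
  ps <- replicate(400, {
    id <- rep(1:10, each = 8)
    within_subject_ancova(runif(80), rnorm(80), id)$slope_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ANCOVA input contracts are enforced", {
  expect_error(within_subject_ancova(1:4, 1:4, c(1, 1, 2, 2)), "at least 3")
  x <- rep(1, 12)  # no covariate variance -> rank deficient
  expect_error(within_subject_ancova(x, rnorm(12), rep(1:2, each = 6)))
})

test_that("repeated-measures ANOVA matches the 2 x 12 df layout", {
  set.seed(23)
  d <- expand.grid(participant = 1:19, condition = c("matched", "unmatched"),
                   frequency = presentation_frequencies)
  d$amplitude <- rnorm(nrow(d))
  r <- rm_anova_2x12(d)
  expect_equal(r$df_main, c(1, 18))
  expect_equal(r$df_interaction, c(11, 198))
  expect_equal(r$bf_main$df, 18)
  # duplicated conditions collapse the main effect
  d2 <- expand.grid(participant = 1:19, frequency = presentation_frequencies)
  d2$base <- rnorm(nrow(d2))
  dup <- rbind(
    data.frame(participant = d2$participant, condition = "matched",
               frequency = d2$frequency, amplitude = d2$base),
    data.frame(participant = d2$participant, condition = "unmatched",
               frequency = d2$frequency, amplitude = d2$base))
  expect_lt(rm_anova_2x12(dup)$f_main, 1e-9)
  # missing cells error
  expect_error(rm_anova_2x12(d[-1, ]), "missing cells")
})

test_that("repeated-measures ANOVA has power for a 1 SD condition offset", {
  set.seed(24)
  hits <- replicate(300, {
    base <- matrix(rnorm(19 * 12), 19, 12)
    diff_p <- rnorm(19, mean = 1, sd = 1)
    d <- rbind(
      data.frame(participant = rep(1:19, 12), condition = "matched",
                 frequency = rep(presentation_frequencies, each = 19),
                 amplitude = as.vector(base + diff_p)),
      data.frame(participant = rep(1:19, 12), condition = "unmatched",
                 frequency = rep(presentation_frequencies, each = 19),
                 amplitude = as.vector(base + matrix(rnorm(19 * 12), 19, 12))))
    rm_anova_2x12(d)$p_main < 0.05
  })
  expect_gt(mean(hits), 0.9)
})
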