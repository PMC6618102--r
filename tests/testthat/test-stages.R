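test_that("min-max normalisation spans [0,1] and is affine-invariant", {
  expect_equal(normalize_profile(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1)
  expect_equal(normalize_profile(v), v)
  set.seed(40)
  x <- rnorm(12)
  expect_equal(normalize_profile(3.2 * x - 7), normalize_profile(x))
  expect_error(normalize_profile(rep(1, 5)), "zero range")
})

test_that("correlation stage recovers the behaviour/amplitude coupling", {
  cr <- run_correlation_stage(coupled_study())
  expect_s3_class(cr, "osc_correlation")
  expect_equal(cr$ancova$slope, 1, tolerance = 0.2)
  expect_gt(cr$ancova$r, 0.7)
  expect_lt(cr$ancova$slope_p, 1e-6)
  # normalised profiles span [0,1] per participant
  pr <- cr$profiles
  for (p in unique(pr$participant)) {
    expect_equal(range(pr$amplitude_norm[pr$participant == p]), c(0, 1))
    expect_equal(range(pr$accuracy_norm[pr$participant == p]), c(0, 1))
  }
})

test_that("correlation stage rejects missing behaviour", {
  st <- coupled_study()
  st$schedule$response <- NA_integer_
  expect_error(run_correlation_stage(st), "behavioural responses")
})

test_that("single-participant correlation degrades to ordinary regression", {
  st <- simulate_study(gamma_off(reject_rate = 0), 1, 1, 12, 12, seed = 87)
  cr <- run_correlation_stage(st)
  expect_equal(cr$ancova$slope_df, c(1, 10))
})

test_that("entrainment stage finds matched > unmatched with injected gain", {
  st <- coupled_study()
  en <- run_entrainment_stage(st)
  expect_s3_class(en, "osc_entrainment")
  expect_gt(en$anova$mean_difference, 0)
  expect_lt(en$anova$p_main, 0.01)
  expect_gt(en$anova$bf_main$bf10, 3)
  # identical band/window measurement: only provenance differs, so the
  # matched and unmatched columns are on a common scale
  expect_equal(dim(table(en$table$participant, en$table$frequency)),
               c(8, 12))
  # reproducible under the stage seed
  en2 <- run_entrainment_stage(st, seed = en$seed)
  expect_identical(en$table, en2$table)
})

test_that("a constructed outlier participant is excluded by Chauvenet", {
  st <- coupled_study()
  st$epochs[[3]] <- st$epochs[[3]] * 40  # wildly scaled virtual sensor
  en <- run_entrainment_stage(st)
  expect_true(3 %in% en$excluded)
  expect_equal(en$anova$n_participants, 7)
})

test_that("success contrast enforces equal trial counts per condition", {
  st <- success_study()
  sc <- run_success_contrast_stage(st, n_permutations = 60, decim = 24)
  expect_s3_class(sc, "osc_success")
  expect_true(all(sc$counts >= 1))
  sched <- st$schedule
  for (p in sc$participants) {
    hp <- sched[sched$participant == p & !sched$rejected &
                  sched$frequency %in% high_prevalence_frequencies, ]
    expect_lte(2 * sc$counts[as.character(p)],
               nrow(hp))
    expect_equal(unname(sc$counts[as.character(p)]),
                 min(sum(hp$correct), sum(!hp$correct)))
  }
  expect_identical(dim(sc$clusters$amplitude_raw$stat_map),
                   c(98L, length(sc$times)))
})

test_that("participants without failures are dropped with a warning", {
  st <- success_study()
  rows <- st$schedule$participant == 2 &
    st$schedule$frequency %in% high_prevalence_frequencies
  st$schedule$correct[rows] <- TRUE
  expect_warning(
    sc <- run_success_contrast_stage(st, n_permutations = 40, decim = 24),
    "excluded from the success contrast")
  expect_true(2 %in% sc$excluded)
  expect_false(2 %in% sc$participants)
})

test_that("success contrast is bit-reproducible under its seed", {
  st <- success_study()
  s1 <- run_success_contrast_stage(st, seed = 5, n_permutations = 40, decim = 24)
  s2 <- run_success_contrast_stage(st, seed = 5, n_permutations = 40, decim = 24)
  expect_identical(s1$clusters$phase_angle$clusters,
                   s2$clusters$phase_angle$clusters)
  expect_identical(s1$counts, s2$counts)
})

test_that("raising the entrainment gain raises the matched-unmatched difference", {
  diffs <- vapply(c(0, 1, 2.5), function(g) {
    st <- simulate_study(gamma_off(entrain_gain = g, reject_rate = 0),
                         4, 1, 8, 8, seed = 55)
    en <- run_entrainment_stage(st, seed = 1)
    en$anova$mean_difference
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})
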