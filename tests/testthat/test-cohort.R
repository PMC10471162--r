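test_that("sliding windows count, drop and order subjects deterministically", {
  mk <- function(n) tibble::tibble(id = sprintf("s%03d", 1:n), score = rnorm(n))
  set.seed(20)
  w <- sliding_windows(mk(292), "score")
  expect_equal(nrow(w), 55L)   # floor((292 - 20)/5) + 1
  expect_equal(nrow(sliding_windows(mk(20), "score")), 1L)
  expect_message(w24 <- sliding_windows(mk(24), "score"), "4 trailing")
  expect_equal(nrow(w24), 1L)
  expect_error(sliding_windows(mk(10), "score"), "window_length")

  # ties in score are broken by id
  d <- tibble::tibble(id = c("b", "a", "c"), score = c(1, 1, 0))
  s <- attr(sliding_windows(d, "score", window_length = 3L, step = 1L), "sorted")
  expect_equal(s$id, c("c", "a", "b"))

  # window starts advance by the step
  expect_equal(diff(w$start), rep(5L, 54L))
  expect_true(all(lengths(w$members) == 20L))
})

test_that("windowed behavioral analysis is deterministic and order-invariant", {
  coh <- fixture("cohort_beh", simulate_cohort(60, seed = 31))
  r1 <- suppressMessages(window_behavior_analysis(coh, "em_recognition",
                                                  window_length = 10L, step = 5L,
                                                  parameters = c("left_y", "right_y")))
  r2 <- suppressMessages(window_behavior_analysis(coh, "em_recognition",
                                                  window_length = 10L, step = 5L,
                                                  parameters = c("left_y", "right_y")))
  expect_identical(r1$f_test, r2$f_test)

  # permuting the cohort row order leaves the result unchanged
  perm <- withr::with_seed(1, sample(60))
  coh_p <- coh
  coh_p$covariates <- coh$covariates[perm, ]
  coh_p$sims <- coh$sims[perm]
  r3 <- suppressMessages(window_behavior_analysis(coh_p, "em_recognition",
                                                  window_length = 10L, step = 5L,
                                                  parameters = c("left_y", "right_y")))
  expect_equal(r3$f_test, r1$f_test, tolerance = 1e-12)
  expect_equal(r3$correlations, r1$correlations, tolerance = 1e-12)
})

test_that("missing scores are dropped listwise per analysis", {
  coh <- fixture("cohort_beh", simulate_cohort(60, seed = 31))
  coh$covariates$em_recognition[c(3, 10, 50)] <- NA
  r <- suppressMessages(window_behavior_analysis(coh, "em_recognition",
                                                 window_length = 10L, step = 5L,
                                                 parameters = c("left_y", "right_y")))
  used <- unique(unlist(r$windows$ids))
  expect_false(any(coh$covariates$id[c(3, 10, 50)] %in% used))

  # with all 18 parameters there are too few windows at this n
  expect_error(suppressMessages(window_behavior_analysis(coh, "em_recognition",
                                                         window_length = 10L,
                                                         step = 5L)),
               "regressors")
})

test_that("per-year analysis reduces to the subject TSM for singleton bins", {
  coh <- fixture("cohort_year", simulate_cohort(30, age_range = c(18, 88), seed = 33))
  res <- suppressWarnings(per_year_age_analysis(coh, parameters = c("left_y", "right_y")))
  year <- floor(coh$covariates$age)
  singles <- which(table(year)[as.character(res$bins$year)] == 1)
  b <- singles[1]
  subj <- which(year == res$bins$year[b])
  own <- lcgrad:::bilateral_params(fit_bilateral(roi_gradient(coh$sims[[subj]], coh$coords,
                                                     source = "group")))
  expect_equal(unname(res$params[b, "left_y"]), own[["left_y"]], tolerance = 1e-12)
  expect_equal(nrow(res$bins), length(unique(year)))
})

test_that("clusterability analysis is reproducible and tidy-accessible", {
  coh <- fixture("cohort_year", simulate_cohort(30, age_range = c(18, 88), seed = 33))
  c1 <- clusterability_vs_age(coh)
  c2 <- clusterability_vs_age(coh)
  expect_identical(c1$subjects$ch, c2$subjects$ch)
  expect_true(all(c1$subjects$ch > 0))
  expect_equal(nrow(tidy(c1)), 30L)
  expect_named(glance(c1), c("rho", "statistic", "df", "p_value", "n"))
})

test_that("bootstrap group comparison validates groups and is seed-stable", {
  coh <- fixture("cohort_boot", simulate_cohort(70, seed = 35))
  ids <- coh$covariates$id
  g1 <- bootstrap_group_comparison(coh, groups = list(a = ids[1:35], b = ids[36:70]),
                                   draw = 10L, iterations = 25L, seed = 9)
  g2 <- bootstrap_group_comparison(coh, groups = list(a = ids[1:35], b = ids[36:70]),
                                   draw = 10L, iterations = 25L, seed = 9)
  expect_identical(g1$manova, g2$manova)
  expect_identical(g1$posthoc, g2$posthoc)
  expect_equal(nrow(g1$posthoc), 18L)
  expect_true(all(g1$posthoc$p_adjusted >= g1$posthoc$p_value))
  expect_error(bootstrap_group_comparison(coh, groups = list(ids[1:5], ids[6:70]),
                                          draw = 10L),
               "smaller than draw")
})

test_that("zero-variance voxels are excluded and imputed from neighbours", {
  cfg <- phantom_config(n_timepoints = 40L)
  sub <- simulate_subject(cfg, seed = 13)
  # flatten one ROI voxel's series
  idx <- which(sub$mask$data)
  m <- matrix(sub$bold$data, prod(dim(sub$mask$data)), 40)
  m[idx[10], ] <- 7
  bold <- sub$bold; bold$data <- array(m, dim = dim(bold$data))
  covs <- tibble::tibble(id = "s1", age = 50, sex = 0, education = 12)
  expect_message(coh <- cohort_from_volumes(list(bold), sub$mask, sub$atlas, covs),
                 "zero-variance")
  expect_equal(coh$exclude, 10L)
  g <- roi_gradient(coh$sims[[1]], coh$coords, exclude = coh$exclude)
  expect_true(is.finite(g$values[10]))
  # imputed as the mean of its in-mask 6-neighbours
  co <- coh$coords
  d <- abs(co$i - co$i[10]) + abs(co$j - co$j[10]) + abs(co$k - co$k[10])
  expect_equal(g$values[10], mean(g$values[which(d == 1)]), tolerance = 1e-12)
})

test_that("windowed F separates a coupled score from a pure-noise score", {
  # The windowed wrapper is anticonservative by construction (overlapping
  # windows), so its value lies in effect-size contrast, not in nominal
  # size: the score coupled to the planted gradient must dominate a
  # pure-noise score from the same cohorts.
  f_pair <- vapply(1:5, function(s) {
    coh <- simulate_cohort(150, seed = 700 + s)
    c(coupled = suppressMessages(window_behavior_analysis(coh, "em_recognition"))$f_test$statistic,
      noise = suppressMessages(window_behavior_analysis(coh, "er_reappraisal"))$f_test$statistic)
  }, numeric(2))
  # individual noise seeds can still produce large spurious F values
  # (that is the documented anticonservatism), so the claim is about the
  # typical contrast, not every seed
  expect_gt(median(f_pair["coupled", ]), 2 * median(f_pair["noise", ]))
})

test_that("per-year and clusterability analyses hold their size under the null", {
  # one cohort's gradients, ages redrawn: gradients are independent of age
  coh <- simulate_cohort(120, seed = 801,
                         effects = cohort_effects(age_effect = 0,
                                                  sharpness_age_effect = 0,
                                                  em_coupling = 0,
                                                  er_coupling = 0,
                                                  hads_effect = 0))
  set.seed(802)
  rej_year <- mean(vapply(1:100, function(r) {
    coh$covariates$age <- runif(120, 18, 88)
    suppressWarnings(per_year_age_analysis(coh))$f_test$p_value < 0.05
  }, logical(1)))
  expect_gte(rej_year, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 100) - 1e-9)
  expect_lte(rej_year, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))

  ch <- clusterability_vs_age(coh)$subjects$ch
  set.seed(803)
  rej_ch <- mean(vapply(1:400, function(r) {
    age <- runif(120, 18, 88)
    sex <- rbinom(120, 1, 0.5)
    partial_spearman(ch, age, cbind(sex))$p_value < 0.05
  }, logical(1)))
  expect_gte(rej_ch, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lte(rej_ch, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})
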