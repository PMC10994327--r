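test_that("aic follows the SSE form and flags perfect fits", {
  expect_equal(aic(80, 80, 0), 0)                      # ln(1) = 0
  expect_equal(aic(0.8, 80, 2), 80 * log(0.01) + 4)    # -364.4136
  expect_equal(aic(3, 40, 2) - aic(3, 40, 0), 4)       # penalty arithmetic
  expect_equal(aic(0, 80, 2), -Inf)
  expect_error(aic(-1, 10, 0), "sse")
})

test_that("compare_paired reproduces textbook paired-t results", {
  mk <- function(model, aics, sses = rep(1, length(aics))) {
    data.frame(participant_id = paste0("S", seq_along(aics)), model = model,
               sse = sses, aic = aics, stringsAsFactors = FALSE)
  }
  # differences (-1, -2, -3): mean -2, sd 1 -> t = -2 / (1/sqrt(3))
  res <- compare_paired(mk("ARS", c(9, 8, 7)), mk("MT", c(10, 10, 10)))
  expect_equal(res$t_statistic, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$t_statistic, -3.464, tolerance = 1e-3)
  expect_equal(res$df, 2L)
  expect_equal(res$cohens_d, 2)
  expect_equal(res$p_value, pt(-2 * sqrt(3), 2))
  # identical vectors: exact null
  res0 <- compare_paired(mk("ARS", c(1, 2, 3)), mk("MT", c(1, 2, 3)))
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 0.5)
  expect_equal(res0$cohens_d, 0)
  # perfectly predicted participants are excluded first
  a <- mk("ARS", c(9, 8, 7, 5))
  b <- mk("MT", c(10, 10, 10, 4), sses = c(1, 1, 1, 0))
  res2 <- compare_paired(a, b)
  expect_equal(res2$n_pairs, 3L)
  expect_equal(res2$excluded_ids, "S4")
  expect_error(compare_paired(mk("ARS", c(1, 2)), mk("MT", c(2, 3))),
               "insufficient")
})

test_that("classification follows the threshold rule and is configurable", {
  expect_equal(classify_strategy(c(0.50, 0.00, 0.30, 1.00, 0.80),
                                 c(0.00, 0.00, 0.90, 0.00, 0.20)),
               c("MT", "LAT", "HR", "HAT", "HAT"))
  # psi dominates tau
  expect_equal(classify_strategy(0.9, 0.51), "HR")
  loose <- list(psi = 0.5, tau_low = 0.1, tau_high = 0.9)
  expect_equal(classify_strategy(0.2, 0, loose), "MT")
  # noiseless archetype fits classify perfectly for any interior thresholds
  chain <- run_chain(rbind(pure_mixture("MT", 1, 0.5),
                           pure_mixture("LAT", 1, 0.5),
                           pure_mixture("HAT", 1, 0.5),
                           pure_mixture("HR", 1, 0.5)),
                     design_seed = 41L, cohort_seed = 42L)
  ars <- merge(chain$fits[chain$fits$model == "ARS", ], chain$truth,
               by = "participant_id")
  for (thr in list(default_thresholds(),
                   list(psi = 0.2, tau_low = 0.05, tau_high = 0.95),
                   list(psi = 0.8, tau_low = 0.45, tau_high = 0.55))) {
    expect_equal(classify_strategy(ars$tau_hat, ars$psi_hat, thr),
                 ars$strategy_label)
  }
})

test_that("cohort_report aggregates scores, prevalence and recovery", {
  chain <- run_chain(default_mixture(), design_seed = 51L, cohort_seed = 52L)
  rep <- cohort_report(chain$scores, truth = chain$truth,
                       delta_fits = chain$delta_fits,
                       choices = chain$choices, design = chain$design,
                       inferences = chain$inferences)
  expect_s3_class(rep, "hetg_report")
  expect_setequal(rep$aic_summary$model, c("ARS", "HAT", "LAT", "MT", "HR"))
  expect_true(all(is.finite(rep$aic_summary$mean_aic)))
  expect_equal(sum(rep$prevalence$count), 34L)
  expect_equal(sum(rep$prevalence$percent), 100, tolerance = 0.2)
  expect_equal(nrow(rep$comparisons), 4L)
  expect_true(all(rep$comparisons$model_a == "ARS"))
  # ARS AIC never exceeds the matching archetype AIC by more than the
  # 2-parameter penalty (nesting + k = 2)
  sc <- chain$scores
  wide <- tapply(sc$aic, list(sc$participant_id, sc$model), mean)
  fin <- is.finite(wide[, "ARS"])
  expect_true(all(wide[fin, "ARS"] <=
                    apply(wide[fin, colnames(wide) != "ARS", drop = FALSE], 1, min) + 4 + 1e-9))
  expect_gte(rep$recovery$strategy_accuracy, 0.7)
  expect_output(print(rep), "Strategy prevalence")
  # in a cohort dominated by equity-minded agents, ARS should strictly
  # dominate badly-matched archetype models
  hat_vs <- rep$comparisons[rep$comparisons$model_b == "HAT", ]
  expect_lt(hat_vs$p_value, 0.05)
})
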