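test_that("preference matches hand evaluations and stays in [0, 1]", {
  expect_equal(preference(5, 2, tau = 0.5, psi = 0), 0.9)
  expect_equal(preference(10, 2, tau = 0.3, psi = 1), 1.0)
  expect_equal(preference(5, 2, tau = 0.4, psi = 0.5), 0.9)
  # all valid task inputs give scores in [0, 1]
  for (cand in list(c(2, 5, 10), c(5, 10, 20), c(10, 20, 50))) {
    for (i in 1:10) {
      if (i <= min(cand)) {
        p <- outer(seq(0, 1, 0.1), seq(0, 1, 0.1),
                   Vectorize(function(tau, psi) max(preference(cand, i, tau, psi))))
        expect_true(all(p >= 0 & p <= 1))
      }
    }
  }
  expect_error(preference(0, 2, 0.5, 0), "E")
})

# noiseless archetype cohorts used by several blocks below
noiseless <- run_chain(rbind(pure_mixture("MT", 1, 0.6),
                             pure_mixture("LAT", 1, 0.6),
                             pure_mixture("HAT", 1, 0.6),
                             pure_mixture("HR", 1, 0.6)))

test_that("noiseless archetype agents recover their exact coordinates", {
  ars <- merge(noiseless$fits[noiseless$fits$model == "ARS", ], noiseless$truth,
               by = "participant_id")
  expect_equal(nrow(ars), 4L)
  expect_equal(ars$sse, rep(0, 4L))
  expect_equal(ars$deviance, rep(-Inf, 4L))
  expect_equal(ars$tau_hat[ars$strategy_label == "MT"], 0.5)
  expect_equal(ars$psi_hat[ars$strategy_label == "MT"], 0)
  expect_equal(ars$tau_hat[ars$strategy_label == "LAT"], 0)
  expect_equal(ars$tau_hat[ars$strategy_label == "HAT"], 1)
  expect_equal(ars$psi_hat[ars$strategy_label == "HR"], 1)
})

test_that("matching single-strategy models fit noiseless archetypes perfectly", {
  fits <- merge(noiseless$fits, noiseless$truth, by = "participant_id")
  own <- fits[fits$model == fits$strategy_label, ]
  expect_equal(own$sse, rep(0, 4L))
  expect_true(all(own$k == 0L))
  # HAT prefers the smallest candidate on every block-1 trial
  hat_id <- noiseless$truth$participant_id[noiseless$truth$strategy_label == "HAT"]
  ch <- noiseless$choices
  b1 <- ch$participant_id == hat_id & ch$condition == "ambiguous" & ch$investment == 2
  expect_true(all(ch$resolved_endowment[b1] == 2))
  expect_error(fit_single_strategy(noiseless$inferences, noiseless$design, "XX"),
               "unknown strategy")
})

test_that("ARS nests the archetypes: its SSE never exceeds theirs", {
  for (chain in list(noiseless,
                     run_chain(default_mixture(), design_seed = 31L,
                               cohort_seed = 32L))) {
    sse <- tapply(chain$fits$sse, list(chain$fits$participant_id, chain$fits$model), mean)
    expect_true(all(sse[, "ARS"] <= apply(sse[, colnames(sse) != "ARS"], 1L, min) + 1e-12))
  }
})

test_that("halving the grid spacing never increases the minimal deviance", {
  one <- noiseless$inferences[noiseless$inferences$participant_id ==
                                noiseless$truth$participant_id[1L], ]
  coarse <- fit_ars_grid(one, noiseless$design, grid_points = 26L)
  fine <- fit_ars_grid(one, noiseless$design, grid_points = 51L)
  expect_lte(fine$sse, coarse$sse)
})

test_that("a noisy MT agent's tau is recovered within 0.05", {
  # Monte-Carlo oracle, scaled down from 200 to 40 replicates for runtime;
  # the median-error bound is unchanged.
  des <- generate_session(seed = 17L)
  errs <- vapply(seq_len(40L), function(r) {
    set.seed(4000L + r)
    agent <- agent_params(0.5, tau = 0.5, psi = 0, noise_sd = 0.05)
    choices <- cbind(participant_id = "S1", simulate_session(agent, des),
                     stringsAsFactors = FALSE)
    dfit <- fit_delta_cohort(choices, des)
    inf <- infer_endowments(choices, des, dfit)
    fit_ars_grid(inf, des)$tau_hat - 0.5
  }, 0)
  expect_lte(median(abs(errs)), 0.05)
})

test_that("the preference-gap loss is available and also nests", {
  one <- noiseless$inferences[noiseless$inferences$participant_id ==
                                noiseless$truth$participant_id[1L], ]
  ars <- fit_ars_grid(one, noiseless$design, loss = "preference")
  expect_equal(ars$sse, 0)
  for (s in c("HAT", "LAT", "MT", "HR")) {
    single <- fit_single_strategy(one, noiseless$design, s, loss = "preference")
    expect_gte(single$sse + 1e-12, ars$sse)
  }
})
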