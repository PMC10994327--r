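test_that("exact inverse recovers the worked example and round-trips", {
  res <- invert_return_exact(7.5, 5, 0.5, c(5, 10, 20))
  expect_equal(res$e_inferred, 10)
  expect_equal(res$snapped_candidate, 10)
  expect_false(res$censored)

  # round trip: forward-evaluate at the inverse for every block, candidate,
  # integer investment and a delta sweep with positive predicted return
  blocks <- list(list(i = 2L, cand = c(2, 5, 10)),
                 list(i = 4:5, cand = c(5, 10, 20)),
                 list(i = 7:10, cand = c(10, 20, 50)))
  for (b in blocks) {
    for (i in b$i) {
      for (E in b$cand[b$cand >= i]) {
        for (delta in seq(0.05, 0.95, by = 0.05)) {
          r2 <- predict_return(E, i, 4, delta)
          if (r2 > 0) {
            got <- invert_return_exact(r2, i, delta, b$cand)
            expect_equal(got$e_inferred, E, tolerance = 1e-9)
          }
        }
      }
    }
  }
})

test_that("unclamped exact inverse is strictly decreasing in the return", {
  for (delta in c(0.2, 0.5, 0.8)) {
    r2 <- seq(0.5, 8, by = 0.5)
    e <- (r2 - 2 - 3 * 2 * delta) / (delta - 1)
    expect_true(all(diff(e) < 0))
  }
})

test_that("zero returns are censored and assigned the largest candidate", {
  res <- invert_return_exact(0, 2, 0.3, c(2, 5, 10))
  expect_true(res$censored)
  expect_equal(res$e_inferred, 10)
  expect_equal(res$snapped_candidate, 10)
  # continuity: a tiny positive return snaps like the zero return does
  eps <- invert_return_exact(0.05, 2, 0.3, c(2, 5, 10))
  expect_false(eps$censored)
  expect_equal(eps$snapped_candidate, 10)
  expect_error(invert_return_exact(5, 2, 1, c(2, 5, 10)), "singular")
})

test_that("uncorrected shortcut differs from the exact inverse by I/(delta-1)", {
  expect_equal(invert_return_uncorrected(7.5, 5, 0.5, 20), 0)  # vs exact 10
  for (delta in seq(0.1, 0.9, by = 0.1)) {
    for (i in c(2, 5, 9)) {
      for (r2 in c(1, 4, 4 * i - 0.5)) {
        exact <- (r2 - i - 3 * i * delta) / (delta - 1)
        shortcut <- (r2 - 3 * i * delta) / (delta - 1)
        expect_equal(shortcut - exact, i / (delta - 1), tolerance = 1e-12)
        if (shortcut < 1e6) {
          expect_equal(invert_return_uncorrected(r2, i, delta, 1e6), shortcut)
        }
      }
    }
  }
})

test_that("cohort inference joins fits and design and respects the method switch", {
  des <- generate_session(seed = 5L)
  sim <- simulate_cohort(pure_mixture("MT", 2, 0.55), des, seed = 2L)
  fits <- fit_delta_cohort(sim$choices, des)
  inf <- infer_endowments(sim$choices, des, fits)
  expect_equal(nrow(inf), 2L * 80L)
  expect_true(all(inf$method == "exact_inverse"))
  amb <- des[des$condition == "ambiguous", ]
  lo <- pmin(amb$cand1, amb$cand2, amb$cand3)[match(inf$trial_index, amb$trial_index)]
  hi <- pmax(amb$cand1, amb$cand2, amb$cand3)[match(inf$trial_index, amb$trial_index)]
  expect_true(all(inf$e_inferred >= lo - 1e-9 & inf$e_inferred <= hi + 1e-9))
  # noiseless agents acted on their resolved endowment: inference recovers it
  ch <- sim$choices[sim$choices$condition == "ambiguous", ]
  key <- paste(ch$participant_id, ch$trial_index)
  ikey <- paste(inf$participant_id, inf$trial_index)
  uncensored <- !inf$censored[match(key, ikey)]
  expect_true(all(inf$snapped_candidate[match(key, ikey)][uncensored] ==
                    ch$resolved_endowment[uncensored]))
  un <- infer_endowments(sim$choices, des, fits, method = "uncorrected")
  expect_true(all(un$method == "uncorrected"))
  expect_false(all(un$e_inferred == inf$e_inferred))
})
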