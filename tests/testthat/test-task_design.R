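test_that("trust bands follow the printed closed intervals, gaps unbanded", {
  expect_equal(trust_band(c(0.20, 0.50, 0.30)), c("low", "medium", "unbanded"))
  expect_equal(trust_band(c(0.05, 0.25, 0.35, 0.70, 1.00)),
               c("low", "low", "medium", "high", "high"))
  expect_equal(trust_band(7 / 20), "medium")  # exact boundary via division
  expect_equal(trust_band(0.02), "unbanded")  # below the lowest band
  expect_error(trust_band(0), "ratio")
  expect_error(trust_band(1.2), "ratio")
})

test_that("unambiguous generator matches the stated design constraints", {
  trials <- generate_unambiguous_trials(seed = 42L)
  expect_equal(nrow(trials), 40L)
  expect_true(all(trials$condition == "unambiguous"))
  expect_true(all(trials$multiplier == 4))
  expect_true(all(trials$investment > 0 & trials$investment <= trials$endowment))
  # modal endowment is 10 and modal transfer is half the endowment
  expect_equal(as.integer(names(which.max(table(trials$endowment)))), 10L)
  ratio <- trials$investment / trials$endowment
  expect_equal(as.numeric(names(which.max(table(ratio)))), 0.5)
  expect_setequal(unique(trials$trust_band), c("low", "medium", "high"))
})

test_that("single-entry frequency table passes through; bad counts error", {
  cfg <- list(unambiguous = data.frame(endowment = 10, investment = 5, count = 1))
  one <- generate_unambiguous_trials(1L, cfg, seed = 1L)
  expect_equal(one$endowment, 10)
  expect_equal(one$investment, 5)
  expect_equal(one$multiplier, 4)
  expect_error(generate_unambiguous_trials(40L, cfg, seed = 1L), "configuration")
  bad <- list(unambiguous = data.frame(endowment = 5, investment = 7, count = 40))
  expect_error(generate_unambiguous_trials(40L, bad, seed = 1L), "configuration")
})

test_that("ambiguous generator reproduces the printed block structure", {
  trials <- generate_ambiguous_trials(seed = 3L)
  expect_equal(nrow(trials), 80L)
  key <- paste(trials$cand1, trials$cand2, trials$cand3)
  expect_equal(sum(key == "2 5 10"), 20L)
  expect_equal(sum(key == "5 10 20"), 20L)
  expect_equal(sum(key == "10 20 50"), 40L)
  expect_true(all(trials$investment[key == "2 5 10"] == 2))
  expect_true(all(trials$investment[key == "5 10 20"] %in% 4:5))
  expect_true(all(trials$investment[key == "10 20 50"] %in% 7:10))
  # truth is always drawn among the displayed candidates
  expect_true(all(trials$endowment == trials$cand1 |
                    trials$endowment == trials$cand2 |
                    trials$endowment == trials$cand3))
})

test_that("candidate trust ratios occupy all three bands, exhaustively", {
  # every integer investment in each printed block x its candidate triple
  blocks <- list(list(i = 2L, cand = c(2, 5, 10)),
                 list(i = 4:5, cand = c(5, 10, 20)),
                 list(i = 7:10, cand = c(10, 20, 50)))
  for (b in blocks) {
    for (i in b$i) {
      bands <- trust_band(i / b$cand)
      expect_setequal(bands, c("high", "medium", "low"))
    }
  }
})

test_that("session generation is a pure function of (config, seed)", {
  a <- generate_session(seed = 9L)
  b <- generate_session(seed = 9L)
  expect_identical(a, b)
  expect_equal(table(a$condition), table(c(rep("ambiguous", 80), rep("unambiguous", 40))))
  # unambiguous rounds strictly precede ambiguous ones
  expect_true(all(which(a$condition == "unambiguous") <= 40))
  d <- generate_session(seed = 10L)
  expect_false(identical(a$endowment, d$endowment))
})

test_that("design CSV round-trips", {
  des <- generate_session(seed = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(des, path)
  back <- read_design_csv(path)
  expect_equal(back$endowment, des$endowment)
  expect_equal(back$cand3, des$cand3)
  expect_equal(back$trust_band, des$trust_band)
})
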