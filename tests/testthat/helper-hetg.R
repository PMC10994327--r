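# Shared fixtures, all built in code.

# One ambiguous trial row, as the design functions would emit it.
amb_trial <- function(investment, candidates, trial_index = 1L) {
  data.frame(
    trial_index = trial_index, condition = "ambiguous",
    endowment = candidates[2L], investment = investment, multiplier = 4,
    cand1 = candidates[1L], cand2 = candidates[2L], cand3 = candidates[3L],
    trust_band = "unbanded", stringsAsFactors = FALSE
  )
}

unamb_trial <- function(endowment, investment, trial_index = 1L) {
  data.frame(
    trial_index = trial_index, condition = "unambiguous",
    endowment = endowment, investment = investment, multiplier = 4,
    cand1 = NA_real_, cand2 = NA_real_, cand3 = NA_real_,
    trust_band = "unbanded", stringsAsFactors = FALSE
  )
}

# Full analysis chain (delta fit -> inversion -> ARS fits) for a cohort.
run_chain <- function(mixture, design_seed = 7L, cohort_seed = 13L,
                      grid_points = 101L) {
  design <- generate_session(seed = design_seed)
  sim <- simulate_cohort(mixture, design, seed = cohort_seed)
  delta_fits <- fit_delta_cohort(sim$choices, design)
  inferences <- infer_endowments(sim$choices, design, delta_fits)
  fits <- fit_ars_cohort(inferences, design, grid_points = grid_points)
  list(design = design, choices = sim$choices, truth = sim$truth,
       delta_fits = delta_fits, inferences = inferences,
       fits = fits, scores = score_models(fits))
}

# Single-archetype mixture row.
pure_mixture <- function(strategy, count, delta, noise_sd = 0) {
  data.frame(strategy = strategy, count = as.integer(count),
             delta_min = delta, delta_max = delta, noise_sd = noise_sd,
             stringsAsFactors = FALSE)
}
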