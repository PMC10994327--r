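# Synthetic trustee agents.
#
# An agent is described by a fairness norm delta (inequity-aversion model),
# an ambiguity-resolution preference (tau, psi) and a response-noise scale
# expressed as a proportion of the pot. Simulated cohorts come with a
# ground-truth table so estimator recovery can be scored.

#' Construct a synthetic trustee's generating parameters
#'
#' @param delta Fairness norm, in \[0, 1\]: the share of all money in the
#'   game the trustee deems fair for the Investor to end with (0 = return
#'   nothing, 0.5 = equalize payouts, 1 = return the whole pot).
#' @param tau Default assumed trustingness, in \[0, 1\].
#' @param psi Weight on the investment-magnitude heuristic, in \[0, 1\].
#' @param noise_sd Response-noise standard deviation as a proportion of the
#'   pot (I x M); >= 0.
#' @param label Optional strategy label carried into ground-truth tables.
#' @return An object of class `hetg_agent`.
#' @export
agent_params <- function(delta, tau = 0.5, psi = 0, noise_sd = 0, label = NULL) {
  assert_unit_interval(delta, "delta")
  assert_unit_interval(tau, "tau")
  assert_unit_interval(psi, "psi")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_usage("`noise_sd` must be >= 0")
  structure(
    list(delta = delta, tau = tau, psi = psi, noise_sd = noise_sd,
         label = label %||% NA_character_),
    class = "hetg_agent"
  )
}

#' Construct an archetype-strategy agent
#'
#' @param strategy One of `"HAT"`, `"LAT"`, `"MT"`, `"HR"`.
#' @param delta Fairness norm of the agent.
#' @param noise_sd Response-noise scale (proportion of the pot).
#' @return An object of class `hetg_agent` at the archetype's (tau, psi).
#' @export
archetype_agent <- function(strategy, delta, noise_sd = 0) {
  if (!strategy %in% names(ARCHETYPES)) {
    stop_usage("unknown strategy '%s' (use HAT, LAT, MT or HR)", strategy)
  }
  a <- ARCHETYPES[[strategy]]
  agent_params(delta, tau = a[["tau"]], psi = a[["psi"]],
               noise_sd = noise_sd, label = strategy)
}

#' Resolve an ambiguous endowment by ARS preference
#'
#' Returns the candidate endowment maximizing the agent's [preference()];
#' ties break toward the smaller endowment.
#'
#' @param agent A `hetg_agent`.
#' @param trial One ambiguous design row.
#' @return The acted-upon endowment (currency units).
#' @export
resolve_endowment <- function(agent, trial) {
  if (!identical(as.character(trial$condition), "ambiguous")) {
    stop_usage("resolve_endowment() applies to ambiguous trials only")
  }
  cands <- trial_candidates(trial)
  p <- preference(cands, trial$investment, agent$tau, agent$psi)
  cands[which.max(p)]
}

#' Simulate a trustee's return on one trial
#'
#' The acted-upon endowment is the true endowment on unambiguous trials and
#' the ARS-resolved candidate on ambiguous ones. The returned amount is the
#' inequity-aversion prediction ([predict_return()]) plus additive Gaussian
#' noise of scale `noise_sd * pot`, clipped to the feasible range
#' \[0, pot\] (the slider cannot return less than 0 or more than the pot, so
#' clipping puts point mass at the bounds — zero returns do occur, as in
#' real data). With `noise_sd = 0` the output equals the model prediction
#' exactly. Uses the current RNG stream; seed the caller.
#'
#' @param agent A `hetg_agent`.
#' @param trial One design row.
#' @return One-row data.frame: `trial_index`, `condition`, `investment`,
#'   `pot`, `returned`, `reciprocity`, `resolved_endowment` (`NA` on
#'   unambiguous trials).
#' @export
simulate_return <- function(agent, trial) {
  ambiguous <- identical(as.character(trial$condition), "ambiguous")
  e_act <- if (ambiguous) resolve_endowment(agent, trial) else trial$endowment
  pot <- trial$investment * trial$multiplier
  mu <- predict_return(e_act, trial$investment, trial$multiplier, agent$delta)
  ret <- if (agent$noise_sd > 0) {
    min(max(mu + rnorm(1L, 0, agent$noise_sd * pot), 0), pot)
  } else {
    mu
  }
  data.frame(
    trial_index = trial$trial_index,
    condition = as.character(trial$condition),
    investment = trial$investment,
    pot = pot,
    returned = ret,
    reciprocity = ret / pot,
    resolved_endowment = if (ambiguous) e_act else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate one agent's full session
#'
#' Vectorized equivalent of calling [simulate_return()] on every design row
#' in order (one noise draw per trial). Uses the current RNG stream; seed
#' the caller for reproducibility.
#'
#' @param agent A `hetg_agent`.
#' @param design Session design (or any subset of its rows).
#' @return Data.frame of choice records, one row per trial.
#' @export
simulate_session <- function(agent, design) {
  amb <- design$condition == "ambiguous"
  e_act <- design$endowment
  if (any(amb)) {
    cand <- t(apply(cbind(design$cand1[amb], design$cand2[amb], design$cand3[amb]),
                    1L, sort))
    p <- matrix(NA_real_, nrow(cand), ncol(cand))
    for (k in seq_len(ncol(cand))) {
      p[, k] <- preference(cand[, k], design$investment[amb], agent$tau, agent$psi)
    }
    pick <- max.col(p, ties.method = "first")   # ascending -> smaller endowment
    e_act[amb] <- cand[cbind(seq_len(nrow(cand)), pick)]
  }
  pot <- design$investment * design$multiplier
  mu <- predict_return(e_act, design$investment, design$multiplier, agent$delta)
  ret <- if (agent$noise_sd > 0) {
    pmin(pmax(mu + rnorm(nrow(design), 0, agent$noise_sd * pot), 0), pot)
  } else {
    mu
  }
  data.frame(
    trial_index = design$trial_index,
    condition = as.character(design$condition),
    investment = design$investment,
    pot = pot,
    returned = ret,
    reciprocity = ret / pot,
    resolved_endowment = ifelse(amb, e_act, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Default cohort mixture specification
#'
#' Emulates the strategy prevalence reported for the original 34-participant
#' cohort: 24 Modal Trust, 8 Lowest Assumed Trust and 2 Highest Assumed
#' Trust agents (roughly 71% / 23% / 6%), each with a fairness norm drawn
#' uniformly from \[0.3, 0.7\] (equal-split-centred norms typical of
#' trust-game trustees) and response noise of 0.05 of the pot.
#'
#' @return Data.frame with columns `strategy`, `count`, `delta_min`,
#'   `delta_max`, `noise_sd`.
#' @export
default_mixture <- function() {
  data.frame(
    strategy  = c("MT", "LAT", "HAT"),
    count     = c(24L, 8L, 2L),
    delta_min = 0.3,
    delta_max = 0.7,
    noise_sd  = 0.05
  )
}

#' Simulate a cohort of synthetic trustees over one session design
#'
#' Each mixture row contributes `count` agents of the given archetype
#' `strategy` (optionally with explicit `tau` / `psi` columns overriding the
#' archetype coordinates). Each agent's fairness norm is drawn uniformly
#' from \[`delta_min`, `delta_max`\] (rounded to the 0.01 grid) or fixed when
#' the two coincide. Every participant gets an independent, index-keyed RNG
#' substream derived from `seed`, so enlarging the cohort never changes the
#' data of existing participants.
#'
#' @param mixture Data.frame with columns `strategy`, `count`, `delta_min`,
#'   `delta_max`, `noise_sd` (see [default_mixture()]); optional `tau`,
#'   `psi`, `label` columns.
#' @param design Session design from [generate_session()].
#' @param seed Integer master seed.
#' @param id_prefix Participant-identifier prefix.
#' @return A list with elements `choices` (one row per participant x trial)
#'   and `truth` (per-participant generating parameters and strategy label).
#' @export
simulate_cohort <- function(mixture, design, seed = 1L, id_prefix = "S") {
  if (is.null(mixture) || nrow(mixture) == 0L) stop_usage("empty cohort mixture")
  if (any(mixture$count < 1L)) stop_usage("mixture counts must be >= 1")
  choices <- vector("list", sum(mixture$count))
  truth <- vector("list", sum(mixture$count))
  idx <- 0L
  for (r in seq_len(nrow(mixture))) {
    row <- mixture[r, ]
    for (j in seq_len(row$count)) {
      idx <- idx + 1L
      pid <- sprintf("%s%03d", id_prefix, idx)
      sim <- with_seed(participant_seed(seed, idx), {
        delta <- if (isTRUE(all.equal(row$delta_min, row$delta_max))) {
          row$delta_min
        } else {
          round(runif(1L, row$delta_min, row$delta_max), 2L)
        }
        custom <- all(c("tau", "psi") %in% names(row)) &&
          !is.na(row$tau) && !is.na(row$psi)
        agent <- if (custom) {
          lab <- if ("label" %in% names(row) && !is.na(row$label)) row$label else row$strategy
          agent_params(delta, tau = row$tau, psi = row$psi,
                       noise_sd = row$noise_sd, label = lab)
        } else {
          archetype_agent(row$strategy, delta, row$noise_sd)
        }
        list(agent = agent, session = simulate_session(agent, design))
      })
      ch <- sim$session
      ch <- cbind(participant_id = pid, ch, stringsAsFactors = FALSE)
      choices[[idx]] <- ch
      truth[[idx]] <- data.frame(
        participant_id = pid,
        delta = sim$agent$delta, tau = sim$agent$tau, psi = sim$agent$psi,
        noise_sd = sim$agent$noise_sd,
        strategy_label = sim$agent$label,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    choices = do.call(rbind, choices),
    truth = do.call(rbind, truth)
  )
}

#' Bonus payment for one trial under the session payment rule
#'
#' The trustee's payout is the pot minus what they returned; the total money
#' in the game is what the Investor kept (E - I) plus the pot; the bonus is
#' the trustee's share of that total scaled to EUR 16.
#'
#' @param record Choice record(s) with columns `returned` and (optionally)
#'   `pot`.
#' @param trial Matching design row(s) with `endowment`, `investment`,
#'   `multiplier`.
#' @return Bonus in EUR, in \[0, 16\].
#' @examples
#' tr <- data.frame(trial_index = 1, condition = "unambiguous",
#'                  endowment = 10, investment = 5, multiplier = 4)
#' bonus_payment(data.frame(returned = 10), tr)   # 6.4
#' @export
bonus_payment <- function(record, trial) {
  pot <- trial$investment * trial$multiplier
  payout <- pot - record$returned
  total <- (trial$endowment - trial$investment) + pot
  if (any(total <= 0)) stop_usage("total money in game must be positive")
  payout / total * 16
}
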