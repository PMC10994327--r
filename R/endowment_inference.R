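# Reverse inference of the hidden endowment from an observed return and a
# fitted fairness norm.
#
# Inverting the forward model R2 = max(0, (E + 3I)*delta - (E - I)) at M = 4
# for a positive return gives the exact inverse
#
#   E = (R2 - I - 3*I*delta) / (delta - 1).
#
# A widely circulated shortcut form of this inverse drops the -I term from
# the numerator; it is retained here behind method = "uncorrected" for audit
# comparisons and differs from the exact inverse by I / (delta - 1).

#' Exact inverse of the reciprocity model for one ambiguous trial
#'
#' For a positive observed return the unclamped inverse round-trips through
#' [predict_return()] to machine precision; the result is then clamped to
#' the candidate range (an endowment outside the displayed candidates is
#' impossible in the task). A zero return is censored — the model's max()
#' floor binds, so the endowment is only boundable: the trial is flagged and
#' assigned the largest candidate (the candidate most consistent with a
#' zero prediction).
#'
#' @param R2 Observed returned amount, in \[0, 4*I\].
#' @param I Investment.
#' @param delta Fitted fairness norm, in \[0, 1\). At `delta = 1` every
#'   endowment predicts a full-pot return and inference is singular (error).
#' @param candidates The trial's three candidate endowments.
#' @return One-row data.frame: `e_inferred`, `snapped_candidate`,
#'   `censored`, `method`.
#'
#' @details Snapping is done in observation space: the snapped candidate is
#' the one whose forward-predicted return is nearest the observed return,
#' with ties toward the larger endowment. Away from the zero-return floor
#' the forward model is linear in E, so this is identical to taking the
#' candidate nearest `e_inferred`; at and near the floor it treats a return
#' of 0 and a return of epsilon consistently (both favour the largest
#' candidate whose prediction is ~0), where nearest-endowment snapping
#' would jump discontinuously between candidates.
#'
#' @examples
#' invert_return_exact(7.5, 5, 0.5, c(5, 10, 20))  # e_inferred 10
#' @export
invert_return_exact <- function(R2, I, delta, candidates) {
  if (delta >= 1) stop_usage("inference is singular at delta = 1")
  assert_unit_interval(delta, "delta")
  if (R2 < 0 || R2 > 4 * I + 1e-9) stop_usage("`R2` must lie in [0, 4*I]")
  cands <- sort(as.numeric(candidates))
  if (R2 > 0) {
    e_raw <- (R2 - I - 3 * I * delta) / (delta - 1)
    censored <- FALSE
    e_inf <- min(max(e_raw, cands[1L]), cands[length(cands)])
  } else {
    # Eq-floor binds for all E >= I*(1+3*delta)/(1-delta); report the
    # largest candidate, the one most consistent with a zero return.
    censored <- TRUE
    e_inf <- cands[length(cands)]
  }
  pred <- pmax(0, (cands + 3 * I) * delta - (cands - I))
  dist <- abs(R2 - pred)
  snap_idx <- length(cands) + 1L - which.min(rev(dist))  # ties -> larger E
  data.frame(
    e_inferred = e_inf,
    snapped_candidate = cands[snap_idx],
    censored = censored,
    method = "exact_inverse",
    stringsAsFactors = FALSE
  )
}

#' Uncorrected (shortcut) inverse, for audit comparison
#'
#' Literal evaluation of the shortcut inverse
#' `min((R2 - 3*I*delta) / (delta - 1), E_max)`, which omits the `-I`
#' numerator term of the exact inverse and therefore differs from it by
#' `I / (delta - 1)` at every input. Provided so analyses run under either
#' convention can be compared.
#'
#' @inheritParams invert_return_exact
#' @param E_max Largest candidate endowment (upper clamp).
#' @return The shortcut-inferred endowment (numeric scalar; no lower clamp).
#' @export
invert_return_uncorrected <- function(R2, I, delta, E_max) {
  if (delta >= 1) stop_usage("inference is singular at delta = 1")
  assert_unit_interval(delta, "delta")
  min((R2 - 3 * I * delta) / (delta - 1), E_max)
}

#' Infer hidden endowments for every ambiguous trial in a cohort
#'
#' Joins ambiguous choice rows with the design candidates and each
#' participant's fitted fairness norm, then inverts each observed return.
#' Participants whose `delta_hat` is 1 are singular: their rows are emitted
#' with `NA` inferences and a warning.
#'
#' @param choices Choice table with `participant_id`, `trial_index`,
#'   `condition`, `investment`, `returned`.
#' @param design Session design.
#' @param delta_fits Per-participant fits from [fit_delta_cohort()].
#' @param method `"exact_inverse"` (default) or `"uncorrected"` (shortcut
#'   formula, lower-clamped to the smallest candidate for pipeline use).
#' @return Data.frame: `participant_id`, `trial_index`, `e_inferred`,
#'   `snapped_candidate`, `method`, `censored`.
#' @export
infer_endowments <- function(choices, design, delta_fits,
                             method = c("exact_inverse", "uncorrected")) {
  method <- match.arg(method)
  amb <- choices[choices$condition == "ambiguous", , drop = FALSE]
  if (nrow(amb) == 0L) stop_usage("no ambiguous trials in `choices`")
  didx <- match(amb$trial_index, design$trial_index)
  if (anyNA(didx)) stop_usage("choice rows refer to trials absent from the design")
  cand <- t(apply(cbind(design$cand1[didx], design$cand2[didx], design$cand3[didx]),
                  1L, sort))
  delta <- delta_fits$delta_hat[match(amb$participant_id, delta_fits$participant_id)]
  if (anyNA(delta)) stop_usage("missing delta fit for some participants")
  n <- nrow(amb)
  e_inf <- rep(NA_real_, n)
  snap <- rep(NA_real_, n)
  cens <- rep(NA, n)
  singular <- delta >= 1
  if (any(singular)) {
    warning(sprintf("%d trial(s) skipped: inference singular at delta_hat = 1 for participant(s) %s",
                    sum(singular),
                    paste(unique(amb$participant_id[singular]), collapse = ", ")),
            call. = FALSE)
  }
  for (i in which(!singular)) {
    if (method == "exact_inverse") {
      r <- invert_return_exact(amb$returned[i], amb$investment[i], delta[i], cand[i, ])
      e_inf[i] <- r$e_inferred
      snap[i] <- r$snapped_candidate
      cens[i] <- r$censored
    } else {
      e_raw <- invert_return_uncorrected(amb$returned[i], amb$investment[i],
                                         delta[i], cand[i, ncol(cand)])
      e_inf[i] <- max(e_raw, cand[i, 1L])
      snap[i] <- cand[i, which.min(abs(cand[i, ] - e_inf[i]))]
      cens[i] <- amb$returned[i] <= 0
    }
  }
  data.frame(
    participant_id = amb$participant_id,
    trial_index = amb$trial_index,
    e_inferred = e_inf,
    snapped_candidate = snap,
    method = method,
    censored = cens,
    stringsAsFactors = FALSE
  )
}
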