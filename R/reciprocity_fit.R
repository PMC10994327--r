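# Inequity-aversion reciprocity model: per-participant grid-search fit on
# unambiguous trials.
#
# The forward model predicts the amount a trustee returns as the share of
# all money in the game they deem fair for the Investor to end with, minus
# what the Investor already has, floored at zero (no repossession):
#
#   R2 = max(0, (E - I + I*M) * delta - (E - I))

#' Predicted return of the inequity-aversion model
#'
#' @param E Endowment (currency units), with `I <= E`.
#' @param I Investment (currency units), > 0.
#' @param M Multiplier (4 throughout the task).
#' @param delta Fairness norm in \[0, 1\].
#' @return Predicted returned amount, in \[0, I*M\].
#' @examples
#' predict_return(10, 5, 4, 0.5)  # 7.5: both players end with 12.5
#' @export
predict_return <- function(E, I, M = 4, delta) {
  if (any(I <= 0)) stop_usage("`I` must be > 0")
  if (any(I > E)) stop_usage("`I` must not exceed `E`")
  assert_unit_interval(delta, "delta")
  pmax(0, (E - I + I * M) * delta - (E - I))
}

#' Fit the fairness norm by grid-search least squares / NLL
#'
#' Minimizes the sum of squared residuals between observed and predicted
#' returns over an even `grid_points` grid on \[0, 1\] — equivalently
#' minimizes the Gaussian deviance with the ML plug-in scale
#' `sigma^2 = SSE / n`, since that deviance is monotone in SSE. Ties break
#' to the smallest delta.
#'
#' @param records Unambiguous-condition choice rows for one participant,
#'   with columns `endowment`, `investment`, `multiplier`, `returned`
#'   (optional `participant_id`).
#' @param grid_points Number of grid points on \[0, 1\] (default 101).
#' @param on Fit residuals on returned amounts (`"amount"`, default — the
#'   scale on which the forward model is stated) or on reciprocity
#'   proportions (`"proportion"`).
#' @return One-row data.frame: `participant_id`, `delta_hat`, `sse`,
#'   `sigma_hat`, `n`, `r_squared` (`NA` with a warning if the observed
#'   returns are constant), `deviance`.
#' @export
fit_delta <- function(records, grid_points = 101L, on = c("amount", "proportion")) {
  on <- match.arg(on)
  if (is.null(records) || nrow(records) == 0L) stop_usage("no trials to fit")
  if (grid_points < 2L) stop_usage("`grid_points` must be >= 2")
  E <- records$endowment
  I <- records$investment
  M <- records$multiplier
  obs <- records$returned
  if (anyNA(E)) stop_usage("fit_delta() needs trials with a known endowment")
  grid <- seq(0, 1, length.out = grid_points)
  A <- E - I + I * M
  B <- E - I
  P <- A %o% grid - B                 # n x grid predicted returns
  P[P < 0] <- 0                       # game-rule floor at zero
  if (on == "proportion") {
    pot <- I * M
    P <- P / pot
    obs <- obs / pot
  }
  sse_g <- colSums((obs - P)^2)
  j <- which.min(sse_g)               # first minimum = smallest delta
  n <- length(obs)
  sse <- sse_g[j]
  tss <- sum((obs - mean(obs))^2)
  r2 <- if (tss <= PERFECT_FIT_TOL) {
    warning("observed returns have zero variance; r_squared undefined", call. = FALSE)
    NA_real_
  } else {
    1 - sse / tss
  }
  data.frame(
    participant_id = if ("participant_id" %in% names(records)) records$participant_id[1L] else NA_character_,
    delta_hat = grid[j],
    sse = sse,
    sigma_hat = sqrt(sse / n),
    n = n,
    r_squared = r2,
    deviance = deviance_from_sse(sse, n),
    stringsAsFactors = FALSE
  )
}

#' Fit the fairness norm for every participant in a choice table
#'
#' Joins the unambiguous choice rows with the design (for the true
#' endowments) and fits each participant separately.
#'
#' @param choices Choice table (simulated or observed) with columns
#'   `participant_id`, `trial_index`, `condition`, `investment`, `returned`.
#' @param design Session design from [generate_session()].
#' @inheritParams fit_delta
#' @return Data.frame of per-participant fits.
#' @export
fit_delta_cohort <- function(choices, design, grid_points = 101L,
                             on = c("amount", "proportion")) {
  on <- match.arg(on)
  un <- choices[choices$condition == "unambiguous", , drop = FALSE]
  if (nrow(un) == 0L) stop_usage("no unambiguous trials in `choices`")
  idx <- match(un$trial_index, design$trial_index)
  un$endowment <- design$endowment[idx]
  un$multiplier <- design$multiplier[idx]
  out <- lapply(split(un, un$participant_id), fit_delta,
                grid_points = grid_points, on = on)
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Proportion of variance explained
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`. Undefined (returned
#' as `NA` with a warning) when the observed sequence is constant.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2).
#' @return A proportion (<= 1; can be negative for fits worse than the mean).
#' @examples
#' variance_explained(c(0, 1, 2, 5), c(0, 1, 2, 3))  # 0.2
#' @export
variance_explained <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2L) {
    stop_usage("`predicted` and `observed` must have equal length >= 2")
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss <= PERFECT_FIT_TOL) {
    warning("observed sequence is constant; variance explained undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / tss
}
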