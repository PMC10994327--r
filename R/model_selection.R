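# Model scoring (AIC), cohort-level paired comparisons and strategy
# classification.

#' Akaike Information Criterion from a sum of squared errors
#'
#' `AIC = n * ln(SSE / n) + 2 * k`, the SSE-based form appropriate for
#' Gaussian residual models with the scale profiled out. A perfect fit
#' (SSE = 0) returns `-Inf`: a signal that the participant is perfectly
#' predicted (and excluded from paired comparisons), not an error.
#'
#' @param sse Sum of squared errors (>= 0).
#' @param n Number of trials.
#' @param k Number of free parameters.
#' @return AIC value (vectorized).
#' @examples
#' aic(0.8, 80, 2)  # 80*log(0.01) + 4
#' @export
aic <- function(sse, n, k) {
  if (any(sse < 0) || any(n < 1) || any(k < 0)) {
    stop_usage("require sse >= 0, n >= 1, k >= 0")
  }
  ifelse(sse <= PERFECT_FIT_TOL, -Inf, n * log(sse / n) + 2 * k)
}

#' Attach AIC scores to a table of model fits
#'
#' @param fits Data.frame with columns `sse`, `n`, `k` (as from
#'   [fit_ars_cohort()]).
#' @return The same data.frame with columns `aic` and `perfect_fit` added.
#' @export
score_models <- function(fits) {
  fits$aic <- aic(fits$sse, fits$n, fits$k)
  fits$perfect_fit <- fits$sse <= PERFECT_FIT_TOL
  fits
}

#' One-tailed paired comparison of two models' AICs
#'
#' Pairs participants by id, removes any participant perfectly predicted
#' (SSE = 0) by either model, and runs an uncorrected one-tailed paired
#' t-test in the direction "model A has lower AIC than model B"
#' (`p = P(T <= t)`). The effect size is the paired Cohen's d,
#' `|mean difference| / sd(differences)`.
#'
#' @param scores_a,scores_b Scored fits for one model each (rows of the
#'   output of [score_models()]), with columns `participant_id`, `model`,
#'   `sse`, `aic`.
#' @return One-row data.frame: `model_a`, `model_b`, `mean_aic_a/b`,
#'   `sd_aic_a/b`, `t_statistic`, `df`, `p_value`, `cohens_d`, `n_pairs`,
#'   `excluded_ids`.
#' @export
compare_paired <- function(scores_a, scores_b) {
  ids <- intersect(scores_a$participant_id, scores_b$participant_id)
  a <- scores_a[match(ids, scores_a$participant_id), ]
  b <- scores_b[match(ids, scores_b$participant_id), ]
  bad <- a$sse <= PERFECT_FIT_TOL | b$sse <= PERFECT_FIT_TOL
  excluded <- ids[bad]
  a <- a[!bad, ]
  b <- b[!bad, ]
  n <- nrow(a)
  if (n < 3L) stop_usage("insufficient data: fewer than 3 usable pairs")
  d <- a$aic - b$aic
  sdd <- sd(d)
  if (sdd <= 0) {
    t_stat <- if (abs(mean(d)) <= PERFECT_FIT_TOL) 0 else sign(mean(d)) * Inf
    p <- pt(t_stat, n - 1L)
    eff <- if (t_stat == 0) 0 else Inf
  } else {
    t_stat <- mean(d) / (sdd / sqrt(n))
    p <- pt(t_stat, n - 1L)
    eff <- abs(mean(d)) / sdd
  }
  data.frame(
    model_a = a$model[1L], model_b = b$model[1L],
    mean_aic_a = mean(a$aic), mean_aic_b = mean(b$aic),
    sd_aic_a = sd(a$aic), sd_aic_b = sd(b$aic),
    t_statistic = t_stat, df = n - 1L, p_value = p, cohens_d = eff,
    n_pairs = n,
    excluded_ids = paste(excluded, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Default strategy-classification thresholds
#'
#' The fitted heuristic weight dominates: `psi_hat` above the psi threshold
#' is Heuristic (HR); otherwise `tau_hat` below/above its thresholds is
#' LAT/HAT, with Modal Trust (MT) in between. Midpoint defaults (0.5 on
#' psi; 0.25 / 0.75 on tau) — the verbal rule behind them only pins the
#' archetypes ("close to 0 / 0.5 / 1"), so the thresholds are configurable.
#'
#' @return List with elements `psi`, `tau_low`, `tau_high`.
#' @export
default_thresholds <- function() {
  list(psi = 0.5, tau_low = 0.25, tau_high = 0.75)
}

#' Classify a fitted (tau, psi) point into a strategy label
#'
#' @param tau_hat,psi_hat Fitted ARS parameters (vectorized).
#' @param thresholds See [default_thresholds()].
#' @return Character vector of labels in `{"HAT","LAT","MT","HR"}`.
#' @examples
#' classify_strategy(c(0.5, 0, 0.3), c(0, 0, 0.9))  # MT, LAT, HR
#' @export
classify_strategy <- function(tau_hat, psi_hat, thresholds = default_thresholds()) {
  assert_unit_interval(tau_hat, "tau_hat")
  assert_unit_interval(psi_hat, "psi_hat")
  ifelse(psi_hat > thresholds$psi, "HR",
         ifelse(tau_hat < thresholds$tau_low, "LAT",
                ifelse(tau_hat > thresholds$tau_high, "HAT", "MT")))
}

#' Cohort-level report: AIC summary, paired comparisons, prevalence,
#' recovery
#'
#' Builds the cohort summary of a completed analysis: mean/SD AIC per model
#' (over the participants with a positive SSE under every summarized model,
#' since a perfect fit has AIC `-Inf`), one-tailed paired comparisons of the
#' ARS model against each archetype model, the strategy-prevalence table
#' from classified ARS fits, and — when simulation ground truth is
#' supplied — recovery diagnostics. If choices/design are supplied,
#' descriptive mean reciprocity per bestowed-trust condition and pooled
#' variance-explained figures are added.
#'
#' @param scores Scored model fits from [score_models()].
#' @param truth Optional ground-truth table from [simulate_cohort()].
#' @param delta_fits Optional per-participant fits from [fit_delta_cohort()].
#' @param choices,design,inferences Optional tables for the descriptive and
#'   variance-explained sections.
#' @param thresholds Classification thresholds.
#' @return A list of class `hetg_report` with components `aic_summary`,
#'   `comparisons`, `prevalence`, `labels`, and optionally `recovery`,
#'   `condition_means`, `variance_explained`.
#' @export
cohort_report <- function(scores, truth = NULL, delta_fits = NULL,
                          choices = NULL, design = NULL, inferences = NULL,
                          thresholds = default_thresholds()) {
  models <- unique(scores$model)
  wide_sse <- tapply(scores$sse, list(scores$participant_id, scores$model), mean)
  ok <- apply(wide_sse, 1L, function(s) all(!is.na(s)) && all(s > PERFECT_FIT_TOL))
  keep_ids <- rownames(wide_sse)[ok]
  kept <- scores[scores$participant_id %in% keep_ids, ]
  aic_summary <- do.call(rbind, lapply(split(kept, kept$model), function(s) {
    data.frame(model = s$model[1L], mean_aic = mean(s$aic), sd_aic = sd(s$aic),
               n = nrow(s), stringsAsFactors = FALSE)
  }))
  aic_summary <- aic_summary[order(aic_summary$mean_aic), ]
  row.names(aic_summary) <- NULL

  comparisons <- NULL
  if ("ARS" %in% models && length(setdiff(models, "ARS")) > 0L) {
    ars <- scores[scores$model == "ARS", ]
    comparisons <- do.call(rbind, lapply(setdiff(models, "ARS"), function(m) {
      tryCatch(compare_paired(ars, scores[scores$model == m, ]),
               error = function(e) {
                 warning(sprintf("ARS vs %s comparison skipped: %s", m,
                                 conditionMessage(e)), call. = FALSE)
                 NULL
               })
    }))
  }

  labels <- NULL
  prevalence <- NULL
  if ("ARS" %in% models) {
    ars <- scores[scores$model == "ARS", ]
    labels <- data.frame(
      participant_id = ars$participant_id,
      label = classify_strategy(ars$tau_hat, ars$psi_hat, thresholds),
      tau_hat = ars$tau_hat, psi_hat = ars$psi_hat,
      stringsAsFactors = FALSE
    )
    tab <- table(factor(labels$label, levels = names(ARCHETYPES)))
    prevalence <- data.frame(
      strategy = names(tab), count = as.integer(tab),
      percent = round(100 * as.integer(tab) / sum(tab), 1L),
      stringsAsFactors = FALSE
    )
  }

  recovery <- NULL
  if (!is.null(truth) && !is.null(labels)) {
    m <- merge(labels, truth, by = "participant_id")
    recovery <- data.frame(
      n = nrow(m),
      strategy_accuracy = mean(m$label == m$strategy_label),
      stringsAsFactors = FALSE
    )
    if (!is.null(delta_fits)) {
      dm <- merge(delta_fits, truth, by = "participant_id")
      recovery$median_abs_delta_error <- stats::median(abs(dm$delta_hat - dm$delta))
    }
  }

  condition_means <- NULL
  if (!is.null(choices) && !is.null(design)) {
    ch <- choices
    band <- design$trust_band[match(ch$trial_index, design$trial_index)]
    cond <- ifelse(ch$condition == "ambiguous", "ambiguous", band)
    condition_means <- do.call(rbind, lapply(split(ch$reciprocity, cond), function(x) {
      data.frame(mean_reciprocity = mean(x), n_trials = length(x))
    }))
    condition_means <- cbind(condition = rownames(condition_means), condition_means,
                             stringsAsFactors = FALSE)
    row.names(condition_means) <- NULL
  }

  varexp <- NULL
  if (!is.null(choices) && !is.null(design) && !is.null(delta_fits)) {
    varexp <- data.frame(
      condition = "unambiguous",
      variance_explained = pooled_variance_explained(choices, design, delta_fits),
      stringsAsFactors = FALSE
    )
    if (!is.null(inferences)) {
      varexp <- rbind(varexp, data.frame(
        condition = "ambiguous",
        variance_explained = pooled_variance_explained(choices, design, delta_fits,
                                                       inferences),
        stringsAsFactors = FALSE
      ))
    }
  }

  structure(
    list(aic_summary = aic_summary, comparisons = comparisons,
         prevalence = prevalence, labels = labels, recovery = recovery,
         condition_means = condition_means, variance_explained = varexp,
         excluded_from_summary = setdiff(rownames(wide_sse), keep_ids)),
    class = "hetg_report"
  )
}

# Pooled (cohort-level) variance explained by the reciprocity model: in the
# unambiguous condition with the true endowment; in the ambiguous condition
# with the reverse-inferred endowment.
pooled_variance_explained <- function(choices, design, delta_fits,
                                      inferences = NULL) {
  if (is.null(inferences)) {
    rows <- choices[choices$condition == "unambiguous", ]
    idx <- match(rows$trial_index, design$trial_index)
    E <- design$endowment[idx]
    M <- design$multiplier[idx]
  } else {
    rows <- choices[choices$condition == "ambiguous", ]
    key_r <- paste(rows$participant_id, rows$trial_index)
    key_i <- paste(inferences$participant_id, inferences$trial_index)
    E <- inferences$e_inferred[match(key_r, key_i)]
    M <- design$multiplier[match(rows$trial_index, design$trial_index)]
  }
  delta <- delta_fits$delta_hat[match(rows$participant_id, delta_fits$participant_id)]
  ok <- !is.na(E) & !is.na(delta) & delta < 1 & E >= rows$investment
  rows <- rows[ok, ]
  pred <- pmax(0, (E[ok] - rows$investment + rows$investment * M[ok]) * delta[ok] -
                 (E[ok] - rows$investment))
  100 * variance_explained(pred, rows$returned)
}

#' @export
print.hetg_report <- function(x, ...) {
  cat("Hidden-endowment Trust Game cohort report\n")
  cat("\nMean AIC by model (lower is better):\n")
  print(x$aic_summary, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nARS vs single-strategy models (one-tailed paired t):\n")
    print(x$comparisons[, c("model_a", "model_b", "t_statistic", "df",
                            "p_value", "cohens_d", "n_pairs")],
          row.names = FALSE)
  }
  if (!is.null(x$prevalence)) {
    cat("\nStrategy prevalence (classified ARS fits):\n")
    print(x$prevalence, row.names = FALSE)
  }
  if (!is.null(x$recovery)) {
    cat("\nRecovery vs ground truth:\n")
    print(x$recovery, row.names = FALSE)
  }
  if (!is.null(x$variance_explained)) {
    cat("\nPooled variance explained by the reciprocity model (%):\n")
    print(x$variance_explained, row.names = FALSE)
  }
  if (length(x$excluded_from_summary)) {
    cat("\nExcluded from AIC summary (perfectly predicted by some model): ",
        paste(x$excluded_from_summary, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
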