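# Session / trial design for the hidden-endowment Trust Game.
#
# A session is 40 unambiguous rounds of the standard Trust Game followed by
# 80 rounds in which the Investor's endowment is hidden and the Trustee sees
# only the investment plus three candidate endowments. The multiplier is
# fixed at 4 throughout.

#: bestowed-trust bands (closed intervals on I/E)
BAND_LIMITS <- list(
  low    = c(0.05, 0.25),
  medium = c(0.35, 0.50),
  high   = c(0.70, 1.00)
)

# Printed composition of the ambiguous condition: each block pairs an
# investment range with a fixed candidate-endowment triple whose implied
# trust ratios I/E fall one per band.
AMBIGUOUS_BLOCKS <- list(
  list(n = 20L, investments = 2L,    candidates = c(2, 5, 10)),
  list(n = 20L, investments = 4:5,   candidates = c(5, 10, 20)),
  list(n = 40L, investments = 7:10,  candidates = c(10, 20, 50))
)

#' Classify a bestowed-trust ratio into a design band
#'
#' Bands are closed intervals on the ratio I/E: low `[0.05, 0.25]`,
#' medium `[0.35, 0.50]`, high `[0.70, 1.00]`. Ratios falling in the gaps
#' between bands (e.g. 0.30) are labelled `"unbanded"` rather than coerced.
#'
#' @param ratio Numeric vector of trust ratios in (0, 1].
#' @return Character vector: `"low"`, `"medium"`, `"high"` or `"unbanded"`.
#' @examples
#' trust_band(c(0.20, 0.50, 0.30))
#' @export
trust_band <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) == 0L || anyNA(ratio) ||
      any(!is.finite(ratio)) || any(ratio <= 0 | ratio > 1)) {
    stop_usage("`ratio` must be numeric in (0, 1]")
  }
  eps <- 1e-9
  out <- rep("unbanded", length(ratio))
  for (band in names(BAND_LIMITS)) {
    lim <- BAND_LIMITS[[band]]
    out[ratio >= lim[1] - eps & ratio <= lim[2] + eps] <- band
  }
  out
}

#' Default unambiguous-condition frequency table
#'
#' The exact unambiguous condition list used in the original task is not
#' publicly deposited, so the shipped default is an emulation of its stated
#' constraints: the modal endowment is 10, the modal transfer is half the
#' endowment, and low/medium/high bestowed-trust trials are all represented.
#' Override by supplying your own table (columns `endowment`, `investment`,
#' `count`) to [generate_unambiguous_trials()].
#'
#' @return A list with element `unambiguous`: a data.frame with columns
#'   `endowment`, `investment`, `count` whose counts sum to 40.
#' @export
default_design_config <- function() {
  list(unambiguous = data.frame(
    endowment  = c(10, 10, 10, 10, 10, 5, 5, 5, 5, 20, 20, 20),
    investment = c( 5,  2,  4,  8, 10, 2, 1, 4, 5, 10,  2, 16),
    count      = c(12,  4,  2,  4,  2, 3, 2, 2, 1,  4,  2,  2)
  ))
}

#' Generate the unambiguous (standard Trust Game) trials
#'
#' Expands a frequency table of (endowment, investment) conditions into
#' `n_trials` rounds and shuffles their order deterministically under `seed`.
#'
#' @param n_trials Number of trials; the frequency-table counts must sum to it.
#' @param config Design configuration as from [default_design_config()].
#' @param seed Integer seed controlling the trial order.
#' @return A data.frame of trial specifications (one row per trial) with
#'   columns `trial_index`, `condition`, `endowment`, `investment`,
#'   `multiplier`, `cand1`..`cand3` (all `NA`), `trust_band`.
#' @export
generate_unambiguous_trials <- function(n_trials = 40L,
                                        config = default_design_config(),
                                        seed = 1L) {
  freq <- config$unambiguous
  if (is.null(freq) || !all(c("endowment", "investment", "count") %in% names(freq))) {
    stop_usage("configuration error: `config$unambiguous` must have columns endowment, investment, count")
  }
  if (n_trials < 1L) stop_usage("`n_trials` must be >= 1")
  if (sum(freq$count) != n_trials) {
    stop_usage("configuration error: frequency counts sum to %d, not n_trials = %d",
               sum(freq$count), n_trials)
  }
  if (any(freq$investment <= 0) || any(freq$investment > freq$endowment)) {
    stop_usage("configuration error: investments must satisfy 0 < I <= E")
  }
  rows <- freq[rep(seq_len(nrow(freq)), freq$count), , drop = FALSE]
  ord <- with_seed(seed, sample.int(n_trials))
  rows <- rows[ord, , drop = FALSE]
  data.frame(
    trial_index = seq_len(n_trials),
    condition   = "unambiguous",
    endowment   = rows$endowment,
    investment  = rows$investment,
    multiplier  = 4,
    cand1       = NA_real_,
    cand2       = NA_real_,
    cand3       = NA_real_,
    trust_band  = trust_band(rows$investment / rows$endowment),
    row.names   = NULL
  )
}

#' Generate the ambiguous (hidden-endowment) trials
#'
#' Produces the 80 hidden-endowment rounds in their three fixed blocks:
#' 20 trials with I = 2 and candidates \{2, 5, 10\}; 20 with I in 4..5 and
#' candidates \{5, 10, 20\}; 40 with I in 7..10 and candidates \{10, 20, 50\}.
#' The true endowment is drawn uniformly from the candidate triple and the
#' investment uniformly over the block's integer range; trial order is
#' shuffled. All draws are deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @return A data.frame of 80 trial specifications (same columns as
#'   [generate_unambiguous_trials()], with `cand1 < cand2 < cand3` filled in).
#' @export
generate_ambiguous_trials <- function(seed = 1L) {
  parts <- with_seed(seed, {
    blocks <- lapply(AMBIGUOUS_BLOCKS, function(b) {
      inv <- b$investments[sample.int(length(b$investments), b$n, replace = TRUE)]
      tru <- b$candidates[sample.int(length(b$candidates), b$n, replace = TRUE)]
      data.frame(
        investment = inv, endowment = tru,
        cand1 = b$candidates[1], cand2 = b$candidates[2], cand3 = b$candidates[3]
      )
    })
    all <- do.call(rbind, blocks)
    all[sample.int(nrow(all)), , drop = FALSE]
  })
  data.frame(
    trial_index = seq_len(nrow(parts)),
    condition   = "ambiguous",
    endowment   = parts$endowment,
    investment  = parts$investment,
    multiplier  = 4,
    cand1       = parts$cand1,
    cand2       = parts$cand2,
    cand3       = parts$cand3,
    trust_band  = trust_band(parts$investment / parts$endowment),
    row.names   = NULL
  )
}

#' Generate a complete 120-trial session design
#'
#' The unambiguous condition always precedes the ambiguous condition (trials
#' 1-40 then 41-120), matching the task's fixed condition order.
#'
#' @inheritParams generate_unambiguous_trials
#' @return A data.frame of 120 trial specifications with attributes `seed`
#'   and `config_digest`.
#' @export
generate_session <- function(config = default_design_config(), seed = 1L) {
  un <- generate_unambiguous_trials(sum(config$unambiguous$count), config, seed)
  am <- generate_ambiguous_trials(seed + 1L)
  am$trial_index <- am$trial_index + nrow(un)
  des <- rbind(un, am)
  attr(des, "seed") <- seed
  attr(des, "config_digest") <- sprintf(
    "u%d-a%d-s%d", nrow(un), nrow(am), as.integer(seed))
  des
}

#' Write / read a session design as CSV
#'
#' One row per trial; candidate columns are empty for unambiguous rows.
#'
#' @param design A design data.frame from [generate_session()].
#' @param path File path.
#' @return `read_design_csv()` returns the design data.frame.
#' @export
write_design_csv <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Candidate endowments of one (ambiguous) design row, ascending.
trial_candidates <- function(trial) {
  sort(as.numeric(c(trial$cand1, trial$cand2, trial$cand3)))
}
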