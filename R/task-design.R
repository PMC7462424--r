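#' Generate a counterbalanced intermixed two-condition event-related design
#'
#' Builds a pseudo-random trial order for an intermixed two-condition
#' (A/B) event-related task. Each condition presents
#' `n_trials_per_condition` trials with numerosities drawn equally from
#' `numerosities`; interstimulus intervals are drawn only from `isi_set`
#' and counterbalanced across condition-by-numerosity cells. No more than
#' `max_run` consecutive trials share the same condition, and none share
#' the same numerosity more than `max_run` in a row. Generation is by
#' constrained sequential sampling with restart on dead ends, capped at
#' `max_attempts` attempts.
#'
#' With the defaults this emulates a 160-trial comparison task: 80 trials
#' per condition, numerosities {2, 4, 6, 8}, ISIs 3300-7300 ms in 1000-ms
#' increments (mean 5300 ms), maximum run length 3.
#'
#' @param n_trials_per_condition trials per condition; must be divisible by
#'   `length(numerosities)`.
#' @param numerosities integer set of stimulus numerosities.
#' @param isi_set candidate interstimulus intervals in milliseconds.
#' @param tr repetition time in seconds.
#' @param max_run maximum run length of identical condition or numerosity.
#' @param seed integer seed; the design is a pure function of the arguments.
#' @param stimulus_duration stimulus duration in seconds.
#' @param response_dur single-trial response duration in seconds, used to
#'   size the run so the last trial's response window fits.
#' @param max_attempts restart cap before declaring the constraints
#'   infeasible.
#' @return an object of class `trial_design`: a list with `trials` (a
#'   data.frame with columns index, condition, numerosity, onset_s,
#'   duration_s, isi_ms), `tr` and `n_volumes`.
#' @export
generate_task_design <- function(n_trials_per_condition = 80,
                                 numerosities = c(2L, 4L, 6L, 8L),
                                 isi_set = seq(3300, 7300, by = 1000),
                                 tr = 2,
                                 max_run = 3,
                                 seed = NULL,
                                 stimulus_duration = 0.5,
                                 response_dur = 13.1,
                                 max_attempts = 10000) {
  if (length(isi_set) < 1) stop("isi_set must be non-empty")
  if (n_trials_per_condition < 1) stop("n_trials_per_condition must be >= 1")
  if (n_trials_per_condition %% length(numerosities) != 0) {
    stop("n_trials_per_condition must be divisible by the number of numerosities")
  }
  if (max_run < 1) stop("max_run must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  conditions <- c("A", "B")
  per_cell <- n_trials_per_condition / length(numerosities)
  # cell table: one row per (condition, numerosity) with its trial count
  cells <- expand.grid(condition = conditions, numerosity = numerosities,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$count <- per_cell

  order_ok <- NULL
  for (attempt in seq_len(max_attempts)) {
    res <- .sample_trial_order(cells, max_run)
    if (!is.null(res)) {
      order_ok <- res
      break
    }
  }
  if (is.null(order_ok)) {
    stop("infeasible design constraints: no valid trial order found in ",
         max_attempts, " attempts (max_run = ", max_run, ")")
  }

  n_total <- nrow(order_ok)
  # counterbalanced ISI assignment: within each (condition, numerosity)
  # cell, the ISI multiset is as balanced as possible over isi_set
  isi <- numeric(n_total)
  for (ci in seq_len(nrow(cells))) {
    rows <- which(order_ok$condition == cells$condition[ci] &
                    order_ok$numerosity == cells$numerosity[ci])
    pool <- rep(isi_set, length.out = length(rows))
    isi[rows] <- pool[sample.int(length(pool))]
  }

  onset <- numeric(n_total)
  onset[1] <- tr
  if (n_total > 1) {
    for (i in 2:n_total) {
      onset[i] <- onset[i - 1] + stimulus_duration + isi[i - 1] / 1000
    }
  }
  n_volumes <- as.integer(ceiling((onset[n_total] + response_dur) / tr))

  trials <- data.frame(
    index = seq_len(n_total),
    condition = order_ok$condition,
    numerosity = order_ok$numerosity,
    onset_s = onset,
    duration_s = stimulus_duration,
    isi_ms = isi,
    stringsAsFactors = FALSE
  )
  design <- structure(
    list(trials = trials, tr = tr, n_volumes = n_volumes,
         response_dur = response_dur, max_run = max_run,
         isi_set = isi_set, numerosities = numerosities),
    class = "trial_design"
  )
  validate_trial_design(design)
  design
}

# Sequential constrained sampling of the (condition, numerosity) order.
# Returns NULL on dead end.
.sample_trial_order <- function(cells, max_run) {
  remaining <- cells$count
  n_total <- sum(remaining)
  cond_out <- character(n_total)
  num_out <- numeric(n_total)
  # with a single configured numerosity the run constraint is vacuous
  check_num <- length(unique(cells$numerosity)) > 1
  for (pos in seq_len(n_total)) {
    ok <- remaining > 0
    if (pos > max_run) {
      last_cond <- cond_out[(pos - max_run):(pos - 1)]
      last_num <- num_out[(pos - max_run):(pos - 1)]
      if (length(unique(last_cond)) == 1) {
        ok <- ok & cells$condition != last_cond[1]
      }
      if (check_num && length(unique(last_num)) == 1) {
        ok <- ok & cells$numerosity != last_num[1]
      }
    }
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    pick <- if (length(idx) == 1) idx else {
      idx[sample.int(length(idx), 1, prob = remaining[idx])]
    }
    cond_out[pos] <- cells$condition[pick]
    num_out[pos] <- cells$numerosity[pick]
    remaining[pick] <- remaining[pick] - 1
  }
  data.frame(condition = cond_out, numerosity = num_out,
             stringsAsFactors = FALSE)
}

#' Validate a trial design against its structural invariants
#'
#' Checks equal trial counts per condition, balanced condition-by-numerosity
#' cells, the run-length constraint on both condition and numerosity, ISI
#' membership in the configured set, strictly increasing onsets, and that the
#' last trial's response window fits within the run.
#'
#' @param design a `trial_design`.
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_trial_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  tr <- design$trials
  counts <- table(tr$condition)
  if (length(unique(counts)) != 1 || length(counts) != 2) {
    stop("unequal trial counts per condition")
  }
  cell <- table(tr$condition, tr$numerosity)
  if (length(unique(as.vector(cell))) != 1) {
    stop("condition x numerosity cells are not balanced")
  }
  runs <- design_run_lengths(design)
  if (runs["condition"] > design$max_run) {
    stop("condition run length ", runs["condition"], " exceeds max_run")
  }
  if (length(unique(design$numerosities)) > 1 &&
        runs["numerosity"] > design$max_run) {
    stop("numerosity run length ", runs["numerosity"], " exceeds max_run")
  }
  if (!all(tr$isi_ms %in% design$isi_set)) {
    stop("ISI values outside the configured set")
  }
  if (nrow(tr) > 1 && any(diff(tr$onset_s) <= 0)) {
    stop("onsets are not strictly increasing")
  }
  if (tr$onset_s[nrow(tr)] + design$response_dur >
        design$n_volumes * design$tr + 1e-9) {
    stop("last trial's response window does not fit within the run")
  }
  invisible(TRUE)
}

#' Longest identical-value runs in a design
#'
#' @param design a `trial_design`.
#' @return named numeric vector with elements `condition` and `numerosity`:
#'   the longest run of consecutive trials sharing that attribute.
#' @export
design_run_lengths <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  longest <- function(x) max(rle(as.vector(x))$lengths)
  c(condition = longest(design$trials$condition),
    numerosity = longest(design$trials$numerosity))
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Trial design:", nrow(x$trials), "trials,",
      length(unique(x$trials$condition)), "conditions, TR =", x$tr,
      "s,", x$n_volumes, "volumes\n")
  cat("  mean ISI:", mean(x$trials$isi_ms), "ms; max runs:",
      paste(names(design_run_lengths(x)), design_run_lengths(x),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
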