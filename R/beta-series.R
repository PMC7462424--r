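#' Construct a per-condition beta series
#'
#' Splits a regions x trials beta matrix by task condition and tracks
#' which trials are retained. Trials with any non-finite beta start out
#' not retained (missing estimates are treated as scrubbed).
#'
#' @param betas numeric matrix, regions x trials (all trials, in design
#'   order).
#' @param design the `trial_design` the trials belong to.
#' @return an object of class `beta_series`: list with `betas` (named list
#'   of regions x trials matrices per condition), `trial_index` (design
#'   trial indices per condition), `retained` (logical per trial per
#'   condition), `n_retained`, and `design`.
#' @export
beta_series <- function(betas, design) {
  stopifnot(inherits(design, "trial_design"))
  betas <- as.matrix(betas)
  if (ncol(betas) != nrow(design$trials)) {
    stop("betas must have one column per design trial")
  }
  conds <- sort(unique(design$trials$condition))
  split_idx <- lapply(conds, function(cc) which(design$trials$condition == cc))
  names(split_idx) <- conds
  b <- lapply(split_idx, function(ix) betas[, ix, drop = FALSE])
  retained <- lapply(b, function(m) apply(is.finite(m), 2, all))
  structure(
    list(betas = b,
         trial_index = split_idx,
         retained = retained,
         n_retained = vapply(retained, sum, integer(1)),
         design = design),
    class = "beta_series"
  )
}

#' @export
print.beta_series <- function(x, ...) {
  cat("Beta series:", nrow(x$betas[[1]]), "regions;",
      paste(names(x$betas), vapply(x$n_retained, identity, integer(1)),
            sep = ": ", collapse = ", "),
      "retained trials\n")
  invisible(x)
}

#' Scrub trials whose response window is motion contaminated
#'
#' Clears the retained flag for any trial whose single-trial response span
#' (see [trial_response_span()]) contains two or more censored volumes.
#' Scrubbing is monotone: it only ever removes trials.
#'
#' @param bs a `beta_series`.
#' @param design the matching `trial_design` (defaults to the one stored
#'   in `bs`).
#' @param censor keep mask (1 = keep) of length n_volumes.
#' @param max_censored trials with at least this many censored volumes in
#'   their span are excluded (default 2).
#' @return the `beta_series` with updated `retained` and `n_retained`.
#' @export
scrub_trials <- function(bs, design = bs$design, censor,
                         max_censored = 2) {
  stopifnot(inherits(bs, "beta_series"), inherits(design, "trial_design"))
  if (length(censor) != design$n_volumes) {
    stop("censor mask length must equal n_volumes")
  }
  censored <- censor == 0
  for (cond in names(bs$betas)) {
    idx <- bs$trial_index[[cond]]
    for (k in seq_along(idx)) {
      span <- trial_response_span(design$trials$onset_s[idx[k]],
                                  design$tr, design$n_volumes,
                                  design$response_dur)
      if (sum(censored[span]) >= max_censored) {
        bs$retained[[cond]][k] <- FALSE
      }
    }
  }
  bs$n_retained <- vapply(bs$retained, sum, integer(1))
  bs
}

#' Normalize a beta series within condition
#'
#' Per region and condition, over retained trials only, centers to mean 0
#' and scales to SD 1. The population SD (divide by n) is the default,
#' matching the common pattern-analysis convention; sample SD is
#' available via `sd_type`.
#'
#' @param bs a `beta_series` with at least 2 retained trials per condition.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return the normalized `beta_series`.
#' @export
normalize_within_condition <- function(bs,
                                       sd_type = c("population", "sample")) {
  stopifnot(inherits(bs, "beta_series"))
  sd_type <- match.arg(sd_type)
  for (cond in names(bs$betas)) {
    ret <- bs$retained[[cond]]
    if (sum(ret) < 2) {
      stop("condition ", cond, " has fewer than 2 retained trials")
    }
    m <- bs$betas[[cond]][, ret, drop = FALSE]
    mu <- rowMeans(m)
    centered <- m - mu
    n <- ncol(m)
    ss <- sqrt(rowSums(centered^2) / if (sd_type == "population") n else n - 1)
    zero <- which(ss == 0)
    if (length(zero)) {
      stop("zero-SD beta series in region(s) ",
           paste(zero, collapse = ", "), " (condition ", cond, ")")
    }
    bs$betas[[cond]][, ret] <- centered / ss
  }
  bs
}
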