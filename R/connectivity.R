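#' Construct a symmetric signed weighted network
#'
#' Container for a z-scored connectivity matrix: symmetric (to machine
#' precision), finite, zero diagonal, with the number of observations
#' (retained betas) behind each correlation.
#'
#' @param w numeric square matrix of edge weights (z-score units).
#' @param n_obs number of observations each weight is based on (may be
#'   `NA` for derived matrices such as thresholded allegiance).
#' @param tol symmetry tolerance.
#' @return an object of class `weighted_network` with elements `w`, `n_obs`
#'   and `n` (number of nodes).
#' @export
weighted_network <- function(w, n_obs = NA_integer_, tol = 1e-8) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) {
    stop("connectivity matrix must be square (got ", nrow(w), " x ",
         ncol(w), ")")
  }
  if (any(!is.finite(w))) stop("connectivity matrix has non-finite entries")
  if (max(abs(w - t(w))) > tol) {
    stop("connectivity matrix is asymmetric beyond tolerance ", tol)
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  structure(list(w = w, n_obs = n_obs, n = nrow(w)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted network:", x$n, "nodes, n_obs =", x$n_obs, "\n")
  cat("  weight range: [", signif(min(x$w), 4), ",", signif(max(x$w), 4),
      "]\n")
  invisible(x)
}

# shared correlation clamp keeping atanh finite
.clamp_r <- function(r, clamp = 1 - 1e-12, warn = TRUE) {
  over <- abs(r) >= clamp
  if (warn && any(over, na.rm = TRUE)) {
    warning("correlations at |r| >= ", format(clamp),
            " clamped before Fisher transform")
  }
  pmin(pmax(r, -clamp), clamp)
}

#' Fisher-z beta-series connectivity
#'
#' Pairwise Pearson correlations over the retained betas of one condition,
#' Fisher Z transformed (`atanh`) and converted to z-scores by dividing by
#' the standard error `1/sqrt(N - 3)`, where N is the number of retained
#' betas. Correlations at `|r| = 1` are clamped to `1 - 1e-12` with a
#' warning. The diagonal is zero.
#'
#' @param bs a `beta_series`.
#' @param condition which condition's betas to correlate.
#' @param min_trials minimum retained trials (default 5).
#' @return a `weighted_network` with `n_obs = ` number of retained betas.
#' @export
compute_connectivity <- function(bs, condition, min_trials = 5) {
  stopifnot(inherits(bs, "beta_series"))
  if (!condition %in% names(bs$betas)) {
    stop("unknown condition: ", condition)
  }
  ret <- bs$retained[[condition]]
  n_obs <- sum(ret)
  if (n_obs < min_trials) {
    stop("condition ", condition, " has ", n_obs,
         " retained trials; need at least ", min_trials)
  }
  b <- bs$betas[[condition]][, ret, drop = FALSE]
  r <- cor(t(b))
  diag(r) <- 0
  z <- atanh(.clamp_r(r)) * sqrt(n_obs - 3)
  diag(z) <- 0
  weighted_network(z, n_obs = n_obs)
}
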