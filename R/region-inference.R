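#' Allegiance-profile dissimilarity of regions between conditions
#'
#' A region's allegiance profile is its row of the group allegiance
#' matrix, excluding the self entry. The profile is correlated across the
#' two conditions (Pearson), Fisher Z transformed with the shared
#' `|r| <= 1 - 1e-12` clamp, and negated so that larger values indicate
#' greater dissimilarity. A zero-variance profile (a region alone in its
#' community in every subject) yields `NA` and is excluded from
#' significance counting.
#'
#' @param aA,aB group allegiance matrices with identical dimensions.
#' @param region optional region index; `NULL` returns all regions.
#' @return numeric dissimilarity value(s); `NA` where undefined.
#' @export
profile_dissimilarity <- function(aA, aB, region = NULL) {
  aA <- as.matrix(aA)
  aB <- as.matrix(aB)
  if (!all(dim(aA) == dim(aB))) stop("allegiance matrices must match")
  n <- nrow(aA)
  one <- function(i) {
    x <- aA[i, -i]
    y <- aB[i, -i]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    -atanh(.clamp_r(cor(x, y), warn = FALSE))
  }
  if (!is.null(region)) one(region) else vapply(seq_len(n), one, numeric(1))
}

# rowwise profile dissimilarity for square matrices with unit diagonal,
# vectorized over regions (used inside the permutation loop)
.profile_dissim_fast <- function(A, B) {
  n <- nrow(A)
  k <- n - 1
  sA <- rowSums(A) - diag(A)
  sB <- rowSums(B) - diag(B)
  sAB <- rowSums(A * B) - diag(A) * diag(B)
  sA2 <- rowSums(A^2) - diag(A)^2
  sB2 <- rowSums(B^2) - diag(B)^2
  num <- sAB - sA * sB / k
  den <- sqrt(pmax(sA2 - sA^2 / k, 0) * pmax(sB2 - sB^2 / k, 0))
  r <- ifelse(den == 0, NA_real_, num / den)
  -atanh(.clamp_r(r, warn = FALSE))
}

#' Region-level dissimilarity across the resolution sweep
#'
#' At each gamma: builds the condition-wise group allegiance matrices from
#' subject partitions, computes the observed profile dissimilarity per
#' region, and assesses significance against a Monte Carlo null in which
#' each subject's condition labels are independently exchanged with
#' probability 1/2 and the group matrices rebuilt. Per region and gamma a
#' z score and one-tailed p value (greater dissimilarity than null;
#' add-one convention) are recorded, and each region's count of gammas
#' with `p < alpha` summarizes the robustness of its profile change.
#'
#' @param parts_A,parts_B lists over gamma grid indices, each a list of
#'   subject-level partitions for that condition.
#' @param grid gamma grid the partitions were computed on.
#' @param n_perm Monte Carlo iterations per gamma (analysis scale:
#'   10,000). p granularity is `1/(n_perm + 1)`.
#' @param alpha per-step significance level for counting (one-tailed,
#'   uncorrected).
#' @param seed optional integer seed.
#' @return object of class `region_sweep_result`: list with matrices
#'   `dissimilarity`, `z`, `p` (regions x gammas), integer `counts` per
#'   region, plus `grid`, `alpha`, `n_perm`.
#' @export
region_sweep <- function(parts_A, parts_B, grid, n_perm = 1000,
                         alpha = 0.05, seed = NULL) {
  if (length(parts_A) != length(grid) || length(parts_B) != length(grid)) {
    stop("subject partitions must be available at every grid value")
  }
  if (!is.null(seed)) set.seed(seed)
  n_gamma <- length(grid)
  n_subj <- length(parts_A[[1]])
  n <- length(parts_A[[1]][[1]])
  dis <- zmat <- pmat <- matrix(NA_real_, n, n_gamma)
  for (g in seq_len(n_gamma)) {
    coA <- lapply(parts_A[[g]], function(p) outer(p, p, "==") * 1)
    coB <- lapply(parts_B[[g]], function(p) outer(p, p, "==") * 1)
    sumA <- Reduce(`+`, coA)
    sumB <- Reduce(`+`, coB)
    gA <- sumA / n_subj
    gB <- sumB / n_subj
    obs <- .profile_dissim_fast(gA, gB)
    Ds <- mapply(function(a, b) b - a, coA, coB, SIMPLIFY = FALSE)
    null_dis <- matrix(NA_real_, n, n_perm)
    for (it in seq_len(n_perm)) {
      swap <- which(runif(n_subj) < 0.5)
      if (length(swap)) {
        delta <- Reduce(`+`, Ds[swap])
        A2 <- (sumA + delta) / n_subj
        B2 <- (sumB - delta) / n_subj
      } else {
        A2 <- gA
        B2 <- gB
      }
      null_dis[, it] <- .profile_dissim_fast(A2, B2)
    }
    mu <- rowMeans(null_dis, na.rm = TRUE)
    sig <- apply(null_dis, 1, sd, na.rm = TRUE)
    zmat[, g] <- ifelse(is.na(obs) | sig == 0, NA_real_,
                        (obs - mu) / sig)
    pmat[, g] <- vapply(seq_len(n), function(i) {
      if (is.na(obs[i])) return(NA_real_)
      (sum(null_dis[i, ] >= obs[i], na.rm = TRUE) + 1) / (n_perm + 1)
    }, numeric(1))
    dis[, g] <- obs
  }
  counts <- apply(pmat, 1, function(p) sum(p < alpha, na.rm = TRUE))
  structure(
    list(dissimilarity = dis, z = zmat, p = pmat,
         counts = as.integer(counts), grid = grid, alpha = alpha,
         n_perm = n_perm),
    class = "region_sweep_result"
  )
}

#' Maximum-likelihood negative-binomial fit to significance counts
#'
#' Fits a negative binomial to the per-region counts of significant sweep
#' steps (ML via `MASS::fitdistr`). When the method-of-moments dispersion
#' estimate is at the boundary (variance <= mean) the fit falls back to
#' Poisson; an all-zero count vector returns a degenerate point mass with
#' a warning.
#'
#' @param counts nonnegative integer vector, length >= 10.
#' @return object of class `count_fit`: list with `type`
#'   (`"nbinom"`, `"poisson"` or `"degenerate"`), parameters (`size`,
#'   `mu`, `prob` for the negative binomial; `lambda` for Poisson),
#'   `qfun(p)` (quantile function) and `p_upper(x)` (`P(X >= x)`).
#' @export
fit_negative_binomial <- function(counts) {
  if (length(counts) < 10) stop("need at least 10 counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  counts <- as.integer(counts)
  if (all(counts == 0)) {
    warning("all counts are zero; returning a degenerate point mass at 0")
    return(structure(
      list(type = "degenerate", mu = 0,
           qfun = function(p) rep(0, length(p)),
           p_upper = function(x) as.numeric(x <= 0)),
      class = "count_fit"
    ))
  }
  m <- mean(counts)
  v <- var(counts)
  if (v <= m) {
    return(structure(
      list(type = "poisson", lambda = m, mu = m,
           qfun = function(p) qpois(p, lambda = m),
           p_upper = function(x) ppois(x - 1, lambda = m,
                                       lower.tail = FALSE)),
      class = "count_fit"
    ))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(counts, "negative binomial")),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("negative-binomial ML fit failed; falling back to Poisson")
    return(structure(
      list(type = "poisson", lambda = m, mu = m,
           qfun = function(p) qpois(p, lambda = m),
           p_upper = function(x) ppois(x - 1, lambda = m,
                                       lower.tail = FALSE)),
      class = "count_fit"
    ))
  }
  size <- unname(fit$estimate["size"])
  mu <- unname(fit$estimate["mu"])
  structure(
    list(type = "nbinom", size = size, mu = mu,
         prob = size / (size + mu),
         qfun = function(p) qnbinom(p, size = size, mu = mu),
         p_upper = function(x) pnbinom(x - 1, size = size, mu = mu,
                                       lower.tail = FALSE)),
    class = "count_fit"
  )
}

#' @export
print.count_fit <- function(x, ...) {
  cat("Count model:", x$type)
  if (x$type == "nbinom") {
    cat(" (size =", signif(x$size, 4), ", mean =", signif(x$mu, 4), ")")
  } else if (x$type == "poisson") {
    cat(" (lambda =", signif(x$lambda, 4), ")")
  }
  cat("\n")
  invisible(x)
}

#' Flag outlier regions against the fitted count distribution
#'
#' `p_obs` is the upper-tail probability `P(X >= count)` under the fitted
#' distribution. QQ residuals compare sorted observed counts with fitted
#' quantiles at the plotting positions `ppoints(n)`; a region is flagged
#' when its QQ residual exceeds `qq_mult` times the interquartile range
#' of the residuals AND `p_obs` is below `p_level`.
#'
#' @param counts per-region counts of significant sweep steps.
#' @param fit a `count_fit` from [fit_negative_binomial()].
#' @param qq_mult residual threshold as a multiple of the residual IQR.
#' @param p_level upper-tail probability threshold.
#' @return data.frame per region: `region`, `count`, `p_obs`,
#'   `qq_residual`, `flagged`.
#' @export
detect_outlier_regions <- function(counts, fit, qq_mult = 2,
                                   p_level = 0.05) {
  stopifnot(inherits(fit, "count_fit"))
  counts <- as.integer(counts)
  n <- length(counts)
  ord <- order(counts)
  resid_sorted <- sort(counts) - fit$qfun(ppoints(n))
  qq_residual <- numeric(n)
  qq_residual[ord] <- resid_sorted
  p_obs <- fit$p_upper(counts)
  thr <- qq_mult * IQR(qq_residual)
  data.frame(region = seq_len(n), count = counts, p_obs = p_obs,
             qq_residual = qq_residual,
             flagged = qq_residual > thr & p_obs < p_level)
}
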