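# Independent oracles and fixture builders used across the suite.

# All set partitions of n elements (restricted growth strings).
enum_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    pos <- length(labels) + 1
    if (pos > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(k + 1)) {
      rec(c(labels, lab), max(k, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Direct double-sum evaluation of the signed quality function, written
# from the formula (kept independent of modularity_matrix()).
qstar_brute <- function(w, labels, gamma) {
  n <- nrow(w)
  wp <- pmax(w, 0)
  wn <- -pmin(w, 0)
  sp <- rowSums(wp)
  sn <- rowSums(wn)
  vp <- sum(sp)
  vn <- sum(sn)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] != labels[j]) next
      if (vp > 0) {
        ep <- sp[i] * sp[j] / vp
        q <- q + (wp[i, j] - gamma * ep) / vp
      }
      if (vn > 0) {
        en <- sn[i] * sn[j] / vn
        q <- q - (wn[i, j] - gamma * en) / (vp + vn)
      }
    }
  }
  q
}

# Random symmetric signed matrix with zero diagonal.
rand_signed_matrix <- function(n, sd = 1) {
  w <- matrix(rnorm(n * n, sd = sd), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# Noise-free block network on the Fisher-Z scale implied by a partition.
block_network <- function(partition, z_within = 6, z_between = 0.5) {
  same <- outer(partition, partition, "==")
  w <- matrix(z_between, length(partition), length(partition))
  w[same] <- z_within
  diag(w) <- 0
  weighted_network(w)
}

# Subject-level partition: base labels with independent per-region label
# noise (reassignment to a uniformly random community with probability q).
noisy_partition <- function(base, q = 0.15) {
  k <- max(base)
  p <- base
  flip <- runif(length(base)) < q
  p[flip] <- sample.int(k, sum(flip), replace = TRUE)
  p
}

# All permutations of 1..n (for brute-force label-matching checks).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

# Two regions x trials beta matrices whose first two regions have an
# exact sample correlation r over n trials.
betas_with_exact_r <- function(r, n) {
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  e <- scale(e)[, 1]
  y <- r * x + sqrt(1 - r^2) * e
  rbind(x, y)
}
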