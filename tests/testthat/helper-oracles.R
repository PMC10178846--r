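# Independent oracles used to validate the package's implementations.
# These deliberately use different computational routes than the package.

# Mann-Whitney U by the pair-counting definition, over an explicit
# enumeration of all labelings of the pooled data: returns exact one- and
# two-sided p-values for untied samples.
mwu_label_oracle <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  count_u <- function(xs, ys) sum(outer(xs, ys, ">"))
  U_obs <- count_u(x, y)
  labelings <- combn(n1 + n2, n1)
  Us <- apply(labelings, 2L, function(ix)
    count_u(pooled[ix], pooled[-ix]))
  total <- length(Us)
  mu <- n1 * n2 / 2
  switch(alternative,
         greater = sum(Us >= U_obs) / total,
         less = sum(Us <= U_obs) / total,
         two.sided = min(1, sum(abs(Us - mu) >= abs(U_obs - mu)) / total))
}

# Exact null distribution of U by the classical counting recursion
# (number of ways to obtain statistic u from samples of sizes m and n).
mwu_count_recursion <- function(m, n) {
  # counts[i+1, j+1, u+1] = number of rank arrangements of i x's and j y's
  # with statistic u; recursion f(i,j,u) = f(i-1,j,u-j) + f(i,j-1,u)
  maxu <- m * n
  counts <- array(0, dim = c(m + 1L, n + 1L, maxu + 1L))
  counts[1L, , 1L] <- 1
  counts[, 1L, 1L] <- 1
  for (i in 1:m) for (j in 1:n) for (u in 0:(i * j)) {
    a <- if (u - j >= 0) counts[i, j + 1L, u - j + 1L] else 0
    b <- counts[i + 1L, j, u + 1L]
    counts[i + 1L, j + 1L, u + 1L] <- a + b
  }
  cnt <- counts[m + 1L, n + 1L, ]
  cnt / sum(cnt)
}

# Brute-force permutation p-value for possibly tied samples (difference in
# rank-sum direction assessed via U computed by pair counting with halves
# for ties).
mwu_perm_oracle <- function(x, y, alternative, n_resample = 1e5, seed = 1) {
  set.seed(seed)
  n1 <- length(x)
  pooled <- c(x, y)
  count_u <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U_obs <- count_u(x, y)
  mu <- n1 * length(y) / 2
  Us <- replicate(n_resample, {
    ix <- sample.int(length(pooled), n1)
    count_u(pooled[ix], pooled[-ix])
  })
  switch(alternative,
         greater = mean(Us >= U_obs),
         less = mean(Us <= U_obs),
         two.sided = mean(abs(Us - mu) >= abs(U_obs - mu)))
}

# Geometric mean distance computed the naive way (double loop, direct
# product), for cross-checking delta_g.
delta_g_naive <- function(positions, L) {
  positions <- unique(positions)
  k <- length(positions)
  prod_d <- 1
  npair <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    prod_d <- prod_d * abs(positions[i] - positions[j]) / L
    npair <- npair + 1L
  }
  prod_d^(1 / npair)
}

# One-way ANOVA from the explicit sum-of-squares decomposition.
anova_decomposition_oracle <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(y) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}

fixture_path <- function(file) system.file("extdata", file,
                                           package = "certra")

cert_transcript <- function() {
  transcript_model("NM_005713.3", 624,
                   domains = data.frame(name = c("PH", "START"),
                                        start = c(23, 389),
                                        end = c(117, 618)))
}
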