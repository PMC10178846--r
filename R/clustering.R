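#' Normalized pairwise distances between variant positions
#'
#' Computes `|x_i - x_j| / L` for every unordered pair of distinct positions,
#' in lexicographic pair order. These are the terms whose geometric mean is
#' the linear clustering statistic [delta_g()].
#'
#' @param positions Integer vector of distinct amino-acid positions.
#' @param L Transcript (protein) length in residues.
#' @return Numeric vector of length `choose(k, 2)`, values in `[0, 1]`.
#' @examples
#' pairwise_normalized_distances(c(10, 20, 30), 100)
#' @export
pairwise_normalized_distances <- function(positions, L) {
  L <- as.integer(L)
  stopifnot(length(L) == 1L, L >= 1L)
  positions <- as.integer(positions)
  if (anyDuplicated(positions))
    stop("duplicated positions; use delta_g(duplicate_policy = \"keep\") ",
         "for multisets", call. = FALSE)
  out <- positions < 1L | positions > L
  if (any(out))
    stop("position out of [1, ", L, "]: ",
         paste(positions[out], collapse = ", "), call. = FALSE)
  if (length(positions) < 2L)
    stop("insufficient positions (need >= 2)", call. = FALSE)
  positions <- sort(positions)
  pr <- combn(positions, 2L)
  abs(pr[2L, ] - pr[1L, ]) / L
}

#' Geometric-mean-distance clustering statistic
#'
#' The geometric mean of transcript-length-normalized pairwise distances
#' between missense variant positions. Small values indicate linear
#' clustering of the variants along the protein.
#'
#' @param positions Integer vector (multiset) of amino-acid positions.
#' @param L Transcript length in residues.
#' @param duplicate_policy `"collapse"` (default) computes the statistic over
#'   distinct positions, mirroring a cohort tested on its distinct variant
#'   sites; `"keep"` retains recurrences, in which case any coincident pair
#'   annihilates the geometric mean (`delta_g = 0`).
#' @return Scalar in `[0, 1]`.
#' @examples
#' delta_g(c(10, 20, 30), 100) # (0.1 * 0.2 * 0.1)^(1/3)
#' @export
delta_g <- function(positions, L, duplicate_policy = c("collapse", "keep")) {
  duplicate_policy <- match.arg(duplicate_policy)
  positions <- as.integer(positions)
  if (duplicate_policy == "collapse") positions <- unique(positions)
  if (length(positions) < 2L)
    stop("insufficient positions (need >= 2 after '",
         duplicate_policy, "')", call. = FALSE)
  if (duplicate_policy == "keep" && anyDuplicated(positions)) return(0)
  d <- pairwise_normalized_distances(positions, L)
  exp(mean(log(d)))
}

# mean log pairwise distance, unnormalized by L (the permutation engines
# compare on this scale; the 1/L factor cancels)
mean_log_pairdist <- function(positions) {
  pr <- combn(sort(as.integer(positions)), 2L)
  mean(log(abs(pr[2L, ] - pr[1L, ])))
}

derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 10007) %% 2147483563)
}

new_cluster_test_result <- function(scope, delta_g_obs, k, n_perm, n_le,
                                    seed, testable = TRUE) {
  p <- if (testable) (n_le + 1) / (n_perm + 1) else NA_real_
  structure(
    list(scope = scope, delta_g_obs = delta_g_obs, k = k,
         n_perm = n_perm, n_le = n_le, p_empirical = p, seed = seed,
         testable = testable),
    class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("[%s] untestable (%d observed position%s)\n", x$scope, x$k,
                if (x$k == 1L) "" else "s"))
  } else {
    cat(sprintf(
      "[%s] delta_g = %.5g over %d positions; p = %.3g (%d of %g permutations <= observed; seed %d)\n",
      x$scope, x$delta_g_obs, x$k, x$p_empirical, as.integer(x$n_le),
      x$n_perm, x$seed))
  }
  invisible(x)
}

#' Permutation test for linear variant clustering
#'
#' Tests whether the observed distinct variant positions are more tightly
#' clustered (smaller [delta_g()]) than `k` positions drawn uniformly without
#' replacement from `[1, L]`. The one-sided empirical p-value uses the +1
#' pseudocount, `p = (n_le + 1) / (n_perm + 1)`, where `n_le` counts
#' permutations with a statistic smaller than or equal to the observed one
#' (ties count toward rejection).
#'
#' @param panel A [variant_panel()], or an integer vector of positions.
#' @param transcript A [transcript_model()]; may be omitted when `panel` is a
#'   `variant_panel` (its own transcript is used).
#' @param n_perm Number of permutations (default `1e5`; the statistic scales
#'   to `1e8` if asked).
#' @param seed Integer seed; identical seeds give identical results.
#' @param duplicate_policy Passed to [delta_g()] for the observed statistic.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both consume the R random-number stream.
#' @return A `cluster_test_result` with the observed statistic, permutation
#'   counts, empirical p-value and seed.
#' @seealso [exhaustive_test()] for the exact small-instance null.
#' @export
permutation_test <- function(panel, transcript = NULL, n_perm = 1e5,
                             seed, duplicate_policy = "collapse",
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(panel, "variant_panel")) {
    if (is.null(transcript)) transcript <- panel$transcript
    positions <- panel$distinct_positions
  } else {
    positions <- unique(as.integer(panel))
  }
  stopifnot(inherits(transcript, "transcript_model"))
  L <- transcript$aa_length
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  n_perm <- as.double(n_perm)
  if (is.na(n_perm) || n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  k <- length(positions)
  if (k < 2L) stop("insufficient positions (need >= 2)", call. = FALSE)
  if (k > L) stop("cannot draw ", k, " distinct positions from 1..", L,
                  call. = FALSE)
  dg_obs <- delta_g(positions, L, duplicate_policy)
  mlo <- mean_log_pairdist(unique(positions))
  set.seed(seed)
  n_le <- if (engine == "cpp") {
    cpp_perm_null_count(mlo, L, k, n_perm)
  } else {
    r_perm_null_count(mlo, L, k, n_perm)
  }
  new_cluster_test_result("global", dg_obs, k, n_perm, n_le, seed)
}

# pure-R permutation engine (reference path for the compiled one)
r_perm_null_count <- function(mean_log_obs, L, k, n_perm) {
  eps <- 1e-12
  n_le <- 0
  for (b in seq_len(n_perm)) {
    pos <- sample.int(L, k)
    if (mean_log_pairdist(pos) <= mean_log_obs + eps) n_le <- n_le + 1
  }
  n_le
}

#' Exact null by exhaustive enumeration
#'
#' Enumerates every `k`-subset of `1..L` and returns the exact lower-tail
#' probability of the clustering statistic. This is the brute-force oracle
#' the sampled permutation test is validated against; it refuses instances
#' with more than one million subsets.
#'
#' @param positions Integer vector of distinct observed positions.
#' @param L Transcript length (small).
#' @return List with `p_exact` (`#\{delta_g <= observed\} / C(L,k)`),
#'   `p_plus1` (the +1-corrected analogue comparable to the sampled test),
#'   `n_subsets` and `delta_g_obs`.
#' @examples
#' exhaustive_test(c(1, 2), 8)$p_exact # 7/28
#' @export
exhaustive_test <- function(positions, L) {
  L <- as.integer(L)
  positions <- unique(as.integer(positions))
  k <- length(positions)
  if (k < 2L) stop("insufficient positions (need >= 2)", call. = FALSE)
  if (any(positions < 1L | positions > L))
    stop("position out of [1, ", L, "]", call. = FALSE)
  n_subsets <- choose(L, k)
  if (n_subsets > 1e6)
    stop("instance too large for oracle (C(L,k) = ", format(n_subsets),
         " > 1e6)", call. = FALSE)
  eps <- 1e-12
  mlo <- mean_log_pairdist(positions)
  ml <- combn(seq_len(L), k, mean_log_pairdist)
  n_le <- sum(ml <= mlo + eps)
  list(p_exact = n_le / n_subsets,
       p_plus1 = (n_le + 1) / (n_subsets + 1),
       n_subsets = n_subsets,
       delta_g_obs = delta_g(positions, L))
}

#' Per-cluster clustering tests
#'
#' Computes the observed [delta_g()] over the distinct observed positions
#' falling inside each predefined spatial cluster interval, against a null of
#' equally many distinct positions drawn uniformly over the whole transcript.
#' Clusters holding fewer than two observed positions are returned flagged
#' `testable = FALSE` rather than dropped. Per-cluster seeds are derived
#' deterministically from the master seed and the cluster index.
#'
#' @param panel A [variant_panel()].
#' @param clusters A [cluster_definitions()] table.
#' @param n_perm Permutations per cluster.
#' @param seed Master integer seed.
#' @inheritParams permutation_test
#' @return List of `cluster_test_result`, one per cluster, in input order.
#' @export
cluster_delta_g <- function(panel, clusters, n_perm = 1e5, seed,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(panel, "variant_panel"),
            inherits(clusters, "cluster_definition"))
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  transcript <- panel$transcript
  L <- transcript$aa_length
  out <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    inside <- panel$distinct_positions[
      panel$distinct_positions >= clusters$start[i] &
        panel$distinct_positions <= clusters$end[i]]
    k <- length(inside)
    sd_i <- derive_seed(seed, i)
    if (k < 2L) {
      out[[i]] <- new_cluster_test_result(clusters$name[i], NA_real_, k,
                                          n_perm, NA_real_, sd_i,
                                          testable = FALSE)
      next
    }
    res <- permutation_test(inside, transcript, n_perm = n_perm,
                            seed = sd_i, engine = engine)
    res$scope <- clusters$name[i]
    out[[i]] <- res
  }
  names(out) <- clusters$name
  out
}

#' Summarize cluster test results as a data frame
#'
#' @param results List of `cluster_test_result` (e.g. from
#'   [cluster_delta_g()]).
#' @return `data.frame` with one row per result.
#' @export
cluster_results_table <- function(results) {
  if (inherits(results, "cluster_test_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(scope = r$scope, delta_g_obs = r$delta_g_obs, k = r$k,
               n_perm = r$n_perm, n_le = r$n_le,
               p_empirical = r$p_empirical, seed = r$seed,
               testable = r$testable)))
}
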