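test_that("pairwise normalized distances are correct, ordered, and guarded", {
  expect_equal(pairwise_normalized_distances(c(10, 20), 100), 0.1)
  expect_equal(pairwise_normalized_distances(c(10, 20, 30), 100),
               c(0.1, 0.2, 0.1))
  L <- 57
  expect_equal(pairwise_normalized_distances(c(1, L), L), (L - 1) / L)
  expect_length(pairwise_normalized_distances(c(3, 9, 21, 40), 50),
                choose(4, 2))
  expect_error(pairwise_normalized_distances(5, 100),
               "insufficient positions")
  expect_error(pairwise_normalized_distances(c(0, 10), 100), "out of")
  expect_error(pairwise_normalized_distances(c(10, 101), 100), "101")
})

test_that("delta_g matches hand values, the naive oracle, and duplicate policies", {
  expect_equal(delta_g(c(10, 20, 30), 100), (0.1 * 0.1 * 0.2)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(delta_g(c(10, 20), 100), 0.1)
  # coincident pair annihilates the geometric mean under "keep"
  expect_identical(delta_g(c(5, 5, 80), 100, "keep"), 0)
  # but collapses to a usable pair under the default policy
  expect_equal(delta_g(c(5, 5, 80), 100), 0.75)
  expect_error(delta_g(c(7, 7), 100), "insufficient")
  for (i in 1:20) {
    set.seed(i)
    L <- sample(50:500, 1)
    pos <- sample.int(L, sample(3:10, 1))
    expect_equal(delta_g(pos, L), delta_g_naive(pos, L), tolerance = 1e-10)
  }
})

test_that("delta_g is invariant to translation and integer rescaling", {
  set.seed(42)
  for (i in 1:20) {
    L <- 200
    pos <- sort(sample.int(100, 5))
    shift <- sample(0:100, 1)
    expect_equal(delta_g(pos, L), delta_g(pos + shift, L), tolerance = 1e-12)
    m <- sample(2:5, 1)
    expect_equal(delta_g(pos, L), delta_g(pos * m, L * m), tolerance = 1e-12)
  }
})

test_that("exhaustive oracle matches hand-enumerable cases", {
  # {1,2} on L=8: delta_g_obs = 1/8, exactly the 7 adjacent pairs qualify
  ex <- exhaustive_test(c(1, 2), 8)
  expect_equal(ex$p_exact, 7 / 28)
  expect_equal(ex$p_plus1, 8 / 29)
  expect_equal(ex$n_subsets, 28)
  # maximally spread pair: every subset has delta_g <= observed
  expect_equal(exhaustive_test(c(1, 19), 19)$p_exact, 1)
  # {1,2,3} on L=5: independent full enumeration over the 10 triples
  dgs <- combn(5, 3, function(s) delta_g_naive(s, 5))
  obs <- delta_g_naive(c(1, 2, 3), 5)
  expect_equal(exhaustive_test(c(1, 2, 3), 5)$p_exact,
               mean(dgs <= obs + 1e-12))
  expect_error(exhaustive_test(c(1, 5), 4), "out of")
  expect_error(exhaustive_test(c(1, 2, 3, 4, 5, 6, 7, 8), 500),
               "too large")
})

test_that("permutation p-values behave at the edges and reproduce exactly", {
  tm <- transcript_model("t", 100)
  # n_perm = 1: p is (0+1)/2 or (1+1)/2
  r1 <- permutation_test(c(10, 60), tm, n_perm = 1, seed = 5)
  expect_true(r1$p_empirical %in% c(0.5, 1))
  # tight triplet is significant
  rt <- permutation_test(c(10, 11, 12), tm, n_perm = 9999, seed = 1)
  expect_lt(rt$p_empirical, 0.05)
  expect_equal(rt$p_empirical, (rt$n_le + 1) / (rt$n_perm + 1))
  # maximally spread positions: p near 1
  rs <- permutation_test(c(1, 50, 100), tm, n_perm = 9999, seed = 2)
  expect_gt(rs$p_empirical, 0.95)
  # determinism: identical seed => identical result, both engines
  for (eng in c("cpp", "r")) {
    a <- permutation_test(c(10, 30, 80), tm, n_perm = 2000, seed = 11,
                          engine = eng)
    b <- permutation_test(c(10, 30, 80), tm, n_perm = 2000, seed = 11,
                          engine = eng)
    expect_identical(a$n_le, b$n_le)
  }
  expect_error(permutation_test(c(10, 30), tm, n_perm = 0, seed = 1),
               "n_perm")
  expect_error(permutation_test(c(1, 2, 3), transcript_model("t", 2),
                                n_perm = 10, seed = 1))
})

test_that("compiled and reference permutation engines agree with the exact null", {
  tm <- transcript_model("t", 20)
  pos <- c(4, 7, 9)
  ex <- exhaustive_test(pos, 20)$p_exact
  pc <- permutation_test(pos, tm, n_perm = 4e4, seed = 3,
                         engine = "cpp")$p_empirical
  pr <- permutation_test(pos, tm, n_perm = 4e4, seed = 3,
                         engine = "r")$p_empirical
  se <- sqrt(ex * (1 - ex) / 4e4)
  expect_lt(abs(pc - ex), 4 * se)
  expect_lt(abs(pr - ex), 4 * se)
})

test_that("translation of observed positions changes p only by Monte-Carlo noise", {
  tm <- transcript_model("t", 300)
  pos <- c(40, 44, 52, 60)
  p1 <- permutation_test(pos, tm, n_perm = 2e4, seed = 9)$p_empirical
  p2 <- permutation_test(pos + 150, tm, n_perm = 2e4, seed = 10)$p_empirical
  expect_equal(delta_g(pos, 300), delta_g(pos + 150, 300))
  expect_lt(abs(p1 - p2), 4 * sqrt(p1 * (1 - p1) / 2e4) + 1e-4)
})

test_that("per-cluster tests use whole-transcript nulls, flag untestable clusters, and reproduce", {
  tm <- cert_transcript()
  panel <- variant_panel(
    data.frame(subject_id = paste0("s", 1:6),
               aa_pos = c(132, 135, 138, 141, 166, 500)),
    tm)
  cl <- cluster_definitions(c("srr", "lone", "start"),
                            c(132, 160, 389), c(141, 172, 618), tm)
  res <- cluster_delta_g(panel, cl, n_perm = 2000, seed = 77)
  # frozen oracle value: geometric mean of {3,6,9,3,6,3}/624
  expect_equal(res$srr$delta_g_obs, prod(c(3, 6, 9, 3, 6, 3) / 624)^(1 / 6),
               tolerance = 1e-12)
  expect_equal(res$srr$delta_g_obs, 0.00727445, tolerance = 1e-6)
  expect_true(res$srr$testable)
  expect_lt(res$srr$p_empirical, 0.05)
  expect_false(res$lone$testable)
  expect_identical(res$lone$k, 1L)
  expect_false(res$start$testable) # one observed position (500)
  res2 <- cluster_delta_g(panel, cl, n_perm = 2000, seed = 77)
  expect_identical(cluster_results_table(res), cluster_results_table(res2))
  # per-cluster seeds differ from each other and derive from the master
  expect_false(res$srr$seed == res$lone$seed)
})

test_that("power increases as simulated clusters tighten", {
  tm <- transcript_model("t", 624)
  sigmas <- c(20, 6, 1.5)
  med_p <- vapply(seq_along(sigmas), function(si) {
    ps <- vapply(1:30, function(i) {
      sim <- simulate_variant_panel(L = 624, k = 12,
                                    cluster_centers = c(150, 300, 450),
                                    sigma = sigmas[si], mixing = 1,
                                    seed = 1000 * si + i)
      permutation_test(sim$panel, n_perm = 2000,
                       seed = 7000 + i)$p_empirical
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})
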