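test_that("threshold classification follows strict 'over' cutoffs", {
  all_path <- classify_variant(list(cadd = 25, revel = 0.6, mcap = 0.03,
                                    eigen = 0.7))
  expect_true(all(all_path$verdicts == "pathogenic"))
  expect_identical(all_path$consensus, "consistent-pathogenic")
  # boundary values equal to the cutoffs are benign (strictly greater)
  bound <- classify_variant(list(cadd = 20, revel = 0.5, mcap = 0.025,
                                 eigen = 0.5))
  expect_true(all(bound$verdicts == "benign"))
  expect_identical(bound$consensus, "consistent-benign")
  mixed <- classify_variant(list(cadd = 30, mcap = 0.01))
  expect_identical(unname(mixed$verdicts["cadd"]), "pathogenic")
  expect_identical(unname(mixed$verdicts["revel"]), "indeterminate")
  expect_identical(unname(mixed$verdicts["mcap"]), "benign")
  expect_identical(mixed$consensus, "inconsistent")
  expect_error(classify_variant(list()), "unclassifiable")
  expect_error(classify_variant(list(revel = 1.2)), "REVEL")
  # majority mode
  maj <- classify_variant(list(cadd = 30, revel = 0.9, mcap = 0.01),
                          consensus = "majority")
  expect_identical(maj$consensus, "consistent-pathogenic")
})

test_that("classification is monotone in each score", {
  pol <- score_thresholds()
  set.seed(1)
  rank_of <- c(benign = 1, indeterminate = 2, pathogenic = 3)
  upper <- c(cadd = 99, revel = 1, mcap = 1, eigen = 10)
  for (i in 1:50) {
    rec <- list(cadd = runif(1, 0, 40), revel = runif(1), mcap = runif(1),
                eigen = rnorm(1))
    tool <- sample(names(rec), 1)
    rec2 <- rec
    rec2[[tool]] <- runif(1, rec[[tool]], upper[[tool]])
    v1 <- classify_variant(rec, pol)$verdicts[tool]
    v2 <- classify_variant(rec2, pol)$verdicts[tool]
    expect_gte(rank_of[[v2]], rank_of[[v1]])
  }
})

test_that("U statistic identities and symmetric cases hold", {
  set.seed(2)
  for (i in 1:30) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
    ux <- mann_whitney_u(x, y, method = "approx")$U
    uy <- mann_whitney_u(y, x, method = "approx")$U
    expect_equal(ux + uy, length(x) * length(y))
  }
  # identical multisets: U = n1*n2/2 and two-sided p = 1
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), method = "approx")
  expect_equal(res$U, 4.5)
  expect_equal(res$p_value, 1)
})

test_that("exact Mann-Whitney p matches the labeling-enumeration oracle", {
  # spec worked example: complete separation, one-sided toward y
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                        method = "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 20)
  set.seed(3)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    for (alt in c("two.sided", "greater", "less")) {
      mine <- mann_whitney_u(x, y, alternative = alt, method = "exact")
      expect_equal(mine$p_value, mwu_label_oracle(x, y, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact refuses ties; approximation matches a permutation oracle under ties", {
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 2, 2), method = "exact"),
               "untied")
  # tie-corrected normal approximation tracks the permutation null at
  # moderate n (the approximation is known to be poor on tiny tied
  # lattices, so agreement is asserted from n ~ 8 per group upward)
  set.seed(42)
  x8 <- c(1, 1, 2, 3, 3, 4, 5, 5)
  y8 <- c(1, 2, 2, 3, 4, 4, 5, 6)
  x20 <- round(rnorm(20, 0.3, 1), 0)
  y20 <- round(rnorm(25, 0, 1), 0)
  for (alt in c("two.sided", "greater")) {
    pa8 <- mann_whitney_u(x8, y8, alternative = alt,
                          method = "approx")$p_value
    pp8 <- mwu_perm_oracle(x8, y8, alt, n_resample = 4e4, seed = 42)
    expect_lt(abs(pa8 - pp8), 0.08)
    pa20 <- mann_whitney_u(x20, y20, alternative = alt,
                           method = "approx")$p_value
    pp20 <- mwu_perm_oracle(x20, y20, alt, n_resample = 4e4, seed = 43)
    expect_lt(abs(pa20 - pp20), 0.02)
  }
})

test_that("exact and approximate p agree for untied moderate samples", {
  set.seed(4)
  diffs <- replicate(100, {
    x <- rnorm(10); y <- rnorm(10)
    pe <- mann_whitney_u(x, y, method = "exact")$p_value
    pa <- mann_whitney_u(x, y, method = "approx")$p_value
    abs(pe - pa)
  })
  expect_lt(max(diffs), 0.01)
})

test_that("implementation agrees with wilcox.test across random instances", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    for (alt in c("two.sided", "greater", "less")) {
      mine <- mann_whitney_u(x, y, alternative = alt)
      ref <- wilcox.test(x, y, alternative = alt, exact = TRUE,
                         correct = TRUE)
      expect_equal(mine$U, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("cohort comparison drops missing values per tool and flags untested tools", {
  pat <- data.frame(cadd = c(30, 32, NA, 35), revel = c(0.9, 0.8, 0.7, 0.95),
                    mcap = c(NA, NA, NA, 0.5), eigen = c(1, 2, 1.5, 1.2))
  bg <- data.frame(cadd = c(5, 8, 10, 12, 15), revel = c(0.1, 0.2, 0.3, 0.15, 0.25),
                   mcap = c(0.01, 0.02, 0.01, 0.03, 0.02),
                   eigen = c(-0.5, 0, 0.2, -1, 0.3))
  cmp <- compare_cohorts(pat, bg)
  expect_identical(cmp$tool, c("cadd", "revel", "mcap", "eigen"))
  expect_identical(cmp$tested, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(cmp$n1[cmp$tool == "cadd"], 3)
  expect_true(is.na(cmp$p_value[cmp$tool == "mcap"]))
  # complete separation: smallest attainable one-sided exact p
  expect_equal(cmp$p_value[cmp$tool == "revel"],
               1 / choose(4 + 5, 4))
  # identical cohorts: one-sided p near 1
  same <- data.frame(cadd = 1:6 + 0.5, revel = seq(0.1, 0.6, 0.1),
                     mcap = seq(0.01, 0.06, 0.01), eigen = rnorm(6))
  cmp2 <- compare_cohorts(same, same, method = "approx")
  expect_true(all(cmp2$p_value > 0.5))
})

test_that("shifted synthetic cohorts are detected at stringent alpha", {
  rej <- vapply(1:50, function(i) {
    sim <- simulate_score_table(n_pathogenic = 20, n_background = 200,
                                effect_sd = 1, seed = 100 + i)
    cmp <- compare_cohorts(sim$patient, sim$background)
    mean(cmp$p_value < 0.001)
  }, numeric(1))
  expect_gt(mean(rej), 0.5)
})
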