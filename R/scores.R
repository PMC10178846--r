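#' Pathogenicity score thresholds
#'
#' Default per-tool cutoffs above which a variant is called pathogenic:
#' M-CAP > 0.025, REVEL > 0.5, Eigen > 0.5, CADD (PHRED scale) > 20.
#' Comparison is strictly greater; a score equal to its cutoff is benign.
#'
#' @param mcap,revel,eigen,cadd Numeric cutoffs overriding the defaults.
#' @return Named list of class `threshold_policy`.
#' @export
score_thresholds <- function(mcap = 0.025, revel = 0.5, eigen = 0.5,
                             cadd = 20) {
  stopifnot(mcap > 0, revel > 0, eigen > 0, cadd > 0)
  structure(list(mcap = mcap, revel = revel, eigen = eigen, cadd = cadd),
            class = "threshold_policy")
}

score_tools <- c("cadd", "revel", "mcap", "eigen")

validate_score_record <- function(record) {
  vals <- lapply(score_tools, function(t)
    if (is.null(record[[t]])) NA_real_ else as.numeric(record[[t]]))
  names(vals) <- score_tools
  if (all(vapply(vals, is.na, logical(1))))
    stop("unclassifiable: all four scores missing", call. = FALSE)
  if (!is.na(vals$revel) && (vals$revel < 0 || vals$revel > 1))
    stop("REVEL score outside [0, 1]", call. = FALSE)
  if (!is.na(vals$mcap) && (vals$mcap < 0 || vals$mcap > 1))
    stop("M-CAP score outside [0, 1]", call. = FALSE)
  if (!is.na(vals$cadd) && vals$cadd < 0)
    stop("CADD score must be >= 0", call. = FALSE)
  vals
}

#' Classify a variant by in-silico score thresholds
#'
#' Each present score is called `"pathogenic"` (strictly above its cutoff)
#' or `"benign"`; missing scores are `"indeterminate"`. The consensus is
#' `"consistent-pathogenic"` / `"consistent-benign"` when all present
#' verdicts agree, else `"inconsistent"`. `consensus = "majority"` instead
#' takes the majority vote of present verdicts (ties are `"inconsistent"`).
#'
#' @param record List or one-row data frame with any of `cadd`, `revel`,
#'   `mcap`, `eigen` (missing entries may be `NULL` or `NA`).
#' @param policy A [score_thresholds()] object.
#' @param consensus `"all-agree"` (default) or `"majority"`.
#' @return List with `verdicts` (named character vector over the four
#'   tools) and `consensus`.
#' @examples
#' classify_variant(list(cadd = 25, revel = 0.6, mcap = 0.03, eigen = 0.7))
#' @export
classify_variant <- function(record, policy = score_thresholds(),
                             consensus = c("all-agree", "majority")) {
  consensus <- match.arg(consensus)
  stopifnot(inherits(policy, "threshold_policy"))
  vals <- validate_score_record(record)
  verdicts <- vapply(score_tools, function(t) {
    v <- vals[[t]]
    if (is.na(v)) "indeterminate"
    else if (v > policy[[t]]) "pathogenic"
    else "benign"
  }, character(1))
  present <- verdicts[verdicts != "indeterminate"]
  cons <- if (consensus == "all-agree") {
    if (all(present == "pathogenic")) "consistent-pathogenic"
    else if (all(present == "benign")) "consistent-benign"
    else "inconsistent"
  } else {
    np <- sum(present == "pathogenic"); nb <- sum(present == "benign")
    if (np > nb) "consistent-pathogenic"
    else if (nb > np) "consistent-benign"
    else "inconsistent"
  }
  list(verdicts = verdicts, consensus = cons)
}

#' Classify a table of variants
#'
#' @param scores `data.frame` with column `variant_id` plus score columns.
#' @inheritParams classify_variant
#' @return `data.frame` with per-tool verdicts and the consensus per row.
#' @export
classify_score_table <- function(scores, policy = score_thresholds(),
                                 consensus = "all-agree") {
  scores <- as.data.frame(scores)
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    cl <- classify_variant(scores[i, , drop = FALSE], policy, consensus)
    cbind(data.frame(variant_id = if ("variant_id" %in% names(scores))
      scores$variant_id[i] else as.character(i)),
      as.data.frame(as.list(cl$verdicts)),
      data.frame(consensus = cl$consensus))
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test (from scratch)
#'
#' Rank-sum U statistic with mid-ranks for ties. `method = "exact"`
#' enumerates all `C(n1+n2, n1)` labelings (admissible only for untied data
#' with `min(n1, n2) <= 12`); `"approx"` uses the normal approximation with
#' tie-corrected variance and continuity correction; `"auto"` picks exact
#' when admissible and the enumeration is small enough to be cheap
#' (at most 3e5 labelings). `alternative = "greater"` tests whether `x` tends to
#' exceed `y`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return List with `U` (for `x`), `n1`, `n2`, `p_value`, `method`,
#'   `alternative`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p_value # 0.05
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "greater", "less"),
                           method = c("auto", "exact", "approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("NA in samples; drop missing values first",
                                 call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("empty sample", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (method == "exact" && has_ties)
    stop("exact method requires untied data; use method = \"approx\"",
         call. = FALSE)
  if (method == "exact" && min(n1, n2) > 12L)
    stop("exact method limited to min(n1, n2) <= 12", call. = FALSE)
  n_label <- choose(n1 + n2, min(n1, n2))
  if (method == "exact" && n_label > 5e6)
    stop("instance too large for exact enumeration (", format(n_label),
         " labelings)", call. = FALSE)
  # auto additionally requires the enumeration to be cheap
  use_exact <- method == "exact" ||
    (method == "auto" && !has_ties && min(n1, n2) <= 12L &&
       n_label <= 3e5)
  if (use_exact) {
    p <- mwu_exact_p(U, n1, n2, alternative)
    return(list(U = U, n1 = n1, n2 = n2, p_value = p, method = "exact",
                alternative = alternative))
  }
  # normal approximation, tie-corrected variance, continuity correction
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) { # all observations identical
    p <- 1
  } else {
    sigma <- sqrt(sigma2)
    z <- U - mu
    p <- switch(alternative,
      greater = pnorm((z - 0.5) / sigma, lower.tail = FALSE),
      less = pnorm((z + 0.5) / sigma),
      two.sided = {
        zc <- max(abs(z) - 0.5, 0)
        min(1, 2 * pnorm(zc / sigma, lower.tail = FALSE))
      })
  }
  list(U = U, n1 = n1, n2 = n2, p_value = p,
       method = "normal_approx_tie_corrected", alternative = alternative)
}

# exact p by full enumeration of rank labelings (untied data): the null
# distribution of U is the distribution of rank-sum choices of n1 ranks
# among 1..N; enumeration runs over the smaller sample and maps back via
# U_x = n1*n2 - U_y
mwu_exact_p <- function(U, n1, n2, alternative) {
  N <- n1 + n2
  m <- min(n1, n2)
  Us <- colSums(combn(N, m)) - m * (m + 1) / 2
  if (m != n1) Us <- n1 * n2 - Us
  total <- length(Us)
  switch(alternative,
    greater = sum(Us >= U) / total,
    less = sum(Us <= U) / total,
    two.sided = {
      mu <- n1 * n2 / 2
      min(1, sum(abs(Us - mu) >= abs(U - mu)) / total)
    })
}

#' Compare patient and background score cohorts per tool
#'
#' One [mann_whitney_u()] test per tool (default one-sided: patients
#' greater), with missing values dropped pairwise per tool. Tools with fewer
#' than two non-missing values in either cohort are flagged untested.
#'
#' @param patient,background Score tables (`data.frame`s with columns among
#'   `cadd`, `revel`, `mcap`, `eigen`).
#' @param alternative,method Passed to [mann_whitney_u()].
#' @param tools Character vector of score columns to test.
#' @return `data.frame` with one row per tool: `tool`, `U`, `n1`, `n2`,
#'   `p_value`, `method`, `alternative`, `tested`.
#' @export
compare_cohorts <- function(patient, background, alternative = "greater",
                            method = "auto", tools = score_tools) {
  patient <- as.data.frame(patient); background <- as.data.frame(background)
  rows <- lapply(tools, function(t) {
    x <- patient[[t]]; y <- background[[t]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(tool = t, U = NA_real_, n1 = length(x),
                        n2 = length(y), p_value = NA_real_,
                        method = NA_character_, alternative = alternative,
                        tested = FALSE))
    res <- mann_whitney_u(x, y, alternative = alternative, method = method)
    data.frame(tool = t, U = res$U, n1 = res$n1, n2 = res$n2,
               p_value = res$p_value, method = res$method,
               alternative = alternative, tested = TRUE)
  })
  do.call(rbind, rows)
}
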