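#' Aggregate species-level sphingolipid amounts into class totals
#'
#' Sums amounts over fatty-acyl chains within each (sample, lipid class,
#' label channel), i.e. "total levels across the major fatty acid chain
#' lengths". Classes absent for a sample but present elsewhere in the table
#' appear with total 0 rather than being dropped, so per-sample totals are
#' conserved.
#'
#' @param species `data.frame` with columns `sample_id`, `condition`,
#'   `lipid_class`, `chain`, `label_channel` (`"M0"` or `"M3"`), `amount`.
#' @return `data.frame` with columns `sample_id`, `condition`,
#'   `lipid_class`, `label_channel`, `total`.
#' @export
aggregate_class_totals <- function(species) {
  species <- as.data.frame(species)
  need <- c("sample_id", "condition", "lipid_class", "label_channel",
            "chain", "amount")
  if (!all(need %in% names(species)))
    stop("species table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(species) == 0L) stop("empty species table", call. = FALSE)
  if (any(species$amount < 0)) stop("negative amount", call. = FALSE)
  key <- interaction(species$sample_id, species$lipid_class, species$chain,
                     species$label_channel, drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- unique(as.character(key[duplicated(key)]))
    stop("duplicate (sample, class, chain, channel) rows: ",
         paste(head(dup, 5L), collapse = "; "), call. = FALSE)
  }
  # complete the (sample, class, channel) grid so empty cells report 0
  cond_of <- unique(species[c("sample_id", "condition")])
  grid <- expand.grid(sample_id = unique(species$sample_id),
                      lipid_class = unique(species$lipid_class),
                      label_channel = unique(species$label_channel),
                      stringsAsFactors = FALSE)
  agg <- aggregate(amount ~ sample_id + lipid_class + label_channel,
                   data = species, FUN = sum)
  out <- merge(grid, agg, all.x = TRUE,
               by = c("sample_id", "lipid_class", "label_channel"))
  out$amount[is.na(out$amount)] <- 0
  out <- merge(cond_of, out, by = "sample_id")
  names(out)[names(out) == "amount"] <- "total"
  out[order(out$sample_id, out$lipid_class, out$label_channel), ,
      drop = FALSE]
}

#' Newly synthesized fraction of a long-chain-base pool
#'
#' For a serine-labeling experiment where the +3 heavy channel marks newly
#' synthesized backbones: `f = heavy / (unlabeled + heavy)` per backbone
#' (sphingosine SO and sphinganine SA).
#'
#' @param lcb `data.frame` (or one-row list) with columns `SO`, `SO3`, `SA`,
#'   `SA3` (all `>= 0`).
#' @return `data.frame` with columns `f_SO` and `f_SA` (values in `[0, 1]`;
#'   `NA` with a warning where a backbone total is zero).
#' @examples
#' newly_synthesized_fraction(data.frame(SO = 90, SO3 = 10, SA = 50, SA3 = 50))
#' @export
newly_synthesized_fraction <- function(lcb) {
  lcb <- as.data.frame(lcb)
  need <- c("SO", "SO3", "SA", "SA3")
  if (!all(need %in% names(lcb)))
    stop("need columns SO, SO3, SA, SA3", call. = FALSE)
  if (any(unlist(lcb[need]) < 0, na.rm = TRUE))
    stop("negative backbone amount", call. = FALSE)
  tot_so <- lcb$SO + lcb$SO3
  tot_sa <- lcb$SA + lcb$SA3
  f_SO <- ifelse(tot_so > 0, lcb$SO3 / tot_so, NA_real_)
  f_SA <- ifelse(tot_sa > 0, lcb$SA3 / tot_sa, NA_real_)
  if (anyNA(f_SO) || anyNA(f_SA))
    warning("zero total backbone; fraction undefined (NA)", call. = FALSE)
  data.frame(f_SO = f_SO, f_SA = f_SA)
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`; a 4-fold level over the
#' reference is a +300% change.
#'
#' @param value Nonnegative numeric vector.
#' @param reference Positive scalar (or vector recycled against `value`).
#' @return Percent change(s), `>= -100`.
#' @export
relative_change <- function(value, reference) {
  if (any(reference <= 0)) stop("undefined change: reference <= 0",
                                call. = FALSE)
  100 * (value - reference) / reference
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA assuming equal group variances;
#' the F statistic is `(SSB/df_B) / (SSW/df_W)` and the p-value comes from
#' the F distribution. Identical groups give `F = 0`, `p = 1`.
#'
#' @param groups List of numeric vectors, each of length `>= 2`.
#' @return List with `F`, `df_between`, `df_within`, `p_value`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))) # F = 3, df (2, 6)
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("each group needs >= 2 observations", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  Fv <- unname(ow$statistic)
  if (is.nan(Fv)) Fv <- 0 # zero within- and between-group variance
  list(F = Fv,
       df_between = unname(ow$parameter[1L]),
       df_within = unname(ow$parameter[2L]),
       p_value = if (Fv == 0) 1 else unname(ow$p.value))
}

#' Flux report: channel means, labeled fractions and percent changes
#'
#' Per condition: mean SO/SO3/SA/SA3 levels, newly synthesized fractions on
#' those means, and percent change of each channel versus the reference
#' condition (changes are computed on condition means; per-replicate
#' changes can be recovered from the returned sample table). Across
#' conditions, a one-way ANOVA per channel. Optional seeded percentile
#' bootstrap intervals for the percent changes.
#'
#' @param lcb `data.frame` with columns `sample_id`, `condition`, `SO`,
#'   `SO3`, `SA`, `SA3` (one row per replicate).
#' @param reference Name of the reference condition (must have `>= 2`
#'   replicates).
#' @param n_boot Number of bootstrap resamples for percentile CIs of the
#'   percent changes (0 disables; default 0).
#' @param seed Integer seed, mandatory when `n_boot > 0`.
#' @return List of class `flux_report`: `conditions` (per-condition means,
#'   fractions, percent changes, replicate counts and a `single_replicate`
#'   flag), `anova` (per-channel F/df/p), `boot_ci` (or `NULL`), `reference`.
#' @export
flux_report <- function(lcb, reference, n_boot = 0, seed = NULL) {
  lcb <- as.data.frame(lcb)
  need <- c("condition", "SO", "SO3", "SA", "SA3")
  if (!all(need %in% names(lcb)))
    stop("LCB table needs columns condition, SO, SO3, SA, SA3",
         call. = FALSE)
  channels <- c("SO", "SO3", "SA", "SA3")
  if (!reference %in% lcb$condition)
    stop("reference condition '", reference, "' not present", call. = FALSE)
  if (sum(lcb$condition == reference) < 2L)
    stop("reference condition needs >= 2 replicates", call. = FALSE)
  conds <- unique(lcb$condition)
  conds <- c(reference, setdiff(conds, reference))
  n_rep <- vapply(conds, function(cc) sum(lcb$condition == cc), integer(1))
  means <- t(vapply(conds, function(cc)
    colMeans(lcb[lcb$condition == cc, channels, drop = FALSE]),
    numeric(length(channels))))
  ref_means <- means[1L, ]
  pct <- sweep(sweep(means, 2L, ref_means, "-"), 2L, ref_means, "/") * 100
  fr <- newly_synthesized_fraction(as.data.frame(means))
  cond_tab <- data.frame(condition = conds, n = n_rep,
                         single_replicate = n_rep < 2L,
                         means, f_SO = fr$f_SO, f_SA = fr$f_SA,
                         setNames(as.data.frame(pct),
                                  paste0("pct_change_", channels)),
                         row.names = NULL, check.names = FALSE)
  anova_tab <- do.call(rbind, lapply(channels, function(ch) {
    gr <- lapply(conds[n_rep >= 2L], function(cc)
      lcb[[ch]][lcb$condition == cc])
    if (length(gr) < 2L)
      return(data.frame(channel = ch, F = NA_real_, df_between = NA_real_,
                        df_within = NA_real_, p_value = NA_real_))
    a <- one_way_anova(gr)
    data.frame(channel = ch, F = a$F, df_between = a$df_between,
               df_within = a$df_within, p_value = a$p_value)
  }))
  boot_ci <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) stop("'seed' is mandatory when n_boot > 0",
                            call. = FALSE)
    set.seed(as.integer(seed))
    ref_rows <- which(lcb$condition == reference)
    boot_ci <- do.call(rbind, lapply(conds[-1L], function(cc) {
      rows <- which(lcb$condition == cc)
      reps <- vapply(seq_len(n_boot), function(b) {
        rb <- sample(ref_rows, replace = TRUE)
        cb <- sample(rows, replace = TRUE)
        vapply(channels, function(ch) {
          m_ref <- mean(lcb[[ch]][rb])
          if (m_ref <= 0) return(NA_real_)
          relative_change(mean(lcb[[ch]][cb]), m_ref)
        }, numeric(1))
      }, numeric(length(channels)))
      qs <- apply(reps, 1L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
      data.frame(condition = cc, channel = channels,
                 lower = qs[1L, ], upper = qs[2L, ], row.names = NULL)
    }))
  }
  structure(list(conditions = cond_tab, anova = anova_tab,
                 boot_ci = boot_ci, reference = reference),
            class = "flux_report")
}

#' @export
print.flux_report <- function(x, ...) {
  cat("Flux report (reference: ", x$reference, ")\n", sep = "")
  print(x$conditions, digits = 4)
  cat("\nPer-channel one-way ANOVA across conditions:\n")
  print(x$anova, digits = 4)
  invisible(x)
}
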