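#' Simulate a variant panel with linear positional clusters
#'
#' Each variant is, with probability `mixing`, a clustered draw: a random
#' cluster center plus discretized Gaussian jitter with spread `sigma`
#' (rounded, clamped to `[1, L]`); otherwise its position is uniform on
#' `[1, L]`. Defaults emulate the CerTra cohort geometry: 17 variant
#' positions on a 624-residue transcript with four tight clusters (the SRR
#' spans about ten residues, hence `sigma = 3`) and most variants falling
#' inside clusters.
#'
#' @param L Transcript length (residues).
#' @param k Number of variants (one subject each).
#' @param cluster_centers Integer positions of cluster centers.
#' @param sigma Positional spread of a cluster (residues, `> 0`).
#' @param mixing Probability that a variant is clustered rather than
#'   uniform.
#' @param seed Integer seed (mandatory).
#' @return List with `panel` (a [variant_panel()]) and `truth`
#'   (`data.frame`: per-variant `origin` `"clustered"`/`"uniform"` and the
#'   generating `center`, `NA` for uniform draws).
#' @export
simulate_variant_panel <- function(L = 624, k = 17,
                                   cluster_centers = c(136, 166, 246, 328),
                                   sigma = 3, mixing = 0.87, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(sigma > 0, mixing >= 0, mixing <= 1,
            all(cluster_centers >= 1 & cluster_centers <= L))
  set.seed(as.integer(seed))
  clustered <- runif(k) < mixing
  center <- ifelse(clustered,
                   cluster_centers[sample.int(length(cluster_centers), k,
                                              replace = TRUE)],
                   NA_integer_)
  pos <- integer(k)
  pos[clustered] <- pmin(pmax(round(rnorm(sum(clustered),
                                          mean = center[clustered],
                                          sd = sigma)), 1L), L)
  pos[!clustered] <- sample.int(L, sum(!clustered), replace = TRUE)
  tm <- transcript_model("synthetic", L)
  panel <- variant_panel(
    data.frame(subject_id = paste0("S", seq_len(k)), aa_pos = pos),
    tm)
  list(panel = panel,
       truth = data.frame(subject_id = paste0("S", seq_len(k)),
                          aa_pos = pos,
                          origin = ifelse(clustered, "clustered", "uniform"),
                          center = center))
}

#' Simulate patient and background pathogenicity score tables
#'
#' Background scores come from tool-shaped baseline distributions bounded to
#' each tool's range (CADD: truncated normal on the PHRED scale; REVEL and
#' M-CAP: Beta; Eigen: normal). Patient ("pathogenic-shifted") scores add
#' `effect_sd` baseline standard deviations before re-bounding. Missingness
#' is applied independently per tool and variant.
#'
#' @param n_pathogenic,n_background Cohort sizes.
#' @param effect_sd Shift of the pathogenic cohort, in units of each tool's
#'   baseline SD (0 = null).
#' @param missing_rate Probability a given score is missing.
#' @param seed Integer seed (mandatory).
#' @return List with `patient` and `background` score `data.frame`s
#'   (`variant_id`, `cadd`, `revel`, `mcap`, `eigen`).
#' @export
simulate_score_table <- function(n_pathogenic = 20, n_background = 200,
                                 effect_sd = 1, missing_rate = 0, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(n_pathogenic >= 1, n_background >= 1, effect_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  set.seed(as.integer(seed))
  base_sd <- c(cadd = 6, revel = sqrt(2 * 5 / ((2 + 5)^2 * 8)),
               mcap = sqrt(1.2 * 20 / ((1.2 + 20)^2 * 22.2)),
               eigen = 1)
  draw <- function(n, shift_sd) {
    df <- data.frame(
      cadd = pmax(rnorm(n, 15 + shift_sd * base_sd["cadd"], base_sd["cadd"]),
                  0),
      revel = pmin(pmax(stats::rbeta(n, 2, 5) + shift_sd * base_sd["revel"],
                        0), 1),
      mcap = pmin(pmax(stats::rbeta(n, 1.2, 20) + shift_sd * base_sd["mcap"],
                       0), 1),
      eigen = rnorm(n, 0 + shift_sd * base_sd["eigen"], base_sd["eigen"]))
    if (missing_rate > 0)
      for (t in names(df))
        df[[t]][runif(n) < missing_rate] <- NA_real_
    df
  }
  patient <- draw(n_pathogenic, effect_sd)
  background <- draw(n_background, 0)
  patient <- cbind(variant_id = paste0("P", seq_len(n_pathogenic)), patient)
  background <- cbind(variant_id = paste0("B", seq_len(n_background)),
                      background)
  list(patient = patient, background = background)
}

#' Simulate a labeled long-chain-base dataset with species table
#'
#' Per condition, true backbone totals are the reference totals times the
#' condition `fold_change`; the heavy (+3) channel carries `label_fraction`
#' of each total. Replicate measurements multiply truth by mean-one
#' log-normal noise with coefficient of variation `cv`. A species-level
#' table is emitted by splitting noisy per-sample class totals over
#' fatty-acyl chains with fixed proportions, so class aggregation can be
#' checked exactly against the emitted totals.
#'
#' @param conditions `data.frame` with columns `condition`, `fold_change`
#'   (`> 0`), `label_fraction` (in `[0, 1]`); the first row is the
#'   reference. Defaults use fold changes 1, 2, 4 at label fraction 0.25.
#' @param n_replicates Replicates per condition.
#' @param cv Measurement coefficient of variation (log-normal, mean one).
#' @param base_so,base_sa Reference total sphingosine / sphinganine backbone
#'   amounts (pmol).
#' @param seed Integer seed (mandatory).
#' @return List with `lcb` (replicate-level `SO`, `SO3`, `SA`, `SA3`),
#'   `species` (per-sample species rows), `class_totals` (the emitted noisy
#'   class totals the species table must aggregate back to) and `truth`
#'   (the noiseless expectations and the generating config).
#' @export
simulate_lcb_dataset <- function(conditions = data.frame(
                                   condition = c("reference", "fold2",
                                                 "fold4"),
                                   fold_change = c(1, 2, 4),
                                   label_fraction = c(0.25, 0.25, 0.25)),
                                 n_replicates = 3, cv = 0.10,
                                 base_so = 100, base_sa = 20, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  conditions <- as.data.frame(conditions)
  stopifnot(all(c("condition", "fold_change", "label_fraction") %in%
                  names(conditions)),
            all(conditions$fold_change > 0),
            all(conditions$label_fraction >= 0 &
                  conditions$label_fraction <= 1),
            cv >= 0, n_replicates >= 1)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) if (cv == 0) rep(1, n) else
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  classes <- data.frame(
    lipid_class = c("Cer", "dhCer", "SM", "dhSM", "GlcCer"),
    base = c(50, 5, 200, 10, 80))
  chains <- c("C16:0" = 0.4, "C22:0" = 0.2, "C24:0" = 0.25, "C24:1" = 0.15)
  lcb <- NULL; species <- NULL; class_totals <- NULL; truth_rows <- NULL
  for (i in seq_len(nrow(conditions))) {
    cc <- conditions$condition[i]
    fc <- conditions$fold_change[i]
    lf <- conditions$label_fraction[i]
    tot_so <- base_so * fc; tot_sa <- base_sa * fc
    expect <- c(SO = tot_so * (1 - lf), SO3 = tot_so * lf,
                SA = tot_sa * (1 - lf), SA3 = tot_sa * lf)
    truth_rows <- rbind(truth_rows,
                        data.frame(condition = cc, fold_change = fc,
                                   label_fraction = lf, t(expect)))
    for (r in seq_len(n_replicates)) {
      sid <- paste0(cc, "_r", r)
      meas <- expect * noise(4L)
      lcb <- rbind(lcb, data.frame(sample_id = sid, condition = cc,
                                   t(meas)))
      for (j in seq_len(nrow(classes))) {
        cls_tot <- classes$base[j] * fc
        for (ch in c("M0", "M3")) {
          frac <- if (ch == "M3") lf else 1 - lf
          tot <- cls_tot * frac * noise(1L)
          class_totals <- rbind(class_totals,
            data.frame(sample_id = sid, condition = cc,
                       lipid_class = classes$lipid_class[j],
                       label_channel = ch, total = tot))
          species <- rbind(species,
            data.frame(sample_id = sid, condition = cc,
                       lipid_class = classes$lipid_class[j],
                       chain = names(chains),
                       label_channel = ch,
                       amount = tot * unname(chains)))
        }
      }
    }
  }
  list(lcb = lcb, species = species, class_totals = class_totals,
       truth = list(conditions = truth_rows, cv = cv,
                    base_so = base_so, base_sa = base_sa))
}

#' Simulate oligomer mass peaks
#'
#' Peaks at `k * monomer_mw * (1 + eps)` with `eps ~ N(0, rel_noise)`.
#'
#' @param monomer_mw Monomer mass (kDa).
#' @param stoichiometries Integer vector of true oligomer orders.
#' @param rel_noise Relative mass noise SD (`>= 0`).
#' @param seed Integer seed (mandatory).
#' @return `data.frame` with `observed_kda`, `true_k`, `source`.
#' @export
simulate_mass_peaks <- function(monomer_mw, stoichiometries, rel_noise = 0,
                                seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  stopifnot(monomer_mw > 0, rel_noise >= 0,
            all(stoichiometries == as.integer(stoichiometries)),
            all(stoichiometries >= 1))
  set.seed(as.integer(seed))
  k <- as.integer(stoichiometries)
  eps <- rnorm(length(k), 0, rel_noise)
  data.frame(observed_kda = k * monomer_mw * (1 + eps), true_k = k,
             source = "nativeMS")
}
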