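## Residue (monomer minus water) masses in Da for the 20 canonical amino
## acids, plus water. Average masses are the convention for intact-protein
## measurements reported in kDa (native MS, SEC-MALS); monoisotopic masses
## are provided for completeness.
AA_MASS_AVERAGE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

WATER_AVERAGE <- 18.0153
WATER_MONO <- 18.010565

#' Theoretical molecular weight of a protein sequence
#'
#' Sum of residue masses plus one water. Average masses (default) match how
#' intact masses are reported by native MS and SEC-MALS; monoisotopic masses
#' are selectable. No post-translational adjustments are applied.
#'
#' @param sequence One-letter amino-acid string (case-insensitive), or a
#'   vector of strings.
#' @param mass_table `"average"` or `"monoisotopic"`.
#' @return Mass(es) in Da.
#' @examples
#' theoretical_mw("G")  # 75.07 Da
#' theoretical_mw("GG") # 132.12 Da
#' @export
theoretical_mw <- function(sequence, mass_table = c("average",
                                                    "monoisotopic")) {
  mass_table <- match.arg(mass_table)
  tab <- if (mass_table == "average") AA_MASS_AVERAGE else AA_MASS_MONO
  water <- if (mass_table == "average") WATER_AVERAGE else WATER_MONO
  vapply(as.character(sequence), function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty sequence", call. = FALSE)
    aa <- strsplit(toupper(s), "")[[1L]]
    bad <- which(!aa %in% names(tab))
    if (length(bad))
      stop("unknown residue '", aa[bad[1L]], "' at position ", bad[1L],
           call. = FALSE)
    sum(tab[aa]) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' Infer oligomeric stoichiometry from an observed mass
#'
#' Finds the integer `k` in `1..k_max` minimizing the relative error
#' `|observed - k * monomer| / (k * monomer)`; ties break toward smaller
#' `k`. The call is accepted when the best relative error is within
#' `tolerance` (default 5%, wide enough to accept a tetramer observed 3.4%
#' off its theoretical mass while rejecting ambiguous assignments).
#'
#' @param observed_mass Observed mass (same unit as `monomer_mw`, e.g. kDa).
#' @param monomer_mw Theoretical monomer mass, positive.
#' @param k_max Largest stoichiometry considered.
#' @param tolerance Relative error above which the call is not accepted.
#' @return List of class `stoichiometry_call`: `k`, `relative_error`,
#'   `accepted`, `observed_mass`, `monomer_mw`.
#' @examples
#' infer_stoichiometry(37, 18.5)   # dimer, relative error 0
#' infer_stoichiometry(71.5, 18.5) # tetramer, relative error ~0.034
#' @export
infer_stoichiometry <- function(observed_mass, monomer_mw, k_max = 8L,
                                tolerance = 0.05) {
  if (!is.finite(observed_mass) || observed_mass <= 0)
    stop("'observed_mass' must be positive", call. = FALSE)
  if (!is.finite(monomer_mw) || monomer_mw <= 0)
    stop("'monomer_mw' must be positive", call. = FALSE)
  ks <- seq_len(k_max)
  rel <- abs(observed_mass - ks * monomer_mw) / (ks * monomer_mw)
  k <- ks[which.min(rel)] # which.min takes the first (smallest k) on ties
  structure(list(k = k, relative_error = rel[k],
                 accepted = rel[k] <= tolerance,
                 observed_mass = observed_mass, monomer_mw = monomer_mw),
            class = "stoichiometry_call")
}

#' @export
print.stoichiometry_call <- function(x, ...) {
  cat(sprintf("observed %.4g vs %d x %.4g: k = %d, relative error %.3g%s\n",
              x$observed_mass, x$k, x$monomer_mw, x$k,
              x$relative_error,
              if (x$accepted) " (accepted)" else " (NOT accepted)"))
  invisible(x)
}

#' Annotate a list of mass peaks with stoichiometry calls
#'
#' @param peaks Numeric vector of observed masses, or a `data.frame` with
#'   column `observed_kda` (and optionally `source`).
#' @inheritParams infer_stoichiometry
#' @return `data.frame` with one row per peak, input order preserved:
#'   `observed_mass`, `k`, `expected_mass`, `relative_error`, `accepted`
#'   (plus `source` if supplied).
#' @examples
#' annotate_peaks(c(18.5, 37, 71.5), 18.5)
#' @export
annotate_peaks <- function(peaks, monomer_mw, k_max = 8L, tolerance = 0.05) {
  src <- NULL
  if (is.data.frame(peaks)) {
    if (!"observed_kda" %in% names(peaks))
      stop("peaks data.frame needs column 'observed_kda'", call. = FALSE)
    src <- peaks$source
    peaks <- peaks$observed_kda
  }
  if (length(peaks) == 0L) stop("empty peak list", call. = FALSE)
  calls <- lapply(peaks, infer_stoichiometry, monomer_mw = monomer_mw,
                  k_max = k_max, tolerance = tolerance)
  out <- data.frame(
    observed_mass = peaks,
    k = vapply(calls, `[[`, integer(1), "k"),
    relative_error = vapply(calls, `[[`, numeric(1), "relative_error"),
    accepted = vapply(calls, `[[`, logical(1), "accepted"))
  out$expected_mass <- out$k * monomer_mw
  if (!is.null(src)) out$source <- src
  out[, c("observed_mass", "k", "expected_mass", "relative_error",
          "accepted", if (!is.null(src)) "source")]
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10 / extend 0.5 via
#' Biostrings) between two protein sequences; identity is the percentage of
#' identical aligned positions over the alignment length including gaps
#' (`pid` type `PID2`).
#'
#' @param a,b One-letter amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID2")
}

#' Load a reference protein sequence bundled or supplied by the user
#'
#' Reference sequences (e.g. the human CERT isoform-1 protein NP_005704 and
#' the Drosophila CERT orthologue) are inputs, not package contents: this
#' package ships only clearly-labelled synthetic sequences. Place the real
#' FASTA files under `inst/extdata/reference/<accession>.fasta` (or pass
#' `path`) to run the sequence-dependent checks; the loader errors when the
#' file is absent.
#'
#' @param accession File stem, e.g. `"NP_005704"`.
#' @param path Optional explicit path to a FASTA file.
#' @return Single character string (the sequence, uppercase).
#' @export
certra_reference_protein <- function(accession, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference",
                        paste0(accession, ".fasta"), package = "certra")
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("reference sequence '", accession, "' not available: supply the ",
         "FASTA under inst/extdata/reference/ or via 'path'",
         call. = FALSE)
  seqs <- read_fasta(path)
  unname(seqs[[1L]])
}
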