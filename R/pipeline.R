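## TSV dialect: tab-separated, UTF-8, mandatory header, '.' decimals.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated with header `subject_id  aa_pos  ref_aa  alt_aa`
#' (`ref_aa`/`alt_aa` optional). Rows with non-integer or out-of-range
#' positions are rejected with their line numbers; duplicated
#' subject+position rows are preserved (recurrence is meaningful).
#'
#' @param path TSV file path.
#' @param transcript A [transcript_model()] for validation.
#' @return A [variant_panel()].
#' @export
read_variant_table <- function(path, transcript) {
  df <- read_tsv_checked(path, c("subject_id", "aa_pos"))
  pos_num <- suppressWarnings(as.numeric(df$aa_pos))
  bad <- which(is.na(pos_num) | pos_num != round(pos_num))
  if (length(bad))
    stop(path, ": non-integer aa_pos at data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  oob <- which(pos_num < 1 | pos_num > transcript$aa_length)
  if (length(oob))
    stop(path, ": aa_pos out of [1, ", transcript$aa_length,
         "] at data line(s) ", paste(oob, collapse = ", "), call. = FALSE)
  df$aa_pos <- as.integer(pos_num)
  variant_panel(df, transcript)
}

#' Read a transcript model table
#'
#' Expects a TSV with a `transcript_id  aa_length` row and optional
#' `domain  name  start  end` rows (column 1 is the record type).
#'
#' @param path TSV file path with columns `record`, `name`, `start`, `end`
#'   where the `transcript` record stores `aa_length` in `start`.
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(path) {
  df <- read_tsv_checked(path, c("record", "name", "start", "end"))
  tr <- df[df$record == "transcript", , drop = FALSE]
  if (nrow(tr) != 1L)
    stop(path, ": need exactly one 'transcript' row", call. = FALSE)
  dom <- df[df$record == "domain", c("name", "start", "end"), drop = FALSE]
  transcript_model(tr$name, as.integer(tr$start),
                   domains = if (nrow(dom)) dom else NULL)
}

#' Read a pathogenicity score table
#'
#' TSV with header `variant_id  cadd  revel  mcap  eigen`; empty cells are
#' missing scores.
#'
#' @param path TSV file path.
#' @return `data.frame` with numeric score columns (NA = missing).
#' @export
read_score_table <- function(path) {
  df <- read_tsv_checked(path, c("variant_id"))
  for (t in intersect(score_tools, names(df)))
    df[[t]] <- suppressWarnings(as.numeric(df[[t]]))
  df
}

#' Read a long-chain-base table
#'
#' TSV with header `sample_id  condition  SO  SO3  SA  SA3`.
#' @param path TSV file path.
#' @return `data.frame`.
#' @export
read_lcb_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "condition", "SO", "SO3", "SA",
                           "SA3"))
}

#' Read a species-level sphingolipid table
#'
#' TSV with header
#' `sample_id  condition  lipid_class  chain  label_channel  amount`.
#' @param path TSV file path.
#' @return `data.frame`.
#' @export
read_species_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "condition", "lipid_class",
                           "chain", "label_channel", "amount"))
}

#' Read a mass peak table
#'
#' TSV with header `observed_kda  source`.
#' @param path TSV file path.
#' @return `data.frame`.
#' @export
read_peaks_table <- function(path) {
  df <- read_tsv_checked(path, "observed_kda")
  df$observed_kda <- as.numeric(df$observed_kda)
  df
}

#' Read a FASTA file of protein sequences
#'
#' Wrapped lines are joined, sequences are upper-cased, and duplicate
#' identifiers are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector, identifier to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop(path, ": empty FASTA", call. = FALSE)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(path, ": duplicate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  setNames(toupper(as.character(ss)), ids)
}

pipeline_known_keys <- c("seed", "out_prefix", "transcript", "variants",
                         "clusters", "n_perm", "patient_scores",
                         "background_scores", "lcb", "species", "reference",
                         "fasta", "fragment_range", "peaks", "monomer_kda",
                         "k_max", "tolerance", "stages")

#' Run selected analysis stages end to end
#'
#' Orchestrates the clustering, score-comparison, flux and mass stages over
#' file inputs, validates the configuration up front (unknown keys and
#' missing input files fail before any stage runs), and returns a run
#' report sufficient to reproduce the run: package version, configuration
#' echo, MD5 digests of input files, seed, and per-stage result tables.
#' With `out_prefix` set, per-stage TSVs and a JSON run record are written.
#'
#' @param config Named list. Common keys: `stages` (subset of `"cluster"`,
#'   `"scores"`, `"flux"`, `"mass"`), `seed` (mandatory when a stochastic
#'   stage is selected), `out_prefix`. Stage inputs: `transcript`,
#'   `variants`, `clusters` (TSV with `name`, `start`, `end`), `n_perm`;
#'   `patient_scores`, `background_scores`; `lcb`, `reference`, `species`;
#'   `peaks` plus either `monomer_kda` or `fasta` (+ optional
#'   `fragment_range` `c(start, end)`), `k_max`, `tolerance`.
#' @return List of class `certra_run` with `results` (per stage), `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stages <- config$stages
  if (is.null(stages)) stop("config$stages is required", call. = FALSE)
  bad <- setdiff(stages, c("cluster", "scores", "flux", "mass"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stochastic <- any(c("cluster") %in% stages)
  if (stochastic && is.null(config$seed))
    stop("config$seed is mandatory for stochastic stages", call. = FALSE)
  # pre-flight: every referenced input file must exist
  file_keys <- c("transcript", "variants", "clusters", "patient_scores",
                 "background_scores", "lcb", "species", "fasta", "peaks")
  paths <- unlist(config[intersect(file_keys, names(config))])
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("input file(s) not found: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  results <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
  }
  if ("cluster" %in% stages) {
    results$cluster <- run_stage("cluster", {
      tm <- read_transcript_model(config$transcript)
      panel <- read_variant_table(config$variants, tm)
      n_perm <- if (is.null(config$n_perm)) 1e5 else config$n_perm
      global <- permutation_test(panel, n_perm = n_perm,
                                 seed = config$seed)
      tabs <- list(global = cluster_results_table(global))
      if (!is.null(config$clusters)) {
        cl <- read_tsv_checked(config$clusters, c("name", "start", "end"))
        cl <- cluster_definitions(cl$name, cl$start, cl$end, tm)
        tabs$clusters <- cluster_results_table(
          cluster_delta_g(panel, cl, n_perm = n_perm, seed = config$seed))
      }
      tabs
    })
  }
  if ("scores" %in% stages) {
    results$scores <- run_stage("scores", {
      pat <- read_score_table(config$patient_scores)
      bg <- read_score_table(config$background_scores)
      list(classification = classify_score_table(pat),
           comparison = compare_cohorts(pat, bg))
    })
  }
  if ("flux" %in% stages) {
    results$flux <- run_stage("flux", {
      lcb <- read_lcb_table(config$lcb)
      if (is.null(config$reference))
        stop("'reference' condition required", call. = FALSE)
      rep_ <- flux_report(lcb, config$reference)
      out <- list(conditions = rep_$conditions, anova = rep_$anova)
      if (!is.null(config$species))
        out$class_totals <-
          aggregate_class_totals(read_species_table(config$species))
      out
    })
  }
  if ("mass" %in% stages) {
    results$mass <- run_stage("mass", {
      monomer <- config$monomer_kda
      if (is.null(monomer)) {
        if (is.null(config$fasta))
          stop("need 'monomer_kda' or 'fasta'", call. = FALSE)
        seqs <- read_fasta(config$fasta)
        s <- seqs[[1L]]
        if (!is.null(config$fragment_range))
          s <- substr(s, config$fragment_range[1L],
                      config$fragment_range[2L])
        monomer <- theoretical_mw(s) / 1000
      }
      peaks <- read_peaks_table(config$peaks)
      k_max <- if (is.null(config$k_max)) 8L else config$k_max
      tol <- if (is.null(config$tolerance)) 0.05 else config$tolerance
      list(monomer_kda = monomer,
           calls = annotate_peaks(peaks, monomer, k_max = k_max,
                                  tolerance = tol))
    })
  }
  report <- list(
    package = "certra",
    version = as.character(utils::packageVersion("certra")),
    config = config,
    input_digests = if (length(paths))
      as.list(tools::md5sum(paths)) else list(),
    seed = config$seed)
  run <- structure(list(results = results, report = report),
                   class = "certra_run")
  if (!is.null(config$out_prefix)) write_run(run, config$out_prefix)
  run
}

# write per-stage TSVs and the JSON run record next to `prefix`
write_run <- function(run, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  flat <- function(x, name) {
    if (is.data.frame(x)) write_tsv(x, paste0(prefix, "_", name, ".tsv"))
    else if (is.list(x))
      for (nm in names(x)) flat(x[[nm]], paste0(name, "_", nm))
  }
  for (stage in names(run$results)) flat(run$results[[stage]], stage)
  jsonlite::write_json(run$report, paste0(prefix, "_run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(prefix)
}

#' @export
print.certra_run <- function(x, ...) {
  cat("certra run (stages: ", paste(names(x$results), collapse = ", "),
      "; seed ", if (is.null(x$report$seed)) "none" else x$report$seed,
      ")\n", sep = "")
  invisible(x)
}
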