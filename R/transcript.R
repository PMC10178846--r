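#' Transcript model in protein coordinates
#'
#' A minimal gene model on which linear variant clustering is computed: the
#' protein length `L` (residues) and, optionally, named domain intervals.
#' All coordinates are 1-based, inclusive amino-acid positions; the clustering
#' statistic normalizes pairwise distances by `aa_length`.
#'
#' @param transcript_id Character scalar naming the transcript (e.g. a RefSeq
#'   accession).
#' @param aa_length Protein length in residues; must be at least 2.
#' @param domains Optional `data.frame` with columns `name`, `start`, `end`
#'   giving inclusive residue intervals (e.g. the PH and START globular
#'   domains of CERT, aa 23-117 and 389-618).
#' @return An object of class `transcript_model`.
#' @examples
#' cert <- transcript_model("NM_005713.3", 624,
#'   domains = data.frame(name = c("PH", "START"),
#'                        start = c(23, 389), end = c(117, 618)))
#' cert
#' @export
transcript_model <- function(transcript_id, aa_length, domains = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  aa_length <- as.integer(aa_length)
  if (length(aa_length) != 1L || is.na(aa_length) || aa_length < 2L)
    stop("'aa_length' must be a single integer >= 2", call. = FALSE)
  if (!is.null(domains)) {
    domains <- as.data.frame(domains)
    need <- c("name", "start", "end")
    if (!all(need %in% names(domains)))
      stop("'domains' needs columns name, start, end", call. = FALSE)
    domains$start <- as.integer(domains$start)
    domains$end <- as.integer(domains$end)
    bad <- domains$start < 1L | domains$end > aa_length |
      domains$start > domains$end
    if (any(bad))
      stop("domain interval out of [1, ", aa_length, "] or reversed: ",
           paste(domains$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, aa_length = aa_length,
         domains = domains),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model ", x$transcript_id, " (", x$aa_length,
      " aa)\n", sep = "")
  if (!is.null(x$domains) && nrow(x$domains))
    for (i in seq_len(nrow(x$domains)))
      cat(sprintf("  domain %-8s %d-%d\n", x$domains$name[i],
                  x$domains$start[i], x$domains$end[i]))
  invisible(x)
}

#' Panel of missense variants at protein positions
#'
#' Holds per-subject missense records. Recurrence (the same position in
#' several subjects) is preserved in `records`; `distinct_positions` is the
#' deduplicated, sorted position set on which the clustering statistic is
#' computed by default.
#'
#' @param records `data.frame` with columns `subject_id`, `aa_pos` and
#'   optionally `ref_aa`, `alt_aa`.
#' @param transcript A [transcript_model()] used for bounds checking.
#' @return An object of class `variant_panel` with elements `records`,
#'   `distinct_positions` and `transcript`.
#' @export
variant_panel <- function(records, transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  records <- as.data.frame(records)
  if (!all(c("subject_id", "aa_pos") %in% names(records)))
    stop("'records' needs columns subject_id, aa_pos", call. = FALSE)
  if (nrow(records) < 1L) stop("empty variant panel", call. = FALSE)
  pos <- records$aa_pos
  if (any(pos != as.integer(pos)) || anyNA(pos))
    stop("non-integer amino-acid position", call. = FALSE)
  records$aa_pos <- as.integer(pos)
  out <- records$aa_pos < 1L | records$aa_pos > transcript$aa_length
  if (any(out))
    stop("position out of [1, ", transcript$aa_length, "]: ",
         paste(unique(records$aa_pos[out]), collapse = ", "), call. = FALSE)
  structure(
    list(records = records,
         distinct_positions = sort(unique(records$aa_pos)),
         transcript = transcript),
    class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("Variant panel: ", nrow(x$records), " records, ",
      length(x$distinct_positions), " distinct positions on ",
      x$transcript$transcript_id, " (L = ", x$transcript$aa_length, ")\n",
      sep = "")
  invisible(x)
}

#' Spatial cluster definitions
#'
#' Inclusive residue intervals within which variant clustering is tested
#' separately (the "spatial groups" of the cohort).
#'
#' @param name Character vector of cluster names.
#' @param start,end Integer vectors of inclusive interval bounds.
#' @param transcript A [transcript_model()] for bounds checking.
#' @return `data.frame` of class `cluster_definition`.
#' @export
cluster_definitions <- function(name, start, end, transcript) {
  stopifnot(inherits(transcript, "transcript_model"),
            length(name) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  bad <- start < 1L | end > transcript$aa_length | start > end
  if (any(bad))
    stop("cluster interval invalid: ", paste(name[bad], collapse = ", "),
         call. = FALSE)
  structure(data.frame(name = as.character(name), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("cluster_definition", "data.frame"))
}
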