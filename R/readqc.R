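#' Quality-control configuration for paired-end read filtering
#'
#' Thresholds for the five raw-read filtering rules, applied in order:
#' (a) ambiguous bases, (b) poly-A structure, (c) low-quality bases,
#' (d) adapter contamination, (e) mate overlap. A pair is dropped when any
#' rule fails on either mate (rules a-d) or at the pair level (rule e), and
#' the first failing rule is recorded.
#'
#' The published rules leave two thresholds implicit, fixed here with common
#' conventions: "poly-A structure" means whole-read A-fraction at or above
#' `polya_min_fraction`, and "low quality" means Phred score at or below
#' `lowq_phred_threshold`.
#'
#' @param max_n_fraction Drop when N-fraction strictly exceeds this (rule a).
#' @param polya_min_fraction Drop when A-fraction reaches this (rule b).
#' @param lowq_phred_threshold Phred score at or below which a base counts
#'   as low quality (rule c).
#' @param lowq_max_count Drop when at least this many low-quality bases
#'   occur (rule c).
#' @param adapter_sequence Adapter to scan for (rule d).
#' @param adapter_min_match Minimum aligned length of an adapter hit;
#'   "more than 10 bp" is read as at least 11 (rule d).
#' @param adapter_max_mismatch Maximum mismatches in an adapter hit (rule d).
#' @param overlap_min Minimum mate overlap length (rule e).
#' @param overlap_max_mismatch_fraction Maximum mismatch fraction within the
#'   overlap (rule e).
#' @param apply_overlap_filter_only_to_short_insert If `TRUE`, rule e is
#'   applied only to pairs whose `insert` annotation is below
#'   `2 * read length` (the small-insert library); by default it applies to
#'   all pairs.
#' @return A `qc_config` list.
#' @export
qc_config <- function(max_n_fraction = 0.05,
                      polya_min_fraction = 0.80,
                      lowq_phred_threshold = 7L,
                      lowq_max_count = 20L,
                      adapter_sequence = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                      adapter_min_match = 11L,
                      adapter_max_mismatch = 3L,
                      overlap_min = 10L,
                      overlap_max_mismatch_fraction = 0.10,
                      apply_overlap_filter_only_to_short_insert = FALSE) {
  stopifnot(
    max_n_fraction >= 0, max_n_fraction <= 1,
    polya_min_fraction >= 0, polya_min_fraction <= 1,
    lowq_phred_threshold >= 0, lowq_max_count >= 0,
    adapter_min_match >= 1, adapter_max_mismatch >= 0,
    overlap_min >= 1,
    overlap_max_mismatch_fraction >= 0, overlap_max_mismatch_fraction <= 1
  )
  structure(
    list(
      max_n_fraction = max_n_fraction,
      polya_min_fraction = polya_min_fraction,
      lowq_phred_threshold = as.integer(lowq_phred_threshold),
      lowq_max_count = as.integer(lowq_max_count),
      adapter_sequence = adapter_sequence,
      adapter_min_match = as.integer(adapter_min_match),
      adapter_max_mismatch = as.integer(adapter_max_mismatch),
      overlap_min = as.integer(overlap_min),
      overlap_max_mismatch_fraction = overlap_max_mismatch_fraction,
      apply_overlap_filter_only_to_short_insert =
        apply_overlap_filter_only_to_short_insert
    ),
    class = "qc_config"
  )
}

#' Rule (a): excess ambiguous bases
#'
#' @param seq Character vector of read sequences.
#' @param config A [qc_config()].
#' @return Logical vector, `TRUE` where the read violates the rule (its
#'   N-fraction strictly exceeds `max_n_fraction`).
#' @export
check_n_fraction <- function(seq, config = qc_config()) {
  if (any(nchar(seq) == 0L)) stop("empty read")
  count_char(seq, "N") / nchar(seq) > config$max_n_fraction
}

#' Rule (b): poly-A structure
#'
#' @inheritParams check_n_fraction
#' @return Logical vector, `TRUE` where the A-fraction is at or above
#'   `polya_min_fraction`.
#' @export
check_polya <- function(seq, config = qc_config()) {
  if (any(nchar(seq) == 0L)) stop("empty read")
  count_char(seq, "A") / nchar(seq) >= config$polya_min_fraction
}

#' Rule (c): too many low-quality bases
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @param config A [qc_config()].
#' @return Logical vector, `TRUE` where at least `lowq_max_count` bases have
#'   Phred score at or below `lowq_phred_threshold`.
#' @export
check_low_quality <- function(qual, config = qc_config()) {
  thr <- config$lowq_phred_threshold
  n_low <- vapply(qual, function(q) sum(utf8ToInt(q) - 33L <= thr), integer(1),
                  USE.NAMES = FALSE)
  n_low >= config$lowq_max_count
}

#' Rule (d): adapter contamination
#'
#' Scans every ungapped offset of the adapter against the read, including
#' partial overhangs at both read ends.
#'
#' @inheritParams check_n_fraction
#' @return Logical vector, `TRUE` where some offset aligns at least
#'   `adapter_min_match` bases with at most `adapter_max_mismatch`
#'   mismatches.
#' @export
check_adapter <- function(seq, config = qc_config()) {
  if (nchar(config$adapter_sequence) == 0L) stop("adapter_sequence is empty")
  adapter_scan_cpp(seq, config$adapter_sequence,
                   config$adapter_min_match, config$adapter_max_mismatch)
}

#' Rule (e): mate overlap
#'
#' Slides the reverse complement of mate 2 against mate 1 over every
#' overlap length consistent with a short-insert fragment.
#'
#' @param seq1,seq2 Character vectors of mate sequences.
#' @param config A [qc_config()].
#' @return Logical vector, `TRUE` where some overlap of at least
#'   `overlap_min` bp has mismatch fraction at or below
#'   `overlap_max_mismatch_fraction`.
#' @export
check_overlap <- function(seq1, seq2, config = qc_config()) {
  overlap_scan_cpp(seq1, revcomp(seq2), config$overlap_min,
                   config$overlap_max_mismatch_fraction)
}

#' Filter read pairs by the five QC rules
#'
#' Applies rules (a)-(e) in order to each pair; a pair is dropped at the
#' first rule that fails on either mate (or at pair level for the overlap
#' rule), and that rule is recorded as the drop reason.
#'
#' @param pairs Tibble/data.frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2` and optionally `insert` (used when the overlap rule is
#'   restricted to the short-insert library).
#' @param config A [qc_config()].
#' @return List with `kept` (the surviving rows) and `report`, a
#'   `qc_report` containing `pairs_in`, `pairs_kept`, per-rule drop counts
#'   and the per-pair `first_rule` attribution.
#' @export
filter_pairs <- function(pairs, config = qc_config()) {
  required <- c("id", "seq1", "qual1", "seq2", "qual2")
  if (!all(required %in% names(pairs))) {
    stop("pairs must have columns ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(pairs$id)) stop("desynchronized mates: duplicated ids")
  n <- nrow(pairs)
  rules <- c("N", "polyA", "lowQ", "adapter", "overlap")
  if (n == 0L) {
    report <- structure(
      list(pairs_in = 0L, pairs_kept = 0L,
           drops = stats::setNames(integer(5), rules),
           first_rule = character(0)),
      class = "qc_report"
    )
    return(list(kept = pairs, report = report))
  }
  fail_n <- check_n_fraction(pairs$seq1, config) | check_n_fraction(pairs$seq2, config)
  fail_pa <- check_polya(pairs$seq1, config) | check_polya(pairs$seq2, config)
  fail_lq <- check_low_quality(pairs$qual1, config) | check_low_quality(pairs$qual2, config)
  fail_ad <- check_adapter(pairs$seq1, config) | check_adapter(pairs$seq2, config)
  fail_ov <- check_overlap(pairs$seq1, pairs$seq2, config)
  if (config$apply_overlap_filter_only_to_short_insert) {
    if (is.null(pairs$insert)) {
      stop("insert column required to restrict the overlap filter")
    }
    short <- pairs$insert < 2L * nchar(pairs$seq1)
    fail_ov <- fail_ov & short
  }
  fails <- cbind(N = fail_n, polyA = fail_pa, lowQ = fail_lq,
                 adapter = fail_ad, overlap = fail_ov)
  first_idx <- apply(fails, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  first_rule <- ifelse(is.na(first_idx), NA_character_, rules[first_idx])
  dropped <- !is.na(first_idx)
  drops <- vapply(rules, function(r) sum(first_rule == r, na.rm = TRUE), integer(1))
  report <- structure(
    list(
      pairs_in = n,
      pairs_kept = sum(!dropped),
      drops = drops,
      first_rule = stats::setNames(first_rule, pairs$id)
    ),
    class = "qc_report"
  )
  list(kept = pairs[!dropped, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("read-pair QC: %d in, %d kept (%.2f%%)\n",
              x$pairs_in, x$pairs_kept,
              if (x$pairs_in > 0) 100 * x$pairs_kept / x$pairs_in else 100))
  for (r in names(x$drops)) {
    cat(sprintf("  dropped by %-7s %d\n", paste0(r, ":"), x$drops[[r]]))
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [filter_pairs()].
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(pairs_in = report$pairs_in,
         pairs_kept = report$pairs_kept,
         drops = as.list(report$drops)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a pair of FASTQ files into the paired-read table
#'
#' @param file1,file2 Paths to the mate FASTQ files (Phred+33; plain or
#'   gzip-compressed).
#' @return Tibble with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("desynchronized mates: file lengths differ")
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  if (!identical(id1, id2)) stop("desynchronized mates: ids differ")
  tibble::tibble(
    id = id1,
    seq1 = unname(as.character(r1)),
    qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
    seq2 = unname(as.character(r2)),
    qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities))
  )
}
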