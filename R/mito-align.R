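#' Filter contig-to-mitochondrion alignments
#'
#' Keeps alignment records passing the specificity filters used when fishing
#' mitochondrial contigs out of a nuclear assembly: e-value at most
#' `max_evalue`, percent identity at least `min_identity`, and per-contig
#' accumulated alignment coverage (union of the contig's aligned query
#' intervals over its length) at least `min_coverage`. Coverage is
#' accumulated per contig across its records after the e-value and identity
#' filters.
#'
#' @param records Data frame of alignment records with columns `query`,
#'   `query_length`, `qstart`, `qend`, `rstart`, `rend` (0-based half-open,
#'   reference coordinates strand-normalized to forward), `strand`
#'   (`"+"`/`"-"`), `identity` (percent), `evalue`.
#' @param max_evalue,min_identity,min_coverage Filter thresholds.
#' @return The kept records.
#' @export
filter_mito_alignments <- function(records, max_evalue = 1e-6,
                                   min_identity = 90, min_coverage = 0.90) {
  cols <- c("query", "query_length", "qstart", "qend", "rstart", "rend",
            "identity", "evalue")
  if (!all(cols %in% names(records))) {
    stop("records must have columns ", paste(cols, collapse = ", "))
  }
  if (anyNA(records$query_length)) stop("missing query length")
  keep <- records$evalue <= max_evalue & records$identity >= min_identity
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) return(records)
  cov <- vapply(split(seq_len(nrow(records)), records$query), function(i) {
    interval_union_bp(records$qstart[i], records$qend[i]) /
      records$query_length[i][1L]
  }, numeric(1))
  covered <- names(cov)[cov >= min_coverage]
  records[records$query %in% covered, , drop = FALSE]
}

#' Fraction of a mitochondrial reference covered by kept alignments
#'
#' @param records Kept alignment records (see [filter_mito_alignments()]).
#' @param ref_length Reference length in bp.
#' @return List with `fraction` (union of reference intervals / length) and
#'   `n_contigs` (distinct aligned contigs).
#' @export
reference_coverage <- function(records, ref_length) {
  if (nrow(records) == 0L) {
    return(list(fraction = 0, n_contigs = 0L))
  }
  list(
    fraction = interval_union_bp(records$rstart, records$rend) / ref_length,
    n_contigs = length(unique(records$query))
  )
}

#' Build a greedy tiling path of contigs over a reference
#'
#' Chains alignment records left to right: starting from reference position
#' 0, repeatedly selects, among unused records starting at or before the
#' current covered end plus `max_gap`, the one extending furthest right;
#' records fully contained in the already-tiled span are skipped. When no
#' record starts within reach, the uncovered interval is recorded as a gap
#' and tiling resumes at the next record. Records shorter than `min_len` on
#' the reference are ignored (short spurious matches).
#'
#' @param records Alignment records on one reference (columns `query`,
#'   `rstart`, `rend`, `strand`).
#' @param ref_length Reference length in bp.
#' @param max_gap Maximum gap jumped silently while chaining; `Inf` chains
#'   through any gap (gaps are still reported).
#' @param min_len Minimum reference-span length of a usable record.
#' @return A `tiling_path`: list with `segments` (selected records in
#'   reference order, with `offset` = rstart and per-segment `strand`),
#'   `covered_fraction`, and `gaps` (tibble `start`, `end` of uncovered
#'   intervals between consecutive segments).
#' @export
build_tiling <- function(records, ref_length, max_gap = Inf, min_len = 100L) {
  records <- records[records$rend - records$rstart >= min_len, , drop = FALSE]
  sel <- integer(0)
  covered <- IRanges::IRanges()
  if (nrow(records) > 0L) {
    records <- records[order(records$rstart, -records$rend), , drop = FALSE]
    used <- rep(FALSE, nrow(records))
    current_end <- 0
    repeat {
      idx <- which(!used)
      if (!length(idx)) break
      # skip records fully contained in the already-tiled span
      if (length(covered)) {
        ir <- IRanges::IRanges(records$rstart[idx] + 1L, records$rend[idx])
        within <- IRanges::overlapsAny(ir, covered, type = "within")
        used[idx[within]] <- TRUE
        idx <- idx[!within]
        if (!length(idx)) break
      }
      reach <- idx[records$rstart[idx] <= current_end + max_gap]
      pick <- if (length(reach)) {
        reach[which.max(records$rend[reach])]
      } else {
        idx[1L]  # jump the gap to the next record
      }
      sel <- c(sel, pick)
      used[pick] <- TRUE
      covered <- IRanges::reduce(c(
        covered, IRanges::IRanges(records$rstart[pick] + 1L, records$rend[pick])))
      current_end <- max(current_end, records$rend[pick])
    }
  }
  segments <- records[sort(sel), , drop = FALSE]  # records are rstart-ordered
  uncovered <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(ref_length)),
                                covered)
  gaps <- tibble::tibble(start = IRanges::start(uncovered) - 1L,
                         end = IRanges::end(uncovered))
  structure(
    list(segments = segments,
         covered_fraction = sum(IRanges::width(covered)) / ref_length,
         gaps = gaps,
         ref_length = ref_length),
    class = "tiling_path"
  )
}

#' @export
print.tiling_path <- function(x, ...) {
  cat(sprintf("tiling path: %d segments covering %.1f%% of %d bp; %d gap(s)\n",
              nrow(x$segments), 100 * x$covered_fraction, x$ref_length,
              nrow(x$gaps)))
  invisible(x)
}

#' Read BLAST outfmt-6-style tabular alignments
#'
#' Parses the conventional 12-column tabular output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#' into the package's alignment-record layout, normalizing reverse-strand
#' reference intervals to forward coordinates with a strand flag and
#' converting to 0-based half-open intervals. Query lengths must be supplied
#' (the tabular format does not carry them).
#'
#' @param path Tabular alignment file.
#' @param query_lengths Named integer vector of query sequence lengths.
#' @return Alignment-record data frame (see [filter_mito_alignments()]).
#' @export
read_blast_tab <- function(path, query_lengths) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("qseqid", "sseqid", "pident", "length",
                                       "mismatch", "gapopen", "qstart", "qend",
                                       "sstart", "send", "evalue", "bitscore"))
  rev <- d$sstart > d$send
  rstart <- ifelse(rev, d$send, d$sstart) - 1L
  rend <- ifelse(rev, d$sstart, d$send)
  if (!all(d$qseqid %in% names(query_lengths))) {
    stop("query_lengths missing entries for some queries")
  }
  tibble::tibble(
    query = d$qseqid,
    query_length = as.integer(query_lengths[d$qseqid]),
    ref = d$sseqid,
    qstart = pmin(d$qstart, d$qend) - 1L,
    qend = pmax(d$qstart, d$qend),
    rstart = as.integer(rstart),
    rend = as.integer(rend),
    strand = ifelse(rev, "-", "+"),
    identity = d$pident,
    evalue = d$evalue
  )
}
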