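#' Union length of match intervals on one contig
#'
#' The "accumulated length of the matched regions": the length of the union
#' of 0-based half-open intervals, with overlaps merged so no base is
#' counted twice.
#'
#' @param start,end Integer vectors of interval bounds (0-based half-open).
#' @param contig_length Optional contig length for bounds checking.
#' @return Union length in bp.
#' @export
union_length <- function(start, end, contig_length = NULL) {
  if (length(start) == 0L) return(0L)
  if (!is.null(contig_length) && (any(start < 0) || any(end > contig_length))) {
    stop("interval out of contig bounds")
  }
  interval_union_bp(start, end)
}

#' Stage 1: flag a contig as a contamination candidate
#'
#' A contig is a candidate when the accumulated (union) length of its
#' matched regions strictly exceeds `threshold` (10%) of the contig length.
#'
#' @param contig_length Contig length in bp (> 0).
#' @param start,end Match intervals on the contig (0-based half-open).
#' @param threshold Candidate fraction; strictly-greater comparison.
#' @return `TRUE` when flagged.
#' @export
flag_candidate <- function(contig_length, start, end, threshold = 0.10) {
  if (contig_length <= 0) stop("zero-length contig")
  union_length(start, end, contig_length) / contig_length > threshold
}

#' Stage 2: confirm bacterial origin from protein hits
#'
#' A candidate is confirmed when its best protein hit (lowest e-value, ties
#' broken by highest bit-score) passes the e-value cutoff and is of
#' bacterial origin. A tie on both e-value and bit-score between bacterial
#' and non-bacterial hits is resolved conservatively as not confirmed.
#'
#' @param hits Data frame with columns `evalue`, `bitscore`, `bacterial`
#'   (logical); may have zero rows.
#' @param evalue_cutoff Maximum e-value of the best hit.
#' @return `TRUE` when confirmed bacterial.
#' @export
confirm_bacterial <- function(hits, evalue_cutoff = 1e-6) {
  if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0)) {
    stop("malformed e-values")
  }
  best <- hits[hits$evalue == min(hits$evalue), , drop = FALSE]
  best <- best[best$bitscore == max(best$bitscore), , drop = FALSE]
  if (nrow(best) > 1L && length(unique(best$bacterial)) > 1L) return(FALSE)
  best$evalue[1L] <= evalue_cutoff && isTRUE(best$bacterial[1L])
}

#' Two-stage bacterial contamination screen of an assembly
#'
#' Stage 1 flags contigs whose matched regions (e.g., bacterial k-mer
#' classifier spans) add up, as a union, to more than `threshold` of the
#' contig length. Stage 2 confirms candidates whose best protein hit is
#' bacterial at the e-value cutoff. Confirmed contigs are removed from the
#' returned assembly.
#'
#' @param contigs Named character vector of contig sequences (or a named
#'   integer vector of contig lengths).
#' @param intervals Data frame of match spans: `contig`, `start`, `end`
#'   (0-based half-open).
#' @param hits Data frame of protein hits: `contig`, `evalue`, `bitscore`,
#'   `bacterial` (logical).
#' @param threshold Stage-1 candidate fraction.
#' @param evalue_cutoff Stage-2 best-hit e-value cutoff.
#' @return A `screen_result`: list with `per_contig` tibble (`contig`,
#'   `length`, `matched_bp`, `fraction`, `candidate`, `confirmed`),
#'   `removed` (ids), and `cleaned` (the retained contigs).
#' @export
screen_assembly <- function(contigs, intervals, hits,
                            threshold = 0.10, evalue_cutoff = 1e-6) {
  if (is.null(names(contigs))) stop("contigs must be named")
  lens <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
  names(lens) <- names(contigs)
  if (nrow(intervals) && !all(intervals$contig %in% names(lens))) {
    stop("intervals reference unknown contigs")
  }
  if (nrow(hits) && !all(hits$contig %in% names(lens))) {
    stop("hits reference unknown contigs")
  }
  matched <- vapply(names(lens), function(id) {
    i <- which(intervals$contig == id)
    union_length(intervals$start[i], intervals$end[i], lens[[id]])
  }, numeric(1))
  fraction <- matched / lens
  candidate <- fraction > threshold
  confirmed <- vapply(names(lens), function(id) {
    if (!candidate[[id]]) return(FALSE)
    confirm_bacterial(hits[hits$contig == id, , drop = FALSE], evalue_cutoff)
  }, logical(1))
  per_contig <- tibble::tibble(
    contig = names(lens), length = as.integer(lens),
    matched_bp = as.integer(matched), fraction = fraction,
    candidate = candidate, confirmed = confirmed
  )
  structure(
    list(
      per_contig = per_contig,
      removed = names(lens)[confirmed],
      cleaned = contigs[!confirmed],
      n_in = length(contigs),
      n_candidates = sum(candidate),
      n_removed = sum(confirmed)
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "contamination screen: %d contigs in, %d candidates (>10%% matched), %d confirmed bacterial and removed\n",
    x$n_in, x$n_candidates, x$n_removed))
  invisible(x)
}
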