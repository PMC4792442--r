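#' Count canonical k-mers and build the multiplicity histogram
#'
#' Every window of length `k` not containing an ambiguous base contributes
#' its canonical form (the lexicographic minimum of the k-mer and its
#' reverse complement, so both strands are merged); the histogram records,
#' for each multiplicity, how many distinct canonical k-mers occur that many
#' times. This is the object a k-mer spectrum plot displays and the
#' genome-size formula consumes.
#'
#' Counting is exact (2-bit-encoded k-mers in a hash table); `k` must be odd
#' so no k-mer equals its own reverse complement.
#'
#' @param seqs Character vector of sequences (reads or contigs), or an
#'   `XStringSet`.
#' @param k Odd k-mer length between 1 and 31.
#' @return A `kmer_histogram`: list with `k`, `counts` (data.frame
#'   `multiplicity`, `count`, ascending) and `total_kmers`
#'   (= sum of multiplicity * count = number of counted windows).
#' @examples
#' h <- count_canonical_kmers(c("ACGTACGT"), k = 3)
#' h$total_kmers  # 6 windows
#' @export
count_canonical_kmers <- function(seqs, k) {
  if (k %% 2 == 0) stop("k must be odd (canonical form is ill-defined for palindromes)")
  if (k < 1 || k > 31) stop("k must be between 1 and 31")
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  counts <- kmer_hist_cpp(seqs, as.integer(k))
  structure(
    list(
      k = as.integer(k),
      counts = counts,
      total_kmers = sum(counts$multiplicity * counts$count)
    ),
    class = "kmer_histogram"
  )
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("%d-mer histogram: %d multiplicity classes, %.4g total k-mers\n",
              x$k, nrow(x$counts), x$total_kmers))
  invisible(x)
}

# Dense count vector over multiplicities 1..max.
dense_counts <- function(hist) {
  m_max <- max(hist$counts$multiplicity)
  y <- numeric(m_max)
  y[hist$counts$multiplicity] <- hist$counts$count
  y
}

# Centered moving average with truncated windows at the edges.
smooth_counts <- function(y, window = 3L) {
  if (window < 1L || window %% 2L == 0L) stop("smoothing window must be odd")
  if (window == 1L) return(y)
  half <- (window - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the error trough of a k-mer histogram
#'
#' Sequencing errors generate a mass of near-unique k-mers at low
#' multiplicity; the trough is the smallest multiplicity at which the
#' smoothed histogram stops falling, separating that error component from
#' the genomic peaks. A histogram that rises from multiplicity 1 has no
#' error component and the trough is 1.
#'
#' @param hist A [count_canonical_kmers()] histogram.
#' @param smoothing_window Odd window for the centered moving average.
#' @return The trough multiplicity. If the histogram decreases monotonically
#'   (no genomic peak), the maximum multiplicity is returned with a warning.
#' @export
find_error_trough <- function(hist, smoothing_window = 3L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  y <- dense_counts(hist)
  if (length(y) < 2L) stop("histogram has a single multiplicity class")
  s <- smooth_counts(y, smoothing_window)
  if (s[2L] >= s[1L]) return(1L)  # no low-multiplicity error component
  n <- length(s)
  for (m in 2:(n - 1L)) {
    if (s[m] < s[m - 1L] && s[m + 1L] >= s[m]) return(m)
  }
  warning("histogram decreases monotonically: no genomic peak above the error component")
  n
}

#' Detect peaks of a smoothed k-mer histogram
#'
#' Finds local maxima of the window-averaged histogram restricted to
#' multiplicities above the error trough, ranked by smoothed height; by
#' default at most the top two (the heterozygous and coverage peaks of a
#' diploid spectrum) are retained.
#'
#' @param hist A [count_canonical_kmers()] histogram.
#' @param trough Error trough multiplicity; computed with
#'   [find_error_trough()] when `NULL`.
#' @param smoothing_window Odd window for the centered moving average.
#' @param max_peaks Maximum number of peaks retained.
#' @param min_height_frac Local maxima below this fraction of the tallest
#'   candidate are discarded as sampling noise in the histogram tail.
#' @return A `peak_set`: list with `error_trough`, `peaks` (data.frame
#'   `multiplicity`, `height`, ordered by descending height),
#'   `coverage_peak` and `het_peak` (`NA` until classified).
#' @export
detect_peaks <- function(hist, trough = NULL, smoothing_window = 3L,
                         max_peaks = 2L, min_height_frac = 0.05) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (is.null(trough)) trough <- find_error_trough(hist, smoothing_window)
  y <- dense_counts(hist)
  s <- smooth_counts(y, smoothing_window)
  n <- length(s)
  lo <- trough + 1L
  if (lo > n - 1L) stop("no maxima above the error trough")
  cand <- integer(0)
  for (m in seq(max(lo, 2L), n - 1L)) {
    if (s[m] >= s[m - 1L] && s[m] > s[m + 1L]) cand <- c(cand, m)
  }
  if (!length(cand)) stop("no maxima above the error trough")
  cand <- cand[s[cand] >= min_height_frac * max(s[cand])]
  ord <- order(s[cand], decreasing = TRUE)
  keep <- cand[ord][seq_len(min(max_peaks, length(cand)))]
  structure(
    list(
      error_trough = trough,
      peaks = data.frame(multiplicity = keep, height = s[keep]),
      coverage_peak = NA_integer_,
      het_peak = NA_integer_
    ),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak set: trough %d; peaks at %s\n", x$error_trough,
              paste(sort(x$peaks$multiplicity), collapse = ", ")))
  if (!is.na(x$coverage_peak)) {
    cat(sprintf("  coverage peak %d, heterozygous peak %s\n",
                x$coverage_peak,
                ifelse(is.na(x$het_peak), "absent", x$het_peak)))
  }
  invisible(x)
}

#' Classify heterozygous vs coverage peak across k-mer sizes
#'
#' A diploid k-mer spectrum carries two peaks: homozygous k-mers at the full
#' k-mer depth and heterozygous k-mers at half depth. Which is which is
#' decided by comparing spectra at several k: the number of heterozygous
#' k-mers grows with k (each variant site disrupts k windows per haplotype),
#' so the heterozygous peak's height changes considerably across k while the
#' coverage peak's height stays nearly constant. The peak whose height
#' coefficient of variation across k is smaller is assigned as the coverage
#' peak.
#'
#' @param hists List of [count_canonical_kmers()] histograms at different k
#'   (at least two, conventionally k = 15, 17, 19, 21).
#' @param smoothing_window Odd smoothing window.
#' @param match_tol Peaks are matched across k when their multiplicities
#'   agree within this relative tolerance.
#' @param ratio_range Expected heterozygous/coverage multiplicity ratio; a
#'   warning is emitted when the assignment falls outside it.
#' @return A `peak_set` (peak positions from the first histogram) with
#'   `coverage_peak` and `het_peak` assigned, plus a `heights` matrix
#'   (peak x k) and `height_cv` attribute used for the assignment.
#' @export
classify_peaks <- function(hists, smoothing_window = 3L, match_tol = 0.20,
                           ratio_range = c(0.4, 0.6)) {
  if (length(hists) < 2L) stop("need histograms for at least two k-mer sizes")
  sets <- lapply(hists, detect_peaks, smoothing_window = smoothing_window)
  n_peaks <- vapply(sets, function(p) nrow(p$peaks), integer(1))
  anchor <- sets[[1L]]
  anchor_m <- sort(anchor$peaks$multiplicity)
  if (any(n_peaks != length(anchor_m))) {
    stop("peaks not matchable across k: histograms disagree on peak count")
  }
  # match every histogram's peaks to the anchor positions within tolerance
  heights <- matrix(NA_real_, nrow = length(anchor_m), ncol = length(hists),
                    dimnames = list(multiplicity = anchor_m,
                                    k = vapply(hists, `[[`, integer(1), "k")))
  for (j in seq_along(sets)) {
    pj <- sets[[j]]$peaks
    for (i in seq_along(anchor_m)) {
      d <- abs(pj$multiplicity - anchor_m[i]) / anchor_m[i]
      hit <- which(d <= match_tol)
      if (length(hit) != 1L) stop("peaks not matchable across k within tolerance")
      heights[i, j] <- pj$height[hit]
    }
  }
  if (length(anchor_m) == 1L) {
    anchor$coverage_peak <- anchor_m
    anchor$het_peak <- NA_integer_
  } else {
    cv <- apply(heights, 1L, function(h) sd(h) / mean(h))
    cov_i <- which.min(cv)
    het_i <- which.max(cv)
    anchor$coverage_peak <- anchor_m[cov_i]
    anchor$het_peak <- anchor_m[het_i]
    ratio <- anchor$het_peak / anchor$coverage_peak
    if (ratio < ratio_range[1L] || ratio > ratio_range[2L]) {
      warning(sprintf(
        "heterozygous/coverage peak ratio %.2f outside [%.2f, %.2f]",
        ratio, ratio_range[1L], ratio_range[2L]))
    }
    attr(anchor, "height_cv") <- cv
  }
  attr(anchor, "heights") <- heights
  anchor
}

#' Estimate genome size from a k-mer histogram
#'
#' The haploid genome size is the total k-mer count divided by the
#' coverage-peak depth. K-mers below the error trough are excluded by
#' default, so sequencing-error k-mers do not inflate the total (a no-op on
#' error-free data, where the trough is 1).
#'
#' @param hist A [count_canonical_kmers()] histogram.
#' @param coverage_peak Coverage-peak multiplicity (from [classify_peaks()]
#'   or [detect_peaks()]).
#' @param exclude_below K-mers with multiplicity strictly below this are
#'   excluded; defaults to the error trough.
#' @return A `genome_size_estimate`: list with `size_bp`, `coverage_peak`,
#'   `kmers_used`, `k` and `exclude_below`.
#' @examples
#' h <- structure(list(k = 17L,
#'                     counts = data.frame(multiplicity = 30, count = 1e6),
#'                     total_kmers = 3e7), class = "kmer_histogram")
#' estimate_genome_size(h, coverage_peak = 30)$size_bp  # 1e6
#' @export
estimate_genome_size <- function(hist, coverage_peak, exclude_below = NULL) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (is.na(coverage_peak) || coverage_peak <= 0) {
    stop("coverage_peak must be positive")
  }
  if (is.null(exclude_below)) exclude_below <- find_error_trough(hist)
  keep <- hist$counts$multiplicity >= exclude_below
  kmers_used <- sum(hist$counts$multiplicity[keep] * hist$counts$count[keep])
  if (kmers_used <= 0) stop("no k-mers at or above the error trough")
  structure(
    list(
      size_bp = kmers_used / coverage_peak,
      coverage_peak = coverage_peak,
      kmers_used = kmers_used,
      k = hist$k,
      exclude_below = exclude_below
    ),
    class = "genome_size_estimate"
  )
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "genome size estimate: %.4g bp (%.4g %d-mers / coverage peak %d)\n",
    x$size_bp, x$kmers_used, x$k, x$coverage_peak))
  invisible(x)
}

#' Write a k-mer histogram as two-column TSV
#'
#' The format (multiplicity, count) matches common `histo` outputs of
#' k-mer counting tools.
#'
#' @param hist A [count_canonical_kmers()] histogram.
#' @param path Output file.
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column (multiplicity, count) histogram TSV
#'
#' @param path Input file.
#' @param k The k-mer length the histogram was computed with.
#' @return A `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k) {
  d <- utils::read.table(path, sep = "\t", col.names = c("multiplicity", "count"))
  d <- d[order(d$multiplicity), , drop = FALSE]
  structure(
    list(k = as.integer(k), counts = d,
         total_kmers = sum(d$multiplicity * d$count)),
    class = "kmer_histogram"
  )
}
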