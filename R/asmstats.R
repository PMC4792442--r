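#' Split a scaffold into contigs at captured gaps
#'
#' Contigs are maximal runs not interrupted by a "captured gap": a run of at
#' least `min_gap_len` consecutive `N`s (25 by convention of the
#' Assemblathon 2 metrics). Shorter N runs stay inside contigs.
#'
#' @param scaffold A single sequence string over `{A,C,G,T,N}`.
#' @param min_gap_len Minimum N-run length that separates contigs.
#' @return Character vector of contig sequences.
#' @examples
#' split_into_contigs(paste0("ACGT", strrep("N", 25), "ACGT"))  # 2 contigs
#' @export
split_into_contigs <- function(scaffold, min_gap_len = 25L) {
  stopifnot(length(scaffold) == 1L)
  parts <- strsplit(scaffold, sprintf("[Nn]{%d,}", as.integer(min_gap_len)))[[1L]]
  parts[nzchar(parts)]
}

#' Assembly contiguity statistics
#'
#' Computes the scaffold-level statistics conventionally reported for draft
#' genome assemblies (Assemblathon-2 style): size totals, length
#' distribution, counts above standard size cutoffs, N50, and the partition
#' of the assembly into scaffolded contigs (contigs from scaffolds split
#' into two or more contigs by captured gaps) versus unscaffolded contigs.
#'
#' N50 is the largest length L such that scaffolds of length >= L together
#' contain at least half the total assembly bases.
#'
#' @param scaffolds Named character vector of scaffold sequences, or a
#'   `DNAStringSet`.
#' @param min_gap_len Captured-gap threshold passed to
#'   [split_into_contigs()].
#' @param cutoffs Size cutoffs for the "number of scaffolds > x" rows.
#' @return An `assembly_stats` list with fields `n_scaffolds`, `total_size`,
#'   `longest`, `shortest`, `n_above`/`pct_above` per cutoff, `mean_size`,
#'   `median_size`, `n50`, `n_contigs`, `pct_in_scaffolded_contigs`,
#'   `pct_in_unscaffolded_contigs`, `mean_contigs_per_scaffold`.
#' @export
assembly_stats <- function(scaffolds, min_gap_len = 25L,
                           cutoffs = c(500L, 1000L, 10000L, 100000L, 1000000L)) {
  if (methods::is(scaffolds, "XStringSet")) scaffolds <- as.character(scaffolds)
  if (length(scaffolds) < 1L) stop("empty scaffold set")
  len <- nchar(scaffolds)
  total <- sum(len)
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1L]]
  contigs <- lapply(scaffolds, split_into_contigs, min_gap_len = min_gap_len)
  n_contigs_per <- lengths(contigs)
  scaffolded <- n_contigs_per >= 2L
  n_above <- vapply(cutoffs, function(c) sum(len > c), integer(1))
  structure(
    list(
      n_scaffolds = length(scaffolds),
      total_size = total,
      longest = max(len),
      shortest = min(len),
      cutoffs = cutoffs,
      n_above = stats::setNames(n_above, paste0(">", cutoffs)),
      pct_above = stats::setNames(
        round_half_up(100 * n_above / length(scaffolds), 1), paste0(">", cutoffs)),
      mean_size = round(mean(len)),
      median_size = median(len),
      n50 = n50,
      n_contigs = sum(n_contigs_per),
      pct_in_scaffolded_contigs =
        round_half_up(100 * sum(len[scaffolded]) / total, 1),
      pct_in_unscaffolded_contigs =
        round_half_up(100 * sum(len[!scaffolded]) / total, 1),
      mean_contigs_per_scaffold =
        round_half_up(sum(n_contigs_per) / length(scaffolds), 1)
    ),
    class = "assembly_stats"
  )
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("assembly statistics\n")
  cat(sprintf("  Number of scaffolds        %s\n", format(x$n_scaffolds, big.mark = ",")))
  cat(sprintf("  Total size of scaffolds    %s\n", format(x$total_size, big.mark = ",")))
  cat(sprintf("  Longest / shortest         %s / %s\n",
              format(x$longest, big.mark = ","), format(x$shortest, big.mark = ",")))
  for (i in seq_along(x$cutoffs)) {
    cat(sprintf("  Scaffolds > %-12s   %s (%.1f%%)\n",
                format(x$cutoffs[i], big.mark = ","),
                format(x$n_above[i], big.mark = ","), x$pct_above[i]))
  }
  cat(sprintf("  Mean / median size         %s / %s\n",
              format(x$mean_size, big.mark = ","), format(x$median_size, big.mark = ",")))
  cat(sprintf("  N50 scaffold length        %s\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  %% in scaffolded contigs    %.1f%%\n", x$pct_in_scaffolded_contigs))
  cat(sprintf("  %% in unscaffolded contigs  %.1f%%\n", x$pct_in_unscaffolded_contigs))
  cat(sprintf("  Mean contigs per scaffold  %.1f\n", x$mean_contigs_per_scaffold))
  invisible(x)
}

#' Summarize a repeat landscape from masked intervals
#'
#' Given intervals masked by repeat annotation (0-based half-open, with a
#' repeat family and class per interval), computes per-family and per-class
#' masked lengths as interval unions (overlaps within a family or class are
#' counted once), the percentage of the assembly masked, and each class's
#' share of the total masked length (the composition a repeat-landscape
#' figure displays).
#'
#' Intervals assigned to several classes at the same position are counted in
#' each class's union but only once in the overall masked total.
#'
#' @param assembly_length Total assembly length in bp.
#' @param intervals Data frame with columns `family`, `class`, `start`,
#'   `end` and optionally `seqid` (intervals on different sequences are
#'   never merged).
#' @return A `repeat_summary`: list with `masked_bp`, `pct_masked`,
#'   `per_family` and `per_class` tibbles (`bp`, `pct_of_assembly`,
#'   `pct_of_masked` for classes).
#' @export
summarize_repeats <- function(assembly_length, intervals) {
  cols <- c("family", "class", "start", "end")
  if (!all(cols %in% names(intervals))) {
    stop("intervals must have columns ", paste(cols, collapse = ", "))
  }
  if (nrow(intervals) == 0L) {
    return(structure(
      list(masked_bp = 0L, pct_masked = 0,
           per_family = tibble::tibble(family = character(0), bp = integer(0)),
           per_class = tibble::tibble(class = character(0), bp = integer(0),
                                      pct_of_assembly = numeric(0),
                                      pct_of_masked = numeric(0)),
           assembly_length = assembly_length),
      class = "repeat_summary"
    ))
  }
  if (any(intervals$end <= intervals$start)) stop("inverted intervals")
  if (any(intervals$start < 0)) stop("interval out of bounds")
  if (is.null(intervals$seqid) && any(intervals$end > assembly_length)) {
    stop("interval out of bounds")
  }
  seqid <- if (!is.null(intervals$seqid)) intervals$seqid else "assembly"
  union_by <- function(group) {
    keys <- split(seq_len(nrow(intervals)), paste(group, seqid, sep = "\r"))
    bp <- vapply(keys, function(i) {
      interval_union_bp(intervals$start[i], intervals$end[i])
    }, numeric(1))
    lab <- vapply(strsplit(names(keys), "\r", fixed = TRUE), `[[`, character(1), 1L)
    tapply(bp, lab, sum)
  }
  fam_bp <- union_by(intervals$family)
  cls_bp <- union_by(intervals$class)
  all_keys <- split(seq_len(nrow(intervals)), seqid)
  masked_bp <- sum(vapply(all_keys, function(i) {
    interval_union_bp(intervals$start[i], intervals$end[i])
  }, numeric(1)))
  total_class_bp <- sum(cls_bp)
  structure(
    list(
      masked_bp = masked_bp,
      pct_masked = 100 * masked_bp / assembly_length,
      per_family = tibble::tibble(
        family = names(fam_bp), bp = as.numeric(fam_bp),
        pct_of_assembly = 100 * as.numeric(fam_bp) / assembly_length
      ),
      per_class = tibble::tibble(
        class = names(cls_bp), bp = as.numeric(cls_bp),
        pct_of_assembly = 100 * as.numeric(cls_bp) / assembly_length,
        pct_of_masked = 100 * as.numeric(cls_bp) / total_class_bp
      ),
      assembly_length = assembly_length
    ),
    class = "repeat_summary"
  )
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("repeat summary: %.0f bp masked (%.2f%% of %.4g bp assembly)\n",
              x$masked_bp, x$pct_masked, x$assembly_length))
  if (nrow(x$per_class)) {
    for (i in seq_len(nrow(x$per_class))) {
      cat(sprintf("  %-20s %8.0f bp  %6.2f%% of masked\n",
                  x$per_class$class[i], x$per_class$bp[i], x$per_class$pct_of_masked[i]))
    }
  }
  invisible(x)
}
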