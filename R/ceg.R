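#' Classify a core-gene match as complete, partial or missing
#'
#' A core eukaryotic gene is "complete" when a significant alignment spans
#' strictly more than 90% of the protein length, "partial" when a
#' significant alignment exists but spans at most 90%, and "missing"
#' otherwise.
#'
#' @param aligned_fraction Fraction of the protein length aligned, in (0, 1];
#'   `NA` for proteins with no alignment.
#' @param significant Logical; whether the alignment is significant.
#' @param complete_min Strictly-greater completeness threshold.
#' @return Character vector over `c("complete", "partial", "missing")`.
#' @export
classify_ceg <- function(aligned_fraction, significant = TRUE,
                         complete_min = 0.90) {
  if (any(!is.na(aligned_fraction) &
          (aligned_fraction <= 0 | aligned_fraction > 1))) {
    stop("aligned_fraction must be in (0, 1]")
  }
  significant <- rep_len(significant, length(aligned_fraction))
  out <- rep("missing", length(aligned_fraction))
  hit <- !is.na(aligned_fraction) & significant
  out[hit & aligned_fraction > complete_min] <- "complete"
  out[hit & aligned_fraction <= complete_min] <- "partial"
  out
}

#' Core-gene completeness report
#'
#' Summarizes a per-protein match table into the conventional completeness
#' report: the number and percentage of core genes recovered completely
#' (alignment spanning > 90% of the protein) and at least partially
#' (complete plus partial-only). Percentages are computed against the full
#' core set and rounded half-up to two decimals.
#'
#' @param matches Tibble/data.frame with `protein_id`, `aligned_fraction`,
#'   `significant`; proteins absent from the table count as missing.
#' @param n_total Size of the core gene set (conventionally 248).
#' @param complete_min Completeness threshold passed to [classify_ceg()].
#' @return A `completeness_report`: list with `n_total`, `n_complete`,
#'   `n_partial` (complete + partial-only), `pct_complete`, `pct_partial`.
#' @examples
#' tab <- simulate_ceg_table(248, 39, 68, seed = 1)
#' completeness_report(tab)$pct_complete  # 15.73
#' @export
completeness_report <- function(matches, n_total = 248L, complete_min = 0.90) {
  if (nrow(matches) > n_total) stop("more matches than core genes")
  if (anyDuplicated(matches$protein_id)) stop("duplicate protein ids")
  cls <- classify_ceg(matches$aligned_fraction, matches$significant,
                      complete_min)
  n_complete <- sum(cls == "complete")
  n_partial <- n_complete + sum(cls == "partial")
  structure(
    list(
      n_total = as.integer(n_total),
      n_complete = n_complete,
      n_partial = n_partial,
      pct_complete = round_half_up(100 * n_complete / n_total, 2),
      pct_partial = round_half_up(100 * n_partial / n_total, 2)
    ),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("core-gene completeness (n = %d)\n", x$n_total))
  cat(sprintf("  complete: %3d (%.2f%%)\n", x$n_complete, x$pct_complete))
  cat(sprintf("  partial:  %3d (%.2f%%)\n", x$n_partial, x$pct_partial))
  invisible(x)
}

#' Extrapolate the gene-repertoire size from completeness
#'
#' Treats the fraction of core genes recovered in the assembly as the
#' fraction of the whole gene repertoire recovered, so the repertoire size
#' is the number of predicted genes divided by that fraction. Conventionally
#' the partial-match fraction is used (a gene fragmented by a low-coverage
#' assembly is still present), but any completeness fraction can be passed.
#'
#' @param n_predicted_genes Number of predicted protein-coding genes.
#' @param completeness_fraction Fraction of core genes recovered, in (0, 1].
#' @return List with `raw` (the quotient) and `nearest_thousand`.
#' @examples
#' extrapolate_repertoire(10891, 107 / 248)$nearest_thousand  # 25000
#' @export
extrapolate_repertoire <- function(n_predicted_genes, completeness_fraction) {
  if (completeness_fraction <= 0 || completeness_fraction > 1) {
    stop("completeness_fraction must be in (0, 1]")
  }
  raw <- n_predicted_genes / completeness_fraction
  list(raw = raw, nearest_thousand = round(raw / 1000) * 1000)
}
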