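#' Simulate a diverged pair of circular mitochondrial genomes with reads
#'
#' Emulates the maternally (F-type) and paternally (M-type) transmitted
#' mitochondrial genomes carried by mussels under doubly uniparental
#' inheritance: the M-type sequence is derived from the F-type by planting
#' SNVs at the given divergence rate, and single-end reads are drawn from
#' both molecules with the M-type sequenced at `depth_f / copy_ratio`,
#' mirroring the unequal copy number of the two genomes in somatic tissue.
#' Reads wrap the circular origin (they are drawn on a doubled sequence and
#' reported modulo the genome length).
#'
#' Read counts are Poisson-distributed around the depth targets, emulating
#' shotgun sampling.
#'
#' @param length Genome length in bp.
#' @param divergence Fraction of sites at which the two genomes differ,
#'   in (0, 0.5) (0 allowed for identical genomes).
#' @param copy_ratio F:M copy-number ratio (> 0).
#' @param depth_f Fold read coverage of the F-type genome; 0 emits no reads.
#' @param seed Integer seed.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @return A list with `mito_f`, `mito_m` (character strings),
#'   `variant_positions` (sorted 0-based sites where the genomes differ),
#'   and `reads`: a tibble `id`, `seq`, `qual`, `source` ("F"/"M"),
#'   `true_pos` (0-based start on the circular genome), `strand`.
#' @export
simulate_mito_pair <- function(length, divergence, copy_ratio, depth_f,
                               seed = NULL, read_length = 100L,
                               error_rate = 0) {
  if (length <= read_length) stop("degenerate length: must exceed read_length")
  if (divergence < 0 || divergence >= 0.5) stop("divergence must be in [0, 0.5)")
  if (copy_ratio <= 0) stop("copy_ratio must be positive")
  if (depth_f < 0) stop("depth_f must be non-negative")
  length <- as.integer(length)
  read_length <- as.integer(read_length)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    chars_f <- sample(bases, length, replace = TRUE)
    chars_m <- chars_f
    n_var <- rbinom(1L, length, divergence)
    pos <- integer(0)
    if (n_var > 0L) {
      pos <- sort(sample.int(length, n_var))
      ref <- chars_f[pos]
      shift <- sample.int(3L, n_var, replace = TRUE)
      chars_m[pos] <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
    }
    mito_f <- paste(chars_f, collapse = "")
    mito_m <- paste(chars_m, collapse = "")

    draw_reads <- function(genome, depth, source, offset_id) {
      n <- if (depth > 0) rpois(1L, depth * length / read_length) else 0L
      if (n == 0L) {
        return(tibble::tibble(
          id = character(0), seq = character(0), qual = character(0),
          source = character(0), true_pos = integer(0), strand = character(0)
        ))
      }
      doubled <- paste0(genome, genome)
      start <- sample.int(length, n, replace = TRUE)  # 1-based on circle
      seqs <- substring(doubled, start, start + read_length - 1L)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rc <- strand == "-"
      if (any(rc)) seqs[rc] <- revcomp(seqs[rc])
      seqs <- inject_errors(seqs, error_rate)
      tibble::tibble(
        id = sprintf("%s%06d", tolower(source), offset_id + seq_len(n)),
        seq = seqs,
        qual = sim_quals(n, read_length),
        source = source,
        true_pos = start - 1L,
        strand = strand
      )
    }
    reads_f <- draw_reads(mito_f, depth_f, "F", 0L)
    reads_m <- draw_reads(mito_m, depth_f / copy_ratio, "M", nrow(reads_f))
    list(
      mito_f = mito_f, mito_m = mito_m,
      variant_positions = pos - 1L,
      reads = rbind(reads_f, reads_m)
    )
  })
}

#' Simulate a core-eukaryotic-gene (CEG) match table
#'
#' Fabricates the per-protein aligned-fraction table a completeness analysis
#' consumes: `n_complete` proteins with aligned fraction in (0.90, 1],
#' `n_partial_only` with fraction in (0, 0.90], and the remainder absent
#' from the table (missing).
#'
#' @param n_total Size of the core gene set (conventionally 248).
#' @param n_complete Number of completely recovered proteins.
#' @param n_partial_only Number recovered only partially.
#' @param seed Integer seed.
#' @return Tibble with `protein_id`, `aligned_fraction`, `significant`.
#' @export
simulate_ceg_table <- function(n_total, n_complete, n_partial_only, seed = NULL) {
  if (n_total < 0 || n_complete < 0 || n_partial_only < 0) {
    stop("counts must be non-negative")
  }
  if (n_complete + n_partial_only > n_total) {
    stop("n_complete + n_partial_only must not exceed n_total")
  }
  with_seed(seed, {
    ids <- sprintf("KOG%04d", seq_len(n_total))
    matched <- sample(ids, n_complete + n_partial_only)
    frac <- c(
      runif(n_complete, min = 0.90, max = 1.0),      # > 0.90 after nudge
      runif(n_partial_only, min = 0.0, max = 0.90)
    )
    # keep strictly inside the class-defining intervals
    frac[seq_len(n_complete)] <- pmax(frac[seq_len(n_complete)], 0.9000001)
    if (n_partial_only > 0) {
      idx <- n_complete + seq_len(n_partial_only)
      frac[idx] <- pmax(pmin(frac[idx], 0.90), 1e-6)
    }
    tibble::tibble(
      protein_id = matched,
      aligned_fraction = frac,
      significant = TRUE
    )
  })
}

#' Simulate paired GO annotation count tables with planted enrichment
#'
#' Draws per-term gene counts for two annotation sets from binomial
#' distributions with a shared base proportion per term; terms listed in
#' `enriched_terms` have their proportion multiplied by the given fold in
#' table A, planting a known enrichment signal.
#'
#' @param n_terms Number of GO terms.
#' @param background_total_a,background_total_b Total annotated genes per set.
#' @param enriched_terms Named numeric vector mapping term id to fold
#'   change (> 0) applied in table A; empty for a global null.
#' @param seed Integer seed.
#' @param base_prop_range Range the per-term base proportions are drawn from.
#' @return List with `table_a`, `table_b` (tibbles `term`, `count`),
#'   `total_a`, `total_b` and the ground-truth `enriched` term ids.
#' @export
simulate_go_tables <- function(n_terms, background_total_a, background_total_b,
                               enriched_terms = numeric(0), seed = NULL,
                               base_prop_range = c(0.002, 0.02)) {
  if (n_terms < 1) stop("empty term list")
  if (length(enriched_terms) && any(enriched_terms <= 0)) {
    stop("enrichment folds must be positive")
  }
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    base_prop <- runif(n_terms, base_prop_range[1], base_prop_range[2])
    fold <- rep(1, n_terms)
    if (length(enriched_terms)) {
      idx <- match(names(enriched_terms), terms)
      if (anyNA(idx)) stop("enriched term ids must be among the generated terms")
      fold[idx] <- enriched_terms
    }
    count_a <- rbinom(n_terms, background_total_a, pmin(base_prop * fold, 1))
    count_b <- rbinom(n_terms, background_total_b, base_prop)
    list(
      table_a = tibble::tibble(term = terms, count = count_a),
      table_b = tibble::tibble(term = terms, count = count_b),
      total_a = background_total_a,
      total_b = background_total_b,
      enriched = if (length(enriched_terms)) names(enriched_terms) else character(0)
    )
  })
}
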