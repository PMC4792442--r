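#' Simulate a diploid genome with SNV-only heterozygosity
#'
#' Generates two haplotype sequences of equal length that differ only by
#' single-nucleotide variants, emulating a diploid genome whose k-mer
#' spectrum is bimodal: homozygous k-mers occur on both haplotypes (and so at
#' the full k-mer depth) while heterozygous k-mers occur on one haplotype
#' only (half depth). Keeping the haplotypes indel-free means both share one
#' coordinate system, so variant positions are exact ground truth for
#' downstream spectrum and variant-calling checks.
#'
#' The number of variant sites is drawn as Binomial(`length`, `het_rate`);
#' sites are placed uniformly and the alternate allele is drawn uniformly
#' from the three non-reference bases.
#'
#' @param length Haplotype length in bp (positive integer).
#' @param het_rate Target fraction of heterozygous sites, in `[0, 0.5)`.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return An object of class `diploid_genome`: a list with `hap_a`, `hap_b`
#'   (character strings), `variant_positions` (sorted 0-based integer
#'   positions where the haplotypes differ), `het_rate`, `length` and `seed`.
#' @examples
#' g <- simulate_diploid_genome(10000, 0.01, seed = 1)
#' length(g$variant_positions) / g$length  # close to 0.01
#' @export
simulate_diploid_genome <- function(length, het_rate, seed = NULL) {
  if (length <= 0) stop("length must be positive")
  if (het_rate < 0 || het_rate >= 0.5) stop("het_rate must be in [0, 0.5)")
  length <- as.integer(length)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    chars_a <- sample(bases, length, replace = TRUE)
    chars_b <- chars_a
    n_var <- rbinom(1L, length, het_rate)
    pos <- integer(0)
    if (n_var > 0L) {
      pos <- sort(sample.int(length, n_var))
      # alternate allele uniform over the three non-reference bases
      ref <- chars_a[pos]
      shift <- sample.int(3L, n_var, replace = TRUE)
      alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
      chars_b[pos] <- alt
    }
    structure(
      list(
        hap_a = paste(chars_a, collapse = ""),
        hap_b = paste(chars_b, collapse = ""),
        variant_positions = pos - 1L,
        het_rate = het_rate,
        length = length,
        seed = seed
      ),
      class = "diploid_genome"
    )
  })
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf(
    "diploid genome: %d bp per haplotype, %d heterozygous sites (%.3f%%)\n",
    x$length, length(x$variant_positions),
    100 * length(x$variant_positions) / x$length
  ))
  invisible(x)
}

#' Configuration for paired-end read simulation
#'
#' Bundles the parameters of the read simulator. The defaults emulate the
#' sequencing design the package targets: 100-bp paired-end reads from
#' libraries with 180, 500 and 800 bp inserts. `violation_rates` plants the
#' five quality-control violation classes at the given per-pair rates; the
#' classes are assigned disjointly (a pair carries at most one planted
#' class), so the rates must sum to at most 1.
#'
#' The adapter default is the common Illumina TruSeq read-1 adapter; the
#' true adapter of any given dataset should be supplied when known.
#'
#' @param depth Fold base coverage over one haplotype length.
#' @param read_length Read length in bp.
#' @param insert_sizes Insert sizes (bp) sampled uniformly per pair.
#' @param error_rate Per-base substitution error rate.
#' @param adapter_sequence Adapter used when planting adapter contamination.
#' @param violation_rates Named numeric rates for classes
#'   `c("highN", "polyA", "lowQ", "adapter", "overlap")`.
#' @param seed Integer seed.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(depth,
                            read_length = 100L,
                            insert_sizes = c(180L, 500L, 800L),
                            error_rate = 0,
                            adapter_sequence = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                            violation_rates = c(highN = 0, polyA = 0, lowQ = 0,
                                                adapter = 0, overlap = 0),
                            seed = NULL) {
  classes <- c("highN", "polyA", "lowQ", "adapter", "overlap")
  vr <- stats::setNames(rep(0, 5), classes)
  vr[names(violation_rates)] <- violation_rates
  if (any(vr < 0 | vr > 1) || sum(vr) > 1) {
    stop("violation rates must lie in [0,1] and sum to at most 1")
  }
  if (depth <= 0) stop("depth must be positive")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  structure(
    list(
      depth = depth, read_length = as.integer(read_length),
      insert_sizes = as.integer(insert_sizes), error_rate = error_rate,
      adapter_sequence = adapter_sequence, violation_rates = vr, seed = seed
    ),
    class = "read_sim_config"
  )
}

# Inject substitution errors at `rate` into a character vector of reads.
inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  rl <- nchar(reads)
  n_err <- rbinom(length(reads), rl, rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    p <- sample.int(rl[i], n_err[i])
    for (j in p) {
      cur <- substr(reads[i], j, j)
      alt <- sample(setdiff(bases, cur), 1L)
      substr(reads[i], j, j) <- alt
    }
  }
  reads
}

# Quality strings: Q35 with a small per-read jitter (Phred+33).
sim_quals <- function(n, read_length) {
  q <- sample(34:36, n, replace = TRUE)
  vapply(q, function(v) strrep(intToUtf8(v + 33L), read_length), character(1))
}

#' Simulate paired-end reads from a diploid genome
#'
#' Draws read pairs uniformly from both haplotypes in equal proportion,
#' injects base-call errors, and plants the five QC violation classes at the
#' configured rates, recording ground-truth labels. Planting rewrites the
#' pair:
#' * `highN`: the first 10% of bases of mate 1 become `N` (above the 5%
#'   ambiguity threshold);
#' * `polyA`: the final 85% of mate 1 becomes `A`;
#' * `lowQ`: the first 20 quality scores of mate 1 drop to Q2;
#' * `adapter`: the last 30 bp of mate 1 are replaced by the adapter prefix;
#' * `overlap`: the pair is redrawn from a short fragment of
#'   `2 * read_length - 50` bp so the mates overlap by 50 bp.
#'
#' @param genome A [simulate_diploid_genome()] result.
#' @param config A [read_sim_config()].
#' @return A list with `reads` (tibble: `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `insert`), `labels` (tibble: `id`, `class`) for planted
#'   violations, and `truth` (tibble with the originating haplotype and
#'   fragment coordinates per pair).
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(genome, "diploid_genome"), inherits(config, "read_sim_config"))
  rl <- config$read_length
  L <- genome$length
  if (rl > L) stop("read_length exceeds haplotype length")
  if (any(config$insert_sizes > L)) stop("insert size exceeds haplotype length")
  with_seed(config$seed, {
    n_pairs <- max(1L, as.integer(round(config$depth * L / (2 * rl))))
    insert <- config$insert_sizes[
      sample.int(length(config$insert_sizes), n_pairs, replace = TRUE)]
    hap <- sample(c("A", "B"), n_pairs, replace = TRUE)

    # disjoint violation-class assignment by one uniform draw per pair
    vr <- config$violation_rates
    cuts <- cumsum(vr)
    u <- runif(n_pairs)
    class_idx <- findInterval(u, c(0, cuts), rightmost.closed = FALSE)
    # findInterval: 1 .. 5 -> a violation class, 6 -> clean
    planted <- ifelse(class_idx <= length(vr), names(vr)[class_idx], NA_character_)

    # overlap-planted pairs come from a short fragment
    short_insert <- 2L * rl - 50L
    insert[!is.na(planted) & planted == "overlap"] <- short_insert

    start <- as.integer(floor(runif(n_pairs) * (L - insert + 1L))) + 1L
    hapseq <- ifelse(hap == "A", genome$hap_a, genome$hap_b)
    seq1 <- substring(hapseq, start, start + rl - 1L)
    seq2 <- revcomp(substring(hapseq, start + insert - rl, start + insert - 1L))

    seq1 <- inject_errors(seq1, config$error_rate)
    seq2 <- inject_errors(seq2, config$error_rate)
    qual1 <- sim_quals(n_pairs, rl)
    qual2 <- sim_quals(n_pairs, rl)

    n_amb <- as.integer(ceiling(0.10 * rl))
    i <- which(!is.na(planted) & planted == "highN")
    if (length(i)) substr(seq1[i], 1L, n_amb) <- strrep("N", n_amb)
    i <- which(!is.na(planted) & planted == "polyA")
    if (length(i)) {
      tail_start <- as.integer(floor(0.15 * rl)) + 1L
      substr(seq1[i], tail_start, rl) <- strrep("A", rl - tail_start + 1L)
    }
    i <- which(!is.na(planted) & planted == "lowQ")
    if (length(i)) substr(qual1[i], 1L, 20L) <- strrep(intToUtf8(2L + 33L), 20L)
    i <- which(!is.na(planted) & planted == "adapter")
    if (length(i)) {
      alen <- min(30L, nchar(config$adapter_sequence))
      substr(seq1[i], rl - alen + 1L, rl) <- substr(config$adapter_sequence, 1L, alen)
    }

    ids <- sprintf("rp%07d", seq_len(n_pairs))
    reads <- tibble::tibble(
      id = ids, seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
      insert = insert
    )
    labels <- tibble::tibble(id = ids, class = planted)
    labels <- labels[!is.na(labels$class), , drop = FALSE]
    truth <- tibble::tibble(id = ids, hap = hap, start = start - 1L, insert = insert)
    list(reads = reads, labels = labels, truth = truth)
  })
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' @param reads Tibble as returned in `simulate_reads()$reads`.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (Phred+33).
#' @return Invisibly, the two file paths.
#' @export
write_fastq_pair <- function(reads, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(reads$seq1, reads$qual1, reads$id, f1)
  write_one(reads$seq2, reads$qual2, reads$id, f2)
  invisible(c(f1, f2))
}
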