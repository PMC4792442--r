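#' Place reads on a circular reference by exact-seed mapping
#'
#' A deliberately minimal read placer for small circular genomes
#' (mitochondria): seeds of length `seed_k` are looked up exactly in an
#' index of the doubled reference (so reads spanning the circular origin
#' map), candidate placements are extended ungapped, and the placement with
#' the fewest mismatches wins. Ties between distinct placements are reported
#' as unmapped-ambiguous. Reported positions are modulo the reference
#' length. A SAM file produced by a full aligner can be converted to the
#' same placement layout with [read_sam_placements()].
#'
#' @param reads Tibble/data.frame with `id` and `seq`, or a character
#'   vector of sequences (names used as ids).
#' @param ref Reference sequence (single string); must be longer than any
#'   read.
#' @param seed_k Exact seed length.
#' @param n_seeds Number of evenly spaced seed offsets tried per
#'   orientation (robustness to sequencing errors inside one seed).
#' @return Tibble with `id`, `mapped`, `pos` (0-based start on the circular
#'   reference), `strand`, `mismatches`, `length` and `aligned_seq` (the
#'   read oriented to the forward reference strand).
#' @export
map_reads_minimal <- function(reads, ref, seed_k = 21L, n_seeds = 3L) {
  if (is.character(reads)) {
    reads <- tibble::tibble(
      id = if (!is.null(names(reads))) names(reads) else sprintf("r%06d", seq_along(reads)),
      seq = unname(reads)
    )
  }
  L <- nchar(ref)
  if (any(nchar(reads$seq) >= L)) stop("reads must be shorter than the reference")
  doubled <- paste0(ref, ref)
  n_pos <- 2L * L - seed_k + 1L
  starts <- seq_len(n_pos)
  index <- list2env(split(starts, substring(doubled, starts, starts + seed_k - 1L)))

  n <- nrow(reads)
  mapped <- logical(n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  aligned <- rep(NA_character_, n)
  rl_all <- nchar(reads$seq)
  rc_all <- revcomp(reads$seq)
  for (i in seq_len(n)) {
    rl <- rl_all[i]
    offs <- unique(as.integer(round(seq(1L, rl - seed_k + 1L, length.out = n_seeds))))
    cand <- NULL
    for (orient in c("+", "-")) {
      oriented <- if (orient == "+") reads$seq[i] else rc_all[i]
      hits <- integer(0)
      for (off in offs) {
        seed <- substr(oriented, off, off + seed_k - 1L)
        p <- index[[seed]]
        if (!is.null(p)) hits <- c(hits, p - off + 1L)
      }
      hits <- hits[hits >= 1L & hits <= 2L * L - rl + 1L]
      if (length(hits)) {
        p0 <- unique((hits - 1L) %% L)
        cand <- rbind(cand, data.frame(pos = p0, strand = orient,
                                       oriented = oriented))
      }
    }
    if (is.null(cand)) next
    ref_seg <- substring(doubled, cand$pos + 1L, cand$pos + rl)
    mm <- hamming_cpp(cand$oriented, ref_seg)
    best <- which(mm == min(mm))
    if (length(best) > 1L) next  # ambiguous placement
    mapped[i] <- TRUE
    pos[i] <- cand$pos[best]
    strand[i] <- cand$strand[best]
    mism[i] <- mm[best]
    aligned[i] <- cand$oriented[best]
  }
  tibble::tibble(
    id = reads$id, mapped = mapped, pos = pos, strand = strand,
    mismatches = mism, length = rl_all, aligned_seq = aligned
  )
}

#' Convert SAM alignments to the placement layout
#'
#' Minimal SAM reader for single-end, ungapped alignments against one
#' circular reference: keeps mapped records, orients sequences to the
#' forward strand (SAM already stores them that way) and reports 0-based
#' positions.
#'
#' @param path SAM file.
#' @return Placement tibble as from [map_reads_minimal()].
#' @export
read_sam_placements <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  posn <- as.integer(get(4))
  seq <- get(10)
  mapped <- bitwAnd(flag, 4L) == 0L & posn > 0L
  tibble::tibble(
    id = get(1),
    mapped = mapped,
    pos = ifelse(mapped, posn - 1L, NA_integer_),
    strand = ifelse(bitwAnd(flag, 16L) == 16L, "-", "+"),
    mismatches = NA_integer_,
    length = nchar(seq),
    aligned_seq = ifelse(mapped, seq, NA_character_)
  )
}

#' Per-position read depth on a circular reference
#'
#' @param placements Placement tibble (see [map_reads_minimal()]).
#' @param ref_length Reference length in bp.
#' @param window Sliding-window size for the minimum-coverage scan; the
#'   window wraps the circular origin.
#' @return A `depth_profile`: list with `depth` (numeric vector of length
#'   `ref_length`), `mean_depth`, and `min_window` (`start` 0-based,
#'   `depth` = mean depth inside the lowest window).
#' @export
depth_profile <- function(placements, ref_length, window = 50L) {
  L <- as.integer(ref_length)
  p <- placements[placements$mapped, , drop = FALSE]
  depth <- numeric(L)
  if (nrow(p) > 0L) {
    starts <- p$pos + 1L                 # 1-based on doubled axis
    ends <- p$pos + p$length             # inclusive
    inc_tab <- tabulate(starts, nbins = 2L * L + 1L) -
      tabulate(ends + 1L, nbins = 2L * L + 1L)
    depth2 <- cumsum(inc_tab[seq_len(2L * L)])
    depth <- depth2[seq_len(L)] + depth2[L + seq_len(L)]
  }
  w <- min(as.integer(window), L)
  ext <- c(depth, depth[seq_len(w - 1L)])
  cs <- cumsum(c(0, ext))
  wsum <- cs[(w + 1L):(L + w)] - cs[seq_len(L)]
  i_min <- which.min(wsum)
  structure(
    list(depth = depth,
         mean_depth = mean(depth),
         min_window = list(start = i_min - 1L, depth = wsum[i_min] / w),
         window = w,
         ref_length = L),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "depth profile: mean %.1fX over %d bp; lowest %d-bp window at %d (%.1fX)\n",
    x$mean_depth, x$ref_length, x$window, x$min_window$start,
    x$min_window$depth))
  invisible(x)
}

#' Call single-nucleotide variants from read placements
#'
#' Pileup-based caller with an explicit rule: a site is called when its
#' depth is at least `min_depth` and the most frequent non-reference allele
#' has count at least `min_alt_count` and frequency at least `min_alt_frac`.
#'
#' @param placements Placement tibble (see [map_reads_minimal()]).
#' @param ref Reference sequence (single string, circular).
#' @param min_depth Minimum site depth.
#' @param min_alt_frac Minimum alternate-allele fraction.
#' @param min_alt_count Minimum alternate-allele read count.
#' @return Tibble with `pos` (0-based), `ref`, `alt`, `depth`, `alt_count`.
#' @export
call_snvs <- function(placements, ref, min_depth = 10L, min_alt_frac = 0.2,
                      min_alt_count = 4L) {
  L <- nchar(ref)
  p <- placements[placements$mapped, , drop = FALSE]
  empty <- tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), depth = integer(0),
                          alt_count = integer(0))
  if (nrow(p) == 0L) return(empty)
  pos_list <- lapply(seq_len(nrow(p)), function(i) {
    (p$pos[i] + seq_len(p$length[i]) - 1L) %% L
  })
  pos_all <- unlist(pos_list)
  base_all <- unlist(strsplit(p$aligned_seq, "", fixed = TRUE))
  code <- match(base_all, c("A", "C", "G", "T"))
  ok <- !is.na(code)
  idx <- pos_all[ok] * 4L + code[ok]          # 1..4L
  counts <- matrix(tabulate(idx, nbins = 4L * L), nrow = 4L)
  depth <- colSums(counts)
  ref_code <- match(strsplit(ref, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  alt_counts <- counts
  alt_counts[cbind(ref_code, seq_len(L))] <- -1L
  alt_code <- max.col(t(alt_counts), ties.method = "first")
  alt_n <- alt_counts[cbind(alt_code, seq_len(L))]
  called <- depth >= min_depth & alt_n >= min_alt_count &
    alt_n / pmax(depth, 1L) >= min_alt_frac
  if (!any(called)) return(empty)
  bases <- c("A", "C", "G", "T")
  tibble::tibble(
    pos = which(called) - 1L,
    ref = bases[ref_code[called]],
    alt = bases[alt_code[called]],
    depth = as.integer(depth[called]),
    alt_count = as.integer(alt_n[called])
  )
}

#' Write variants as a minimal VCF
#'
#' @param variants Variant tibble from [call_snvs()].
#' @param ref_name Reference sequence name for the CHROM column.
#' @param path Output file.
#' @export
write_minimal_vcf <- function(variants, ref_name, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate allele depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d",
                       ref_name, variants$pos + 1L, variants$ref, variants$alt,
                       variants$depth, variants$alt_count), con)
  }
  invisible(path)
}

#' Variant density per annotated gene
#'
#' Counts variants inside each annotated gene and expresses the count as a
#' percentage of the gene length (variants per bp x 100), ranking genes by
#' density. A variant inside several overlapping genes is attributed to each
#' of them; variants outside every gene are tallied as intergenic.
#'
#' @param variants Variant tibble with 0-based `pos` (see [call_snvs()]).
#' @param genes Data frame with `gene`, `start`, `end` (0-based half-open)
#'   and `coding` (logical).
#' @return A `gene_variant_table`: list with `per_gene` tibble (`gene`,
#'   `length`, `n_variants`, `pct_per_bp`, `coding`, ranked by density),
#'   `n_coding`, `n_noncoding`, `n_intergenic`, `n_total`.
#' @export
variant_density_by_gene <- function(variants, genes) {
  stopifnot(all(c("gene", "start", "end", "coding") %in% names(genes)))
  if (any(genes$end <= genes$start)) stop("invalid gene intervals")
  n_in <- vapply(seq_len(nrow(genes)), function(i) {
    sum(variants$pos >= genes$start[i] & variants$pos < genes$end[i])
  }, integer(1))
  len <- genes$end - genes$start
  per_gene <- tibble::tibble(
    gene = genes$gene,
    length = as.integer(len),
    n_variants = n_in,
    pct_per_bp = 100 * n_in / len,
    coding = genes$coding
  )
  per_gene <- per_gene[order(-per_gene$pct_per_bp, per_gene$gene), , drop = FALSE]
  in_any <- function(which_genes) {
    if (!nrow(variants)) return(0L)
    sum(vapply(variants$pos, function(p) {
      any(p >= genes$start[which_genes] & p < genes$end[which_genes])
    }, logical(1)))
  }
  n_coding <- in_any(genes$coding)
  n_noncoding <- in_any(!genes$coding)
  n_genic <- in_any(rep(TRUE, nrow(genes)))
  structure(
    list(per_gene = per_gene,
         n_coding = n_coding,
         n_noncoding = n_noncoding,
         n_intergenic = nrow(variants) - n_genic,
         n_total = nrow(variants)),
    class = "gene_variant_table"
  )
}

#' @export
print.gene_variant_table <- function(x, ...) {
  cat(sprintf(
    "variants by gene: %d total (%d coding, %d non-coding, %d intergenic)\n",
    x$n_total, x$n_coding, x$n_noncoding, x$n_intergenic))
  print(utils::head(x$per_gene, 5))
  invisible(x)
}
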