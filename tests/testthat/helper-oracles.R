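# Independent brute-force oracles the implementation is checked against.
# These deliberately use naive string/per-base methods, not the package's
# code paths.

# canonical k-mer histogram by explicit string multiset
oracle_kmer_hist <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    w[!grepl("N", w, fixed = TRUE)]
  }))
  if (!length(kmers)) {
    return(data.frame(multiplicity = integer(0), count = numeric(0)))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  mult <- table(canon)
  h <- table(as.integer(mult))
  data.frame(multiplicity = as.integer(names(h)), count = as.numeric(h),
             row.names = NULL)
}

# interval union length by per-base marking (0-based half-open input)
oracle_union_length <- function(start, end) {
  if (!length(start)) return(0L)
  m <- logical(max(end))
  for (i in seq_along(start)) m[(start[i] + 1L):end[i]] <- TRUE
  sum(m)
}

# N50 by scanning every candidate length
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- Filter(function(L) sum(lengths[lengths >= L]) >= total / 2,
                  unique(lengths))
  max(unlist(cands))
}

# two-sided Fisher p by full enumeration of the hypergeometric support
oracle_fisher_p <- function(a, total_a, b, total_b) {
  k <- a + b
  support <- max(0L, k - total_b):min(k, total_a)
  probs <- dhyper(support, total_a, total_b, k)
  p_obs <- dhyper(a, total_a, total_b, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# adapter hit by exhaustive offset scan in plain R
oracle_adapter_hit <- function(read, adapter, min_match = 11L, max_mm = 3L) {
  r <- strsplit(read, "")[[1L]]
  a <- strsplit(adapter, "")[[1L]]
  for (off in (-(length(a) - 1L)):(length(r) - 1L)) {
    lo <- max(0L, off)
    hi <- min(length(r), off + length(a))
    if (hi - lo < min_match) next
    rp <- (lo + 1L):hi
    mm <- sum(r[rp] != a[rp - off] | r[rp] == "N")
    if (mm <= max_mm) return(TRUE)
  }
  FALSE
}

# mate-overlap hit by exhaustive overlap-length scan in plain R
oracle_overlap_hit <- function(seq1, seq2, min_overlap = 10L, max_frac = 0.10) {
  s1 <- strsplit(seq1, "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq2))), "")[[1L]]
  for (o in min_overlap:min(length(s1), length(s2))) {
    mm <- sum(s1[(length(s1) - o + 1L):length(s1)] != s2[seq_len(o)])
    if (mm / o <= max_frac + 1e-12) return(TRUE)
  }
  FALSE
}

# uniform random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
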