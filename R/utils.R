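# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Reverse complement of plain character sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform random DNA sequence as a single string.
random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# Count occurrences of a fixed character in each string.
count_char <- function(x, char) {
  nchar(x) - nchar(gsub(char, "", x, fixed = TRUE))
}

# Half-up rounding to `digits` decimals (percentages in reports).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Phred+33 quality string -> integer scores.
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# Integer scores -> Phred+33 string.
int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

# Union length of 0-based half-open intervals via IRanges.
interval_union_bp <- function(start, end) {
  if (length(start) == 0L) return(0L)
  stopifnot(length(start) == length(end))
  if (any(end <= start)) stop("inverted or empty interval: end must exceed start")
  ir <- IRanges::IRanges(start = start + 1L, end = end)  # to 1-based closed
  sum(IRanges::width(IRanges::reduce(ir)))
}
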