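cfg_default <- qc_config()

test_that("ambiguous-base rule fails strictly above 5%", {
  set.seed(101)
  base <- rand_dna(100)
  with_n <- function(k) {
    s <- base
    if (k > 0) substr(s, 1, k) <- strrep("N", k)
    s
  }
  expect_false(check_n_fraction(with_n(5), cfg_default))   # boundary: 5% passes
  expect_true(check_n_fraction(with_n(6), cfg_default))
  expect_false(check_n_fraction(with_n(0), cfg_default))
  expect_error(check_n_fraction(""), "empty")
})

test_that("poly-A rule fails at or above the A-fraction threshold", {
  expect_true(check_polya(strrep("A", 100), cfg_default))
  set.seed(102)
  rnd <- vapply(1:50, function(i) rand_dna(100), character(1))
  expect_false(any(check_polya(rnd, cfg_default)))
  at_threshold <- paste0(strrep("A", 80), strrep("C", 20))
  expect_true(check_polya(at_threshold, cfg_default))      # >= convention
  expect_false(check_polya(paste0(strrep("A", 79), strrep("C", 21)), cfg_default))
})

test_that("low-quality rule counts bases at or below Phred 7, failing at 20", {
  q35 <- strrep(intToUtf8(35 + 33), 100)
  mixq <- function(k) paste0(strrep(intToUtf8(2 + 33), k),
                             strrep(intToUtf8(35 + 33), 100 - k))
  expect_false(check_low_quality(mixq(19), cfg_default))   # boundary: 19 passes
  expect_true(check_low_quality(mixq(20), cfg_default))
  expect_false(check_low_quality(q35, cfg_default))
})

test_that("adapter rule needs >= 11 aligned bases with <= 3 mismatches", {
  adapter <- "TTTTGGGGTTT"
  cfg <- qc_config(adapter_sequence = adapter)
  bg <- strrep("C", 100)  # background cannot chance-match this adapter
  plant <- function(insert) {
    s <- bg
    substr(s, 45, 44 + nchar(insert)) <- insert
    s
  }
  expect_true(check_adapter(plant(adapter), cfg))
  with_mm <- function(k) {  # k mismatches inside the 11-bp match
    a <- strsplit(adapter, "")[[1]]
    a[seq_len(k) * 2] <- "C"
    paste(a, collapse = "")
  }
  expect_true(check_adapter(plant(with_mm(3)), cfg))
  expect_false(check_adapter(plant(with_mm(4)), cfg))
  # a hit flush against the read end is still found
  s <- bg
  substr(s, 90, 100) <- substr(adapter, 1, 11)
  expect_true(check_adapter(s, cfg))
})

test_that("overlap rule detects short-insert mates including the 10% boundary", {
  set.seed(103)
  frag150 <- rand_dna(150)
  s1 <- substr(frag150, 1, 100)
  s2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag150, 51, 150))))
  expect_true(check_overlap(s1, s2, cfg_default))

  frag400 <- rand_dna(400)
  l1 <- substr(frag400, 1, 100)
  l2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag400, 301, 400))))
  expect_false(check_overlap(l1, l2, cfg_default))

  # exactly 10 bp overlap with 1 mismatch (10%) still counts as overlapping
  frag190 <- rand_dna(190)
  m1 <- substr(frag190, 1, 100)
  tail10 <- strsplit(substr(frag190, 91, 190), "")[[1]]
  tail10[1] <- setdiff(c("A", "C", "G", "T"), tail10[1])[1]
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste(tail10, collapse = ""))))
  expect_true(check_overlap(m1, m2, cfg_default))
})

test_that("adapter and overlap scans agree with exhaustive brute-force oracles", {
  set.seed(104)
  n <- 500
  adapter <- qc_config()$adapter_sequence
  reads <- vapply(seq_len(n), function(i) rand_dna(100), character(1))
  # make a third of the reads borderline cases by planting noisy adapter bits
  for (i in seq_len(n %/% 3)) {
    piece <- substr(adapter, 1, sample(8:14, 1))
    pc <- strsplit(piece, "")[[1]]
    k <- sample(0:4, 1)
    if (k > 0) pc[sample(length(pc), min(k, length(pc)))] <- "T"
    piece <- paste(pc, collapse = "")
    at <- sample(100 - nchar(piece), 1)
    substr(reads[i], at, at + nchar(piece) - 1) <- piece
  }
  got <- check_adapter(reads)
  want <- vapply(reads, oracle_adapter_hit, logical(1), adapter = adapter,
                 USE.NAMES = FALSE)
  expect_identical(got, want)

  # overlap: random pairs plus true short-fragment pairs with a few errors
  s1 <- character(n)
  s2 <- character(n)
  for (i in seq_len(n)) {
    if (i %% 3 == 0) {
      frag <- rand_dna(sample(120:190, 1))
      a <- substr(frag, 1, 100)
      btxt <- strsplit(substr(frag, nchar(frag) - 99, nchar(frag)), "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) btxt[sample(100, k)] <- "A"
      b <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(btxt, collapse = ""))))
    } else {
      a <- rand_dna(100)
      b <- rand_dna(100)
    }
    s1[i] <- a
    s2[i] <- b
  }
  got_ov <- check_overlap(s1, s2)
  want_ov <- mapply(oracle_overlap_hit, s1, s2, USE.NAMES = FALSE)
  expect_identical(got_ov, want_ov)
})

test_that("pair filtering conserves counts, attributes first rule, is idempotent", {
  g <- simulate_diploid_genome(5e4, 0.005, seed = 105)
  cfg_sim <- read_sim_config(
    depth = 2, insert_sizes = c(500L, 800L),
    violation_rates = c(highN = 0.05, polyA = 0.05, lowQ = 0.05,
                        adapter = 0.05, overlap = 0.05),
    seed = 106)
  sim <- simulate_reads(g, cfg_sim)
  res <- filter_pairs(sim$reads, qc_config())
  rep <- res$report
  # conservation on every input
  expect_equal(rep$pairs_in, rep$pairs_kept + sum(rep$drops))
  expect_equal(rep$pairs_in, nrow(sim$reads))
  # every planted pair is dropped
  fr <- rep$first_rule
  dropped <- names(fr)[!is.na(fr)]
  expect_length(setdiff(sim$labels$id, dropped), 0)
  # idempotence: re-filtering the kept pairs drops nothing
  res2 <- filter_pairs(res$kept, qc_config())
  expect_equal(res2$report$pairs_kept, nrow(res$kept))
  expect_equal(sum(res2$report$drops), 0)
})

test_that("clean, empty and malformed inputs are handled", {
  g <- simulate_diploid_genome(2e4, 0, seed = 107)
  sim <- simulate_reads(g, read_sim_config(depth = 1, insert_sizes = c(500L),
                                           seed = 108))
  # exclude rare chance adapter matches via the independent oracle
  res <- filter_pairs(sim$reads, qc_config())
  chance <- vapply(seq_len(nrow(sim$reads)), function(i) {
    oracle_adapter_hit(sim$reads$seq1[i], qc_config()$adapter_sequence) ||
      oracle_adapter_hit(sim$reads$seq2[i], qc_config()$adapter_sequence)
  }, logical(1))
  expect_equal(res$report$pairs_kept, sum(!chance))

  empty <- sim$reads[0, ]
  res0 <- filter_pairs(empty, qc_config())
  expect_equal(res0$report$pairs_in, 0)
  expect_equal(sum(res0$report$drops), 0)

  dup <- sim$reads[c(1, 1), ]
  expect_error(filter_pairs(dup, qc_config()), "desynchronized")
})

test_that("FASTQ pair round-trip preserves sequences and qualities", {
  g <- simulate_diploid_genome(2e4, 0, seed = 109)
  sim <- simulate_reads(g, read_sim_config(depth = 0.5, seed = 110))
  prefix <- file.path(tempdir(), "gsqc")
  write_fastq_pair(sim$reads, prefix)
  back <- read_fastq_pairs(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"))
  expect_equal(back$seq1, sim$reads$seq1)
  expect_equal(back$seq2, sim$reads$seq2)
  expect_equal(back$qual1, sim$reads$qual1)
  unlink(paste0(prefix, c("_1.fastq", "_2.fastq")))
})
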