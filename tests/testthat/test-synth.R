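# string Hamming distance helper (test-local)
str_hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

test_that("diploid genome respects the heterozygosity target and coordinates", {
  g0 <- simulate_diploid_genome(10000, 0, seed = 1)
  expect_identical(g0$hap_a, g0$hap_b)
  expect_length(g0$variant_positions, 0)

  g <- simulate_diploid_genome(1e6, 0.01, seed = 2)
  h <- str_hamming(g$hap_a, g$hap_b)
  # binomial oracle: 10^6 * 0.01 within 4 standard deviations
  expect_lt(abs(h - 10000), 4 * sqrt(1e6 * 0.01 * 0.99))
  expect_identical(h, length(g$variant_positions))
  # the haplotypes differ exactly at the recorded positions
  ca <- strsplit(g$hap_a, "")[[1]]
  cb <- strsplit(g$hap_b, "")[[1]]
  expect_identical(which(ca != cb) - 1L, g$variant_positions)

  expect_identical(simulate_diploid_genome(5000, 0.02, seed = 3),
                   simulate_diploid_genome(5000, 0.02, seed = 3))
  expect_error(simulate_diploid_genome(0, 0.01), "positive")
  expect_error(simulate_diploid_genome(100, 0.6), "het_rate")
})

test_that("simulated reads are genome substrings at the configured depth", {
  g <- simulate_diploid_genome(1e5, 0.005, seed = 4)
  cfg <- read_sim_config(depth = 5, seed = 5)
  sim <- simulate_reads(g, cfg)
  expect_equal(nrow(sim$labels), 0)
  total_bases <- sum(nchar(sim$reads$seq1)) + sum(nchar(sim$reads$seq2))
  expect_lt(abs(total_bases / g$length - 5) / 5, 0.05)
  # error-free, violation-free reads occur verbatim in a haplotype
  some <- sim$reads[sample.int(nrow(sim$reads), 30), ]
  hits <- vapply(some$seq1, function(s) {
    grepl(s, g$hap_a, fixed = TRUE) || grepl(s, g$hap_b, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  # mate 2 is reverse-complemented
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(some$seq2)))
  hits2 <- vapply(rc2, function(s) {
    grepl(s, g$hap_a, fixed = TRUE) || grepl(s, g$hap_b, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits2))
})

test_that("violation planting labels are sound and saturating rates label all", {
  g <- simulate_diploid_genome(5e4, 0, seed = 6)
  cfg <- read_sim_config(depth = 1, violation_rates = c(polyA = 1), seed = 7)
  sim <- simulate_reads(g, cfg)
  expect_setequal(sim$labels$id, sim$reads$id)
  expect_true(all(sim$labels$class == "polyA"))
  # planted poly-A tails are directly visible in the emitted reads
  a_frac <- vapply(sim$reads$seq1, function(s) {
    mean(strsplit(s, "")[[1]] == "A")
  }, numeric(1))
  expect_true(all(a_frac >= 0.80))

  cfg2 <- read_sim_config(depth = 1, violation_rates = c(highN = 0.5, lowQ = 0.5),
                          seed = 8)
  sim2 <- simulate_reads(g, cfg2)
  expect_setequal(sim2$labels$id, sim2$reads$id)
  byclass <- split(sim2$labels$id, sim2$labels$class)
  # labels are disjoint by construction
  expect_length(intersect(byclass$highN, byclass$lowQ), 0)
  nfrac <- count_n <- vapply(sim2$reads$seq1, function(s) {
    lengths(regmatches(s, gregexpr("N", s)))
  }, integer(1))
  expect_true(all(nfrac[sim2$reads$id %in% byclass$highN] > 5))
})

test_that("mitochondrial pair has the configured divergence and copy ratio", {
  mp <- simulate_mito_pair(16000, divergence = 0.2, copy_ratio = 10,
                           depth_f = 30, seed = 9)
  ident <- 1 - str_hamming(mp$mito_f, mp$mito_m) / 16000
  expect_lt(abs(ident - 0.8), 0.01)
  n_f <- sum(mp$reads$source == "F")
  n_m <- sum(mp$reads$source == "M")
  expect_lt(abs(n_f / n_m - 10) / 10, 0.2)
  # reads wrap the circular origin
  doubled_f <- paste0(mp$mito_f, mp$mito_f)
  wrap <- mp$reads[mp$reads$source == "F" & mp$reads$true_pos > 16000 - 100, ]
  expect_gt(nrow(wrap), 0)
  fwd <- wrap[wrap$strand == "+", ]
  expect_true(all(substring(doubled_f, fwd$true_pos + 1,
                            fwd$true_pos + 100) == fwd$seq))

  none <- simulate_mito_pair(16000, 0.2, 10, depth_f = 0, seed = 10)
  expect_equal(nrow(none$reads), 0)
  expect_error(simulate_mito_pair(50, 0.2, 10, 5), "degenerate")
})

test_that("CEG match tables realize the requested completeness classes", {
  tab <- simulate_ceg_table(248, 39, 68, seed = 11)
  expect_equal(nrow(tab), 107)
  expect_equal(sum(tab$aligned_fraction > 0.90), 39)
  expect_equal(sum(tab$aligned_fraction <= 0.90), 68)
  expect_true(all(tab$aligned_fraction > 0 & tab$aligned_fraction <= 1))

  all_complete <- simulate_ceg_table(10, 10, 0, seed = 12)
  expect_true(all(all_complete$aligned_fraction > 0.90))
  expect_equal(nrow(simulate_ceg_table(10, 0, 0, seed = 13)), 0)
  expect_error(simulate_ceg_table(10, 8, 5, seed = 1), "exceed")
})

test_that("GO tables plant enrichment where requested and are reproducible", {
  null_tab <- simulate_go_tables(50, 3000, 3000, seed = 14)
  expect_identical(null_tab, simulate_go_tables(50, 3000, 3000, seed = 14))
  expect_length(null_tab$enriched, 0)

  enr <- simulate_go_tables(50, 3000, 3000,
                            enriched_terms = c("GO:0000007" = 8), seed = 15)
  diff_prop <- enr$table_a$count / 3000 - enr$table_b$count / 3000
  expect_equal(enr$table_a$term[which.max(diff_prop)], "GO:0000007")
})
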