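mk_rec <- function(query, qlen, qs, qe, rs, re, ident = 99, ev = 1e-30,
                   strand = "+") {
  data.frame(query = query, query_length = qlen, ref = "mt",
             qstart = qs, qend = qe, rstart = rs, rend = re,
             strand = strand, identity = ident, evalue = ev)
}

test_that("alignment filtering applies the e-value, identity and coverage gates", {
  recs <- rbind(
    mk_rec("a", 1000, 0, 950, 0, 950, ident = 89.9),          # identity fails
    mk_rec("b", 1000, 0, 900, 100, 1000, ident = 95),         # coverage == 0.90
    mk_rec("c", 1000, 0, 950, 0, 950, ev = 1e-5),             # e-value fails
    mk_rec("d", 1000, 0, 500, 0, 500),                        # coverage 0.50
    mk_rec("d", 1000, 450, 1000, 500, 1050)                   # union -> 1.0
  )
  kept <- filter_mito_alignments(recs)
  expect_setequal(unique(kept$query), c("b", "d"))
  # per-contig accumulated coverage keeps both of d's records
  expect_equal(sum(kept$query == "d"), 2)
})

test_that("reference coverage is the union fraction with contig count", {
  full <- reference_coverage(mk_rec("a", 1000, 0, 1000, 0, 16000), 16000)
  expect_equal(full$fraction, 1)
  expect_equal(full$n_contigs, 1)

  two <- reference_coverage(rbind(mk_rec("a", 1, 0, 1, 0, 8000),
                                  mk_rec("b", 1, 0, 1, 4000, 12000)), 16000)
  expect_equal(two$fraction, 0.75)
  expect_equal(two$n_contigs, 2)

  expect_equal(reference_coverage(mk_rec("a", 1, 0, 1, 0, 1)[0, ], 16000)$fraction, 0)
})

test_that("greedy tiling covers planted fragmentations and reports holes", {
  # contigs fragment the reference with ~10% overlaps
  L <- 16000
  starts <- seq(0, L - 1600, by = 1440)  # 1600-bp pieces, 160-bp overlap
  recs <- mk_rec(sprintf("c%02d", seq_along(starts)), 1600, 0, 1600,
                 starts, pmin(starts + 1600, L))
  tp <- build_tiling(recs, L)
  expect_gte(tp$covered_fraction, 0.99)
  expect_equal(nrow(tp$segments), length(starts))  # each used exactly once

  # duplicate records: the copy is skipped as contained
  dup <- rbind(mk_rec("x", 1000, 0, 1000, 0, 1000),
               mk_rec("x2", 1000, 0, 1000, 0, 1000))
  tp2 <- build_tiling(dup, 1000)
  expect_equal(nrow(tp2$segments), 1)

  # a hole in the records appears as exactly that gap
  holey <- rbind(mk_rec("l", 5000, 0, 5000, 0, 5000),
                 mk_rec("r", 6000, 0, 6000, 6000, 12000))
  tp3 <- build_tiling(holey, 12000)
  expect_equal(as.data.frame(tp3$gaps), data.frame(start = 5000, end = 6000))

  # with unlimited gap jumping the tiling matches the plain union coverage
  set.seed(501)
  rnd <- mk_rec(sprintf("r%02d", 1:20), 2000, 0, 2000,
                sample(0:14000, 20), 0)
  rnd$rend <- pmin(rnd$rstart + sample(200:2000, 20, replace = TRUE), 16000)
  rnd <- rnd[rnd$rend - rnd$rstart >= 100, ]
  tp4 <- build_tiling(rnd, 16000, max_gap = Inf, min_len = 100)
  expect_equal(tp4$covered_fraction, reference_coverage(rnd, 16000)$fraction)
})

test_that("minimal mapping recovers true origins, circularity and ambiguity", {
  mp <- simulate_mito_pair(6000, divergence = 0, copy_ratio = 1, depth_f = 8,
                           seed = 502)
  f_reads <- mp$reads[mp$reads$source == "F", ]
  pl <- map_reads_minimal(f_reads, mp$mito_f)
  expect_true(all(pl$mapped))
  expect_equal(pl$pos, f_reads$true_pos)
  expect_equal(pl$strand, f_reads$strand)
  # reads spanning the origin mapped with modular coordinates
  expect_gt(sum(f_reads$true_pos > 6000 - 100), 0)

  # unrelated reads stay unmapped (no exact seed exists, w.h.p.)
  set.seed(503)
  junk <- vapply(1:50, function(i) rand_dna(100), character(1))
  plj <- map_reads_minimal(junk, mp$mito_f)
  expect_false(any(plj$mapped))

  # a read with two equally good placements is ambiguous
  rep_ref <- paste0(strrep("ACGT", 75), rand_dna(400), strrep("ACGT", 75),
                    rand_dna(400))
  dup_read <- strrep("ACGT", 25)
  pla <- map_reads_minimal(c(r1 = dup_read), rep_ref)
  expect_false(pla$mapped[1])
})

test_that("depth profiles count every placed base and find planted low spots", {
  mp <- simulate_mito_pair(8000, divergence = 0, copy_ratio = 1, depth_f = 50,
                           seed = 504)
  f_reads <- mp$reads[mp$reads$source == "F", ]
  pl <- map_reads_minimal(f_reads, mp$mito_f)
  dp <- depth_profile(pl, 8000)
  expect_lt(abs(dp$mean_depth - 50) / 50, 0.05)
  expect_gt(dp$min_window$depth, 0)
  # coverage-depth consistency under modular arithmetic
  expect_equal(sum(dp$depth), sum(pl$length[pl$mapped]))

  none <- depth_profile(pl[0, ], 8000)
  expect_true(all(none$depth == 0))

  # remove reads starting inside [3000, 3500): min window falls in the hole
  keep <- f_reads[!(f_reads$true_pos >= 2900 & f_reads$true_pos < 3500), ]
  dp2 <- depth_profile(map_reads_minimal(keep, mp$mito_f), 8000)
  expect_true(dp2$min_window$start >= 2950 && dp2$min_window$start < 3500)
})

test_that("SNV calling recovers planted variants and applies its gates", {
  mp <- simulate_mito_pair(8000, divergence = 20 / 8000, copy_ratio = 1,
                           depth_f = 50, seed = 505, error_rate = 0.001)
  m_reads <- mp$reads[mp$reads$source == "M", ]
  pl <- map_reads_minimal(m_reads, mp$mito_f)
  v <- call_snvs(pl, mp$mito_f)
  truth <- mp$variant_positions
  expect_gte(mean(truth %in% v$pos), 0.95)   # recall
  expect_gte(mean(v$pos %in% truth), 0.95)   # precision

  # reads identical to the reference yield no variants
  f_reads <- mp$reads[mp$reads$source == "F", ]
  v0 <- call_snvs(map_reads_minimal(f_reads, mp$mito_f), mp$mito_f)
  expect_equal(nrow(v0), 0)

  # depth gate: 9 alternate reads at depth 9 are not enough
  ref <- rand_dna(300)
  alt_read <- substr(ref, 101, 200)
  substr(alt_read, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                      substr(alt_read, 50, 50))[1]
  mk_pl <- function(n) tibble::tibble(
    id = sprintf("x%d", seq_len(n)), mapped = TRUE, pos = 100L,
    strand = "+", mismatches = 1L, length = 100L, aligned_seq = alt_read)
  expect_equal(nrow(call_snvs(mk_pl(9), ref)), 0)
  expect_equal(nrow(call_snvs(mk_pl(10), ref)), 1)
})

test_that("variant density ranks genes and partitions coding space", {
  genes <- data.frame(gene = c("ND4", "CYTB", "CR"),
                      start = c(0, 2000, 4000),
                      end = c(1000, 3000, 4500),
                      coding = c(TRUE, TRUE, FALSE))
  vars <- tibble::tibble(pos = c(10L, 20L, 30L, 2100L, 4100L, 5000L))
  gv <- variant_density_by_gene(vars, genes)
  expect_equal(gv$per_gene$gene[1], "ND4")  # densest gene first
  expect_equal(gv$n_coding, 4)
  expect_equal(gv$n_noncoding, 1)
  expect_equal(gv$n_intergenic, 1)

  # closed-form densities: 1 variant in 100 bp vs 1 in 1000 bp
  g2 <- data.frame(gene = c("small", "big"), start = c(0, 1000),
                   end = c(100, 2000), coding = TRUE)
  gv2 <- variant_density_by_gene(tibble::tibble(pos = c(50L, 1500L)), g2)
  expect_equal(gv2$per_gene$pct_per_bp,
               c(1, 0.1)[match(gv2$per_gene$gene, c("small", "big"))])

  gv0 <- variant_density_by_gene(tibble::tibble(pos = integer(0)), genes)
  expect_true(all(gv0$per_gene$n_variants == 0))
})

test_that("minimal VCF output carries positions, alleles and depths", {
  v <- tibble::tibble(pos = c(9L, 99L), ref = c("A", "C"), alt = c("G", "T"),
                      depth = c(30L, 42L), alt_count = c(12L, 40L))
  path <- tempfile(fileext = ".vcf")
  write_minimal_vcf(v, "mt", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[2], "10")  # 1-based POS
  expect_equal(f[4], "A")
  expect_equal(f[8], "DP=30;AD=12")
  unlink(path)
})
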