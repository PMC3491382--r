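# minimal observation-table constructor for recalibration tests
robs <- function(base, ref_base, template_strand = "+", mate = "first",
                 qual = 30L, cycle = 7L, contig = "chr1",
                 pos = seq_along(base) - 1L) {
  n <- length(base)
  data.frame(read_id = paste0("r", seq_len(n)), contig = contig,
             pos = pos, base = base,
             qual = rep_len(as.integer(qual), n),
             cycle = rep_len(as.integer(cycle), n),
             template_strand = rep_len(template_strand, n),
             mate = rep_len(mate, n), mapq = 60L,
             strand = "+", ref_base = ref_base,
             stringsAsFactors = FALSE)
}

test_that("empirical quality is Laplace-smoothed and capped", {
  expect_equal(empirical_quality(1000, 10), -10 * log10(11 / 1002),
               tolerance = 1e-12)
  expect_equal(round(empirical_quality(1000, 10), 1), 19.6)
  expect_equal(empirical_quality(0, 0), -10 * log10(1 / 2),
               tolerance = 1e-12)
  expect_equal(empirical_quality(1e7, 0), 60)
})

test_that("mismatch tabulation excludes the bisulfite fifth base", {
  # forward template, T at reference C: neither match nor mismatch
  tab <- build_recal_table(robs("T", "C", "+"))
  expect_identical(nrow(as.data.frame(tab)), 0L)

  # reverse template, A at reference G (the second-end mirror): excluded
  tab2 <- build_recal_table(robs("A", "G", "-", mate = "second"))
  expect_identical(nrow(as.data.frame(tab2)), 0L)

  # a genuine mismatch increments its (R, cycle) bin
  tab3 <- build_recal_table(robs("G", "A", "+", qual = 30, cycle = 7))
  expect_identical(tab3$n, 1L)
  expect_identical(tab3$mismatch, 1L)
  expect_identical(tab3$qual, 30L)
  expect_identical(tab3$cycle, 7L)

  # known polymorphic sites are skipped entirely
  ks <- structure(list(keys = "chr1:1", alt = list("G"),
                       af = list(numeric(0))), class = "known_sites")
  tab4 <- build_recal_table(robs("G", "A", "+"), known_sites = ks)
  expect_identical(nrow(as.data.frame(tab4)), 0L)

  # matched bases count as observations without mismatches
  tab5 <- build_recal_table(robs(c("A", "A", "G"), c("A", "A", "A"), "+"))
  expect_identical(tab5$n, 3L)
  expect_identical(tab5$mismatch, 1L)

  # increments at reference cytosines equal the count of non-T bases
  obs <- robs(c("C", "T", "C", "G", "T"), rep("C", 5), "+")
  tab6 <- build_recal_table(obs)
  expect_identical(sum(tab6$n), sum(obs$base != "T"))
})

test_that("recalibration replaces qualities by bin, with fallback and
           X-base protection", {
  obs <- robs(c("A", "G", "T"), c("A", "A", "C"), "+",
              qual = 30, cycle = c(7, 7, 7))
  # a big synthetic table: bin (30,7) has 1% mismatches
  tab <- structure(
    data.frame(qual = 30L, cycle = 7L, mate = "first",
               n = 10000L, mismatch = 100L, stringsAsFactors = FALSE),
    marginal = data.frame(qual = 30L, mate = "first", n = 10000L,
                          mismatch = 100L, stringsAsFactors = FALSE),
    min_bin_count = 100L, class = c("recal_table", "data.frame"))
  rec <- apply_recalibration(obs, tab)
  expect_identical(rec$qual[1:2], c(20L, 20L))     # ~ -10log10(0.01)
  expect_identical(rec$qual[3], 30L)               # X base untouched
  expect_identical(rec$qual_reported, c(30L, 30L, 30L))
  expect_identical(rec$base, obs$base)             # identities unchanged

  # below min_bin_count: the per-quality marginal takes over
  tab_thin <- structure(
    data.frame(qual = 30L, cycle = 7L, mate = "first", n = 10L,
               mismatch = 5L, stringsAsFactors = FALSE),
    marginal = data.frame(qual = 30L, mate = "first", n = 5000L,
                          mismatch = 500L, stringsAsFactors = FALSE),
    min_bin_count = 100L, class = c("recal_table", "data.frame"))
  rec2 <- apply_recalibration(obs, tab_thin)
  expect_identical(rec2$qual[1], 10L)              # marginal 10% errors
  # absent from table and marginal: reported value kept
  obs3 <- robs("A", "A", "+", qual = 35)
  expect_identical(apply_recalibration(obs3, tab)$qual, 35L)
})

test_that("orientation normalization maps SEQ, cycles and template
           strands correctly", {
  reads <- data.frame(
    read_id = c("f1", "r1", "m2f", "m2r"),
    contig = "chr1",
    pos = c(0L, 0L, 10L, 10L),
    strand = c("+", "-", "+", "-"),
    mapq = 60L,
    cigar = c("4M", "4M", "4M", "2S2M"),
    seq = c("ACGT", "ACGT", "TTAA", "GGCC"),
    qual = c("IIII", "&III", "IIII", "II!I"),
    paired = c(FALSE, FALSE, TRUE, TRUE),
    proper_pair = c(FALSE, FALSE, TRUE, TRUE),
    mate = c("first", "first", "second", "second"),
    duplicate = FALSE, multimapped = FALSE,
    stringsAsFactors = FALSE)
  obs <- normalize_read_orientation(reads)

  f1 <- obs[obs$read_id == "f1", ]
  expect_identical(f1$base, c("A", "C", "G", "T"))  # bases unchanged
  expect_identical(f1$cycle, 1:4)
  expect_identical(f1$pos, 0:3)
  expect_true(all(f1$template_strand == "+"))

  # reverse-aligned first end: template "-", cycles reversed
  r1 <- obs[obs$read_id == "r1", ]
  expect_true(all(r1$template_strand == "-"))
  expect_identical(r1$cycle, 4:1)
  expect_identical(r1$qual[1], utf8ToInt("&") - 33L)

  # forward-aligned second end: mate 1 was reverse -> template "-"
  m2f <- obs[obs$read_id == "m2f", ]
  expect_true(all(m2f$template_strand == "-"))
  # reverse-aligned second end: template "+", like its mate
  m2r <- obs[obs$read_id == "m2r", ]
  expect_true(all(m2r$template_strand == "+"))

  # soft-clipped bases emit no observations; aligned part starts at pos
  expect_identical(nrow(m2r), 2L)
  expect_identical(m2r$pos, c(10L, 11L))
  expect_identical(m2r$base, c("C", "C"))
  expect_identical(m2r$cycle, c(2L, 1L))   # clip consumed cycles 4:3

  # missing CIGAR: skipped with a warning
  reads$cigar[1] <- "*"
  expect_warning(obs2 <- normalize_read_orientation(reads), "CIGAR")
  expect_false("f1" %in% obs2$read_id)
})

test_that("miscalibrated simulated reads are recalibrated to the true
           error rate", {
  # reported Q30 but true error 1% (Q20)
  p <- sim_params(genome_length = 20000L, coverage = 15,
                  error_profile = 0.01, miscalibration = 10,
                  snp_rate = 1e-3, seed = 11)
  ts <- simulate_bsseq(p)
  sam <- write_sam(ts$reads, ts$genome$reference,
                   tempfile(fileext = ".sam"))
  genome <- ts$genome$reference
  reads <- read_alignments(sam)
  obs <- normalize_read_orientation(reads)
  obs <- add_ref_base(obs, genome)
  expect_true(all(obs$qual == 30L))

  # exclude true SNP sites via the truth VCF, as the tool would dbSNP
  ks <- structure(list(keys = paste0("sim1:", ts$genome$snps$pos + 1L),
                       alt = as.list(rep("N", nrow(ts$genome$snps))),
                       af = rep(list(numeric(0)), nrow(ts$genome$snps))),
                  class = "known_sites")
  tab <- build_recal_table(obs, ks)
  big <- tab[tab$n >= 1000, ]
  expect_gt(nrow(big), 50)
  eq <- empirical_quality(big$n, big$mismatch)
  # pooled estimate recovers the true Q20; individual bins wander by
  # binomial sampling but stay close
  pooled <- empirical_quality(sum(big$n), sum(big$mismatch))
  expect_lt(abs(pooled - 20), 1)
  expect_lt(abs(mean(eq) - 20), 1)
  expect_true(all(abs(eq - 20) <= 3))

  rec <- apply_recalibration(obs, tab)
  xb <- methcall:::is_x_base(obs)
  expect_true(all(rec$qual[xb] == 30L))
  expect_lt(abs(mean(rec$qual[!xb]) - 20), 1)
  expect_true(all(abs(rec$qual[!xb] - 20) <= 3))
})

test_that("recalibrate_sam rewrites qualities but not bases", {
  p <- sim_params(genome_length = 3000L, coverage = 8,
                  error_profile = 0.01, miscalibration = 10, seed = 3)
  ts <- simulate_bsseq(p, dir = tempfile("recal"))
  out <- tempfile(fileext = ".sam")
  r <- recalibrate_sam(ts$paths[["sam"]], ts$paths[["fasta"]], out)
  expect_true(file.exists(out))
  before <- read_alignments(ts$paths[["sam"]])
  after <- read_alignments(out)
  o1 <- before[order(before$read_id), ]
  o2 <- after[order(after$read_id), ]
  expect_identical(o1$seq, o2$seq)
  expect_false(identical(o1$qual, o2$qual))
  tsv <- tempfile(fileext = ".tsv")
  write_recal_table(r$table, tsv)
  expect_true(all(c("qual", "cycle", "empirical_quality") %in%
                    names(utils::read.table(tsv, header = TRUE))))
})
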