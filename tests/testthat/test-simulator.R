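test_that("zero SNP rate reproduces the reference exactly", {
  p <- sim_params(genome_length = 5000L, snp_rate = 0, seed = 2)
  g <- simulate_genome(p)
  expect_identical(g$hap1, g$ref_chars)
  expect_identical(g$hap2, g$ref_chars)
  expect_identical(nrow(g$snps), 0L)
})

test_that("SNP count and composition follow the requested rates", {
  p <- sim_params(genome_length = 200000L, snp_rate = 1e-3,
                  het_fraction = 0.67, seed = 4)
  g <- simulate_genome(p)
  n <- nrow(g$snps)
  expected <- p$genome_length * p$snp_rate
  expect_lt(abs(n - expected), 3 * sqrt(expected) + 1)
  # het fraction within binomial error
  ph <- mean(g$snps$het)
  expect_lt(abs(ph - 0.67), 3 * sqrt(0.67 * 0.33 / n))
  # transitions outnumber transversions (titv 2, CpG-boosted)
  ts <- is_transition(g$snps$ref, ifelse(g$snps$a1 != g$snps$ref,
                                         g$snps$a1, g$snps$a2))
  expect_gt(mean(ts), 0.5)
  # haplotypes differ from the reference exactly at SNP positions
  diff1 <- which(g$hap1 != g$ref_chars) - 1L
  expect_true(all(diff1 %in% g$snps$pos))
})

test_that("same seed gives byte-identical outputs, different seeds differ", {
  p <- sim_params(genome_length = 4000L, coverage = 5, seed = 99)
  d1 <- tempfile("s1"); d2 <- tempfile("s2"); d3 <- tempfile("s3")
  simulate_bsseq(p, d1)
  simulate_bsseq(p, d2)
  for (f in c("reference.fa", "reads.sam", "truth.vcf",
              "truth_methylation.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  p3 <- sim_params(genome_length = 4000L, coverage = 5, seed = 100)
  simulate_bsseq(p3, d3)
  expect_false(identical(readLines(file.path(d1, "reads.sam")),
                         readLines(file.path(d3, "reads.sam"))))
})

test_that("methylation truth respects contexts and shares CpG dyads", {
  p <- sim_params(genome_length = 30000L, snp_rate = 0, seed = 6)
  g <- simulate_genome(p)
  meth <- assign_methylation(g, p)
  expect_true(all(meth$beta >= 0 & meth$beta <= 1))
  # forward-strand records sit on Cs, reverse on Gs
  expect_true(all(g$ref_chars[meth$pos[meth$strand == "+"] + 1L] == "C"))
  expect_true(all(g$ref_chars[meth$pos[meth$strand == "-"] + 1L] == "G"))
  # CpG dyads share one beta across strands
  cg_f <- meth[meth$strand == "+" & meth$context == "CG", ]
  partner <- match(paste0(cg_f$pos + 1L, ":-"),
                   paste0(meth$pos, ":", meth$strand))
  ok <- !is.na(partner)
  expect_gt(sum(ok), 100)
  expect_equal(meth$beta[partner[ok]], cg_f$beta[ok])
  # CH methylation is near its nominal mean
  ch <- meth$beta[meth$context == "CH"]
  expect_lt(abs(mean(ch) - p$beta_ch_mean), 0.005)
  # CpG methylation is bimodal: mass near both ends
  cg <- meth$beta[meth$context == "CG"]
  expect_gt(mean(cg > 0.6), 0.5)
  expect_gt(mean(cg < 0.2), 0.2)
})

test_that("conversion chemistry behaves at the beta extremes", {
  base_p <- list(genome_length = 10000L, coverage = 10, snp_rate = 0,
                 error_profile = 0, alpha = 0, gamma = 0, seed = 13)
  # beta forced to 0: every template-strand C reads as T
  p0 <- do.call(sim_params, c(base_p, list(
    beta_cg_mixture = list(weight = 1, shape1a = 1e-9, shape2a = 1,
                           shape1b = 1, shape2b = 1),
    beta_ch_mean = 0)))
  ts0 <- simulate_bsseq(p0)
  obs0 <- normalize_read_orientation(ts0$reads)
  obs0 <- add_ref_base(obs0, ts0$genome$reference)
  fwd_c <- obs0$template_strand == "+" & obs0$ref_base == "C"
  expect_true(all(obs0$base[fwd_c] == "T"))
  rev_g <- obs0$template_strand == "-" & obs0$ref_base == "G"
  expect_true(all(obs0$base[rev_g] == "A"))
  # opposite strand untouched
  opp_c <- obs0$template_strand == "-" & obs0$ref_base == "C"
  expect_true(all(obs0$base[opp_c] == "C"))

  # beta forced to 1, gamma 0: every template-strand C stays C
  p1 <- do.call(sim_params, c(base_p, list(
    beta_cg_mixture = list(weight = 1, shape1a = 1, shape2a = 1e-9,
                           shape1b = 1, shape2b = 1),
    beta_ch_mean = 1)))
  ts1 <- simulate_bsseq(p1)
  obs1 <- normalize_read_orientation(ts1$reads)
  obs1 <- add_ref_base(obs1, ts1$genome$reference)
  fwd_c1 <- obs1$template_strand == "+" & obs1$ref_base == "C"
  expect_true(all(obs1$base[fwd_c1] == "C"))
})

test_that("underconversion leaves alpha of unmethylated Cs unconverted", {
  p <- do.call(sim_params, list(
    genome_length = 20000L, coverage = 20, snp_rate = 0,
    error_profile = 0, alpha = 0.01, gamma = 0, seed = 14,
    beta_cg_mixture = list(weight = 1, shape1a = 1e-9, shape2a = 1,
                           shape1b = 1, shape2b = 1),
    beta_ch_mean = 0))
  ts <- simulate_bsseq(p)
  obs <- normalize_read_orientation(ts$reads)
  obs <- add_ref_base(obs, ts$genome$reference)
  fwd_c <- obs$template_strand == "+" & obs$ref_base == "C"
  n <- sum(fwd_c)
  frac_c <- mean(obs$base[fwd_c] == "C")
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(frac_c - 0.01), 3 * se)
})

test_that("coverage is near target and both strands/haplotypes sampled", {
  p <- sim_params(genome_length = 20000L, coverage = 25, seed = 15)
  ts <- simulate_bsseq(p)
  obs <- normalize_read_orientation(ts$reads)
  interior <- obs$pos >= 1000 & obs$pos < 19000
  depth <- table(obs$pos[interior])
  expect_lt(abs(mean(depth) - 25), 3 * sqrt(25) / sqrt(1))
  expect_gt(mean(ts$reads$template_strand == "+"), 0.45)
  expect_lt(mean(ts$reads$template_strand == "+"), 0.55)
  expect_gt(mean(ts$reads$hap == 1), 0.45)
})

test_that("paired simulation flags mates consistently", {
  p <- sim_params(genome_length = 10000L, coverage = 10, paired = TRUE,
                  seed = 21)
  ts <- simulate_bsseq(p)
  reads <- ts$reads
  expect_true(all(bitwAnd(reads$flag, 1L) > 0))
  expect_true(all(bitwAnd(reads$flag, 2L) > 0))
  first <- bitwAnd(reads$flag, 64L) > 0
  second <- bitwAnd(reads$flag, 128L) > 0
  expect_identical(sum(first), sum(second))
  # mates of one fragment share the template strand
  sp <- split(reads$template_strand, reads$read_id)
  expect_true(all(vapply(sp, function(x) length(unique(x)) == 1,
                         logical(1))))
  # in forward space both mates of a "+" template show C->T only:
  obs <- normalize_read_orientation(ts$reads)
  obs <- add_ref_base(obs, ts$genome$reference)
  plus <- obs[obs$template_strand == "+" & obs$ref_base == "C", ]
  expect_gt(nrow(plus), 100)
  expect_true(all(plus$base[plus$mate == "second"] %in%
                    c("C", "T", "A", "G")))
  # second-end template assignment mirrors the first end
  m2 <- reads[second, ]
  expect_true(all((bitwAnd(m2$flag, 16L) > 0) ==
                    (m2$template_strand == "+")))
})

test_that("downsampling follows the z = m*n/N rule", {
  obs <- obs_df(base = rep("A", 40))
  expect_identical(nrow(downsample_pileup(obs, n = 8, N = 32, seed = 1)),
                   10L)
  # n == N: unchanged
  expect_identical(nrow(downsample_pileup(obs, n = 32, N = 32)), 40L)
  # cannot exceed available reads
  small <- obs_df(base = rep("A", 3))
  expect_identical(nrow(downsample_pileup(small, n = 30, N = 32)), 3L)
  # whole-table version: per-locus depths scale by n/N
  p <- sim_params(genome_length = 10000L, coverage = 24, seed = 16)
  ts <- simulate_bsseq(p)
  obs2 <- normalize_read_orientation(ts$reads)
  N <- nrow(obs2) / p$genome_length
  ds <- downsample_observations(obs2, n = 6, N = N, seed = 3)
  ratio <- nrow(ds) / nrow(obs2)
  expect_lt(abs(ratio - 6 / N), 0.02)
  # per-locus: no locus exceeds its allowance
  d_orig <- table(obs2$pos)
  d_down <- table(ds$pos)
  common <- intersect(names(d_orig), names(d_down))
  z <- round(as.integer(d_orig[common]) * 6 / N)
  expect_true(all(as.integer(d_down[common]) <= pmax(z, 1)))
})
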