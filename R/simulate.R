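#' Simulation parameters
#'
#' Parameters of the directional bisulfite-seq read simulator. Defaults
#' describe a small human-like whole-genome experiment: 41% GC, SNPs at
#' 1/kb of which two thirds are heterozygous with a 2:1
#' transition:transversion ratio, bimodal CpG methylation (a 70:30
#' mixture of Beta(8,2) and Beta(1,20), i.e. mostly-methylated CpGs with
#' a low-methylation class), near-zero CpH methylation (Beta(1,99), mean
#' 0.01), 0.25% underconversion, 75 bp single-end reads at 30x with a
#' flat Q30 error profile.
#'
#' @param genome_length reference length in bp.
#' @param gc_content fraction G+C (default 0.41).
#' @param cpg_enrichment multiplicative adjustment to the probability of
#'   a G following a C (default 1: no adjustment of the i.i.d. base
#'   model).
#' @param snp_rate per-bp SNP probability (default 1e-3).
#' @param het_fraction fraction of SNPs heterozygous (default 0.67).
#' @param titv_ratio transition:transversion ratio for simulated alleles
#'   (default 2); transitions are further favoured 2-fold at CpG
#'   cytosines.
#' @param beta_cg_mixture CpG methylation distribution:
#'   `list(weight, shape1a, shape2a, shape1b, shape2b)` giving
#'   `weight`*Beta(a) + (1-weight)*Beta(b).
#' @param beta_ch_mean mean CpH methylation; drawn from
#'   Beta(1, 1/mean - 1) (default 0.01).
#' @param alpha,gamma under-/over-conversion rates used to generate reads
#'   (defaults 0.0025 and 0).
#' @param coverage mean read depth (default 30).
#' @param read_length read length in bp (default 75).
#' @param paired paired-end protocol (default FALSE).
#' @param fragment_length physical fragment size for paired mode
#'   (default 200).
#' @param error_profile per-cycle true base-call error rates, recycled to
#'   `read_length` (default 0.001, i.e. Q30).
#' @param error_sd per-base gaussian jitter of the true error rate
#'   (default 0).
#' @param miscalibration phred offset added to reported qualities
#'   relative to the true error rate (default 0; +10 means reported
#'   qualities are 10 phred optimistic).
#' @param seed integer seed; every simulation function is deterministic
#'   given it.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100000L, gc_content = 0.41,
                       cpg_enrichment = 1.0, snp_rate = 1e-3,
                       het_fraction = 0.67, titv_ratio = 2.0,
                       beta_cg_mixture = list(weight = 0.7, shape1a = 8,
                                              shape2a = 2, shape1b = 1,
                                              shape2b = 20),
                       beta_ch_mean = 0.01, alpha = 0.0025, gamma = 0.0,
                       coverage = 30, read_length = 75L, paired = FALSE,
                       fragment_length = 200L,
                       error_profile = 0.001, error_sd = 0,
                       miscalibration = 0, seed = 1L) {
  stopifnot(genome_length >= read_length, gc_content > 0, gc_content < 1,
            snp_rate >= 0, snp_rate <= 1, het_fraction >= 0,
            het_fraction <= 1, alpha >= 0, alpha <= 1, gamma >= 0,
            gamma <= 1, coverage > 0, read_length > 0)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, cpg_enrichment = cpg_enrichment,
                 snp_rate = snp_rate, het_fraction = het_fraction,
                 titv_ratio = titv_ratio, beta_cg_mixture = beta_cg_mixture,
                 beta_ch_mean = beta_ch_mean, alpha = alpha, gamma = gamma,
                 coverage = coverage, read_length = as.integer(read_length),
                 paired = isTRUE(paired),
                 fragment_length = as.integer(fragment_length),
                 error_profile = error_profile, error_sd = error_sd,
                 miscalibration = miscalibration, seed = as.integer(seed)),
            class = "sim_params")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate a reference and a diploid sample genome
#'
#' Draws a reference sequence (i.i.d. bases at the requested GC content,
#' with an optional first-order CpG adjustment), then plants SNPs at
#' `snp_rate`: heterozygous with probability `het_fraction`, alternate
#' alleles transition-biased per `titv_ratio` and additionally
#' transition-favoured at CpG cytosines (mimicking deamination of
#' methylated CpGs, the dominant source of C>T variants).
#'
#' @param p [sim_params()].
#' @param contig contig name (default "sim1").
#' @return list of class `sim_genome`: `reference` (DNAStringSet), `hap1`,
#'   `hap2` (character vectors of bases), `snps` (data.frame: `contig`,
#'   `pos` 0-based, `ref`, `a1`, `a2`, `genotype`, `het`), `contig`.
#' @export
simulate_genome <- function(p = sim_params(), contig = "sim1") {
  set.seed(p$seed)
  L <- p$genome_length
  probs <- c(A = (1 - p$gc_content) / 2, C = p$gc_content / 2,
             G = p$gc_content / 2, T = (1 - p$gc_content) / 2)
  ref <- sample(BASES, L, replace = TRUE, prob = probs[BASES])
  if (p$cpg_enrichment != 1) {
    # one vectorized pass: re-draw bases following a C from the
    # CpG-adjusted conditional distribution
    after_c <- which(ref[-L] == "C") + 1L
    q <- probs
    q["G"] <- q["G"] * p$cpg_enrichment
    q <- q / sum(q)
    ref[after_c] <- sample(BASES, length(after_c), replace = TRUE,
                           prob = q[BASES])
  }

  is_snp <- stats::runif(L) < p$snp_rate
  idx <- which(is_snp)
  n <- length(idx)
  h1 <- ref; h2 <- ref
  snps <- data.frame(contig = character(0), pos = integer(0),
                     ref = character(0), a1 = character(0),
                     a2 = character(0), genotype = character(0),
                     het = logical(0), stringsAsFactors = FALSE)
  if (n > 0) {
    refb <- ref[idx]
    # CpG cytosines: C followed by G, or G preceded by C
    cpg <- (refb == "C" & c(ref, "N")[idx + 1L] == "G") |
      (refb == "G" & c("N", ref)[idx] == "C")
    ts_w <- ifelse(cpg, 2 * p$titv_ratio, p$titv_ratio)
    alt <- character(n)
    for (i in seq_len(n)) {
      alts <- setdiff(BASES, refb[i])
      w <- ifelse(alts == TRANSITION[[refb[i]]], ts_w[i], 0.5)
      alt[i] <- sample(alts, 1, prob = w)
    }
    het <- stats::runif(n) < p$het_fraction
    which_hap <- stats::runif(n) < 0.5
    a1 <- ifelse(het, ifelse(which_hap, alt, refb), alt)
    a2 <- ifelse(het, ifelse(which_hap, refb, alt), alt)
    h1[idx] <- a1
    h2[idx] <- a2
    snps <- data.frame(contig = contig, pos = idx - 1L, ref = refb,
                       a1 = a1, a2 = a2,
                       genotype = genotype(a1, a2), het = het,
                       stringsAsFactors = FALSE)
  }
  reference <- Biostrings::DNAStringSet(paste0(ref, collapse = ""))
  names(reference) <- contig
  structure(list(reference = reference, ref_chars = ref,
                 hap1 = h1, hap2 = h2, snps = snps, contig = contig,
                 params = p),
            class = "sim_genome")
}

#' Assign true methylation levels to every cytosine
#'
#' Every cytosine present on either strand of either haplotype receives a
#' true methylation level beta drawn from the context-appropriate
#' distribution: the bimodal CpG mixture for CpG cytosines, a low-mean
#' Beta for everything else (CpH). The two cytosines of a CpG dyad share
#' one beta, as do the two haplotypes.
#'
#' @param g [simulate_genome()] output.
#' @param p [sim_params()].
#' @return data.frame of class `sim_methylation`: `contig`, `pos`
#'   (0-based position of the cytosine), `strand` ("+" for a C on the
#'   forward sample sequence, "-" for a G), `context` ("CG"/"CH"),
#'   `beta`.
#' @export
assign_methylation <- function(g, p = g$params) {
  set.seed(p$seed + 1L)
  L <- length(g$hap1)
  # a cytosine exists at (pos, +) if either haplotype has C there
  c_fwd <- g$hap1 == "C" | g$hap2 == "C"
  c_rev <- g$hap1 == "G" | g$hap2 == "G"

  # context from the haplotype carrying the C (hap1 when both do)
  nb_fwd <- function(h) c(h[-1L], "N")   # base following, forward strand
  nb_rev <- function(h) c("N", h[-L])    # base preceding, reverse strand
  next_fwd <- ifelse(g$hap1 == "C", nb_fwd(g$hap1), nb_fwd(g$hap2))
  next_rev <- ifelse(g$hap1 == "G", nb_rev(g$hap1), nb_rev(g$hap2))

  pos_f <- which(c_fwd)
  pos_r <- which(c_rev)
  cx_f <- ifelse(next_fwd[pos_f] == "G", "CG", "CH")
  cx_r <- ifelse(next_rev[pos_r] == "C", "CG", "CH")

  meth <- data.frame(
    contig = g$contig,
    pos = c(pos_f, pos_r) - 1L,
    strand = c(rep("+", length(pos_f)), rep("-", length(pos_r))),
    context = c(cx_f, cx_r),
    stringsAsFactors = FALSE)

  draw_cg <- function(n) {
    m <- p$beta_cg_mixture
    pick <- stats::runif(n) < m$weight
    ifelse(pick, stats::rbeta(n, m$shape1a, m$shape2a),
           stats::rbeta(n, m$shape1b, m$shape2b))
  }
  draw_ch <- function(n) {
    if (p$beta_ch_mean <= 0) return(rep(0, n))
    if (p$beta_ch_mean >= 1) return(rep(1, n))
    stats::rbeta(n, 1, 1 / p$beta_ch_mean - 1)
  }

  beta <- numeric(nrow(meth))
  cg <- meth$context == "CG"
  beta[cg] <- draw_cg(sum(cg))
  beta[!cg] <- draw_ch(sum(!cg))
  meth$beta <- beta

  # CpG dyads share beta across strands: a (pos, +) CG whose partner
  # (pos+1, -) exists copies its beta onto the partner
  fwd_cg <- meth$strand == "+" & meth$context == "CG"
  partner <- match(paste0(meth$pos[fwd_cg] + 1L, ":-"),
                   paste0(meth$pos, ":", meth$strand))
  ok <- !is.na(partner)
  meth$beta[partner[ok]] <- meth$beta[fwd_cg][ok]

  class(meth) <- c("sim_methylation", "data.frame")
  meth
}

#' Simulate directional bisulfite reads
#'
#' Samples fragments uniformly from both haplotypes and both template
#' strands (the directional protocol: only the two original
#' bisulfite-converted templates are sequenced). On each fragment the
#' template strand's cytosines are methylated with their locus beta and
#' then converted according to `alpha`/`gamma`; in reference-forward
#' space a converted forward-template C reads as T and a converted
#' reverse-template C as A at the corresponding G. Sequencing errors are
#' added per cycle from the error profile; reported qualities are offset
#' from the true error rate by `miscalibration` phred. Alignment
#' coordinates and flags are emitted directly (simulation bypasses
#' mapping), giving a coordinate-sortable SAM.
#'
#' @param g [simulate_genome()] output.
#' @param meth [assign_methylation()] output.
#' @param p [sim_params()].
#' @return data.frame of reads (SAM-like columns as accepted by
#'   [write_sam()]): `read_id`, `flag`, `contig`, `pos` (0-based),
#'   `mapq`, `cigar`, `seq`, `qual`, `rnext`, `pnext`, `tlen`, plus
#'   provenance columns `hap` and `template_strand`.
#' @export
simulate_reads <- function(g, meth, p = g$params) {
  stopifnot(p$coverage > 0)
  set.seed(p$seed + 2L)
  L <- p$genome_length
  rl <- p$read_length

  # per-position beta lookup tables, one per strand
  bplus <- rep(NA_real_, L); bminus <- rep(NA_real_, L)
  mp <- meth[meth$strand == "+", ]; bplus[mp$pos + 1L] <- mp$beta
  mm <- meth[meth$strand == "-", ]; bminus[mm$pos + 1L] <- mm$beta

  if (p$paired) {
    fl <- max(p$fragment_length, rl)
    n_frag <- ceiling(L * p$coverage / (2 * rl))
    fstart <- sample.int(L - fl + 1L, n_frag, replace = TRUE) - 1L
    hap <- sample(1:2, n_frag, replace = TRUE)
    tstrand <- sample(c("+", "-"), n_frag, replace = TRUE)
    # mate coordinates: template "+": mate1 fwd at start, mate2 rev at end
    #                   template "-": mate1 rev at end, mate2 fwd at start
    m1_rev <- tstrand == "-"
    start1 <- ifelse(m1_rev, fstart + fl - rl, fstart)
    start2 <- ifelse(m1_rev, fstart, fstart + fl - rl)
    reads <- data.frame(
      frag = rep(seq_len(n_frag), 2L),
      start = c(start1, start2),
      hap = rep(hap, 2L),
      template_strand = rep(tstrand, 2L),
      mate = rep(c("first", "second"), each = n_frag),
      aln_rev = c(m1_rev, !m1_rev),
      stringsAsFactors = FALSE)
    reads$flag <- 1L + 2L + 32L * (!reads$aln_rev) +
      16L * reads$aln_rev + 64L * (reads$mate == "first") +
      128L * (reads$mate == "second")
    reads$rnext <- "="
    other <- ifelse(reads$mate == "first", start2[reads$frag],
                    start1[reads$frag])
    reads$pnext <- other + 1L
    reads$tlen <- ifelse(reads$aln_rev, -fl, fl)
    reads$read_id <- paste0("frag", reads$frag)
  } else {
    n_reads <- ceiling(L * p$coverage / rl)
    reads <- data.frame(
      start = sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L,
      hap = sample(1:2, n_reads, replace = TRUE),
      template_strand = sample(c("+", "-"), n_reads, replace = TRUE),
      mate = "first", stringsAsFactors = FALSE)
    reads$aln_rev <- reads$template_strand == "-"
    reads$flag <- 16L * reads$aln_rev
    reads$rnext <- "*"; reads$pnext <- 0L; reads$tlen <- 0L
    reads$read_id <- paste0("read", seq_len(n_reads))
  }
  n <- nrow(reads)

  # haplotype bases for every read position (forward space)
  posmat <- rep(reads$start, each = rl) + seq_len(rl)  # 1-based genome pos
  hapsel <- rep(reads$hap, each = rl)
  chars <- ifelse(hapsel == 1L, g$hap1[posmat], g$hap2[posmat])

  # bisulfite conversion on the template strand
  tplus <- rep(reads$template_strand == "+", each = rl)
  u <- stats::runif(n * rl)
  conv <- stats::runif(n * rl)
  is_c <- tplus & chars == "C"
  is_g <- !tplus & chars == "G"
  b <- ifelse(is_c, bplus[posmat], ifelse(is_g, bminus[posmat], NA))
  b[is.na(b) & (is_c | is_g)] <- 0   # cytosine absent from truth: treat unmethylated
  methylated <- (is_c | is_g) & u < b
  converted <- (is_c | is_g) &
    ifelse(methylated, conv < p$gamma, conv >= p$alpha)
  chars[converted & is_c] <- "T"
  chars[converted & is_g] <- "A"

  # sequencing error per original cycle
  prof <- rep_len(p$error_profile, rl)
  offset <- rep(seq_len(rl), n)  # position within forward-space SEQ
  cyc <- ifelse(rep(reads$aln_rev, each = rl), rl - offset + 1L, offset)
  err_rate <- prof[cyc]
  if (p$error_sd > 0)
    err_rate <- pmin(0.75, pmax(1e-6,
      err_rate + stats::rnorm(n * rl, 0, p$error_sd)))
  is_err <- stats::runif(n * rl) < err_rate
  if (any(is_err)) {
    cur <- chars[is_err]
    pick <- ceiling(stats::runif(sum(is_err)) * 3)
    repl <- vapply(seq_along(cur), function(i)
      setdiff(BASES, cur[i])[pick[i]], character(1))
    chars[is_err] <- repl
  }

  # sequences: one string per read
  mat <- matrix(chars, nrow = rl)
  seqs <- do.call(paste0, as.data.frame(t(mat), stringsAsFactors = FALSE))

  # reported qualities per cycle (profile-based, miscalibration offset)
  qrep <- pmin(93L, pmax(2L,
    as.integer(round(-10 * log10(pmax(prof, 1e-9)))) +
      as.integer(round(p$miscalibration))))
  qual_fwd <- intToUtf8(qrep + 33L)
  qual_rev <- intToUtf8(rev(qrep) + 33L)
  quals <- ifelse(reads$aln_rev, qual_rev, qual_fwd)

  data.frame(read_id = reads$read_id, flag = reads$flag,
             contig = g$contig, pos = reads$start, mapq = 60L,
             cigar = paste0(rl, "M"), seq = seqs, qual = quals,
             rnext = reads$rnext, pnext = reads$pnext, tlen = reads$tlen,
             hap = reads$hap, template_strand = reads$template_strand,
             stringsAsFactors = FALSE)
}

#' Simulate a complete bisulfite-seq truth set
#'
#' Runs [simulate_genome()], [assign_methylation()] and
#' [simulate_reads()] and optionally writes the four artifacts: reference
#' FASTA (+ .fai), coordinate-sorted SAM, truth VCF of simulated
#' genotypes, and a per-cytosine truth methylation TSV.
#'
#' @param p [sim_params()].
#' @param dir output directory; `NULL` keeps everything in memory.
#' @return list of class `truth_set`: `genome`, `methylation`, `reads`,
#'   and (when written) `paths` (named: fasta, sam, vcf, methylation).
#' @export
simulate_bsseq <- function(p = sim_params(), dir = NULL) {
  g <- simulate_genome(p)
  meth <- assign_methylation(g, p)
  reads <- simulate_reads(g, meth, p)
  out <- structure(list(genome = g, methylation = meth, reads = reads,
                        params = p),
                   class = "truth_set")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "reference.fa"),
               sam = file.path(dir, "reads.sam"),
               vcf = file.path(dir, "truth.vcf"),
               methylation = file.path(dir, "truth_methylation.tsv"))
    write_reference(g$reference, paths[["fasta"]])
    write_sam(reads, g$reference, paths[["sam"]])
    write_truth_vcf(g$snps, paths[["vcf"]], p$seed)
    utils::write.table(meth, paths[["methylation"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

# truth VCF: simulated genotypes, sorted, 1-based
write_truth_vcf <- function(snps, path, seed = NA) {
  hdr <- c("##fileformat=VCFv4.1",
           "##source=methcall_simulator",
           if (!is.na(seed)) paste0("##methcall_seed=", seed),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTRUTH")
  snps <- snps[order(snps$contig, snps$pos), , drop = FALSE]
  lines <- vapply(seq_len(nrow(snps)), function(i) {
    al <- vcf_alleles(snps$ref[i], snps$genotype[i])
    paste(snps$contig[i], snps$pos[i] + 1L, ".", snps$ref[i], al$alt,
          ".", "PASS", ".", "GT", al$gt, sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("simulated bisulfite-seq truth set:\n")
  cat("  genome:", x$params$genome_length, "bp,",
      nrow(x$genome$snps), "SNPs\n")
  cat("  cytosines:", nrow(x$methylation),
      sprintf("(%d CpG)", sum(x$methylation$context == "CG")), "\n")
  cat("  reads:", nrow(x$reads),
      sprintf("(%.0fx, %s)", x$params$coverage,
              if (x$params$paired) "paired" else "single-end"), "\n")
  invisible(x)
}

#' Downsample a pileup to a target mean coverage
#'
#' Retains `z = round(m * n / N)` observations at a locus of depth `m`,
#' where `N` is the dataset's mean coverage and `n` the desired one; a
#' uniform random subset is kept (all observations when `z >= m`).
#'
#' @param locus pileup data.frame (or list with `$observations`).
#' @param n target mean coverage.
#' @param N mean coverage of the full dataset.
#' @param seed optional seed for the subset draw.
#' @return the downsampled pileup data.frame.
#' @export
downsample_pileup <- function(locus, n, N, seed = NULL) {
  stopifnot(N > 0, n > 0, n <= N)
  obs <- as_pileup_df(locus)
  m <- nrow(obs)
  z <- round(m * n / N)
  if (z >= m) return(obs)
  if (!is.null(seed)) set.seed(seed)
  obs[sort(sample.int(m, z)), , drop = FALSE]
}

#' Downsample a whole observation table by locus
#'
#' Applies the [downsample_pileup()] rule independently at every covered
#' position.
#'
#' @param obs observation table (`contig`, `pos`, ... one row per base).
#' @param n,N target and dataset mean coverage.
#' @param seed seed for the subset draws.
#' @return filtered observation table.
#' @export
downsample_observations <- function(obs, n, N, seed = 1L) {
  stopifnot(N > 0, n > 0, n <= N)
  if (n == N) return(obs)
  set.seed(seed)
  key <- paste0(obs$contig, ":", obs$pos)
  # random rank within each locus; keep ranks <= z
  r <- stats::runif(nrow(obs))
  rk <- stats::ave(r, key, FUN = rank)
  m <- stats::ave(rep(1L, nrow(obs)), key, FUN = sum)
  z <- round(m * n / N)
  obs[rk <= z, , drop = FALSE]
}
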