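#' Build the filtered observation table for calling
#'
#' Runs the read-level pipeline: prefilters, orientation normalization,
#' reference annotation, optional base-quality recalibration, the
#' five-prime non-conversion mask, and the base-quality cutoff
#' (strictly greater than `min_base_quality`; N bases dropped). The
#' result is the package's pileup representation: one row per retained
#' aligned base, from which per-locus pileups are formed by grouping on
#' (`contig`, `pos`).
#'
#' @param reads data.frame from [read_alignments()] (or a SAM/BAM path).
#' @param genome DNAStringSet (or FASTA path).
#' @param thresholds [filter_thresholds()].
#' @param params [model_params()].
#' @param five_prime_filter apply the 5' non-conversion mask (turn off
#'   for RRBS).
#' @param recalibrate `FALSE`, `TRUE` (build a table from these reads
#'   and apply it), or a prebuilt `recal_table`.
#' @param known_sites known-variant set, used only when building a
#'   recalibration table.
#' @return observation data.frame; attributes `drop_counts` (read-level
#'   filter tally), `masked_5p`, `coverage` (per-contig list with
#'   `depth_all` and `mq0` integer vectors over positions) and
#'   `recal_table` when one was built.
#' @export
build_observations <- function(reads, genome,
                               thresholds = filter_thresholds(),
                               params = model_params(),
                               five_prime_filter = TRUE,
                               recalibrate = FALSE,
                               known_sites = NULL) {
  if (is.character(reads)) reads <- read_alignments(reads)
  if (is.character(genome)) genome <- read_reference(genome)

  # raw per-position coverage (incl. reads the prefilters drop) for the
  # MQ0-region annotation
  cov <- raw_coverage(reads, genome)

  pf <- read_prefilters(reads, thresholds)
  obs <- normalize_read_orientation(reads[pf$keep, , drop = FALSE])
  obs <- add_ref_base(obs, genome)

  tab <- NULL
  if (isTRUE(recalibrate)) {
    tab <- build_recal_table(obs, known_sites)
    obs <- apply_recalibration(obs, tab)
  } else if (methods::is(recalibrate, "recal_table")) {
    tab <- recalibrate
    obs <- apply_recalibration(obs, tab)
  }

  obs <- five_prime_nonconversion_mask(obs, enabled = five_prime_filter)
  masked <- attr(obs, "masked")

  keep <- obs$base %in% BASES & obs$qual > params$min_base_quality
  obs <- obs[keep, , drop = FALSE]
  obs$epsilon <- pmin(1 - 1e-12, 10^(-obs$qual / 10))

  attr(obs, "drop_counts") <- attr(pf, "counts")
  attr(obs, "masked_5p") <- masked
  attr(obs, "coverage") <- cov
  attr(obs, "recal_table") <- tab
  obs
}

# total and MAPQ0 coverage per position, per contig
raw_coverage <- function(reads, genome) {
  out <- list()
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  for (ctg in names(genome)) {
    sel <- reads$contig == ctg
    L <- Biostrings::width(genome)[match(ctg, names(genome))]
    ir <- IRanges::IRanges(start = reads$pos[sel] + 1L,
                           width = rw[sel])
    depth_all <- as.integer(IRanges::coverage(ir, width = L))
    ir0 <- ir[reads$mapq[sel] == 0L]
    mq0 <- as.integer(IRanges::coverage(ir0, width = L))
    out[[ctg]] <- list(depth_all = depth_all, mq0 = mq0)
  }
  out
}

# vectorized context annotation: context string per (contig, pos, strand)
# for cytosine positions of the *reference*; NA elsewhere / no match
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    bases <- map[[ch]]
    if (nchar(bases) == 1) bases else paste0("[", bases, "]")
  }, character(1)), collapse = "")
}

annotate_contexts <- function(genome, contig, pos, strand,
                              patterns = context_patterns()) {
  cs <- as.character(genome[[contig]])
  L <- nchar(cs)
  strand <- rep_len(strand, length(pos))
  out <- rep(NA_character_, length(pos))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  for (i in seq_len(nrow(patterns))) {
    pat <- patterns$pattern[i]
    off <- patterns$offset[i]
    w <- nchar(pat)
    rx <- paste0("^", iupac_regex(pat), "$")
    todo <- which(is.na(out))
    if (length(todo) == 0) break
    p <- pos[todo]
    fwd <- strand[todo] == "+"
    start <- ifelse(fwd, p - off, p + off - w + 1L)  # 0-based
    okb <- start >= 0L & start + w - 1L < L
    win <- rep(NA_character_, length(todo))
    win[okb] <- substring(cs, start[okb] + 1L, start[okb] + w)
    win[okb & !fwd] <- rc(win[okb & !fwd])
    hit <- !is.na(win) & grepl(rx, win)
    out[todo[hit]] <- pat
  }
  out
}

#' Call genotypes and methylation from bisulfite alignments
#'
#' The package's central fitting function: builds pileups from
#' directional bisulfite alignments, evaluates the posterior over the
#' ten diploid genotypes at every covered position, and summarizes
#' per-cytosine methylation, with the methylation prior estimated in the
#' requested mode (locus-specific by default; context mode runs the
#' two-round procedure internally). Site filters annotate but never
#' remove calls.
#'
#' @param alignments SAM/BAM path or [read_alignments()] data.frame.
#' @param reference FASTA path or named DNAStringSet.
#' @param known_sites optional VCF path or [load_known_sites()] object.
#' @param params [model_params()].
#' @param thresholds [filter_thresholds()].
#' @param priors [prior_params()].
#' @param contexts [context_patterns()] (default CG, CH).
#' @param five_prime_filter apply the 5' non-conversion mask
#'   (default TRUE; set FALSE for RRBS).
#' @param recalibrate as in [build_observations()].
#' @param sample_name sample label for VCF output.
#' @return object of class `methcall_calls`: list with `calls`
#'   (data.frame, one row per covered locus), `beta` (context estimates
#'   when mode is "context"), `params`, `thresholds`, `stats`.
#' @seealso [write_vcf()], [write_methylation()], [evaluate_calls()]
#' @export
methcall <- function(alignments, reference, known_sites = NULL,
                     params = model_params(),
                     thresholds = filter_thresholds(),
                     priors = prior_params(),
                     contexts = context_patterns(),
                     five_prime_filter = TRUE,
                     recalibrate = FALSE,
                     sample_name = "SAMPLE") {
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.character(known_sites)) known_sites <- load_known_sites(known_sites)

  obs <- build_observations(alignments, reference, thresholds, params,
                            five_prime_filter, recalibrate, known_sites)
  out <- call_pileups(obs, reference, known_sites, params, thresholds,
                      priors, contexts, sample_name)
  out$recal_table <- attr(obs, "recal_table")
  out
}

#' Call genotypes from a prepared observation table
#'
#' The calling stage of [methcall()] alone, for workflows that
#' manipulate the observation table first (e.g. coverage downsampling
#' with [downsample_observations()]).
#'
#' @param obs observation table from [build_observations()].
#' @param reference named DNAStringSet.
#' @inheritParams methcall
#' @return `methcall_calls` object.
#' @export
call_pileups <- function(obs, reference, known_sites = NULL,
                         params = model_params(),
                         thresholds = filter_thresholds(),
                         priors = prior_params(),
                         contexts = context_patterns(),
                         sample_name = "SAMPLE") {
  beta_ctx <- NULL
  if (params$beta_mode == "context") {
    round1 <- call_engine(obs, reference, known_sites, params, priors,
                          beta_mode = "naive", contexts = contexts)
    beta_ctx <- beta_context(round1$calls, contexts)
    res <- call_engine(obs, reference, known_sites, params, priors,
                       beta_mode = "context", contexts = contexts,
                       beta_by_context = beta_ctx)
  } else {
    res <- call_engine(obs, reference, known_sites, params, priors,
                       beta_mode = params$beta_mode, contexts = contexts)
  }

  calls <- site_filters(res$calls, thresholds)
  low <- calls$is_variant & calls$score < params$score_threshold
  calls$filter[low] <- ifelse(calls$filter[low] == "PASS", "LowQual",
                              paste0(calls$filter[low], ";LowQual"))

  structure(list(calls = calls, beta = beta_ctx, params = params,
                 thresholds = thresholds, priors = priors,
                 contexts = contexts, sample = sample_name,
                 stats = list(drop_counts = attr(obs, "drop_counts"),
                              masked_5p = attr(obs, "masked_5p"),
                              n_obs = nrow(obs))),
            class = "methcall_calls")
}

# The vectorized per-locus engine. obs must carry epsilon and ref_base.
call_engine <- function(obs, genome, known_sites, params, priors,
                        beta_mode, contexts,
                        beta_by_context = NULL) {
  if (nrow(obs) == 0) stop("no observations left after filtering")
  key <- paste0(obs$contig, ":", obs$pos)
  first <- !duplicated(key)
  loci <- data.frame(contig = obs$contig[first], pos = obs$pos[first],
                     ref = obs$ref_base[first],
                     stringsAsFactors = FALSE)
  o <- order(loci$contig, loci$pos)
  loci <- loci[o, , drop = FALSE]
  li <- match(key, paste0(loci$contig, ":", loci$pos))
  nl <- nrow(loci)

  # methylation-informative counts per locus and strand
  fwd <- obs$template_strand == "+"
  cnt <- function(sel) {
    v <- integer(nl)
    t <- tapply(rep(1L, sum(sel)), li[sel], sum)
    v[as.integer(names(t))] <- as.integer(t)
    v
  }
  c_plus <- cnt(fwd & obs$base == "C")
  t_plus <- cnt(fwd & obs$base == "T")
  g_minus <- cnt(!fwd & obs$base == "G")
  a_minus <- cnt(!fwd & obs$base == "A")

  # context of the cytosine at each locus, per strand (reference-based)
  cx_plus <- rep(NA_character_, nl)
  cx_minus <- rep(NA_character_, nl)
  for (ctg in unique(loci$contig)) {
    sel <- which(loci$contig == ctg)
    isc <- loci$ref[sel] == "C"
    isg <- loci$ref[sel] == "G"
    cx_plus[sel[isc]] <- annotate_contexts(genome, ctg, loci$pos[sel[isc]],
                                           "+", contexts)
    cx_minus[sel[isg]] <- annotate_contexts(genome, ctg, loci$pos[sel[isg]],
                                            "-", contexts)
  }

  # methylation priors per locus, per strand
  if (beta_mode == "naive") {
    beta_c <- rep(0.5, nl); beta_g <- rep(0.5, nl)
  } else if (beta_mode == "locus") {
    beta_c <- ifelse(c_plus + t_plus > 0, c_plus / (c_plus + t_plus), 0.5)
    beta_g <- ifelse(g_minus + a_minus > 0,
                     g_minus / (g_minus + a_minus), 0.5)
  } else if (beta_mode == "context") {
    stopifnot(!is.null(beta_by_context))
    lk <- function(cx) ifelse(is.na(cx), 0.5,
                              unname(beta_by_context[cx]))
    beta_c <- lk(cx_plus)
    beta_g <- lk(cx_minus)
    beta_c[is.na(beta_c)] <- 0.5
    beta_g[is.na(beta_g)] <- 0.5
  } else stop("unknown beta mode: ", beta_mode)

  # observation-level allele likelihoods
  lik <- obs_lik_matrix(obs$base, obs$epsilon, obs$template_strand,
                        beta_c = beta_c[li], beta_g = beta_g[li],
                        alpha = params$alpha, gamma = params$gamma)

  grp <- factor(li, levels = seq_len(nl))
  loglik <- matrix(0, nrow = nl, ncol = 10,
                   dimnames = list(NULL, GENOTYPES))
  for (g in GENOTYPES) {
    a <- GT_ALLELES[g, "a"]; b <- GT_ALLELES[g, "b"]
    v <- log(0.5 * lik[, a] + 0.5 * lik[, b])
    loglik[, g] <- rowsum(v, grp)[, 1]
  }

  # genotype priors per locus
  known <- known_site_member(known_sites, loci$contig, loci$pos)
  logprior <- matrix(NA_real_, nrow = nl, ncol = 10)
  for (b in c(BASES, "N")) {
    sel <- which(loci$ref == b & !known)
    if (length(sel) > 0)
      logprior[sel, ] <- matrix(log(genotype_priors(b, NULL, priors)),
                                nrow = length(sel), ncol = 10,
                                byrow = TRUE)
  }
  for (i in which(known)) {
    rec <- known_site_record(known_sites, loci$contig[i], loci$pos[i])
    logprior[i, ] <- log(genotype_priors(loci$ref[i], rec, priors))
  }

  lp <- logprior + loglik
  mx <- do.call(pmax, as.data.frame(lp))
  pw <- exp(lp - mx)
  psum <- rowSums(pw)
  best_i <- max.col(pw, ties.method = "first")
  pw2 <- pw
  pw2[cbind(seq_len(nl), best_i)] <- -Inf
  next_i <- max.col(pw2, ties.method = "first")
  p_best <- pw[cbind(seq_len(nl), best_i)] / psum
  lp_best <- lp[cbind(seq_len(nl), best_i)]
  lp_next <- lp[cbind(seq_len(nl), next_i)]
  score <- ifelse(lp_best == lp_next, 0,
                  10 / log(10) * (lp_best - lp_next))

  best <- GENOTYPES[best_i]
  nxt <- GENOTYPES[next_i]

  # methylation summary per locus: prefer the strand whose cytosine is in
  # the best genotype; C/T (and mirrored G/A) hets are not measurable
  has_c <- best %in% c("AC", "CC", "CG", "CT")
  has_g <- best %in% c("AG", "CG", "GG", "GT")
  meas_c <- best %in% c("AC", "CC", "CG") & (c_plus + t_plus) > 0
  meas_g <- best %in% c("CG", "GG", "GT") & (g_minus + a_minus) > 0
  meth_strand <- ifelse(meas_c, "+", ifelse(meas_g, "-", NA_character_))
  c_reads <- ifelse(meas_c, c_plus, ifelse(meas_g, g_minus, 0L))
  t_reads <- ifelse(meas_c, t_plus, ifelse(meas_g, a_minus, 0L))
  meth_fraction <- ifelse(c_reads + t_reads > 0,
                          c_reads / (c_reads + t_reads), NA_real_)
  meth_fraction[is.na(meth_strand)] <- NA_real_
  context <- ifelse(meth_strand == "+", cx_plus,
                    ifelse(meth_strand == "-", cx_minus, NA_character_))

  # depth, variant annotations
  depth <- as.integer(table(grp))
  is_variant <- best != paste0(loci$ref, loci$ref)

  # strand bias / QD inputs: alt = non-reference alleles of best
  aL <- substr(best, 1, 1); bL <- substr(best, 2, 2)
  alt1 <- ifelse(aL != loci$ref, aL, "")
  alt2 <- ifelse(bL != loci$ref & bL != aL, bL, "")
  is_alt <- obs$base == alt1[li] | obs$base == alt2[li]
  aln_fwd <- obs$strand == "+"

  # Bisulfite entanglement: wherever a C (or mirrored G) allele is in
  # play, conversion confines part of the allele evidence to one strand
  # by protocol design, so a strand-confinement test cannot distinguish
  # artifact from chemistry; bias is marked unmeasurable there (-Inf,
  # never filtered) and measured normally at pure A/T loci.
  entangled <- loci$ref %in% c("C", "G") | aL %in% c("C", "G") |
    bL %in% c("C", "G")
  ref_f <- cnt(!is_alt & aln_fwd)
  ref_r <- cnt(!is_alt & !aln_fwd)
  alt_f <- cnt(is_alt & aln_fwd)
  alt_r <- cnt(is_alt & !aln_fwd)
  alt_n <- alt_f + alt_r

  sb <- rep(-Inf, nl)
  for (i in which(is_variant & !entangled & alt_n > 0))
    sb[i] <- strand_bias(ref_f[i], ref_r[i], alt_f[i], alt_r[i])
  qd <- quality_by_depth(pmax(score, 0), alt_n)
  qd[!is_variant] <- NA_real_

  cov <- attr(obs, "coverage")
  depth_all <- depth
  mq0 <- integer(nl)
  if (!is.null(cov)) {
    for (ctg in unique(loci$contig)) {
      sel <- loci$contig == ctg
      depth_all[sel] <- cov[[ctg]]$depth_all[loci$pos[sel] + 1L]
      mq0[sel] <- cov[[ctg]]$mq0[loci$pos[sel] + 1L]
    }
  }

  calls <- data.frame(
    contig = loci$contig, pos = loci$pos, ref = loci$ref,
    best = best, next_best = nxt, score = score, post_best = p_best,
    depth = depth, depth_all = depth_all, mq0 = mq0,
    is_variant = is_variant, known = known,
    c_reads = as.integer(c_reads), t_reads = as.integer(t_reads),
    meth_fraction = meth_fraction, meth_strand = meth_strand,
    context = context, sb = sb, qd = qd,
    stringsAsFactors = FALSE)
  list(calls = calls,
       beta = list(beta_c = beta_c, beta_g = beta_g))
}

#' @export
print.methcall_calls <- function(x, ...) {
  calls <- x$calls
  cat("methcall genotype/methylation calls\n")
  cat(sprintf("  loci: %d  variants: %d (%d PASS)\n",
              nrow(calls), sum(calls$is_variant),
              sum(calls$is_variant & calls$filter == "PASS")))
  cat(sprintf("  methylation-measurable cytosines: %d\n",
              sum(!is.na(calls$meth_fraction))))
  cat(sprintf("  beta mode: %s  alpha: %g  gamma: %g\n",
              x$params$beta_mode, x$params$alpha, x$params$gamma))
  if (!is.null(x$beta)) {
    cat("  context priors:",
        paste(names(x$beta), round(unname(x$beta), 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.methcall_calls <- function(object, ...) {
  calls <- object$calls
  variants <- calls[calls$is_variant, , drop = FALSE]
  by_cx <- tapply(calls$meth_fraction, calls$context, mean,
                  na.rm = TRUE)
  out <- list(
    n_loci = nrow(calls),
    n_variant = nrow(variants),
    n_pass = sum(variants$filter == "PASS"),
    filter_table = table(variants$filter),
    het = sum(substr(variants$best, 1, 1) !=
                substr(variants$best, 2, 2)),
    hom = sum(substr(variants$best, 1, 1) ==
                substr(variants$best, 2, 2)),
    mean_methylation_by_context = by_cx,
    score_quantiles = stats::quantile(variants$score,
                                      c(0.25, 0.5, 0.75, 0.95)),
    stats = object$stats)
  class(out) <- "summary.methcall_calls"
  out
}

#' @export
print.summary.methcall_calls <- function(x, ...) {
  cat("Loci called:", x$n_loci, "\n")
  cat("Variant calls:", x$n_variant,
      sprintf("(%d het, %d hom-alt; %d PASS)\n", x$het, x$hom, x$n_pass))
  cat("Mean methylation by context:\n")
  print(round(x$mean_methylation_by_context, 4))
  cat("Variant score quartiles:\n")
  print(round(x$score_quantiles, 2))
  invisible(x)
}

#' @export
as.data.frame.methcall_calls <- function(x, ...) x$calls

#' Plot methylation and score distributions of a call set
#'
#' Two-panel base-graphics display: the per-context methylation-level
#' histogram (typically bimodal for CpG) and the variant score
#' distribution.
#'
#' @param x `methcall_calls`.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.methcall_calls <- function(x, ...) {
  calls <- x$calls
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  m <- calls$meth_fraction[!is.na(calls$meth_fraction)]
  graphics::hist(m, breaks = 20, main = "methylation levels",
                 xlab = "C / (C + T)", col = "grey80", ...)
  s <- calls$score[calls$is_variant]
  if (length(s) > 0)
    graphics::hist(pmin(s, 200), breaks = 30, main = "variant scores",
                   xlab = "phred-scaled best/next odds", col = "grey80",
                   ...)
  invisible(x)
}
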