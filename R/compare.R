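#' K-allele heterozygote caller
#'
#' Count-based baseline without base qualities. At reference-cytosine
#' positions only the genotype-informative strand is used (the strand
#' opposite the cytosine: reverse-template reads at a reference C,
#' forward-template reads at a reference G), since the bisulfite strand
#' merges C and T into one allele. With `n` passing reads, a
#' heterozygote requires each of the two alleles on at least `K` reads
#' when `n < 10`, and the minor allele on at least `ceiling(n*K/10)`
#' reads when `n >= 10`.
#'
#' @param locus pileup data.frame (`base`, `template_strand`).
#' @param ref_base reference base at the locus.
#' @param K integer stringency, 0-10.
#' @return list: `call` ("het", "hom" or "no-call"), `alleles` (top two),
#'   `n` (reads used).
#' @export
k_allele_call <- function(locus, ref_base, K = 3L) {
  stopifnot(K >= 0, K <= 10)
  obs <- as_pileup_df(locus)
  if (ref_base == "C") obs <- obs[obs$template_strand == "-", , drop = FALSE]
  if (ref_base == "G") obs <- obs[obs$template_strand == "+", , drop = FALSE]
  obs <- obs[obs$base %in% BASES, , drop = FALSE]
  n <- nrow(obs)
  if (n == 0) return(list(call = "no-call", alleles = character(0), n = 0L))
  tab <- sort(table(obs$base), decreasing = TRUE)
  if (length(tab) == 1)
    return(list(call = "hom", alleles = names(tab), n = n))
  minor <- as.integer(tab[2])
  need <- if (n < 10) K else ceiling(n * K / 10)
  het <- minor >= need && as.integer(tab[1]) >= need
  list(call = if (het) "het" else "no-call",
       alleles = names(tab)[1:2], n = as.integer(n))
}

#' Reference-cytosine consensus caller (threshold method)
#'
#' Count-threshold baseline restricted to reference cytosines: requires
#' at least 3 C-or-T reads on the bisulfite strand, then calls a
#' homozygous cytosine when at least `k` percent of bisulfite-strand
#' reads are C or T and at least `k` percent of the opposite-strand
#' reads support the cytosine allele. Mirrored at reference Gs.
#'
#' @param locus pileup data.frame.
#' @param ref_base "C" or "G".
#' @param k percentage threshold (default 10).
#' @return list: `call` ("cytosine", "rejected" or "filtered"), counts.
#' @export
berman2012_call <- function(locus, ref_base, k = 10) {
  stopifnot(ref_base %in% c("C", "G"))
  obs <- as_pileup_df(locus)
  obs <- obs[obs$base %in% BASES, , drop = FALSE]
  if (ref_base == "C") {
    bis <- obs[obs$template_strand == "+", , drop = FALSE]
    opp <- obs[obs$template_strand == "-", , drop = FALSE]
    bis_ok <- bis$base %in% c("C", "T")
    opp_ok <- opp$base == "C"    # unconverted strand reads the genotype
  } else {
    bis <- obs[obs$template_strand == "-", , drop = FALSE]
    opp <- obs[obs$template_strand == "+", , drop = FALSE]
    bis_ok <- bis$base %in% c("G", "A")
    opp_ok <- opp$base == "G"
  }
  ct <- sum(bis_ok)
  if (ct < 3) return(list(call = "filtered", ct_reads = ct))
  p_bis <- if (nrow(bis) > 0) 100 * mean(bis_ok) else 100
  p_opp <- if (nrow(opp) > 0) 100 * mean(opp_ok) else 100
  ok <- p_bis >= k && p_opp >= k
  list(call = if (ok) "cytosine" else "rejected",
       ct_reads = ct, pct_bisulfite = p_bis, pct_opposite = p_opp)
}

#' Demethylation-based frequency-matrix caller
#'
#' Baseline re-implementation of a published pipeline that cannot see
#' C/T SNPs by construction: reads are demethylated in silico (C->T on
#' forward templates, G->A on reverse templates in forward space), bases
#' require quality >= 15 at the site and three flanking positions, a
#' base present on more than 20% of one strand's reads must appear on at
#' least 20% of the other strand's, and a quality-weighted nucleotide
#' frequency matrix is scored per genotype by Fisher exact tests
#' (observed vs genotype-expected counts, one per allele, p-values
#' multiplied and normalized). A genotype is reported only when it is at
#' least 10x more likely than the runner-up, the site is in the
#' known-variant set, and depth is at least 10.
#'
#' @param obs observation table covering the site and its flanks
#'   (columns `read_id`, `pos`, `base`, `qual`, `template_strand`).
#' @param pos 0-based site position.
#' @param known logical: is the site in the known-variant set?
#' @param min_qual,flank,min_depth,ratio method constants (15, 3, 10,
#'   10).
#' @return list: `call` (genotype or NA), `posterior` (normalized
#'   p-value products) and `reason` for no-calls.
#' @export
shoemaker_call <- function(obs, pos, known, min_qual = 15L, flank = 3L,
                           min_depth = 10L, ratio = 10) {
  if (!known)
    return(list(call = NA_character_, reason = "not_in_known_sites"))
  site <- obs[obs$pos == pos & obs$base %in% BASES, , drop = FALSE]
  if (nrow(site) == 0)
    return(list(call = NA_character_, reason = "no_coverage"))

  # quality gate: site and +-flank bases of the same read all >= min_qual
  near <- obs[abs(obs$pos - pos) <= flank, , drop = FALSE]
  bad_reads <- unique(near$read_id[near$qual < min_qual])
  site <- site[!(site$read_id %in% bad_reads), , drop = FALSE]
  if (nrow(site) < min_depth)
    return(list(call = NA_character_, reason = "low_depth"))

  # in-silico demethylation
  b <- site$base
  b[site$template_strand == "+" & b == "C"] <- "T"
  b[site$template_strand == "-" & b == "G"] <- "A"

  # reciprocal strand rule
  for (s in c("+", "-")) {
    bs <- b[site$template_strand == s]
    bo <- b[site$template_strand != s]
    if (length(bs) == 0 || length(bo) == 0) next
    f <- table(factor(bs, levels = BASES)) / length(bs)
    fo <- table(factor(bo, levels = BASES)) / length(bo)
    viol <- names(f)[f > 0.2 & fo < 0.2]
    if (length(viol) > 0)
      return(list(call = NA_character_, reason = "strand_reciprocity"))
  }

  # quality-weighted frequency matrix, scaled back to read counts
  wt <- 1 - 10^(-site$qual / 10)
  wsum <- tapply(wt, factor(b, levels = BASES), sum)
  wsum[is.na(wsum)] <- 0
  freq <- wsum / sum(wsum)
  n <- length(b)
  counts <- freq * n
  err <- mean(10^(-site$qual / 10))

  pvals <- vapply(GENOTYPES, function(g) {
    a1 <- GT_ALLELES[g, "a"]; a2 <- GT_ALLELES[g, "b"]
    p <- 1
    for (al in c(a1, a2)) {
      share <- (as.integer(a1 == al) + as.integer(a2 == al)) / 2
      exp_al <- n * (share * (1 - err) + (1 - share) * err / 3)
      m <- round(rbind(c(counts[[al]], n - counts[[al]]),
                       c(exp_al, n - exp_al)))
      m[m < 0] <- 0
      p <- p * stats::fisher.test(m)$p.value
    }
    p
  }, numeric(1))
  post <- pvals / sum(pvals)
  o <- order(-post)
  if (post[o[1]] < ratio * post[o[2]])
    return(list(call = NA_character_, posterior = post,
                reason = "ambiguous"))
  list(call = GENOTYPES[o[1]], posterior = post, reason = NA_character_)
}

truth_classes <- function(truth) {
  if (methods::is(truth, "truth_set")) {
    g <- truth$genome
    gt <- genotype(g$hap1, g$hap2)
    data.frame(contig = g$contig,
               pos = seq_along(g$hap1) - 1L,
               ref = g$ref_chars,
               genotype = gt,
               stringsAsFactors = FALSE)
  } else truth
}

stratum_truth <- function(tc, stratum) {
  het <- substr(tc$genotype, 1, 1) != substr(tc$genotype, 2, 2)
  switch(stratum,
    hom_cytosine = tc$genotype %in% c("CC", "GG"),
    het_all = het,
    het_CT = het & tc$genotype %in% c("CT", "AG"),
    het_nonCT = het & !tc$genotype %in% c("CT", "AG"),
    stop("unknown stratum: ", stratum))
}

#' Sensitivity / FDR evaluation against simulated truth
#'
#' Sweeps a score threshold and, per stratum, counts true positives
#' (calls matching the truth genotype), false positives (calls placed in
#' the stratum's class where the truth disagrees) and false negatives.
#' Strata: `hom_cytosine` (homozygous C or G in the sample genome),
#' `het_all` (any heterozygote), `het_CT` (bisulfite-ambiguous C/T and
#' mirrored G/A heterozygotes), `het_nonCT` (all other heterozygotes).
#' The operating point reported is the least stringent threshold with
#' false discovery rate below `fdr_target`.
#'
#' @param calls calls data.frame (needs `contig`, `pos`, `best`,
#'   `score`), e.g. `methcall(...)$calls`, or a comparator's equivalent.
#' @param truth [simulate_bsseq()] truth set or a data.frame with
#'   `contig`, `pos`, `ref`, `genotype` for every locus.
#' @param stratum one of the four strata.
#' @param thresholds numeric vector of score cutoffs; defaults to a grid
#'   over the observed score range (always includes 0).
#' @param fdr_target operating-point FDR bound (default 0.05).
#' @return data.frame of class `eval_points` (threshold, tp, fp, fn,
#'   sensitivity, fdr, fpr) with attributes `operating_point` (row at
#'   the FDR target) and `stratum`.
#' @export
evaluate_calls <- function(calls, truth, stratum = "het_all",
                           thresholds = NULL, fdr_target = 0.05) {
  tc <- truth_classes(truth)
  in_stratum <- stratum_truth(tc, stratum)
  n_true <- sum(in_stratum)
  if (n_true == 0) {
    warning("empty truth stratum: ", stratum)
    out <- data.frame(threshold = numeric(0), tp = integer(0),
                      fp = integer(0), fn = integer(0),
                      sensitivity = numeric(0), fdr = numeric(0),
                      fpr = numeric(0))
    attr(out, "stratum") <- stratum
    class(out) <- c("eval_points", "data.frame")
    return(out)
  }

  key_t <- paste0(tc$contig, ":", tc$pos)
  key_c <- paste0(calls$contig, ":", calls$pos)
  mi <- match(key_c, key_t)
  ok <- !is.na(mi)
  calls <- calls[ok, , drop = FALSE]
  mi <- mi[ok]

  het_call <- substr(calls$best, 1, 1) != substr(calls$best, 2, 2)
  in_class <- switch(stratum,
    hom_cytosine = calls$best %in% c("CC", "GG"),
    het_all = het_call,
    het_CT = het_call & calls$best %in% c("CT", "AG"),
    het_nonCT = het_call & !calls$best %in% c("CT", "AG"))
  correct <- calls$best == tc$genotype[mi]

  if (is.null(thresholds)) {
    smax <- max(calls$score[in_class], 0)
    thresholds <- sort(unique(c(0, stats::quantile(
      calls$score[in_class], probs = seq(0, 1, 0.02), names = FALSE),
      smax)))
  }
  n_neg <- sum(!in_stratum)

  rows <- lapply(thresholds, function(t) {
    pred <- in_class & calls$score >= t
    tp <- sum(pred & correct & in_stratum[mi])
    fp <- sum(pred & !(correct & in_stratum[mi]))
    fn <- n_true - tp
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               sensitivity = tp / n_true,
               fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
               fpr = if (n_neg > 0) fp / n_neg else NA_real_)
  })
  out <- do.call(rbind, rows)
  pass <- which(out$fdr < fdr_target)
  attr(out, "operating_point") <- if (length(pass) > 0)
    out[min(pass), , drop = FALSE] else NULL
  attr(out, "stratum") <- stratum
  class(out) <- c("eval_points", "data.frame")
  out
}

#' Operating-point sensitivity at an FDR bound
#'
#' @param ev [evaluate_calls()] result.
#' @return sensitivity at the least stringent threshold whose FDR is
#'   below the target, or 0 when no threshold qualifies.
#' @export
operating_sensitivity <- function(ev) {
  op <- attr(ev, "operating_point")
  if (is.null(op)) 0 else op$sensitivity
}

#' Run the count-based comparators over an observation table
#'
#' Vectorized harness applying the k-allele caller (sweeping K) and the
#' reference-cytosine consensus caller (sweeping k%) to the same
#' observation table the Bayesian caller uses. For the k-allele caller
#' the per-locus "score" is the largest K that still calls a
#' heterozygote (closed form: the minor-allele count for depth < 10,
#' `floor(10 * minor / n)` otherwise), so thresholding the score at K
#' reproduces the K-allele decision exactly; [k_allele_call()] is the
#' reference implementation for single loci.
#'
#' @param obs observation table from [build_observations()].
#' @param genome reference DNAStringSet.
#' @param k_values percentage sweep for the consensus caller.
#' @return list with `k_allele` (data.frame: `contig`, `pos`, `best`,
#'   `score`) and `berman` (list of data.frames, one per k, reference
#'   cytosines only).
#' @export
run_comparators <- function(obs, genome, k_values = c(10, 30, 50, 70, 90)) {
  obs <- add_ref_base(obs, genome)
  obs <- obs[obs$base %in% BASES, , drop = FALSE]
  key <- paste0(obs$contig, ":", obs$pos)
  uk <- unique(key)
  li <- match(key, uk)
  nl <- length(uk)
  first <- !duplicated(key)
  loci <- data.frame(contig = obs$contig[first], pos = obs$pos[first],
                     ref = obs$ref_base[first], stringsAsFactors = FALSE)

  # genotype-informative subset for the k-allele rule
  use <- rep(TRUE, nrow(obs))
  use[loci$ref[li] == "C" & obs$template_strand == "+"] <- FALSE
  use[loci$ref[li] == "G" & obs$template_strand == "-"] <- FALSE
  cntb <- function(sel, base) {
    v <- integer(nl)
    t <- tapply(rep(1L, sum(sel & obs$base == base)),
                li[sel & obs$base == base], sum)
    v[as.integer(names(t))] <- as.integer(t)
    v
  }
  cb <- vapply(BASES, function(b) cntb(use, b), integer(nl))
  if (nl == 1) cb <- matrix(cb, nrow = 1, dimnames = list(NULL, BASES))
  n <- rowSums(cb)
  ord <- t(apply(cb, 1, order, decreasing = TRUE))
  top <- cb[cbind(seq_len(nl), ord[, 1])]
  minor <- cb[cbind(seq_len(nl), ord[, 2])]
  a1 <- BASES[ord[, 1]]; a2 <- BASES[ord[, 2]]
  kmax <- ifelse(minor == 0, 0L,
                 ifelse(n < 10, pmin(minor, top),
                        floor(10 * minor / n)))
  best <- ifelse(kmax >= 1, genotype(a1, a2), genotype(a1, a1))
  k_allele <- data.frame(contig = loci$contig, pos = loci$pos,
                         best = best, score = as.integer(kmax),
                         stringsAsFactors = FALSE)[n > 0, , drop = FALSE]

  # consensus caller counts
  cyt <- loci$ref %in% c("C", "G")
  bis <- ifelse(loci$ref[li] == "C", obs$template_strand == "+",
                obs$template_strand == "-")
  bis_ok <- ifelse(loci$ref[li] == "C", obs$base %in% c("C", "T"),
                   obs$base %in% c("G", "A"))
  opp_ok <- ifelse(loci$ref[li] == "C", obs$base == "C",
                   obs$base == "G")
  cnt1 <- function(sel) {
    v <- integer(nl)
    t <- tapply(rep(1L, sum(sel)), li[sel], sum)
    v[as.integer(names(t))] <- as.integer(t)
    v
  }
  n_bis <- cnt1(bis); n_opp <- cnt1(!bis)
  ct <- cnt1(bis & bis_ok); gg <- cnt1(!bis & opp_ok)
  p_bis <- ifelse(n_bis > 0, 100 * ct / n_bis, 100)
  p_opp <- ifelse(n_opp > 0, 100 * gg / n_opp, 100)
  berman <- lapply(stats::setNames(k_values, k_values), function(k) {
    call <- ifelse(ct < 3, "filtered",
                   ifelse(p_bis >= k & p_opp >= k, "cytosine", "rejected"))
    data.frame(contig = loci$contig[cyt], pos = loci$pos[cyt],
               ref = loci$ref[cyt], call = call[cyt],
               ct_reads = ct[cyt], stringsAsFactors = FALSE)
  })
  list(k_allele = k_allele, berman = berman)
}
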