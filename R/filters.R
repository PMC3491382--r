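#' Site and read filter thresholds
#'
#' Thresholds for the read-level prefilters and the pre-call site filter
#' stack. Boundary semantics follow the printed rules exactly: reads with
#' mapping quality *less than* `min_mapping_quality` are dropped, sites
#' with depth *above* `max_depth` are labelled.
#'
#' @param min_mapping_quality reads below this MAPQ are dropped (default 30).
#' @param max_depth sites with more passing reads are labelled HighDepth
#'   (default 120).
#' @param sb_cutoff strand-bias scores above this are labelled StrandBias
#'   (default -0.02; bisulfite data shows apparent strand bias at
#'   cytosines because the G-strand contributes more reads, so the cutoff
#'   is deliberately lax).
#' @param min_qd variant calls with score/alt-depth below this are
#'   labelled LowQD (default 1.0).
#' @param cluster_window,cluster_min label variant calls when
#'   `cluster_min` or more fall within any `cluster_window` bp (defaults
#'   2 within 10 bp).
#' @param mq0_fraction,mq0_min_reads label sites where more than
#'   `mq0_fraction` of reads have MAPQ 0, provided at least
#'   `mq0_min_reads` reads align (defaults 0.10 and 40).
#' @param remove_duplicates drop reads flagged as PCR duplicates
#'   (default TRUE).
#' @param require_proper_pair drop paired reads without the
#'   properly-paired flag (default TRUE; ignored for unpaired data).
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_mapping_quality = 30L, max_depth = 120L,
                              sb_cutoff = -0.02, min_qd = 1.0,
                              cluster_window = 10L, cluster_min = 2L,
                              mq0_fraction = 0.10, mq0_min_reads = 40L,
                              remove_duplicates = TRUE,
                              require_proper_pair = TRUE) {
  structure(list(min_mapping_quality = as.integer(min_mapping_quality),
                 max_depth = as.integer(max_depth),
                 sb_cutoff = sb_cutoff, min_qd = min_qd,
                 cluster_window = as.integer(cluster_window),
                 cluster_min = as.integer(cluster_min),
                 mq0_fraction = mq0_fraction,
                 mq0_min_reads = as.integer(mq0_min_reads),
                 remove_duplicates = isTRUE(remove_duplicates),
                 require_proper_pair = isTRUE(require_proper_pair)),
            class = "filter_thresholds")
}

#' Read-level prefilters
#'
#' Vectorized keep/drop decision applied before any pileup is built:
#' drops reads with mapping quality below the threshold, multi-mapping
#' reads, PCR duplicates (optional) and, for paired data, pairs without
#' the properly-paired flag.
#'
#' @param reads data.frame with columns `mapq`, `duplicate`, `paired`,
#'   `proper_pair`, and optionally `multimapped`.
#' @param t [filter_thresholds()].
#' @return list with `keep` (logical vector) and `reason` (character;
#'   `NA` for kept reads). A table of drop reasons is attached as
#'   attribute `counts`.
#' @export
read_prefilters <- function(reads, t = filter_thresholds()) {
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  multim <- if (!is.null(reads$multimapped)) reads$multimapped else
    rep(FALSE, n)
  drop_mapq <- reads$mapq < t$min_mapping_quality
  drop_dup <- t$remove_duplicates & reads$duplicate
  drop_pair <- t$require_proper_pair & reads$paired & !reads$proper_pair
  # first matching reason wins, in a fixed order
  reason[drop_pair] <- "improper_pair"
  reason[drop_dup] <- "duplicate"
  reason[multim] <- "multimapped"
  reason[drop_mapq] <- "mapq"
  keep <- is.na(reason)
  structure(list(keep = keep, reason = reason),
            counts = table(reason, useNA = "no"))
}

#' Five-prime non-conversion mask
#'
#' Unconverted cytosines cluster at the 5' end of reads (adapter-proximal
#' conversion failure). Walking each read 5'->3' in its original
#' sequencing orientation (ascending cycle), every bisulfite-strand C at
#' a reference C is masked until the first reference C observed as
#' converted (read as T); if the read contains no converted C, all its
#' unconverted Cs are masked. In reference-forward space this applies to
#' C-at-reference-C observations on forward templates and, mirrored, to
#' G-at-reference-G observations on reverse templates (where conversion
#' reads as A). Disable for RRBS, which gleans most methylation signal
#' from the first cycle.
#'
#' @param obs observation data.frame with columns `read_id`, `cycle`,
#'   `base`, `ref_base`, `template_strand`.
#' @param enabled set `FALSE` to return `obs` unchanged (RRBS mode).
#' @return `obs` with masked rows removed; the number of masked
#'   observations is attached as attribute `masked`.
#' @export
five_prime_nonconversion_mask <- function(obs, enabled = TRUE) {
  if (!enabled || nrow(obs) == 0) {
    attr(obs, "masked") <- 0L
    return(obs)
  }
  fwd <- obs$template_strand == "+"
  at_bis_c <- ifelse(fwd, obs$ref_base == "C", obs$ref_base == "G")
  converted <- at_bis_c & ifelse(fwd, obs$base == "T", obs$base == "A")
  unconverted <- at_bis_c & ifelse(fwd, obs$base == "C", obs$base == "G")

  # first conversion cycle per read (Inf when the read never converts)
  conv_cycle <- ifelse(converted, obs$cycle, Inf)
  first_conv <- stats::ave(conv_cycle, obs$read_id, FUN = min)
  mask <- unconverted & obs$cycle < first_conv
  out <- obs[!mask, , drop = FALSE]
  attr(out, "masked") <- sum(mask)
  out
}

#' Strand-bias score
#'
#' Likelihood-ratio strand-bias annotation: the per-depth log10 gain of
#' the best "alternate allele confined to one strand" model over a
#' strand-free model. Under confinement to strand s the alternate-allele
#' fraction on s is the total alternate count over that strand's depth,
#' while alternate reads on the other strand can only arise as sequencing
#' errors (rate `err`). Strand-balanced variants score strongly negative;
#' variants whose support sits on one strand score near or above zero.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev read counts by allele class and
#'   alignment strand.
#' @param err sequencing-error floor for the off-strand (default 1e-3).
#' @return the score (log10 units per read); `-Inf` when there is no
#'   alternate evidence at all (never filtered).
#' @export
strand_bias <- function(ref_fwd, ref_rev, alt_fwd, alt_rev, err = 1e-3) {
  stopifnot(ref_fwd >= 0, ref_rev >= 0, alt_fwd >= 0, alt_rev >= 0)
  alt <- alt_fwd + alt_rev
  if (alt == 0) return(-Inf)
  n_fwd <- ref_fwd + alt_fwd
  n_rev <- ref_rev + alt_rev
  depth <- n_fwd + n_rev
  stopifnot(depth > 0)

  l10 <- function(k, n, p) {
    if (n == 0) return(0)
    stats::dbinom(k, n, p, log = TRUE) / log(10)
  }
  p_free <- alt / depth
  l_free <- l10(alt_fwd, n_fwd, p_free) + l10(alt_rev, n_rev, p_free)
  l_fwd <- l10(alt_fwd, n_fwd, min(1, alt / max(n_fwd, 1))) +
    l10(alt_rev, n_rev, err)
  l_rev <- l10(alt_rev, n_rev, min(1, alt / max(n_rev, 1))) +
    l10(alt_fwd, n_fwd, err)
  (max(l_fwd, l_rev) - l_free) / depth
}

#' Quality by depth
#'
#' The call score divided by the number of reads supporting the
#' alternate allele. Low values indicate inflated scores from sheer
#' depth. Homozygous-reference calls (no alternate support) are exempt.
#'
#' @param score phred-scaled call score.
#' @param alt_supporting_reads count of alternate-supporting reads.
#' @return QD value, or `NA` for calls with no alternate support.
#' @export
quality_by_depth <- function(score, alt_supporting_reads) {
  stopifnot(all(score >= 0))
  ifelse(alt_supporting_reads == 0, NA_real_,
         score / pmax(1, alt_supporting_reads))
}

#' Pre-call site filter stack
#'
#' Labels (never deletes) calls failing any of: depth above
#' `max_depth` (`HighDepth`), strand bias above `sb_cutoff`
#' (`StrandBias`), quality-by-depth below `min_qd` for variant calls
#' (`LowQD`), two or more variant calls within `cluster_window` bp
#' (`SnpCluster`, all members labelled), or an MQ0 region: at least
#' `mq0_min_reads` aligned reads of which more than `mq0_fraction` have
#' mapping quality zero (`MQ0Region`). Calls passing everything are
#' labelled `PASS`.
#'
#' @param calls data.frame sorted by (`contig`, `pos`) with columns
#'   `contig`, `pos`, `is_variant`, `depth`, `sb`, `qd`, `mq0`,
#'   `depth_all` (total aligned reads incl. MAPQ 0; defaults to `depth`).
#' @param t [filter_thresholds()].
#' @return `calls` with a `filter` character column (semicolon-joined
#'   labels or "PASS").
#' @export
site_filters <- function(calls, t = filter_thresholds()) {
  if (nrow(calls) == 0) {
    calls$filter <- character(0)
    return(calls)
  }
  o <- order(calls$contig, calls$pos)
  if (any(o != seq_len(nrow(calls)))) stop("calls must be position-sorted")

  labels <- vector("list", nrow(calls))
  add <- function(idx, lab) for (i in which(idx)) labels[[i]] <<- c(labels[[i]], lab)

  add(calls$depth > t$max_depth, "HighDepth")
  sb <- if (!is.null(calls$sb)) calls$sb else rep(-Inf, nrow(calls))
  add(calls$is_variant & !is.na(sb) & sb > t$sb_cutoff, "StrandBias")
  qd <- if (!is.null(calls$qd)) calls$qd else rep(NA_real_, nrow(calls))
  add(calls$is_variant & !is.na(qd) & qd < t$min_qd, "LowQD")

  depth_all <- if (!is.null(calls$depth_all)) calls$depth_all else calls$depth
  mq0 <- if (!is.null(calls$mq0)) calls$mq0 else rep(0L, nrow(calls))
  add(depth_all >= t$mq0_min_reads & mq0 / pmax(depth_all, 1) > t$mq0_fraction,
      "MQ0Region")

  # SNP cluster: cluster_min or more variant calls within any window
  vidx <- which(calls$is_variant)
  if (length(vidx) >= t$cluster_min) {
    vpos <- calls$pos[vidx]
    vcontig <- calls$contig[vidx]
    clustered <- rep(FALSE, length(vidx))
    k <- t$cluster_min
    for (i in seq_along(vidx)) {
      same <- which(vcontig == vcontig[i] &
                      abs(vpos - vpos[i]) <= t$cluster_window)
      if (length(same) >= k) clustered[same] <- TRUE
    }
    inc <- rep(FALSE, nrow(calls))
    inc[vidx[clustered]] <- TRUE
    add(inc, "SnpCluster")
  }

  calls$filter <- vapply(labels, function(l)
    if (is.null(l)) "PASS" else paste(unique(l), collapse = ";"),
    character(1))
  calls
}
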