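#' Build a bisulfite-aware base-quality recalibration table
#'
#' Tabulates empirical mismatches against the reference, binned by
#' reported quality (R), sequencing cycle (C) and mate end, at all loci
#' not present in the known-variant set. Bisulfite-ambiguous bases are
#' treated as a fifth base "X" and excluded from tabulation entirely:
#' a T at a reference C on a forward-template observation (read-space
#' C->T, possibly conversion rather than error) and its mirror image, an
#' A at a reference G on a reverse-template observation. Ns in read or
#' reference are skipped.
#'
#' @param obs observation data.frame from [normalize_read_orientation()]
#'   with a `ref_base` column (see [add_ref_base()]).
#' @param known_sites optional known-variant set from
#'   [load_known_sites()]; covered positions are excluded.
#' @param min_bin_count bins with fewer observations fall back to the
#'   per-quality marginal when applied (default 100).
#' @return object of class `recal_table`: data.frame of bins
#'   (`qual`, `cycle`, `mate`, `n`, `mismatch`) plus marginal bins and
#'   settings in attributes.
#' @export
build_recal_table <- function(obs, known_sites = NULL, min_bin_count = 100L) {
  keep <- !is.na(obs$ref_base) & obs$ref_base %in% BASES & obs$base %in% BASES
  if (!is.null(known_sites))
    keep <- keep & !known_site_member(known_sites, obs$contig, obs$pos)
  o <- obs[keep, , drop = FALSE]

  x_base <- is_x_base(o)
  o <- o[!x_base, , drop = FALSE]

  if (nrow(o) == 0) {
    bins <- data.frame(qual = integer(0), cycle = integer(0),
                       mate = character(0), n = integer(0),
                       mismatch = integer(0), stringsAsFactors = FALSE)
    marginal <- data.frame(qual = integer(0), mate = character(0),
                           n = integer(0), mismatch = integer(0),
                           stringsAsFactors = FALSE)
    return(structure(bins, marginal = marginal,
                     min_bin_count = as.integer(min_bin_count),
                     class = c("recal_table", "data.frame")))
  }
  mism <- o$base != o$ref_base
  key <- paste(o$qual, o$cycle, o$mate, sep = "\r")
  n <- tapply(mism, key, length)
  m <- tapply(mism, key, sum)
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  bins <- data.frame(
    qual = as.integer(vapply(parts, `[`, "", 1L)),
    cycle = as.integer(vapply(parts, `[`, "", 2L)),
    mate = vapply(parts, `[`, "", 3L),
    n = as.integer(n), mismatch = as.integer(m),
    stringsAsFactors = FALSE)
  rownames(bins) <- NULL

  mkey <- paste(o$qual, o$mate, sep = "\r")
  mn <- tapply(mism, mkey, length)
  mm <- tapply(mism, mkey, sum)
  mparts <- strsplit(names(mn), "\r", fixed = TRUE)
  marginal <- data.frame(
    qual = as.integer(vapply(mparts, `[`, "", 1L)),
    mate = vapply(mparts, `[`, "", 2L),
    n = as.integer(mn), mismatch = as.integer(mm),
    stringsAsFactors = FALSE)
  rownames(marginal) <- NULL

  structure(bins, marginal = marginal,
            min_bin_count = as.integer(min_bin_count),
            class = c("recal_table", "data.frame"))
}

# bisulfite-ambiguous "fifth base X" positions
is_x_base <- function(obs) {
  (obs$template_strand == "+" & obs$ref_base == "C" & obs$base == "T") |
    (obs$template_strand == "-" & obs$ref_base == "G" & obs$base == "A")
}

#' Empirical phred quality of a bin
#'
#' Laplace-smoothed mismatch rate on the phred scale:
#' \eqn{Q = -10 \log_{10}[(mismatches + 1)/(observations + 2)]}, capped
#' at 60.
#'
#' @param observations,mismatches bin counts (vectorized).
#' @return phred quality (numeric).
#' @export
empirical_quality <- function(observations, mismatches) {
  stopifnot(all(observations >= 0), all(mismatches <= observations))
  pmin(60, -10 * log10((mismatches + 1) / (observations + 2)))
}

#' Apply quality recalibration to observations
#'
#' Replaces each base's reported quality with the empirical quality of
#' its (reported quality, cycle, mate) bin when that bin holds at least
#' `min_bin_count` observations; thin bins fall back to the per-quality
#' marginal bin, and bases whose bin is absent keep their reported
#' value. Fifth-base "X" positions (T at reference C / A at reference G
#' per template strand) always keep their reported quality — their
#' mismatch rate is unobservable. Base identities are never changed.
#'
#' @param obs observation data.frame with `qual`, `cycle`, `mate`, and —
#'   for X-base protection — `ref_base` and `template_strand`.
#' @param table [build_recal_table()] output.
#' @return `obs` with `qual` replaced by the recalibrated quality
#'   (rounded to integer phred) and the reported value kept in
#'   `qual_reported`.
#' @export
apply_recalibration <- function(obs, table) {
  min_n <- attr(table, "min_bin_count")
  marginal <- attr(table, "marginal")

  bq <- empirical_quality(table$n, table$mismatch)
  bin_ok <- table$n >= min_n
  bkey <- paste(table$qual, table$cycle, table$mate, sep = "\r")
  bmap <- stats::setNames(ifelse(bin_ok, bq, NA_real_), bkey)

  mq <- empirical_quality(marginal$n, marginal$mismatch)
  m_ok <- marginal$n >= min_n
  mkey <- paste(marginal$qual, marginal$mate, sep = "\r")
  mmap <- stats::setNames(ifelse(m_ok, mq, NA_real_), mkey)

  new_q <- bmap[paste(obs$qual, obs$cycle, obs$mate, sep = "\r")]
  fallback <- mmap[paste(obs$qual, obs$mate, sep = "\r")]
  new_q[is.na(new_q)] <- fallback[is.na(new_q)]
  new_q[is.na(new_q)] <- obs$qual[is.na(new_q)]

  if (!is.null(obs$ref_base)) {
    xb <- is_x_base(obs)
    new_q[xb] <- obs$qual[xb]
  }
  obs$qual_reported <- obs$qual
  obs$qual <- as.integer(round(new_q))
  obs
}

#' Recalibrate a SAM/BAM file
#'
#' End-to-end recalibration: builds the table from reads passing the
#' prefilters, then rewrites every read's quality string (all reads,
#' including prefiltered ones, are emitted; only qualities change).
#'
#' @param input SAM or BAM path.
#' @param reference FASTA path or DNAStringSet.
#' @param output output SAM path.
#' @param known_sites optional [load_known_sites()] set.
#' @param thresholds [filter_thresholds()] for the table-building pass.
#' @param min_bin_count see [build_recal_table()].
#' @return invisibly, a list with the `recal_table` and the output path.
#' @export
recalibrate_sam <- function(input, reference, output, known_sites = NULL,
                            thresholds = filter_thresholds(),
                            min_bin_count = 100L) {
  genome <- if (methods::is(reference, "DNAStringSet")) reference
            else read_reference(reference)
  reads <- read_alignments(input)
  pf <- read_prefilters(reads, thresholds)
  obs <- normalize_read_orientation(reads[pf$keep, , drop = FALSE])
  obs <- add_ref_base(obs, genome)
  tab <- build_recal_table(obs, known_sites, min_bin_count)

  # recalibrate every read's qualities (identity of bases untouched)
  all_obs <- normalize_read_orientation(reads)
  all_obs <- add_ref_base(all_obs, genome)
  rec <- apply_recalibration(all_obs, tab)

  # rebuild per-read quality strings at aligned positions
  qlist <- lapply(reads$qual, utf8ToInt)
  rid <- match(rec$read_id, reads$read_id)
  # query position within SEQ: recompute cycle -> qpos
  qpos <- ifelse(rec$strand == "-",
                 nchar(reads$seq[rid]) - rec$cycle + 1L, rec$cycle)
  by_read <- split(data.frame(qpos = qpos, q = rec$qual + 33L), rid)
  for (r in names(by_read)) {
    i <- as.integer(r)
    qlist[[i]][by_read[[r]]$qpos] <- by_read[[r]]$q
  }
  reads$new_qual <- vapply(qlist, intToUtf8, character(1))

  write_sam(reads, genome, output, qual_col = "new_qual")
  invisible(list(table = tab, output = output))
}

#' @export
print.recal_table <- function(x, ...) {
  cat("bisulfite-aware recalibration table:", nrow(x), "bins,",
      sum(x$n), "observations\n")
  invisible(x)
}

#' Dump a recalibration table to TSV
#'
#' @param table `recal_table`.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_recal_table <- function(table, path) {
  df <- as.data.frame(table)
  df$empirical_quality <- round(empirical_quality(df$n, df$mismatch), 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
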