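#' Write per-context methylation tracks
#'
#' One output file per cytosine context. BED6+2 records hold
#' `chrom start end name score strand coverage methylation_percent`,
#' with the methylation percentage (0-100) in the score field, the
#' C-or-T read count in the coverage field and the cytosine's strand
#' relative to the reference. The wig format carries the percentage
#' only (variableStep, 1-based). Loci where methylation is not
#' measurable (C/T heterozygotes, zero informative coverage) are
#' omitted.
#'
#' @param calls calls data.frame with `contig`, `pos`, `context`,
#'   `meth_strand`, `meth_fraction`, `c_reads`, `t_reads`.
#' @param dir output directory (created if missing).
#' @param format "bed" or "wig".
#' @param prefix file-name prefix (default "methylation").
#' @param gzip compress outputs.
#' @return character vector of files written (named by context),
#'   invisibly.
#' @export
write_methylation <- function(calls, dir, format = c("bed", "wig"),
                              prefix = "methylation", gzip = FALSE) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- !is.na(calls$context) & !is.na(calls$meth_fraction) &
    (calls$c_reads + calls$t_reads) >= 1
  calls <- calls[ok, , drop = FALSE]
  contexts <- sort(unique(calls$context))
  out <- character(0)
  for (cx in contexts) {
    d <- calls[calls$context == cx, , drop = FALSE]
    d <- d[order(d$contig, d$pos), , drop = FALSE]
    ext <- paste0(".", format, if (gzip) ".gz" else "")
    path <- file.path(dir, paste0(prefix, ".", cx, ext))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    pct <- round(100 * d$meth_fraction, 2)
    if (format == "bed") {
      lines <- paste(d$contig, d$pos, d$pos + 1L, cx, pct,
                     d$meth_strand, d$c_reads + d$t_reads, pct,
                     sep = "\t")
      writeLines(lines, con)
    } else {
      lines <- character(0)
      for (ctg in unique(d$contig)) {
        s <- d[d$contig == ctg, , drop = FALSE]
        lines <- c(lines,
                   paste0("variableStep chrom=", ctg, " span=1"),
                   paste(s$pos + 1L, pct[d$contig == ctg]))
      }
      writeLines(c(paste0("track type=wiggle_0 name=\"", prefix, ".", cx,
                          "\""), lines), con)
    }
    close(con)
    out[cx] <- path
  }
  invisible(out)
}

#' Read a BED6+2 methylation file
#'
#' Inverse of [write_methylation()]'s BED output, for round-trips and
#' downstream analysis.
#'
#' @param path BED6+2 file.
#' @return data.frame with the eight columns.
#' @export
read_methylation_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("contig", "start", "end", "name", "score", "strand",
                "coverage", "methylation_percent")
  d
}

#' Write alignments as SAM
#'
#' Emits a coordinate-sorted SAM with @HD/@SQ headers derived from the
#' reference. Used by the simulator and the recalibration rewriter.
#'
#' @param reads data.frame with `read_id`, `flag`, `contig`, `pos`
#'   (0-based), `mapq`, `cigar`, `seq`, and a quality column; optional
#'   `rnext`, `pnext`, `tlen`.
#' @param genome named DNAStringSet (for @SQ lines).
#' @param path output SAM path.
#' @param qual_col which column holds the quality string.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path, qual_col = "qual") {
  o <- order(reads$contig, reads$pos)
  reads <- reads[o, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  Biostrings::width(genome)),
           "@PG\tID:methcall\tPN:methcall")
  rnext <- if (!is.null(reads$rnext)) reads$rnext else
    ifelse(bitwAnd(reads$flag, 1L) > 0L, "=", "*")
  pnext <- if (!is.null(reads$pnext)) reads$pnext else 0L
  tlen <- if (!is.null(reads$tlen)) reads$tlen else 0L
  lines <- paste(reads$read_id, reads$flag, reads$contig, reads$pos + 1L,
                 reads$mapq, reads$cigar, rnext, pnext, tlen,
                 reads$seq, reads[[qual_col]], sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a reference genome as FASTA with index
#'
#' @param genome named DNAStringSet.
#' @param path output FASTA path.
#' @return `path`, invisibly; a `.fai` index is created alongside.
#' @export
write_reference <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  Rsamtools::indexFa(path)
  invisible(path)
}
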