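#' Load a known-variant set from VCF
#'
#' Reads a VCF (e.g. a dbSNP extract) into a membership structure used
#' for genotype priors, recalibration-site exclusion and the
#' context-prior SNP mask. Alternate alleles of multi-allelic records are
#' all retained; allele frequencies are taken from the `AF` INFO field
#' when present.
#'
#' @param path VCF file (plain or bgzipped).
#' @return object of class `known_sites`.
#' @export
load_known_sites <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(gr))
  pos1 <- GenomicRanges::start(gr)
  alt <- lapply(seq_along(gr), function(i)
    as.character(gr$ALT[[i]]))
  info <- VariantAnnotation::info(vcf)
  af <- if ("AF" %in% colnames(info)) {
    lapply(seq_along(gr), function(i) as.numeric(info$AF[[i]]))
  } else {
    rep(list(numeric(0)), length(gr))
  }
  keys <- paste0(contig, ":", pos1)
  structure(list(keys = keys, alt = alt, af = af),
            class = "known_sites")
}

#' Membership query against a known-variant set
#'
#' @param ks [load_known_sites()] object (or NULL: everything novel).
#' @param contig,pos vectors; `pos` is 0-based.
#' @return logical vector.
#' @export
known_site_member <- function(ks, contig, pos) {
  if (is.null(ks)) return(rep(FALSE, length(pos)))
  paste0(contig, ":", pos + 1L) %in% ks$keys
}

# allele/AF record for one site (0-based pos); NULL when absent
known_site_record <- function(ks, contig, pos) {
  if (is.null(ks)) return(NULL)
  i <- match(paste0(contig, ":", pos + 1L), ks$keys)
  if (is.na(i)) return(NULL)
  list(alt = ks$alt[[i]], af = ks$af[[i]])
}

#' @export
print.known_sites <- function(x, ...) {
  cat("known-variant set:", length(x$keys), "sites\n")
  invisible(x)
}

vcf_alleles <- function(ref, best) {
  a <- substr(best, 1, 1); b <- substr(best, 2, 2)
  alts <- setdiff(unique(c(a, b)), ref)
  gt_idx <- function(x) if (x == ref) 0L else match(x, alts)
  list(alt = if (length(alts) == 0) "." else paste(alts, collapse = ","),
       gt = paste(sort(c(gt_idx(a), gt_idx(b))), collapse = "/"))
}

#' Write calls to VCF 4.1
#'
#' One record per emitted call. `QUAL` is the phred-scaled
#' best-vs-next-best score, `FILTER` the site-filter labels, `INFO`
#' carries depth (DP), strand bias (SB), quality-by-depth (QD) and
#' cytosine context (CX), and the sample `FORMAT` carries the genotype
#' plus methylation percentage (MP) and methylated/unmethylated read
#' counts (CM/CU). Positions are converted from the package's 0-based
#' convention to VCF's 1-based one.
#'
#' @param calls calls data.frame (see [methcall()]); required columns
#'   `contig`, `pos`, `ref`, `best`, `score`, `filter`, `depth`; optional
#'   `sb`, `qd`, `context`, `meth_fraction`, `c_reads`, `t_reads`.
#' @param path output file (".gz" suffix gives gzip).
#' @param sample_name sample column header.
#' @param command command line recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE",
                      command = "methcall") {
  hdr <- c(
    "##fileformat=VCFv4.1",
    paste0("##source=methcall"),
    paste0("##methcall_command=", command),
    "##FILTER=<ID=HighDepth,Description=\"Coverage depth above maximum\">",
    "##FILTER=<ID=StrandBias,Description=\"Strand bias score above cutoff\">",
    "##FILTER=<ID=LowQD,Description=\"Quality by depth below minimum\">",
    "##FILTER=<ID=SnpCluster,Description=\"Two or more variants in a short window\">",
    "##FILTER=<ID=MQ0Region,Description=\"Excess fraction of mapping-quality-zero reads\">",
    "##FILTER=<ID=LowQual,Description=\"Score below emission threshold\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias score\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=CX,Number=1,Type=String,Description=\"Cytosine context\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=MP,Number=1,Type=Float,Description=\"Methylation percentage of the cytosine allele\">",
    "##FORMAT=<ID=CM,Number=1,Type=Integer,Description=\"Methylated (C) read count on the cytosine strand\">",
    "##FORMAT=<ID=CU,Number=1,Type=Integer,Description=\"Unmethylated (T) read count on the cytosine strand\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))

  n <- nrow(calls)
  lines <- character(n)
  num <- function(x, digits = 4) ifelse(is.na(x) | is.infinite(x), ".",
                                        formatC(x, digits = digits,
                                                format = "g"))
  for (i in seq_len(n)) {
    al <- vcf_alleles(calls$ref[i], calls$best[i])
    info <- paste0("DP=", calls$depth[i])
    if (!is.null(calls$sb) && !is.na(calls$sb[i]) &&
        is.finite(calls$sb[i]))
      info <- paste0(info, ";SB=", num(calls$sb[i]))
    if (!is.null(calls$qd) && !is.na(calls$qd[i]))
      info <- paste0(info, ";QD=", num(calls$qd[i]))
    if (!is.null(calls$context) && !is.na(calls$context[i]))
      info <- paste0(info, ";CX=", calls$context[i])
    mp <- if (!is.null(calls$meth_fraction) && !is.na(calls$meth_fraction[i]))
      num(100 * calls$meth_fraction[i]) else "."
    cm <- if (!is.null(calls$c_reads)) calls$c_reads[i] else "."
    cu <- if (!is.null(calls$t_reads)) calls$t_reads[i] else "."
    smp <- paste(al$gt, calls$depth[i], mp, cm, cu, sep = ":")
    lines[i] <- paste(calls$contig[i], calls$pos[i] + 1L, ".",
                      calls$ref[i], al$alt,
                      num(calls$score[i], 6), calls$filter[i],
                      info, "GT:DP:MP:CM:CU", smp, sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}
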