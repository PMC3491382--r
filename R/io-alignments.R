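#' Read bisulfite alignments from SAM/BAM
#'
#' Loads alignment records via Rsamtools into the flat data.frame the
#' rest of the package operates on. A `.sam` file is converted to BAM
#' (and sorted/indexed) in a temporary location first.
#'
#' @param path SAM or BAM file.
#' @param region optional `GRanges`-style restriction as
#'   `list(contig =, start =, end =)` (1-based, inclusive).
#' @return data.frame with one row per aligned read: `read_id`, `contig`,
#'   `pos` (0-based leftmost), `strand`, `mapq`, `cigar`, `seq`, `qual`
#'   (phred+33 string), `paired`, `proper_pair`, `mate` ("first" or
#'   "second"), `duplicate`, `multimapped`.
#' @export
read_alignments <- function(path, region = NULL) {
  bam <- ensure_bam(path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what)
  } else {
    gr <- GenomicRanges::GRanges(region$contig,
                                 IRanges::IRanges(region$start, region$end))
    Rsamtools::ScanBamParam(what = what, which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- do.call(Map, c(list(c), res))  # merge ranges
  flag <- res$flag
  keep <- !is.na(res$pos) & !bitwAnd(flag, 4L)  # mapped only
  data.frame(
    read_id = res$qname[keep],
    flag = flag[keep],
    contig = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    mapq = res$mapq[keep],
    cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep],
    paired = bitwAnd(flag[keep], 1L) > 0L,
    proper_pair = bitwAnd(flag[keep], 2L) > 0L,
    mate = ifelse(bitwAnd(flag[keep], 128L) > 0L, "second", "first"),
    duplicate = bitwAnd(flag[keep], 1024L) > 0L,
    multimapped = bitwAnd(flag[keep], 256L) > 0L |
      bitwAnd(flag[keep], 2048L) > 0L,
    stringsAsFactors = FALSE)
}

# Convert SAM to sorted, indexed BAM when needed; returns a BAM path.
ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai")))
    tryCatch(Rsamtools::indexBam(path), error = function(e)
      stop("input BAM could not be indexed; is it coordinate-sorted? (",
           conditionMessage(e), ")"))
  path
}

#' Read a reference genome
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Per-base observations in reference-forward space
#'
#' Expands aligned reads into one row per aligned base. SAM stores the
#' sequence of reverse-strand alignments already reverse-complemented, so
#' bases come out in reference-forward space directly; what remains is to
#' recover each base's original sequencing cycle (reversed for
#' reverse-strand alignments) and the *template strand* of the bisulfite
#' fragment. For the directional protocol the template strand is the
#' alignment strand of the first end: a second-end read reports the
#' complement of the same converted template, so its bisulfite
#' substitution class matches its mate's (C->T for forward templates,
#' G->A in forward space for reverse templates). Soft-clipped and
#' inserted bases generate no observations; deletions and skips consume
#' reference without emitting rows.
#'
#' @param reads data.frame as returned by [read_alignments()].
#' @return data.frame with columns `read_id`, `contig`, `pos` (0-based),
#'   `base`, `qual` (integer phred), `cycle` (1-based original sequencing
#'   cycle), `template_strand`, `mate`, `mapq`, `strand` (alignment
#'   strand). Reads with unparseable CIGARs are skipped with a warning.
#' @export
normalize_read_orientation <- function(reads) {
  n <- nrow(reads)
  if (n == 0) {
    return(data.frame(read_id = character(0), contig = character(0),
                      pos = integer(0), base = character(0),
                      qual = integer(0), cycle = integer(0),
                      template_strand = character(0), mate = character(0),
                      mapq = integer(0), strand = character(0)))
  }
  if (is.null(reads$strand) || is.null(reads$mate)) {
    fl <- as.integer(reads$flag)
    if (is.null(reads$strand))
      reads$strand <- ifelse(bitwAnd(fl, 16L) > 0L, "-", "+")
    if (is.null(reads$mate))
      reads$mate <- ifelse(bitwAnd(fl, 128L) > 0L, "second", "first")
  }
  bad <- is.na(reads$cigar) | reads$cigar == "*"
  if (any(bad)) {
    warning(sum(bad), " read(s) with missing/unparseable CIGAR skipped")
    reads <- reads[!bad, , drop = FALSE]
    n <- nrow(reads)
  }
  cig <- reads$cigar
  qry <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  ref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = c("M", "=", "X"))
  op_read <- rep(seq_len(n), S4Vectors::elementNROWS(qry))

  qstart <- unlist(IRanges::start(qry), use.names = FALSE)
  w <- unlist(IRanges::width(qry), use.names = FALSE)
  rstart <- unlist(IRanges::start(ref), use.names = FALSE)
  opidx <- rep(seq_along(w), w)
  off <- sequence(w) - 1L
  rowi <- op_read[opidx]

  qpos <- qstart[opidx] + off                    # 1-based position in SEQ
  rpos <- reads$pos[rowi] + rstart[opidx] + off - 1L

  # flatten sequences and qualities once, then index per base
  lens <- nchar(reads$seq)
  start0 <- c(0L, cumsum(lens))[seq_len(n)]
  sall <- unlist(strsplit(reads$seq, ""), use.names = FALSE)
  qall <- unlist(lapply(reads$qual, utf8ToInt), use.names = FALSE)
  flat <- start0[rowi] + qpos
  base <- sall[flat]
  qual <- qall[flat] - 33L

  readlen <- lens[rowi]
  revaln <- reads$strand[rowi] == "-"
  cycle <- ifelse(revaln, readlen - qpos + 1L, qpos)

  second <- reads$mate[rowi] == "second"
  template <- ifelse(xor(revaln, second), "-", "+")

  data.frame(read_id = reads$read_id[rowi],
             contig = reads$contig[rowi],
             pos = rpos,
             base = base,
             qual = as.integer(qual),
             cycle = as.integer(cycle),
             template_strand = template,
             mate = reads$mate[rowi],
             mapq = reads$mapq[rowi],
             strand = reads$strand[rowi],
             stringsAsFactors = FALSE)
}

#' Annotate observations with the reference base
#'
#' Adds a `ref_base` column looked up from the reference at each
#' observation's position.
#'
#' @param obs observation data.frame with `contig` and `pos` (0-based).
#' @param genome named DNAStringSet.
#' @return `obs` with a `ref_base` character column.
#' @export
add_ref_base <- function(obs, genome) {
  obs$ref_base <- NA_character_
  for (ctg in unique(obs$contig)) {
    sel <- obs$contig == ctg
    cs <- strsplit(as.character(genome[[ctg]]), "")[[1]]
    obs$ref_base[sel] <- cs[obs$pos[sel] + 1L]
  }
  obs
}
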