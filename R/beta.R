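#' Cytosine context patterns
#'
#' Parse IUPAC context patterns such as `"CG"`, `"CH"`, `"CHH"` or
#' `"CCGG"`. `offset` gives the 0-based position of the scored cytosine
#' within the pattern (0 unless stated otherwise, e.g. 1 for the MspI
#' CCGG site scored at the inner C).
#'
#' @param pattern character vector of IUPAC strings, each containing a C
#'   at its offset.
#' @param offset integer vector (recycled), 0-based index of the scored C.
#' @return data.frame with columns `pattern` and `offset`.
#' @export
context_patterns <- function(pattern = c("CG", "CH"), offset = 0L) {
  pattern <- toupper(pattern)
  offset <- as.integer(rep_len(offset, length(pattern)))
  ok <- vapply(pattern, function(p)
    all(strsplit(p, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)),
    logical(1))
  if (!all(ok)) stop("invalid IUPAC code in pattern(s): ",
                     paste(pattern[!ok], collapse = ", "))
  if (any(substr(pattern, offset + 1, offset + 1) != "C"))
    stop("pattern must have C at the scored offset")
  data.frame(pattern = pattern, offset = offset, stringsAsFactors = FALSE)
}

iupac_match <- function(seq_chars, pattern_chars) {
  if (length(seq_chars) != length(pattern_chars)) return(FALSE)
  map <- Biostrings::IUPAC_CODE_MAP
  all(mapply(function(s, p) {
    s %in% strsplit(map[[p]], "")[[1]]
  }, seq_chars, pattern_chars))
}

#' Match a cytosine against context patterns
#'
#' Tests the strand-appropriate sequence window around a cytosine against
#' each pattern in user-given order and returns the first match. For a
#' reverse-strand cytosine (a G on the forward reference sequence) the
#' window is reverse-complemented before matching, so that patterns are
#' always read 5'->3' on the cytosine's own strand.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or object coercible
#'   to one) holding the reference.
#' @param contig contig name.
#' @param position 0-based position of the cytosine (a C on the forward
#'   sequence for `strand = "+"`, a G for `strand = "-"`).
#' @param strand "+" or "-".
#' @param patterns [context_patterns()] data.frame.
#' @return the matching pattern string, or `NA_character_` when no
#'   pattern matches or the window runs off the contig.
#' @export
match_context <- function(genome, contig, position, strand,
                          patterns = context_patterns()) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  contig_seq <- genome[[contig]]
  clen <- length(contig_seq)
  for (i in seq_len(nrow(patterns))) {
    pat <- patterns$pattern[i]
    off <- patterns$offset[i]
    L <- nchar(pat)
    if (strand == "+") {
      start <- position - off           # 0-based window start
      end <- start + L - 1
      if (start < 0 || end >= clen) next
      win <- as.character(Biostrings::subseq(contig_seq, start + 1, end + 1))
    } else {
      end <- position + off             # window on forward coords
      start <- end - L + 1
      if (start < 0 || end >= clen) next
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(contig_seq, start + 1, end + 1)))
    }
    if (iupac_match(strsplit(win, "")[[1]], strsplit(pat, "")[[1]]))
      return(pat)
  }
  NA_character_
}

#' Naive methylation prior
#'
#' The flat prior: every cytosine is methylated with probability 0.5,
#' independent of the data. Used on its own (`beta_mode = "naive"`) and as
#' round one of the context-specific procedure.
#'
#' @return 0.5.
#' @export
beta_naive <- function() 0.5

#' Context-specific methylation priors from first-round calls
#'
#' Round two of the context-specific procedure: from calls produced with
#' the naive prior, select high-confidence non-SNP homozygous cytosines
#' (posterior probability of the homozygous-cytosine genotype > 0.9999,
#' absent from the known-variant set) and average their per-locus
#' C/(C+T) within each sequence context.
#'
#' @param first_round_calls data.frame of calls with columns `best`,
#'   `post_best`, `known` (logical), `context`, `c_reads`, `t_reads`.
#' @param patterns [context_patterns()].
#' @param posterior_min selection threshold (default 0.9999).
#' @return named numeric vector, one mean methylation level per context
#'   pattern; contexts with no qualifying loci fall back to 0.5 with
#'   attribute `fallback` naming them.
#' @export
beta_context <- function(first_round_calls, patterns = context_patterns(),
                         posterior_min = 0.9999) {
  out <- stats::setNames(rep(0.5, nrow(patterns)), patterns$pattern)
  fb <- patterns$pattern
  calls <- first_round_calls
  if (!is.null(calls) && nrow(calls) > 0) {
    sel <- calls$best %in% c("CC", "GG") &
      calls$post_best > posterior_min &
      !calls$known &
      !is.na(calls$context) &
      (calls$c_reads + calls$t_reads) > 0
    calls <- calls[sel, , drop = FALSE]
    frac <- calls$c_reads / (calls$c_reads + calls$t_reads)
    for (p in patterns$pattern) {
      v <- frac[calls$context == p]
      if (length(v) > 0) {
        out[p] <- mean(v)
        fb <- setdiff(fb, p)
      }
    }
  }
  if (length(fb) == length(out))
    warning("no qualifying loci for any context; all priors fall back to 0.5")
  attr(out, "fallback") <- fb
  out
}

#' Locus-specific methylation prior
#'
#' \eqn{\beta_j = C/(C+T)} over bisulfite-affected observations at the
#' locus itself (the default mode): forward-template C and T reads for a
#' forward-strand cytosine, mirrored G and A reads on reverse templates
#' for a reverse-strand one. Falls back to 0.5 when no informative reads
#' are present.
#'
#' @param locus pileup data.frame (columns `base`, `template_strand`) or
#'   list with `$observations`.
#' @param strand strand of the cytosine being scored ("+" or "-").
#' @return methylation prior in `[0,1]`; attribute `fallback` is TRUE
#'   when no informative reads were available.
#' @export
beta_locus <- function(locus, strand = "+") {
  obs <- as_pileup_df(locus)
  if (strand == "+") {
    sel <- obs$template_strand == "+" & obs$base %in% c("C", "T")
    cc <- sum(obs$base[sel] == "C")
  } else {
    sel <- obs$template_strand == "-" & obs$base %in% c("G", "A")
    cc <- sum(obs$base[sel] == "G")
  }
  n <- sum(sel)
  if (n == 0) return(structure(0.5, fallback = TRUE))
  structure(cc / n, fallback = FALSE)
}
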