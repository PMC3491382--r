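#' The ten diploid genotypes
#'
#' Canonical, lexicographically ordered unordered allele pairs over
#' \{A,C,G,T\}: four homozygous and six heterozygous genotypes. All
#' posterior vectors and prior vectors in the package are indexed in this
#' order, and ties between equally probable genotypes are broken by it.
#'
#' @format Character vector of length 10 ("AA", "AC", ..., "TT").
#' @export
GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

BASES <- c("A", "C", "G", "T")

# allele_a / allele_b per genotype, canonical order (a <= b)
GT_ALLELES <- matrix(
  c("A","A", "A","C", "A","G", "A","T", "C","C",
    "C","G", "C","T", "G","G", "G","T", "T","T"),
  ncol = 2, byrow = TRUE,
  dimnames = list(GENOTYPES, c("a", "b"))
)

#' Canonicalize an unordered allele pair
#'
#' @param a,b single nucleotides (A/C/G/T).
#' @return Genotype label with alleles in canonical (sorted) order, so that
#'   `genotype("T", "C") == genotype("C", "T") == "CT"`.
#' @export
genotype <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(all(a %in% BASES), all(b %in% BASES))
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

#' Is a substitution a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' substitutions; everything else is a transversion.
#' @param ref,alt nucleotide vectors.
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Genotype prior parameters
#'
#' Parameters of the population-genetic genotype prior \eqn{\pi(G)}. The
#' reference homozygote receives mass \eqn{1 - \theta}, where \eqn{\theta}
#' is the expected heterozygosity: `theta_novel` at sites absent from the
#' known-variant set and `theta_known` at sites present in it. The
#' remaining \eqn{\theta} is distributed over the nine non-reference
#' genotypes with transition alleles up-weighted by `titv_ratio` and
#' genotypes retaining the reference allele (reference hets) up-weighted
#' by `het_vs_homalt_weight`.
#'
#' @param theta_novel heterozygosity at novel sites (default 1e-3).
#' @param theta_known heterozygosity at known polymorphic sites (default 0.1).
#' @param titv_ratio transition:transversion allele weight (default 2).
#' @param het_vs_homalt_weight relative mass of a reference-containing
#'   heterozygote versus non-reference genotypes (default 2).
#' @return object of class `prior_params`.
#' @export
prior_params <- function(theta_novel = 1e-3, theta_known = 0.1,
                         titv_ratio = 2.0, het_vs_homalt_weight = 2.0) {
  stopifnot(theta_novel > 0, theta_known > 0,
            titv_ratio > 0, het_vs_homalt_weight > 0)
  structure(list(theta_novel = theta_novel, theta_known = theta_known,
                 titv_ratio = titv_ratio,
                 het_vs_homalt_weight = het_vs_homalt_weight),
            class = "prior_params")
}

#' Genotype prior distribution at one site
#'
#' Builds \eqn{\pi(G)} over the ten diploid genotypes given the reference
#' base and (optionally) a known-variant record. Each non-reference allele
#' x gets weight `titv_ratio` if ref->x is a transition and 1 otherwise; a
#' genotype's weight is the product of its non-reference allele weights,
#' multiplied by `het_vs_homalt_weight` when it still carries the
#' reference allele. These weights are scaled to sum to \eqn{\theta}.
#'
#' When `known_site` carries allele frequencies (a list with elements
#' `alt` and `af`), the listed alternate alleles absorb the variant mass
#' in proportion to their frequencies; unlisted alleles share the residual
#' mass `max(1 - sum(af), 0.01)` according to their transition/transversion
#' weights.
#'
#' @param ref_base reference base (A/C/G/T; N yields a flagged uniform
#'   prior).
#' @param known_site `NULL` for a novel site, `TRUE` for a known site
#'   without frequency data, or `list(alt=, af=)` with per-allele
#'   frequencies.
#' @param p [prior_params()].
#' @return named numeric vector over [GENOTYPES] summing to 1; attribute
#'   `flagged` is TRUE for an N reference.
#' @export
genotype_priors <- function(ref_base, known_site = NULL, p = prior_params()) {
  ref_base <- toupper(ref_base)
  if (identical(ref_base, "N")) {
    pr <- stats::setNames(rep(1 / 10, 10), GENOTYPES)
    attr(pr, "flagged") <- TRUE
    return(pr)
  }
  stopifnot(ref_base %in% BASES)
  known <- !is.null(known_site) && !identical(known_site, FALSE)
  theta <- if (known) p$theta_known else p$theta_novel

  # per-allele weights for the three non-reference alleles
  alts <- setdiff(BASES, ref_base)
  w <- ifelse(is_transition(ref_base, alts), p$titv_ratio, 1.0)
  names(w) <- alts

  if (known && is.list(known_site) && !is.null(known_site$af) &&
      length(known_site$af) > 0) {
    af <- known_site$af
    listed <- toupper(known_site$alt)
    keep <- listed %in% alts & !is.na(af) & af > 0
    listed <- listed[keep]; af <- af[keep]
    if (length(listed) > 0) {
      resid <- max(1 - sum(af), 0.01)
      unlisted <- setdiff(alts, listed)
      w2 <- w
      w2[listed] <- af / sum(af)
      if (length(unlisted) > 0)
        w2[unlisted] <- resid * w[unlisted] / sum(w[unlisted])
      w <- w2
    }
  }

  gw <- numeric(10); names(gw) <- GENOTYPES
  for (g in GENOTYPES) {
    a <- GT_ALLELES[g, "a"]; b <- GT_ALLELES[g, "b"]
    if (a == ref_base && b == ref_base) next
    # product over distinct non-reference alleles, so that a reference het
    # outweighs the matching non-reference homozygote by exactly
    # het_vs_homalt_weight
    wt <- prod(w[unique(setdiff(c(a, b), ref_base))])
    if (a == ref_base || b == ref_base) wt <- wt * p$het_vs_homalt_weight
    gw[g] <- wt
  }
  pr <- gw / sum(gw) * theta
  pr[genotype(ref_base, ref_base)] <- 1 - theta
  attr(pr, "flagged") <- FALSE
  pr
}
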