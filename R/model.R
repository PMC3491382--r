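#' Caller model parameters
#'
#' Bisulfite-specific parameters of the observation model and calling
#' thresholds.
#'
#' @param alpha underconversion rate: probability that an unmethylated
#'   cytosine fails to convert (default 0.0025). Often estimated from
#'   unmethylated spike-in DNA or the mitochondrial genome.
#' @param gamma overconversion rate: probability that a methylated
#'   cytosine is converted anyway (default 0).
#' @param min_base_quality phred cutoff; only bases with quality strictly
#'   greater than this are used (default 5).
#' @param score_threshold phred-scaled log-odds between best and
#'   second-best genotype required to emit a confident call (default 20).
#' @param beta_mode methylation-prior estimation mode: `"locus"`
#'   (per-cytosine C/(C+T), the default), `"context"` (two-round
#'   per-context means), or `"naive"` (flat 0.5).
#' @return object of class `model_params`.
#' @export
model_params <- function(alpha = 0.0025, gamma = 0.0,
                         min_base_quality = 5L, score_threshold = 20,
                         beta_mode = c("locus", "context", "naive")) {
  beta_mode <- match.arg(beta_mode)
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1,
            min_base_quality >= 0, score_threshold >= 0)
  structure(list(alpha = alpha, gamma = gamma,
                 min_base_quality = as.integer(min_base_quality),
                 score_threshold = score_threshold, beta_mode = beta_mode),
            class = "model_params")
}

#' Likelihood of one base call given one allele
#'
#' The per-read observation model. For A and T alleles bisulfite
#' conversion does not apply and the likelihood is the plain error model:
#' \eqn{1-\epsilon} for a matching call, \eqn{\epsilon/3} otherwise. For a
#' C allele, reads whose template strand carries the cytosine are
#' bisulfite-affected: with methylation prior \eqn{\beta}, the template
#' retains the C with probability
#' \eqn{p_C = \beta(1-\gamma) + (1-\beta)\alpha} (methylated and not
#' overconverted, or unmethylated and underconverted) and is converted to
#' T with probability \eqn{p_T = 1 - p_C}; sequencing error is then
#' applied on top, so e.g.
#' \eqn{P(C) = p_C(1-\epsilon) + p_T\epsilon/3}. Reads from the opposite
#' strand see the unconverted base and use the plain error model. G
#' alleles are the strand mirror image (reverse-strand templates are
#' affected, conversion appears as G->A in reference-forward space).
#'
#' @param obs a read observation: list or one-row data.frame with fields
#'   `base` (A/C/G/T, reference-forward), `epsilon` (base-call error
#'   probability), `template_strand` ("+" or "-").
#' @param allele the allele hypothesis (A/C/G/T).
#' @param beta methylation prior in `[0,1]` for the cytosine carried by
#'   this allele (ignored for A/T).
#' @param params [model_params()] supplying `alpha` and `gamma`.
#' @return probability of observing `obs$base` under the allele.
#' @export
allele_observation_likelihood <- function(obs, allele, beta = 0.5,
                                          params = model_params()) {
  stopifnot(allele %in% BASES, beta >= 0, beta <= 1)
  if (obs$base == "N") stop("N base calls must be excluded upstream")
  lik <- obs_lik_matrix(base = obs$base, epsilon = obs$epsilon,
                        template_strand = obs$template_strand,
                        beta_c = beta, beta_g = beta,
                        alpha = params$alpha, gamma = params$gamma)
  as.numeric(lik[1, allele])
}

# Vectorized observation-likelihood engine.
#
# Returns an n x 4 matrix (columns A,C,G,T) of P(obs | allele) for each
# observation. beta_c is the methylation prior of the forward-strand
# cytosine at the observation's locus (used for the C allele), beta_g the
# reverse-strand one (used for the G allele). All arguments are recycled
# to a common length.
obs_lik_matrix <- function(base, epsilon, template_strand,
                           beta_c, beta_g, alpha, gamma) {
  n <- max(length(base), length(epsilon), length(template_strand),
           length(beta_c), length(beta_g))
  base <- rep_len(base, n)
  e <- rep_len(epsilon, n)
  ts <- rep_len(template_strand, n)
  beta_c <- rep_len(beta_c, n)
  beta_g <- rep_len(beta_g, n)

  e3 <- e / 3
  out <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, BASES))

  # plain error-model columns
  out[, "A"] <- ifelse(base == "A", 1 - e, e3)
  out[, "T"] <- ifelse(base == "T", 1 - e, e3)

  # C allele: "+" templates are bisulfite-affected
  pc <- beta_c * (1 - gamma) + (1 - beta_c) * alpha
  pt <- 1 - pc
  fwd <- ts == "+"
  out[, "C"] <- ifelse(fwd,
    ifelse(base == "C", pc * (1 - e) + pt * e3,
    ifelse(base == "T", pt * (1 - e) + pc * e3, e3)),
    ifelse(base == "C", 1 - e, e3))

  # G allele: "-" templates are affected; conversion reads G->A in
  # reference-forward space
  pg <- beta_g * (1 - gamma) + (1 - beta_g) * alpha
  pa <- 1 - pg
  out[, "G"] <- ifelse(!fwd,
    ifelse(base == "G", pg * (1 - e) + pa * e3,
    ifelse(base == "A", pa * (1 - e) + pg * e3, e3)),
    ifelse(base == "G", 1 - e, e3))

  out
}

#' Likelihood of a pileup under one diploid genotype
#'
#' \eqn{\Pr(D|G{=}AB) = \prod_j [\tfrac12 \Pr(D_j|A) + \tfrac12
#' \Pr(D_j|B)]}: each read is assumed equally likely to originate from
#' either parental allele. Computed in log space; an empty pileup returns
#' log-likelihood 0 for every genotype.
#'
#' @param locus a pileup: data.frame of observations with columns `base`,
#'   `epsilon`, `template_strand`.
#' @param g genotype label (one of [GENOTYPES], any allele order).
#' @param beta methylation prior used for both C and G alleles; see
#'   [locus_posterior()] for strand-specific priors.
#' @param params [model_params()].
#' @return log-likelihood (natural log).
#' @export
genotype_likelihood <- function(locus, g, beta = 0.5,
                                params = model_params()) {
  obs <- as_pileup_df(locus)
  g <- genotype(substr(g, 1, 1), substr(g, 2, 2))
  if (nrow(obs) == 0) return(0)
  lik <- obs_lik_matrix(obs$base, obs$epsilon, obs$template_strand,
                        beta_c = beta, beta_g = beta,
                        alpha = params$alpha, gamma = params$gamma)
  a <- GT_ALLELES[g, "a"]; b <- GT_ALLELES[g, "b"]
  sum(log(0.5 * lik[, a] + 0.5 * lik[, b]))
}

as_pileup_df <- function(locus) {
  if (is.data.frame(locus)) return(locus)
  if (is.list(locus) && !is.null(locus$observations))
    return(locus$observations)
  stop("expected a pileup data.frame or a list with $observations")
}

#' Posterior genotype call at one locus
#'
#' Combines the genotype prior with the read-product likelihood:
#' \eqn{\Pr(G|D) = \pi(G)\Pr(D|G) / \sum_{AB} \pi(AB)\Pr(D|AB)},
#' normalized over all ten diploid genotypes in log space. The reported
#' score is the phred-scaled log-odds between the best and second-best
#' genotype, \eqn{10\log_{10}[\Pr(G_{best}|D)/\Pr(G_{nextbest}|D)]}; ties
#' are broken by canonical genotype order, giving score 0.
#'
#' @param locus pileup data.frame (columns `base`, `epsilon`,
#'   `template_strand`), or a list with `$observations` and optionally
#'   `$ref_base`, `$contig`, `$position`.
#' @param priors named vector over [GENOTYPES] summing to 1 (see
#'   [genotype_priors()]).
#' @param beta methylation prior; either a single value used for both
#'   strands or `c(beta_c, beta_g)` for the forward/reverse-strand
#'   cytosine.
#' @param params [model_params()].
#' @return list of class `genotype_call` with elements `posterior` (named
#'   vector), `best`, `next_best`, `score`, `methylation` (fraction,
#'   c_reads, t_reads, measurable flag), and `filters` (character).
#' @export
locus_posterior <- function(locus, priors, beta = 0.5,
                            params = model_params()) {
  stopifnot(abs(sum(priors) - 1) < 1e-6)
  priors <- priors[GENOTYPES]
  obs <- as_pileup_df(locus)
  beta_c <- beta[[1]]
  beta_g <- if (length(beta) > 1) beta[[2]] else beta[[1]]

  loglik <- numeric(10); names(loglik) <- GENOTYPES
  if (nrow(obs) > 0) {
    lik <- obs_lik_matrix(obs$base, obs$epsilon, obs$template_strand,
                          beta_c = beta_c, beta_g = beta_g,
                          alpha = params$alpha, gamma = params$gamma)
    for (g in GENOTYPES) {
      a <- GT_ALLELES[g, "a"]; b <- GT_ALLELES[g, "b"]
      loglik[g] <- sum(log(0.5 * lik[, a] + 0.5 * lik[, b]))
    }
  }
  lp <- log(priors) + loglik
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))

  ord <- order(-post)              # stable: ties keep canonical order
  best <- GENOTYPES[ord[1]]
  next_best <- GENOTYPES[ord[2]]
  score <- if (post[ord[1]] == post[ord[2]]) 0 else
    10 * (log10(post[ord[1]]) - log10(post[ord[2]]))

  call <- structure(
    list(posterior = post, best = best, next_best = next_best,
         score = unname(score), filters = character(0), locus = locus),
    class = "genotype_call")
  call$methylation <- methylation_from_call(call, locus)
  call
}

#' Methylation summary for a genotype call
#'
#' The methylation fraction is the number of C reads divided by the
#' number of C-or-T reads among bisulfite-affected (forward-template)
#' observations; for reverse-strand cytosines (G alleles) the mirrored
#' G/(G+A) count over reverse-template observations is used. Methylation
#' is only defined when the best genotype carries a cytosine allele, is
#' flagged not measurable for C/T (or mirrored G/A) heterozygotes —
#' C-strand reads cannot distinguish an unmethylated C from the T allele
#' — and is undefined when no informative reads remain.
#'
#' @param call a `genotype_call` (needs `$best`).
#' @param locus pileup as in [locus_posterior()].
#' @return list with `fraction` (NA when undefined), `c_reads`,
#'   `t_reads`, `strand` ("+", "-" or NA), and `measurable` flag.
#' @export
methylation_from_call <- function(call, locus) {
  obs <- as_pileup_df(locus)
  best <- call$best
  has_c <- grepl("C", best, fixed = TRUE)
  has_g <- grepl("G", best, fixed = TRUE)
  none <- list(fraction = NA_real_, c_reads = 0L, t_reads = 0L,
               strand = NA_character_, measurable = FALSE)
  if (!has_c && !has_g) return(none)

  if (has_c) {
    if (best == "CT") return(none)  # C/T het: C-strand reads are ambiguous
    sel <- obs$template_strand == "+" & obs$base %in% c("C", "T")
    cc <- sum(obs$base[sel] == "C"); tt <- sum(obs$base[sel] == "T")
    strand <- "+"
  } else {
    if (best == "AG") return(none)  # mirrored G/A het
    sel <- obs$template_strand == "-" & obs$base %in% c("G", "A")
    cc <- sum(obs$base[sel] == "G"); tt <- sum(obs$base[sel] == "A")
    strand <- "-"
  }
  if (cc + tt == 0)
    return(list(fraction = NA_real_, c_reads = 0L, t_reads = 0L,
                strand = strand, measurable = FALSE))
  list(fraction = cc / (cc + tt), c_reads = as.integer(cc),
       t_reads = as.integer(tt), strand = strand, measurable = TRUE)
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("genotype call:", x$best,
      sprintf("(score %.2f, next %s)\n", x$score, x$next_best))
  if (isTRUE(x$methylation$measurable))
    cat(sprintf("methylation: %.3f (%dC/%dT, strand %s)\n",
                x$methylation$fraction, x$methylation$c_reads,
                x$methylation$t_reads, x$methylation$strand))
  invisible(x)
}
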