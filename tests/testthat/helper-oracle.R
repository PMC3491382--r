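# Independent brute-force oracles, kept deliberately separate from the
# package's own arithmetic.

# Exhaustive enumeration over latent (methylated, converted, error-target)
# states for the likelihood of observing `base` given a single C allele on
# its bisulfite-affected strand.
enumerate_c_strand_lik <- function(base, eps, beta, alpha, gamma) {
  total <- 0
  for (meth in c(TRUE, FALSE)) {
    p_m <- if (meth) beta else 1 - beta
    for (conv in c(TRUE, FALSE)) {
      p_c <- if (meth) {
        if (conv) gamma else 1 - gamma
      } else {
        if (conv) 1 - alpha else alpha
      }
      template <- if (conv) "T" else "C"
      for (obs in c("A", "C", "G", "T")) {
        p_e <- if (obs == template) 1 - eps else eps / 3
        if (obs == base) total <- total + p_m * p_c * p_e
      }
    }
  }
  total
}

# Brute-force posterior over the 10 genotypes for a pileup data.frame,
# multiplying per-read terms one by one (no log-space, no vectorization).
brute_force_posterior <- function(obs, priors, beta_c, beta_g,
                                  alpha, gamma) {
  gts <- c("AA","AC","AG","AT","CC","CG","CT","GG","GT","TT")
  one_allele <- function(base, eps, tstrand, allele) {
    if (allele %in% c("A", "T"))
      return(if (base == allele) 1 - eps else eps / 3)
    if (allele == "C") {
      if (tstrand == "+")
        return(enumerate_c_strand_lik(base, eps, beta_c, alpha, gamma))
      return(if (base == "C") 1 - eps else eps / 3)
    }
    # G allele: mirror, reverse templates affected, G->A conversion
    if (tstrand == "-") {
      mirror <- c(A = "T", C = "G", G = "C", T = "A")[[base]]
      return(enumerate_c_strand_lik(mirror, eps, beta_g, alpha, gamma))
    }
    if (base == "G") 1 - eps else eps / 3
  }
  lik <- sapply(gts, function(g) {
    a <- substr(g, 1, 1); b <- substr(g, 2, 2)
    p <- 1
    for (j in seq_len(nrow(obs))) {
      p <- p * (0.5 * one_allele(obs$base[j], obs$epsilon[j],
                                 obs$template_strand[j], a) +
                0.5 * one_allele(obs$base[j], obs$epsilon[j],
                                 obs$template_strand[j], b))
    }
    p
  })
  post <- priors[gts] * lik
  post <- post / sum(post)
  attr(post, "likelihood") <- lik
  post
}

# quick constructor for pileup observation tables in tests
obs_df <- function(base, epsilon = 0.001, template_strand = "+",
                   cycle = 1L, mapq = 40L) {
  n <- length(base)
  data.frame(base = base,
             epsilon = rep_len(epsilon, n),
             template_strand = rep_len(template_strand, n),
             cycle = rep_len(as.integer(cycle), n),
             mapq = rep_len(as.integer(mapq), n),
             stringsAsFactors = FALSE)
}
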