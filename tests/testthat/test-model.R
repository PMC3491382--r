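test_that("genotype set is canonical and priors allocate theta correctly", {
  expect_length(GENOTYPES, 10)
  expect_identical(genotype("T", "C"), "CT")
  expect_identical(genotype("C", "T"), "CT")

  p <- prior_params()
  pr <- genotype_priors("A", known_site = NULL, p = p)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(unname(pr[["AA"]]), 0.999, tolerance = 1e-12)

  # known site: theta = 0.1, transition het outweighs transversion het
  prk <- genotype_priors("A", known_site = TRUE, p = p)
  expect_equal(unname(prk[["AA"]]), 0.9, tolerance = 1e-12)
  expect_gt(prk[["AG"]], prk[["AC"]])
  expect_equal(unname(prk[["AG"]] / prk[["AC"]]), p$titv_ratio)

  # ref het outweighs the non-ref homozygote of the same allele
  expect_equal(unname(prk[["AG"]] / prk[["GG"]]),
               p$het_vs_homalt_weight)

  # every reference base yields a normalized prior
  for (b in c("A", "C", "G", "T"))
    expect_equal(sum(genotype_priors(b)), 1, tolerance = 1e-12)

  # N reference: flagged uniform
  prn <- genotype_priors("N")
  expect_true(attr(prn, "flagged"))
  expect_equal(as.numeric(prn), rep(0.1, 10))

  # allele frequencies concentrate variant mass on listed alleles
  praf <- genotype_priors("A", known_site = list(alt = "T", af = 0.3))
  expect_gt(praf[["AT"]], praf[["AG"]])
})

test_that("A/T allele likelihoods follow the plain error model", {
  p <- model_params()
  o <- list(base = "A", epsilon = 0.03, template_strand = "+")
  expect_equal(allele_observation_likelihood(o, "T", 0.5, p), 0.01)
  expect_equal(allele_observation_likelihood(o, "A", 0.5, p), 0.97)
  o2 <- list(base = "T", epsilon = 0.12, template_strand = "-")
  expect_equal(allele_observation_likelihood(o2, "T", 0.5, p), 0.88)
})

test_that("C-allele likelihood matches worked values and strand branches", {
  # unmethylated, perfect conversion, no error: T is certain
  p0 <- model_params(alpha = 0, gamma = 0)
  expect_equal(allele_observation_likelihood(
    list(base = "T", epsilon = 0, template_strand = "+"), "C", 0, p0), 1.0)
  # methylated, protected: C is certain
  expect_equal(allele_observation_likelihood(
    list(base = "C", epsilon = 0, template_strand = "+"), "C", 1, p0), 1.0)
  # half-methylated with sequencing error
  expect_equal(allele_observation_likelihood(
    list(base = "C", epsilon = 0.01, template_strand = "+"), "C", 0.5, p0),
    0.5 * 0.99 + 0.5 * 0.01 / 3, tolerance = 1e-12)
  # opposite-strand read: plain error model
  expect_equal(allele_observation_likelihood(
    list(base = "C", epsilon = 0.02, template_strand = "-"), "C", 0.5,
    model_params()), 0.98)
})

test_that("C/G observation model equals exhaustive latent-state enumeration", {
  grid <- expand.grid(beta = c(0, 0.1, 0.5, 0.9, 1),
                      alpha = c(0, 0.0025, 0.05),
                      gamma = c(0, 0.01),
                      eps = c(1e-4, 0.01, 0.25),
                      base = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  expect_gte(nrow(grid), 100)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- model_params(alpha = g$alpha, gamma = g$gamma)
    got <- allele_observation_likelihood(
      list(base = g$base, epsilon = g$eps, template_strand = "+"),
      "C", g$beta, p)
    want <- enumerate_c_strand_lik(g$base, g$eps, g$beta, g$alpha, g$gamma)
    expect_equal(got, want, tolerance = 1e-12)
    # G allele on a reverse-template read is the strand mirror image
    mirror <- c(A = "T", C = "G", G = "C", T = "A")[[g$base]]
    got_g <- allele_observation_likelihood(
      list(base = g$base, epsilon = g$eps, template_strand = "-"),
      "G", g$beta, p)
    expect_equal(got_g,
                 enumerate_c_strand_lik(mirror, g$eps, g$beta,
                                        g$alpha, g$gamma),
                 tolerance = 1e-12)
  }
})

test_that("observation model is normalized over the four bases", {
  set.seed(7)
  for (i in 1:200) {
    beta <- runif(1); alpha <- runif(1, 0, 0.1); gamma <- runif(1, 0, 0.1)
    eps <- runif(1, 1e-6, 0.5)
    ts <- sample(c("+", "-"), 1)
    p <- model_params(alpha = alpha, gamma = gamma)
    for (allele in c("A", "C", "G", "T")) {
      tot <- sum(vapply(c("A", "C", "G", "T"), function(b)
        allele_observation_likelihood(
          list(base = b, epsilon = eps, template_strand = ts),
          allele, beta, p), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("degenerate limit: alpha=gamma=0, beta=1 reduces to error model", {
  p <- model_params(alpha = 0, gamma = 0)
  for (b in c("A", "C", "G", "T")) {
    eps <- 0.07
    bis <- allele_observation_likelihood(
      list(base = b, epsilon = eps, template_strand = "+"), "C", 1, p)
    plain <- if (b == "C") 1 - eps else eps / 3
    expect_identical(bis, plain)
  }
})

test_that("genotype likelihood equals brute-force per-read product", {
  p <- model_params(alpha = 0.0025, gamma = 0)
  obs <- obs_df(base = c("C", "T", "G", "A", "C"),
                epsilon = c(0.01, 0.001, 0.05, 0.02, 0.003),
                template_strand = c("+", "+", "-", "-", "+"))
  pr <- genotype_priors("C")
  want <- brute_force_posterior(obs, pr, beta_c = 0.3, beta_g = 0.3,
                                alpha = p$alpha, gamma = p$gamma)
  lik <- attr(want, "likelihood")
  for (g in GENOTYPES)
    expect_equal(genotype_likelihood(obs, g, beta = 0.3, p),
                 log(lik[[g]]), tolerance = 1e-9)
  # homozygous genotype collapses to a single-allele product
  expect_equal(genotype_likelihood(obs, "AA", beta = 0.3, p),
               sum(log(sapply(seq_len(nrow(obs)), function(j)
                 allele_observation_likelihood(obs[j, ], "A", 0.3, p)))),
               tolerance = 1e-9)
  # empty pileup: unit likelihood for every genotype
  for (g in c("AA", "CT", "GG"))
    expect_identical(genotype_likelihood(obs[0, ], g, 0.3, p), 0)
  got <- locus_posterior(obs, pr, beta = 0.3, p)
  expect_equal(unname(got$posterior[GENOTYPES]), unname(want[GENOTYPES]),
               tolerance = 1e-9)
})

test_that("posterior normalizes, empty pileup returns the prior", {
  p <- model_params()
  pr <- genotype_priors("G")
  empty <- obs_df(character(0))
  call <- locus_posterior(empty, pr, beta = 0.5, p)
  expect_equal(as.numeric(call$posterior), as.numeric(pr[GENOTYPES]),
               tolerance = 1e-12)
  expect_identical(call$best, "GG")
  expect_equal(call$score,
               unname(10 * log10(max(pr) / sort(pr, decreasing = TRUE)[2])),
               tolerance = 1e-9)

  # random pileups: posterior sums to one
  set.seed(11)
  for (i in 1:50) {
    n <- sample(0:20, 1)
    obs <- obs_df(base = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  epsilon = runif(n, 1e-4, 0.3),
                  template_strand = sample(c("+", "-"), n, replace = TRUE))
    cl <- locus_posterior(obs, genotype_priors(sample(c("A","C","G","T"), 1)),
                          beta = runif(1), p)
    expect_equal(sum(cl$posterior), 1, tolerance = 1e-9)
    expect_gte(cl$score, 0)
  }
})

test_that("het C/T pileup is recovered by posterior and matches brute force", {
  p <- model_params(alpha = 0, gamma = 0)
  # het C/T at a reference C: five bisulfite-strand reads all read T
  # (converted C allele or true T); five G-strand reads observe the
  # genotype directly in reference-forward space: 3 C, 2 T
  obs <- obs_df(base = c(rep("T", 5), rep("C", 3), rep("T", 2)),
                epsilon = 0.001,
                template_strand = c(rep("+", 5), rep("-", 5)))
  pr <- genotype_priors("C")
  call <- locus_posterior(obs, pr, beta = 0.5, p)
  want <- brute_force_posterior(obs, pr, 0.5, 0.5, 0, 0)
  expect_identical(call$best, names(which.max(want)))
  expect_identical(call$best, "CT")
  expect_equal(unname(call$posterior[GENOTYPES]), unname(want[GENOTYPES]),
               tolerance = 1e-9)
})

test_that("score never decreases when adding a read concordant with a
           homozygous best genotype", {
  p <- model_params()
  pr <- genotype_priors("A")
  set.seed(3)
  tested <- 0
  for (i in 1:40) {
    n <- sample(3:15, 1)
    obs <- obs_df(base = sample(c("A", "G"), n, replace = TRUE,
                                prob = c(0.85, 0.15)),
                  epsilon = 0.01, template_strand = "+")
    c0 <- locus_posterior(obs, pr, 0.5, p)
    if (substr(c0$best, 1, 1) != substr(c0$best, 2, 2)) next
    extra <- obs_df(base = substr(c0$best, 1, 1), epsilon = 0.01,
                    template_strand = "+")
    c1 <- locus_posterior(rbind(obs, extra), pr, 0.5, p)
    expect_gte(c1$score + 1e-9, c0$score)
    tested <- tested + 1
  }
  expect_gt(tested, 10)
})

test_that("methylation summary counts C-strand reads only", {
  obs <- obs_df(base = c("C", "C", "C", "T", "G", "A"),
                template_strand = c("+", "+", "+", "+", "-", "-"))
  call <- list(best = "CC")
  m <- methylation_from_call(call, obs)
  expect_equal(m$fraction, 0.75)
  expect_equal(m$c_reads, 3L)
  expect_equal(m$t_reads, 1L)
  expect_true(m$measurable)

  # empty denominator -> undefined and flagged
  m0 <- methylation_from_call(list(best = "CC"),
                              obs_df("G", template_strand = "-"))
  expect_true(is.na(m0$fraction))
  expect_false(m0$measurable)

  # no cytosine allele -> no record
  mt <- methylation_from_call(list(best = "TT"), obs)
  expect_false(mt$measurable)
  expect_true(is.na(mt$strand))

  # C/T het: not measurable
  mct <- methylation_from_call(list(best = "CT"), obs)
  expect_false(mct$measurable)

  # reverse-strand cytosine: mirrored G/(G+A)
  obs2 <- obs_df(base = c("G", "G", "A"), template_strand = "-")
  mg <- methylation_from_call(list(best = "GG"), obs2)
  expect_equal(mg$fraction, 2 / 3)
  expect_identical(mg$strand, "-")
})
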