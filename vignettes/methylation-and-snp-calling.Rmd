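---
title: "Joint methylation and SNP calling from directional bisulfite sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint methylation and SNP calling from directional bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcall)
```

## The problem

Bisulfite treatment converts unmethylated cytosines to uracil (read as
T) while methylated cytosines are protected. This is the basis of
base-resolution methylome sequencing, but it breaks the assumptions of
every ordinary SNP caller: the two genomic strands are no longer
complementary in read space, and a genuine C>T polymorphism is
indistinguishable, on the cytosine's own strand, from an unmethylated
cytosine. Since C>T is the most common substitution in mammalian
genomes — and concentrated at CpG sites, exactly where methylation is
measured — ignoring SNPs corrupts methylation estimates, and ignoring
methylation corrupts SNP calls.

The directional (Illumina-style) library protocol sequences only the
two original bisulfite-converted template strands. At any cytosine this
splits the reads into a *C-strand* population (bisulfite-affected,
methylation-informative, C/T-ambiguous) and a *G-strand* population
(unaffected by conversion, genotype-informative). `methcall` exploits
this split in a single Bayesian model that calls the ten diploid
genotypes and per-cytosine methylation at the same time.

Throughout the package, observations live in *reference-forward space*:
SAM alignments already store reverse-strand reads reverse-complemented,
so a forward-template C>T conversion appears as a T at a reference C,
and a reverse-template conversion appears as an A at a reference G. The
model's strand logic is expressed entirely in terms of the *template
strand* of each read, which for the directional protocol is the
alignment strand of the first mate.

## The model

At a locus covered by $r$ reads with base calls
$D = (D_1, \dots, D_r)$, the posterior over diploid genotypes
$G = AB$ is

$$\Pr(G \mid D) \;=\; \frac{\pi(G) \Pr(D \mid G)}{\sum_{A'B'} \pi(A'B')\,\Pr(D \mid A'B')},
\qquad
\Pr(D \mid G{=}AB) = \prod_{j=1}^{r}\Big[\tfrac12 \Pr(D_j \mid A) + \tfrac12 \Pr(D_j \mid B)\Big].$$

For A and T alleles the per-read term is the plain quality-score error
model: $1-\epsilon_j$ for a matching call and $\epsilon_j/3$ otherwise,
with $\epsilon_j$ the (possibly recalibrated) base-call error
probability. For a C allele, a read whose template strand carries that
cytosine sees a two-stage generative process: the template retains the
C with probability

$$p_C \;=\; \beta(1-\gamma) + (1-\beta)\alpha,$$

(methylated and not overconverted, or unmethylated and underconverted)
and is converted to T with probability $p_T = 1 - p_C$; sequencing
error acts on top, e.g.
$\Pr(D_j{=}\mathrm{C}) = p_C(1-\epsilon_j) + p_T\,\epsilon_j/3$. Reads
from the opposite strand see the unconverted base and use the plain
error model. G alleles are the exact strand mirror image. This
fully-normalized mixture sums to one over the four observable bases for
every parameter combination, which the test suite verifies against an
independent exhaustive enumeration of the latent
(methylated, converted, error) states.

The reported score is the phred-scaled odds between the best and
second-best genotype, $10\log_{10}[\Pr(G_{best}|D)/\Pr(G_{nextbest}|D)]$,
with ties broken by canonical genotype order (so a tie scores exactly
0). Phred scaling was chosen for consistency with VCF `QUAL`
conventions.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | underconversion rate (unmethylated C fails to convert) | 0.0025 | estimable from unmethylated spike-ins or chrM |
| `gamma` | overconversion rate (methylated C converts) | 0 | rarely measurable; kept explicit |
| `min_base_quality` | exclusive phred cutoff for pileup bases | 5 | "greater than 5" |
| `score_threshold` | phred odds for a confident variant | 20 | evaluation sweeps thresholds, so no result hinges on it |
| `beta_mode` | methylation prior estimation | `"locus"` | see below |

### Genotype priors

$\pi(G)$ gives the reference homozygote $1-\theta$, with
$\theta = 10^{-3}$ at novel sites and $0.1$ at known polymorphic sites
(a dbSNP-style VCF). The variant mass is spread over the nine remaining
genotypes with transition alleles up-weighted 2:1 and
reference-carrying heterozygotes up-weighted 2:1 against the matching
non-reference homozygote; when the known-sites file records allele
frequencies, the listed alleles absorb the variant mass in proportion.
The exact allocation is a design choice of this package (standard
population-genetic defaults, fully configurable via `prior_params()`);
only the $1-\theta$ reference mass and the known/novel split are
externally fixed conventions.

### Methylation priors: naive, context, locus

The critical nuisance parameter in the C/G likelihood is $\beta$, the
prior probability that a read's template was methylated:

* **naive** — $\beta = 0.5$ everywhere; no assumptions, weakest.
* **context** — a two-round procedure: round one calls with the naive
  prior; high-confidence homozygous cytosines (posterior > 0.9999,
  absent from the known-variant set) are averaged per IUPAC context
  (default `CG`, `CH`) and those means drive round two. We stop after
  two rounds; no further iteration is performed because the estimates
  are already means over thousands of loci and further rounds changed
  nothing in testing.
* **locus** (default) — $\beta_j = C/(C+T)$ from the locus's own
  bisulfite-strand reads, computed in the same single pass (no
  iteration), falling back to 0.5 when no informative reads exist.
  CpG methylation is strongly bimodal, so a genome-wide mean is wrong
  at most individual CpGs; the locus estimate adapts automatically.

Methylation itself is reported as the fraction of C reads among
C-or-T reads on the cytosine's strand (mirrored G/(G+A) for
reverse-strand cytosines). For C/T heterozygotes the C-strand reads
cannot be attributed to an allele, so methylation is marked
not-measurable and the locus is omitted from methylation output;
allele-resolved methylation via read phasing is out of scope.

## Pre-processing and filters

**Read prefilters.** Reads with mapping quality below 30, multi-mapping
or duplicate flags, or (for paired data) without the properly-paired
flag are dropped before pileup.

**Bisulfite-aware recalibration.** Reported quality scores are
miscalibrated in a context-dependent way. The package tabulates
empirical mismatches against the reference, binned by reported quality
and sequencing cycle (and mate end), at sites not in the known-variant
set. A T at a reference C on the bisulfite strand cannot be classified
as error or conversion, so such bases are treated as a fifth base "X"
and excluded from the tabulation entirely (mirrored: A at reference G
on reverse templates); they keep their reported quality when the table
is applied. Bins are converted to phred via a Laplace-smoothed rate
$-10\log_{10}[(m+1)/(n+2)]$ capped at Q60 — the smoothing, cap and the
`min_bin_count = 100` marginal fallback are this package's choices,
made to keep sparse bins from injecting noise. Whether per-bin
empirical quality should instead be combined with a global shift (the
full GATK scheme) is not determinable here; direct bin-wise replacement
is simpler and testable.

**Five-prime non-conversion mask.** Conversion failures concentrate at
the 5' ends of reads (adapter-proximal re-annealing). Walking each read
5'→3', unconverted Cs at reference Cs are masked until the first
converted C is seen; if a read never converts, all its unconverted Cs
are masked. Masked bases are excluded from both genotype likelihoods
and methylation counts. The filter must be disabled for RRBS, whose
first cycle carries most of the methylation signal
(`five_prime_filter = FALSE`, CLI `--no-five-prime-filter`).

**Site filters** annotate but never delete: depth above 120
(`HighDepth`), quality-by-depth below 1.0 (`LowQD`, score divided by
alternate-supporting reads, homozygous-reference calls exempt), two or
more variants within 10 bp (`SnpCluster`, all members labelled), MQ0
regions (≥ 40 reads, > 10% mapping quality zero), and strand bias
(`StrandBias`, cutoff −0.02). All bounds follow their printed
inequality directions strictly.

**Strand bias in bisulfite data.** The SB score is a per-depth log10
likelihood ratio between the best "alternate allele confined to one
strand" model and a strand-free model (`strand_bias()`). Directional
bisulfite-seq complicates it: for any C>T-class (or mirrored
G>A-class) variant the protocol itself confines the allele evidence to
one strand, so confinement is chemistry, not artifact. After
experimenting with partial exclusion schemes — which manufactured bias
of their own by removing one strand's reference evidence — the engine
takes the conservative position: SB is computed only where neither C
nor G participates at the locus (pure A/T substitutions) and is
otherwise reported as unmeasurable (−Inf, never filtered). This keeps
the filter's false-kill rate on clean simulated variants well under 1%
while still catching strand-confined artifacts in the substitution
classes where the test is meaningful.

## The simulator

`simulate_bsseq()` generates the complete acceptance surface: a
reference genome, a diploid sample genome, per-cytosine methylation
truth, and directional reads with controlled conversion and error —
so every claim the package makes is testable without any external
dataset.

What it emulates, and the defaults chosen where no external convention
exists (all set once in `sim_params()` and not tuned per analysis):

* i.i.d. reference bases at 41% GC (human-like); `cpg_enrichment`
  optionally adjusts P(G | preceding C) in a single first-order pass,
  default 1 (no adjustment — CpG density is then ~4/100 bp, ample for
  methylation statistics).
* SNPs at $10^{-3}$ per bp, 67% heterozygous, transition:transversion
  2:1, with transitions further favoured 2-fold at CpG cytosines to
  mimic deamination of methylated CpGs (the reason most human SNPs are
  C>T).
* CpG methylation from a bimodal 0.7·Beta(8,2) + 0.3·Beta(1,20)
  mixture (mostly-methylated CpGs plus a low-methylation island-like
  class); CpH from Beta(1,99), mean 1%. CpG dyads share one level
  across strands and haplotypes.
* fragments sampled uniformly from both haplotypes and both template
  strands; only the two original converted templates are sequenced
  (directional protocol), paired mode adds the complementary second
  mate. Per-locus coverage is therefore approximately Poisson.
* per-cycle true error rates with an optional reported-quality offset
  (`miscalibration`) — a single per-run offset, which is all the
  recalibration machinery needs to be exercised.

What it does **not** emulate: indels, PCR duplicates, mapping error and
mapping bias, RRBS fragment-end structure, non-directional protocols,
context-dependent error (only cycle-dependent), and methylation
differences between haplotypes. Passing recovery tests on this
simulator therefore demonstrates correctness of the model and
machinery under the protocol's idealized geometry, not robustness to
alignment artifacts on real data.

Downsampling follows the per-locus rule $z = \text{round}(m\,n/N)$
(locus depth $m$, dataset mean $N$, target $n$), retaining a seeded
uniform subset.

## Evaluation harness and comparators

`evaluate_calls()` sweeps the call score and reports sensitivity, FDR
and FPR per stratum — homozygous cytosines, all heterozygotes, and the
bisulfite-ambiguous heterozygote class (C/T and its reverse-strand
mirror G/A) versus the rest. The operating point is the least
stringent threshold with FDR below 5%. Three count-based baselines are
included: the k-allele rule (no base qualities; at reference cytosines
only the G-strand counts, with the `n ≥ 10` branch interpreted as
requiring `ceiling(n·K/10)` minor-allele reads — the only reading
consistent with K's 0–10 range, and `n = 10` uses that branch), a
reference-cytosine consensus threshold caller (default k = 10%), and a
demethylation-based frequency-matrix caller whose Fisher-test expected
counts are reconstructed from the error-rate-implied background (its
original supplement is not reproducible from the published
description; the gates — quality ≥ 15 over site ± 3, 20% strand
reciprocity, dbSNP membership, depth ≥ 10, 10× odds — are as
described).

## Numerical choices and degenerate inputs

* All likelihood products are accumulated in log space; posteriors are
  normalized with the max-subtraction trick, so underflow cannot raise.
* An empty pileup returns the prior as posterior (and the prior's odds
  as score).
* Bases called N, and bases at or below the quality cutoff, never
  enter a pileup; a reference N yields a flagged uniform prior.
* `beta` fallbacks are always 0.5 (the naive prior) and flagged.
* Tie-breaks (equal posteriors, equal allele counts) resolve by
  canonical genotype order, making every output deterministic; with a
  fixed seed the whole pipeline is byte-reproducible, and per-locus
  independence makes results independent of any work partitioning.

## Problem sizes used in the test suite

The acceptance-scale checks simulate a 100 kb genome at 30× (≈ 40,000
reads, ≈ 3 M pileup observations, ≈ 100 SNPs) and titrate coverage at
4/8/16/30×; unit tests use 3–30 kb genomes. These sizes give the
sensitivity estimates binomial standard errors of a few percent at
most while keeping the full suite comfortably reproducible on a
single CPU; they are the package's reference study conditions, stated
here so that every reported number can be traced to a generating
configuration.

## Known limitations

* No indel genotypes, no local realignment: input BAMs are assumed
  already realigned upstream; CIGARs are honored, not recomputed.
* No read-phasing, hence no allele-specific methylation and no
  methylation estimate at C/T heterozygotes.
* Single-sample calling only.
* The strand-bias reconstruction differs from the (unpublished)
  original; its cutoff semantics are honored against our stated
  formula only.
* The context-prior mode assumes contexts from the *reference*
  sequence; a SNP that changes the context of a neighbouring cytosine
  is not re-evaluated against the sample genome.
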