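# methcall

Joint SNP and DNA methylation calling from directional bisulfite
sequencing (WGBS / RRBS) alignments, in R.

Bisulfite conversion reads unmethylated cytosines as thymine, so a
genuine C>T polymorphism and an unmethylated cytosine look identical on
the cytosine's own strand — and C>T is the most common substitution in
mammalian genomes, concentrated at the CpG sites where methylation is
measured. `methcall` resolves the ambiguity with the strand structure
of the directional protocol: at each cytosine, reads from the *C-strand*
carry methylation information while reads from the opposing *G-strand*
carry the genotype, untouched by conversion.

## The model

At each covered position with base calls $D = (D_1,\dots,D_r)$ the
caller evaluates all ten diploid genotypes:

$$\Pr(G\mid D) \propto \pi(G)\prod_{j=1}^{r}\left[\tfrac12\Pr(D_j\mid A)+\tfrac12\Pr(D_j\mid B)\right],\qquad G = AB,$$

with a population-genetic prior $\pi(G)$ (heterozygosity $10^{-3}$,
or $0.1$ at known dbSNP-style sites; transition:transversion 2:1). For
A/T alleles $\Pr(D_j\mid B)$ is the usual quality-score error model;
for a C allele on its bisulfite-affected strand the template keeps its
C with probability

$$p_C=\beta(1-\gamma)+(1-\beta)\alpha$$

($\beta$ = methylation prior, $\alpha$ = underconversion, default
0.0025, $\gamma$ = overconversion, default 0) before sequencing error
is applied; G alleles are the strand mirror image. $\beta$ can be
naive (0.5), context-specific (two-round per-context means over
high-confidence homozygous cytosines), or locus-specific
($C/(C{+}T)$ at the locus itself — the default). Calls are scored by
the phred-scaled odds between the best and second-best genotype, and
methylation is reported as C/(C+T) on the cytosine's strand.

Around the model: bisulfite-aware base-quality recalibration (Ts at
reference Cs are a fifth base, excluded from mismatch tabulation), a
five-prime non-conversion mask, read prefilters (MAPQ ≥ 30, proper
pairs, duplicates), label-only site filters (depth, strand bias,
quality-by-depth, SNP clusters, MQ0 regions), VCF 4.1 / BED6+2 / wig
output, count-based comparator callers with a sensitivity/FDR harness,
and a directional bisulfite read simulator that generates complete
truth sets. See the vignette
(`vignettes/methylation-and-snp-calling.Rmd`) for the full model
description and design rationale.

## Worked example

Simulate a 20 kb diploid methylome at 20x and call it:

```r
library(methcall)
p  <- sim_params(genome_length = 20000L, coverage = 20, seed = 42)
ts <- simulate_bsseq(p, dir = "demo")      # reference.fa, reads.sam, truth.*
res <- methcall("demo/reads.sam", "demo/reference.fa")
summary(res)
```

```
Loci called: 20000
Variant calls: 21 (13 het, 8 hom-alt; 19 PASS)
Mean methylation by context:
    CG     CH
0.5534 0.0122
Variant score quartiles:
   25%    50%    75%    95%
 27.06  83.21 107.52 158.84
```

All 21 simulated SNPs are recovered (the two non-PASS calls are
low-depth sites labelled `LowQual`, labels never delete calls). The
mean CpG methylation of 0.55 reflects the simulator's bimodal CpG
mixture and the CpH mean sits at its nominal 1%. Sensitivity at the
FDR < 5% operating point:

```r
ev <- evaluate_calls(res$calls, ts, "het_all")
operating_sensitivity(ev)
#> [1] 1
```

Write standard outputs:

```r
write_vcf(res$calls[res$calls$is_variant, ], "demo/calls.vcf")
write_methylation(res$calls, "demo", format = "bed")  # one file per context
```

```
sim1  4   5   CG  100  -  1  100     # chrom start end context pct strand cov pct
sim1  29  30  CG  0    +  6  0
```

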