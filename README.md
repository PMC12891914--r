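# mhctsp

Multi-species MHC amplicon analysis: allele QC, diversity summaries, a
Monte-Carlo codon-usage test discriminating **co-ancestry** from
**convergent evolution** for alleles shared among species, and functional
**supertyping** by discriminant analysis of principal components (DAPC).

## The problem

Balancing selection on major histocompatibility complex (MHC) loci can
preserve allelic lineages across speciation events, so related species often
share similar or identical peptide-binding alleles (trans-species
polymorphism). The same similarity can, however, arise by convergent
evolution under shared pathogen pressure. Codon usage tells the two apart:
inherited amino acids ride on inherited codons, while convergently acquired
amino acids sit on codons drawn from the synonymous family. `mhctsp` is for
researchers running multi-species MHC amplicon studies (typically a handful
of species, hundreds of genotyped individuals, exon-scale alleles) who need
the whole downstream chain after read clustering: QC of candidate alleles,
diversity summaries, the co-ancestry test, and supertype assignment.
Selection inference (positively selected sites, PSS) and phylogeny
inference are inputs, not reimplemented.

## The statistic

For a species pair (A, B), define Bernoulli events over allele pairs and
codon positions where both alleles carry the same amino acid: outcome 1 if
the codons are identical, 0 if synonymous-different. Then

* **obs** — proportion of identical codons over cross-species allele pairs
  at the PSS (event count *k*);
* **CEd** — Monte-Carlo distribution (1,000 replicates of *k* draws with
  replacement) from the *cross-species, whole-exon* event pool: the
  convergent-evolution null;
* **CAd** — the same from the *within-species, whole-exon* pools of both
  species: the co-ancestry null;
* one-tailed Z-tests of obs against each distribution (upper tail vs CEd,
  lower tail vs CAd), Benjamini–Hochberg-corrected across species pairs per
  locus and direction;
* the **co-ancestry score**

  ```
  score = (obs − median(CEd)) / (median(CAd) − median(CEd))
  ```

  placing the observation on an affine scale from 0 (convergence) to 1
  (co-ancestry), correlated with patristic distance via Pearson's r.

QC follows the conservative amplicon conventions (exact expected length;
kept if seen in ≥ 2 individuals or in 1 individual across ≥ 2 runs; intron
and ORF trimming; stop-codon screen; collapse to unique proteins).
Diversity summaries are Nei's nucleotide diversity with its sampling
variance, Hurlbert rarefaction, per-individual allele counts with the
`ceiling(max/2)` minimum gene-copy bound, and exact shared-allele Venn
partitions. Supertyping builds a five-z-scale descriptor matrix at the PSS
and fits k-means + LDA on retained principal components, with a BIC-guided
choice of k and cross-validated choice of the PC count. A seeded generator
(`simulate_dataset()`) produces multi-species datasets with known
co-ancestry/convergence truth so the whole chain is testable offline. See
`vignettes/mhc-coancestry.Rmd` for the full methods account.

## Worked example

```r
library(mhctsp)

cfg <- sim_config("CA", seed = 42)        # co-ancestry ground truth
sim <- simulate_dataset(cfg)              # 4 species x 12 alleles, 60 codons
align <- codon_alignment(sim$combined, sim$membership)
fit <- coancestry_test(align, sim$pss, seed = 42)
print(fit)
#> Codon-usage co-ancestry test, locus 'SIM' (10 PSS, 1000 MC reps)
#>  species_a species_b observed   k  q_vs_CE q_vs_CA score
#>        sp1       sp2        1 337 1.81e-68       1  1.55
#>        sp1       sp3        1 317 2.07e-73       1  1.58
#>        sp1       sp4        1 312 1.86e-84       1  1.38
#>        sp2       sp3        1 308 1.57e-75       1  1.65
#>        sp2       sp4        1 326 7.38e-73       1  1.50
#>        sp3       sp4        1 316 9.09e-65       1  1.64
```

Every species pair shows codon identity 1.0 at the PSS — far above the
convergent-evolution null (all `q_vs_CE` ≈ 0) and at or beyond the
co-ancestry null (scores ≥ 1), exactly the signature of inherited alleles.
`k` is the number of identical-amino-acid events behind each observation.

```r
corr <- score_distance_correlation(fit, sim$tree)
#> r = -0.351, p = 0.495 (n = 6 pairs)

allele_stats(sim$genotypes, "sp1", "SIM")
#> sp1: 20 individuals, 12 alleles, 3.6 +/- 1.5 per individual, >= 3 gene copies
```

The score–distance correlation is weakly negative and non-significant, as
expected when ancestral polymorphism is maintained across the whole panel;
the per-individual maximum allele count bounds the gene-copy number from
below. Re-running with `sim_config("CE", seed = 42)` flips the picture:
observed identity ≈ 0.25 (four-fold-degenerate sites), `q_vs_CE` ≈ 1, and
scores near or below 0.

The same chain runs from the shell over files:

```sh
Rscript inst/scripts/mhctsp.R simulate --config cfg.json --out data/
Rscript inst/scripts/mhctsp.R all      --config run.json --out results/
```

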