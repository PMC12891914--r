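---
title: "Methods: codon-usage co-ancestry testing, diversity summaries, and supertyping for multi-species MHC amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-usage co-ancestry testing, diversity summaries, and supertyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctsp)
```

## The problem

Major histocompatibility complex (MHC) loci are the most polymorphic gene
family in vertebrates. Balancing selection can preserve allelic lineages
across speciation events ("trans-species polymorphism"), so closely related
species often carry similar — sometimes identical — MHC alleles. Two very
different histories produce that similarity:

* **Co-ancestry (CA):** the allele predates the species split and has been
  maintained in both descendants by balancing selection.
* **Convergent evolution (CE):** similar selective pressures independently
  produced alleles with similar *amino-acid* sequences after the split.

Codon usage separates the two. A codon is a three-base word; most amino
acids are encoded by several synonymous codons. If two species share an
amino acid at a positively selected site (PSS) *because they inherited it*,
they will usually share the same codon. If they converged on the amino acid
independently, the codon behind it is essentially a draw from the synonymous
family, so codon identity given amino-acid identity drops toward
1/(family size). `mhctsp` implements this contrast as a Monte-Carlo
resampling test, together with the supporting machinery a multi-species MHC
amplicon study needs: allele QC, diversity summaries, and functional
supertyping. Selection inference itself (the PSS list) and phylogeny
inference (the species tree) are treated as inputs, produced by dedicated
external tools.

## Allele QC

Amplicon genotyping pipelines emit candidate alleles that still contain
artifacts. `qc_alleles()` applies, in order:

1. **Length filter.** An allele must have exactly the configured
   post-primer-trim amplicon length (`locus_config()`). Indel-bearing
   variants are rejected rather than aligned — a deliberately conservative
   allele-calling stance, since length polymorphism in these short
   peptide-binding exons is rare and hard to distinguish from artifact.
2. **Prevalence/replication filter.** Retained alleles must be seen in at
   least two individuals, or in one individual across two independent
   amplification/sequencing runs. This is the standard guard against
   PCR/sequencing singletons.
3. **Intron and ORF trimming.** An optional fixed intron window is deleted
   (the chromosome-1 class II amplicon carries a 20-bp leading intron
   fragment), then the in-frame open reading frame window is extracted. If
   the frame is not configured, the offset (0/1/2) minimizing the total
   internal stop-codon count across all alleles is chosen; a tie is a hard
   error asking for explicit configuration rather than a silent guess.
4. **Stop-codon screen.** These are internal exon fragments, so *any* stop
   codon marks a non-functional artifact; such alleles are removed.
5. **Protein collapse.** Surviving nucleotide alleles are grouped by
   identical translation. The protein ID is the lexicographically smallest
   member ID plus `_p`, which makes the collapse invariant to input order.

Every rejection is a row in a ledger (`allele_id`, `reason`, `detail`), a
first-class output: what was removed should be auditable, not just counted.
All codon indices in the package are 1-based within the trimmed ORF; all
string positions in error messages are 1-based.

## Diversity summaries

* **Nucleotide diversity.** `nucleotide_diversity()` computes pi as the mean
  proportion of differing sites over all unordered sequence pairs, with the
  Nei sampling variance
  Var(pi) = (n+1)/(3(n−1)L)·pi + 2(n²+n+3)/(9n(n−1))·pi².
  Pi is computed over the *distinct alleles* recovered per species,
  unweighted by carrier frequency — the allele set, not the genotype table,
  is the deposited unit. This convention must be kept in mind when comparing
  against frequency-weighted values.
* **Rarefaction.** `rarefaction_curve()` reports the Hurlbert expectation
  E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n)) of allele richness at standardized
  sampling depth, with occurrence counts defined as the number of
  individuals carrying each allele (allele discovery against sampling
  effort). The computation is delegated to `vegan::rarefy()`, which
  evaluates the same expression in log-gamma arithmetic; the test suite
  pins it against exhaustive subsample enumeration.
* **Allele counts and copy number.** Per-individual allele counts are
  pooled across sequencing runs (union of calls). A diploid individual with
  `m` distinct alleles at a primer-defined region implies at least
  `ceiling(m/2)` gene copies; `allele_stats()` reports that lower bound.
  Standard deviations are sample (n−1) SDs.
* **Shared alleles.** `shared_allele_partition()` returns the exact Venn
  partition: each allele counted once, in the cell of the exact species set
  carrying it.

## The codon-usage co-ancestry test

The unit of evidence is a Bernoulli **event**: one (allele pair, codon
position) at which the two alleles carry the same amino acid; the outcome is
1 if the codons are identical, 0 if they differ synonymously. Granularity is
per allele pair, not per consensus: it uses all the information in the
allele sets and maximizes pool sizes for small species panels.

For a species pair (A, B) at one locus:

* **Observed statistic.** Events over all cross-species allele pairs,
  restricted to the PSS columns; the statistic is the proportion of 1s and
  `k` is the event count. Alleles shared by both species contribute each
  unordered cross-pair once; self-pairs (an allele against itself) are
  excluded everywhere — identical shared alleles are precisely the signal
  under test, but a self-comparison is not evidence.
* **CE null pool.** The same cross-species events computed over the *whole
  exon*. Exon-wide, cross-species codon identity given amino-acid identity
  reflects overall codon usage and between-species synonymous divergence —
  what convergence would produce at PSS.
* **CA null pool.** Within-species events (all unordered allele pairs
  inside A, plus those inside B, merged to symmetrize the null) over the
  whole exon. Within one species, alleles share recent ancestry, so this
  pool approximates codon identity under inheritance. If both species are
  mono-allelic this null is undefined and the pair errors out explicitly.
* **Monte-Carlo distributions.** Each null is resampled 1,000 times
  (default): a replicate draws `k` events uniformly *with replacement* from
  the pool and records the mean. With-replacement draws keep replicates
  i.i.d. even when pools are small. The CE-derived distribution is `CEd`,
  the CA-derived one `CAd`.
* **Tests.** One-tailed Z-tests with a normal reference:
  z = (obs − mean)/sd per distribution; against CEd the upper tail (is the
  observed identity *higher* than convergence predicts?), against CAd the
  lower tail (is it *below* full co-ancestry?). A degenerate distribution
  (sd = 0) yields p ∈ {0, 0.5, 1} by sign convention plus a warning.
  Benjamini–Hochberg FDR is applied across the species pairs of one locus,
  separately for the CE-direction and CA-direction families.
* **Co-ancestry score.**
  score = (obs − median(CEd)) / (median(CAd) − median(CEd)),
  an affine placement of the observation between the convergence null (0)
  and the co-ancestry null (1). Values outside [0, 1] are meaningful (the
  observation sits beyond one of the medians). If the medians coincide to
  within 1e-12 the score is undefined and flagged rather than fabricated.
* **Distance correlation.** `score_distance_correlation()` relates per-pair
  scores to patristic distances from the species tree via the Pearson
  coefficient with the usual t reference (n−2 df). Under deep trans-species
  maintenance the correlation is expected to be weak or slightly negative.

The PSS set used here is the union of sites flagged by any provided
selection test. Sites supported only by episodic-selection tests are
excluded from *supertyping* inputs (where a single anomalous site would
perturb the descriptor space) but retained for the codon-usage test.

## Supertyping (DAPC)

Functionally similar alleles are grouped by the physiochemical profile of
their PSS residues:

1. **Descriptor matrix.** Each protein allele becomes a row of five z-scale
   descriptors (Sandberg et al. 1998: lipophilicity, steric bulk, polarity,
   and two electronic-property scales) per PSS position, site-major.
   Supertyping operates on protein alleles because the descriptors are
   amino-acid properties; synonymous nucleotide variants are functionally
   identical by construction.
2. **Cluster count.** Columns are standardized, PCA is applied, and k-means
   (25 restarts, best within-cluster sum of squares kept) is run for each
   candidate k. The reported curve is BIC(k) = n·ln(WSS_k/n) + k·ln(n).
   The *selection rule* is the sharp/flat elbow grouping (a Ward two-group
   split of the successive BIC decreases, as in the reference DAPC
   implementation's non-interactive criterion) rather than the raw argmin:
   for tight clusters, splitting pure within-cluster noise still lowers
   this BIC by more than ln(n) per extra cluster, so the argmin
   systematically over-fragments — the elbow rule recovers the simulated
   cluster count across seeds where the argmin does not. A perfect fit
   (WSS = 0, e.g. all rows identical) short-circuits to the smallest such k.
3. **Retained PCs.** Stratified 90/10 cross-validation (30 replicates by
   default): PCA + linear discriminant fit on the training split, held-out
   rows scored by assignment to their own cluster; the PC count maximizing
   mean held-out accuracy is kept, smallest on ties (all tie-breaks in the
   package prefer the smallest value, for determinism).
4. **Final fit.** k-means labels on the retained PCs, then a linear
   discriminant analysis of those PCs on the labels — discriminant analysis
   of principal components. Posterior assignment proportions come from the
   discriminant model. When clusters are perfectly separated with zero
   within-cluster variance the discriminant is degenerate; the package then
   uses the nearest-centroid rule, which is its limiting form, and reports
   one-hot posteriors. `predict()` places new alleles through the same
   standardization/projection/classification chain.

## The synthetic-data generator

`simulate_alleles()` produces multi-species allele sets with known truth.
It is deliberately minimal: the statistics under test depend only on codon
identity conditional on amino-acid identity, which the generator controls
exactly, rather than on a full codon-substitution model.

* **Co-ancestry regime.** All species share an ancestral pool
  (30 alleles by default). At each PSS, each pool allele draws its amino
  acid from a shared profile and its codon from a fixed
  (site, amino acid) → codon map, so identical amino acids at PSS are
  codon-identical — the co-ancestry signature. Species sample 12 alleles
  each (default) from the pool; overlap creates genuinely shared alleles.
  Each species then accumulates lineage-specific synonymous substitutions
  (probability 0.5 per non-PSS codon) and occasional nonsynonymous ones
  (0.05), applied as one species-level map — this is what separates the
  within-species (high) from the cross-species (lower) whole-exon codon
  identity, exactly the contrast the CAd/CEd nulls formalize. A fraction
  (0.3) of pool alleles is trans-species conserved and inherited verbatim,
  so identical alleles shared between species exist for the Venn/sharing
  summaries. Small per-allele synonymous drift (0.02) adds within-species
  variation.
* **Convergence regime.** Each species draws its PSS amino acids from the
  same shared profile (shared selective pressure), but every allele picks
  its codon uniformly from the amino acid's synonymous family, so
  cross-species codon identity given amino-acid identity equals
  1/(family size) — with the default profile of four-fold-degenerate
  residues (A, G, P, T, V), 0.25. Non-PSS structure is as above.
* **Mixed regime.** Species are split into two blocks; pairs within a
  block behave as co-ancestry, pairs across blocks as convergence. Truth
  labels record the per-pair regime.
* **Genotypes.** Each of 20 individuals per species (default) carries 1–6
  allele copies drawn without replacement; a quarter of individuals are
  sequenced in two runs; each run re-observes each carried allele with
  probability 0.9 (10% dropout). This exercises the prevalence/replication
  filter and the run-pooling logic.

What the generator does *not* emulate: read-level error, chimeras, PCR
bias, codon-usage bias (the CE codon choice is uniform within family — a
usage-bias table is a documented extension point), recombination, and
realistic phylogenetic branch-length structure (the emitted tree is
balanced with uniform branch lengths). Passing the scenario-recovery tests
therefore demonstrates that the inference machinery separates the two
codon-usage regimes it formalizes — not that it is robust to every
real-data artifact upstream of its inputs.

## Numerical and reproducibility choices

* One master seed is fanned out to per-stage child seeds through a fixed
  counter scheme, so each stage is individually reproducible and two runs
  with the same configuration produce byte-identical result files (the run
  manifest carries the only timestamp and is excluded from that guarantee).
* All RNG use is wrapped so the caller's `.Random.seed` is untouched.
* Monte-Carlo sizes: 1,000 replicates per null distribution; scenario
  recovery is assessed over 20 seeded datasets per regime of 4 species ×
  12 alleles × 60 codons with 10 PSS, and supertype recovery over 20
  seeded datasets of 2–4 groups × 15 alleles at 10 PSS — sizes chosen so
  the full battery runs in well under a minute on a laptop while leaving
  the binomial standard errors far smaller than the decision margins.
* Degenerate cases are flagged, not silently patched: empty PSS event sets
  are "not evaluable", zero-sd null distributions warn and use the sign
  convention, coincident null medians make the score `NA`, and a
  mono-allelic co-ancestry null is an error.

## Limitations

* The test cannot distinguish co-ancestry from adaptive introgression;
  both place inherited codons in two species.
* Alleles cannot be assigned to specific gene copies from primer-defined
  amplicons, so pools mix paralogs.
* The unweighted pi convention differs from frequency-weighted nucleotide
  diversity; compare like with like.
* PSS lists are inputs; errors in the upstream selection analysis propagate
  directly into both the observed statistic and the supertype space.
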