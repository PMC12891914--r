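# Allelic and nucleotide diversity summaries: Nei nucleotide diversity with
# its sampling variance, Hurlbert rarefaction of allele discovery,
# per-individual allele counts with the minimum gene-copy bound, and exact
# shared-allele Venn partitions.

#' Nucleotide diversity with Nei sampling variance
#'
#' Pi is the mean, over all C(n,2) unordered sequence pairs, of the
#' proportion of differing sites. The variance is Nei's (1987, eq. 10.7)
#' sampling formula
#' \deqn{Var(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2.}
#'
#' @param seqs Character vector of >= 2 equal-length nucleotide sequences.
#' @return List with `pi`, `variance`, `n`, and `L`.
#' @examples
#' nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTTT"))$pi  # 0.2
#' @export
nucleotide_diversity <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop_fmt("nucleotide diversity needs >= 2 sequences, got %d", n)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop_fmt("sequences must be equal length (found lengths %s)",
             paste(sort(L), collapse = ", "))
  m <- do.call(rbind, strsplit(seqs, ""))
  total <- 0
  for (i in seq_len(n - 1L)) {
    diffs <- colSums(t(m[(i + 1L):n, , drop = FALSE]) != m[i, ])
    total <- total + sum(diffs)
  }
  npairs <- n * (n - 1) / 2
  pi <- total / (npairs * L)
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, variance = v, n = n, L = L)
}

#' Hurlbert rarefaction of allele richness
#'
#' Expected number of distinct alleles in a random subsample of `n` of the
#' `N = sum(counts)` allele observations:
#' \deqn{E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n} / \binom{N}{n}\right),}
#' evaluated with log-gamma arithmetic for stability.
#'
#' @param counts Positive integer occurrence counts per allele (here: the
#'   number of individuals carrying each allele).
#' @param sample_sizes Integer grid of subsample sizes, each `<= sum(counts)`.
#' @return Data frame with columns `n` and `expected_richness`.
#' @examples
#' rarefaction_curve(c(2, 1), 2)$expected_richness  # 5/3
#' @export
rarefaction_curve <- function(counts, sample_sizes) {
  counts <- as.numeric(counts)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop_fmt("occurrence counts must be positive integers")
  N <- sum(counts)
  sample_sizes <- as.integer(sample_sizes)
  if (any(sample_sizes < 1L) || any(sample_sizes > N))
    stop_fmt("sample sizes must lie in [1, %d]", as.integer(N))
  es <- vapply(sample_sizes, function(n) {
    # muffle vegan's data-shape heuristic: these are genuine counts
    withCallingHandlers(
      unname(vegan::rarefy(matrix(counts, nrow = 1), n)[1]),
      warning = function(w) {
        if (grepl("observed count data", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }, numeric(1))
  data.frame(n = sample_sizes, expected_richness = es)
}

#' Per-individual allele counts and the minimum gene-copy bound
#'
#' Allele calls are pooled across sequencing runs (union of allele IDs per
#' individual). Reports mean, sample (n-1) SD, min and max alleles per
#' individual, and the minimum number of gene copies implied by the maximum:
#' `ceiling(max / 2)` (a diploid carries at most two alleles per copy).
#'
#' @param genotypes A genotype table.
#' @param species,locus Selection; the species/locus pair must be sampled.
#' @return List with `species`, `locus`, `n_individuals`, `total_alleles`,
#'   `mean`, `sd`, `min`, `max`, and `min_gene_copies`.
#' @export
allele_stats <- function(genotypes, species, locus) {
  g <- genotypes[genotypes$species == species & genotypes$locus == locus, ,
                 drop = FALSE]
  if (nrow(g) == 0L)
    stop_fmt("no genotype rows for species '%s', locus '%s'", species, locus)
  counts <- tapply(g$allele_id, g$individual_id,
                   function(x) length(unique(x)))
  counts <- as.integer(counts)
  list(species = species, locus = locus,
       n_individuals = length(counts),
       total_alleles = length(unique(g$allele_id)),
       mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else NA_real_,
       min = min(counts), max = max(counts),
       min_gene_copies = as.integer(ceiling(max(counts) / 2)))
}

#' Exact shared-allele Venn partition
#'
#' Counts each allele once, in the cell corresponding to the exact set of
#' species carrying it; cell counts sum to the size of the union.
#'
#' @param sets Named list (>= 2 entries) of per-species allele-ID vectors.
#' @return Data frame with columns `species_set` (species names joined by
#'   `&`, in input order) and `count`, covering every non-empty subset.
#' @examples
#' shared_allele_partition(list(A = c("x", "y"), B = "y"))
#' @export
shared_allele_partition <- function(sets) {
  if (length(sets) < 2L) stop_fmt("need >= 2 species sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_fmt("species sets must be named")
  sp <- names(sets)
  sets <- lapply(sets, unique)
  alleles <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) alleles %in% s,
                   logical(length(alleles)))
  if (!is.matrix(member))
    member <- matrix(member, nrow = 1L, dimnames = list(NULL, sp))
  # enumerate all non-empty subsets in subset-size-then-input order
  subsets <- unlist(lapply(seq_along(sp), function(k)
    utils::combn(sp, k, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(subsets, function(ss) {
    inside <- rowSums(member[, ss, drop = FALSE]) == length(ss)
    outside <- if (length(setdiff(sp, ss)))
      rowSums(member[, setdiff(sp, ss), drop = FALSE]) == 0L else TRUE
    sum(inside & outside)
  }, numeric(1))
  data.frame(species_set = vapply(subsets, paste, character(1), collapse = "&"),
             count = as.integer(counts), stringsAsFactors = FALSE)
}

#' Per-species/locus diversity summary table
#'
#' One row per (species, locus) present in the genotype table: sample size,
#' allele totals, per-individual allele counts with the minimum gene-copy
#' bound, and nucleotide diversity (with Nei variance) over the set of
#' distinct alleles recovered in that species (unweighted by carrier
#' frequency).
#'
#' @param genotypes A genotype table.
#' @param alleles Named list of [allele_set()] objects keyed by locus, used
#'   to look up sequences for pi (alleles must be equal length per locus,
#'   i.e. post-QC).
#' @return Data frame mirroring the usual summary-table columns.
#' @export
diversity_summary <- function(genotypes, alleles) {
  combos <- unique(genotypes[, c("species", "locus")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sp <- combos$species[i]; loc <- combos$locus[i]
    st <- allele_stats(genotypes, sp, loc)
    ids <- unique(genotypes$allele_id[genotypes$species == sp &
                                        genotypes$locus == loc])
    aset <- alleles[[loc]]
    seqs <- aset$sequence[match(intersect(ids, aset$allele_id),
                                aset$allele_id)]
    pi <- if (length(seqs) >= 2L) nucleotide_diversity(seqs) else
      list(pi = NA_real_, variance = NA_real_)
    data.frame(species = sp, locus = loc,
               n_individuals = st$n_individuals,
               total_alleles = st$total_alleles,
               mean_alleles = st$mean, sd_alleles = st$sd,
               min_alleles = st$min, max_alleles = st$max,
               min_gene_copies = st$min_gene_copies,
               pi = pi$pi, pi_var = pi$variance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
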