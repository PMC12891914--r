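# Shared fixture builders and independent oracles. Oracles are brute-force
# or closed-form and never call the code paths they check.

fasta_file <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

geno_df <- function(individual, species, locus, run, allele) {
  data.frame(individual_id = individual, species = species, locus = locus,
             run_id = run, allele_id = allele, stringsAsFactors = FALSE)
}

geno_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force nucleotide diversity: explicit loop over unordered pairs.
oracle_pi <- function(seqs) {
  n <- length(seqs); L <- nchar(seqs[1])
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    tot <- tot + sum(a != b) / L
    np <- np + 1
  }
  tot / np
}

# Nei (1987, eq. 10.7) sampling variance, written independently.
oracle_nei_var <- function(pi, n, L) {
  (n + 1) / (3 * (n - 1) * L) * pi + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
}

# Exhaustive-enumeration rarefaction: mean richness over all C(N, n)
# subsamples of the expanded occurrence vector.
oracle_rarefaction <- function(counts, n) {
  units <- rep(seq_along(counts), counts)
  subs <- combn(length(units), n)
  mean(apply(subs, 2, function(ix) length(unique(units[ix]))))
}

# Exhaustive double-loop pool oracle over allele index sets. `within` pools
# unordered pairs inside each set; otherwise unordered cross pairs
# (excluding self-pairs, each counted once).
oracle_pool <- function(codons, rows_a, rows_b, columns, within = FALSE) {
  translate <- function(cod) unname(Biostrings::GENETIC_CODE[cod])
  seen <- character(0); out <- integer(0)
  pairs <- if (within) {
    rbind(if (length(rows_a) > 1) t(combn(rows_a, 2)),
          if (length(rows_b) > 1) t(combn(rows_b, 2)))
  } else as.matrix(expand.grid(rows_a, rows_b))
  if (is.null(pairs)) return(integer(0))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) next
    key <- paste(min(i, j), max(i, j))
    if (key %in% seen) next
    seen <- c(seen, key)
    for (cc in columns) {
      if (translate(codons[i, cc]) == translate(codons[j, cc]))
        out <- c(out, as.integer(codons[i, cc] == codons[j, cc]))
    }
  }
  out
}

# Hand-written Benjamini-Hochberg step-up: q_i = min_{j >= rank(i)} p_(j) m/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) for (pos in 0:(n - 1))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# Best label agreement over all relabelings of `labels` onto `truth`.
agreement_upto_permutation <- function(labels, truth) {
  k <- max(labels, truth)
  best <- 0
  for (p in perms(k))
    best <- max(best, mean(unlist(p)[labels] == truth))
  best
}

# Small in-frame codon alignment builder from codon-string rows.
toy_alignment <- function(rows, species, locus = "TOY") {
  seqs <- vapply(rows, paste, character(1), collapse = "")
  aset <- allele_set(locus, names(rows), seqs)
  codon_alignment(aset, species)
}

# Protein alleles with g latent functional groups at PSS: group consensus
# amino acids per site; within-group variation uses physiochemically
# conservative substitutions (one of the two nearest amino acids in
# z-scale space), keeping members close to their group centroid.
gen_supertype_proteins <- function(g, n_per_group = 20, n_pss = 10,
                                   mut = 0.05, seed = 1) {
  z <- mhctsp::aa_zscales
  aa20 <- rownames(z)
  nearest2 <- lapply(aa20, function(a) {
    d <- sqrt(colSums((t(z) - z[a, ])^2))
    names(sort(d))[2:3]
  })
  names(nearest2) <- aa20
  set.seed(seed)
  seqs <- character(0); truth <- integer(0)
  consensi <- replicate(g, sample(aa20, n_pss, replace = TRUE),
                        simplify = FALSE)
  for (gi in seq_len(g)) for (m in seq_len(n_per_group)) {
    s <- consensi[[gi]]
    for (site in which(runif(n_pss) < mut))
      s[site] <- sample(nearest2[[s[site]]], 1)
    seqs <- c(seqs, paste(s, collapse = ""))
    truth <- c(truth, gi)
  }
  names(seqs) <- sprintf("p%03d", seq_along(seqs))
  list(proteins = seqs, truth = truth)
}
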