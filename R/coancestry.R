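# Monte-Carlo codon-usage test of co-ancestry vs. convergent evolution for
# alleles shared among species. Bernoulli events are codon identities at
# sites where two alleles carry the same amino acid: cross-species events
# across the whole exon form the convergent-evolution drawing pool (CEd),
# within-species events the co-ancestry pool (CAd), and the observed
# statistic is the cross-species codon-identity proportion restricted to
# positively selected sites (PSS). One-tailed Z-tests compare the observed
# proportion to each resampled distribution, and the co-ancestry score
# locates it on the affine [median(CEd), median(CAd)] -> [0, 1] scale.

#' Build a codon alignment with species membership
#'
#' @param alleles An in-frame, stop-screened [allele_set()] (all sequences
#'   equal length, divisible by 3).
#' @param species Named list mapping each allele ID to the non-empty
#'   character vector of species carrying it.
#' @return Object of class `codon_alignment`: list with `locus`,
#'   `allele_id`, `codons` (allele x codon matrix of 3-mers), `aa`
#'   (amino-acid matrix), and `species` (membership list).
#' @export
codon_alignment <- function(alleles, species) {
  L <- unique(nchar(alleles$sequence))
  if (length(L) != 1L || L %% 3 != 0)
    stop_fmt("alleles must be equal length and in frame")
  miss <- setdiff(alleles$allele_id, names(species))
  if (length(miss))
    stop_fmt("no species membership for allele(s): %s",
             paste(utils::head(miss, 5L), collapse = ", "))
  species <- species[alleles$allele_id]
  if (any(lengths(species) == 0L))
    stop_fmt("empty species membership for allele '%s'",
             alleles$allele_id[lengths(species) == 0L][1L])
  nc <- L %/% 3
  raw <- vapply(alleles$sequence, split_codons, character(nc),
                USE.NAMES = FALSE)
  cod <- if (nc == 1L) matrix(raw, ncol = 1L) else t(raw)
  aa <- matrix(translate_codons(cod), nrow = nrow(cod))
  rownames(cod) <- rownames(aa) <- alleles$allele_id
  structure(list(locus = alleles$locus_id, allele_id = alleles$allele_id,
                 codons = cod, aa = aa, species = species),
            class = "codon_alignment")
}

#' Species membership of alleles from a genotype table
#'
#' @param genotypes A genotype table.
#' @param locus Locus to restrict to.
#' @return Named list: allele ID -> sorted character vector of species in
#'   which the allele was recovered.
#' @export
species_membership <- function(genotypes, locus) {
  g <- genotypes[genotypes$locus == locus, , drop = FALSE]
  lapply(split(g$species, g$allele_id), function(x) sort(unique(x)))
}

# Rows of the alignment carrying a given species.
species_rows <- function(align, sp) {
  which(vapply(align$species, function(s) sp %in% s, logical(1)))
}

# Unordered allele-row pairs between (or within) index sets, excluding
# self-pairs, each pair counted once even when an allele is shared.
unordered_pairs <- function(rows_a, rows_b) {
  if (!length(rows_a) || !length(rows_b))
    return(matrix(integer(0), ncol = 2))
  gr <- expand.grid(i = rows_a, j = rows_b)
  gr <- gr[gr$i != gr$j, , drop = FALSE]
  key <- cbind(pmin(gr$i, gr$j), pmax(gr$i, gr$j))
  unique(key)
}

# Collect codon-identity events for a set of row pairs over given columns.
pool_events <- function(align, pairs, columns, provenance = TRUE) {
  if (nrow(pairs) == 0L)
    return(list(outcomes = integer(0), provenance = NULL))
  aa1 <- align$aa[pairs[, 1], columns, drop = FALSE]
  aa2 <- align$aa[pairs[, 2], columns, drop = FALSE]
  same_aa <- aa1 == aa2
  eq <- align$codons[pairs[, 1], columns, drop = FALSE] ==
    align$codons[pairs[, 2], columns, drop = FALSE]
  outcomes <- as.integer(eq[same_aa])
  prov <- NULL
  if (provenance) {
    idx <- which(same_aa, arr.ind = TRUE)
    prov <- data.frame(
      allele_a = align$allele_id[pairs[idx[, 1], 1]],
      allele_b = align$allele_id[pairs[idx[, 1], 2]],
      codon = columns[idx[, 2]],
      outcome = as.integer(eq[same_aa]),
      stringsAsFactors = FALSE)
  }
  list(outcomes = outcomes, provenance = prov)
}

#' Convergent-evolution drawing pool (cross-species, whole exon)
#'
#' One Bernoulli event per cross-species allele pair and codon position at
#' which the two alleles carry the same amino acid: 1 if the codons are
#' identical, 0 otherwise. Alleles shared by both species contribute each
#' unordered cross-pair once; self-pairs are excluded.
#'
#' @param align A [codon_alignment()].
#' @param species_a,species_b The species pair.
#' @param provenance Keep the per-event (allele pair, codon) table?
#' @return Object of class `outcome_pool` with `scenario = "CE"`,
#'   `species`, `outcomes` (0/1 integer vector), and `provenance`.
#' @export
build_ce_pool <- function(align, species_a, species_b, provenance = TRUE) {
  ra <- species_rows(align, species_a); rb <- species_rows(align, species_b)
  if (!length(ra) || !length(rb))
    stop_fmt("species '%s' has no alleles in the alignment",
             if (length(ra)) species_b else species_a)
  ev <- pool_events(align, unordered_pairs(ra, rb),
                    seq_len(ncol(align$codons)), provenance)
  if (!length(ev$outcomes))
    stop_fmt("empty CE pool for %s vs %s: no identical amino acids anywhere",
             species_a, species_b)
  structure(list(scenario = "CE", species = c(species_a, species_b),
                 outcomes = ev$outcomes, provenance = ev$provenance),
            class = "outcome_pool")
}

#' Co-ancestry drawing pool (within-species, whole exon)
#'
#' Events from all within-species unordered allele pairs of both members of
#' the species pair (merged to symmetrize the null), same event rule as the
#' CE pool. Both species mono-allelic is an error: the co-ancestry null is
#' then undefined.
#'
#' @inheritParams build_ce_pool
#' @return An `outcome_pool` with `scenario = "CA"`.
#' @export
build_ca_pool <- function(align, species_a, species_b, provenance = TRUE) {
  ra <- species_rows(align, species_a); rb <- species_rows(align, species_b)
  pairs <- rbind(
    if (length(ra) > 1L) t(utils::combn(ra, 2L)) else NULL,
    if (length(rb) > 1L) t(utils::combn(rb, 2L)) else NULL)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop_fmt("co-ancestry null undefined: both '%s' and '%s' are mono-allelic",
             species_a, species_b)
  ev <- pool_events(align, pairs, seq_len(ncol(align$codons)), provenance)
  if (!length(ev$outcomes))
    stop_fmt("empty CA pool for %s vs %s", species_a, species_b)
  structure(list(scenario = "CA", species = c(species_a, species_b),
                 outcomes = ev$outcomes, provenance = ev$provenance),
            class = "outcome_pool")
}

#' @export
print.outcome_pool <- function(x, ...) {
  cat(sprintf("%s drawing pool (%s vs %s): %d events, identity %.3f\n",
              x$scenario, x$species[1], x$species[2], length(x$outcomes),
              mean(x$outcomes)))
  invisible(x)
}

#' Observed codon identity at positively selected sites
#'
#' Cross-species events built exactly as for the CE pool but restricted to
#' PSS columns. Zero events is flagged `evaluable = FALSE` (not an error)
#' so batch runs continue.
#'
#' @inheritParams build_ce_pool
#' @param pss Integer vector of 1-based codon indices within the ORF.
#' @return List with `observed` (proportion of identical codons), `k`
#'   (event count; parameterizes the Monte-Carlo draws), and `evaluable`.
#' @export
observed_pss_identity <- function(align, species_a, species_b, pss) {
  nc <- ncol(align$codons)
  pss <- as.integer(pss)
  if (!length(pss)) stop_fmt("PSS set is empty")
  if (any(pss < 1L | pss > nc))
    stop_fmt("PSS indices must lie in [1, %d]", nc)
  ra <- species_rows(align, species_a); rb <- species_rows(align, species_b)
  ev <- pool_events(align, unordered_pairs(ra, rb), pss, provenance = FALSE)
  if (!length(ev$outcomes))
    return(list(observed = NA_real_, k = 0L, evaluable = FALSE))
  list(observed = mean(ev$outcomes), k = length(ev$outcomes),
       evaluable = TRUE)
}

#' Monte-Carlo distribution of resampled codon-identity proportions
#'
#' Each of `n_reps` replicates draws `k` outcomes uniformly with replacement
#' from the pool and records their mean. Fully reproducible given `seed`;
#' the caller's RNG state is untouched.
#'
#' @param pool An `outcome_pool`.
#' @param k Events per replicate (the observed PSS event count).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return Object of class `mc_distribution`: `scenario`, `samples`,
#'   `k`, `n_reps`, `mean`, `sd`, `median`, `degenerate` (sd == 0), `seed`.
#' @export
mc_distribution <- function(pool, k, n_reps = 1000L, seed = 1L) {
  if (!length(pool$outcomes)) stop_fmt("cannot resample an empty pool")
  k <- as.integer(k)
  if (k < 1L) stop_fmt("k must be >= 1")
  samples <- with_seed(seed, {
    draws <- sample(pool$outcomes, k * n_reps, replace = TRUE)
    colMeans(matrix(draws, nrow = k, ncol = n_reps))
  })
  s <- stats::sd(samples)
  if (s == 0)
    warn_fmt("degenerate %s distribution (all resampled proportions %.3f)",
             pool$scenario, samples[1])
  structure(list(scenario = pool$scenario, samples = samples, k = k,
                 n_reps = as.integer(n_reps), mean = mean(samples), sd = s,
                 median = stats::median(samples), degenerate = s == 0,
                 seed = seed),
            class = "mc_distribution")
}

# One-tailed normal p-value of obs against an MC distribution.
# direction "upper" tests obs > mean, "lower" tests obs < mean.
# Degenerate sd: p by sign convention (0 / 0.5 / 1).
one_tailed_p <- function(obs, dist, direction) {
  if (dist$degenerate) {
    z <- if (obs == dist$mean) 0 else sign(obs - dist$mean) * Inf
    p <- if (obs == dist$mean) 0.5
    else if (direction == "upper") as.numeric(obs < dist$mean)
    else as.numeric(obs > dist$mean)
    return(list(z = z, p = p))
  }
  z <- (obs - dist$mean) / dist$sd
  p <- if (direction == "upper") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z, lower.tail = TRUE)
  list(z = z, p = p)
}

#' Evaluate one species pair against its CE and CA distributions
#'
#' Z = (observed - mean)/sd per distribution; one-tailed p-values test
#' whether the observed proportion exceeds the convergent-evolution mean
#' (upper tail vs CEd) and falls below the co-ancestry mean (lower tail vs
#' CAd), with a normal reference. The co-ancestry score is
#' `(observed - median(CEd)) / (median(CAd) - median(CEd))`; a vanishing
#' denominator (< 1e-12 in absolute value) yields `NA` with a flag.
#'
#' @param obs Observed PSS codon-identity proportion.
#' @param k PSS event count used for the Monte-Carlo draws.
#' @param ce,ca `mc_distribution` objects built with this pair's `k`.
#' @return One-row data frame: `observed`, `k`, `z_vs_CE`, `p_vs_CE`,
#'   `z_vs_CA`, `p_vs_CA`, `score`, `score_defined`.
#' @export
evaluate_pair <- function(obs, k, ce, ca) {
  stopifnot(ce$scenario == "CE", ca$scenario == "CA")
  if (ce$k != k || ca$k != k)
    stop_fmt("distributions were built with k = %d / %d, but obs has k = %d",
             ce$k, ca$k, k)
  e <- one_tailed_p(obs, ce, "upper")
  a <- one_tailed_p(obs, ca, "lower")
  denom <- ca$median - ce$median
  defined <- abs(denom) >= 1e-12
  if (!defined) warn_fmt("co-ancestry score undefined: median(CAd) == median(CEd)")
  data.frame(observed = obs, k = k,
             z_vs_CE = e$z, p_vs_CE = e$p,
             z_vs_CA = a$z, p_vs_CA = a$p,
             score = if (defined) (obs - ce$median) / denom else NA_real_,
             score_defined = defined)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone and capped at 1 (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
fdr_bh <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Codon-usage co-ancestry test across all species pairs of a region
#'
#' For every unordered species pair: the observed cross-species codon
#' identity at PSS, the resampled convergent-evolution (CEd) and
#' co-ancestry (CAd) distributions (each with the pair's event count `k`),
#' one-tailed Z-tests, and the co-ancestry score. BH-FDR is applied within
#' the region, separately for the CE-direction and CA-direction families.
#'
#' @param align A [codon_alignment()].
#' @param pss Integer PSS codon indices (1-based within the ORF).
#' @param species Species to compare (default: all present in the
#'   alignment, sorted).
#' @param n_reps Monte-Carlo replicates per distribution (default 1000).
#' @param seed Master seed; per-pair child seeds are derived from it.
#' @param keep_samples Keep full Monte-Carlo sample vectors?
#' @return Object of class `coancestry_test`: list with `pairs` (one row
#'   per species pair: observed, k, z/p/q vs CE and CA, score, evaluable),
#'   `distributions` (if kept), `pss`, `n_reps`, `seed`, `locus`.
#' @export
coancestry_test <- function(align, pss, species = NULL, n_reps = 1000L,
                            seed = 1L, keep_samples = TRUE) {
  if (is.null(species))
    species <- sort(unique(unlist(align$species, use.names = FALSE)))
  if (length(species) < 2L) stop_fmt("need >= 2 species")
  combos <- utils::combn(species, 2L)
  rows <- vector("list", ncol(combos))
  dists <- if (keep_samples) vector("list", ncol(combos)) else NULL
  for (i in seq_len(ncol(combos))) {
    sa <- combos[1, i]; sb <- combos[2, i]
    obs <- observed_pss_identity(align, sa, sb, pss)
    if (!obs$evaluable) {
      rows[[i]] <- data.frame(species_a = sa, species_b = sb,
                              observed = NA_real_, k = 0L,
                              z_vs_CE = NA_real_, p_vs_CE = NA_real_,
                              z_vs_CA = NA_real_, p_vs_CA = NA_real_,
                              score = NA_real_, score_defined = FALSE,
                              evaluable = FALSE)
      next
    }
    ce <- build_ce_pool(align, sa, sb, provenance = FALSE)
    ca <- build_ca_pool(align, sa, sb, provenance = FALSE)
    ced <- mc_distribution(ce, obs$k, n_reps, child_seed(seed, 2L * i))
    cad <- mc_distribution(ca, obs$k, n_reps, child_seed(seed, 2L * i + 1L))
    ev <- evaluate_pair(obs$observed, obs$k, ced, cad)
    rows[[i]] <- cbind(data.frame(species_a = sa, species_b = sb), ev,
                       evaluable = TRUE)
    if (keep_samples)
      dists[[i]] <- list(species = c(sa, sb), CEd = ced, CAd = cad)
  }
  pairs <- do.call(rbind, rows)
  pairs$q_vs_CE <- pairs$q_vs_CA <- NA_real_
  ok <- pairs$evaluable
  pairs$q_vs_CE[ok] <- fdr_bh(pairs$p_vs_CE[ok])
  pairs$q_vs_CA[ok] <- fdr_bh(pairs$p_vs_CA[ok])
  structure(list(pairs = pairs, distributions = dists, pss = pss,
                 n_reps = as.integer(n_reps), seed = seed,
                 locus = align$locus),
            class = "coancestry_test")
}

#' @export
print.coancestry_test <- function(x, ...) {
  cat(sprintf("Codon-usage co-ancestry test, locus '%s' (%d PSS, %d MC reps)\n",
              x$locus, length(x$pss), x$n_reps))
  cols <- c("species_a", "species_b", "observed", "k", "q_vs_CE",
            "q_vs_CA", "score")
  print(format(x$pairs[, cols], digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.coancestry_test <- function(object, ...) {
  p <- object$pairs[object$pairs$evaluable, , drop = FALSE]
  out <- list(
    locus = object$locus,
    n_pairs = nrow(object$pairs),
    n_evaluable = nrow(p),
    mean_score = mean(p$score, na.rm = TRUE),
    n_sig_vs_CE = sum(p$q_vs_CE < 0.05, na.rm = TRUE),
    n_sig_vs_CA = sum(p$q_vs_CA < 0.05, na.rm = TRUE))
  class(out) <- "summary.coancestry_test"
  out
}

#' @export
print.summary.coancestry_test <- function(x, ...) {
  cat(sprintf(paste0("Locus '%s': %d/%d species pairs evaluable; mean ",
                     "co-ancestry score %.3f;\n  %d pair(s) above the CE ",
                     "null (q < 0.05), %d below the CA null (q < 0.05)\n"),
              x$locus, x$n_evaluable, x$n_pairs, x$mean_score,
              x$n_sig_vs_CE, x$n_sig_vs_CA))
  invisible(x)
}

#' Correlation of co-ancestry score with phylogenetic distance
#'
#' Pearson correlation between per-pair co-ancestry scores and patristic
#' distances, with the two-sided t-test p-value
#' (t = r sqrt((n-2)/(1-r^2)), n-2 df).
#'
#' @param fit A [coancestry_test()] result.
#' @param tree A species tree (`phylo`) whose tips cover all species.
#' @return List with `r`, `p`, `n_pairs`, and the underlying data frame
#'   (`score`, `distance` per pair). Zero variance in either vector is
#'   flagged (`r = NA`, `defined = FALSE`).
#' @export
score_distance_correlation <- function(fit, tree) {
  p <- fit$pairs[fit$pairs$evaluable & fit$pairs$score_defined, ,
                 drop = FALSE]
  if (nrow(p) < 3L)
    stop_fmt("need >= 3 evaluable species pairs, have %d", nrow(p))
  dmat <- patristic_matrix(tree)
  for (sp in unique(c(p$species_a, p$species_b)))
    if (!sp %in% rownames(dmat))
      stop_fmt("species '%s' is not a tip of the tree", sp)
  d <- dmat[cbind(p$species_a, p$species_b)]
  if (stats::sd(p$score) == 0 || stats::sd(d) == 0)
    return(list(r = NA_real_, p = NA_real_, n_pairs = nrow(p),
                defined = FALSE,
                data = data.frame(score = p$score, distance = d)))
  ct <- stats::cor.test(p$score, d, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(p),
       defined = TRUE, data = data.frame(score = p$score, distance = d))
}
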