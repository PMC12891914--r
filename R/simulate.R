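# Seeded synthetic multi-species MHC data with known ground truth.
#
# The generator is deliberately simple: the codon-usage statistics under
# test depend only on codon identity conditional on amino-acid identity,
# which these models control exactly. Under the co-ancestry (CA) regime a
# group of species shares an ancestral allele pool whose PSS codons follow
# a fixed (site, amino acid) -> codon map, so identical amino acids shared
# between species at PSS are codon-identical; species lineages then
# accumulate their own synonymous/nonsynonymous substitutions at non-PSS
# sites, and a fraction of pool alleles is trans-species conserved
# (inherited verbatim, giving genuinely shared identical alleles). Under
# the convergent-evolution (CE) regime each allele draws its PSS amino
# acids from the shared profile and picks a codon uniformly from that
# amino acid's synonymous family, so codon identity given amino-acid
# identity equals the family-wise 1/|family| expectation.

#' Simulation configuration
#'
#' @param scenario `"CA"` (all species share one ancestral pool), `"CE"`
#'   (every species independent), or `"mixed"` (two co-ancestry blocks;
#'   cross-block pairs behave as CE).
#' @param n_species Number of species (named `sp1`, `sp2`, ...).
#' @param tree_depth Branch length (substitutions/site) used for every edge
#'   of the balanced species tree emitted alongside the alleles.
#' @param n_codons Codons per allele.
#' @param pss_indices 1-based PSS codon positions (default: 10 positions
#'   evenly spread).
#' @param ancestral_pool_size Alleles in each ancestral pool; must be >=
#'   `alleles_per_species`.
#' @param alleles_per_species Alleles sampled per species.
#' @param synonymous_mutation_rate Per-codon probability that a species
#'   lineage carries a synonymous substitution at a non-PSS site.
#' @param nonsynonymous_rate Per-codon probability of a lineage
#'   nonsynonymous substitution at a non-PSS site.
#' @param per_allele_drift Per-codon probability of an additional
#'   per-allele synonymous change at non-PSS sites.
#' @param conserved_fraction Fraction of pool alleles inherited verbatim
#'   (trans-species conserved lineages).
#' @param aa_profile Amino acids drawn at PSS (shared across species);
#'   defaults to five four-fold-degenerate residues.
#' @param n_individuals Individuals per species.
#' @param copies_per_individual Length-2 integer range of allele copies
#'   drawn per individual (e.g. `c(1, 6)`).
#' @param replicate_runs Number of sequencing runs for replicated
#'   individuals.
#' @param replicate_fraction Fraction of individuals sequenced in
#'   `replicate_runs` runs (others get one run).
#' @param allele_dropout_prob Probability an allele is missed in any one
#'   run.
#' @param locus_id Locus label stamped on outputs.
#' @param seed Master seed; all stages derive child seeds from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("CA", "CE", "mixed"),
                       n_species = 4L, tree_depth = 0.05,
                       n_codons = 60L, pss_indices = NULL,
                       ancestral_pool_size = 30L,
                       alleles_per_species = 12L,
                       synonymous_mutation_rate = 0.5,
                       nonsynonymous_rate = 0.05,
                       per_allele_drift = 0.02,
                       conserved_fraction = 0.3,
                       aa_profile = c("A", "G", "P", "T", "V"),
                       n_individuals = 20L,
                       copies_per_individual = c(1L, 6L),
                       replicate_runs = 2L,
                       replicate_fraction = 0.25,
                       allele_dropout_prob = 0.1,
                       locus_id = "SIM", seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(pss_indices))
    pss_indices <- unique(round(seq(2, n_codons - 1, length.out = 10)))
  pss_indices <- sort(unique(as.integer(pss_indices)))
  rates <- c(synonymous_mutation_rate, nonsynonymous_rate,
             per_allele_drift, conserved_fraction, allele_dropout_prob,
             replicate_fraction)
  if (any(rates < 0 | rates > 1)) stop_fmt("rates must lie in [0, 1]")
  if (any(pss_indices < 1L | pss_indices > n_codons))
    stop_fmt("pss_indices must lie in [1, n_codons]")
  if (ancestral_pool_size < alleles_per_species)
    stop_fmt("ancestral pool (%d) smaller than alleles_per_species (%d)",
             ancestral_pool_size, alleles_per_species)
  stopifnot(length(copies_per_individual) == 2L,
            copies_per_individual[1] >= 1L,
            copies_per_individual[2] >= copies_per_individual[1])
  structure(list(scenario = scenario, n_species = as.integer(n_species),
                 tree_depth = tree_depth, n_codons = as.integer(n_codons),
                 pss_indices = pss_indices,
                 ancestral_pool_size = as.integer(ancestral_pool_size),
                 alleles_per_species = as.integer(alleles_per_species),
                 synonymous_mutation_rate = synonymous_mutation_rate,
                 nonsynonymous_rate = nonsynonymous_rate,
                 per_allele_drift = per_allele_drift,
                 conserved_fraction = conserved_fraction,
                 aa_profile = aa_profile,
                 n_individuals = as.integer(n_individuals),
                 copies_per_individual = as.integer(copies_per_individual),
                 replicate_runs = as.integer(replicate_runs),
                 replicate_fraction = replicate_fraction,
                 allele_dropout_prob = allele_dropout_prob,
                 locus_id = locus_id, seed = as.integer(seed)),
            class = "sim_config")
}

# Non-stop codons of the standard code.
non_stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

# A random synonymous replacement for a codon (the codon itself if its
# family is a singleton).
synonymous_swap <- function(codon) {
  fam <- setdiff(codon_family(translate_codons(codon)), codon)
  if (!length(fam)) codon else sample(fam, 1L)
}

# Species grouping by scenario: CA one block, CE singletons, mixed halves.
scenario_groups <- function(scenario, species) {
  switch(scenario,
    CA = list(species),
    CE = as.list(species),
    mixed = {
      h <- ceiling(length(species) / 2)
      list(species[seq_len(h)], species[-seq_len(h)])
    })
}

#' Simulate per-species allele sets with known ground truth
#'
#' See the package vignette for the generative model. Byte-identical output
#' for identical configurations (including seed).
#'
#' @param cfg A [sim_config()].
#' @return List with `alleles` (named list of per-species [allele_set()]),
#'   `truth` (data frame `species_a`, `species_b`, `scenario` per pair),
#'   `membership` (allele ID -> species vector, over the union of alleles),
#'   `combined` (one [allele_set()] over the union), `tree` (`phylo`),
#'   `pss`, and `config`.
#' @export
simulate_alleles <- function(cfg) {
  species <- paste0("sp", seq_len(cfg$n_species))
  groups <- scenario_groups(cfg$scenario, species)
  nonpss <- setdiff(seq_len(cfg$n_codons), cfg$pss_indices)
  per_species <- with_seed(child_seed(cfg$seed, 1L), {
    consensus <- sample(non_stop_codons(), cfg$n_codons, replace = TRUE)
    out <- list()
    for (gi in seq_along(groups)) {
      gsp <- groups[[gi]]
      per_allele_codon <- cfg$scenario == "CE"
      # fixed ancestral (site, aa) -> codon map for the group
      pss_map <- lapply(cfg$pss_indices, function(site)
        vapply(cfg$aa_profile, function(aa) sample(codon_family(aa), 1L),
               character(1)))
      names(pss_map) <- as.character(cfg$pss_indices)
      # ancestral pool
      pool <- lapply(seq_len(cfg$ancestral_pool_size), function(ai) {
        cod <- consensus
        for (si in seq_along(cfg$pss_indices)) {
          aa <- sample(cfg$aa_profile, 1L)
          cod[cfg$pss_indices[si]] <-
            if (per_allele_codon) sample(codon_family(aa), 1L)
            else pss_map[[si]][[aa]]
        }
        cod
      })
      pool_ids <- sprintf("%s_g%danc%03d", cfg$locus_id, gi,
                          seq_len(cfg$ancestral_pool_size))
      conserved <- stats::runif(cfg$ancestral_pool_size) <
        cfg$conserved_fraction
      for (sp in gsp) {
        # lineage-specific substitution map at non-PSS sites
        smap <- consensus
        for (site in nonpss) {
          if (stats::runif(1) < cfg$synonymous_mutation_rate)
            smap[site] <- synonymous_swap(smap[site])
          if (stats::runif(1) < cfg$nonsynonymous_rate) {
            aa_now <- translate_codons(smap[site])
            other <- non_stop_codons()
            other <- other[translate_codons(other) != aa_now]
            smap[site] <- sample(other, 1L)
          }
        }
        lineage_delta <- which(smap != consensus)
        take <- sort(sample(cfg$ancestral_pool_size,
                            cfg$alleles_per_species))
        ids <- character(length(take)); seqs <- character(length(take))
        for (t in seq_along(take)) {
          ai <- take[t]
          cod <- pool[[ai]]
          if (conserved[ai]) {
            ids[t] <- pool_ids[ai]
          } else {
            cod[lineage_delta] <- smap[lineage_delta]
            for (site in nonpss)
              if (stats::runif(1) < cfg$per_allele_drift)
                cod[site] <- synonymous_swap(cod[site])
            ids[t] <- paste0(pool_ids[ai], "_", sp)
          }
          seqs[t] <- paste(cod, collapse = "")
        }
        out[[sp]] <- allele_set(cfg$locus_id, ids, seqs)
      }
    }
    out[species]
  })
  # per-pair truth labels
  group_of <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                              unlist(groups))
  combos <- utils::combn(species, 2L)
  truth <- data.frame(species_a = combos[1, ], species_b = combos[2, ],
                      scenario = ifelse(
                        group_of[combos[1, ]] == group_of[combos[2, ]] &
                          cfg$scenario != "CE", "CA", "CE"),
                      stringsAsFactors = FALSE)
  # union allele set + species membership
  all_ids <- unique(unlist(lapply(per_species, `[[`, "allele_id")))
  seq_of <- new.env()
  for (sp in species) {
    a <- per_species[[sp]]
    for (i in seq_along(a$allele_id)) assign(a$allele_id[i], a$sequence[i],
                                             envir = seq_of)
  }
  combined <- allele_set(cfg$locus_id, all_ids,
                         vapply(all_ids, get, character(1), envir = seq_of))
  membership <- lapply(stats::setNames(all_ids, all_ids), function(id)
    species[vapply(per_species, function(a) id %in% a$allele_id,
                   logical(1))])
  list(alleles = per_species, truth = truth, membership = membership,
       combined = combined, tree = balanced_tree(species, cfg$tree_depth),
       pss = cfg$pss_indices, config = cfg)
}

# Balanced (or ladderized, for non-powers of two) species tree with a
# uniform branch length.
balanced_tree <- function(species, depth) {
  n <- length(species)
  type <- if (n >= 2 && log2(n) %% 1 == 0) "balanced" else "left"
  tree <- ape::stree(n, type = type)
  tree$tip.label <- species
  tree$edge.length <- rep(depth, nrow(tree$edge))
  tree
}

#' Simulate a genotype table over simulated allele sets
#'
#' Each individual draws its allele copies without replacement from its
#' species' allele set; a configurable subset of individuals is sequenced
#' in replicate runs, and each run re-observes each carried allele with
#' probability `1 - allele_dropout_prob`.
#'
#' @param alleles Named list of per-species [allele_set()] objects.
#' @param cfg A [sim_config()].
#' @return A genotype table `data.frame` (may have zero rows if dropout is
#'   total, in which case downstream validation errors).
#' @export
simulate_genotypes <- function(alleles, cfg) {
  if (any(vapply(alleles, length, integer(1)) == 0L))
    stop_fmt("species allele sets must be non-empty")
  rows <- with_seed(child_seed(cfg$seed, 2L), {
    acc <- list()
    for (sp in names(alleles)) {
      ids <- alleles[[sp]]$allele_id
      n_rep <- ceiling(cfg$replicate_fraction * cfg$n_individuals)
      replicated <- sample(cfg$n_individuals, n_rep)
      for (ind in seq_len(cfg$n_individuals)) {
        lo <- cfg$copies_per_individual[1]
        hi <- min(cfg$copies_per_individual[2], length(ids))
        if (lo > length(ids))
          stop_fmt("individual needs %d copies but species '%s' has %d alleles",
                   lo, sp, length(ids))
        nc <- sample(seq(lo, hi), 1L)
        carried <- sample(ids, nc)
        n_runs <- if (ind %in% replicated) cfg$replicate_runs else 1L
        for (r in seq_len(n_runs)) {
          seen <- carried[stats::runif(length(carried)) >=
                            cfg$allele_dropout_prob]
          if (length(seen))
            acc[[length(acc) + 1L]] <- data.frame(
              individual_id = sprintf("%s_ind%03d", sp, ind),
              species = sp, locus = cfg$locus_id,
              run_id = sprintf("%s_run%d", sp, r),
              allele_id = seen, stringsAsFactors = FALSE)
        }
      }
    }
    acc
  })
  if (!length(rows))
    return(data.frame(individual_id = character(0), species = character(0),
                      locus = character(0), run_id = character(0),
                      allele_id = character(0), stringsAsFactors = FALSE))
  genotype_table(do.call(rbind, rows))
}

#' Simulate a complete dataset (alleles, genotypes, tree, PSS, truth)
#'
#' @param cfg A [sim_config()].
#' @return The [simulate_alleles()] result plus `genotypes`.
#' @export
simulate_dataset <- function(cfg) {
  sim <- simulate_alleles(cfg)
  sim$genotypes <- simulate_genotypes(sim$alleles, cfg)
  sim
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits per-species and combined FASTA, genotype TSV, PSS TSV, Newick
#' tree, and a truth JSON.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_allele_fasta(sim$combined, file.path(dir, "alleles.fasta"))
  utils::write.table(sim$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(locus = sim$config$locus_id, codon = sim$pss),
    file.path(dir, "pss.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(scenario = sim$config$scenario, truth = sim$truth,
         seed = sim$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
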