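# Orchestration: a single entry point running any stage (or the whole
# chain) from a JSON config, writing tabular/JSON artifacts plus a run
# manifest (resolved config, input checksums, seed, package version).
# All randomness flows from one master seed fanned out to per-stage child
# seeds, so stages are individually reproducible and result files are
# byte-identical across reruns (the manifest carries the only timestamp).

pipeline_subcommands <- c("simulate", "qc", "diversity", "coancestry",
                          "supertype", "all")

allowed_config_keys <- c("seed", "sim", "inputs", "qc", "coancestry",
                         "supertype")

read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  unknown <- setdiff(names(cfg), allowed_config_keys)
  if (length(unknown))
    stop_fmt("unknown config key '%s' (allowed: %s)", unknown[1L],
             paste(allowed_config_keys, collapse = ", "))
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run pipeline stages from a configuration
#'
#' Subcommands: `"simulate"` (emit a synthetic dataset), `"qc"`,
#' `"diversity"`, `"coancestry"`, `"supertype"`, or `"all"`
#' (qc -> diversity -> coancestry -> supertype on the same inputs).
#' Outputs are written under `out_dir` together with `manifest.json`.
#'
#' @param subcommand One of the six subcommands above.
#' @param config Path to a JSON config file, or an equivalent list.
#'   Top-level keys: `seed`; `sim` ([sim_config()] arguments, for
#'   `simulate`); `inputs` (`fasta`, `genotypes`, `pss`, `tree`, `locus`);
#'   `qc` (overrides for [locus_config()]); `coancestry` (`n_reps`);
#'   `supertype` (`k_range`, `pc_grid`, `n_starts`, `xval_reps`).
#' @param out_dir Output directory, created if missing.
#' @param seed Optional master seed overriding `config$seed` (default 1).
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(subcommand, config, out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand, pipeline_subcommands)
  cfg <- read_pipeline_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if (subcommand == "simulate") {
    sim_args <- cfg$sim %||% list()
    sim_args$seed <- seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    write_dataset(sim, out_dir)
    results$simulate <- sim
    write_manifest(subcommand, cfg, out_dir, seed, character(0))
    return(invisible(results))
  }

  inputs <- cfg$inputs
  needed <- c("fasta", "genotypes", "pss")
  if (subcommand %in% c("coancestry", "all")) needed <- c(needed, "tree")
  missing <- setdiff(needed, names(inputs))
  if (length(missing))
    stop_fmt("config inputs missing: %s", paste(missing, collapse = ", "))
  for (f in needed)
    if (!file.exists(inputs[[f]]))
      stop_fmt("input file not found: %s", inputs[[f]])

  locus <- inputs$locus %||% "SIM"
  alleles <- read_allele_fasta(inputs$fasta, locus)
  genotypes <- read_genotype_table(inputs$genotypes)
  pss <- read_pss_list(inputs$pss, locus)

  qc_over <- cfg$qc %||% list()
  lcfg <- locus_config(
    locus,
    qc_over$expected_amplicon_length %||%
      as.integer(names(sort(table(nchar(alleles$sequence)),
                            decreasing = TRUE))[1L]),
    qc_over$intron_trim,
    qc_over$orf_offset %||% 0L,
    qc_over$orf_length %||%
      {len <- qc_over$expected_amplicon_length %||%
         as.integer(names(sort(table(nchar(alleles$sequence)),
                               decreasing = TRUE))[1L])
       len - len %% 3L})

  run_qc <- function() {
    q <- qc_alleles(alleles, genotypes, lcfg)
    write_allele_fasta(q$alleles, file.path(out_dir, "alleles_qc.fasta"))
    prot <- q$proteins
    pfa <- Biostrings::BStringSet(prot$aa_sequence)
    names(pfa) <- prot$protein_id
    Biostrings::writeXStringSet(pfa, file.path(out_dir, "proteins.fasta"))
    write_tsv(q$rejected, file.path(out_dir, "rejection_ledger.tsv"))
    q
  }
  run_diversity <- function(q) {
    g <- genotypes[genotypes$allele_id %in% q$alleles$allele_id, ,
                   drop = FALSE]
    summ <- diversity_summary(g, stats::setNames(list(q$alleles), locus))
    write_tsv(summ, file.path(out_dir, "diversity_summary.tsv"))
    sets <- lapply(split(g$allele_id, g$species), unique)
    rare <- do.call(rbind, lapply(names(sets), function(sp) {
      counts <- tapply(g$individual_id[g$species == sp],
                       g$allele_id[g$species == sp],
                       function(x) length(unique(x)))
      N <- sum(counts)
      grid <- unique(pmin(N, c(1, 2, 5, 10, 20, 50, 100, N)))
      cbind(species = sp, rarefaction_curve(as.numeric(counts), grid))
    }))
    write_tsv(rare, file.path(out_dir, "rarefaction.tsv"))
    if (length(sets) >= 2L)
      write_tsv(shared_allele_partition(sets),
                file.path(out_dir, "shared_alleles.tsv"))
    summ
  }
  run_coancestry <- function(q) {
    align <- codon_alignment(q$alleles, species_membership(genotypes, locus))
    fit <- coancestry_test(align, pss, n_reps = cfg$coancestry$n_reps %||% 1000L,
                           seed = child_seed(seed, 30L))
    write_tsv(fit$pairs, file.path(out_dir, "coancestry_pairs.tsv"))
    samples <- lapply(fit$distributions, function(d) if (is.null(d)) NULL else
      list(species = d$species, CEd = d$CEd$samples, CAd = d$CAd$samples))
    jsonlite::write_json(samples, file.path(out_dir, "coancestry_mc.json"),
                         auto_unbox = TRUE, digits = NA)
    tree <- read_species_tree(inputs$tree)
    corr <- tryCatch(score_distance_correlation(fit, tree),
                     error = function(e) NULL)
    if (!is.null(corr))
      jsonlite::write_json(corr[c("r", "p", "n_pairs", "defined")],
                           file.path(out_dir, "score_distance.json"),
                           auto_unbox = TRUE, digits = NA)
    fit
  }
  run_supertype <- function(q) {
    st <- supertype(q$proteins, pss,
                    k_range = cfg$supertype$k_range %||% 1:6,
                    pc_grid = cfg$supertype$pc_grid,
                    n_starts = cfg$supertype$n_starts %||% 25L,
                    xval_reps = cfg$supertype$xval_reps %||% 30L,
                    seed = child_seed(seed, 40L))
    write_tsv(data.frame(protein_id = names(st$model$labels),
                         supertype = st$model$labels,
                         max_posterior = apply(st$model$posterior, 1, max)),
              file.path(out_dir, "supertypes.tsv"))
    jsonlite::write_json(
      list(k = st$model$k, n_pcs = st$model$n_pcs,
           bic = st$k_selection$bic,
           accuracy = st$pc_selection$accuracy),
      file.path(out_dir, "supertype_model.json"),
      auto_unbox = TRUE, digits = NA)
    st
  }

  q <- run_qc()
  results$qc <- q
  if (subcommand %in% c("diversity", "all"))
    results$diversity <- run_diversity(q)
  if (subcommand %in% c("coancestry", "all"))
    results$coancestry <- run_coancestry(q)
  if (subcommand %in% c("supertype", "all"))
    results$supertype <- run_supertype(q)

  write_manifest(subcommand, cfg, out_dir, seed,
                 unlist(inputs[needed], use.names = FALSE))
  invisible(results)
}

write_manifest <- function(subcommand, cfg, out_dir, seed, input_files) {
  checksums <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  jsonlite::write_json(
    list(subcommand = subcommand, config = cfg, seed = seed,
         input_md5 = checksums,
         package_version = as.character(utils::packageVersion("mhctsp")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
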