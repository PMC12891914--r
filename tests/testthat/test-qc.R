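# Length/prevalence filtering, ORF trimming, stop screening, and the
# protein collapse, against the rules and worked examples of the QC stage.

make_cfg <- function(len = 6L, orf = 6L, offset = 0L, intron = NULL)
  locus_config("L1", len, intron, offset, orf)

test_that("prevalence filter keeps replicated or multi-individual alleles", {
  al <- allele_set("L1", c("short", "two_ind", "one_ind_two_runs", "single"),
                   c("ACGTA", "ACGTAA", "ACGTAC", "ACGTAG"))
  g <- geno_df(
    individual = c("i1", "i2", "i3", "i3", "i4"),
    species = "spA", locus = "L1",
    run = c("r1", "r1", "r1", "r2", "r1"),
    allele = c("two_ind", "two_ind", "one_ind_two_runs",
               "one_ind_two_runs", "single"))
  res <- filter_prevalence(al, genotype_table(g), make_cfg())
  expect_setequal(res$alleles$allele_id, c("two_ind", "one_ind_two_runs"))
  expect_equal(res$rejected$reason[res$rejected$allele_id == "short"], "length")
  expect_equal(res$rejected$reason[res$rejected$allele_id == "single"],
               "singleton")

  # allele called in genotypes but absent from FASTA is a hard error
  g_bad <- rbind(g, geno_df("i9", "spA", "L1", "r1", "ghost"))
  expect_error(filter_prevalence(al, genotype_table(g_bad), make_cfg()),
               "ghost")

  # idempotence: filtering the retained set (with its genotype rows) again
  # changes nothing
  g_keep <- g[g$allele_id %in% res$alleles$allele_id, ]
  res2 <- filter_prevalence(res$alleles, genotype_table(g_keep), make_cfg())
  expect_equal(res2$alleles$allele_id, res$alleles$allele_id)
  expect_equal(nrow(res2$rejected), 0L)
})

test_that("ORF trimming deletes the intron window then extracts the frame", {
  # leading 20-bp intron, 269-bp exon, 267-bp ORF (no internal stops)
  exon267 <- strrep("GCT", 89)
  amplicon <- paste0(strrep("T", 20), exon267, "GC")
  cfg <- locus_config("II01", 289L, c(1L, 20L), 0L, 267L)
  out <- trim_to_orf(allele_set("II01", "a", amplicon), cfg)
  expect_equal(nchar(out$sequence), 267L)
  expect_equal(out$sequence, exon267)

  cfg14 <- locus_config("II14", 167L, NULL, 0L, 165L)
  out14 <- trim_to_orf(allele_set("II14", "a",
                                  paste0(strrep("GGA", 55), "GT")), cfg14)
  expect_equal(nchar(out14$sequence), 165L)
})

test_that("frame inference minimizes internal stops and errors on ties", {
  # "TAAGCTGA": frame 0 reads TAA|GCT (1 stop), frame 1 AAG|CTG (0 stops),
  # frame 2 AGC|TGA (1 stop) -> frame 1 is the unique stop-minimizer
  al <- allele_set("LX", "a", "TAAGCTGA")
  cfg <- locus_config("LX", 8L, NULL, "infer", 6L)
  out <- trim_to_orf(al, cfg)
  expect_equal(attr(out, "frame"), 1L)
  expect_equal(out$sequence, "AAGCTG")

  # frames 1 and 2 both stop-free: inference must refuse to guess
  tie <- allele_set("LY", "a", "TAATAATAATAA")
  cfg_tie <- locus_config("LY", 12L, NULL, "infer", 6L)
  expect_error(trim_to_orf(tie, cfg_tie), "tie")
})

test_that("translation screens stop-bearing alleles with codon position", {
  al <- allele_set("L1", c("ok", "stopped"), c("ATGGCC", "ATGTAA"))
  scr <- translate_and_screen(al)
  expect_equal(unname(scr$proteins["ok"]), "MA")
  expect_equal(scr$rejected$allele_id, "stopped")
  expect_match(scr$rejected$detail, "codon 2")

  clean <- translate_and_screen(allele_set("L1", "a", "ATGGCC"))
  expect_equal(nrow(clean$rejected), 0L)
})

test_that("protein collapse groups synonymous alleles and partitions", {
  # GCT/GCC/GCA all encode A; AAA encodes K
  al <- allele_set("L1", c("n3", "n1", "n2", "k1"),
                   c("GCAGCT", "GCTGCT", "GCCGCT", "AAAGCT"))
  prot <- collapse_to_protein(al)
  expect_length(prot, 2L)
  expect_equal(sum(lengths(prot$members)), length(al))
  aa_group <- prot$members[[which(prot$aa_sequence == "AA")]]
  expect_setequal(aa_group, c("n1", "n2", "n3"))
  # protein id from lexicographically smallest member
  expect_true("n1_p" %in% prot$protein_id)

  # collapse is invariant to input order
  perm <- c(3, 1, 4, 2)
  prot2 <- collapse_to_protein(subset_al <- allele_set(
    "L1", al$allele_id[perm], al$sequence[perm]))
  expect_equal(prot2$protein_id, prot$protein_id)
  expect_equal(prot2$members, prot$members)
})

test_that("full QC chain composes and ledgers every rejection", {
  orf <- strrep("GCT", 2)                 # 6-bp ORF
  al <- allele_set("L1", c("good1", "good2", "stopbear", "shorty"),
                   c(orf, "GCAGCC", "TAAGCT", "GCT"))
  g <- geno_df(rep(c("i1", "i2"), 3), "spA", "L1", "r1",
               rep(c("good1", "good2", "stopbear"), each = 2))
  res <- qc_alleles(al, genotype_table(g), make_cfg(6L, 6L, 0L))
  expect_setequal(res$alleles$allele_id, c("good1", "good2"))
  expect_setequal(res$rejected$reason, c("length", "stop_codon"))
  expect_length(res$proteins, 1L)  # GCT GCT and GCA GCC are both "AA"
})
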