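# Drawing pools against exhaustive double-loop oracles, Monte-Carlo
# distributions, one-tailed Z evaluation, the co-ancestry score, BH-FDR,
# and the score-distance correlation.

# two species, one identical allele each (distinct ids), 10 codons
identical_pair_alignment <- function() {
  cod <- rep("GCT", 10)
  toy_alignment(list(a1 = cod, b1 = cod),
                list(a1 = "A", b1 = "B"))
}

test_that("CE pool collects cross-species codon-identity events", {
  al <- identical_pair_alignment()
  pool <- build_ce_pool(al, "A", "B")
  expect_equal(pool$outcomes, rep(1L, 10))

  # same AA at 4 sites, codons equal at 3 of them; other sites different AA
  x <- c("GCT", "GGT", "CCT", "ACT", "AAA", "TGG")
  y <- c("GCT", "GGT", "CCT", "ACA", "CAA", "CGG")  # ACT/ACA both T (syn)
  al2 <- toy_alignment(list(a1 = x, b1 = y), list(a1 = "A", b1 = "B"))
  pool2 <- build_ce_pool(al2, "A", "B")
  expect_equal(sort(pool2$outcomes), sort(c(1L, 1L, 1L, 0L)))

  expect_error(build_ce_pool(
    toy_alignment(list(a1 = "GCT", b1 = "AAA"),
                  list(a1 = "A", b1 = "B")), "A", "B"), "empty CE pool")
})

test_that("CA pool merges within-species pairs from both species", {
  cod <- rep("GAT", 10)
  al <- toy_alignment(list(a1 = cod, a2 = cod, b1 = cod),
                      list(a1 = "A", a2 = "A", b1 = "B"))
  pool <- build_ca_pool(al, "A", "B")
  expect_equal(pool$outcomes, rep(1L, 10))  # only the one A-pair

  # synonymous difference at exactly one codon
  al2 <- toy_alignment(list(a1 = c("GCT", rep("AAA", 4)),
                            a2 = c("GCC", rep("AAA", 4)),
                            b1 = rep("TTT", 5)),
                       list(a1 = "A", a2 = "A", b1 = "B"))
  pool2 <- build_ca_pool(al2, "A", "B")
  expect_equal(sum(pool2$outcomes == 0L), 1L)
  expect_equal(length(pool2$outcomes), 5L)

  expect_error(build_ca_pool(identical_pair_alignment(), "A", "B"),
               "mono-allelic")
})

test_that("pools equal the exhaustive double-loop oracle", {
  set.seed(11)
  codons <- names(Biostrings::GENETIC_CODE)
  for (rep in 1:8) {
    nA <- sample(2:3, 1); nB <- sample(2:3, 1); nc <- sample(4:12, 1)
    n_shared <- sample(0:1, 1)
    rows <- lapply(seq_len(nA + nB - n_shared), function(i)
      sample(codons, nc, replace = TRUE))
    ids <- sprintf("al%d", seq_along(rows))
    names(rows) <- ids
    species <- c(as.list(rep("A", nA - n_shared)),
                 as.list(rep("B", nB - n_shared)),
                 rep(list(c("A", "B")), n_shared))
    names(species) <- ids
    # drop alignment rows whose species set is ill-formed (none here)
    aset <- allele_set("O", ids, vapply(rows, paste, character(1),
                                       collapse = ""))
    al <- codon_alignment(aset, species)
    codmat <- al$codons
    ra <- which(vapply(al$species, function(s) "A" %in% s, logical(1)))
    rb <- which(vapply(al$species, function(s) "B" %in% s, logical(1)))

    got_ce <- tryCatch(build_ce_pool(al, "A", "B")$outcomes,
                       error = function(e) integer(0))
    want_ce <- oracle_pool(codmat, ra, rb, seq_len(nc), within = FALSE)
    expect_equal(sort(got_ce), sort(want_ce))

    got_ca <- tryCatch(build_ca_pool(al, "A", "B")$outcomes,
                       error = function(e) integer(0))
    want_ca <- oracle_pool(codmat, ra, rb, seq_len(nc), within = TRUE)
    expect_equal(sort(got_ca), sort(want_ca))
  }
})

test_that("observed PSS identity restricts events to PSS columns", {
  al <- identical_pair_alignment()
  obs <- observed_pss_identity(al, "A", "B", c(2, 5, 9))
  expect_equal(obs$observed, 1.0)
  expect_equal(obs$k, 3L)

  # same AA everywhere at PSS but synonymous-different codons
  al2 <- toy_alignment(list(a1 = c("GCT", "GGT", "CCT"),
                            b1 = c("GCC", "GGC", "CCA")),
                       list(a1 = "A", b1 = "B"))
  obs2 <- observed_pss_identity(al2, "A", "B", 1:3)
  expect_equal(obs2$observed, 0.0)

  # mixed toy alignment vs hand enumeration: 2x1 alleles, PSS {1,3}
  al3 <- toy_alignment(list(a1 = c("GCT", "AAA", "TTT"),
                            a2 = c("GCC", "AAA", "TTC"),
                            b1 = c("GCT", "AAA", "TTA")),
                       list(a1 = "A", a2 = "A", b1 = "B"))
  # events at PSS {1,3}: (a1,b1): GCT==GCT ->1, TTT vs TTA (F vs L, no event)
  # (a2,b1): GCC vs GCT ->0, TTC vs TTA (F vs L, no event)
  obs3 <- observed_pss_identity(al3, "A", "B", c(1, 3))
  expect_equal(obs3$k, 2L)
  expect_equal(obs3$observed, 0.5)

  # no identical AA at PSS: flagged, not an error
  al4 <- toy_alignment(list(a1 = c("GCT", "AAA"), b1 = c("TGG", "CAA")),
                       list(a1 = "A", b1 = "B"))
  expect_false(observed_pss_identity(al4, "A", "B", 1:2)$evaluable)

  expect_error(observed_pss_identity(al, "A", "B", 99), "\\[1, 10\\]")
})

test_that("Monte-Carlo distributions are seeded, sized, and flagged", {
  ones <- structure(list(scenario = "CE", species = c("A", "B"),
                         outcomes = rep(1L, 10), provenance = NULL),
                    class = "outcome_pool")
  expect_warning(d <- mc_distribution(ones, 5, 100, seed = 1), "degenerate")
  expect_true(d$degenerate)
  expect_equal(d$samples, rep(1, 100))

  half <- structure(list(scenario = "CE", species = c("A", "B"),
                         outcomes = rep(c(0L, 1L), 50), provenance = NULL),
                    class = "outcome_pool")
  d2 <- mc_distribution(half, 20, 1000, seed = 2)
  expect_length(d2$samples, 1000)
  expect_true(all(d2$samples >= 0 & d2$samples <= 1))
  # per-replicate SD is sqrt(0.25/20) = 0.1118; mean within 3 SE of 0.5
  expect_lt(abs(d2$mean - 0.5), 3 * sqrt(0.25 / 20) / sqrt(1000))

  d3 <- mc_distribution(half, 20, 1000, seed = 2)
  expect_identical(d2$samples, d3$samples)
  d4 <- mc_distribution(half, 20, 1000, seed = 3)
  expect_false(identical(d2$samples, d4$samples))
})

fake_dist <- function(scenario, mean, sd, median, k) {
  structure(list(scenario = scenario, samples = numeric(0), k = k,
                 n_reps = 1000L, mean = mean, sd = sd, median = median,
                 degenerate = sd == 0, seed = 0L),
            class = "mc_distribution")
}

test_that("pair evaluation: Z-tests, tails, and the affine score", {
  ce <- fake_dist("CE", 0.40, 0.05, 0.40, 10L)
  ca <- fake_dist("CA", 0.90, 0.05, 0.90, 10L)

  r <- evaluate_pair(0.40, 10L, ce, ca)
  expect_equal(r$z_vs_CE, 0)
  expect_equal(r$p_vs_CE, 0.5)
  expect_equal(r$score, 0.0)

  r2 <- evaluate_pair(0.65, 10L, ce, ca)
  expect_equal(r2$score, 0.5)           # affine midpoint
  expect_equal(r2$p_vs_CE, pnorm((0.65 - 0.40) / 0.05, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$p_vs_CA, pnorm((0.65 - 0.90) / 0.05, lower.tail = TRUE),
               tolerance = 1e-12)

  expect_equal(evaluate_pair(0.90, 10L, ce, ca)$score, 1.0)

  # score is invariant under a common affine map of obs and the medians
  aff <- function(x) 0.2 + 0.5 * x
  ce_a <- fake_dist("CE", aff(0.40), 0.025, aff(0.40), 10L)
  ca_a <- fake_dist("CA", aff(0.90), 0.025, aff(0.90), 10L)
  expect_equal(evaluate_pair(aff(0.65), 10L, ce_a, ca_a)$score, 0.5)

  # degenerate CE null: sign-convention p
  ce_d <- fake_dist("CE", 0.40, 0, 0.40, 10L)
  expect_equal(suppressWarnings(evaluate_pair(0.9, 10L, ce_d, ca))$p_vs_CE, 0)
  expect_equal(suppressWarnings(evaluate_pair(0.1, 10L, ce_d, ca))$p_vs_CE, 1)

  # coincident medians: score undefined but flagged
  ca_same <- fake_dist("CA", 0.40, 0.05, 0.40, 10L)
  r3 <- suppressWarnings(evaluate_pair(0.5, 10L, ce, ca_same))
  expect_true(is.na(r3$score))
  expect_false(r3$score_defined)
})

test_that("BH-FDR matches the hand step-up and is monotone", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  set.seed(5)
  for (rep in 1:5) {
    p <- runif(sample(3:8, 1))
    q <- fdr_bh(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("the full pair test is reproducible and FDR-corrected per family", {
  cfg <- sim_config("CA", n_individuals = 6L, seed = 31L)
  sim <- simulate_alleles(cfg)
  al <- codon_alignment(sim$combined, sim$membership)
  f1 <- coancestry_test(al, sim$pss, n_reps = 200, seed = 5)
  f2 <- coancestry_test(al, sim$pss, n_reps = 200, seed = 5)
  expect_identical(f1$pairs, f2$pairs)
  expect_equal(nrow(f1$pairs), choose(4, 2))
  ok <- f1$pairs$evaluable
  expect_equal(f1$pairs$q_vs_CE[ok], fdr_bh(f1$pairs$p_vs_CE[ok]))
  expect_equal(f1$pairs$q_vs_CA[ok], fdr_bh(f1$pairs$p_vs_CA[ok]))
  expect_true(all(f1$pairs$q_vs_CE >= f1$pairs$p_vs_CE, na.rm = TRUE))
})

test_that("score-distance correlation matches the closed form", {
  fit <- list(pairs = data.frame(
    species_a = c("A", "A", "B"), species_b = c("B", "C", "C"),
    score = c(1, 2, 3), evaluable = TRUE, score_defined = TRUE))
  class(fit) <- "coancestry_test"
  # distances: AB = 2, AC = 5, BC = 5 under this tree
  tree <- read_species_tree(text = "((A:1,B:1):1,C:3);")
  # make scores exactly linear in distance
  fit$pairs$score <- c(2, 5, 5) * 0.5 + 1
  r <- score_distance_correlation(fit, tree)
  expect_equal(r$r, 1.0)

  fit$pairs$score <- c(1, 2, 3)
  r2 <- score_distance_correlation(fit, tree)
  x <- c(1, 2, 3); y <- c(2, 5, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2$r, r_hand)
  t_hand <- r_hand * sqrt(1 / (1 - r_hand^2))  # n - 2 = 1 df
  expect_equal(r2$p, 2 * pt(abs(t_hand), df = 1, lower.tail = FALSE))

  fit$pairs$score <- c(2, 2, 2)
  expect_false(score_distance_correlation(fit, tree)$defined)

  fit$pairs <- fit$pairs[1:2, ]
  expect_error(score_distance_correlation(fit, tree), ">= 3")
})
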