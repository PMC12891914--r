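# Descriptor matrix construction, BIC cluster-count selection,
# cross-validated PC choice, and the final DAPC fit.

test_that("descriptor matrix is site-major, 5 z-scales per PSS", {
  prots <- setNames(replicate(10, paste(
    sample(rownames(aa_zscales), 20, replace = TRUE), collapse = "")),
    sprintf("p%02d", 1:10))
  set.seed(1)
  m <- descriptor_matrix(prots, pss = c(1:5, 8:13))  # 11 PSS
  expect_equal(dim(m), c(10L, 55L))
  expect_equal(colnames(m)[1:5], paste0("site1_z", 1:5))

  # identical residues at all PSS -> identical rows
  twins <- c(a = "AAARW", b = "AAARW", cdiff = "AAAWW")
  m2 <- descriptor_matrix(twins, 1:5)
  expect_equal(unname(m2["a", ]), unname(m2["b", ]))
  expect_gt(sum((m2["a", ] - m2["cdiff", ])^2), 0)

  # single PSS, equal residue -> equal single-site block
  m3 <- descriptor_matrix(c(x = "ARN", y = "AWC"), 1)
  expect_equal(unname(m3["x", ]), unname(m3["y", ]))

  expect_error(descriptor_matrix(c(x = "AXZ"), 2), "non-standard")
})

test_that("BIC selects the simulated cluster count and is deterministic", {
  set.seed(9)
  centers <- matrix(c(rep(0, 6), rep(10, 6)), nrow = 2, byrow = TRUE)
  m <- rbind(sweep(matrix(rnorm(20 * 6), 20), 2, centers[1, ], "+"),
             sweep(matrix(rnorm(20 * 6), 20), 2, centers[2, ], "+"))
  rownames(m) <- sprintf("r%02d", 1:40)
  ks <- select_k(m, 1:6, seed = 4)
  expect_equal(ks$k, 2L)
  # WSS at the chosen k agrees with brute-force assignment to the centers
  fitted <- kmeans(prcomp(scale(m))$x, 2, nstart = 25)
  expect_lte(abs(ks$bic$wss[ks$bic$k == 2] - fitted$tot.withinss) /
               fitted$tot.withinss, 0.05)

  same <- matrix(1, nrow = 8, ncol = 10,
                 dimnames = list(sprintf("r%d", 1:8), NULL))
  expect_equal(select_k(same, 1:4, seed = 1)$k, 1L)

  ks2 <- select_k(m, 1:6, seed = 4)
  expect_identical(ks$bic, ks2$bic)
})

test_that("PC cross-validation scores held-out assignment accuracy", {
  gen <- gen_supertype_proteins(2, n_per_group = 15, mut = 0, seed = 2)
  m <- descriptor_matrix(gen$proteins, 1:10)
  xv <- xval_pcs(m, gen$truth, pc_grid = c(2, 5, 8), n_reps = 10, seed = 3)
  expect_true(all(xv$accuracy$mean_accuracy == 1))
  expect_equal(xv$n_pcs, 2L)  # smallest grid value on ties

  # random labels on structureless data: accuracy near chance
  set.seed(8)
  noise <- matrix(rnorm(60 * 10), 60)
  rownames(noise) <- sprintf("n%02d", 1:60)
  labs <- rep(1:2, each = 30)
  xr <- xval_pcs(noise, labs, pc_grid = 3, n_reps = 40, seed = 5)
  expect_lt(abs(xr$accuracy$mean_accuracy - 0.5), 0.2)

  expect_error(xval_pcs(m, c(rep(1, 29), 2), pc_grid = 2), "single member")
  xv2 <- xval_pcs(m, gen$truth, pc_grid = c(2, 5, 8), n_reps = 10, seed = 3)
  expect_identical(xv$accuracy, xv2$accuracy)
})

test_that("final fit partitions alleles with near-one-hot posteriors", {
  gen <- gen_supertype_proteins(3, n_per_group = 12, mut = 0.05, seed = 6)
  m <- descriptor_matrix(gen$proteins, 1:10)
  fit <- fit_assign(m, k = 3, n_pcs = 3, seed = 7)
  expect_setequal(unique(fit$labels), 1:3)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, nrow(m)),
               tolerance = 1e-9)
  expect_gt(mean(apply(fit$posterior, 1, max)), 0.95)
  expect_gte(agreement_upto_permutation(unname(fit$labels), gen$truth), 0.95)

  # k = 1: single label, all posteriors 1, no discriminant axes
  f1 <- fit_assign(m, k = 1, n_pcs = 2, seed = 1)
  expect_true(all(f1$labels == 1L))
  expect_true(all(f1$posterior == 1))
  expect_null(f1$lda)

  expect_error(fit_assign(m, k = 2, n_pcs = 999, seed = 1), "rank")

  # permuting input rows permutes outputs identically
  perm <- sample(nrow(m))
  fitp <- fit_assign(m[perm, ], k = 3, n_pcs = 3, seed = 7)
  expect_gte(agreement_upto_permutation(unname(fitp$labels),
                                        gen$truth[perm]), 0.95)
})

test_that("duplicating an allele row never changes another row's label", {
  gen <- gen_supertype_proteins(2, n_per_group = 10, mut = 0.05, seed = 12)
  m <- descriptor_matrix(gen$proteins, 1:10)
  base <- fit_assign(m, k = 2, n_pcs = 2, seed = 3)
  m_dup <- rbind(m, dup = m[1, ])
  rownames(m_dup)[nrow(m_dup)] <- "dup"
  with_dup <- fit_assign(m_dup, k = 2, n_pcs = 2, seed = 3)
  agree <- agreement_upto_permutation(
    unname(with_dup$labels[rownames(m)]), unname(base$labels))
  expect_equal(agree, 1.0)
  # the duplicate inherits its twin's label
  expect_equal(unname(with_dup$labels["dup"]),
               unname(with_dup$labels[rownames(m)[1]]))
})

test_that("predict reassigns training alleles to their own supertype", {
  gen <- gen_supertype_proteins(3, n_per_group = 10, mut = 0.05, seed = 31)
  m <- descriptor_matrix(gen$proteins, 1:10)
  fit <- fit_assign(m, k = 3, n_pcs = 3, seed = 2)
  pr <- predict(fit, m)
  expect_equal(unname(pr$supertype), unname(fit$labels))
  # novel member of group 1's consensus lands with its group
  novel <- descriptor_matrix(
    setNames(substr(gen$proteins[1], 1, 10), "novel"), 1:10)
  expect_equal(unname(predict(fit, novel)$supertype),
               unname(fit$labels[1]))
})

test_that("the supertype pipeline wires k and PC selection together", {
  gen <- gen_supertype_proteins(3, n_per_group = 10, mut = 0.05, seed = 21)
  st <- supertype(gen$proteins, 1:10, k_range = 1:5, xval_reps = 8,
                  seed = 9)
  expect_equal(st$model$k, 3L)
  expect_gte(agreement_upto_permutation(unname(st$model$labels), gen$truth),
             0.95)
  expect_equal(st$model$n_pcs, st$pc_selection$n_pcs)
})
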