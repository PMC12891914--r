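# Functional supertyping of protein alleles: a physiochemical descriptor
# matrix (five z-scales per PSS position), BIC-guided k selection on
# k-means clusters of principal components, cross-validated choice of the
# number of PCs, and a final discriminant analysis of principal components
# (DAPC = PCA + linear discriminant analysis on cluster labels).

#' Amino-acid z-scale descriptors
#'
#' The five extended z-scales of Sandberg et al. (1998) for the 20
#' proteinogenic amino acids: z1 (lipophilicity), z2 (steric bulk /
#' polarizability), z3 (polarity / charge), z4 and z5 (electronic effects).
#'
#' @format A 20 x 5 numeric matrix, rows named by one-letter amino-acid
#'   code, columns `z1`..`z5`.
#' @export
aa_zscales <- local({
  m <- matrix(c(
     0.24, -2.32,  0.60, -0.14,  1.30,  # A
     3.52,  2.50, -3.50,  1.99, -0.17,  # R
     3.05,  1.62,  1.04, -1.15,  1.61,  # N
     3.98,  0.93,  1.93, -2.46,  0.75,  # D
     0.84, -1.67,  3.71,  0.18, -2.65,  # C
     1.75,  0.50, -1.44, -1.34,  0.66,  # Q
     3.11,  0.26, -0.11, -3.04, -0.25,  # E
     2.05, -4.06,  0.36, -0.82, -0.38,  # G
     2.47,  1.95,  0.26,  3.90,  0.09,  # H
    -3.89, -1.73, -1.71, -0.84,  0.26,  # I
    -4.28, -1.30, -1.49, -0.72,  0.84,  # L
     2.29,  0.89, -2.49,  1.49,  0.31,  # K
    -2.85, -0.22,  0.47,  1.94, -0.98,  # M
    -4.22,  1.94,  1.06,  0.54, -0.62,  # F
    -1.66,  0.27,  1.84,  0.70,  2.00,  # P
     2.39, -1.07,  1.15, -1.39,  0.67,  # S
     0.75, -2.18, -1.12, -1.46, -0.40,  # T
    -4.36,  3.94,  0.59,  3.44, -1.59,  # W
    -2.54,  2.44,  0.43,  0.04, -1.47,  # Y
    -2.59, -2.64, -1.54, -0.85, -0.02   # V
  ), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  paste0("z", 1:5)))
  m
})

#' Physiochemical descriptor matrix at PSS
#'
#' One row per protein allele; columns are the five z-scale descriptors of
#' the amino acid at each PSS position, site-major
#' (`site<p>_z1 .. site<p>_z5`). Column centering/scaling happens
#' downstream, not here.
#'
#' @param proteins A `protein_allele_set` (see [collapse_to_protein()]), or
#'   a named character vector of amino-acid sequences.
#' @param pss Integer vector of 1-based residue positions.
#' @return Numeric matrix, `length(proteins)` x `5 * length(pss)`, rows
#'   named by protein ID.
#' @export
descriptor_matrix <- function(proteins, pss) {
  if (inherits(proteins, "protein_allele_set"))
    proteins <- stats::setNames(proteins$aa_sequence, proteins$protein_id)
  pss <- as.integer(pss)
  if (!length(pss)) stop_fmt("PSS set is empty")
  plen <- unique(nchar(proteins))
  if (any(pss < 1L | pss > min(plen)))
    stop_fmt("PSS indices must lie in [1, %d]", min(plen))
  rows <- lapply(proteins, function(p) {
    aas <- substring(p, pss, pss)
    bad <- !aas %in% rownames(aa_zscales)
    if (any(bad))
      stop_fmt("non-standard amino acid '%s' at position %d", aas[bad][1L],
               pss[bad][1L])
    as.vector(t(aa_zscales[aas, , drop = FALSE]))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(proteins)
  colnames(m) <- as.vector(t(outer(pss, colnames(aa_zscales),
                                   function(s, z) paste0("site", s, "_", z))))
  m
}

# Standardize columns; zero-variance columns are centered only.
standardize_columns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s == 0] <- 1
  scale(m, center = mu, scale = s)
}

# k-means with WSS; k = 1 handled directly, impossible k gives WSS = Inf.
kmeans_wss <- function(scores, k, n_starts, return_fit = FALSE) {
  n <- nrow(scores)
  if (k == 1L) {
    ctr <- colMeans(scores)
    wss <- sum(sweep(scores, 2, ctr)^2)
    fit <- list(cluster = rep(1L, n), centers = matrix(ctr, nrow = 1),
                tot.withinss = wss)
  } else {
    fit <- tryCatch(
      stats::kmeans(scores, centers = k, nstart = n_starts, iter.max = 100L),
      error = function(e) NULL)
    if (is.null(fit)) return(if (return_fit) NULL else Inf)
    wss <- fit$tot.withinss
  }
  if (return_fit) fit else wss
}

#' Choose the number of supertype clusters by BIC
#'
#' PCA on the standardized descriptor matrix; for each candidate k,
#' k-means (with restarts, best within-cluster sum of squares kept) on the
#' retained principal components;
#' `BIC(k) = n * ln(WSS_k / n) + k * ln(n)`. The chosen k is the value at
#' the foot of the sharp-decrease regime of the BIC curve (a Ward
#' two-group split of the successive decreases, as in the reference DAPC
#' implementation): the raw argmin over-fragments tight clusters because
#' splitting pure within-cluster noise still lowers this BIC by more than
#' `ln(n)` per extra cluster. A perfect fit (`WSS = 0`) short-circuits to
#' the smallest such k.
#'
#' @param m Descriptor matrix (see [descriptor_matrix()]).
#' @param k_range Integer candidate cluster counts (sorted internally).
#' @param pcs_for_clustering Number of PCs used for clustering, or `"all"`.
#' @param n_starts k-means restarts per k.
#' @param seed Integer seed.
#' @return List with `k` (chosen), `bic` (data frame `k`, `wss`, `bic`),
#'   `pcs_used`.
#' @export
select_k <- function(m, k_range = 1:6, pcs_for_clustering = "all",
                     n_starts = 25L, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop_fmt("k_range is empty")
  if (any(k_range < 1L) || any(k_range > nrow(m) - 1L))
    stop_fmt("k_range must lie within [1, n_alleles - 1]")
  scores <- pca_scores(m, pcs_for_clustering)
  res <- with_seed(seed, {
    t(vapply(k_range, function(k) {
      wss <- kmeans_wss(scores, k, n_starts)
      bic <- if (is.finite(wss)) {
        n <- nrow(scores)
        # log(0) guards the exact-duplicate / perfect-fit case
        n * log(max(wss, .Machine$double.xmin) / n) + k * log(n)
      } else Inf
      c(wss = wss, bic = bic)
    }, numeric(2)))
  })
  bic <- data.frame(k = k_range, wss = res[, "wss"], bic = res[, "bic"])
  list(k = choose_k_from_bic(k_range, bic$bic, bic$wss), bic = bic,
       pcs_used = ncol(scores))
}

# Elbow rule on the BIC curve: Ward-split the successive decreases into a
# "sharp" and a "flat" group and take the k ending the sharp regime.
choose_k_from_bic <- function(k_range, bic, wss) {
  if (any(wss == 0 & is.finite(bic)))
    return(k_range[which(wss == 0)[1L]])
  keep <- is.finite(bic)
  ks <- k_range[keep]; b <- bic[keep]
  if (length(ks) == 0L) stop_fmt("no candidate k admits a clustering")
  if (length(ks) <= 2L) return(ks[which.min(b)])
  d <- -diff(b)
  if (all(d <= 0)) return(ks[1L])  # BIC never improves: one cluster
  grp <- stats::cutree(stats::hclust(stats::dist(d), method = "ward.D"), 2L)
  sharp <- which(grp == grp[which.max(d)])
  ks[max(sharp) + 1L]
}

# Linear discriminant classification with a nearest-centroid fallback:
# when a retained component has zero within-group variance everywhere
# (perfectly separated clusters), lda() is degenerate and the
# nearest-centroid rule is its limit. Returns class labels and posteriors
# for `newdata`, plus the lda fit when one exists.
lda_classify <- function(train, grouping, newdata) {
  grouping <- factor(grouping)
  fit <- tryCatch(suppressWarnings(MASS::lda(train, grouping = grouping)),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    pr <- stats::predict(fit, newdata)
    return(list(class = pr$class, posterior = pr$posterior, lda = fit))
  }
  centroids <- apply(train, 2, function(col) tapply(col, grouping, mean))
  if (is.null(dim(centroids)))
    centroids <- matrix(centroids, ncol = 1,
                        dimnames = list(levels(grouping), NULL))
  d2 <- vapply(seq_len(nrow(centroids)), function(g)
    rowSums(sweep(newdata, 2, centroids[g, ])^2), numeric(nrow(newdata)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = nrow(newdata))
  cls <- factor(levels(grouping)[apply(d2, 1, which.min)],
                levels = levels(grouping))
  post <- matrix(0, nrow(newdata), nlevels(grouping),
                 dimnames = list(rownames(newdata), levels(grouping)))
  post[cbind(seq_len(nrow(post)), as.integer(cls))] <- 1
  list(class = cls, posterior = post, lda = NULL)
}

# PCA scores with a requested number of components ("all" = full rank).
pca_scores <- function(m, n_pcs) {
  p <- stats::prcomp(standardize_columns(m), center = FALSE, scale. = FALSE)
  rank <- sum(p$sdev > 1e-10)
  if (identical(n_pcs, "all")) n_pcs <- rank
  n_pcs <- as.integer(n_pcs)
  if (n_pcs > rank)
    stop_fmt("requested %d PCs but matrix rank is %d", n_pcs, rank)
  p$x[, seq_len(n_pcs), drop = FALSE]
}

#' Cross-validate the number of retained principal components
#'
#' Per replicate: a stratified train/held-out split by cluster label; PCA +
#' linear discriminant fit on the training rows; held-out rows scored by
#' whether they are assigned to their own cluster. The chosen number of PCs
#' maximizes mean held-out accuracy, smallest value on ties.
#'
#' @param m Descriptor matrix.
#' @param labels Integer cluster labels (every cluster needs >= 2 members).
#' @param pc_grid Candidate numbers of PCs.
#' @param train_fraction Fraction of each cluster used for training.
#' @param n_reps Replicates per grid value.
#' @param seed Integer seed.
#' @return List with `n_pcs` (chosen) and `accuracy` (data frame `n_pcs`,
#'   `mean_accuracy`).
#' @export
xval_pcs <- function(m, labels, pc_grid, train_fraction = 0.9,
                     n_reps = 30L, seed = 1L) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop_fmt("cluster %s has a single member; cannot cross-validate",
             names(tab)[tab < 2L][1L])
  pc_grid <- sort(unique(as.integer(pc_grid)))
  ms <- standardize_columns(m)
  acc <- with_seed(seed, {
    vapply(pc_grid, function(npc) {
      mean(vapply(seq_len(n_reps), function(rep) {
        train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
          ntr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
          sample(idx, ntr)
        }), use.names = FALSE)
        test <- setdiff(seq_along(labels), train)
        p <- stats::prcomp(ms[train, , drop = FALSE], center = TRUE,
                           scale. = FALSE)
        npc_eff <- min(npc, sum(p$sdev > 1e-10))
        tr_scores <- p$x[, seq_len(npc_eff), drop = FALSE]
        te_scores <- predict(p, ms[test, , drop = FALSE])[, seq_len(npc_eff),
                                                          drop = FALSE]
        pred <- lda_classify(tr_scores, labels[train], te_scores)$class
        mean(as.integer(as.character(pred)) == labels[test])
      }, numeric(1)))
    }, numeric(1))
  })
  accuracy <- data.frame(n_pcs = pc_grid, mean_accuracy = acc)
  list(n_pcs = pc_grid[which.max(acc)], accuracy = accuracy)
}

#' Final supertype fit: k-means labels + discriminant axes + posteriors
#'
#' k-means on the retained principal components, then a linear discriminant
#' analysis of those components on the cluster labels (DAPC). Posterior
#' assignment proportions come from the discriminant model; with `k = 1`
#' there are no discriminant axes and all posteriors are 1.
#'
#' @param m Descriptor matrix.
#' @param k Number of supertypes (from [select_k()]).
#' @param n_pcs Retained PCs (from [xval_pcs()]); must not exceed the
#'   matrix rank.
#' @param n_starts k-means restarts.
#' @param seed Integer seed.
#' @return Object of class `supertype_model`: `k`, `n_pcs`, `labels`
#'   (named integer vector, values in 1..k), `posterior` (allele x k
#'   matrix, rows sum to 1), `centroids` (cluster centers in PC space),
#'   `lda` (the discriminant fit, `NULL` if k = 1), `pca` (the PCA
#'   rotation), `seed`.
#' @export
fit_assign <- function(m, k, n_pcs, n_starts = 25L, seed = 1L) {
  mu <- colMeans(m)
  sg <- apply(m, 2, stats::sd); sg[sg == 0] <- 1
  ms <- scale(m, center = mu, scale = sg)
  p <- stats::prcomp(ms, center = FALSE, scale. = FALSE)
  rank <- sum(p$sdev > 1e-10)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs > rank)
    stop_fmt("n_pcs (%d) exceeds matrix rank (%d)", n_pcs, rank)
  scores <- p$x[, seq_len(n_pcs), drop = FALSE]
  fit <- with_seed(seed, kmeans_wss(scores, as.integer(k), n_starts,
                                    return_fit = TRUE))
  if (is.null(fit)) stop_fmt("k-means failed for k = %d", k)
  labels <- stats::setNames(as.integer(fit$cluster), rownames(m))
  if (k == 1L) {
    post <- matrix(1, nrow = nrow(m), ncol = 1,
                   dimnames = list(rownames(m), "1"))
    lda_fit <- NULL
  } else {
    cl <- lda_classify(scores, factor(labels, levels = 1:k), scores)
    lda_fit <- cl$lda
    post <- cl$posterior
    rownames(post) <- rownames(m)
  }
  structure(list(k = as.integer(k), n_pcs = n_pcs, labels = labels,
                 posterior = post, centroids = fit$centers, lda = lda_fit,
                 pca = p, center = mu, scale = sg, scores = scores,
                 seed = seed),
            class = "supertype_model")
}

#' Assign new alleles to fitted supertypes
#'
#' Projects new descriptor rows through the model's standardization and
#' retained principal components, then classifies them with the fitted
#' discriminant functions (nearest supertype centroid when the
#' discriminant is degenerate).
#'
#' @param object A `supertype_model` from [fit_assign()].
#' @param newdata Descriptor matrix with the same columns as the training
#'   matrix (see [descriptor_matrix()]).
#' @param ... Unused.
#' @return List with `supertype` (integer labels) and `posterior`.
#' @export
predict.supertype_model <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$center))
    stop_fmt("newdata has %d columns; model expects %d", ncol(newdata),
             length(object$center))
  ms <- scale(newdata, center = object$center, scale = object$scale)
  sc <- ms %*% object$pca$rotation[, seq_len(object$n_pcs), drop = FALSE]
  if (object$k == 1L)
    return(list(supertype = stats::setNames(rep(1L, nrow(newdata)),
                                            rownames(newdata)),
                posterior = matrix(1, nrow(newdata), 1,
                                   dimnames = list(rownames(newdata), "1"))))
  cl <- if (!is.null(object$lda)) {
    pr <- stats::predict(object$lda, sc)
    list(class = pr$class, posterior = pr$posterior)
  } else {
    lda_classify(object$scores, factor(object$labels, levels = 1:object$k), sc)
  }
  list(supertype = stats::setNames(as.integer(as.character(cl$class)),
                                   rownames(newdata)),
       posterior = cl$posterior)
}

#' @export
print.supertype_model <- function(x, ...) {
  cat(sprintf("Supertype model: k = %d, %d PCs, %d allele(s)\n",
              x$k, x$n_pcs, length(x$labels)))
  print(table(supertype = x$labels))
  invisible(x)
}

#' @export
summary.supertype_model <- function(object, ...) {
  cat(sprintf("Supertype model: k = %d, %d retained PCs\n", object$k,
              object$n_pcs))
  cat("Cluster sizes:\n"); print(table(object$labels))
  cat(sprintf("Mean max posterior: %.3f\n",
              mean(apply(object$posterior, 1, max))))
  invisible(object)
}

#' Full supertyping pipeline
#'
#' Descriptor matrix at PSS, BIC choice of k, cross-validated choice of the
#' number of PCs, and the final DAPC fit.
#'
#' @inheritParams descriptor_matrix
#' @param k_range Candidate cluster counts.
#' @param pc_grid Candidate numbers of retained PCs (default: up to the
#'   matrix rank, capped at 20).
#' @param n_starts k-means restarts.
#' @param xval_reps Cross-validation replicates.
#' @param seed Master seed (per-stage child seeds are derived from it).
#' @return List with `model` (a `supertype_model`), `k_selection`,
#'   `pc_selection`, and `matrix`.
#' @export
supertype <- function(proteins, pss, k_range = 1:6, pc_grid = NULL,
                      n_starts = 25L, xval_reps = 30L, seed = 1L) {
  m <- descriptor_matrix(proteins, pss)
  ks <- select_k(m, k_range, "all", n_starts, child_seed(seed, 1L))
  if (ks$k == 1L) {
    model <- fit_assign(m, 1L, 1L, n_starts, child_seed(seed, 3L))
    return(list(model = model, k_selection = ks, pc_selection = NULL,
                matrix = m))
  }
  scores <- pca_scores(m, "all")
  lab_fit <- with_seed(child_seed(seed, 2L),
                       kmeans_wss(scores, ks$k, n_starts, return_fit = TRUE))
  if (is.null(pc_grid)) pc_grid <- seq_len(min(ncol(scores), 20L))
  pcs <- if (any(table(lab_fit$cluster) < 2L)) {
    # singleton cluster: hold-out validation is undefined, keep a
    # conservative default instead of failing the whole run
    list(n_pcs = min(ncol(scores), 10L), accuracy = NULL)
  } else {
    xval_pcs(m, lab_fit$cluster, pc_grid, 0.9, xval_reps,
             child_seed(seed, 2L))
  }
  model <- fit_assign(m, ks$k, pcs$n_pcs, n_starts, child_seed(seed, 3L))
  list(model = model, k_selection = ks, pc_selection = pcs, matrix = m)
}
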