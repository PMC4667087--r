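#' @name dc-segment
#' @title Self-supervised discriminative clustering tissue segmentation
#'
#' @description The segmenter treats every in-mask voxel as a point in
#' multispectral intensity space and partitions that space into many small
#' clusters with near-uniform intensity distributions whose members carry
#' consistent tissue labels. The labels come from the data itself
#' (self-supervision): a coarse 4-group clustering is mapped to tissues by
#' its channel-wise intensity rank signature, and only the most confident
#' voxels of each group are kept as seeds. The fitted model converts
#' cluster memberships into per-voxel tissue probabilities, which is what
#' makes partial-volume (mixed-tissue) voxels recoverable.
NULL

#' Robust per-channel intensity normalization
#'
#' Subtracts the in-mask median and divides by 1.4826 x MAD per channel,
#' making features dimensionless and invariant to global intensity
#' scaling, so a single clustering configuration works across subjects.
#'
#' @param msv a `multispectral_volume`.
#' @return a `feature_matrix`: matrix `X` (one row per in-mask voxel, one
#'   column per channel), `voxel_idx` (linear grid indices), grid `dim`,
#'   `voxel_size_mm`, `channel_names`, and the `location`/`scale` used.
#' @export
normalize_channels <- function(msv) {
  stopifnot(inherits(msv, "multispectral_volume"))
  idx <- which(msv$brain_mask)
  if (length(idx) == 0L) stopf("empty brain mask")
  X <- vapply(msv$channels, function(ch) ch$data[idx], numeric(length(idx)))
  cn <- vapply(msv$channels, `[[`, "", "channel_name")
  colnames(X) <- cn
  loc <- apply(X, 2, median)
  sc <- apply(X, 2, mad)               # 1.4826 * MAD
  for (k in seq_along(sc)) {
    if (sc[k] <= 0) sc[k] <- sd(X[, k])   # piecewise-constant channel: MAD
    if (!is.finite(sc[k]) || sc[k] <= 0)  # collapses, SD still informative
      stopf("channel '%s' is constant inside the mask", cn[k])
  }
  X <- sweep(sweep(X, 2, loc, `-`), 2, sc, `/`)
  structure(list(X = X, voxel_idx = idx, dim = dim(msv$brain_mask),
                 voxel_size_mm = msv$voxel_size_mm, channel_names = cn,
                 location = loc, scale = sc),
            class = "feature_matrix")
}

#' Canonical tissue intensity rank signatures
#'
#' For each channel, the expected ordering of the four tissue classes
#' (rank 4 = brightest). Used to map anonymous intensity groups to
#' tissues without an annotator.
#'
#' @param channel_names channel labels; FLAIR/T2/MT get their known
#'   orderings, unknown names fall back to the FLAIR/T2/MT order by
#'   position.
#' @return 4 x n_channels integer matrix of ranks (rows CSF/GM/WM/LESION).
#' @export
canonical_rank_signatures <- function(channel_names = c("FLAIR", "T2", "MT")) {
  known <- cbind(FLAIR = c(CSF = 1, GM = 3, WM = 2, LESION = 4),
                 T2    = c(CSF = 4, GM = 2, WM = 1, LESION = 3),
                 MT    = c(CSF = 1, GM = 3, WM = 4, LESION = 2))
  out <- matrix(NA_integer_, 4, length(channel_names),
                dimnames = list(TISSUES, channel_names))
  fallback <- colnames(known)
  for (k in seq_along(channel_names)) {
    nm <- toupper(channel_names[k])
    if (!nm %in% colnames(known)) nm <- fallback[min(k, length(fallback))]
    out[, k] <- known[TISSUES, nm]
  }
  out
}

#' Generate self-supervised seed labels
#'
#' Coarsely clusters the features into 4 groups, maps each group to a
#' tissue by matching its channel-mean rank signature against the
#' canonical signatures (best assignment over all 24 permutations), then
#' keeps only the `confidence_fraction` of voxels nearest each group
#' center as labeled seeds — a small, high-purity labeled set.
#'
#' @param features a `feature_matrix`.
#' @param confidence_fraction fraction of voxels labeled, in (0, 0.25].
#' @param seed integer RNG seed (coarse clustering restarts).
#' @return `seed_labels`: integer `rows` into the feature matrix, factor
#'   `tissue`, the group-to-tissue `mapping`, and `confidence_fraction`.
#' @export
generate_seed_labels <- function(features, confidence_fraction = 0.1, seed = 0L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (confidence_fraction <= 0 || confidence_fraction > 0.25)
    stopf("confidence_fraction must be in (0, 0.25]")
  X <- features$X
  canon <- canonical_rank_signatures(features$channel_names)
  # Initialize each group at the componentwise median of the voxels that
  # score highest on the tissue's canonical rank contrast (all channels
  # jointly). Top fractions reflect expected prevalence: this anchors a
  # center on minority classes (lesions can be well under 1% of the
  # brain), which a variance-driven random start tends to miss.
  contrast <- sweep(canon, 2, colMeans(canon), `-`)       # 4 x channels
  score <- X %*% t(contrast)                              # n x 4
  top_frac <- c(CSF = 0.01, GM = 0.10, WM = 0.10, LESION = 0.002)
  init <- matrix(0, 4, ncol(X))
  for (t in seq_len(4)) {
    n_top <- max(20L, ceiling(top_frac[t] * nrow(X)))
    sel <- order(score[, t], decreasing = TRUE)[seq_len(n_top)]
    init[t, ] <- apply(X[sel, , drop = FALSE], 2, median)
  }
  km <- with_seed(seed, tryCatch(
    kmeans(X, centers = init, iter.max = 200, algorithm = "Lloyd"),
    error = function(e) kmeans(X, centers = 4, nstart = 8, iter.max = 200)))
  gm <- km$centers                                   # 4 x channels
  grp_rank <- apply(gm, 2, rank)                     # rank within channel

  perms <- permutations4()
  cost <- vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]                                  # group p[t] -> tissue t
    sum(abs(grp_rank[p, , drop = FALSE] - canon))
  }, numeric(1))
  best <- which.min(cost)
  if (sum(abs(cost - cost[best]) < 1e-9) > 1L)
    stopf("ambiguous tissue signature match: two group-to-tissue assignments fit equally well; consider different channels or less noise")
  p <- perms[best, ]
  tissue_of_group <- integer(4); tissue_of_group[p] <- seq_len(4)

  rows <- integer(0); labs <- integer(0)
  for (g in seq_len(4)) {
    members <- which(km$cluster == g)
    d <- rowSums(sweep(X[members, , drop = FALSE], 2, gm[g, ], `-`)^2)
    n_keep <- max(1L, floor(confidence_fraction * length(members)))
    keep <- members[order(d)[seq_len(n_keep)]]
    rows <- c(rows, keep)
    labs <- c(labs, rep(tissue_of_group[g], length(keep)))
  }
  o <- order(rows)
  structure(list(rows = rows[o],
                 tissue = factor(TISSUES[labs[o]], levels = TISSUES),
                 mapping = setNames(TISSUES[tissue_of_group], paste0("group", 1:4)),
                 confidence_fraction = confidence_fraction),
            class = "seed_labels")
}

permutations4 <- function() {
  m <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  m[apply(m, 1, function(r) length(unique(r)) == 4L), , drop = FALSE]
}

#' Fit the discriminative clustering model
#'
#' Alternating minimization of
#' `J = sum_v ||x_v - mu_c(v)||^2 + lambda * sum_(v in seeds) (1 - P(label_v | c(v)))`
#' where `P(. | c)` is the Laplace-smoothed (alpha = 1) seed-label
#' distribution of cluster c. The assignment step places each voxel in the
#' cluster minimizing its summed contribution (ties to the lowest cluster
#' index); the update step recomputes centroids and label distributions.
#' With `lambda = 0` this reduces exactly to Lloyd K-means. Initialization
#' is farthest-point seeding from a seeded RNG. The soft-assignment
#' temperature `tau` is set to the RMS distance between voxels and their
#' second-nearest centroid at convergence — the local inter-cluster
#' separation scale, which calibrates the soft memberships so that
#' partial-volume voxels lying between two tissue modes receive graded
#' (rather than near-binary) probabilities.
#'
#' @param features a `feature_matrix`.
#' @param seeds `seed_labels` (may be NULL when `lambda = 0`).
#' @param K number of clusters, >= 4; default 6 (one to two clusters per
#'   tissue keeps every cluster anchored by seed labels; raise it for
#'   strongly multimodal data).
#' @param lambda label-consistency weight >= 0; default 10 (squared
#'   distances are O(1) after robust normalization).
#' @param max_iter,tol stop when fewer than `tol` of assignments change,
#'   or after `max_iter` iterations (then a warning is issued).
#' @param seed integer RNG seed for initialization.
#' @param init optional K x n_channels matrix of initial centroids
#'   (overrides farthest-point seeding; used for oracle comparisons).
#' @return a `dc_model`: `centroids` (K x channels),
#'   `cluster_tissue_dist` (K x 4 row-stochastic), `temperature`,
#'   `lambda`, `objective_trace`, final `assignment`, convergence info.
#' @export
dc_fit <- function(features, seeds = NULL, K = 6, lambda = 10,
                   max_iter = 100, tol = 1e-4, seed = 0L, init = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  if (K < 4) stopf("K must be >= 4 (one cluster per tissue at minimum)")
  if (lambda < 0) stopf("lambda must be >= 0")
  X <- features$X
  n <- nrow(X); k <- ncol(X)
  if (lambda > 0 && is.null(seeds)) stopf("seeds required when lambda > 0")

  seed_rows <- if (is.null(seeds)) integer(0) else seeds$rows
  seed_lab <- if (is.null(seeds)) integer(0) else as.integer(seeds$tissue)
  if (!is.null(seeds) && nlevels(droplevels(seeds$tissue)) < 4)
    warnf("degenerate seed set: not every tissue has a seed")

  C <- if (is.null(init)) farthest_point_init(X, K, seed) else {
    stopifnot(nrow(init) == K, ncol(init) == k); as.matrix(init)
  }
  P <- matrix(1 / 4, K, 4, dimnames = list(NULL, TISSUES))
  x2 <- rowSums(X^2)
  assign_old <- rep(0L, n)
  trace <- numeric(0)

  for (iter in seq_len(max_iter)) {
    D <- sq_dist(X, C, x2)                     # n x K
    if (lambda > 0 && length(seed_rows) > 0) {
      pen <- lambda * (1 - P[, seed_lab, drop = FALSE])   # K x n_seeds
      D[seed_rows, ] <- D[seed_rows, ] + t(pen)
    }
    a <- max.col(-D, ties.method = "first")

    # re-seed empty clusters from the voxel farthest from its centroid
    dmin <- D[cbind(seq_len(n), a)]
    repeat {
      counts <- tabulate(a, K)
      empty <- which(counts == 0L)
      if (length(empty) == 0L) break
      far <- which.max(dmin)
      C[empty[1], ] <- X[far, ]
      a[far] <- empty[1]
      dmin[far] <- 0
      message(sprintf("dc_fit: re-seeded empty cluster %d", empty[1]))
    }

    C <- rowsum(X, a) / counts
    P <- matrix(1, K, 4, dimnames = list(NULL, TISSUES))
    if (length(seed_rows) > 0) {
      tab <- table(factor(a[seed_rows], levels = seq_len(K)),
                   factor(seed_lab, levels = 1:4))
      P <- P + unclass(tab)
    }
    P <- P / rowSums(P)

    d2 <- rowSums((X - C[a, , drop = FALSE])^2)
    J <- sum(d2)
    if (lambda > 0 && length(seed_rows) > 0)
      J <- J + lambda * sum(1 - P[cbind(a[seed_rows], seed_lab)])
    trace <- c(trace, J)

    changed <- mean(a != assign_old)
    assign_old <- a
    if (iter > 1 && changed < tol) break
  }
  converged <- iter < max_iter || changed < tol
  if (!converged)
    warnf("dc_fit did not converge in %d iterations (%.3f%% of assignments still changing); returning current model",
          max_iter, 100 * changed)

  D <- sq_dist(X, C, x2)
  D[cbind(seq_len(n), max.col(-D, ties.method = "first"))] <- Inf
  tau <- sqrt(mean(D[cbind(seq_len(n), max.col(-D, ties.method = "first"))]))
  structure(list(K = K, centroids = C, cluster_tissue_dist = P,
                 temperature = tau, lambda = lambda,
                 objective_trace = trace, assignment = a,
                 n_iter = iter, converged = converged,
                 channel_names = features$channel_names),
            class = "dc_model")
}

farthest_point_init <- function(X, K, seed) {
  n <- nrow(X)
  with_seed(seed, {
    first <- sample.int(n, 1)
    C <- matrix(NA_real_, K, ncol(X))
    C[1, ] <- X[first, ]
    dmin <- rowSums(sweep(X, 2, C[1, ], `-`)^2)
    for (j in seq_len(K - 1)) {
      nxt <- which.max(dmin)
      C[j + 1, ] <- X[nxt, ]
      dmin <- pmin(dmin, rowSums(sweep(X, 2, C[j + 1, ], `-`)^2))
    }
    C
  })
}

# squared Euclidean distances voxels x centroids, clamped at 0
sq_dist <- function(X, C, x2 = rowSums(X^2)) {
  D <- outer(x2, rowSums(C^2), `+`) - 2 * X %*% t(C)
  D[D < 0] <- 0
  D
}

#' @export
print.dc_model <- function(x, ...) {
  cat(sprintf("Discriminative clustering model: K = %d, lambda = %g, tau = %.3f\n",
              x$K, x$lambda, x$temperature))
  cat(sprintf("  converged: %s after %d iterations; objective %.4g -> %.4g\n",
              x$converged, x$n_iter,
              x$objective_trace[1], tail(x$objective_trace, 1)))
  invisible(x)
}

#' Per-voxel tissue membership probabilities
#'
#' Gaussian-kernel cluster responsibilities
#' `P(c | x) ~ exp(-||x - mu_c||^2 / (2 tau^2))` mixed through the
#' cluster label distributions: `P(t | x) = sum_c P(t | c) P(c | x)`.
#' This is the step that turns the hard clustering into the per-voxel
#' probability of membership in every tissue class, from which partial
#' lesion volumes are estimated.
#'
#' @param model a `dc_model`.
#' @param features a `feature_matrix` on the same channels.
#' @return a `tissue_prob_map`: matrix `prob` (voxels x 4, rows sum to
#'   1), plus `voxel_idx`, grid `dim`, `voxel_size_mm`.
#' @export
tissue_probabilities <- function(model, features) {
  stopifnot(inherits(model, "dc_model"), inherits(features, "feature_matrix"))
  if (!is.finite(model$temperature) || model$temperature <= 0)
    stopf("temperature tau must be positive")
  D <- sq_dist(features$X, model$centroids)
  E <- exp(-(D - apply(D, 1, min)) / (2 * model$temperature^2))
  R <- E / rowSums(E)
  prob <- R %*% model$cluster_tissue_dist
  prob <- prob / rowSums(prob)
  colnames(prob) <- TISSUES
  structure(list(prob = prob, voxel_idx = features$voxel_idx,
                 dim = features$dim, voxel_size_mm = features$voxel_size_mm),
            class = "tissue_prob_map")
}

#' @rdname tissue_probabilities
#' @param object a `dc_model`.
#' @param newdata a `feature_matrix`.
#' @param ... unused.
#' @export
predict.dc_model <- function(object, newdata, ...) {
  tissue_probabilities(object, newdata)
}

#' Full grid array of one tissue's probability
#'
#' @param tpm a `tissue_prob_map`.
#' @param tissue one of CSF, GM, WM, LESION.
#' @return 3-D array (0 outside the mask).
#' @export
tissue_prob_array <- function(tpm, tissue) {
  stopifnot(inherits(tpm, "tissue_prob_map"), tissue %in% TISSUES)
  a <- array(0, tpm$dim)
  a[tpm$voxel_idx] <- tpm$prob[, tissue]
  a
}

#' Purity of seed labels against phantom truth
#'
#' Fraction of seed voxels whose labeled tissue has true fraction at or
#' above a cutoff in the phantom ground truth.
#'
#' @param seeds `seed_labels`.
#' @param features the `feature_matrix` the seeds index into.
#' @param fraction_maps named list of true tissue fraction arrays.
#' @param cutoff minimum true fraction counted as correct (default 0.5).
#' @return purity in `[0, 1]`.
#' @export
seed_purity <- function(seeds, features, fraction_maps, cutoff = 0.5) {
  idx <- features$voxel_idx[seeds$rows]
  truth <- vapply(seq_along(idx), function(i)
    fraction_maps[[as.character(seeds$tissue[i])]][idx[i]], numeric(1))
  mean(truth >= cutoff)
}
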