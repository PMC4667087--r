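test_that("robust normalization centers, scales, and is scale-equivariant", {
  ph <- small_phantom()
  msv <- ph$visits[[1]]
  feats <- normalize_channels(msv)
  med <- apply(feats$X, 2, median)
  scl <- apply(feats$X, 2, mad)
  expect_true(all(abs(med) < 0.05))
  expect_true(all(abs(scl - 1) < 0.05))
  expect_false(any(!is.finite(feats$X)))

  scaled <- msv
  for (k in 1:3) scaled$channels[[k]]$data <- 3.7 * scaled$channels[[k]]$data
  expect_equal(normalize_channels(scaled)$X, feats$X, tolerance = 1e-12)

  const <- msv
  const$channels[[2]]$data[] <- 42
  expect_error(normalize_channels(const), "T2.*constant")
})

test_that("self-supervised seeds are pure, small, and deterministic", {
  seg <- small_segmentation()
  ph <- small_phantom()
  expect_identical(unname(sort(seg$seeds$mapping)), sort(wmlstager:::TISSUES))
  expect_lte(length(seg$seeds$rows), 0.25 * nrow(seg$feats$X))
  expect_gte(seed_purity(seg$seeds, seg$feats, ph$truth$fraction_maps[[1]]),
             0.95)
  again <- generate_seed_labels(seg$feats, 0.1, seed = 1)
  expect_identical(again$rows, seg$seeds$rows)
  expect_identical(again$tissue, seg$seeds$tissue)
  expect_error(generate_seed_labels(seg$feats, 0.4), "confidence_fraction")
})

test_that("noiseless phantom yields perfectly pure seeds", {
  ph0 <- noiseless_phantom()
  feats <- normalize_channels(ph0$visits[[1]])
  seeds <- generate_seed_labels(feats, 0.1, seed = 1)
  expect_equal(seed_purity(seeds, feats, ph0$truth$fraction_maps[[1]],
                           cutoff = 0.99), 1)
})

test_that("label penalty zero reduces to Lloyd K-means", {
  seg <- small_segmentation()
  set.seed(3)
  sub <- seg$feats$X[sample(nrow(seg$feats$X), 500), ]
  fsub <- seg$feats; fsub$X <- sub; fsub$voxel_idx <- seq_len(500)
  init <- wmlstager:::farthest_point_init(sub, 5, seed = 4)
  fit <- dc_fit(fsub, seeds = NULL, K = 5, lambda = 0, max_iter = 200,
                tol = 1e-12, init = init)
  km <- kmeans(sub, centers = init, iter.max = 200, algorithm = "Lloyd")
  expect_lt(max(abs(fit$centroids - km$centers)), 1e-6)
})

test_that("well-separated labelled blobs are clustered with full purity", {
  set.seed(5)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 10))
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(150, 0, 0.3), 50, 3), 2, centers[i, ], `+`)))
  feats <- structure(list(X = X, voxel_idx = seq_len(200),
                          dim = c(200L, 1L, 1L), voxel_size_mm = c(1, 1, 1),
                          channel_names = c("FLAIR", "T2", "MT")),
                     class = "feature_matrix")
  seeds <- structure(list(rows = seq(1, 200, by = 5),
                          tissue = factor(wmlstager:::TISSUES[rep(1:4, each = 10)],
                                          levels = wmlstager:::TISSUES),
                          confidence_fraction = 0.2), class = "seed_labels")
  fit <- suppressMessages(dc_fit(feats, seeds, K = 4, lambda = 10, seed = 1))
  lab <- apply(fit$cluster_tissue_dist, 1, which.max)[fit$assignment]
  truth <- rep(1:4, each = 50)
  expect_equal(mean(lab == truth), 1)
})

test_that("the objective trace never increases", {
  seg <- small_segmentation()
  tr <- seg$model$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
  fit0 <- dc_fit(seg$feats, seeds = NULL, K = 5, lambda = 0, seed = 9)
  tr0 <- fit0$objective_trace
  expect_true(all(diff(tr0) <= 1e-8 * abs(tr0[-length(tr0)])))
})

test_that("stronger label penalties never reduce seed-label consistency", {
  seg <- small_segmentation()
  purity <- vapply(c(0, 1, 10), function(lam) {
    fit <- suppressMessages(dc_fit(seg$feats, seg$seeds, K = 6, lambda = lam,
                                   seed = 2))
    lab <- apply(fit$cluster_tissue_dist, 1, which.max)[fit$assignment]
    mean(lab[seg$seeds$rows] == as.integer(seg$seeds$tissue))
  }, numeric(1))
  expect_true(all(diff(purity) >= -1e-9))
})

test_that("soft memberships behave like a Gaussian kernel mixture", {
  model <- structure(list(K = 2,
                          centroids = rbind(c(0, 0, 0), c(100, 0, 0)),
                          cluster_tissue_dist = rbind(c(0, 0, 0, 1),
                                                      c(1, 0, 0, 0)),
                          temperature = 1, lambda = 10,
                          objective_trace = 1, assignment = 1L,
                          n_iter = 1, converged = TRUE,
                          channel_names = c("FLAIR", "T2", "MT")),
                     class = "dc_model")
  feats <- structure(list(X = rbind(c(0, 0, 0), c(50, 0, 0)),
                          voxel_idx = 1:2, dim = c(2L, 1L, 1L),
                          voxel_size_mm = c(1, 1, 1),
                          channel_names = c("FLAIR", "T2", "MT")),
                     class = "feature_matrix")
  tpm <- tissue_probabilities(model, feats)
  expect_gte(tpm$prob[1, "LESION"], 0.99)          # at an isolated centroid
  expect_equal(unname(tpm$prob[2, "LESION"]), 0.5) # equidistant symmetry
  expect_equal(unname(tpm$prob[2, "CSF"]), 0.5)
  expect_equal(unname(rowSums(tpm$prob)), c(1, 1))
  bad <- model; bad$temperature <- 0
  expect_error(tissue_probabilities(bad, feats), "temperature")
  expect_equal(predict(model, feats)$prob, tpm$prob)
})

test_that("full segmentation is reproducible given config and seeds", {
  seg <- small_segmentation()
  again <- suppressMessages(dc_fit(seg$feats,
                                   generate_seed_labels(seg$feats, 0.1, seed = 1),
                                   seed = 2))
  expect_identical(again$centroids, seg$model$centroids)
  expect_identical(tissue_probabilities(again, seg$feats)$prob, seg$tpm$prob)
})
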