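# Shared fixtures, built once per test run and cached.
.fixtures <- new.env()

small_phantom <- function() {
  if (is.null(.fixtures$ph)) {
    cfg <- phantom_config(grid_shape = c(48, 48, 16),
                          voxel_size_mm = c(4, 4, 7.5), rng_seed = 42)
    .fixtures$ph <- suppressWarnings(generate_longitudinal_phantom(cfg))
  }
  .fixtures$ph
}

small_segmentation <- function() {
  if (is.null(.fixtures$seg)) {
    ph <- small_phantom()
    feats <- normalize_channels(ph$visits[[1]])
    seeds <- generate_seed_labels(feats, 0.1, seed = 1)
    model <- suppressMessages(dc_fit(feats, seeds, seed = 2))
    .fixtures$seg <- list(feats = feats, seeds = seeds, model = model,
                          tpm = tissue_probabilities(model, feats))
  }
  .fixtures$seg
}

noiseless_phantom <- function() {
  if (is.null(.fixtures$ph0)) {
    cfg <- phantom_config(grid_shape = c(48, 48, 16),
                          voxel_size_mm = c(4, 4, 7.5), noise_sigma = 0,
                          bias_field_amplitude = 0, rng_seed = 42)
    .fixtures$ph0 <- suppressWarnings(generate_longitudinal_phantom(cfg))
  }
  .fixtures$ph0
}

# hand-built probability map on a tiny grid
make_tpm <- function(p, voxel_size_mm = c(2, 2, 6)) {
  p <- matrix(p, ncol = 4, byrow = FALSE)
  colnames(p) <- c("CSF", "GM", "WM", "LESION")
  n <- nrow(p)
  dm <- c(n, 1L, 1L)
  structure(list(prob = p, voxel_idx = seq_len(n), dim = dm,
                 voxel_size_mm = voxel_size_mm),
            class = "tissue_prob_map")
}

make_catmap <- function(categories, voxel_size_mm = c(2, 2, 6)) {
  n <- length(categories)
  structure(list(category = factor(categories,
                                   levels = c("NONE", "DC33", "DC66", "DC100")),
                 voxel_idx = seq_len(n), dim = c(n, 1L, 1L),
                 voxel_size_mm = voxel_size_mm,
                 thresholds = c(t_high = 2/3, t_small = 1/3)),
            class = "lesion_category_map")
}

# balanced complete multivariate-normal cohort for covariance checks
balanced_mvn_cohort <- function(n = 40, Sigma = default_residual_cov(4),
                                means = c(0, -0.2, -0.5, -0.9), seed = 1) {
  m <- length(means)
  set.seed(seed)
  Y <- matrix(rnorm(n * m), n, m) %*% chol(Sigma) +
    matrix(rep(means, each = n), n, m)
  list(Y = Y,
       df = data.frame(subject_id = rep(seq_len(n), each = m),
                       visit_year = rep(seq_len(m) - 1, n),
                       y = as.vector(t(Y))))
}
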