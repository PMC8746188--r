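# shared fixtures: everything is generated in code, no stored data

# 30-ROI demo parcellation (6 dorsal-left + 12 ventral per hemisphere)
demo_parcellation <- function() make_parcellation(6, 12)

demo_cohort_config <- function(n_subjects = 97, truth = ground_truth(),
                               avc_baseline = 8.5, n_timepoints = 427) {
  cohort_config(n_subjects = n_subjects, n_dorsal_left = 6,
                n_ventral_per_hemi = 12, n_timepoints = n_timepoints,
                truth = truth, avc_baseline = avc_baseline)
}

# tiny fast cohort for structural/io tests
tiny_cohort <- function(n_subjects = 6, seed = 1, n_timepoints = 60) {
  generate_cohort(cohort_config(n_subjects = n_subjects, n_dorsal_left = 2,
                                n_ventral_per_hemi = 3,
                                n_timepoints = n_timepoints), seed = seed)
}

# mediation-null construction: behavior driven by a structural edge, each
# subject's functional connectome an affine function of the structural one
# plus independent noise, so FC carries no information beyond SC
mediated_cohort <- function(n_subjects, seed, sc_edge = c(7, 10),
                            beta_sc = 0.02) {
  tt <- ground_truth(planted_sc_edges = data.frame(i = sc_edge[1],
                                                   j = sc_edge[2],
                                                   beta = beta_sc))
  coh <- generate_cohort(demo_cohort_config(n_subjects, truth = tt,
                                            avc_baseline = 6), seed = seed)
  smax <- max(vapply(coh$subjects, function(s) max(s$structural), numeric(1)))
  set.seed(seed + 31L)
  R <- n_rois(coh$parcellation)
  for (si in seq_along(coh$subjects)) {
    S <- coh$subjects[[si]]$structural
    noise <- matrix(stats::rnorm(R * R, sd = 0.02), R, R)
    noise <- (noise + t(noise)) / 2
    fc <- pmin(pmax(0.8 * S / smax + noise, -1), 1)
    diag(fc) <- 1
    coh$subjects[[si]]$fc <- fc
    coh$subjects[[si]]$roi_timecourses <- NULL
  }
  coh
}

# independent oracle: feature t statistic from a full lm() fit
lm_feature_t <- function(y, feature, covariates = NULL) {
  df <- data.frame(y = y, feature = feature)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    df <- cbind(df, covariates)
  }
  fit <- stats::lm(y ~ ., data = df)
  summary(fit)$coefficients["feature", c("t value", "Pr(>|t|)")]
}

# independent oracle: residuals from an explicit normal-equations solve
normal_eq_residuals <- function(y, X) {
  X <- cbind(1, X)
  beta <- solve(crossprod(X), crossprod(X, y))
  drop(y - X %*% beta)
}

# FFT amplitude of a sinusoid at frequency f in a sampled series
fft_amplitude <- function(x, f, tr) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  k <- which.min(abs(freqs - f))
  2 * Mod(stats::fft(x)[k]) / n
}

# digital ball mask of given radius (voxels) centred in a cube
ball_mask <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  idx <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  d2 <- (idx$x - ctr)^2 + (idx$y - ctr)^2 + (idx$z - ctr)^2
  array(d2 <= radius^2, dim = c(n, n, n))
}
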