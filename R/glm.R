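#' Residualize a variable on covariates
#'
#' Least-squares residuals of `y` after regression on `X` plus an intercept
#' (always appended). Collinear designs are handled by an SVD projection.
#'
#' @param y Numeric vector (or matrix, column-wise).
#' @param X Covariate matrix/vector over the same observations, or `NULL`
#'   for intercept-only (mean-centering).
#' @return Residuals with the same shape as `y`: mean ~ 0 and orthogonal to
#'   every column of `X`.
#' @export
residualize <- function(y, X = NULL) {
  ym <- as.matrix(y)
  design <- matrix(1, nrow(ym), 1)
  if (!is.null(X) && length(X) > 0) {
    X <- as.matrix(X)
    if (nrow(X) != nrow(ym)) stop("`X` rows must match length of `y`")
    design <- cbind(design, X)
  }
  out <- project_residuals(ym, design)
  if (is.null(dim(y))) drop(out) else out
}

#' Convert a t statistic to a z score
#'
#' Probability-preserving map `z = qnorm(pt(t, dof))`, evaluated on the log
#' scale so extreme tails keep full precision. Sign is preserved; for large
#' `dof` the map approaches the identity.
#'
#' @param t Numeric t statistic(s).
#' @param dof Degrees of freedom (>= 1).
#' @return Signed z score(s).
#' @export
t_to_z <- function(t, dof) {
  if (any(!is.finite(t))) stop("non-finite t statistic")
  if (any(dof < 1)) stop("`dof` must be >= 1")
  z <- numeric(length(t))
  neg <- t < 0
  if (any(neg)) {
    z[neg] <- stats::qnorm(stats::pt(t[neg], dof, log.p = TRUE), log.p = TRUE)
  }
  if (any(!neg)) {
    z[!neg] <- -stats::qnorm(
      stats::pt(t[!neg], dof, lower.tail = FALSE, log.p = TRUE),
      lower.tail = TRUE, log.p = TRUE)
  }
  if (length(dim(t))) dim(z) <- dim(t)
  z
}

#' Single-feature GLM statistic
#'
#' Ordinary least squares of `y` on `[intercept | feature | covariates]`.
#' The feature coefficient's t statistic (dof = n - 2 - #covariates) is
#' computed via the Frisch-Waugh-Lovell partial-correlation identity and
#' converted to a signed z score.
#'
#' @param y Response vector.
#' @param feature Feature vector.
#' @param covariates Optional covariate matrix/vector.
#' @return List with `t`, `z`, `p` (two-sided, uncorrected), `dof`, and
#'   `undefined` (TRUE for a zero-variance feature, in which case the
#'   statistics are `NA`).
#' @export
glm_feature_z <- function(y, feature, covariates = NULL) {
  n <- length(y)
  if (length(feature) != n) stop("`y` and `feature` lengths differ")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  dof <- n - 2L - k
  if (dof < 1 || n < (2 + k) + 3) {
    stop("insufficient subjects for the number of regressors")
  }
  ry <- residualize(y, covariates)
  rf <- residualize(feature, covariates)
  sf <- sqrt(sum(rf^2))
  if (sf <= 1e-10 * max(sqrt(sum(feature^2)), 1)) {
    return(list(t = NA_real_, z = NA_real_, p = NA_real_, dof = dof,
                undefined = TRUE))
  }
  r <- sum(ry * rf) / (sqrt(sum(ry^2)) * sf)
  r <- max(min(r, 1), -1)
  t <- r * sqrt(dof / max(1 - r^2, .Machine$double.eps))
  z <- t_to_z(t, dof)
  p <- 2 * stats::pt(-abs(t), dof)
  list(t = t, z = z, p = p, dof = dof, undefined = FALSE)
}

#' Permutation settings for familywise error control
#'
#' @param n_perm Number of permutations (study default 5000).
#' @param alpha Familywise error level.
#' @param seed Integer seed; permutation indices are pre-generated from it,
#'   so results are reproducible and order-independent.
#' @param sidedness "two_sided" (max |z|), "one_sided_pos" or
#'   "one_sided_neg".
#' @param scheme "freedman_lane" (permute covariate-residualized responses;
#'   the accepted scheme in the presence of nuisance covariates) or "raw_y".
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(n_perm = 5000, alpha = 0.05, seed = 1,
                               sidedness = c("two_sided", "one_sided_pos",
                                             "one_sided_neg"),
                               scheme = c("freedman_lane", "raw_y")) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed),
                 sidedness = match.arg(sidedness),
                 scheme = match.arg(scheme)),
            class = "permutation_config")
}

#' Mass-univariate GLM with max-statistic permutation FWE threshold
#'
#' Fits `y ~ intercept + feature + covariates` independently for every
#' feature (column of `features`), converts each feature t statistic to a
#' z score, and calibrates a familywise threshold as the empirical
#' `1 - alpha` quantile of the permutation distribution of the maximum
#' statistic (max |z| when two-sided). Under the default Freedman-Lane
#' scheme the covariate-residualized response is permuted and
#' re-residualized each round, which keeps nuisance structure out of the
#' null distribution.
#'
#' @param y Response vector over subjects.
#' @param features subjects x features numeric matrix.
#' @param covariates Optional covariate matrix/vector.
#' @param cfg A [permutation_config()].
#' @return A `glm_result` list: `feature_ids`, `z`, `t`, `p_uncorrected`,
#'   `p_fwe`, `fwe_threshold`, `survivors`, `undefined` (zero-variance
#'   flags), `dof`, `max_dist` and provenance (`n_perm`, `alpha`, `seed`,
#'   `sidedness`, `scheme`).
#' @export
permutation_fwe <- function(y, features, covariates = NULL,
                            cfg = permutation_config()) {
  features <- as.matrix(features)
  n <- length(y)
  if (nrow(features) != n) stop("`features` rows must match length of `y`")
  if (cfg$n_perm < 1 / cfg$alpha) {
    warning(sprintf(
      "n_perm = %d is small for alpha = %g (threshold resolution limited)",
      cfg$n_perm, cfg$alpha))
  }
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  dof <- n - 2L - k
  if (dof < 1) stop("insufficient subjects for the number of regressors")

  design <- matrix(1, n, 1)
  if (k > 0) design <- cbind(design, as.matrix(covariates))
  s <- svd(design)
  keep <- s$d > max(dim(design)) * .Machine$double.eps * s$d[1]
  U <- s$u[, keep, drop = FALSE]
  resid_on <- function(v) v - U %*% crossprod(U, v)

  RF <- resid_on(features)
  fnorm <- sqrt(colSums(RF^2))
  undefined <- fnorm <= 1e-10 * pmax(sqrt(colSums(features^2)), 1)
  RFs <- RF
  RFs[, !undefined] <- sweep(RF[, !undefined, drop = FALSE], 2,
                             fnorm[!undefined], `/`)
  RFs[, undefined] <- 0

  ry <- drop(resid_on(matrix(y, ncol = 1)))
  r_of <- function(v) {
    # v: residualized response; returns per-feature partial correlation
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(rep(0, ncol(RFs)))
    drop(crossprod(RFs, v)) / nv
  }
  r_to_t <- function(r) {
    r <- pmax(pmin(r, 1), -1)
    r * sqrt(dof / pmax(1 - r^2, .Machine$double.eps))
  }

  r_obs <- r_of(ry)
  t_obs <- r_to_t(r_obs)
  z_obs <- t_to_z(ifelse(undefined, 0, t_obs), dof)
  z_obs[undefined] <- NA_real_
  t_obs[undefined] <- NA_real_
  p_unc <- 2 * stats::pt(-abs(t_obs), dof)

  stat_of <- function(z) {
    switch(cfg$sidedness,
           two_sided = abs(z),
           one_sided_pos = z,
           one_sided_neg = -z)
  }

  perms <- with_seed(cfg$seed, {
    replicate(cfg$n_perm, sample.int(n))
  })
  # z is monotone in r at fixed dof, so only the per-permutation extreme
  # correlation needs the t -> z conversion
  max_dist <- numeric(cfg$n_perm)
  base <- if (cfg$scheme == "freedman_lane") ry else y
  any_def <- any(!undefined)
  for (b in seq_len(cfg$n_perm)) {
    yb <- base[perms[, b]]
    vb <- drop(resid_on(matrix(yb, ncol = 1)))
    rb <- r_of(vb)[!undefined]
    if (!any_def) { max_dist[b] <- -Inf; next }
    max_dist[b] <- switch(cfg$sidedness,
      two_sided = t_to_z(r_to_t(max(abs(rb))), dof),
      one_sided_pos = t_to_z(r_to_t(max(rb)), dof),
      one_sided_neg = -t_to_z(r_to_t(min(rb)), dof))
  }

  ord <- sort(max_dist)
  idx <- ceiling((1 - cfg$alpha) * cfg$n_perm)
  fwe_threshold <- ord[max(idx, 1L)]

  stat_obs <- stat_of(z_obs)
  survivors <- !undefined & !is.na(stat_obs) & stat_obs > fwe_threshold
  p_fwe <- vapply(stat_obs, function(s) {
    if (is.na(s)) return(NA_real_)
    (1 + sum(max_dist >= s)) / (cfg$n_perm + 1)
  }, numeric(1))

  ids <- colnames(features)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(features)))
  structure(list(
    feature_ids = ids, z = z_obs, t = t_obs, p_uncorrected = p_unc,
    p_fwe = p_fwe, fwe_threshold = fwe_threshold, survivors = survivors,
    undefined = undefined, dof = dof, max_dist = max_dist,
    n_perm = cfg$n_perm, alpha = cfg$alpha, seed = cfg$seed,
    sidedness = cfg$sidedness, scheme = cfg$scheme
  ), class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf(
    "GLM permutation result: %d features, %d undefined, FWE |z| threshold %.3f (alpha %.3g, %d perms, %s, %s)\n",
    length(x$z), sum(x$undefined), x$fwe_threshold, x$alpha, x$n_perm,
    x$sidedness, x$scheme))
  cat(sprintf("survivors: %d\n", sum(x$survivors)))
  invisible(x)
}
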