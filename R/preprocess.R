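#' Voxel time-series container
#'
#' @param data voxels x time numeric matrix (voxels in column-major order of
#'   `grid_shape`), or a 4-D array (x, y, z, time).
#' @param tr Sampling interval in seconds.
#' @param grid_shape Length-3 integer vector; inferred when `data` is 4-D.
#' @return A `voxel_ts` list with fields `data`, `tr`, `grid_shape`.
#' @export
voxel_ts <- function(data, tr, grid_shape = NULL) {
  if (length(dim(data)) == 4) {
    grid_shape <- dim(data)[1:3]
    data <- matrix(data, prod(grid_shape), dim(data)[4])
  }
  if (is.null(grid_shape)) stop("`grid_shape` required for matrix input")
  if (!is.matrix(data) || nrow(data) != prod(grid_shape)) {
    stop("`data` must be a voxels x time matrix matching `grid_shape`")
  }
  if (ncol(data) < 2) stop("need at least 2 time points")
  if (tr <= 0) stop("`tr` must be > 0")
  structure(list(data = data, tr = tr, grid_shape = as.integer(grid_shape)),
            class = "voxel_ts")
}

#' Nuisance regressor set for BOLD detrending
#'
#' Bundles the standard rsfMRI nuisance design: six motion parameters, mean
#' white-matter and CSF signals, and linear/quadratic/cubic polynomial
#' trends (generated internally from the time dimension).
#'
#' @param n_time Number of time points.
#' @param motion Optional n_time x 6 matrix of motion parameters.
#' @param wm_mean,csf_mean Optional length-`n_time` mean tissue signals.
#' @return A `nuisance_regressors` object: a design matrix (without
#'   intercept) with named columns.
#' @export
nuisance_regressors <- function(n_time, motion = NULL, wm_mean = NULL,
                                csf_mean = NULL) {
  tt <- seq_len(n_time) / n_time
  poly <- cbind(linear = tt, quadratic = tt^2, cubic = tt^3)
  X <- poly
  add <- function(X, cols, prefix) {
    if (is.null(cols)) return(X)
    cols <- as.matrix(cols)
    if (nrow(cols) != n_time) {
      stop(sprintf("`%s` must have %d rows", prefix, n_time))
    }
    colnames(cols) <- paste0(prefix, seq_len(ncol(cols)))
    cbind(X, cols)
  }
  X <- add(X, motion, "motion")
  X <- add(X, wm_mean, "wm")
  X <- add(X, csf_mean, "csf")
  structure(X, class = c("nuisance_regressors", class(X)))
}

#' Remove nuisance signal from time courses
#'
#' Least-squares projection of every series onto the intercept plus the
#' nuisance columns; returns the residuals. Rank-deficient designs are
#' handled by an SVD pseudoinverse.
#'
#' @param ts time x series numeric matrix (or vector).
#' @param regressors A [nuisance_regressors()] matrix or any time x k design
#'   (intercept appended internally).
#' @return Residual array, same shape as `ts`.
#' @export
detrend_timecourses <- function(ts, regressors) {
  x <- as.matrix(ts)
  X <- as.matrix(regressors)
  if (nrow(X) != nrow(x)) stop("regressor length does not match time dimension")
  out <- project_residuals(x, cbind(1, X))
  if (is.null(dim(ts))) drop(out) else out
}

# residuals of each column of y on the column space of X (SVD projection,
# tolerant to rank deficiency)
project_residuals <- function(y, X) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
  U <- s$u[, keep, drop = FALSE]
  y - U %*% crossprod(U, y)
}

# ---- Butterworth band-pass (zero-phase) ------------------------------------

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  p <- 1
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

# digital Butterworth band-pass coefficients via analog prototype,
# LP->BP transform and bilinear transform
butter_bandpass <- function(low_hz, high_hz, fs, order = 4) {
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # LP -> BP: each prototype pole maps to a conjugate-free pair
  half <- bw * proto / 2
  poles_a <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  fs2 <- 2 * fs
  poles_d <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_d <- c(rep(1, order), rep(-1, order))
  a <- Re(poly_from_roots(poles_d))
  b <- Re(poly_from_roots(zeros_d))
  # unit gain at the geometric band center
  wc <- 2 * pi * sqrt(low_hz * high_hz) / fs
  ew <- exp(-1i * wc * (seq_along(b) - 1))
  gain <- abs(sum(b * ew) / sum(a * ew))
  list(b = b / gain, a = a)
}

# steady-state initial conditions for a step input (direct form II transposed)
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  A <- t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

# direct form II transposed filter over the rows of x (time x series),
# vectorized across series
df2t_filter <- function(b, a, x, zi = NULL) {
  n <- length(b)
  TT <- nrow(x)
  K <- ncol(x)
  z <- if (is.null(zi)) matrix(0, n - 1, K) else zi
  y <- matrix(0, TT, K)
  for (t in seq_len(TT)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2) {
      z[1:(n - 2), ] <- b[2:(n - 1)] %o% xt + z[2:(n - 1), , drop = FALSE] -
        a[2:(n - 1)] %o% yt
    }
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# zero-phase filtering: forward-backward pass with odd-reflection padding
filtfilt_mat <- function(b, a, x, padlen = NULL) {
  TT <- nrow(x)
  if (is.null(padlen)) padlen <- min(3 * (length(a) - 1) * 4, TT - 1)
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(padlen + 1, 2), , drop = FALSE]
  bot <- 2 * matrix(x[TT, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(TT - 1, TT - padlen), , drop = FALSE]
  ext <- rbind(top, x, bot)
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, ext, zi = zi %o% ext[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- df2t_filter(b, a, y, zi = zi %o% y[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y[seq(padlen + 1, padlen + TT), , drop = FALSE]
}

#' Band-pass filter BOLD time courses
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The
#' default 0.01-0.1 Hz band isolates the low-frequency fluctuations used for
#' resting-state functional connectivity.
#'
#' @param ts time x series matrix (or vector).
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param tr Sampling interval in seconds.
#' @param order Butterworth prototype order.
#' @return Filtered array, same shape as `ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1, tr, order = 4) {
  if (missing(tr) || tr <= 0) stop("`tr` must be supplied and > 0")
  nyq <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq) {
    stop(sprintf("`high_hz` (%g) must be below Nyquist (%g Hz)", high_hz, nyq))
  }
  x <- as.matrix(ts)
  co <- butter_bandpass(low_hz, high_hz, fs = 1 / tr, order = order)
  out <- filtfilt_mat(co$b, co$a, x)
  if (is.null(dim(ts))) drop(out) else out
}

# ---- lesion masks ----------------------------------------------------------

# zero-padded 1-D convolution along the given axis of a 3-D array
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, dim(a)[1], prod(dim(a)[2:3]))
  r <- (length(kernel) - 1) / 2
  pad <- matrix(0, r, ncol(m))
  f <- stats::filter(rbind(pad, m, pad), kernel, sides = 2)
  f <- f[seq(r + 1, r + nrow(m)), , drop = FALSE]
  out <- array(as.numeric(f), dim(a))
  aperm(out, order(perm))
}

#' Smooth and binarize a lesion probability mask
#'
#' Gaussian smoothing (FWHM in mm, separable per axis) followed by a cutoff
#' threshold. With the default 50% cutoff a large solid lesion keeps its
#' volume: smoothing removes jagged edges without dilating or eroding.
#'
#' @param prob_mask 3-D numeric array with values in [0, 1].
#' @param fwhm_mm Full width at half maximum of the Gaussian kernel, mm.
#' @param voxel_size_mm Isotropic voxel edge length, mm.
#' @param cutoff Binarization threshold in (0, 1); voxels `>= cutoff` are set.
#' @return 3-D logical array (a binary mask).
#' @export
smooth_binarize_mask <- function(prob_mask, fwhm_mm = 3, voxel_size_mm = 1,
                                 cutoff = 0.5) {
  if (length(dim(prob_mask)) != 3) stop("`prob_mask` must be a 3-D array")
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must be in (0, 1)")
  if (fwhm_mm == 0) return(prob_mask >= cutoff)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sm <- prob_mask
  for (ax in 1:3) sm <- conv_axis(sm, k, ax)
  sm >= cutoff
}

#' Jaccard overlap of two binary masks
#'
#' `|A intersect B| / |A union B|`; 0 when both masks are empty (no overlap
#' evidence), so an empty mask can never trigger component removal.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Overlap in [0, 1].
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("masks must have identical shape")
  }
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# ---- ICA lesion-overlap filter ---------------------------------------------

#' Spatial ICA decomposition container
#'
#' The filter consumes a decomposition produced elsewhere (any spatial ICA
#' backend); no estimation is performed here.
#'
#' @param spatial_z components x voxels matrix of z-scored spatial maps.
#' @param timecourses components x time matrix.
#' @return An `ica_decomposition` list.
#' @export
ica_decomposition <- function(spatial_z, timecourses) {
  spatial_z <- as.matrix(spatial_z)
  timecourses <- as.matrix(timecourses)
  if (nrow(spatial_z) != nrow(timecourses)) {
    stop("component counts of `spatial_z` and `timecourses` differ")
  }
  structure(list(spatial_z = spatial_z, timecourses = timecourses),
            class = "ica_decomposition")
}

#' Remove lesion-driven independent components
#'
#' Each component's z-scored spatial map is thresholded at a two-sided
#' normal `p < map_alpha` (i.e. `|z| > qnorm(1 - map_alpha/2)`) into a binary
#' mask. Components whose Jaccard overlap with the lesion mask strictly
#' exceeds `overlap_threshold` are deemed lesion-driven and their time
#' courses are regressed out of every voxel series (least squares with
#' intercept). All other components are left untouched.
#'
#' @param ts A [voxel_ts()].
#' @param ica An [ica_decomposition()] sharing `ts`'s grid and time length.
#' @param lesion Logical 3-D lesion mask on the same grid.
#' @param map_alpha Two-sided significance level for map thresholding.
#' @param overlap_threshold Jaccard cutoff (strictly greater flags removal).
#' @return List with `ts` (filtered [voxel_ts()]) and `removed` (integer ids
#'   of removed components; empty when none qualify).
#' @export
lesion_component_filter <- function(ts, ica, lesion, map_alpha = 0.05,
                                    overlap_threshold = 0.05) {
  stopifnot(inherits(ts, "voxel_ts"), inherits(ica, "ica_decomposition"))
  if (!identical(as.integer(dim(lesion)), ts$grid_shape)) {
    stop("lesion mask grid does not match the time series grid")
  }
  n_vox <- nrow(ts$data)
  if (ncol(ica$spatial_z) != n_vox) stop("ICA maps do not match the voxel grid")
  if (ncol(ica$timecourses) != ncol(ts$data)) {
    stop("ICA time courses do not match the time dimension")
  }
  n_comp <- nrow(ica$spatial_z)
  if (n_comp == 0) return(list(ts = ts, removed = integer(0)))

  zc <- stats::qnorm(1 - map_alpha / 2)
  lesion_vec <- as.logical(lesion)
  removed <- integer(0)
  for (ci in seq_len(n_comp)) {
    comp_mask <- abs(ica$spatial_z[ci, ]) > zc
    u <- sum(comp_mask | lesion_vec)
    jac <- if (u == 0) 0 else sum(comp_mask & lesion_vec) / u
    if (jac > overlap_threshold) removed <- c(removed, ci)
  }
  if (length(removed) == 0) return(list(ts = ts, removed = integer(0)))

  X <- cbind(1, t(ica$timecourses[removed, , drop = FALSE]))
  filtered <- t(project_residuals(t(ts$data), X))
  list(ts = voxel_ts(filtered, ts$tr, ts$grid_shape), removed = removed)
}

#' Average voxel time courses within each ROI
#'
#' @param ts A [voxel_ts()].
#' @param roi_map 3-D integer array of ROI labels (0-based `roi_id`;
#'   `NA` or negative marks background).
#' @param parcellation A [make_parcellation()] object defining valid labels.
#' @return ROI x time matrix (rows in parcellation order, rownames = ROI
#'   names). ROIs with no voxels get all-`NA` rows and are listed in the
#'   `missing_rois` attribute.
#' @export
roi_mean_timecourses <- function(ts, roi_map, parcellation) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (!identical(as.integer(dim(roi_map)), ts$grid_shape)) {
    stop("`roi_map` grid does not match the time series grid")
  }
  labels <- as.vector(roi_map)
  fg <- !is.na(labels) & labels >= 0
  bad <- setdiff(unique(labels[fg]), parcellation$roi_id)
  if (length(bad) > 0) {
    stop("roi_map labels not in parcellation: ", paste(bad, collapse = ", "))
  }
  R <- n_rois(parcellation)
  out <- matrix(NA_real_, R, ncol(ts$data),
                dimnames = list(parcellation$name, NULL))
  for (k in seq_len(R)) {
    sel <- fg & labels == parcellation$roi_id[k]
    if (any(sel)) out[k, ] <- colMeans(ts$data[sel, , drop = FALSE])
  }
  missing <- parcellation$name[rowSums(is.na(out)) == ncol(out)]
  attr(out, "missing_rois") <- missing
  out
}

#' Pearson functional connectome from ROI time courses
#'
#' @param roi_ts ROI x time matrix (>= 3 time points).
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   series yield `NA` entries (flagged with a warning), never silent zeros.
#' @export
functional_connectome <- function(roi_ts) {
  roi_ts <- as.matrix(roi_ts)
  if (ncol(roi_ts) < 3) stop("need at least 3 time points")
  sds <- apply(roi_ts, 1, stats::sd)
  flat <- which(!is.na(sds) & sds == 0)
  if (length(flat) > 0) {
    warning("zero-variance ROI series: entries flagged NA (rows ",
            paste(flat, collapse = ", "), ")")
  }
  r <- suppressWarnings(stats::cor(t(roi_ts)))
  diag(r) <- 1
  if (length(flat) > 0) {
    r[flat, ] <- NA
    r[, flat] <- NA
    diag(r) <- 1
  }
  rownames(r) <- colnames(r) <- rownames(roi_ts)
  r
}
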