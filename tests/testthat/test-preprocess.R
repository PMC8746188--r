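test_that("mask smoothing conserves the volume of a solid lesion", {
  ball <- ball_mask(20)
  out <- smooth_binarize_mask(ball * 1, fwhm_mm = 3, voxel_size_mm = 1)
  # brute-force voxel counts
  expect_lt(abs(sum(out) - sum(ball)) / sum(ball), 0.02)
})

test_that("mask smoothing edge cases", {
  z <- array(0, c(5, 5, 5))
  expect_false(any(smooth_binarize_mask(z, 3, 1)))
  # fwhm 0 reduces to pure thresholding: a 0/1 mask is unchanged
  m <- array(as.numeric(runif(125) > 0.5), c(5, 5, 5))
  expect_identical(smooth_binarize_mask(m, 0, 1), m == 1)
  expect_error(smooth_binarize_mask(matrix(0, 2, 2), 3, 1), "3-D")
  expect_error(smooth_binarize_mask(z, 3, 1, cutoff = 1.5), "cutoff")
})

test_that("detrending removes exactly the nuisance span", {
  set.seed(4)
  TT <- 100
  reg <- nuisance_regressors(TT, motion = matrix(rnorm(TT * 6), TT),
                             wm_mean = rnorm(TT), csf_mean = rnorm(TT))
  # a series equal to the linear trend column vanishes
  lin <- reg[, "linear"]
  expect_lt(max(abs(detrend_timecourses(lin, reg))), 1e-10)
  # residuals orthogonal to every regressor (vs explicit normal equations)
  x <- matrix(rnorm(TT * 5), TT)
  res <- detrend_timecourses(x, reg)
  expect_lt(max(abs(crossprod(cbind(1, reg), res))) /
              max(abs(crossprod(cbind(1, reg), x))), 1e-08)
  oracle <- vapply(seq_len(ncol(x)),
                   function(k) normal_eq_residuals(x[, k], unclass(reg)),
                   numeric(TT))
  expect_equal(res, oracle, tolerance = 1e-08, ignore_attr = TRUE)
  # a mean-zero series orthogonal to the span is unchanged
  ortho <- normal_eq_residuals(rnorm(TT), unclass(reg))
  expect_equal(detrend_timecourses(ortho, reg), ortho, tolerance = 1e-08)
  expect_error(detrend_timecourses(x[1:50, ], reg), "match")
})

test_that("band-pass keeps the passband and kills the stopband (FFT oracle)", {
  tr <- 1.65
  tt <- (0:426) * tr
  s_in <- sin(2 * pi * 0.05 * tt)
  out <- bandpass(s_in, tr = tr)
  expect_gt(fft_amplitude(out, 0.05, tr) / fft_amplitude(s_in, 0.05, tr), 0.9)
  s_out <- sin(2 * pi * 0.25 * tt)
  expect_lt(fft_amplitude(bandpass(s_out, tr = tr), 0.25, tr) /
              fft_amplitude(s_out, 0.25, tr), 0.1)
  # one octave outside the band on both sides: >= 90% attenuation
  s_lo <- sin(2 * pi * 0.005 * tt)
  expect_lt(fft_amplitude(bandpass(s_lo, tr = tr), 0.005, tr) /
              fft_amplitude(s_lo, 0.005, tr), 0.1)
  s_hi <- sin(2 * pi * 0.2 * tt)
  expect_lt(fft_amplitude(bandpass(s_hi, tr = tr), 0.2, tr) /
              fft_amplitude(s_hi, 0.2, tr), 0.1)
  # DC removal
  expect_lt(max(abs(bandpass(rep(5, 427), tr = tr))), 1e-08)
  expect_error(bandpass(s_in, 0.01, 0.4, tr = tr), "Nyquist")
})

test_that("detrend and bandpass are linear operators", {
  set.seed(8)
  TT <- 120
  x <- rnorm(TT); y <- rnorm(TT)
  reg <- nuisance_regressors(TT)
  f <- function(v) detrend_timecourses(v, reg)
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-10)
  g <- function(v) bandpass(v, tr = 2)
  expect_equal(g(2 * x - 3 * y), 2 * g(x) - 3 * g(y), tolerance = 1e-08)
})

test_that("jaccard index on constructed masks", {
  d <- c(4, 4, 4)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:4] <- TRUE          # |a| = 4
  b[4:5] <- TRUE          # |b| = 2, shared voxel 4 -> union 5
  expect_equal(jaccard(a, b), 0.2)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, array(FALSE, d) | (array(seq_len(64), d) > 60)), 0)
  expect_equal(jaccard(array(FALSE, d), array(FALSE, d)), 0)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_error(jaccard(a, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("lesion component filter removes exactly the overlapping components", {
  # grid of 100 voxels; lesion occupies voxels 1:20
  d <- c(10, 5, 2); nv <- prod(d); TT <- 80
  lesion <- array(FALSE, d); lesion[1:20] <- TRUE
  zhi <- 5  # clearly above the |z| > 1.96 map threshold
  # comp 1: thresholded map == lesion -> jaccard 1, removed
  # comp 2: disjoint from lesion -> kept
  # comp 3: jaccard 4/96 ~ 0.0417 < 0.05 -> kept
  # comp 4: jaccard 5/95 ~ 0.0526 > 0.05 -> removed
  maps <- matrix(0, 4, nv)
  maps[1, 1:20] <- zhi
  maps[2, 30:40] <- -zhi          # negative loading must also threshold
  maps[3, c(1:4, 21:96)] <- zhi   # overlap 4, union 96
  maps[4, c(1:5, 21:95)] <- zhi   # overlap 5, union 95
  set.seed(2)
  tc <- matrix(rnorm(4 * TT), 4, TT)
  ts <- voxel_ts(matrix(rnorm(nv * TT), nv, TT), tr = 2, grid_shape = d)
  out <- lesion_component_filter(ts, ica_decomposition(maps, tc), lesion)
  expect_identical(out$removed, c(1L, 4L))
  # filtered data orthogonal to removed component time courses
  ip <- out$ts$data %*% t(tc[out$removed, , drop = FALSE])
  expect_lt(max(abs(ip)) / max(abs(ts$data %*% t(tc))), 1e-08)
  # untouched when no component overlaps
  out2 <- lesion_component_filter(ts, ica_decomposition(maps[2, , drop = FALSE],
                                                        tc[2, , drop = FALSE]),
                                  lesion)
  expect_identical(out2$removed, integer(0))
  expect_identical(out2$ts$data, ts$data)
})

test_that("component filter is linear in the input series", {
  d <- c(4, 4, 2); nv <- prod(d); TT <- 50
  lesion <- array(FALSE, d); lesion[1:8] <- TRUE
  maps <- matrix(0, 1, nv); maps[1, 1:8] <- 4
  set.seed(3)
  ica <- ica_decomposition(maps, matrix(rnorm(TT), 1, TT))
  x <- matrix(rnorm(nv * TT), nv, TT); y <- matrix(rnorm(nv * TT), nv, TT)
  f <- function(m) lesion_component_filter(voxel_ts(m, 2, d), ica, lesion)$ts$data
  expect_equal(f(2 * x - y), 2 * f(x) - f(y), tolerance = 1e-10)
})

test_that("ROI averaging matches the brute-force mean and flags empty ROIs", {
  p <- make_parcellation(1, 1)   # 3 ROIs: ids 0, 1, 2
  d <- c(3, 2, 1); TT <- 10
  roi_map <- array(NA_integer_, d)
  roi_map[1, 1, 1] <- 0L                       # single voxel
  roi_map[2:3, 1, 1] <- 1L; roi_map[1:2, 2, 1] <- 1L   # 4-voxel ROI
  set.seed(6)
  dat <- matrix(rnorm(prod(d) * TT), prod(d), TT)
  ts <- voxel_ts(dat, tr = 1, grid_shape = d)
  out <- roi_mean_timecourses(ts, roi_map, p)
  expect_equal(out[1, ], dat[1, ])
  members <- which(as.vector(roi_map) == 1L)
  expect_equal(out[2, ], colSums(dat[members, ]) / length(members))
  expect_true(all(is.na(out[3, ])))
  expect_identical(attr(out, "missing_rois"), p$name[3])
  # two voxels carrying x and -x average to zero
  roi2 <- array(NA_integer_, d); roi2[1:2, 1, 1] <- 2L
  dat2 <- dat; dat2[2, ] <- -dat2[1, ]
  out2 <- roi_mean_timecourses(voxel_ts(dat2, 1, d), roi2, p)
  expect_equal(out2[3, ], rep(0, TT))
  bad <- roi_map; bad[3, 2, 1] <- 9L
  expect_error(roi_mean_timecourses(ts, bad, p), "not in parcellation")
})

test_that("functional connectome basics and permutation equivariance", {
  set.seed(10)
  x <- rnorm(200)
  m <- rbind(a = x, b = x, c = -x + 0, d = rnorm(200))
  expect_warning(r <- functional_connectome(rbind(m, e = rep(1, 200))),
                 "zero-variance")
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_true(all(is.na(r["e", c("a", "b", "c", "d")])))
  expect_identical(r, t(r))
  expect_true(all(diag(r) == 1))
  # long independent white noise: |r| below the sampling bound
  set.seed(12)
  w <- rbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(functional_connectome(w)[1, 2]), 0.05)
  # permuting ROI order permutes the matrix consistently
  mm <- matrix(rnorm(5 * 100), 5, 100, dimnames = list(letters[1:5], NULL))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(functional_connectome(mm[perm, ]),
               functional_connectome(mm)[perm, perm])
})
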