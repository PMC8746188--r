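test_that("edge index map covers the upper triangle in fixed order", {
  m3 <- edge_index_map(3)
  expect_equal(nrow(m3), 3)
  expect_equal(m3$i, c(0, 0, 1))
  expect_equal(m3$j, c(1, 2, 2))
  expect_equal(nrow(edge_index_map(make_parcellation(26, 41))), 5778)
})

test_that("edge vectorization round-trips and rejects asymmetry", {
  p <- make_parcellation(2, 2)
  map <- edge_index_map(p)
  set.seed(1)
  m <- matrix(rnorm(36), 6); m <- m + t(m); diag(m) <- 0
  v <- edge_vectorize(m, map)
  expect_equal(length(v), 15)
  expect_equal(edge_devectorize(v, map, diag_value = 0), m)
  r <- m; diag(r) <- 1
  expect_equal(edge_devectorize(v, map, diag_value = 1), r)
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(edge_vectorize(bad, map), "asymmetric")
})

test_that("region LSM applies the minimum-damage inclusion rule", {
  coh <- tiny_cohort(n_subjects = 20, seed = 2)
  loads <- lesion_load_matrix(coh)
  damaged_n <- colSums(loads > 0)
  pc <- permutation_config(n_perm = 50, seed = 1)
  res_all <- suppressWarnings(region_lsm(coh, "avc", pc,
                                         min_damage_subjects = 1))
  # right-hemisphere ROIs are never damaged -> excluded even at threshold 1
  expect_true(all(coh$parcellation$name[coh$parcellation$hemisphere == "R"]
                  %in% attr(res_all, "excluded_rois")))
  # an ROI damaged in d subjects is excluded at threshold d + 1
  d <- max(damaged_n)
  res_hi <- suppressWarnings(region_lsm(coh, "avc", pc,
                                        min_damage_subjects = d + 1))
  expect_length(res_hi$feature_ids, 0)
  # decreasing the threshold never removes a previously included ROI
  prev <- character(0)
  for (mds in c(15, 10, 5, 1)) {
    r <- suppressWarnings(region_lsm(coh, "avc", pc,
                                     min_damage_subjects = mds))
    expect_true(all(prev %in% r$feature_ids))
    prev <- r$feature_ids
  }
})

test_that("region LSM recovers a planted lesion-symptom effect", {
  # calibrate the planted slope from an unplanted pilot (power analysis on
  # the generative model, not on test outcomes)
  pilot <- generate_cohort(demo_cohort_config(n_subjects = 150), seed = 555)
  loads <- lesion_load_matrix(pilot)
  tlv <- lesion_volume_vector(pilot)
  roi <- 8L   # a left ventral ROI
  n_feat <- sum(colSums(loads > 0) >= 10)
  sd_res <- stats::sd(residualize(loads[, roi + 1L], tlv))
  k <- planted_beta_for_power(97, n_feat, sd_res, 1, power = 0.98)
  tt <- ground_truth(planted_lesion_rois = data.frame(roi = roi, beta = -k))
  hits <- 0
  for (s in 1:10) {
    coh <- generate_cohort(demo_cohort_config(truth = tt), seed = 3000 + s)
    res <- region_lsm(coh, "avc", permutation_config(n_perm = 300, seed = s))
    idx <- match(coh$parcellation$name[roi + 1L], res$feature_ids)
    hits <- hits + (res$survivors[idx] && res$z[idx] < 0)
  }
  expect_gte(hits, 9)
})

test_that("structural edge analysis ranks a planted edge first", {
  pilot <- generate_cohort(demo_cohort_config(n_subjects = 150), seed = 556)
  map <- edge_index_map(pilot$parcellation)
  target <- which(map$i == 7 & map$j == 10)
  sc <- sc_edge_matrix(pilot, map)
  sd_res <- stats::sd(residualize(sc[, target],
                                  lesion_volume_vector(pilot)))
  k <- planted_beta_for_power(97, nrow(map), sd_res, 1, power = 0.98)
  tt <- ground_truth(planted_sc_edges = data.frame(i = 7, j = 10, beta = k))
  firsts <- 0
  for (s in 1:10) {
    coh <- generate_cohort(demo_cohort_config(truth = tt, avc_baseline = 5),
                           seed = 4000 + s)
    out <- structural_edge_analysis(coh, "avc",
                                    permutation_config(n_perm = 50, seed = s))
    firsts <- firsts + (which.max(abs(out$result$z)) == target)
  }
  expect_gte(firsts, 9)
})

test_that("constant fiber counts give flagged, survivor-free results", {
  coh <- tiny_cohort(n_subjects = 8, seed = 3)
  const <- matrix(5, 8, 8); diag(const) <- 0
  for (i in seq_along(coh$subjects)) coh$subjects[[i]]$structural <- const
  out <- structural_edge_analysis(coh, "avc",
                                  permutation_config(n_perm = 50, seed = 1))
  expect_true(all(out$result$undefined))
  expect_false(any(out$result$survivors))
  expect_equal(nrow(out$findings), 0)
  coh$subjects[[3]]$structural <- NULL
  expect_error(structural_edge_analysis(coh, "avc"), "subject 3")
})

test_that("per-edge structural residualization matches its oracle", {
  set.seed(4)
  n <- 40; E <- 12
  sc <- matrix(rexp(n * E), n)
  fc <- matrix(rnorm(n * E), n)
  # an exactly linear edge vanishes
  fc[, 3] <- 0.2 * sc[, 3] - 1
  # a constant-SC edge reduces to mean-centering
  sc[, 5] <- 7
  res <- sc_residualize_fc(fc, sc)
  expect_lt(max(abs(res[, 3])), 1e-10)
  expect_equal(res[, 5], fc[, 5] - mean(fc[, 5]))
  for (e in c(1, 2, 7)) {
    expect_equal(res[, e], normal_eq_residuals(fc[, e], sc[, e]),
                 tolerance = 1e-10)
    expect_lt(abs(sum(res[, e] * sc[, e])), 1e-08)
  }
  expect_error(sc_residualize_fc(fc, sc[, 1:3]), "shapes")
})

test_that("critical-area lesion load sums damage over the listed ROIs", {
  p <- make_parcellation(2, 4, roi_volumes = rep(100, 10))
  crit <- p$name[3:6]
  subj <- structure(list(lesion_load = rep(0, 10)), class = "subject_record")
  expect_equal(critical_area_lesion_load(subj, crit, p), 0)
  subj$lesion_load[3:6] <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(critical_area_lesion_load(subj, crit, p), 100)
  # damage outside the critical set contributes nothing
  subj2 <- structure(list(lesion_load = c(1, rep(0, 9))),
                     class = "subject_record")
  expect_equal(critical_area_lesion_load(subj2, crit, p), 0)
  expect_error(critical_area_lesion_load(subj, "nope", p), "unknown ROI")
})

test_that("analysis config validates critical ROIs", {
  expect_error(analysis_config("avc", "CRITICAL_AREAS_PLUS_SC"),
               "critical_rois")
  cfg <- analysis_config("avc", "CRITICAL_AREAS_PLUS_SC",
                         critical_rois = "ventral_L_(1)")
  expect_s3_class(cfg, "analysis_config")
})

test_that("structural-adjusted modes are invariant to fiber-count rescaling", {
  coh <- tiny_cohort(n_subjects = 15, seed = 5, n_timepoints = 80)
  pc <- permutation_config(n_perm = 60, seed = 3)
  crit <- coh$parcellation$name[3:4]
  for (mode in c("LESION_VOLUME_PLUS_SC", "CRITICAL_AREAS_PLUS_SC")) {
    cfg <- analysis_config("avc", mode, pc, critical_rois = crit)
    base <- functional_edge_analysis(coh, cfg)
    scaled <- coh
    for (i in seq_along(scaled$subjects)) {
      scaled$subjects[[i]]$structural <-
        scaled$subjects[[i]]$structural * 13 + 2
    }
    # keep zero diagonal after the affine map
    for (i in seq_along(scaled$subjects)) diag(scaled$subjects[[i]]$structural) <- 0
    again <- functional_edge_analysis(scaled, cfg)
    expect_equal(again$result$z, base$result$z, tolerance = 1e-08)
    expect_equal(again$result$fwe_threshold, base$result$fwe_threshold,
                 tolerance = 1e-08)
  }
})

test_that("findings carry valid labels and anatomical filters work", {
  coh <- tiny_cohort(n_subjects = 12, seed = 6, n_timepoints = 80)
  out <- functional_edge_analysis(
    coh, analysis_config("avc", "LESION_VOLUME",
                         permutation_config(n_perm = 60, seed = 4)))
  # force a findings table by taking all edges regardless of survival
  all_findings <- data.frame(roi_a = out$map$name_a, roi_b = out$map$name_b,
                             z = out$result$z, survived = TRUE)
  expect_true(all(all_findings$roi_a %in% coh$parcellation$name))
  lv <- filter_findings(all_findings, coh$parcellation,
                        hemisphere = "L", stream = "ventral")
  expect_true(all(lv$hemi_a == "L" & lv$hemi_b == "L" &
                    lv$stream_a == "ventral" & lv$stream_b == "ventral"))
  expect_equal(nrow(lv), 3)   # 3 left ventral ROIs -> 3 edges
})

test_that("mode (a) uses lesion volume as covariate, (b) pre-residualizes", {
  # the two schemes must genuinely differ on the same cohort
  coh <- tiny_cohort(n_subjects = 15, seed = 7, n_timepoints = 80)
  pc <- permutation_config(n_perm = 60, seed = 5)
  a <- functional_edge_analysis(coh, analysis_config("avc", "LESION_VOLUME", pc))
  b <- functional_edge_analysis(coh, analysis_config("avc", "LESION_VOLUME_PLUS_SC", pc))
  expect_false(isTRUE(all.equal(a$result$z, b$result$z)))
  expect_equal(a$mode, "LESION_VOLUME")
  expect_equal(b$mode, "LESION_VOLUME_PLUS_SC")
})
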