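#' Edge index map over a parcellation
#'
#' Fixed bijection between upper-triangle ROI pairs (i < j, 0-based ids) and
#' edge positions; every connectome analysis uses the same ordering. All
#' possible node pairs are included.
#'
#' @param parcellation A [make_parcellation()] object (or an ROI count).
#' @return An `edge_map` data.frame with columns `edge`, `i`, `j`, `name_a`,
#'   `name_b`; `R(R-1)/2` rows.
#' @export
edge_index_map <- function(parcellation) {
  if (is.numeric(parcellation)) {
    R <- as.integer(parcellation)
    names <- as.character(seq_len(R) - 1L)
  } else {
    R <- n_rois(parcellation)
    names <- parcellation$name
  }
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out <- data.frame(
    edge = seq_len(nrow(pairs)),
    i = pairs[, 1] - 1L,
    j = pairs[, 2] - 1L,
    name_a = names[pairs[, 1]],
    name_b = names[pairs[, 2]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("edge_map", "data.frame")
  out
}

#' Vectorize a symmetric connectome matrix
#'
#' @param mat Symmetric ROI x ROI matrix.
#' @param map An [edge_index_map()] of matching dimension.
#' @param tol Relative asymmetry tolerance.
#' @return Numeric vector of upper-triangle values in map order.
#' @export
edge_vectorize <- function(mat, map, tol = 1e-08) {
  mat <- as.matrix(mat)
  R <- nrow(mat)
  if (ncol(mat) != R) stop("matrix must be square")
  if (nrow(map) != R * (R - 1) / 2) stop("edge map does not match matrix size")
  asym <- max(abs(mat - t(mat)), na.rm = TRUE)
  scale <- max(abs(mat), na.rm = TRUE)
  if (asym > tol * max(scale, 1)) stop("matrix is asymmetric beyond tolerance")
  mat[cbind(map$i + 1L, map$j + 1L)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' @param vec Per-edge values in map order.
#' @param map An [edge_index_map()].
#' @param diag_value Diagonal fill (0 for structural, 1 for correlation).
#' @return Symmetric ROI x ROI matrix.
#' @export
edge_devectorize <- function(vec, map, diag_value = 0) {
  R <- max(map$j) + 1L
  if (length(vec) != nrow(map)) stop("vector length does not match edge map")
  m <- matrix(diag_value, R, R)
  m[cbind(map$i + 1L, map$j + 1L)] <- vec
  m[cbind(map$j + 1L, map$i + 1L)] <- vec
  diag(m) <- diag_value
  m
}

#' Subjects x edges matrix of structural fiber counts
#' @param cohort A `cohort`.
#' @param map An [edge_index_map()] (defaults to the cohort's parcellation).
#' @return subjects x edges matrix, columns named `name_a|name_b`.
#' @export
sc_edge_matrix <- function(cohort, map = edge_index_map(cohort$parcellation)) {
  rows <- lapply(seq_along(cohort$subjects), function(si) {
    s <- cohort$subjects[[si]]
    if (is.null(s$structural)) stop("missing structural matrix for subject ", si)
    edge_vectorize(s$structural, map)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- paste(map$name_a, map$name_b, sep = "|")
  out
}

#' Subjects x edges matrix of functional connectivity
#'
#' Uses each subject's precomputed connectome (`fc`) when present, otherwise
#' computes the Pearson connectome from `roi_timecourses`.
#'
#' @inheritParams sc_edge_matrix
#' @return subjects x edges matrix of Pearson r values.
#' @export
fc_edge_matrix <- function(cohort, map = edge_index_map(cohort$parcellation)) {
  rows <- lapply(seq_along(cohort$subjects), function(si) {
    s <- cohort$subjects[[si]]
    fc <- s$fc
    if (is.null(fc)) {
      if (is.null(s$roi_timecourses)) {
        stop("subject ", si, " has neither fc nor roi_timecourses")
      }
      fc <- functional_connectome(s$roi_timecourses)
    }
    edge_vectorize(fc, map)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- paste(map$name_a, map$name_b, sep = "|")
  out
}

#' Region-based lesion-symptom mapping
#'
#' Mass-univariate GLM of a behavioral score on per-ROI lesion load,
#' controlling for total lesion volume, with max-statistic permutation FWE
#' correction. Only ROIs damaged in at least `min_damage_subjects` subjects
#' enter the analysis (the inclusion rule is applied before permutation).
#'
#' @param cohort A `cohort`.
#' @param behavior "avc" or "spontaneous_speech".
#' @param permutation A [permutation_config()].
#' @param min_damage_subjects Minimum number of subjects with damage for an
#'   ROI to be included.
#' @return A `glm_result` over the included ROIs, with attribute
#'   `excluded_rois` naming those that failed the inclusion rule. If no ROI
#'   qualifies, an empty result with a warning.
#' @export
region_lsm <- function(cohort, behavior = "avc",
                       permutation = permutation_config(),
                       min_damage_subjects = 10) {
  y <- behavior_vector(cohort, behavior)
  loads <- lesion_load_matrix(cohort)
  colnames(loads) <- cohort$parcellation$name
  damaged_n <- colSums(loads > 0)
  include <- damaged_n >= min_damage_subjects
  excluded <- colnames(loads)[!include]
  if (!any(include)) {
    warning("no ROI damaged in >= ", min_damage_subjects, " subjects")
    res <- structure(list(feature_ids = character(0), z = numeric(0),
                          t = numeric(0), p_uncorrected = numeric(0),
                          p_fwe = numeric(0), fwe_threshold = NA_real_,
                          survivors = logical(0), undefined = logical(0),
                          dof = NA_integer_, max_dist = numeric(0),
                          n_perm = permutation$n_perm,
                          alpha = permutation$alpha, seed = permutation$seed,
                          sidedness = permutation$sidedness,
                          scheme = permutation$scheme),
                     class = "glm_result")
    attr(res, "excluded_rois") <- excluded
    return(res)
  }
  tlv <- lesion_volume_vector(cohort)
  res <- permutation_fwe(y, loads[, include, drop = FALSE],
                         covariates = tlv, cfg = permutation)
  attr(res, "excluded_rois") <- excluded
  res
}

# build the sorted survivor table from a glm_result over edges
edge_findings <- function(result, map) {
  df <- data.frame(
    roi_a = map$name_a, roi_b = map$name_b,
    z = result$z, survived = result$survivors,
    stringsAsFactors = FALSE
  )
  df <- df[df$survived, , drop = FALSE]
  df <- df[order(-abs(df$z), df$roi_a, df$roi_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Structural-connectome edge analysis
#'
#' GLM of behavior on each structural edge's fiber count, controlling for
#' total lesion volume, permutation-FWE corrected. All node pairs are
#' included; zero-variance edges are flagged and skipped, never tested.
#'
#' @inheritParams region_lsm
#' @return List with `result` (a `glm_result`), `findings` (survivors sorted
#'   by |z| descending, ties broken by ROI labels) and `map`.
#' @export
structural_edge_analysis <- function(cohort, behavior = "avc",
                                     permutation = permutation_config()) {
  map <- edge_index_map(cohort$parcellation)
  feats <- sc_edge_matrix(cohort, map)
  y <- behavior_vector(cohort, behavior)
  tlv <- lesion_volume_vector(cohort)
  res <- permutation_fwe(y, feats, covariates = tlv, cfg = permutation)
  list(result = res, findings = edge_findings(res, map), map = map)
}

#' Residualize functional connectivity on structural connectivity, per edge
#'
#' For each edge independently (across subjects), regresses that edge's
#' functional connectivity on the same edge's fiber count (with intercept)
#' and returns the residuals. Edges with constant fiber counts reduce to
#' mean-centering.
#'
#' @param fc_edges subjects x edges functional values.
#' @param sc_edges subjects x edges fiber counts, same shape.
#' @return subjects x edges residual matrix.
#' @export
sc_residualize_fc <- function(fc_edges, sc_edges) {
  fc_edges <- as.matrix(fc_edges)
  sc_edges <- as.matrix(sc_edges)
  if (!all(dim(fc_edges) == dim(sc_edges))) {
    stop("`fc_edges` and `sc_edges` shapes differ")
  }
  fc_c <- sweep(fc_edges, 2, colMeans(fc_edges))
  sc_c <- sweep(sc_edges, 2, colMeans(sc_edges))
  ss <- colSums(sc_c^2)
  b <- ifelse(ss > 0, colSums(fc_c * sc_c) / pmax(ss, 1), 0)
  fc_c - sweep(sc_c, 2, b, `*`)
}

#' Lesion load summed over critical areas
#'
#' Total damaged volume (mm^3) within a named set of "critical" ROIs: the
#' sum over those ROIs of damaged fraction times ROI volume.
#'
#' @param subject A `subject_record`.
#' @param critical_rois Character vector of parcellation ROI names.
#' @param parcellation The cohort's parcellation.
#' @return Lesion load in mm^3.
#' @export
critical_area_lesion_load <- function(subject, critical_rois, parcellation) {
  idx <- roi_index(parcellation, critical_rois)
  sum(subject$lesion_load[idx] * parcellation$volume_mm3[idx])
}

#' Analysis configuration for the functional-connectome GLMs
#'
#' @param behavior "avc" or "spontaneous_speech".
#' @param covariate_mode One of:
#'   `"LESION_VOLUME"` (mode a: total lesion volume enters the GLM as a
#'   confound covariate), `"LESION_VOLUME_PLUS_SC"` (mode b: behavior is
#'   pre-residualized on total lesion volume and each FC edge on its own
#'   structural fiber count), `"CRITICAL_AREAS_PLUS_SC"` (mode c: as b but
#'   behavior is residualized on critical-area lesion load).
#' @param permutation A [permutation_config()].
#' @param min_damage_subjects Region-LSM inclusion rule (unused by the FC
#'   modes, carried for pipeline configs).
#' @param critical_rois ROI names; required for mode c.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(behavior = c("avc", "spontaneous_speech"),
                            covariate_mode = c("LESION_VOLUME",
                                               "LESION_VOLUME_PLUS_SC",
                                               "CRITICAL_AREAS_PLUS_SC"),
                            permutation = permutation_config(),
                            min_damage_subjects = 10,
                            critical_rois = NULL) {
  behavior <- match.arg(behavior)
  covariate_mode <- match.arg(covariate_mode)
  if (covariate_mode == "CRITICAL_AREAS_PLUS_SC" &&
      (is.null(critical_rois) || length(critical_rois) == 0)) {
    stop("`critical_rois` must be non-empty for CRITICAL_AREAS_PLUS_SC")
  }
  structure(list(behavior = behavior, covariate_mode = covariate_mode,
                 permutation = permutation,
                 min_damage_subjects = min_damage_subjects,
                 critical_rois = critical_rois),
            class = "analysis_config")
}

#' Functional-connectome edge analysis (three covariate modes)
#'
#' Relates behavioral scores to resting-state functional connectivity edge
#' by edge, under one of three anatomical-covariate schemes: (a) total
#' lesion volume as a GLM confound; (b) total lesion volume regressed out of
#' behavior and each edge's fiber count regressed out of the same edge's
#' functional connectivity; (c) as (b) but with critical-area lesion load in
#' place of total lesion volume. All modes are permutation-FWE corrected.
#'
#' @param cohort A `cohort`.
#' @param config An [analysis_config()].
#' @return List with `result`, `findings`, `map` and `mode`.
#' @export
functional_edge_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  map <- edge_index_map(cohort$parcellation)
  fc <- fc_edge_matrix(cohort, map)
  y <- behavior_vector(cohort, config$behavior)
  mode <- config$covariate_mode

  if (mode == "LESION_VOLUME") {
    res <- permutation_fwe(y, fc, covariates = lesion_volume_vector(cohort),
                           cfg = config$permutation)
  } else {
    sc <- sc_edge_matrix(cohort, map)
    fc_res <- sc_residualize_fc(fc, sc)
    nuis <- if (mode == "LESION_VOLUME_PLUS_SC") {
      lesion_volume_vector(cohort)
    } else {
      vapply(cohort$subjects, critical_area_lesion_load, numeric(1),
             critical_rois = config$critical_rois,
             parcellation = cohort$parcellation)
    }
    y_res <- residualize(y, nuis)
    res <- permutation_fwe(y_res, fc_res, covariates = NULL,
                           cfg = config$permutation)
  }
  list(result = res, findings = edge_findings(res, map), map = map,
       mode = mode)
}

#' Filter edge findings by hemisphere and stream
#'
#' Survivor summaries are often restricted anatomically (e.g. left ventral
#' stream only); this propagates the parcellation labels onto findings.
#'
#' @param findings An edge-findings data.frame (from an analysis result).
#' @param parcellation The parcellation.
#' @param hemisphere Optional "L"/"R" filter (both endpoints must match).
#' @param stream Optional "dorsal"/"ventral" filter.
#' @return Filtered findings with `hemi_a`, `hemi_b`, `stream_a`, `stream_b`
#'   columns added.
#' @export
filter_findings <- function(findings, parcellation, hemisphere = NULL,
                            stream = NULL) {
  ia <- roi_index(parcellation, findings$roi_a)
  ib <- roi_index(parcellation, findings$roi_b)
  findings$hemi_a <- parcellation$hemisphere[ia]
  findings$hemi_b <- parcellation$hemisphere[ib]
  findings$stream_a <- parcellation$stream[ia]
  findings$stream_b <- parcellation$stream[ib]
  keep <- rep(TRUE, nrow(findings))
  if (!is.null(hemisphere)) {
    keep <- keep & findings$hemi_a == hemisphere & findings$hemi_b == hemisphere
  }
  if (!is.null(stream)) {
    keep <- keep & findings$stream_a == stream & findings$stream_b == stream
  }
  out <- findings[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
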