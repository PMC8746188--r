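#' Write a labeled square connectome matrix as CSV
#'
#' @param mat Square numeric matrix.
#' @param path Output file path.
#' @param labels ROI labels (defaults to `rownames(mat)`).
#' @export
write_connectome_csv <- function(mat, path, labels = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(mat)))
  df <- data.frame(roi = labels, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("roi", labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square connectome matrix from CSV
#'
#' Validates squareness and row/column label agreement. Asymmetric matrices
#' (beyond `tol`) are symmetrized by averaging with a warning.
#'
#' @param path CSV path as written by [write_connectome_csv()].
#' @param parcellation Optional parcellation; when given, rows/columns are
#'   reindexed into parcellation order (all parcellation ROIs must be
#'   present).
#' @param tol Relative asymmetry tolerance before symmetrization kicks in.
#' @return Labeled symmetric numeric matrix.
#' @export
read_connectome_csv <- function(path, parcellation = NULL, tol = 1e-08) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(mat) != ncol(mat)) {
    stop(sprintf("connectome file %s is not square (%d rows, %d columns)",
                 path, nrow(mat), ncol(mat)))
  }
  if (!identical(labels, colnames(mat))) {
    bad <- which(labels != colnames(mat))[1]
    stop(sprintf("row/column label mismatch in %s at line %d: '%s' vs '%s'",
                 path, bad + 1L, labels[bad], colnames(mat)[bad]))
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- labels
  asym <- max(abs(mat - t(mat)), na.rm = TRUE)
  if (asym > tol * max(max(abs(mat), na.rm = TRUE), 1)) {
    warning(sprintf("asymmetric connectome in %s (max |delta| = %g); symmetrized by averaging",
                    path, asym))
    mat <- (mat + t(mat)) / 2
  }
  if (!is.null(parcellation)) {
    idx <- match(parcellation$name, labels)
    if (anyNA(idx)) {
      stop("connectome labels missing parcellation ROIs: ",
           paste(parcellation$name[is.na(idx)], collapse = ", "))
    }
    mat <- mat[idx, idx, drop = FALSE]
  }
  mat
}

#' Serialize a cohort to a directory of plain-text files
#'
#' Layout: `parcellation.csv`, `behavior.csv` (one row per subject with the
#' WAB-R subtests, composites and total lesion volume), `lesion_loads.csv`,
#' per-subject structural and functional connectome matrices
#' (`sc_sub<k>.csv`, `fc_sub<k>.csv`), and a `cohort.json` sidecar with the
#' config, master seed and ground truth.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$parcellation
  utils::write.csv(as.data.frame(p), file.path(dir, "parcellation.csv"),
                   row.names = FALSE)

  beh <- do.call(rbind, lapply(seq_along(cohort$subjects), function(si) {
    s <- cohort$subjects[[si]]
    data.frame(subject = si, s$behavior,
               total_lesion_volume = s$total_lesion_volume)
  }))
  utils::write.csv(beh, file.path(dir, "behavior.csv"), row.names = FALSE)

  loads <- lesion_load_matrix(cohort)
  colnames(loads) <- p$name
  utils::write.csv(data.frame(subject = seq_len(nrow(loads)), loads,
                              check.names = FALSE),
                   file.path(dir, "lesion_loads.csv"), row.names = FALSE)

  map <- edge_index_map(p)
  for (si in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[si]]
    write_connectome_csv(s$structural, file.path(dir, sprintf("sc_sub%03d.csv", si)),
                         labels = p$name)
    fc <- if (!is.null(s$fc)) s$fc else functional_connectome(s$roi_timecourses)
    write_connectome_csv(round(fc, 10), file.path(dir, sprintf("fc_sub%03d.csv", si)),
                         labels = p$name)
  }

  gt <- cohort$ground_truth
  sidecar <- list(
    seed = cohort$seed,
    n_subjects = length(cohort$subjects),
    config = cohort$config[setdiff(names(cohort$config), "truth")],
    ground_truth = list(
      planted_fc_edges = gt$planted_fc_edges,
      planted_sc_edges = gt$planted_sc_edges,
      planted_lesion_rois = gt$planted_lesion_rois,
      lesion_behavior_coef = gt$lesion_behavior_coef,
      noise_sd = gt$noise_sd,
      fc_sc_coupling = gt$fc_sc_coupling
    )
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Reconstructed subjects carry precomputed functional connectomes (`fc`)
#' rather than raw time courses.
#'
#' @param dir Cohort directory.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  pdf <- utils::read.csv(file.path(dir, "parcellation.csv"),
                         stringsAsFactors = FALSE)
  p <- make_parcellation(sum(pdf$stream == "dorsal"),
                         sum(pdf$stream == "ventral" & pdf$hemisphere == "L"),
                         roi_volumes = pdf$volume_mm3)
  beh <- utils::read.csv(file.path(dir, "behavior.csv"))
  loads <- utils::read.csv(file.path(dir, "lesion_loads.csv"),
                           check.names = FALSE)
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE)
  gt_in <- sidecar$ground_truth
  gt <- ground_truth(
    planted_fc_edges = if (is.data.frame(gt_in$planted_fc_edges))
      gt_in$planted_fc_edges else NULL,
    planted_sc_edges = if (is.data.frame(gt_in$planted_sc_edges))
      gt_in$planted_sc_edges else NULL,
    planted_lesion_rois = if (is.data.frame(gt_in$planted_lesion_rois))
      gt_in$planted_lesion_rois else NULL,
    lesion_behavior_coef = gt_in$lesion_behavior_coef,
    noise_sd = gt_in$noise_sd,
    fc_sc_coupling = gt_in$fc_sc_coupling
  )
  subjects <- lapply(seq_len(nrow(beh)), function(si) {
    sc <- read_connectome_csv(file.path(dir, sprintf("sc_sub%03d.csv", si)), p)
    fc <- read_connectome_csv(file.path(dir, sprintf("fc_sub%03d.csv", si)), p)
    structure(list(
      lesion_load = as.numeric(loads[si, -1]),
      total_lesion_volume = beh$total_lesion_volume[si],
      lesion_mask = NULL,
      structural = sc,
      roi_timecourses = NULL,
      tr = sidecar$config$tr,
      fc = fc,
      behavior = as.list(beh[si, c("yes_no", "word_recognition",
                                   "sequential_commands", "avc",
                                   "info_content", "fluency",
                                   "spontaneous_speech")])
    ), class = "subject_record")
  })
  structure(list(parcellation = p, subjects = subjects, ground_truth = gt,
                 seed = sidecar$seed, config = NULL),
            class = "cohort")
}

#' Write a GLM result as CSV plus a JSON provenance block
#'
#' @param result A `glm_result`.
#' @param csv_path Per-feature table destination (feature id, z, p,
#'   survivor flag).
#' @param json_path Provenance destination (n_perm, alpha, seed, sidedness,
#'   scheme, dof, FWE threshold).
#' @export
write_glm_result <- function(result, csv_path, json_path = NULL) {
  df <- data.frame(feature = result$feature_ids, z = result$z,
                   p_uncorrected = result$p_uncorrected,
                   p_fwe = result$p_fwe, survivor = result$survivors)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_perm = result$n_perm, alpha = result$alpha, seed = result$seed,
      sidedness = result$sidedness, scheme = result$scheme, dof = result$dof,
      fwe_threshold = result$fwe_threshold,
      n_features = length(result$z), n_survivors = sum(result$survivors)
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
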