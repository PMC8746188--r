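#' Build a dual-stream parcellation specification
#'
#' Constructs the ROI bookkeeping table used throughout the package: a set of
#' dorsal-stream ROIs restricted to the left hemisphere plus a bilateral
#' ventral stream with the same number of ROIs in each hemisphere. The default
#' configuration (26 dorsal-left + 41 ventral per hemisphere = 108 ROIs)
#' mirrors the dual-stream region set commonly used in aphasia connectome
#' studies.
#'
#' @param n_dorsal_left Number of dorsal-stream ROIs (left hemisphere only).
#' @param n_ventral_per_hemi Number of ventral-stream ROIs per hemisphere.
#' @param roi_volumes Optional numeric vector of ROI volumes in mm^3, one per
#'   ROI. If `NULL`, deterministic volumes with a realistic spread around
#'   8000 mm^3 are assigned (no randomness: volumes are a fixed property of
#'   the parcellation).
#' @return A `parcellation` object: a data.frame with columns `roi_id`
#'   (0-based integer index), `name`, `hemisphere` ("L"/"R"), `stream`
#'   ("dorsal"/"ventral"), `subregion` (integer) and `volume_mm3`.
#' @examples
#' p <- make_parcellation()
#' nrow(p)            # 108
#' table(p$stream, p$hemisphere)
#' @export
make_parcellation <- function(n_dorsal_left = 26, n_ventral_per_hemi = 41,
                              roi_volumes = NULL) {
  if (!is.numeric(n_dorsal_left) || length(n_dorsal_left) != 1 ||
      n_dorsal_left < 1 || n_dorsal_left != round(n_dorsal_left)) {
    stop("`n_dorsal_left` must be a positive integer count")
  }
  if (!is.numeric(n_ventral_per_hemi) || length(n_ventral_per_hemi) != 1 ||
      n_ventral_per_hemi < 1 || n_ventral_per_hemi != round(n_ventral_per_hemi)) {
    stop("`n_ventral_per_hemi` must be a positive integer count")
  }
  n_total <- n_dorsal_left + 2L * n_ventral_per_hemi

  hemisphere <- c(rep("L", n_dorsal_left),
                  rep("L", n_ventral_per_hemi),
                  rep("R", n_ventral_per_hemi))
  stream <- c(rep("dorsal", n_dorsal_left),
              rep("ventral", 2L * n_ventral_per_hemi))
  subregion <- c(seq_len(n_dorsal_left),
                 seq_len(n_ventral_per_hemi),
                 seq_len(n_ventral_per_hemi))
  name <- sprintf("%s_%s_(%d)",
                  ifelse(stream == "dorsal", "dorsal", "ventral"),
                  hemisphere, subregion)

  if (is.null(roi_volumes)) {
    # fixed, aperiodic spread of volumes around 8000 mm^3; deterministic so
    # the parcellation carries no random state
    k <- seq_len(n_total)
    roi_volumes <- round(8000 * exp(0.4 * sin(2.3 * k) + 0.25 * cos(0.7 * k)))
  }
  if (length(roi_volumes) != n_total || any(roi_volumes <= 0)) {
    stop("`roi_volumes` must be positive and have one entry per ROI")
  }

  out <- data.frame(
    roi_id = seq_len(n_total) - 1L,
    name = name,
    hemisphere = hemisphere,
    stream = stream,
    subregion = as.integer(subregion),
    volume_mm3 = as.numeric(roi_volumes),
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d ROIs (%d dorsal-L, %d ventral-L, %d ventral-R)\n",
              nrow(x),
              sum(x$stream == "dorsal"),
              sum(x$stream == "ventral" & x$hemisphere == "L"),
              sum(x$stream == "ventral" & x$hemisphere == "R")))
  invisible(x)
}

#' Number of ROIs in a parcellation
#' @param parcellation A `parcellation` object.
#' @return Integer ROI count.
#' @export
n_rois <- function(parcellation) nrow(parcellation)

# internal: map ROI labels to 1-based row indices, erroring on unknowns
roi_index <- function(parcellation, labels) {
  idx <- match(labels, parcellation$name)
  if (anyNA(idx)) {
    stop("unknown ROI label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}
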