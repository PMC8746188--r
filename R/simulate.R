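#' Ground truth for a synthetic stroke cohort
#'
#' Records the planted effects that the analysis stages are expected to
#' recover: functional-connectivity edges whose coherence drives behavior,
#' structural edges whose fiber count drives behavior, the slope of behavior
#' on total lesion volume, behavioral noise, and the strength with which
#' pairwise BOLD correlation tracks the structural backbone.
#'
#' @param planted_fc_edges Data frame with columns `i`, `j` (0-based ROI ids,
#'   `i < j`) and `beta` (AVC points per unit Pearson r), or `NULL`.
#' @param planted_sc_edges Same layout, `beta` in AVC points per fiber,
#'   or `NULL`.
#' @param planted_lesion_rois Data frame with columns `roi` (0-based ROI id)
#'   and `beta` (AVC points lost per unit damaged fraction), or `NULL`;
#'   plants region-specific lesion-symptom effects beyond the global
#'   lesion-volume slope.
#' @param lesion_behavior_coef Slope of behavioral decline per mm^3 of total
#'   lesion volume (positive = larger lesions, lower scores).
#' @param noise_sd Standard deviation of the behavioral noise (AVC points).
#' @param fc_sc_coupling Scalar in [0, 1]: how strongly an ROI's time course
#'   loads on the shared latent signal as a function of its structural
#'   connection strength (0 = functional and structural connectomes
#'   decoupled).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(planted_fc_edges = NULL, planted_sc_edges = NULL,
                         lesion_behavior_coef = 3e-05, noise_sd = 1,
                         fc_sc_coupling = 0.6, planted_lesion_rois = NULL) {
  check_edges <- function(e, what) {
    if (is.null(e)) return(NULL)
    if (!is.data.frame(e) || !all(c("i", "j", "beta") %in% names(e))) {
      stop(sprintf("`%s` must be a data frame with columns i, j, beta", what))
    }
    if (any(e$i >= e$j)) stop(sprintf("`%s` requires i < j", what))
    if (any(e$i < 0)) stop(sprintf("`%s` ROI ids must be >= 0", what))
    e
  }
  if (!is.null(planted_lesion_rois) &&
      (!is.data.frame(planted_lesion_rois) ||
       !all(c("roi", "beta") %in% names(planted_lesion_rois)))) {
    stop("`planted_lesion_rois` must be a data frame with columns roi, beta")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (fc_sc_coupling < 0 || fc_sc_coupling > 1) {
    stop("`fc_sc_coupling` must be in [0, 1]")
  }
  structure(list(
    planted_fc_edges = check_edges(planted_fc_edges, "planted_fc_edges"),
    planted_sc_edges = check_edges(planted_sc_edges, "planted_sc_edges"),
    planted_lesion_rois = planted_lesion_rois,
    lesion_behavior_coef = lesion_behavior_coef,
    noise_sd = noise_sd,
    fc_sc_coupling = fc_sc_coupling
  ), class = "ground_truth")
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe the emulated study population: 97 left-hemisphere
#' chronic stroke subjects on a 108-ROI dual-stream parcellation, 427
#' resting-state volumes at TR = 1.65 s.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_dorsal_left,n_ventral_per_hemi Parcellation counts.
#' @param n_timepoints Number of BOLD samples per subject.
#' @param tr Sampling interval in seconds.
#' @param truth A [ground_truth()] object.
#' @param fiber_meanlog,fiber_sdlog Lognormal parameters of baseline fiber
#'   counts before lesion suppression.
#' @param avc_baseline,ss_baseline Behavioral intercepts (score of an
#'   unlesioned subject before noise), on the 0-10 AVC and 0-20
#'   Spontaneous Speech scales.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 97, n_dorsal_left = 26,
                          n_ventral_per_hemi = 41, n_timepoints = 427,
                          tr = 1.65, truth = ground_truth(),
                          fiber_meanlog = 4, fiber_sdlog = 1,
                          avc_baseline = 8.5, ss_baseline = 17) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  if (n_timepoints < 3) stop("`n_timepoints` must be >= 3")
  if (tr <= 0) stop("`tr` must be > 0")
  if (!inherits(truth, "ground_truth")) stop("`truth` must be a ground_truth")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_dorsal_left = as.integer(n_dorsal_left),
    n_ventral_per_hemi = as.integer(n_ventral_per_hemi),
    n_timepoints = as.integer(n_timepoints),
    tr = tr, truth = truth,
    fiber_meanlog = fiber_meanlog, fiber_sdlog = fiber_sdlog,
    avc_baseline = avc_baseline, ss_baseline = ss_baseline
  ), class = "cohort_config")
}

# Share of variance a planted edge's private latent can contribute at u = 1.
# Fixed property of the generative model, not a tuning knob.
PLANTED_SHARE <- 0.5

#' Across-subject standard deviation of a planted edge's Pearson r
#'
#' Under the generative model a planted edge's correlation is
#' `PLANTED_SHARE * u` with `u ~ Uniform(0, 1)` per subject, plus sampling
#' noise of variance ~ 1/T in the empirical correlation. Used to convert a
#' target statistical power into a behavioral effect size.
#'
#' @param n_timepoints Number of BOLD samples.
#' @return Theoretical standard deviation of the planted edge's measured r.
#' @export
planted_edge_sd <- function(n_timepoints) {
  sqrt(PLANTED_SHARE^2 / 12 + 1 / n_timepoints)
}

#' Behavioral effect size for a target familywise power
#'
#' Computes the slope `beta` of behavior on a planted edge value such that
#' the edge's GLM statistic exceeds a Bonferroni-style familywise threshold
#' with at least the requested power, assuming `y = beta * e + noise` with
#' `sd(e) = sd_edge`, `sd(noise) = sd_noise`, and a mass-univariate test over
#' `n_features` features at level `alpha`.
#'
#' @param n Number of subjects.
#' @param n_features Number of features tested.
#' @param sd_edge Across-subject SD of the planted feature.
#' @param sd_noise SD of everything else in the behavioral score.
#' @param alpha Familywise error level.
#' @param power Target power.
#' @return The required slope `beta`.
#' @export
planted_beta_for_power <- function(n, n_features, sd_edge, sd_noise,
                                   alpha = 0.05, power = 0.95) {
  z_crit <- stats::qnorm(1 - alpha / (2 * n_features))
  ncp <- z_crit + stats::qnorm(power)
  f <- ncp / sqrt(n - 2)
  rho <- f / sqrt(1 + f^2)
  rho * sd_noise / (sd_edge * sqrt(1 - rho^2))
}

#' Calibrate a planted-edge effect size from the generative model
#'
#' Power analysis for the planted-edge recovery design. The partial
#' correlation a planted edge attains in the structural-residualized
#' analysis is diluted by (i) the edge's base coupling variance (driven by
#' the structural backbone, and regressed out with it) and (ii) sampling
#' noise in the empirical correlation. This helper estimates those nuisance
#' moments by simulating a pilot cohort from the same generative
#' configuration *without* any planted effect, then solves analytically for
#' the behavioral slope `beta` that yields the requested familywise power at
#' a Bonferroni-style threshold. The structural-residualized analysis is the
#' harder of the covariate modes, so the returned `beta` meets the target in
#' both.
#'
#' @param config A [cohort_config()] describing the target experiment
#'   (its `truth` is used with planted edges stripped).
#' @param edge Length-2 integer vector: the (i, j) ROI ids (0-based, i < j)
#'   of the edge to be planted.
#' @param alpha Familywise error level.
#' @param power Target power.
#' @param pilot_n Pilot cohort size for moment estimation.
#' @param pilot_seed Seed of the pilot cohort.
#' @return List with `beta`, the target partial correlation `rho`, and the
#'   estimated moments (`base_mean`, `var_edge`, `var_edge_res`,
#'   `var_planted`).
#' @export
calibrate_planted_beta <- function(config, edge, alpha = 0.05, power = 0.95,
                                   pilot_n = 200, pilot_seed = 424242) {
  stopifnot(inherits(config, "cohort_config"))
  t0 <- config$truth
  pilot_truth <- ground_truth(NULL, NULL, t0$lesion_behavior_coef,
                              t0$noise_sd, t0$fc_sc_coupling)
  pcfg <- config
  pcfg$n_subjects <- as.integer(pilot_n)
  pcfg$truth <- pilot_truth
  pilot <- generate_cohort(pcfg, seed = pilot_seed)
  map <- edge_index_map(pilot$parcellation)
  target <- which(map$i == edge[1] & map$j == edge[2])
  if (length(target) != 1) stop("edge not found in the parcellation")
  fc <- fc_edge_matrix(pilot, map)
  sc <- sc_edge_matrix(pilot, map)
  e0 <- fc[, target]
  e0r <- sc_residualize_fc(fc, sc)[, target]

  c0 <- mean(e0)                  # base coupling level of this edge
  vb <- stats::var(e0)            # base + sampling variance
  vbr <- stats::var(e0r)          # after structural residualization
  vp <- (PLANTED_SHARE * (1 - c0))^2 / 12   # planted loading u ~ U(0,1)

  n_edges <- nrow(map)
  n <- config$n_subjects
  z_crit <- stats::qnorm(1 - alpha / (2 * n_edges))
  ncp <- z_crit + stats::qnorm(power)
  f <- ncp / sqrt(n - 3)
  rho <- f / sqrt(1 + f^2)

  a <- vp + vbr                   # variance retained after residualization
  btot <- vp + vb                 # total edge variance feeding behavior
  denom <- a - rho^2 * btot
  if (denom <= 0) stop("requested power unattainable in this configuration")
  beta <- rho * t0$noise_sd / sqrt(denom)
  list(beta = beta, rho = rho, base_mean = c0, var_edge = vb,
       var_edge_res = vbr, var_planted = vp)
}

# restore the caller's RNG state on exit
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a single stroke subject
#'
#' Generative model: (1) a left-lateralized lesion assigns each left ROI a
#' damaged fraction; (2) baseline fiber counts are drawn from a rounded
#' lognormal and suppressed multiplicatively by the two endpoint lesion
#' loads; (3) ROI time courses load on a shared latent signal with weight
#' proportional to structural connection strength (`fc_sc_coupling`), plus
#' extra private coherence on planted functional edges; (4) behavior is
#' linear in total lesion volume and planted edge values plus Gaussian
#' noise, then discretized into WAB-R subtests and truncated to legal
#' ranges.
#'
#' @param parcellation A [make_parcellation()] object.
#' @param truth A [ground_truth()] object.
#' @param config A [cohort_config()] (supplies time-series length, TR,
#'   fiber-count distribution and behavioral baselines).
#' @param seed Integer seed; identical seeds give identical records.
#' @return A `subject_record` list with fields `lesion_load`,
#'   `total_lesion_volume`, `structural`, `roi_timecourses`, `tr`,
#'   `behavior`, and optionally `fc` (precomputed connectome) and
#'   `lesion_mask`.
#' @export
simulate_subject <- function(parcellation, truth, config, seed) {
  with_seed(seed, {
    R <- n_rois(parcellation)
    left <- parcellation$hemisphere == "L"

    # lesion: per-subject extent, per-ROI thinning, left hemisphere only
    extent <- stats::rbeta(1, 2, 4)
    lesion_load <- numeric(R)
    lesion_load[left] <- extent * stats::rbeta(sum(left), 0.6, 1.8)
    total_lesion_volume <- sum(lesion_load * parcellation$volume_mm3)

    # structural connectome: lognormal baseline, lesion suppression
    base <- matrix(0, R, R)
    ut <- upper.tri(base)
    base[ut] <- stats::rlnorm(sum(ut), config$fiber_meanlog, config$fiber_sdlog)
    base <- base + t(base)
    suppress <- outer(1 - lesion_load, 1 - lesion_load)
    structural <- round(base * suppress)
    diag(structural) <- 0

    # time courses: ROI signals are linear mixtures of shared latents whose
    # mixing weights follow the structural backbone. Target correlation
    # C_ij = coupling * S_ij / (S_ij + s0) (saturating in fiber count, so
    # expected pairwise r increases with fiber count), projected to the
    # nearest PSD correlation matrix by eigenvalue clipping.
    TT <- config$n_timepoints
    ut_vals <- structural[ut]
    s0 <- stats::median(ut_vals[ut_vals > 0])
    if (!is.finite(s0) || s0 <= 0) s0 <- 1
    C <- truth$fc_sc_coupling * structural / (structural + s0)
    diag(C) <- 1
    ee <- eigen(C, symmetric = TRUE)
    L <- ee$vectors %*% (sqrt(pmax(ee$values, 1e-06)) * t(ee$vectors))
    L <- L / sqrt(rowSums(L^2))
    x <- L %*% matrix(stats::rnorm(R * TT), R, TT)   # ROI x time

    # planted coherence: mix a private latent into both endpoints with
    # per-subject loading u ~ U(0,1), adding ~ PLANTED_SHARE * u to that
    # edge's correlation independently of structure
    pe <- truth$planted_fc_edges
    planted_u <- numeric(if (is.null(pe)) 0 else nrow(pe))
    if (!is.null(pe) && nrow(pe) > 0) {
      for (k in seq_len(nrow(pe))) {
        u <- stats::runif(1)
        planted_u[k] <- u
        h <- stats::rnorm(TT)
        v <- sqrt(PLANTED_SHARE * u)
        for (node in c(pe$i[k], pe$j[k]) + 1L) {
          x[node, ] <- sqrt(1 - v^2) * x[node, ] + v * h
        }
      }
    }

    # behavior: linear model on lesion volume and planted edge values
    avc_lin <- config$avc_baseline -
      truth$lesion_behavior_coef * total_lesion_volume
    if (!is.null(pe) && nrow(pe) > 0) {
      for (k in seq_len(nrow(pe))) {
        r_e <- stats::cor(x[pe$i[k] + 1L, ], x[pe$j[k] + 1L, ])
        avc_lin <- avc_lin + pe$beta[k] * r_e
      }
    }
    se <- truth$planted_sc_edges
    if (!is.null(se) && nrow(se) > 0) {
      for (k in seq_len(nrow(se))) {
        avc_lin <- avc_lin + se$beta[k] * structural[se$i[k] + 1L, se$j[k] + 1L]
      }
    }
    pl <- truth$planted_lesion_rois
    if (!is.null(pl) && nrow(pl) > 0) {
      avc_lin <- avc_lin + sum(pl$beta * lesion_load[pl$roi + 1L])
    }
    avc_lin <- avc_lin + stats::rnorm(1, 0, truth$noise_sd)
    avc_lin <- min(max(avc_lin, 0), 10)

    # discretize into the three comprehension subtests (integer points)
    total200 <- round(avc_lin * 20)
    yes_no <- min(round(total200 * 60 / 200), 60)
    word_recognition <- min(round(total200 * 60 / 200), 60)
    seq_commands <- min(max(total200 - yes_no - word_recognition, 0), 80)

    ss_lin <- config$ss_baseline -
      2 * truth$lesion_behavior_coef * total_lesion_volume +
      stats::rnorm(1, 0, 2 * truth$noise_sd)
    ss_lin <- min(max(ss_lin, 0), 20)
    info_content <- min(max(round(ss_lin / 2), 0), 10)
    fluency <- min(max(round(ss_lin) - info_content, 0), 10)

    behavior <- list(
      yes_no = yes_no,
      word_recognition = word_recognition,
      sequential_commands = seq_commands,
      avc = avc_score(yes_no, word_recognition, seq_commands),
      info_content = info_content,
      fluency = fluency,
      spontaneous_speech = spontaneous_speech_score(info_content, fluency)
    )

    structure(list(
      lesion_load = lesion_load,
      total_lesion_volume = total_lesion_volume,
      lesion_mask = NULL,
      structural = structural,
      roi_timecourses = x,
      tr = config$tr,
      fc = NULL,
      behavior = behavior,
      planted_u = planted_u
    ), class = "subject_record")
  })
}

#' Generate a synthetic stroke cohort
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed. Per-subject seeds are derived
#'   deterministically from it (counter-based), so regeneration is
#'   bit-identical and independent of generation order.
#' @return A `cohort` list with `parcellation`, `subjects`, `ground_truth`,
#'   `seed` and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 5, n_dorsal_left = 2,
#'                                      n_ventral_per_hemi = 3,
#'                                      n_timepoints = 50), seed = 1)
#' length(coh$subjects)
#' @export
generate_cohort <- function(config, seed) {
  if (!inherits(config, "cohort_config")) stop("`config` must be a cohort_config")
  if (config$n_subjects < 2) stop("`n_subjects` must be >= 2")
  parcellation <- make_parcellation(config$n_dorsal_left,
                                    config$n_ventral_per_hemi)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(parcellation, config$truth, config,
                     seed = subject_seed(seed, i))
  })
  structure(list(
    parcellation = parcellation,
    subjects = subjects,
    ground_truth = config$truth,
    seed = as.integer(seed),
    config = config
  ), class = "cohort")
}

# counter-based per-subject seed, kept inside 32-bit integer range
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 1009) %% 2147483647)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d ROIs, seed %d\n",
              length(x$subjects), n_rois(x$parcellation), x$seed))
  invisible(x)
}

#' Extract a behavioral score vector from a cohort
#' @param cohort A `cohort`.
#' @param behavior One of "avc", "spontaneous_speech".
#' @return Numeric vector, one score per subject.
#' @export
behavior_vector <- function(cohort, behavior = c("avc", "spontaneous_speech")) {
  behavior <- match.arg(behavior)
  vapply(cohort$subjects, function(s) s$behavior[[behavior]], numeric(1))
}

#' Total lesion volumes of a cohort
#' @param cohort A `cohort`.
#' @return Numeric vector of mm^3 volumes.
#' @export
lesion_volume_vector <- function(cohort) {
  vapply(cohort$subjects, function(s) s$total_lesion_volume, numeric(1))
}

#' Per-ROI lesion-load matrix of a cohort
#' @param cohort A `cohort`.
#' @return subjects x ROI matrix of damaged fractions.
#' @export
lesion_load_matrix <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) s$lesion_load))
}
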