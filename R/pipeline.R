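#' Run configuration for the end-to-end pipeline
#'
#' @param input Either the string "synthetic" (a cohort is generated) or a
#'   path to a cohort directory written by [write_cohort()].
#' @param analyses List of analysis requests; each element is a list with
#'   `type` in `"region_lsm"`, `"structural"`, `"fc"` and optional fields
#'   `behavior`, `mode` (fc only: "LESION_VOLUME", "LESION_VOLUME_PLUS_SC",
#'   "CRITICAL_AREAS_PLUS_SC"), `critical_rois`, `min_damage_subjects`.
#' @param output_dir Where result files are written.
#' @param seed Master seed (mandatory for synthetic input).
#' @param n_perm Permutation count applied to every analysis.
#' @param cohort Optional [cohort_config()] overrides for synthetic input
#'   (a named list of `cohort_config` arguments).
#' @return A `run_config` list.
#' @export
run_config <- function(input = "synthetic", analyses = list(),
                       output_dir = "connlsm_out", seed = NULL,
                       n_perm = 5000, cohort = list()) {
  if (identical(input, "synthetic") && is.null(seed)) {
    stop("`seed` is mandatory for synthetic runs")
  }
  if (!identical(input, "synthetic") && !dir.exists(input)) {
    stop("cohort directory does not exist: ", input)
  }
  structure(list(input = input, analyses = analyses,
                 output_dir = output_dir, seed = seed,
                 n_perm = as.integer(n_perm), cohort = cohort),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  run_config(
    input = if (is.null(cfg$input)) "synthetic" else cfg$input,
    analyses = if (is.null(cfg$analyses)) list() else cfg$analyses,
    output_dir = if (is.null(cfg$output_dir)) "connlsm_out" else cfg$output_dir,
    seed = cfg$seed,
    n_perm = if (is.null(cfg$n_perm)) 5000 else cfg$n_perm,
    cohort = if (is.null(cfg$cohort)) list() else cfg$cohort
  )
}

# one analysis request -> result files; returns a manifest fragment
run_one_analysis <- function(cohort, req, idx, out_dir, n_perm, seed) {
  type <- req$type
  behavior <- if (is.null(req$behavior)) "avc" else req$behavior
  pcfg <- permutation_config(n_perm = n_perm, seed = seed + idx)
  tag <- sprintf("%02d_%s_%s", idx, type,
                 if (type == "fc") tolower(req$mode %||% "LESION_VOLUME")
                 else behavior)

  if (type == "region_lsm") {
    mds <- req$min_damage_subjects %||% 10
    res <- region_lsm(cohort, behavior, pcfg, min_damage_subjects = mds)
    findings <- NULL
  } else if (type == "structural") {
    out <- structural_edge_analysis(cohort, behavior, pcfg)
    res <- out$result; findings <- out$findings
  } else if (type == "fc") {
    mode <- req$mode %||% "LESION_VOLUME"
    acfg <- analysis_config(behavior = behavior, covariate_mode = mode,
                            permutation = pcfg,
                            critical_rois = unlist(req$critical_rois))
    out <- functional_edge_analysis(cohort, acfg)
    res <- out$result; findings <- out$findings
  } else {
    stop("unknown analysis type: ", type)
  }

  z_csv <- file.path(out_dir, paste0(tag, "_z.csv"))
  prov_json <- file.path(out_dir, paste0(tag, "_provenance.json"))
  write_glm_result(res, z_csv, prov_json)
  files <- c(z_csv, prov_json)
  if (!is.null(findings)) {
    surv_csv <- file.path(out_dir, paste0(tag, "_survivors.csv"))
    utils::write.csv(findings, surv_csv, row.names = FALSE)
    files <- c(files, surv_csv)
  }
  list(tag = tag, type = type, behavior = behavior,
       n_survivors = sum(res$survivors),
       fwe_threshold = res$fwe_threshold,
       files = basename(files),
       hashes = unname(tools::md5sum(files)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured pipeline run
#'
#' Generates or loads the cohort, runs every configured analysis, writes
#' per-analysis z-vectors, survivor tables and provenance, and a run
#' manifest. Re-running an identical config reproduces identical output
#' hashes.
#'
#' @param config A [run_config()] (or path to its JSON file).
#' @return The run manifest (invisibly also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (identical(config$input, "synthetic")) {
    ccfg <- do.call(cohort_config, config$cohort)
    cohort <- generate_cohort(ccfg, seed = config$seed)
  } else {
    cohort <- read_cohort(config$input)
  }

  seed <- config$seed %||% cohort$seed %||% 1L
  stages <- lapply(seq_along(config$analyses), function(i) {
    run_one_analysis(cohort, config$analyses[[i]], i, config$output_dir,
                     config$n_perm, seed)
  })

  manifest <- list(
    config = unclass(config),
    seed = seed,
    n_subjects = length(cohort$subjects),
    n_rois = n_rois(cohort$parcellation),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort directory), `analyze`
#' (run a pipeline from a JSON config), `report` (summarize survivors from a
#' manifest). Example:
#' \preformatted{Rscript -e 'connlsm::connlsm_cli()' analyze --config run.json}
#'
#' @param args Character vector of CLI arguments (defaults to the
#'   command line).
#' @return Exit status (0 on success), invisibly.
#' @export
connlsm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: connlsm <simulate|analyze|report> [options]",
    "  simulate --out DIR --seed N [--subjects N] [--dorsal N] [--ventral N]",
    "  analyze  --config FILE [--seed N] [--n-perm N] [--out DIR]",
    "  report   --dir DIR", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  if (cmd == "simulate") {
    out <- opt("out"); seed <- as.integer(opt("seed"))
    if (is.null(out) || is.na(seed)) { message(usage); return(invisible(1L)) }
    cfg <- cohort_config(
      n_subjects = as.integer(opt("subjects", 97)),
      n_dorsal_left = as.integer(opt("dorsal", 26)),
      n_ventral_per_hemi = as.integer(opt("ventral", 41)))
    write_cohort(generate_cohort(cfg, seed), out)
    message("cohort written to ", out)
    return(invisible(0L))
  }
  if (cmd == "analyze") {
    cfg_path <- opt("config")
    if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
    cfg <- read_run_config(cfg_path)
    seed <- opt("seed"); if (!is.null(seed)) cfg$seed <- as.integer(seed)
    np <- opt("n-perm"); if (!is.null(np)) cfg$n_perm <- as.integer(np)
    outd <- opt("out"); if (!is.null(outd)) cfg$output_dir <- outd
    manifest <- tryCatch(run_pipeline(cfg), error = function(e) {
      message("pipeline failed: ", conditionMessage(e)); NULL
    })
    if (is.null(manifest)) return(invisible(1L))
    for (st in manifest$stages) {
      message(sprintf("%s: %d survivor(s), FWE threshold %.3f",
                      st$tag, st$n_survivors, st$fwe_threshold))
    }
    return(invisible(0L))
  }
  if (cmd == "report") {
    d <- opt("dir")
    if (is.null(d)) { message(usage); return(invisible(1L)) }
    manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                    simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
    for (st in manifest$stages) {
      message(sprintf("%s: %d survivor(s), FWE threshold %.3f",
                      st$tag, st$n_survivors, st$fwe_threshold))
    }
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
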