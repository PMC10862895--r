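# Cross-module report assembly and the end-to-end pipeline driver.

ss_version <- function() as.character(utils::packageVersion("switchscope"))

canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Validate a run configuration
#'
#' Configurations are plain lists (usually read from JSON). Recognized
#' thresholds are range-checked; referenced input paths must exist at
#' validation time. Defaults are echoed to stderr so no threshold is applied
#' silently.
#'
#' @param config a list with optional elements `analyses` (character subset of
#'   `"melt"`, `"kinetics"`, `"std"`, `"traj"`), `seed`, `out_dir`, `inputs`
#'   (named list of file paths), and threshold overrides
#'   (`classification_delta_tm`, `fingerprint_ref_tol`, `hbond_max_ha`,
#'   `hbond_min_angle`, `proximity_radius`, `persistence_thresholds`).
#' @param quiet suppress the default echo.
#' @return the completed config (class `run_config`), invisibly usable
#'   downstream.
#' @export
validate_run_config <- function(config = list(), quiet = FALSE) {
  defaults <- list(analyses = c("melt", "kinetics", "std", "traj"),
                   seed = 42L, out_dir = "switchscope-out",
                   inputs = list(),
                   classification_delta_tm = NULL,  # NULL = adaptive rule
                   fingerprint_ref_tol = 0.02,
                   hbond_max_ha = 2.4, hbond_min_angle = 120,
                   proximity_radius = 6,
                   persistence_thresholds = c(0.1, 0.25, 0.5, 0.75))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    ss_config_error(paste("unknown config keys:",
                          paste(unknown, collapse = ", ")))
  bad <- setdiff(cfg$analyses, c("melt", "kinetics", "std", "traj"))
  if (length(bad))
    ss_config_error(paste("unknown analyses:", paste(bad, collapse = ", ")))
  if (cfg$fingerprint_ref_tol < 0 || cfg$fingerprint_ref_tol >= 0.5)
    ss_config_error("fingerprint_ref_tol must lie in [0, 0.5)")
  if (cfg$hbond_max_ha <= 0 || cfg$hbond_min_angle <= 0 ||
      cfg$hbond_min_angle > 180)
    ss_config_error("H-bond criteria out of range")
  if (cfg$proximity_radius <= 0)
    ss_config_error("proximity_radius must be > 0")
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) ss_config_error(sprintf("input path missing: %s", p))
  # hash covers the scientific parameters, not the output location
  cfg$hash <- fnv1a32(canonical_json(
    cfg[setdiff(names(cfg), c("hash", "out_dir"))]))
  if (!quiet)
    message(sprintf(
      "run config: analyses=[%s] seed=%d ref_tol=%g hbond=%g A/%g deg radius=%g A hash=%s",
      paste(cfg$analyses, collapse = ","), cfg$seed, cfg$fingerprint_ref_tol,
      cfg$hbond_max_ha, cfg$hbond_min_angle, cfg$proximity_radius, cfg$hash))
  structure(cfg, class = "run_config")
}

#' Assemble a per-variant dossier
#'
#' Merges heterogeneous stage outputs for one variant into a single
#' self-describing document. Absent stages are marked `"absent"`, never
#' imputed. Conflicting variant labels, or two blocks for the same stage,
#' are a merge error.
#'
#' @param results named list; recognized names are `thermal` (list with
#'   `gdp`/`gtp` [summarize_tm()] results and optionally a
#'   [classify_thermal_phenotype()] result as `phenotype`), `kinetics`
#'   (a `kinetic_fit`), `std` (named list of `std_fingerprint`s per
#'   nucleotide), `traj` (any trajectory read-outs). Each element may carry a
#'   `variant` attribute or `$meta$variant`; all present labels must agree.
#' @param variant variant label; defaults to the one found in `results`.
#' @param config optional `run_config` for the provenance block.
#' @return a list of class `variant_dossier`, serializable with
#'   [jsonlite::write_json()].
#' @export
assemble_dossier <- function(results, variant = NULL, config = NULL) {
  if (!length(results)) ss_merge_error("no stage outputs supplied")
  if (anyDuplicated(names(results)))
    ss_merge_error(sprintf(
      "duplicate stage blocks: %s",
      paste(unique(names(results)[duplicated(names(results))]), collapse = ", ")))
  label_of <- function(x) {
    v <- attr(x, "variant", exact = TRUE)
    if (is.null(v) && is.list(x) && !is.null(x$meta$variant)) v <- x$meta$variant
    v
  }
  labels <- unique(unlist(lapply(results, label_of)))
  if (length(labels) > 1L)
    ss_merge_error(paste("conflicting variant labels:",
                         paste(labels, collapse = " vs ")))
  if (is.null(variant)) variant <- if (length(labels)) labels else "unknown"
  stages <- c("thermal", "kinetics", "std", "traj")
  doc <- stats::setNames(lapply(stages, function(s)
    if (!is.null(results[[s]])) results[[s]] else "absent"), stages)
  doc$variant <- variant
  doc$provenance <- list(
    package_version = ss_version(),
    config_hash = if (!is.null(config)) config$hash else NA_character_,
    seed = if (!is.null(config)) config$seed else NA_integer_)
  structure(doc, class = "variant_dossier")
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates seeded synthetic inputs for every selected analysis, runs the
#' corresponding fits/analyses, and writes all reports under
#' `config$out_dir`: melting CSV + thermal JSON, kinetics JSON, STD
#' fingerprint CSV/JSON, trajectory occupancy/RMSF/proximity CSV/JSON, and a
#' combined dossier JSON. Output is deterministic given config and seed
#' (byte-identical on re-run). On a stage error the completed stages are
#' preserved and the failure is summarized; the function then signals the
#' error.
#'
#' @param config a list or [validate_run_config()] result.
#' @return invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_run_config(config)
  if (!length(cfg$analyses)) {
    warning("empty analysis selection: nothing to do")
    return(invisible(character()))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit_json <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    x$provenance <- list(config_hash = cfg$hash, seed = cfg$seed,
                         package_version = ss_version())
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    written <<- c(written, path)
  }
  emit_csv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.csv(cbind(df, config_hash = cfg$hash), path,
                     row.names = FALSE)
    written <<- c(written, path)
  }
  results <- list()
  failed <- NULL

  stage <- function(name, fun) {
    if (!is.null(failed)) return()
    message(sprintf("[stage %s] starting (seed %d)", name, cfg$seed))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      message(sprintf("[stage %s] FAILED: %s", name, conditionMessage(e)))
      failed <<- e
      FALSE
    })
    if (ok) message(sprintf("[stage %s] done", name))
  }

  if ("melt" %in% cfg$analyses) stage("melt", function() {
    # WT GDP/GTP pair at the canonical ~9 degC separation, in triplicate
    mk <- function(tm, nuc, k) generate_melting_curves(melt_gen_spec(
      tm_true = tm, slope_true = 2, noise_sd = 0.02, replicates = 3,
      seed = derive_seed(cfg$seed, k), nucleotide = nuc))
    curves <- list(gdp = mk(56.2, "GDP", 1), gtp = mk(65.2, "GTPgS", 2))
    write_melting_csv(c(curves$gdp, curves$gtp),
                      file.path(cfg$out_dir, "melting_curves.csv"))
    written <<- c(written, file.path(cfg$out_dir, "melting_curves.csv"))
    sums <- lapply(curves, function(cs)
      summarize_tm(lapply(cs, fit_melting_curve)))
    phen <- classify_thermal_phenotype(sums$gdp, sums$gtp, sums$gdp, sums$gtp,
                                       threshold = cfg$classification_delta_tm)
    results$thermal <<- list(
      gdp = unclass(sums$gdp), gtp = unclass(sums$gtp),
      phenotype = list(delta_tm = phen$delta_tm, category = phen$category,
                       threshold = phen$threshold))
    emit_json(list(thermal = results$thermal), "thermal_report.json")
  })

  if ("kinetics" %in% cfg$analyses) stage("kinetics", function() {
    trace <- generate_kinetic_trace(kinetic_gen_spec(
      y0 = 100, plateau = 300, k_true = 0.05, noise_sd = 2,
      seed = derive_seed(cfg$seed, 3)))
    fit <- fit_one_phase_association(trace)
    results$kinetics <<- list(y0 = fit$y0, plateau = fit$plateau, k = fit$k,
                              half_time = fit$half_time,
                              converged = fit$converged,
                              time_unit = fit$meta$time_unit)
    emit_json(list(kinetics = results$kinetics), "kinetics_report.json")
  })

  if ("std" %in% cfg$analyses) stage("std", function() {
    tab <- generate_std_table(std_gen_spec(
      epitope_weights = c(a = 0.02, b = 0.03, c = 0.025, d = 0.015),
      seed = derive_seed(cfg$seed, 4)))
    fp <- std_fingerprint_from_table(tab, ref_tol = cfg$fingerprint_ref_tol)
    emit_csv(as.data.frame(fp), "std_fingerprint.csv")
    results$std <<- list(GDP = as.data.frame(fp))
    emit_json(list(fingerprint = as.data.frame(fp)), "std_report.json")
  })

  if ("traj" %in% cfg$analyses) stage("traj", function() {
    topo <- toy_topology(c(52L, 173L, 201L, 205L, 230L),
                         proton_labels = c("a", "b"))
    spec <- toy_trajectory_spec(
      topo, hbond_schedule = c("205-230" = 0.9),
      proximity_schedule = c("a:52" = 0.95, "b:173" = 0.7, "b:201" = 0.25),
      jitter_sd = 0.1, n_frames = 50, n_replicas = 5,
      assignment = "bernoulli", seed = derive_seed(cfg$seed, 5))
    trajs <- generate_toy_trajectories(spec)
    crit <- hbond_criteria(cfg$hbond_max_ha, cfg$hbond_min_angle)
    regions <- region_map(list(switch1 = 197:207, switch2 = 225:235,
                               switch3 = 252:268))
    occ <- hbond_occupancy(trajs[[1]], regions, crit)
    emit_csv(as.data.frame(persistence_mask(occ, cfg$persistence_thresholds)),
             "hbond_occupancy.csv")
    rmsf <- compute_rmsf(trajs[[1]], selection = c("N", "O"))
    emit_csv(as.data.frame(rmsf), "rmsf.csv")
    profs <- lapply(trajs, proton_proximity_profile,
                    radius = cfg$proximity_radius)
    agg <- lapply(stats::setNames(nm = names(profs[[1]])), function(lab)
      aggregate_replicas(lapply(profs, `[[`, lab)))
    prox_df <- do.call(rbind, lapply(names(agg), function(lab)
      cbind(proton = lab, as.data.frame(agg[[lab]]))))
    emit_csv(prox_df, "proximity.csv")
    results$traj <<- list(proximity = prox_df)
  })

  if (is.null(failed)) stage("dossier", function() {
    doss <- assemble_dossier(results, variant = "WT", config = cfg)
    emit_json(unclass(doss), "dossier.json")
  })

  if (!is.null(failed)) {
    message(sprintf("pipeline failed after %d artifact(s): %s",
                    length(written), conditionMessage(failed)))
    stop(failed)
  }
  invisible(written)
}
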