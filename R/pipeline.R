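# Pipeline orchestration: the eight heterogeneity-mitigation scenarios
# (extract -> harmonize -> phenotype -> evaluate), demo fixture presets,
# and a small CLI. All run outputs are CSV/JSON; a run is a pure function
# of (config, seed).

#' The heterogeneity-mitigation scenario table
#'
#' Eight scenarios: no mitigation ("original"); feature extraction with a
#' fixed physical offset (3 or 5 mm) followed by harmonization by voxel
#' spacing parameters (1A/1B), by image acquisition parameters (2A/2B), or
#' by both (4A/4B); and resampling every image to the dataset-minimum voxel
#' spacing followed by harmonization by acquisition parameters (3).
#'
#' @return data.frame with columns `scenario`, `offset_mm` (NA where
#'   resampling replaces the physical offset), `resample`, `batch_set`
#'   (one of "none", "spacing", "acquisition", "both").
#' @export
scenario_table <- function() {
  data.frame(
    scenario = c("original", "1A", "1B", "2A", "2B", "3", "4A", "4B"),
    offset_mm = c(NA, 3, 5, 3, 5, NA, 3, 5),
    resample = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    batch_set = c("none", "spacing", "spacing", "acquisition",
                  "acquisition", "acquisition", "both", "both"),
    stringsAsFactors = FALSE)
}

#' Build a run configuration
#'
#' @param features_csv path to a precomputed patient x feature CSV
#'   (feature-only mode), or NULL.
#' @param manifest_csv path to an imaging manifest (from
#'   [write_image_cohort()]), or NULL. Exactly one of the two inputs must
#'   be given.
#' @param cohort_csv path to the cohort CSV (batch variables, covariates,
#'   time, event).
#' @param scenarios scenario ids to run (subset of [scenario_table()]).
#' @param spacing_vars,acquisition_vars cohort columns used as batch
#'   variables for the "spacing" and "acquisition" sets.
#' @param covariate_cols protected clinical covariate columns.
#' @param groupings named list; each element `list(variable =, threshold =)`
#'   or `list(variable =)` for a 2-level categorical split.
#' @param alpha AD significance level.
#' @param n_bins discretization bins.
#' @param seed master seed.
#' @param k_range,n_subsamples,subsample_fraction,n_sim consensus/SigClust
#'   settings.
#' @param output_dir where run artifacts are written.
#' @param group_local cluster phenotypes within each batch group (default)
#'   rather than on the whole cohort.
#' @return list of class `run_config` (validated, JSON-serializable).
#' @export
run_config <- function(features_csv = NULL, manifest_csv = NULL,
                       cohort_csv = NULL,
                       scenarios = scenario_table()$scenario,
                       spacing_vars = c("pixel_spacing_group",
                                        "slice_thickness_group"),
                       acquisition_vars = c("contrast", "kernel"),
                       covariate_cols = "covar1",
                       groupings = NULL,
                       alpha = 0.05, n_bins = 32, seed = 1,
                       k_range = 2:6, n_subsamples = 100,
                       subsample_fraction = 0.8, n_sim = 200,
                       output_dir = tempfile("radbatch_run_"),
                       group_local = TRUE) {
  if (is.null(features_csv) == is.null(manifest_csv))
    stop("give exactly one of 'features_csv' or 'manifest_csv'")
  if (is.null(cohort_csv)) stop("'cohort_csv' is required")
  bad <- setdiff(scenarios, scenario_table()$scenario)
  if (length(bad)) stop("unknown scenario id(s): ", paste(bad, collapse = ", "))
  structure(list(features_csv = features_csv, manifest_csv = manifest_csv,
                 cohort_csv = cohort_csv, scenarios = scenarios,
                 spacing_vars = spacing_vars,
                 acquisition_vars = acquisition_vars,
                 covariate_cols = covariate_cols, groupings = groupings,
                 alpha = alpha, n_bins = n_bins, seed = seed,
                 k_range = k_range, n_subsamples = n_subsamples,
                 subsample_fraction = subsample_fraction, n_sim = n_sim,
                 output_dir = output_dir, group_local = group_local),
            class = "run_config")
}

#' Read a JSON run configuration file
#'
#' @param path JSON file whose keys mirror the [run_config()] arguments.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$groupings <- lapply(raw$groupings, as.list)
  do.call(run_config, raw)
}

load_run_inputs <- function(config) {
  cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  for (v in c(config$spacing_vars, config$acquisition_vars))
    if (v %in% names(cohort)) cohort[[v]] <- factor(cohort[[v]])
  images <- manifest_dir <- NULL
  features <- NULL
  if (!is.null(config$features_csv)) {
    features <- read_feature_table(config$features_csv)
    features <- features[match(cohort$patient_id, rownames(features)), ,
                         drop = FALSE]
  } else {
    manifest <- utils::read.csv(config$manifest_csv,
                                stringsAsFactors = FALSE)
    manifest_dir <- dirname(config$manifest_csv)
    manifest <- manifest[match(cohort$patient_id, manifest$patient_id), ]
    images <- lapply(seq_len(nrow(manifest)), function(i)
      read_voxel_image(file.path(manifest_dir, manifest$image[i]),
                       file.path(manifest_dir, manifest$mask[i])))
  }
  list(cohort = cohort, features = features, images = images)
}

batch_vars_for <- function(config, batch_set) {
  switch(batch_set,
         none = character(0),
         spacing = config$spacing_vars,
         acquisition = config$acquisition_vars,
         both = c(config$spacing_vars, config$acquisition_vars),
         stop("unknown batch set '", batch_set, "'"))
}

resolve_groupings <- function(config, cohort) {
  specs <- config$groupings
  if (is.null(specs)) {
    specs <- lapply(config$acquisition_vars, function(v) list(variable = v))
    names(specs) <- config$acquisition_vars
  }
  out <- lapply(specs, function(s)
    group_by_batch(cohort, s$variable, threshold = s$threshold))
  names(out) <- names(specs) %||%
    vapply(specs, `[[`, "", "variable")
  out
}

#' Run one heterogeneity-mitigation scenario
#'
#' Feature-only inputs skip the extraction stage (scenarios then differ
#' only through their harmonization batch sets). Imaging inputs are
#' optionally resampled to the dataset-minimum spacing (scenario 3) and
#' features are extracted with the scenario's physical offset. The stage
#' log records exactly which stages ran; "original" never invokes the
#' resampling or harmonization code paths.
#'
#' @param config a [run_config()].
#' @param scenario scenario id (row of [scenario_table()]).
#' @param inputs optional preloaded inputs (internal reuse by [run_all()]).
#' @return list of class `scenario_result`: `scenario`, `features`
#'   (post-mitigation table), `harmonization` (NULL for "original"),
#'   `phenotypes` (per grouping/group: labels, chosen k, top-split p),
#'   `stage_log`.
#' @export
run_scenario <- function(config, scenario, inputs = NULL) {
  spec <- scenario_table()
  spec <- spec[spec$scenario == scenario, ]
  if (nrow(spec) != 1) stop("unknown scenario '", scenario, "'")
  if (is.null(inputs)) inputs <- load_run_inputs(config)
  cohort <- inputs$cohort
  stage_log <- character(0)
  log_stage <- function(s) stage_log <<- c(stage_log, s)

  if (!is.null(inputs$features)) {
    features <- inputs$features
    log_stage("features:precomputed")
  } else {
    images <- inputs$images
    offset <- if (is.na(spec$offset_mm)) 3 else spec$offset_mm
    if (spec$resample) {
      target <- compute_min_spacing(images)
      images <- lapply(images, resample_image, target_spacing = target)
      log_stage(sprintf("resample:min_spacing=%s",
                        paste(signif(target, 3), collapse = "x")))
    }
    params <- extraction_params(offset_mm = offset, n_bins = config$n_bins)
    features <- extract_cohort_features(images, params,
                                        ids = cohort$patient_id)
    log_stage(sprintf("extract:offset_mm=%g", offset))
  }

  harmonization <- NULL
  vars <- batch_vars_for(config, spec$batch_set)
  if (length(vars)) {
    covars <- as.matrix(cohort[, config$covariate_cols, drop = FALSE])
    harmonization <- nested_combat(features, cohort[, vars, drop = FALSE],
                                   covariates = covars,
                                   alpha = config$alpha)
    features <- harmonization$features
    log_stage(sprintf("harmonize:%s", paste(vars, collapse = "+")))
  }

  groupings <- resolve_groupings(config, cohort)
  seeds <- derive_seeds(config$seed + match(scenario,
                                            scenario_table()$scenario),
                        length(groupings) * 4L)
  phenotypes <- list()
  si <- 0L
  for (gname in names(groupings)) {
    grouping <- groupings[[gname]]
    phenotypes[[gname]] <- list()
    for (gl in levels(grouping$groups)) {
      si <- si + 1L
      sel <- if (config$group_local) grouping$groups == gl
             else rep(TRUE, nrow(cohort))
      sub <- features[cohort$patient_id[sel], , drop = FALSE]
      k_eff <- config$k_range[config$k_range <= nrow(sub) - 1]
      if (!length(k_eff)) {
        warning("group ", gname, "/", gl, " too small to cluster; ",
                "single phenotype assigned")
        phenotypes[[gname]][[gl]] <- list(
          labels = stats::setNames(rep(1L, nrow(sub)), rownames(sub)),
          chosen_k = 1L, top_split_p = NA_real_)
        next
      }
      cons <- consensus_cluster(sub, k_range = k_eff,
                                n_subsamples = config$n_subsamples,
                                subsample_fraction = config$subsample_fraction,
                                seed = seeds[(si - 1L) %% length(seeds) + 1L],
                                n_sim = config$n_sim, alpha = config$alpha)
      phenotypes[[gname]][[gl]] <- list(
        labels = cons$labels, chosen_k = cons$chosen_k,
        top_split_p = if (!is.null(cons$split_p)) cons$split_p$p[1]
                      else NA_real_)
    }
  }
  log_stage("phenotype:consensus+sigclust")

  structure(list(scenario = scenario, features = features,
                 harmonization = harmonization, phenotypes = phenotypes,
                 groupings = groupings, stage_log = stage_log),
            class = "scenario_result")
}

#' Run every configured scenario and consolidate the reports
#'
#' Stage failures abort the failing scenario (logged) and the remaining
#' scenarios continue. Outputs under `config$output_dir`: per-scenario
#' feature tables, phenotype labels and stage logs; consolidated c-score,
#' NMI and top-split-p CSV tables; a JSON run manifest with the full
#' configuration and seeds.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `report` (a
#'   [build_report()] result), `split_p` (data.frame), `scenario_results`,
#'   `failures`, `output_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_run_inputs(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(); failures <- character(0)
  for (sc in config$scenarios) {
    res <- tryCatch(run_scenario(config, sc, inputs = inputs),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[sc] <- conditionMessage(res)
      message("scenario ", sc, " failed: ", conditionMessage(res))
      next
    }
    results[[sc]] <- res
    sdir <- file.path(config$output_dir, paste0("scenario-", sc))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(res$features, file.path(sdir, "features.csv"))
    writeLines(res$stage_log, file.path(sdir, "stage_log.txt"))
    if (!is.null(res$harmonization))
      write_harmonization_report(res$harmonization, sdir)
    lab_rows <- list()
    for (gname in names(res$phenotypes))
      for (gl in names(res$phenotypes[[gname]])) {
        ph <- res$phenotypes[[gname]][[gl]]
        lab_rows[[length(lab_rows) + 1L]] <- data.frame(
          variable = gname, group = gl,
          patient_id = names(ph$labels), phenotype = unname(ph$labels),
          stringsAsFactors = FALSE)
      }
    utils::write.csv(do.call(rbind, lab_rows),
                     file.path(sdir, "phenotypes.csv"), row.names = FALSE)
  }
  if (!length(results)) stop("every scenario failed")

  phenolists <- lapply(results, function(res)
    lapply(res$phenotypes, function(g) lapply(g, `[[`, "labels")))
  groupings <- results[[1]]$groupings
  reference <- if ("3" %in% names(results)) "3" else names(results)[1]
  report <- build_report(phenolists, inputs$cohort, groupings,
                         config$covariate_cols, reference = reference)

  split_rows <- list()
  for (sc in names(results))
    for (gname in names(results[[sc]]$phenotypes))
      for (gl in names(results[[sc]]$phenotypes[[gname]]))
        split_rows[[length(split_rows) + 1L]] <- data.frame(
          scenario = sc, variable = gname, group = gl,
          top_split_p = results[[sc]]$phenotypes[[gname]][[gl]]$top_split_p,
          chosen_k = results[[sc]]$phenotypes[[gname]][[gl]]$chosen_k,
          stringsAsFactors = FALSE)
  split_p <- do.call(rbind, split_rows)

  utils::write.csv(report$cscores, file.path(config$output_dir,
                                             "cscores.csv"),
                   row.names = FALSE)
  if (!is.null(report$nmi))
    utils::write.csv(report$nmi, file.path(config$output_dir, "nmi.csv"),
                     row.names = FALSE)
  utils::write.csv(split_p, file.path(config$output_dir, "split_p.csv"),
                   row.names = FALSE)
  manifest <- unclass(config)
  manifest$package_version <- as.character(utils::packageVersion("radbatch"))
  manifest$failures <- as.list(failures)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  structure(list(report = report, split_p = split_p,
                 scenario_results = results, failures = failures,
                 output_dir = config$output_dir),
            class = "run_result")
}

#' Generate an on-disk demo cohort
#'
#' Presets: `"feature-only-small"` (150 patients x 60 features, two batch
#' variables with planted location/scale effects, a planted 2-class
#' phenotype at 1.5 SD on 30% of features, survival outcomes);
#' `"imaging-small"` (60 synthetic NIfTI image/mask pairs on grids up to
#' 48^3 voxels with spacing/kernel/contrast batch levels); `"confounded"`
#' (the feature-only cohort with the phenotype-batch association and a
#' batch-grouping alignment used by the reproducibility experiment).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param dir output directory.
#' @return `dir`, invisibly; the directory contains `features.csv` (or
#'   NIfTI files plus `manifest.csv`) and `cohort.csv`.
#' @export
make_fixtures <- function(preset = c("feature-only-small", "imaging-small",
                                     "confounded"),
                          seed = 1, dir = tempfile("radbatch_fixture_")) {
  preset <- tryCatch(match.arg(preset), error = function(e)
    stop("unknown preset '", preset[1], "'; available: feature-only-small, ",
         "imaging-small, confounded"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (preset %in% c("feature-only-small", "confounded")) {
    sim <- simulate_confounded_cohort(
      seed = seed,
      confounding_or = if (preset == "confounded") 2 else 1,
      group_batch_assoc = preset == "confounded")
    write_feature_table(sim$features, file.path(dir, "features.csv"))
    utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                     row.names = FALSE)
  } else {
    sim <- simulate_images(n_patients = 60, seed = seed)
    sim$cohort <- simulate_survival(sim$cohort, survival_design(),
                                    seed = seed + 1L)
    write_image_cohort(sim, dir)
  }
  invisible(dir)
}

# The stated synthetic worlds of the feature-only presets. Both use p = 60
# features with a 2-class phenotype planted at 1.5 SD on features 1:18
# (30%) driving survival, and acquisition batch variables "contrast"
# (location/scale effect on features 19:48, disjoint from the phenotype
# support) and "kernel" (milder effect on 49:58).
#
# The confounded preset is the world of the end-to-end reproducibility
# experiment: n = 400 so per-group concordance noise does not drown the
# planted gap; a strong contrast effect (gamma 3, delta 2) that hijacks
# unsupervised clustering wherever contrast levels are mixed; a
# phenotype-contrast association (odds ratio `confounding_or`); survival
# dominated by the phenotype (log HR 1.2 vs 0.3 for the clinical
# covariate); and a "spacing_group" grouping aligned with the batch
# effect: the "large" group is nearly pure contrast-enhanced while the
# "small" group mixes both contrast levels, so unmitigated phenotypes are
# batch artifacts in one group but genuine in the other.
simulate_confounded_cohort <- function(n_patients = 150, n_features = 60,
                                       seed = 1, confounding_or = 1,
                                       group_batch_assoc = FALSE) {
  if (group_batch_assoc && n_patients == 150) n_patients <- 400
  stopifnot(n_features >= 60)
  strong <- group_batch_assoc
  bd <- batch_design(n_features, list(
    list(name = "contrast", levels = c("nce", "ce"), probs = c(0.5, 0.5),
         gamma = c(0, if (strong) 3 else 1.5), delta = c(1, 2),
         affected = 19:48),
    list(name = "kernel", levels = c("sharp", "soft"), probs = c(0.5, 0.5),
         gamma = c(0, 0.8), delta = c(1, 1.3), affected = 49:58)))
  pd <- phenotype_design(effect_size = 1.5, affected_fraction = 0.3)
  sim <- simulate_feature_table(n_patients, n_features, bd, pd,
                                seed = seed,
                                confounding_or = confounding_or)
  sdesign <- if (strong)
    survival_design(phenotype_loghr = 1.2, covariate_loghr = c(covar1 = 0.3))
  else survival_design()
  sim$cohort <- simulate_survival(sim$cohort, sdesign, seed = seed + 1L)
  sim$cohort$spacing_group <- with_seed(seed + 2L, {
    if (group_batch_assoc) {
      pr <- ifelse(sim$cohort$contrast == "ce", 0.9, 0.02)
      factor(ifelse(stats::runif(n_patients) < pr, "large", "small"),
             levels = c("small", "large"))
    } else {
      factor(sample(c("small", "large"), n_patients, TRUE),
             levels = c("small", "large"))
    }
  })
  sim
}

#' Command-line interface
#'
#' Subcommands: `simulate` (fixtures), `run-all`, `scenarios` (print the
#' scenario table), `defaults` (print default configuration as JSON).
#' Exit codes: 0 success, 2 configuration error, 3 stage failure.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return integer exit code, invisibly.
#' @export
radbatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: radbatch <command> [options]",
    "  simulate --preset <name> --seed <int> --out <dir>",
    "  run-all  --config <config.json>",
    "  scenarios",
    "  defaults", sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  code <- tryCatch({
    switch(args[1],
      scenarios = {
        print(scenario_table())
        0L
      },
      defaults = {
        cfg <- unclass(run_config(features_csv = "features.csv",
                                  cohort_csv = "cohort.csv"))
        cat(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                             null = "null"), "\n")
        0L
      },
      simulate = {
        dir <- make_fixtures(opt("--preset", "feature-only-small"),
                             seed = as.integer(opt("--seed", "1")),
                             dir = opt("--out", "radbatch_fixture"))
        message("fixtures written to ", dir)
        0L
      },
      "run-all" = {
        cfg_path <- opt("--config")
        if (is.null(cfg_path)) stop("run-all requires --config")
        config <- read_run_config(cfg_path)
        res <- tryCatch(run_all(config), error = function(e) e)
        if (inherits(res, "error")) {
          message("run failed: ", conditionMessage(res))
          3L
        } else {
          message("outputs in ", res$output_dir)
          if (length(res$failures)) 3L else 0L
        }
      },
      {
        message("unknown command '", args[1], "'\n", usage)
        2L
      })
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}
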