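## Formats, configuration and the staged pipeline entry point.

#' Read / write a reflectance spectrum CSV
#'
#' Two-column UTF-8 CSV with the exact header `wavelength_nm,reflectance`.
#' Reading enforces a strictly ascending grid and reflectance in [0, 1],
#' naming the offending row on failure; a write/read round trip preserves
#' values to better than 1e-9.
#'
#' @param path file path
#' @return data.frame with `wavelength_nm` and `reflectance`
#' @export
readSpectrum <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(hdr, c("wavelength_nm", "reflectance")))
    stop("expected header 'wavelength_nm,reflectance' in ", path)
  df <- read.csv(path, colClasses = "numeric")
  bad <- which(diff(df$wavelength_nm) <= 0)
  if (length(bad))
    stop(sprintf("wavelength grid not strictly ascending at row %d of %s",
                 bad[1] + 1L, path))
  out <- which(df$reflectance < 0 | df$reflectance > 1 | is.na(df$reflectance))
  if (length(out))
    stop(sprintf("reflectance outside [0,1] at row %d of %s", out[1], path))
  df
}

#' @rdname readSpectrum
#' @param spectrum data.frame with `wavelength_nm` and `reflectance`
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(all(c("wavelength_nm", "reflectance") %in% colnames(spectrum)))
  write.csv(format(spectrum[, c("wavelength_nm", "reflectance")],
                   digits = 12, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

configSchema <- function() {
  list(
    seed = NULL, output_dir = NULL,
    chip = c("period_nm", "hole_diameter_nm", "depth_nm"),
    material = c("eps_metal", "n_medium", "n_analyte"),
    noise = c("sigma_reflectance", "baseline_tilt", "lambda_jitter_nm",
              "gain_sd", "bulk_index_sd", "depth_scale_sd", "seed"),
    binding = c("K", "molar_absorptivity", "path_length",
                "concentration_scale", "absorption_saturation", "beta"),
    grid = c("from", "to", "step", "baseline_reflectance"),
    cohort = c("n_subjects", "class_counts", "markers",
               "replicates_per_marker", "partition_fractions",
               "replicate_jitter_sdlog", "coupling_sdlog", "effect_scale"),
    features = c("patch_length", "windows"),
    model = c("pathway", "hidden", "d_model", "layers", "heads", "head_hidden"),
    train = c("epochs", "batch_size", "lr", "patience"),
    evaluation = c("threshold", "eval_partition"))
}

#' Read and validate a pipeline run configuration
#'
#' YAML with sections `chip:`, `material:`, `noise:`, `binding:`, `grid:`,
#' `cohort:`, `features:`, `model:`, `train:`, `evaluation:` plus top-level
#' `seed` and `output_dir`. Any key the code does not consume is rejected
#' (typo guard); omitted keys fall back to package defaults.
#'
#' @param path YAML file, or a pre-parsed list
#' @return validated configuration list
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  schema <- configSchema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", ")))
  }
  cfg
}

cfgGet <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

configObjects <- function(cfg) {
  grid <- defaultGrid(cfgGet(cfg, "grid", "from", 500),
                      cfgGet(cfg, "grid", "to", 800),
                      cfgGet(cfg, "grid", "step", 0.5))
  seed <- cfg$seed %||% 1L
  design <- cohortDesign(
    markers = cfgGet(cfg, "cohort", "markers", c("GPC1", "EphA2")),
    replicates_per_marker = cfgGet(cfg, "cohort", "replicates_per_marker", 5L),
    replicate_jitter_sdlog = cfgGet(cfg, "cohort", "replicate_jitter_sdlog", 0.05),
    coupling_sdlog = cfgGet(cfg, "cohort", "coupling_sdlog", 0.8),
    effect_scale = cfgGet(cfg, "cohort", "effect_scale", 1),
    seed = deriveSeed(seed, "simulate"))
  cc <- cfg$cohort$class_counts
  if (!is.null(cc)) design@class_counts <- setNames(as.integer(cc), names(cc))
  if (!is.null(cfg$cohort$partition_fractions))
    design@partition_fractions <- unlist(cfg$cohort$partition_fractions)
  if (!is.null(cfg$cohort$n_subjects))
    design <- scaleDesign(design, cfg$cohort$n_subjects)
  list(
    grid = grid, seed = seed, design = design,
    material = materialModel(
      eps_metal = cfgGet(cfg, "material", "eps_metal", -20),
      n_medium = cfgGet(cfg, "material", "n_medium", 1.33),
      n_analyte = cfgGet(cfg, "material", "n_analyte", 1.60)),
    noise = noiseModel(
      sigma_reflectance = cfgGet(cfg, "noise", "sigma_reflectance", 0.004),
      baseline_tilt = cfgGet(cfg, "noise", "baseline_tilt", 0.002),
      lambda_jitter_nm = cfgGet(cfg, "noise", "lambda_jitter_nm", 0.15),
      gain_sd = cfgGet(cfg, "noise", "gain_sd", 0.01),
      bulk_index_sd = cfgGet(cfg, "noise", "bulk_index_sd", 0.002),
      depth_scale_sd = cfgGet(cfg, "noise", "depth_scale_sd", 0.06),
      seed = cfgGet(cfg, "noise", "seed", deriveSeed(seed, "noise"))),
    binding = bindingState(
      K = cfgGet(cfg, "binding", "K", 1),
      molar_absorptivity = cfgGet(cfg, "binding", "molar_absorptivity", 0.35),
      path_length = cfgGet(cfg, "binding", "path_length", 1),
      concentration_scale = cfgGet(cfg, "binding", "concentration_scale", 1),
      absorption_saturation = cfgGet(cfg, "binding", "absorption_saturation", 5)),
    beta = cfgGet(cfg, "binding", "beta", 0.2),
    baseline = cfgGet(cfg, "grid", "baseline_reflectance", 0.95),
    patch_length = as.integer(cfgGet(cfg, "features", "patch_length", 16L)))
}

#' Run the staged pipeline
#'
#' Stages (in order): `simulate` (cohort + spectrum dataset), `features`
#' (RE/SE/NLE feature tables), `train` (per-marker classifiers), `evaluate`
#' (metrics JSON and ROC/PR curve CSVs), `explain` (attention heatmaps).
#' Each stage writes its outputs under the configured output directory; a
#' machine-readable run log records the config hash, derived seeds, package
#' version and per-stage wall time. Identical config and seed reproduce
#' identical manifests.
#'
#' @param config a validated config list from [readRunConfig()]
#' @param stages subset of c("simulate","features","train","evaluate","explain")
#' @param verbose print progress
#' @return (invisibly) list of in-memory stage results
#' @export
runPipeline <- function(config, stages = c("simulate", "features", "train",
                                           "evaluate", "explain"),
                        verbose = FALSE) {
  all_stages <- c("simulate", "features", "train", "evaluate", "explain")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  needs <- list(features = "simulate", train = "simulate",
                evaluate = "train", explain = "train")
  for (s in stages) {
    dep <- needs[[s]]
    if (!is.null(dep) && !dep %in% stages)
      stop(sprintf("stage '%s' requires stage '%s' in the same run", s, dep))
  }
  ob <- configObjects(config)
  outdir <- config$output_dir %||% "plasmokan_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config_hash = configHash(config), seed = ob$seed,
              package_version = as.character(utils::packageVersion("plasmoKAN")),
              r_version = R.version.string, stages = list())
  res <- list()
  for (s in stages) {
    t0 <- Sys.time()
    if (verbose) message("stage: ", s)
    res <- switch(s,
      simulate = stageSimulate(ob, outdir, res),
      features = stageFeatures(ob, outdir, res),
      train = stageTrain(config, ob, outdir, res),
      evaluate = stageEvaluate(config, outdir, res),
      explain = stageExplain(ob, outdir, res))
    log$stages[[s]] <- list(seconds = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")))
  }
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

stageSimulate <- function(ob, outdir, res) {
  cohort <- sampleCohort(ob$design)
  se <- generateDataset(cohort, ob$design, material = ob$material,
                        binding = ob$binding, noise = ob$noise,
                        grid = ob$grid, baseline_reflectance = ob$baseline,
                        beta = ob$beta)
  write.csv(cohort, file.path(outdir, "cohort.csv"), row.names = FALSE)
  write.csv(as.data.frame(recordData(se)), file.path(outdir, "manifest.csv"),
            row.names = FALSE)
  res$cohort <- cohort; res$se <- se
  res
}

stageFeatures <- function(ob, outdir, res) {
  for (eff in c("RE", "SE", "NLE")) {
    tab <- extractFeatureTable(res$se, eff)
    write.csv(tab, file.path(outdir, sprintf("features_%s.csv", eff)),
              row.names = FALSE)
    res$features[[eff]] <- tab
  }
  res
}

stageTrain <- function(config, ob, outdir, res) {
  tc <- trainConfig(epochs = cfgGet(config, "train", "epochs", 30L),
                    batch_size = cfgGet(config, "train", "batch_size", 64L),
                    lr = cfgGet(config, "train", "lr", 1e-3),
                    patience = cfgGet(config, "train", "patience", 10L),
                    seed = deriveSeed(ob$seed, "train"))
  pathway <- cfgGet(config, "model", "pathway", "fullspectrum")
  for (mk in ob$design@markers) {
    fit <- if (pathway == "feature")
      trainEffectClassifier(res$se, mk, "NLE", config = tc)
    else trainFullSpectrumClassifier(res$se, mk,
                                     patch_length = ob$patch_length,
                                     config = tc)
    res$fits[[mk]] <- fit
    ckpt <- file.path(outdir, sprintf("checkpoint_%s.rds", mk))
    saveRDS(fit$model, ckpt)
    jsonlite::write_json(
      list(marker = mk, pathway = pathway, seed = tc$seed,
           config = fit$model@config[setdiff(names(fit$model@config),
                                             c("posenc", "spec"))],
           best_epoch = fit$model@history$best_epoch),
      sub("\\.rds$", ".json", ckpt), auto_unbox = TRUE, digits = NA)
  }
  res
}

stageEvaluate <- function(config, outdir, res) {
  metrics <- list()
  for (mk in names(res$fits)) {
    fit <- res$fits[[mk]]
    metrics[[mk]] <- fit$report
    ev <- fit$scores[[cfgGet(config, "evaluation", "eval_partition", "external")]]
    rc <- rocAuc(ev$score, ev$label)
    pc <- prAuc(ev$score, ev$label)
    write.csv(rc$curve, file.path(outdir, sprintf("roc_%s.csv", mk)),
              row.names = FALSE)
    write.csv(pc$curve, file.path(outdir, sprintf("pr_%s.csv", mk)),
              row.names = FALSE)
  }
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$metrics <- metrics
  res
}

stageExplain <- function(ob, outdir, res) {
  for (mk in names(res$fits)) {
    fit <- res$fits[[mk]]
    if (fit$model@type != "fullspectrum") next
    sem <- markerRecords(res$se, mk)
    cd <- as.data.frame(recordData(sem))
    k <- which(cd$partition == "test")
    X3 <- buildPatchTensor(sem, k, fit$norm, fit$patch_length)
    exportAttentionHeatmaps(fit$model, X3, wavelengthGrid(sem),
                            file.path(outdir, sprintf("attention_%s", mk)))
  }
  res
}
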