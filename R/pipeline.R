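# End-to-end orchestration: screen -> networks -> pathways -> pair rule ->
# ML platform, driven by one declarative config (YAML file or list), with
# per-stage artifacts, md5 checksums and a reproducibility manifest.
# Deterministic stages rerun to byte-identical outputs under the same
# config and seed.

pipeline_defaults <- function() {
  list(
    screen = list(target = "PLAUR", threshold = 0.9,
                  sham_band = c(-0.2, 0.2)),
    network = list(min_compound_degree = 90, ppi_min_score = 0.7,
                   top_k = 10, coexpression_threshold = 0.9),
    pathway = list(denominator = NULL),
    pair_rule = list(markers = c("MYC", "SMAD4"), pair_threshold = 0.85),
    ml = list(folds = 10, train_fraction = 0.7, feature_k = 31,
              mode_reduction = "max",
              algorithms = c("logistic_regression", "svm")),
    seed = 1)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_pertnet("config file not found: %s", config,
                   class = "pertnet_configuration_error")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$inputs) || is.null(cfg$outdir)) {
    stop_pertnet("pipeline config needs 'inputs' and 'outdir'",
                 class = "pertnet_configuration_error")
  }
  needed <- c("matrix", "drivers", "bioactivity", "pathways", "ppi")
  for (nm in needed) {
    p <- cfg$inputs[[nm]]
    if (is.null(p) || !file.exists(p)) {
      stop_pertnet("pipeline input '%s' missing or not found (%s)", nm,
                   p %||% "<unset>", class = "pertnet_configuration_error")
    }
  }
  cfg
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full screening pipeline
#'
#' Executes the five stages in order — modulator/sham screening,
#' transcriptional + translational network construction (with degree, hub,
#' core and PPI-core analysis), pathway repetition-rate mapping, pair-rule
#' stratification, and the ML screening platform — writing every artifact
#' under `outdir` and returning a manifest with md5 checksums.
#'
#' @param config YAML file path or nested list. Required fields:
#'   `inputs` (paths `matrix`, `drivers`, `bioactivity`, `pathways`,
#'   `ppi`; optional `hallmarks`, `matrix_scale`) and `outdir`. Optional
#'   sections `screen`, `network`, `pathway`, `pair_rule`, `ml`, `seed`
#'   override the defaults (threshold 0.9, sham band `[-0.2, 0.2]`, core
#'   degree 90, PPI score 0.7, 10 folds, 0.7 split).
#' @return Object of class `pipeline_manifest` (list of per-stage records
#'   with outputs and checksums), invisibly. On a stage failure the run
#'   aborts with the stage name; a `FAILED` marker naming the stage is
#'   left in `outdir` and earlier artifacts are retained.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("pertnet")),
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    outputs <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop_pertnet("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e), class = "pertnet_pipeline_error")
    })
    manifest$stages[[name]] <<- list(
      stage = name, outputs = unname(outputs),
      checksums = as.list(tools::md5sum(outputs)),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    message(sprintf("[pertnet] stage %-12s done (%d artifacts)", name,
                    length(outputs)))
  }

  run_stage("screen", function() {
    state$pm <- read_perturbation_matrix(cfg$inputs$matrix,
                                         scale = cfg$inputs$matrix_scale %||% "unit")
    state$drivers <- read_driver_catalog(cfg$inputs$drivers)
    sc <- screen_config(target = cfg$screen$target,
                        threshold = cfg$screen$threshold,
                        sham_band = unlist(cfg$screen$sham_band))
    state$screen_cfg <- sc
    state$calls <- identify_modulators(state$pm, sc)
    state$shams <- select_sham_compounds(state$pm, sc)
    c(write_json_artifact(as.data.frame(state$calls),
                          file.path(outdir, "modulator_calls.json")),
      write_json_artifact(state$shams, file.path(outdir, "shams.json")))
  })

  run_stage("networks", function() {
    thr <- cfg$network$coexpression_threshold
    state$profiles <- coexpressed_targets(state$pm, state$calls, thr)
    state$tnet <- build_transcriptional_network(state$profiles,
                                                state$drivers)
    bioact <- read_bioactivity(cfg$inputs$bioactivity)
    state$pnet <- build_translational_network(bioact, state$calls,
                                              state$drivers)
    ppi <- read_ppi(cfg$inputs$ppi)
    dt <- degree_table(state$tnet)
    core <- core_subnetwork(state$tnet, cfg$network$min_compound_degree)
    ppi_core <- induce_ppi_core(core$targets, ppi,
                                cfg$network$ppi_min_score)
    state$top_targets <- top_k_hubs(degree_table(state$pnet), "target",
                                    cfg$network$top_k)
    f1 <- file.path(outdir, "transcriptional.graphml")
    write_network(state$tnet, f1, "graphml")
    f2 <- file.path(outdir, "translational.tsv")
    write_network(state$pnet, f2, "tsv")
    f3 <- file.path(outdir, "degrees.tsv")
    write.table(as.data.frame(dt), f3, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f4 <- file.path(outdir, "ppi_core.tsv")
    write.table(ppi_core$edges, f4, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f5 <- write_json_artifact(
      list(transcriptional = network_summary(state$tnet),
           translational = network_summary(state$pnet),
           core_targets = core$targets,
           top_translational_targets = state$top_targets),
      file.path(outdir, "network_summary.json"))
    c(f1, f2, f3, f4, f5)
  })

  run_stage("pathways", function() {
    gmt <- read_gmt(cfg$inputs$pathways)
    driver_profiles <- lapply(state$profiles, intersect,
                              driver_genes(state$drivers))
    denom <- cfg$pathway$denominator %||% nrow(state$calls)
    top <- state$top_targets
    if (!length(top)) top <- head(driver_genes(state$drivers), cfg$network$top_k)
    rep <- pathway_report(driver_profiles, gmt, top, denom)
    write_json_artifact(
      list(n_active = attr(rep, "n_active"), report = as.data.frame(rep)),
      file.path(outdir, "pathway_report.json"))
  })

  run_stage("pair_rule", function() {
    hm <- if (!is.null(cfg$inputs$hallmarks)) {
      read_hallmark_map(cfg$inputs$hallmarks)
    }
    verdicts <- classify_table(state$pm, state$calls$compound,
                               state$drivers,
                               markers = unlist(cfg$pair_rule$markers),
                               pair_threshold = cfg$pair_rule$pair_threshold,
                               target = cfg$screen$target, hallmarks = hm)
    write_json_artifact(as.data.frame(verdicts),
                        file.path(outdir, "pair_rule_verdicts.json"))
  })

  run_stage("ml", function() {
    feats <- intersect(driver_genes(state$drivers), state$pm$genes)
    ds <- build_dataset(state$pm, state$calls, state$shams, feats,
                        mode_reduction = cfg$ml$mode_reduction)
    k <- min(cfg$ml$feature_k, ncol(ds$x))
    strict <- select_features(ds, k = k)
    reports <- list(
      total = evaluate_models(ds, algorithms = unlist(cfg$ml$algorithms),
                              folds = cfg$ml$folds,
                              train_fraction = cfg$ml$train_fraction,
                              seed = cfg$seed),
      strictly_associated = evaluate_models(
        ds, features = strict, algorithms = unlist(cfg$ml$algorithms),
        folds = cfg$ml$folds, train_fraction = cfg$ml$train_fraction,
        seed = cfg$seed))
    write_json_artifact(
      list(selected_features = as.character(strict),
           reports = lapply(reports, as.data.frame),
           protocol = attr(reports$total, "protocol")),
      file.path(outdir, "model_report.json"))
  })

  manifest_path <- file.path(outdir, "manifest.json")
  write_json_artifact(manifest[c("package_version", "stages")],
                      manifest_path)
  structure(manifest, class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("pipeline_manifest: %d stages completed\n", length(x$stages)))
  for (s in x$stages) {
    cat(sprintf("  %-12s %d artifacts, %.2fs\n", s$stage,
                length(s$outputs), s$elapsed_s))
  }
  invisible(x)
}

#' Simulate a bundle and write it as pipeline-ready input files
#'
#' Convenience wrapper combining [generate_dataset()] and [write_bundle()].
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_bundle <- function(config = simulation_config(), dir) {
  write_bundle(generate_dataset(config), dir)
}
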