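# Synthetic CMap-like data with planted ground truth. The generator plants
# four kinds of structure: (1) modulators whose target-gene score in their
# triggering mode falls strictly above the calling threshold; (2) sham
# compounds whose target scores sit inside the no-activity band in both
# modes; (3) informative driver genes whose scores are mean-shifted in
# modulators relative to everything else (the ML signal); (4) co-expressed
# driver genes planted supra-threshold in modulator profiles (the network
# signal), hub proteins in the bioactivity table, and pathways seeded with
# the planted drivers. Everything is driven by one integer seed through
# fixed per-component sub-streams, so identical configs give identical
# bundles.

#' Simulation configuration
#'
#' Defaults mirror the screening study conditions this generator emulates:
#' a 2429-compound, 3848-gene perturbation database with a driver to
#' non-driver mapping ratio near 1:12, 254 modulators (143 suppressors +
#' 111 stimulators) called at threshold 0.9, and 185 sham compounds inside
#' the `[-0.2, 0.2]` band.
#'
#' @param n_compounds,n_genes matrix dimensions (the gene universe includes
#'   the target gene).
#' @param driver_fraction fraction of genes that are cancer drivers
#'   (default 1/13, i.e. a 1:12 driver:non-driver ratio).
#' @param n_suppressors,n_stimulators planted modulator counts (KD-mode and
#'   OE-mode calls respectively under the default direction mapping).
#' @param n_shams planted sham compounds.
#' @param threshold the calling threshold the planted structure is built
#'   around.
#' @param modulator_score_range interval strictly above `threshold` from
#'   which planted triggering scores are drawn uniformly.
#' @param sham_band closed no-activity band, strictly inside
#'   `(-threshold, threshold)`.
#' @param n_informative_drivers driver genes carrying the class-mean shift.
#' @param informative_shift mean score shift (unit scale) of informative
#'   drivers in modulators.
#' @param noise_sd standard deviation of the background Gaussian scores
#'   (clipped to `[-1, 1]`).
#' @param n_coexpressed_drivers driver genes planted supra-threshold in
#'   modulator co-expression profiles.
#' @param coexpression_prob per-(modulator, co-expressed driver)
#'   probability of a planted supra-threshold score.
#' @param n_hub_proteins driver proteins planted as high-degree hubs of the
#'   bioactivity table.
#' @param n_pathways,pathway_size gene-set collection shape.
#' @param n_planted_pathways pathways seeded with planted driver genes (the
#'   rest receive only non-driver genes).
#' @param target target gene symbol.
#' @param seed integer master seed (keep below 2^31 - 1000).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 2429, n_genes = 3848,
                              driver_fraction = 1 / 13,
                              n_suppressors = 143, n_stimulators = 111,
                              n_shams = 185, threshold = 0.9,
                              modulator_score_range = c(0.905, 0.995),
                              sham_band = c(-0.2, 0.2),
                              n_informative_drivers = 30,
                              informative_shift = 0.3, noise_sd = 0.15,
                              n_coexpressed_drivers = 13,
                              coexpression_prob = 0.6,
                              n_hub_proteins = 12,
                              n_pathways = 21, pathway_size = 60,
                              n_planted_pathways = 10,
                              target = "PLAUR", seed = 1) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  n_mod <- n_suppressors + n_stimulators
  if (n_mod + n_shams > n_compounds) {
    stop_pertnet("planted modulators + shams (%d) exceed n_compounds (%d)",
                 n_mod + n_shams, n_compounds,
                 class = "pertnet_configuration_error")
  }
  if (modulator_score_range[1] <= threshold || modulator_score_range[2] > 1) {
    stop_pertnet("modulator_score_range must lie strictly above the threshold, within (threshold, 1]",
                 class = "pertnet_configuration_error")
  }
  if (sham_band[1] <= -threshold || sham_band[2] >= threshold) {
    stop_pertnet("sham_band must lie strictly inside (-threshold, threshold)",
                 class = "pertnet_configuration_error")
  }
  n_drivers <- round(n_genes * driver_fraction)
  if (n_informative_drivers + n_coexpressed_drivers + n_hub_proteins >
        n_drivers) {
    stop_pertnet("informative + co-expressed + hub drivers exceed the driver count (%d)",
                 n_drivers, class = "pertnet_configuration_error")
  }
  if (seed >= 2^31 - 1000) {
    stop_pertnet("seed too large", class = "pertnet_configuration_error")
  }
  cfg
}

clip_unit <- function(x) pmin(1, pmax(-1, x))

#' Generate a synthetic CMap-like data bundle
#'
#' @param config a [simulation_config()].
#' @return Object of class `cmap_bundle`: list with `matrix`
#'   ([perturbation_matrix()]), `drivers` ([driver_catalog()]),
#'   `bioactivity` ([bioactivity_table()]), `pathways`
#'   ([pathway_collection()]), `ppi` ([ppi_table()]) and `truth` (planted
#'   ground truth: per-compound `labels`
#'   (`suppressor`/`stimulator`/`sham`/`other`), `modulator_mode`,
#'   `informative_drivers`, `coexpressed_drivers`, `hub_proteins`,
#'   `planted_pathways`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  cfg <- config
  n_drivers <- round(cfg$n_genes * cfg$driver_fraction)
  target <- toupper(cfg$target)

  # --- gene universe and driver catalog -------------------------------
  set.seed(derive_seed(cfg$seed, 1))
  drivers <- sprintf("DRV%04d", seq_len(n_drivers))
  others <- sprintf("GEN%04d", seq_len(cfg$n_genes - n_drivers - 1L))
  genes <- sort(c(target, drivers, others))
  roles <- sample(DRIVER_ROLES, n_drivers, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1))
  catalog <- driver_catalog(drivers, roles)
  informative <- drivers[seq_len(cfg$n_informative_drivers)]
  coexpressed <- drivers[cfg$n_informative_drivers +
                           seq_len(cfg$n_coexpressed_drivers)]

  # --- compound labels -------------------------------------------------
  set.seed(derive_seed(cfg$seed, 2))
  compounds <- sprintf("CPD%04d", seq_len(cfg$n_compounds))
  labels <- rep("other", cfg$n_compounds)
  n_mod <- cfg$n_suppressors + cfg$n_stimulators
  planted <- sample(cfg$n_compounds, n_mod + cfg$n_shams)
  labels[planted[seq_len(cfg$n_suppressors)]] <- "suppressor"
  labels[planted[cfg$n_suppressors + seq_len(cfg$n_stimulators)]] <- "stimulator"
  labels[planted[n_mod + seq_len(cfg$n_shams)]] <- "sham"
  names(labels) <- compounds
  is_sup <- labels == "suppressor"
  is_stim <- labels == "stimulator"
  is_mod <- is_sup | is_stim
  is_sham <- labels == "sham"
  is_other <- labels == "other"

  # --- background scores ----------------------------------------------
  set.seed(derive_seed(cfg$seed, 3))
  kd <- matrix(clip_unit(rnorm(cfg$n_compounds * length(genes),
                               sd = cfg$noise_sd)),
               cfg$n_compounds, length(genes),
               dimnames = list(compounds, genes))
  oe <- matrix(clip_unit(rnorm(cfg$n_compounds * length(genes),
                               sd = cfg$noise_sd)),
               cfg$n_compounds, length(genes),
               dimnames = list(compounds, genes))

  # informative drivers: class-mean shift in modulators, both modes
  kd[is_mod, informative] <- clip_unit(kd[is_mod, informative] +
                                         cfg$informative_shift)
  oe[is_mod, informative] <- clip_unit(oe[is_mod, informative] +
                                         cfg$informative_shift)

  # keep all background/informative scores below the calling threshold so
  # that supra-threshold structure is exactly the planted structure
  sub <- cfg$threshold - 0.01
  kd[] <- pmin(pmax(kd, -sub), sub)
  oe[] <- pmin(pmax(oe, -sub), sub)

  # --- planted target-gene scores -------------------------------------
  set.seed(derive_seed(cfg$seed, 4))
  lo <- cfg$modulator_score_range[1]
  hi <- cfg$modulator_score_range[2]
  kd[is_sup, target] <- runif(sum(is_sup), lo, hi)
  oe[is_stim, target] <- runif(sum(is_stim), lo, hi)
  band <- cfg$sham_band
  pad <- 0.02 * diff(band)
  kd[is_sham, target] <- runif(sum(is_sham), band[1] + pad, band[2] - pad)
  oe[is_sham, target] <- runif(sum(is_sham), band[1] + pad, band[2] - pad)
  # "other" compounds: target activity outside the band in one mode but
  # below the calling threshold, so they are neither modulator nor sham
  n_oth <- sum(is_other)
  if (n_oth) {
    out_mag <- runif(n_oth, band[2] + 0.02, sub)
    out_sign <- sample(c(-1, 1), n_oth, replace = TRUE)
    out_mode <- sample(c(TRUE, FALSE), n_oth, replace = TRUE)
    oth_idx <- which(is_other)
    kd[cbind(oth_idx[out_mode], match(target, genes))] <-
      (out_mag * out_sign)[out_mode]
    oe[cbind(oth_idx[!out_mode], match(target, genes))] <-
      (out_mag * out_sign)[!out_mode]
  }

  # --- planted co-expression profiles ---------------------------------
  set.seed(derive_seed(cfg$seed, 5))
  mod_idx <- which(is_mod)
  modulator_mode <- ifelse(is_sup[mod_idx], "KD", "OE")
  names(modulator_mode) <- compounds[mod_idx]
  for (j in seq_along(mod_idx)) {
    on <- runif(length(coexpressed)) < cfg$coexpression_prob
    if (!any(on)) next
    val <- runif(sum(on), lo, hi)
    if (modulator_mode[j] == "KD") {
      kd[mod_idx[j], coexpressed[on]] <- val
    } else {
      oe[mod_idx[j], coexpressed[on]] <- val
    }
  }
  pm <- new_perturbation_matrix(kd, oe)

  # --- bioactivity pairs with planted hub proteins --------------------
  set.seed(derive_seed(cfg$seed, 6))
  hubs <- drivers[cfg$n_informative_drivers + cfg$n_coexpressed_drivers +
                    seq_len(cfg$n_hub_proteins)]
  mods <- compounds[mod_idx]
  hub_rows <- if (length(mods)) {
    lapply(seq_along(hubs), function(h) {
      deg <- max(2L, round(length(mods) * runif(1, 0.5, 0.9)))
      data.frame(compound = sample(mods, min(deg, length(mods))),
                 protein = hubs[h], stringsAsFactors = FALSE)
    })
  } else {
    list()
  }
  n_bg <- 4L * cfg$n_compounds
  bg <- unique(data.frame(
    compound = sample(compounds, n_bg, replace = TRUE),
    protein = sample(c(drivers, others), n_bg, replace = TRUE),
    stringsAsFactors = FALSE))
  pairs <- unique(rbind(do.call(rbind, hub_rows), bg))
  bioactivity <- bioactivity_table(
    pairs$compound, pairs$protein,
    sample(c("experimental", "putative"), nrow(pairs), replace = TRUE))

  # --- pathway collection ---------------------------------------------
  set.seed(derive_seed(cfg$seed, 7))
  planted_drivers <- c(informative, coexpressed)
  ids <- sprintf("pwy%04d", seq_len(cfg$n_pathways))
  sets <- vector("list", cfg$n_pathways)
  for (i in seq_len(cfg$n_pathways)) {
    if (i <= cfg$n_planted_pathways) {
      core <- sample(planted_drivers,
                     max(1L, round(length(planted_drivers) * runif(1, 0.2, 0.6))))
      fill <- sample(others, max(0L, cfg$pathway_size - length(core)))
      sets[[i]] <- c(core, fill)
    } else {
      sets[[i]] <- sample(others, cfg$pathway_size)
    }
  }
  pathways <- pathway_collection(ids, sprintf("synthetic pathway %d",
                                              seq_len(cfg$n_pathways)), sets)
  planted_pathways <- lapply(setNames(seq_len(cfg$n_planted_pathways),
                                      ids[seq_len(cfg$n_planted_pathways)]),
                             function(i) intersect(sets[[i]], planted_drivers))

  # --- PPI edges: high-confidence core among planted drivers ----------
  set.seed(derive_seed(cfg$seed, 8))
  core_df <- data.frame(a = character(), b = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  if (length(coexpressed) >= 2) {
    core_pairs <- t(utils::combn(coexpressed, 2))
    keep_core <- runif(nrow(core_pairs)) < 0.7
    core_df <- data.frame(a = core_pairs[keep_core, 1],
                          b = core_pairs[keep_core, 2],
                          confidence = runif(sum(keep_core), 0.75, 0.99),
                          stringsAsFactors = FALSE)
  }
  n_rand <- 5L * n_drivers
  ra <- sample(drivers, n_rand, replace = TRUE)
  rb <- sample(drivers, n_rand, replace = TRUE)
  ok <- ra != rb
  rand_df <- unique(data.frame(a = pmin(ra[ok], rb[ok]),
                               b = pmax(ra[ok], rb[ok]),
                               stringsAsFactors = FALSE))
  rand_df$confidence <- runif(nrow(rand_df))
  key_core <- paste(core_df$a, core_df$b)
  rand_df <- rand_df[!paste(rand_df$a, rand_df$b) %in% key_core, ,
                     drop = FALSE]
  ppi_df <- rbind(core_df, rand_df)
  ppi <- ppi_table(ppi_df$a, ppi_df$b, ppi_df$confidence)

  truth <- list(labels = labels, modulator_mode = modulator_mode,
                informative_drivers = informative,
                coexpressed_drivers = coexpressed, hub_proteins = hubs,
                planted_pathways = planted_pathways, seed = cfg$seed)
  structure(list(matrix = pm, drivers = catalog, bioactivity = bioactivity,
                 pathways = pathways, ppi = ppi, truth = truth,
                 config = cfg),
            class = "cmap_bundle")
}

#' @export
print.cmap_bundle <- function(x, ...) {
  tab <- table(factor(x$truth$labels,
                      c("suppressor", "stimulator", "sham", "other")))
  cat(sprintf(
    "cmap_bundle: %d compounds x %d genes (seed %d)\n  %s\n",
    length(x$matrix$compounds), length(x$matrix$genes), x$truth$seed,
    paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a synthetic bundle to disk in the package's file dialects
#'
#' Emits `matrix.tsv` (long perturbation TSV), `drivers.tsv`,
#' `bioactivity.tsv`, `pathways.gmt`, `ppi.tsv` and `truth.json`.
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             drivers = file.path(dir, "drivers.tsv"),
             bioactivity = file.path(dir, "bioactivity.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             ppi = file.path(dir, "ppi.tsv"),
             truth = file.path(dir, "truth.json"))
  write_perturbation_matrix(bundle$matrix, paths["matrix"])
  write_driver_catalog(bundle$drivers, paths["drivers"])
  write_bioactivity(bundle$bioactivity, paths["bioactivity"])
  write_gmt(bundle$pathways, paths["pathways"])
  write_ppi(bundle$ppi, paths["ppi"])
  jsonlite::write_json(bundle$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
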