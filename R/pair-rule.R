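# The target-driver gene pair rule. A compound's perturbation evidence on
# the target gene (uPAR) is paired with its evidence on role-annotated
# marker driver genes:
#   (a) target KD-qualified AND an oncogene marker KD-qualified
#       -> anti_cancer (e.g. uPAR + MYC knockdown connectivity);
#   (b) target OE-qualified AND a tumor-suppressor marker KD-qualified
#       -> carcinogenic (e.g. uPAR overexpression + SMAD4 knockdown);
#   otherwise indeterminate. If both branches fire the verdict is
#   indeterminate with a conflict flag. Bifunctional markers match neither
#   branch. The pair threshold (default 0.85) is deliberately independent
#   of the 0.9 calling threshold: printed evidence treats scores just below
#   0.9 as active in pair context.

#' Read a hallmark map (TSV: hallmark, drivers, markers)
#'
#' `drivers` and `markers` are comma-separated gene lists; each hallmark's
#' preferred markers must be a subset of its driver genes.
#'
#' @param path TSV path.
#' @return Object of class `hallmark_map`: named list of
#'   `list(drivers =, markers =)` per hallmark.
#' @export
read_hallmark_map <- function(path) {
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("hallmark", "drivers", "markers") %in% names(df))) {
    stop_pertnet("hallmark map needs columns hallmark, drivers, markers",
                 class = "pertnet_parse_error")
  }
  hallmark_map(df$hallmark,
               strsplit(df$drivers, ",[ ]*"),
               strsplit(df$markers, ",[ ]*"))
}

#' Construct a hallmark map
#' @param hallmarks hallmark names.
#' @param drivers list of driver gene vectors, one per hallmark.
#' @param markers list of preferred-marker vectors (subset of drivers).
#' @return A `hallmark_map`.
#' @export
hallmark_map <- function(hallmarks, drivers, markers) {
  drivers <- lapply(drivers, function(g) sort(unique(toupper(g))))
  markers <- lapply(markers, function(g) sort(unique(toupper(g[nzchar(g)]))))
  for (i in seq_along(hallmarks)) {
    if (!all(markers[[i]] %in% drivers[[i]])) {
      stop_pertnet("hallmark '%s': preferred markers must be driver members",
                   hallmarks[i], class = "pertnet_validation_error")
    }
  }
  structure(setNames(Map(function(d, m) list(drivers = d, markers = m),
                         drivers, markers), hallmarks),
            class = "hallmark_map")
}

#' Hallmark stratification of a driver-gene profile
#'
#' A hallmark is reported when its driver gene set intersects the profile;
#' matched preferred markers are listed separately.
#'
#' @param driver_profile character vector of driver genes affected by a
#'   compound.
#' @param map a [hallmark_map()].
#' @return Named list over matched hallmarks: `list(matched =, markers =)`.
#' @export
hallmark_stratification <- function(driver_profile, map) {
  profile <- toupper(driver_profile)
  out <- lapply(map, function(h) {
    hit <- intersect(h$drivers, profile)
    if (!length(hit)) return(NULL)
    list(matched = hit, markers = intersect(h$markers, profile))
  })
  out[!vapply(out, is.null, TRUE)]
}

qualified_entries <- function(scores, pair_threshold) {
  scores[!is.na(scores$score) & scores$score > pair_threshold, , drop = FALSE]
}

#' Pair-rule classification of one compound
#'
#' @param scores data frame of the compound's measured entries: columns
#'   `gene`, `mode` (`KD`/`OE`), `score` (unit scale).
#' @param drivers a [driver_catalog()] supplying marker roles.
#' @param markers marker gene symbols (must be catalog members); default
#'   `c("MYC", "SMAD4")`.
#' @param pair_threshold qualification threshold for both pair members
#'   (strict `>`; default 0.85).
#' @param target target gene symbol (default `PLAUR`).
#' @param hallmarks optional [hallmark_map()] used to annotate the verdict
#'   with the hallmarks reachable through the matched markers.
#' @param compound compound identifier carried into the verdict.
#' @return Object of class `pair_rule_verdict`: list with `compound`,
#'   `verdict` (`anti_cancer`/`carcinogenic`/`indeterminate`),
#'   `target_direction` (`suppressor`/`stimulator`/`none`), `conflict`,
#'   `evidence` (data frame `gene`, `role`, `mode`, `score`), `hallmarks`.
#' @export
classify_compound <- function(scores, drivers, markers = c("MYC", "SMAD4"),
                              pair_threshold = 0.85, target = "PLAUR",
                              hallmarks = NULL, compound = NA_character_) {
  markers <- toupper(markers)
  absent <- setdiff(markers, driver_genes(drivers))
  if (length(absent)) {
    stop_pertnet("marker gene '%s' absent from driver catalog", absent[1L],
                 class = "pertnet_configuration_error")
  }
  target <- toupper(target)
  scores$gene <- toupper(scores$gene)
  q <- qualified_entries(scores, pair_threshold)
  t_kd <- any(q$gene == target & q$mode == "KD")
  t_oe <- any(q$gene == target & q$mode == "OE")
  mk <- q[q$gene %in% markers & q$mode == "KD", , drop = FALSE]
  mk$role <- driver_role(drivers, mk$gene)
  onc_hit <- mk[mk$role == "oncogene", , drop = FALSE]
  ts_hit <- mk[mk$role == "tumor_suppressor", , drop = FALSE]
  fire_a <- t_kd && nrow(onc_hit) > 0
  fire_b <- t_oe && nrow(ts_hit) > 0
  conflict <- (fire_a && fire_b) || (t_kd && t_oe)
  verdict <- if (conflict) "indeterminate"
             else if (fire_a) "anti_cancer"
             else if (fire_b) "carcinogenic"
             else "indeterminate"
  direction <- if (t_kd && t_oe) "conflict"
               else if (t_kd) "suppressor"
               else if (t_oe) "stimulator"
               else "none"
  evidence <- if (verdict == "anti_cancer") onc_hit
              else if (verdict == "carcinogenic") ts_hit
              else mk
  evidence <- evidence[, c("gene", "role", "mode", "score"), drop = FALSE]
  rownames(evidence) <- NULL
  hm <- if (!is.null(hallmarks) && nrow(evidence)) {
    names(hallmark_stratification(evidence$gene, hallmarks))
  } else character()
  structure(list(compound = compound, verdict = verdict,
                 target_direction = direction, conflict = conflict,
                 evidence = evidence, hallmarks = hm),
            class = "pair_rule_verdict")
}

#' @export
print.pair_rule_verdict <- function(x, ...) {
  cat(sprintf("pair_rule_verdict [%s]: %s (target %s%s)\n",
              x$compound, x$verdict, x$target_direction,
              if (x$conflict) ", CONFLICT" else ""))
  if (nrow(x$evidence)) print.data.frame(x$evidence)
  invisible(x)
}

compound_entries <- function(pm, compound) {
  kd <- pm$kd[compound, ]
  oe <- pm$oe[compound, ]
  rbind(
    data.frame(gene = pm$genes[!is.na(kd)],
               mode = rep("KD", sum(!is.na(kd))),
               score = kd[!is.na(kd)], stringsAsFactors = FALSE),
    data.frame(gene = pm$genes[!is.na(oe)],
               mode = rep("OE", sum(!is.na(oe))),
               score = oe[!is.na(oe)], stringsAsFactors = FALSE))
}

#' Batch pair-rule classification
#'
#' Applies [classify_compound()] to each listed compound of a perturbation
#' matrix; output order follows the input compound order.
#'
#' @param pm a [perturbation_matrix()].
#' @param compounds compound identifiers present in `pm`.
#' @inheritParams classify_compound
#' @return Object of class `pair_rule_table`: data frame `compound`,
#'   `verdict`, `target_direction`, `conflict`, `evidence_genes`
#'   (comma-separated), `hallmarks` (semicolon-separated), with the full
#'   verdict objects in attribute `verdicts`.
#' @export
classify_table <- function(pm, compounds, drivers,
                           markers = c("MYC", "SMAD4"),
                           pair_threshold = 0.85, target = "PLAUR",
                           hallmarks = NULL) {
  missing <- setdiff(compounds, pm$compounds)
  if (length(missing)) {
    stop_pertnet("compound '%s' not present in the matrix", missing[1L],
                 class = "pertnet_lookup_error")
  }
  verdicts <- lapply(compounds, function(cpd) {
    classify_compound(compound_entries(pm, cpd), drivers, markers,
                      pair_threshold, target, hallmarks, compound = cpd)
  })
  out <- data.frame(
    compound = compounds,
    verdict = vapply(verdicts, `[[`, "", "verdict"),
    target_direction = vapply(verdicts, `[[`, "", "target_direction"),
    conflict = vapply(verdicts, `[[`, TRUE, "conflict"),
    evidence_genes = vapply(verdicts, function(v) {
      paste(v$evidence$gene, collapse = ",")
    }, ""),
    hallmarks = vapply(verdicts, function(v) {
      paste(v$hallmarks, collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
  structure(out, class = c("pair_rule_table", "data.frame"),
            verdicts = verdicts)
}
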