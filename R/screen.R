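# Modulator calling. A compound is a modulator of the target gene when its
# perturbation score against one of the target's reference signatures
# strictly exceeds the calling threshold (default 0.9); compounds whose
# target scores stay inside the closed no-activity band (default
# [-0.2, 0.2]) in every measured mode are sham compounds, the negative
# class of the screening platform.

#' Screening configuration
#'
#' @param target target gene symbol (default `PLAUR`, the uPAR gene).
#' @param threshold calling threshold in `(0, 1]`; strict `>` applies.
#' @param sham_band closed no-activity interval, strictly inside
#'   `(-threshold, threshold)`.
#' @param kd_means direction assigned to a KD-mode call: `"suppressor"`
#'   (default; connectivity to a knockdown signature read as functional
#'   suppression) or `"stimulator"`. The OE mode gets the opposite
#'   direction. The mapping is configurable because printed evidence on its
#'   orientation is internally inconsistent in the source data conventions.
#' @param absolute threshold on `|score|` instead of the signed score.
#'   Default `FALSE`: negative scores never qualify.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(target = "PLAUR", threshold = 0.9,
                          sham_band = c(-0.2, 0.2),
                          kd_means = c("suppressor", "stimulator"),
                          absolute = FALSE) {
  kd_means <- match.arg(kd_means)
  if (threshold <= 0 || threshold > 1) {
    stop_pertnet("calling threshold must lie in (0, 1]",
                 class = "pertnet_configuration_error")
  }
  sham_band <- sort(as.numeric(sham_band))
  if (length(sham_band) != 2 || sham_band[1] <= -threshold ||
      sham_band[2] >= threshold) {
    stop_pertnet("sham band must lie strictly inside (-threshold, threshold)",
                 class = "pertnet_configuration_error")
  }
  structure(list(target = toupper(target), threshold = threshold,
                 sham_band = sham_band, kd_means = kd_means,
                 absolute = absolute),
            class = "screen_config")
}

target_scores <- function(pm, config) {
  if (!config$target %in% pm$genes) {
    stop_pertnet("target gene '%s' not present in the matrix", config$target,
                 class = "pertnet_lookup_error")
  }
  cbind(KD = pm$kd[, config$target], OE = pm$oe[, config$target])
}

qualifies <- function(score, config) {
  s <- if (config$absolute) abs(score) else score
  !is.na(s) & s > config$threshold
}

#' Identify target-gene modulators
#'
#' Calls every compound whose target-gene score strictly exceeds the calling
#' threshold in at least one mode. When both modes qualify, the higher score
#' decides the triggering mode (KD on an exact tie); direction follows the
#' configured mode mapping.
#'
#' @param pm a [perturbation_matrix()].
#' @param config a [screen_config()].
#' @return Object of class `modulator_calls`: data frame `compound`,
#'   `direction` (`suppressor`/`stimulator`), `mode` (triggering mode),
#'   `score` (triggering score), sorted by descending score then compound.
#' @export
identify_modulators <- function(pm, config = screen_config()) {
  sc <- target_scores(pm, config)
  eff <- if (config$absolute) abs(sc) else sc
  q_kd <- qualifies(sc[, "KD"], config)
  q_oe <- qualifies(sc[, "OE"], config)
  any_q <- q_kd | q_oe
  # triggering mode: the qualifying mode; both -> higher score, KD on a tie
  use_kd <- q_kd & (!q_oe | eff[, "KD"] >= eff[, "OE"])
  mode <- ifelse(use_kd, "KD", "OE")[any_q]
  cpd <- pm$compounds[any_q]
  score <- ifelse(use_kd, sc[, "KD"], sc[, "OE"])[any_q]
  dir_map <- c(KD = config$kd_means,
               OE = setdiff(c("suppressor", "stimulator"), config$kd_means))
  out <- data.frame(compound = cpd, direction = unname(dir_map[mode]),
                    mode = mode, score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("modulator_calls", "data.frame"),
            config = config)
}

#' Select sham (no-activity) compounds
#'
#' A compound is a sham when it has at least one measured target-gene score
#' and every measured mode lies inside the closed sham band.
#'
#' @param pm a [perturbation_matrix()].
#' @param config a [screen_config()].
#' @return Character vector of compound identifiers, sorted.
#' @export
select_sham_compounds <- function(pm, config = screen_config()) {
  sc <- target_scores(pm, config)
  lo <- config$sham_band[1]
  hi <- config$sham_band[2]
  inside <- sc >= lo & sc <= hi
  measured <- !is.na(sc)
  ok <- rowSums(measured) > 0 & rowSums(measured & !inside, na.rm = TRUE) == 0
  sort(pm$compounds[ok])
}

#' Supra-threshold co-expression profiles of modulators
#'
#' For each modulator, the set of genes whose score in any mode strictly
#' exceeds `threshold` — the same calling rule used for the target gene, so
#' the target itself is a member of every profile.
#'
#' @param pm a [perturbation_matrix()].
#' @param modulators a `modulator_calls` table or character vector of
#'   compound identifiers.
#' @param threshold co-expression score threshold (default 0.9).
#' @param absolute threshold on `|score|` (default `FALSE`).
#' @return Named list: compound -> sorted character vector of gene symbols.
#' @export
coexpressed_targets <- function(pm, modulators, threshold = 0.9,
                                absolute = FALSE) {
  cpds <- if (is.data.frame(modulators)) modulators$compound else modulators
  missing <- setdiff(cpds, pm$compounds)
  if (length(missing)) {
    stop_pertnet("compound '%s' not present in the matrix", missing[1L],
                 class = "pertnet_lookup_error")
  }
  out <- lapply(cpds, function(cpd) {
    kd <- pm$kd[cpd, ]
    oe <- pm$oe[cpd, ]
    if (absolute) {
      kd <- abs(kd)
      oe <- abs(oe)
    }
    hit <- (!is.na(kd) & kd > threshold) | (!is.na(oe) & oe > threshold)
    sort(pm$genes[hit])
  })
  setNames(out, cpds)
}
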