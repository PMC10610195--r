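# Perturbation score matrix: compound x gene scores under gene-knockdown (KD)
# and gene-overexpression (OE) reference signatures, CMap-style. Canonical
# scale is the unit interval [-1, 1]; missing entries are "not measured",
# never zero.

#' Construct a perturbation score matrix
#'
#' Builds the canonical compound x (gene, mode) score container used by all
#' screening and network operations. Scores are connectivity-style similarity
#' values between a compound's expression signature and a gene knockdown
#' (`KD`) or overexpression (`OE`) reference signature, held on the unit
#' scale `[-1, 1]`. Entries absent from `entries` are treated as not
#' measured (`NA`), never as zero.
#'
#' @param entries data frame with columns `compound`, `gene`, `mode`
#'   (`"KD"` or `"OE"`), `score`. At most one row per (compound, gene, mode).
#' @param scale scale the supplied scores are on: `"unit"` (already in
#'   `[-1, 1]`) or `"percent"` (in `[-100, 100]`; divided by 100 on ingest).
#' @return An object of class `perturbation_matrix`: a list with character
#'   vectors `compounds` and `genes` and numeric matrices `kd` and `oe`
#'   (compounds x genes, `NA` = not measured).
#' @export
perturbation_matrix <- function(entries, scale = c("unit", "percent")) {
  scale <- match.arg(scale)
  req <- c("compound", "gene", "mode", "score")
  if (!all(req %in% names(entries))) {
    stop_pertnet("perturbation entries need columns %s",
                 paste(req, collapse = ", "),
                 class = "pertnet_parse_error")
  }
  entries$compound <- trimws(as.character(entries$compound))
  entries$gene <- check_symbols(entries$gene, "perturbation matrix")
  entries$mode <- toupper(trimws(as.character(entries$mode)))
  if (nrow(entries) && any(!entries$mode %in% PERT_MODES)) {
    bad <- which(!entries$mode %in% PERT_MODES)[1L]
    stop_pertnet("row %d: mode must be KD or OE, got '%s'",
                 bad, entries$mode[bad], class = "pertnet_parse_error")
  }
  score <- suppressWarnings(as.numeric(entries$score))
  if (nrow(entries) && anyNA(score)) {
    stop_pertnet("row %d: non-numeric score '%s'",
                 which(is.na(score))[1L], entries$score[which(is.na(score))[1L]],
                 class = "pertnet_parse_error")
  }
  lim <- if (scale == "percent") 100 else 1
  if (nrow(entries) && any(abs(score) > lim)) {
    bad <- which(abs(score) > lim)[1L]
    stop_pertnet("row %d: score %.4g outside declared %s range [-%g, %g]",
                 bad, score[bad], scale, lim, lim,
                 class = "pertnet_validation_error")
  }
  if (scale == "percent") score <- score / 100
  key <- paste(entries$compound, entries$gene, entries$mode, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop_pertnet("duplicate (compound, gene, mode) entry: %s",
                 gsub("\r", " / ", d, fixed = TRUE),
                 class = "pertnet_duplication_error")
  }
  compounds <- sort(unique(entries$compound))
  genes <- sort(unique(entries$gene))
  kd <- matrix(NA_real_, length(compounds), length(genes),
               dimnames = list(compounds, genes))
  oe <- kd
  if (nrow(entries)) {
    i <- cbind(match(entries$compound, compounds), match(entries$gene, genes))
    is_kd <- entries$mode == "KD"
    kd[i[is_kd, , drop = FALSE]] <- score[is_kd]
    oe[i[!is_kd, , drop = FALSE]] <- score[!is_kd]
  }
  structure(list(compounds = compounds, genes = genes, kd = kd, oe = oe),
            class = "perturbation_matrix")
}

# Internal constructor from prebuilt matrices (used by the generator; trusted
# input, already canonical).
new_perturbation_matrix <- function(kd, oe) {
  structure(list(compounds = rownames(kd), genes = colnames(kd),
                 kd = kd, oe = oe),
            class = "perturbation_matrix")
}

#' @export
print.perturbation_matrix <- function(x, ...) {
  n_meas <- sum(!is.na(x$kd)) + sum(!is.na(x$oe))
  cat(sprintf(
    "perturbation_matrix: %d compounds x %d genes, %d measured (KD+OE) entries\n",
    length(x$compounds), length(x$genes), n_meas))
  invisible(x)
}

#' @export
dim.perturbation_matrix <- function(x) {
  c(length(x$compounds), length(x$genes))
}

#' @export
as.data.frame.perturbation_matrix <- function(x, ...) {
  long <- function(m, mode) {
    idx <- which(!is.na(m), arr.ind = TRUE)
    if (!nrow(idx)) {
      return(data.frame(compound = character(), gene = character(),
                        mode = character(), score = numeric()))
    }
    data.frame(compound = rownames(m)[idx[, 1]], gene = colnames(m)[idx[, 2]],
               mode = mode, score = m[idx], stringsAsFactors = FALSE)
  }
  out <- rbind(long(x$kd, "KD"), long(x$oe, "OE"))
  out <- out[order(out$compound, out$gene, out$mode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up perturbation scores
#'
#' @param pm a [perturbation_matrix()].
#' @param compound,gene single identifiers.
#' @param mode `"KD"`, `"OE"`, or `NULL` for both.
#' @return Named numeric vector of scores (`NA` when not measured).
#' @export
pm_score <- function(pm, compound, gene, mode = NULL) {
  gene <- toupper(gene)
  if (!compound %in% pm$compounds) {
    stop_pertnet("compound '%s' not present in matrix", compound,
                 class = "pertnet_lookup_error")
  }
  if (!gene %in% pm$genes) {
    stop_pertnet("gene '%s' not present in matrix", gene,
                 class = "pertnet_lookup_error")
  }
  out <- c(KD = pm$kd[compound, gene], OE = pm$oe[compound, gene])
  if (is.null(mode)) out else out[[match.arg(mode, PERT_MODES)]]
}

#' Read a perturbation score matrix from TSV
#'
#' Two dialects are supported. The primary long layout has header
#' `compound  gene  mode  score` (one measured entry per row). The wide
#' layout has a `compound` column followed by `GENE:MODE` score columns
#' (e.g. `PLAUR:KD`); empty cells are unmeasured.
#'
#' @param path TSV file path.
#' @param scale declared scale of the stored scores (`"unit"` or
#'   `"percent"`); percent scores are divided by 100 on ingest.
#' @param layout `"long"` (default) or `"wide"`.
#' @return A [perturbation_matrix()].
#' @export
read_perturbation_matrix <- function(path, scale = c("unit", "percent"),
                                     layout = c("long", "wide")) {
  scale <- match.arg(scale)
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (layout == "long") {
    return(perturbation_matrix(df, scale = scale))
  }
  if (!"compound" %in% names(df)) {
    stop_pertnet("wide layout needs a 'compound' column",
                 class = "pertnet_parse_error")
  }
  scol <- setdiff(names(df), "compound")
  bad <- scol[!grepl("^[^:]+:(KD|OE)$", scol)]
  if (length(bad)) {
    stop_pertnet("wide column '%s' is not in GENE:MODE form", bad[1L],
                 class = "pertnet_parse_error")
  }
  rows <- lapply(scol, function(cn) {
    parts <- strsplit(cn, ":", fixed = TRUE)[[1L]]
    v <- df[[cn]]
    keep <- nzchar(trimws(v)) & !is.na(v)
    data.frame(compound = df$compound[keep], gene = parts[1L],
               mode = parts[2L], score = v[keep], stringsAsFactors = FALSE)
  })
  perturbation_matrix(do.call(rbind, rows), scale = scale)
}

#' Write a perturbation matrix as long TSV (unit scale)
#'
#' @param pm a [perturbation_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_perturbation_matrix <- function(pm, path) {
  df <- as.data.frame(pm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
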