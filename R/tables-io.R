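# Readers/writers for the flat tables around the perturbation matrix:
# cancer-driver catalogs, compound-protein bioactivity pairs, pathway gene
# sets (GMT) and protein-protein interaction exports. All symbols are
# case-folded to uppercase; matching downstream is exact string equality.

#' Construct a cancer driver gene catalog
#'
#' @param genes character vector of gene symbols.
#' @param roles character vector, one of `"oncogene"`, `"tumor_suppressor"`,
#'   `"bifunctional"` per gene.
#' @return Object of class `driver_catalog`: data frame with columns
#'   `gene`, `role`.
#' @export
driver_catalog <- function(genes, roles) {
  genes <- check_symbols(genes, "driver catalog")
  roles <- trimws(as.character(roles))
  if (length(roles) != length(genes)) {
    stop_pertnet("catalog genes and roles differ in length",
                 class = "pertnet_validation_error")
  }
  if (length(roles) && any(!roles %in% DRIVER_ROLES)) {
    stop_pertnet("unknown driver role '%s' (allowed: %s)",
                 roles[!roles %in% DRIVER_ROLES][1L],
                 paste(DRIVER_ROLES, collapse = ", "),
                 class = "pertnet_validation_error")
  }
  if (anyDuplicated(genes)) {
    stop_pertnet("duplicate gene symbol in driver catalog: %s",
                 genes[duplicated(genes)][1L],
                 class = "pertnet_duplication_error")
  }
  ord <- order(genes)
  structure(data.frame(gene = genes[ord], role = roles[ord],
                       stringsAsFactors = FALSE),
            class = c("driver_catalog", "data.frame"))
}

#' Read a driver gene catalog (TSV: gene, role)
#' @param path TSV with header columns `gene` and `role`.
#' @return A [driver_catalog()].
#' @export
read_driver_catalog <- function(path) {
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "role") %in% names(df))) {
    stop_pertnet("driver catalog needs columns gene, role",
                 class = "pertnet_parse_error")
  }
  driver_catalog(df$gene, df$role)
}

#' @export
#' @rdname read_driver_catalog
#' @param catalog a [driver_catalog()].
write_driver_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

driver_genes <- function(catalog) catalog$gene

driver_role <- function(catalog, gene) {
  catalog$role[match(toupper(gene), catalog$gene)]
}

#' Construct a compound-protein bioactivity pair table
#'
#' @param compound,protein parallel identifier vectors.
#' @param evidence optional evidence tag per pair (`"experimental"` or
#'   `"putative"`); defaults to `"experimental"`.
#' @return Object of class `bioactivity_table` (data frame `compound`,
#'   `protein`, `evidence`).
#' @export
bioactivity_table <- function(compound, protein,
                              evidence = rep("experimental", length(compound))) {
  compound <- trimws(as.character(compound))
  protein <- check_symbols(protein, "bioactivity table")
  evidence <- trimws(as.character(evidence))
  if (length(evidence) && any(!evidence %in% c("experimental", "putative"))) {
    stop_pertnet("bioactivity evidence must be experimental or putative",
                 class = "pertnet_validation_error")
  }
  key <- paste(compound, protein, sep = "\r")
  if (anyDuplicated(key)) {
    stop_pertnet("duplicate bioactivity pair: %s",
                 gsub("\r", " / ", key[duplicated(key)][1L], fixed = TRUE),
                 class = "pertnet_duplication_error")
  }
  ord <- order(compound, protein)
  structure(data.frame(compound = compound[ord], protein = protein[ord],
                       evidence = evidence[ord], stringsAsFactors = FALSE),
            class = c("bioactivity_table", "data.frame"))
}

#' Read/write compound-protein bioactivity pairs (TSV: compound, protein[, evidence])
#' @param path TSV path.
#' @return A [bioactivity_table()].
#' @export
read_bioactivity <- function(path) {
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound", "protein") %in% names(df))) {
    stop_pertnet("bioactivity table needs columns compound, protein",
                 class = "pertnet_parse_error")
  }
  if (is.null(df$evidence)) df$evidence <- rep("experimental", nrow(df))
  bioactivity_table(df$compound, df$protein, df$evidence)
}

#' @export
#' @rdname read_bioactivity
#' @param pairs a [bioactivity_table()].
write_bioactivity <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a protein-protein interaction edge table
#'
#' Edges are undirected and stored canonically with `a < b`
#' (lexicographically); confidence scores live in `[0, 1]`, STRING-style.
#'
#' @param a,b gene symbol endpoint vectors.
#' @param confidence numeric confidence in `[0, 1]`.
#' @return Object of class `ppi_table` (data frame `a`, `b`, `confidence`).
#' @export
ppi_table <- function(a, b, confidence) {
  a <- check_symbols(a, "PPI table")
  b <- check_symbols(b, "PPI table")
  confidence <- as.numeric(confidence)
  if (any(a == b)) {
    stop_pertnet("PPI self-loop on %s", a[a == b][1L],
                 class = "pertnet_validation_error")
  }
  if (length(confidence) && (anyNA(confidence) ||
                             any(confidence < 0 | confidence > 1))) {
    stop_pertnet("PPI confidence scores must lie in [0, 1]",
                 class = "pertnet_validation_error")
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    stop_pertnet("duplicate PPI edge: %s",
                 gsub("\r", " -- ", key[duplicated(key)][1L], fixed = TRUE),
                 class = "pertnet_duplication_error")
  }
  ord <- order(lo, hi)
  structure(data.frame(a = lo[ord], b = hi[ord],
                       confidence = confidence[ord], stringsAsFactors = FALSE),
            class = c("ppi_table", "data.frame"))
}

#' Read/write a PPI edge table (TSV: a, b, confidence)
#' @param path TSV path.
#' @return A [ppi_table()].
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("a", "b", "confidence") %in% names(df))) {
    stop_pertnet("PPI table needs columns a, b, confidence",
                 class = "pertnet_parse_error")
  }
  ppi_table(df$a, df$b, df$confidence)
}

#' @export
#' @rdname read_ppi
#' @param ppi a [ppi_table()].
write_ppi <- function(ppi, path) {
  write.table(ppi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene...`.
#' Gene symbols are uppercased and de-duplicated within each set.
#'
#' @param path GMT path.
#' @return Object of class `pathway_collection`: named list of character
#'   vectors with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short)) {
    stop_pertnet("GMT line %d has fewer than 3 tab-separated fields",
                 short[1L], class = "pertnet_parse_error")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    sort(unique(check_symbols(f[-(1:2)], "GMT gene set")))
  })
  pathway_collection(ids, desc, sets)
}

#' Construct a pathway gene-set collection
#' @param ids unique pathway identifiers (e.g. `hsa04010`).
#' @param descriptions one description per pathway.
#' @param sets list of gene-symbol character vectors, one per pathway.
#' @return A `pathway_collection`.
#' @export
pathway_collection <- function(ids, descriptions, sets) {
  ids <- trimws(as.character(ids))
  if (anyDuplicated(ids)) {
    stop_pertnet("duplicate pathway identifier: %s", ids[duplicated(ids)][1L],
                 class = "pertnet_duplication_error")
  }
  if (any(!vapply(sets, length, 0L))) {
    stop_pertnet("pathway %s has an empty gene set",
                 ids[!vapply(sets, length, 0L)][1L],
                 class = "pertnet_validation_error")
  }
  sets <- lapply(sets, function(s) sort(unique(toupper(s))))
  names(sets) <- ids
  structure(sets, descriptions = setNames(as.character(descriptions), ids),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d gene sets (sizes %s)\n", length(x),
              paste(range(vapply(x, length, 0L)), collapse = "-")))
  invisible(x)
}

#' @export
#' @rdname read_gmt
#' @param collection a `pathway_collection`.
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
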