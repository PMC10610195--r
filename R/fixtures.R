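# Packaged reference tables for the uPAR case study: reported per-pathway
# repetition-rate counts, the experimentally confirmed uPAR modulators with
# their affected driver genes, the hallmark-driver-marker map, and the
# worked pair-rule examples. The demonstration matrix and the pathway
# membership GMT are synthetic stand-ins (marked `_synthetic` in their
# file names): their gene lists follow the curated tables but the
# individual scores / filler members are generated, chosen only to be
# consistent with the reported counts.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "pertnet")
  if (!nzchar(p)) {
    stop_pertnet("packaged fixture '%s' is missing or corrupt", file,
                 class = "pertnet_packaging_error")
  }
  p
}

#' Load the packaged reference tables
#'
#' @return A list:
#' \describe{
#'   \item{pathway_counts}{data frame `pathway`, `description`,
#'     `numerator`, `denominator`, `top10_count`: the reported per-pathway
#'     modulator counts behind the repetition-rate statistic.}
#'   \item{real_modulators}{data frame `compound`, `direction`
#'     (`suppression`/`stimulation`), plus list-column `genes`: the nine
#'     cell-assay-confirmed uPAR modulators and their affected driver
#'     genes.}
#'   \item{hallmarks}{a [hallmark_map()] of the four uPAR-mediated cancer
#'     hallmarks, their driver genes and preferred markers.}
#'   \item{pair_examples}{list: `matrix` (a [perturbation_matrix()] of the
#'     worked pair-rule rows, percent scores normalised to unit scale) and
#'     `effects` (data frame `compound`, `effect` with the reported
#'     verdicts).}
#'   \item{demo_matrix}{synthetic [perturbation_matrix()] in which each
#'     confirmed modulator carries supra-threshold scores exactly on its
#'     curated gene list (plus the target gene).}
#'   \item{memberships}{synthetic [pathway_collection()] whose top-10
#'     driver memberships reproduce the reported per-pathway counts.}
#'   \item{roles}{a [driver_catalog()] covering the top-10 driver genes
#'     with their oncogene / tumor-suppressor / bifunctional roles.}
#'   \item{top10_drivers}{character vector: the top-10 transcriptional
#'     driver hubs.}
#' }
#' @export
load_reference_tables <- function() {
  counts <- read.delim(fixture_path("pathway_counts.tsv"),
                       stringsAsFactors = FALSE)
  rm <- read.delim(fixture_path("real_modulators.tsv"),
                   stringsAsFactors = FALSE)
  rm$genes <- lapply(strsplit(rm$genes, ","), toupper)
  pe <- read.delim(fixture_path("pair_examples.tsv"),
                   stringsAsFactors = FALSE)
  effects <- unique(pe[, c("compound", "effect")])
  rownames(effects) <- NULL
  list(
    pathway_counts = counts,
    real_modulators = rm,
    hallmarks = read_hallmark_map(fixture_path("hallmark_map.tsv")),
    pair_examples = list(
      matrix = perturbation_matrix(pe[, c("compound", "gene", "mode",
                                          "score")], scale = "percent"),
      effects = effects),
    demo_matrix = read_perturbation_matrix(
      fixture_path("demo_matrix_synthetic.tsv"), scale = "unit"),
    memberships = read_gmt(fixture_path("pathway_memberships_synthetic.gmt")),
    roles = read_driver_catalog(fixture_path("driver_roles.tsv")),
    top10_drivers = c("AKT1", "KRAS", "HRAS", "PIK3R1", "JAK1", "EGFR",
                      "MYC", "ERBB3", "FGFR2", "SMAD4"))
}
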