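# Bipartite compound-target networks. The transcriptional layer links a
# modulator to every supra-threshold co-expressed cancer driver gene; the
# translational layer links a modulator to every cancer-driver protein it
# has a bioactivity record against. Degrees are unweighted edge counts;
# edge weights (the qualifying scores) are stored but never enter degree
# computations.

#' Construct a bipartite compound-target network
#'
#' @param edges data frame with columns `compound`, `target` and optionally
#'   `weight` (the qualifying score).
#' @param roles named character vector mapping target genes to driver roles
#'   (optional annotation carried into exports).
#' @param layer `"transcriptional"` or `"translational"`.
#' @return Object of class `bipartite_network`: list with `compounds`,
#'   `targets`, `edges` (canonically ordered), `roles`, `layer`.
#' @export
bipartite_network <- function(edges, roles = NULL,
                              layer = c("transcriptional", "translational")) {
  layer <- match.arg(layer)
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(compound = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (!all(c("compound", "target") %in% names(edges))) {
    stop_pertnet("network edges need columns compound, target",
                 class = "pertnet_validation_error")
  }
  edges$compound <- trimws(as.character(edges$compound))
  edges$target <- check_symbols(edges$target, "network targets")
  if (is.null(edges$weight)) edges$weight <- rep(NA_real_, nrow(edges))
  key <- paste(edges$compound, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    stop_pertnet("duplicate network edge: %s",
                 gsub("\r", " -> ", key[duplicated(key)][1L], fixed = TRUE),
                 class = "pertnet_duplication_error")
  }
  edges <- edges[order(edges$compound, edges$target),
                 c("compound", "target", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  targets <- sort(unique(edges$target))
  roles <- roles[names(roles) %in% targets]
  structure(list(compounds = sort(unique(edges$compound)), targets = targets,
                 edges = edges, roles = roles, layer = layer),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network (%s): %d compounds, %d targets, %d edges\n",
              x$layer, length(x$compounds), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Build the transcriptional compound-driver network
#'
#' One edge per (modulator, driver gene) with the driver gene present in the
#' modulator's supra-threshold co-expression profile (see
#' [coexpressed_targets()]). Non-driver genes are filtered out; target nodes
#' are the driver genes appearing in at least one edge.
#'
#' @param profiles named list: compound -> character vector of co-expressed
#'   genes (any-mode score above the co-expression threshold).
#' @param drivers a [driver_catalog()].
#' @return A [bipartite_network()] with layer `"transcriptional"`.
#' @export
build_transcriptional_network <- function(profiles, drivers) {
  if (!nrow(drivers)) {
    stop_pertnet("empty driver catalog", class = "pertnet_configuration_error")
  }
  dset <- driver_genes(drivers)
  rows <- lapply(names(profiles), function(cpd) {
    genes <- intersect(toupper(profiles[[cpd]]), dset)
    if (!length(genes)) return(NULL)
    data.frame(compound = cpd, target = genes, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  bipartite_network(edges, roles = setNames(drivers$role, drivers$gene),
                    layer = "transcriptional")
}

#' Build the translational compound-driver network
#'
#' One edge per bioactivity pair whose compound is a called modulator and
#' whose protein is a cancer driver gene.
#'
#' @param bioactivity a [bioactivity_table()].
#' @param modulators a modulator call table from [identify_modulators()], or
#'   a character vector of compound identifiers.
#' @param drivers a [driver_catalog()].
#' @return A [bipartite_network()] with layer `"translational"`.
#' @export
build_translational_network <- function(bioactivity, modulators, drivers) {
  cpds <- if (is.data.frame(modulators)) modulators$compound else modulators
  keep <- bioactivity$compound %in% cpds &
    bioactivity$protein %in% driver_genes(drivers)
  edges <- data.frame(compound = bioactivity$compound[keep],
                      target = bioactivity$protein[keep],
                      stringsAsFactors = FALSE)
  bipartite_network(edges, roles = setNames(drivers$role, drivers$gene),
                    layer = "translational")
}

#' Per-node degree table with deterministic ranking
#'
#' Degrees are unweighted edge counts. Within each node class, ranking is by
#' descending degree with ties broken lexicographically by identifier.
#'
#' @param network a [bipartite_network()].
#' @return Object of class `degree_table`: data frame `node`, `class`
#'   (`"compound"`/`"target"`), `degree`, `rank` (within class).
#' @export
degree_table <- function(network) {
  e <- network$edges
  one <- function(nodes, col, cls) {
    deg <- setNames(integer(length(nodes)), nodes)
    if (nrow(e)) {
      tab <- table(e[[col]])
      deg[names(tab)] <- as.integer(tab)
    }
    ord <- order(-deg, names(deg))
    data.frame(node = names(deg)[ord], class = cls,
               degree = as.integer(deg[ord]),
               rank = seq_along(deg), stringsAsFactors = FALSE)
  }
  out <- rbind(one(network$compounds, "compound", "compound"),
               one(network$targets, "target", "target"))
  rownames(out) <- NULL
  structure(out, class = c("degree_table", "data.frame"))
}

#' Top-k hub nodes of one class
#'
#' @param table a [degree_table()].
#' @param node_class `"compound"` or `"target"`.
#' @param k number of hubs wanted (`k >= 1`); if fewer nodes exist, all are
#'   returned in ranked order.
#' @return Character vector of node identifiers, rank order.
#' @export
top_k_hubs <- function(table, node_class = c("target", "compound"), k) {
  node_class <- match.arg(node_class)
  if (k < 1) {
    stop_pertnet("k must be >= 1", class = "pertnet_validation_error")
  }
  sub <- table[table$class == node_class, , drop = FALSE]
  head(sub$node[order(sub$rank)], k)
}

#' Core subnetwork of high-degree targets
#'
#' Keeps the target nodes whose compound degree strictly exceeds
#' `min_compound_degree` (matching "interacted with more than 90 compounds"
#' semantics) together with all their incident compounds and edges.
#'
#' @param network a [bipartite_network()].
#' @param min_compound_degree non-negative degree cutoff (strict `>`).
#' @return The induced [bipartite_network()].
#' @export
core_subnetwork <- function(network, min_compound_degree) {
  if (min_compound_degree < 0) {
    stop_pertnet("min_compound_degree must be >= 0",
                 class = "pertnet_validation_error")
  }
  dt <- degree_table(network)
  keep <- dt$node[dt$class == "target" & dt$degree > min_compound_degree]
  edges <- network$edges[network$edges$target %in% keep, , drop = FALSE]
  bipartite_network(edges, roles = network$roles, layer = network$layer)
}

#' Induce the PPI core on a target set
#'
#' Restricts a PPI edge table to the given genes, keeping edges with
#' confidence strictly above `min_score` (STRING-style "score > 0.7").
#' Targets without any retained interaction remain as isolated nodes.
#'
#' @param targets character vector of gene symbols.
#' @param ppi a [ppi_table()].
#' @param min_score confidence cutoff in `[0, 1]` (strict `>`).
#' @return Object of class `gene_graph`: list with `nodes` (all supplied
#'   targets) and `edges` (data frame `a`, `b`, `confidence`).
#' @export
induce_ppi_core <- function(targets, ppi, min_score = 0.7) {
  if (min_score < 0 || min_score > 1) {
    stop_pertnet("min_score must lie in [0, 1]",
                 class = "pertnet_validation_error")
  }
  targets <- sort(unique(toupper(targets)))
  keep <- ppi$a %in% targets & ppi$b %in% targets & ppi$confidence > min_score
  edges <- ppi[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = targets, edges = as.data.frame(edges)),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network size and mean-degree summary
#'
#' Class means are edge count divided by class size; an empty class reports
#' a mean of 0.
#'
#' @param network a [bipartite_network()].
#' @return List: `n_nodes`, `n_compounds`, `n_targets`, `n_edges`,
#'   `mean_target_degree`, `mean_compound_degree`.
#' @export
network_summary <- function(network) {
  ne <- nrow(network$edges)
  nc <- length(network$compounds)
  nt <- length(network$targets)
  list(n_nodes = nc + nt, n_compounds = nc, n_targets = nt, n_edges = ne,
       mean_target_degree = if (nt) ne / nt else 0,
       mean_compound_degree = if (nc) ne / nc else 0)
}

# Network export/import --------------------------------------------------

#' Write a bipartite network to SIF, GraphML or edge TSV
#'
#' SIF rows are `compound TAB interacts TAB target`. GraphML (written via
#' igraph) carries node attributes `type` (compound/target) and `role`
#' (driver role, empty when unknown) plus edge `weight`. The edge-TSV format
#' is the three-column `compound`, `target`, `weight` table.
#'
#' @param network a [bipartite_network()].
#' @param path output file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  if (length(format) == 1 && !format %in% c("sif", "graphml", "tsv")) {
    stop_pertnet("unknown network format '%s'", format,
                 class = "pertnet_usage_error")
  }
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$compound, "interacts", e$target,
                                  sep = "\t") else character(), path)
  } else if (format == "tsv") {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a bipartite network to an igraph object
#' @param network a [bipartite_network()].
#' @return An undirected `igraph` graph with `type` and `role` vertex
#'   attributes and `weight` edge attribute.
#' @export
as_igraph <- function(network) {
  verts <- data.frame(
    name = c(network$compounds, network$targets),
    type = c(rep("compound", length(network$compounds)),
             rep("target", length(network$targets))),
    stringsAsFactors = FALSE)
  role <- rep("", nrow(verts))
  if (length(network$roles)) {
    hit <- match(verts$name, names(network$roles))
    role[!is.na(hit) & verts$type == "target"] <-
      unname(network$roles[hit[!is.na(hit) & verts$type == "target"]])
  }
  verts$role <- role
  e <- network$edges
  e$weight[is.na(e$weight)] <- 0
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = verts)
}

#' Read a bipartite network written by [write_network()]
#'
#' @param path file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param layer layer tag for the reconstructed network.
#' @return A [bipartite_network()]. SIF carries no weights or roles; the
#'   edge set is still recovered exactly.
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv"),
                         layer = "transcriptional") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_pertnet("file not found: %s", path, class = "pertnet_io_error")
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      return(bipartite_network(NULL, layer = layer))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(parts, length, 0L) != 3L)) {
      stop_pertnet("malformed SIF line", class = "pertnet_parse_error")
    }
    edges <- data.frame(compound = vapply(parts, `[[`, "", 1L),
                        target = vapply(parts, `[[`, "", 3L),
                        stringsAsFactors = FALSE)
    return(bipartite_network(edges, layer = layer))
  }
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    return(bipartite_network(df, layer = layer))
  }
  g <- igraph::read_graph(path, format = "graphml")
  vn <- igraph::V(g)$name
  vtype <- igraph::V(g)$type
  vrole <- igraph::V(g)$role
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight %||% rep(NA_real_, nrow(el))
  is_cpd <- setNames(vtype == "compound", vn)
  # normalize edge orientation: compound endpoint first
  flip <- !is_cpd[el[, 1]]
  edges <- data.frame(
    compound = ifelse(flip, el[, 2], el[, 1]),
    target = ifelse(flip, el[, 1], el[, 2]),
    weight = ifelse(w == 0, NA_real_, w), stringsAsFactors = FALSE)
  roles <- setNames(vrole, vn)[!is_cpd[vn]]
  roles <- roles[nzchar(roles)]
  bipartite_network(edges, roles = roles, layer = layer)
}
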