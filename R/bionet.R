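#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|` on equal-length logical bit vectors. Two all-zero
#' fingerprints have similarity 0 (not 1), so unannotated compounds never
#' form spurious similarity cliques.
#'
#' @param a,b logical vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint length mismatch", call. = FALSE)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Build the integrated metabolite-protein-gene biochemical network
#'
#' Constructs an undirected typed graph with node kinds gene, protein,
#' metabolite and enzyme (EC number), and five edge classes:
#' `gene-enzyme` and `protein-enzyme` (entity annotated with the EC),
#' `compound-enzyme` (metabolite linked to the EC of a transforming enzyme),
#' `rpair` (curated biochemical reactant pairs, symmetric), and
#' `chemical-similarity` (metabolite pairs with Tanimoto similarity strictly
#' greater than `threshold`; the similarity is stored as the edge weight).
#' Gene, protein and metabolite nodes carry fold change, raw p-value and
#' direction from the supplied per-feature statistics; entities without a
#' record get neutral attributes (fold change 1, direction "unchanged") with
#' a warning. Node and edge order is deterministic.
#'
#' @param fingerprints logical matrix of compound fingerprints (metabolite
#'   ids in rownames), or `NULL` for no chemical-similarity edges.
#' @param rpairs two-column data frame of reactant-pair metabolite ids, or
#'   `NULL`.
#' @param compound_ec data frame with columns `metabolite`, `ec`, or `NULL`.
#' @param gene_ec named list gene -> EC vector (see [parse_ec_map()]), or
#'   `NULL`.
#' @param protein_ec data frame with columns `protein`, `ec`, or `NULL`.
#' @param node_stats data frame with columns `feature_id`, `fold_change`,
#'   `raw_p`, `direction` used to decorate nodes (e.g. rbind of
#'   `diff_table`s).
#' @param threshold chemical-similarity edge threshold (strict `>`).
#' @return an [igraph::igraph] graph with vertex attributes `kind`,
#'   `fold_change`, `raw_p`, `direction` and edge attributes `edge_class`,
#'   `weight` (`NA` except on chemical-similarity edges).
#' @export
build_network <- function(fingerprints = NULL, rpairs = NULL,
                          compound_ec = NULL, gene_ec = NULL,
                          protein_ec = NULL, node_stats = NULL,
                          threshold = 0.7) {
  rsort <- function(x) {
    x <- unique(as.character(x[!is.na(x)]))
    if (length(x) == 0) character(0) else sort(x, method = "radix")
  }
  met_ids <- rsort(c(rownames(fingerprints),
                     if (!is.null(rpairs)) c(rpairs[[1]], rpairs[[2]]),
                     compound_ec$metabolite))
  gene_ids <- rsort(names(gene_ec))
  prot_ids <- rsort(protein_ec$protein)
  ec_ids <- rsort(c(unlist(gene_ec, use.names = FALSE), protein_ec$ec,
                    compound_ec$ec))

  ec_nodes <- if (length(ec_ids)) paste0("EC:", ec_ids) else character(0)
  nodes <- data.frame(
    id = c(gene_ids, prot_ids, met_ids, ec_nodes),
    kind = rep(c("gene", "protein", "metabolite", "enzyme"),
               c(length(gene_ids), length(prot_ids), length(met_ids),
                 length(ec_ids))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    stop("node id collision across kinds; use distinct namespaces",
         call. = FALSE)

  edges <- list()
  if (!is.null(gene_ec) && length(gene_ec) > 0) {
    g <- rep(names(gene_ec), lengths(gene_ec))
    edges$gene <- data.frame(from = g,
                             to = paste0("EC:", unlist(gene_ec,
                                                       use.names = FALSE)),
                             edge_class = "gene-enzyme",
                             weight = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(protein_ec) && nrow(protein_ec) > 0) {
    edges$protein <- data.frame(from = protein_ec$protein,
                                to = paste0("EC:", protein_ec$ec),
                                edge_class = "protein-enzyme",
                                weight = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(compound_ec) && nrow(compound_ec) > 0) {
    edges$compound <- data.frame(from = compound_ec$metabolite,
                                 to = paste0("EC:", compound_ec$ec),
                                 edge_class = "compound-enzyme",
                                 weight = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(rpairs) && nrow(rpairs) > 0) {
    a <- pmin(rpairs[[1]], rpairs[[2]])
    b <- pmax(rpairs[[1]], rpairs[[2]])
    keep <- a != b
    rp <- unique(data.frame(from = a[keep], to = b[keep],
                            stringsAsFactors = FALSE))
    edges$rpair <- data.frame(rp, edge_class = "rpair", weight = NA_real_,
                              stringsAsFactors = FALSE)
  }
  if (!is.null(fingerprints) && nrow(fingerprints) >= 2) {
    fp <- fingerprints[sort(rownames(fingerprints), method = "radix"), ,
                       drop = FALSE]
    m <- fp * 1L
    inter <- tcrossprod(m)
    ones <- rowSums(m)
    uni <- outer(ones, ones, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, 0)
    idx <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      edges$chem <- data.frame(from = rownames(fp)[idx[, 1]],
                               to = rownames(fp)[idx[, 2]],
                               edge_class = "chemical-similarity",
                               weight = sim[idx], stringsAsFactors = FALSE)
    }
  }
  if (length(edges) > 0) {
    edges <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        edge_class = character(0), weight = numeric(0))
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges$edge_class, edges$from, edges$to,
                       method = "radix"), , drop = FALSE]

  fold <- rep(1, nrow(nodes))
  rawp <- rep(NA_real_, nrow(nodes))
  dir <- rep("unchanged", nrow(nodes))
  if (!is.null(node_stats)) {
    hit <- match(nodes$id, node_stats$feature_id)
    ok <- !is.na(hit)
    fold[ok] <- node_stats$fold_change[hit[ok]]
    rawp[ok] <- node_stats$raw_p[hit[ok]]
    dir[ok] <- node_stats$direction[hit[ok]]
    missing_entities <- sum(!ok & nodes$kind != "enzyme")
    if (missing_entities > 0)
      warning(missing_entities, " node(s) lack differential statistics; ",
              "neutral attributes assigned", call. = FALSE)
  }
  nodes$fold_change <- fold
  nodes$raw_p <- rawp
  nodes$direction <- dir

  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Label graph communities by modularity clustering
#'
#' Multilevel (Louvain) modularity optimization on the simplified,
#' unweighted graph, with a fixed RNG seed so labels are reproducible.
#' Connected components are never merged: Louvain communities are connected
#' subgraphs and joining disconnected components cannot increase modularity.
#' Every node receives a label, also in the empty graph.
#'
#' @param graph an igraph graph, possibly disconnected.
#' @param seed RNG seed fixing the (otherwise order-dependent) Louvain
#'   refinement.
#' @return named integer vector node id -> community label.
#' @export
detect_communities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) return(stats::setNames(integer(0),
                                                         character(0)))
  g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = NA)
  stats::setNames(igraph::membership(cl), igraph::V(g)$name)
}

#' Export the biochemical network for Cytoscape
#'
#' `"graphml"` writes a single GraphML file whose re-read reproduces the
#' nodes, edges, edge classes, similarity weights and fold changes.
#' `"sif"` writes a SIF file (`source<TAB>edge_class<TAB>target`, one line
#' per edge) plus `<path>.nodes.tsv` / `<path>.edges.tsv` attribute tables;
#' the node table carries Cytoscape-style `size` (fold change) and `color`
#' (direction) visual attributes.
#'
#' @param graph graph from [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  writeLines(paste(el$from, el$edge_class, el$to, sep = "\t"), path)
  nd <- igraph::as_data_frame(graph, what = "vertices")
  nd$size <- nd$fold_change
  nd$color <- ifelse(nd$direction == "up", "red",
                     ifelse(nd$direction == "down", "blue", "grey"))
  utils::write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(el, paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a GraphML file written by [export_graph()]
#'
#' Thin wrapper over [igraph::read_graph()] that restores `NA` edge weights
#' (GraphML serializes them as NaN).
#'
#' @param path GraphML file path.
#' @return an igraph graph.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("weight" %in% igraph::edge_attr_names(g)) {
    w <- igraph::E(g)$weight
    w[is.nan(w)] <- NA_real_
    igraph::E(g)$weight <- w
  }
  g
}

#' Parse and write hex-encoded fingerprint tables
#'
#' Fingerprints are stored as TSV with columns `id` and `fp` (hex string,
#' 4 bits per character, most significant bit first).
#'
#' @param path TSV file path.
#' @param n_bits fingerprint length; inferred from the hex width if `NULL`.
#' @return logical matrix with ids as rownames.
#' @export
read_fingerprints <- function(path, n_bits = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  hex_to_bits <- function(h) {
    nib <- strtoi(strsplit(h, "")[[1]], base = 16L)
    as.logical(as.vector(sapply(nib, function(x) bitwAnd(x, c(8L, 4L, 2L, 1L)) > 0)))
  }
  bits <- t(vapply(df$fp, hex_to_bits, logical(nchar(df$fp[1]) * 4)))
  rownames(bits) <- df$id
  if (!is.null(n_bits)) bits <- bits[, seq_len(n_bits), drop = FALSE]
  bits
}

#' @rdname read_fingerprints
#' @param fingerprints logical matrix (ids in rownames).
#' @export
write_fingerprints <- function(fingerprints, path) {
  n_bits <- ncol(fingerprints)
  pad <- (4 - n_bits %% 4) %% 4
  hex <- apply(fingerprints, 1, function(b) {
    b <- c(b, rep(FALSE, pad))
    nib <- colSums(matrix(as.integer(b), nrow = 4) * c(8L, 4L, 2L, 1L))
    paste(sprintf("%x", nib), collapse = "")
  })
  utils::write.table(data.frame(id = rownames(fingerprints), fp = hex),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
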