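#' Run the full prioritization workflow on a synthetic cohort
#'
#' Executes the complete pipeline end to end on data drawn from a
#' [sim_config()]: (1) simulate the transcriptomics study collection plus
#' one proteomics and one metabolomics study on the anchor cohort (study 1)
#' and the annotation fixtures; (2) prevalence-filter the proteomics matrix
#' (features seen in at least `min_prevalence` samples of either group are
#' kept); (3) per-study differential statistics — Welch t on log2 values for
#' transcripts, Mann-Whitney U for proteins and metabolites — with Table-1
#' style significance summaries; (4) select metabolic genes from the EC map;
#' (5) KS meta-analysis of per-study raw p-values over the metabolic genes;
#' (6) pooled multi-omics pathway over-representation of the significant
#' features with per-omics support flags; (7) integrated biochemical network
#' with community labels, exported as GraphML and SIF; (8) prioritization of
#' the top meta-analysis genes by literature count, plus the
#' proteomics/meta-analysis cross-support table.
#'
#' All output tables are written to `out_dir` with deterministic bytes:
#' repeating a run with the same config and seed reproduces every file
#' exactly.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing.
#' @param alpha raw-p significance level used throughout.
#' @param min_prevalence proteomics prevalence rule (either-group minimum).
#' @param min_studies meta-analysis floor on per-gene study count.
#' @param understudied_threshold literature-count cutoff.
#' @param top_n number of prioritized genes reported.
#' @return invisible list with the main in-memory results: `diff_tables`,
#'   `summaries`, `metabolic_genes`, `meta`, `enrichment`, `graph`,
#'   `communities`, `priority`, `protein_support`, `truth`, `annotations`.
#' @export
full_run <- function(config, out_dir = NULL, alpha = 0.05,
                     min_prevalence = 6L, min_studies = 3L,
                     understudied_threshold = 5L, top_n = 50L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out_path <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)

  ann <- simulate_annotations(config)
  coll <- simulate_collection(config)
  prot <- simulate_study(config, "protein", 1L)$matrix
  met <- simulate_study(config, "metabolite", 1L)$matrix
  truth <- simulate_truth(config)

  prot <- prevalence_filter(prot, min_prevalence)

  diff_tr <- lapply(coll$matrices, run_differential, test = "welch")
  diff_prot <- suppressWarnings(run_differential(prot, test = "mwu"))
  diff_met <- suppressWarnings(run_differential(met, test = "mwu"))

  summaries <- c(
    lapply(diff_tr, summarize_counts, alpha = alpha),
    list(summarize_counts(diff_prot, alpha = alpha),
         summarize_counts(diff_met, alpha = alpha)))
  names(summaries) <- c(vapply(coll$matrices, `[[`, character(1), "study_id"),
                        prot$study_id, met$study_id)

  ec_ann <- lapply(split(ann$ec_map$ec, ann$ec_map$gene),
                   function(e) sort(unique(e)))
  metabolic_genes <- select_metabolic_genes(ec_ann)

  meta <- meta_analyze(diff_tr, gene_universe = metabolic_genes,
                       min_studies = min_studies)

  sig_ids <- function(tbl) tbl$feature_id[tbl$raw_p < alpha]
  gene_sel <- intersect(sig_ids(diff_tr[[1]]), metabolic_genes)
  enrichment <- multiomics_enrich(
    gene_sel = gene_sel, prot_sel = sig_ids(diff_prot),
    met_sel = sig_ids(diff_met),
    gene_univ = intersect(diff_tr[[1]]$feature_id, metabolic_genes),
    prot_univ = diff_prot$feature_id, met_univ = diff_met$feature_id,
    db = ann$pathways)

  sig_mets <- sig_ids(diff_met)
  # proteins share gene symbols; network node ids get a "prot:" namespace
  prot_stats <- as.data.frame(diff_prot)
  prot_stats$feature_id <- paste0("prot:", prot_stats$feature_id)
  node_stats <- rbind(prot_stats, as.data.frame(diff_met),
                      as.data.frame(diff_tr[[1]]))
  node_stats <- node_stats[!duplicated(node_stats$feature_id), ]
  sig_prot_ec <- intersect(sig_ids(diff_prot), ann$ec_map$gene)
  graph <- suppressWarnings(build_network(
    fingerprints = ann$fingerprints[rownames(ann$fingerprints) %in% sig_mets,
                                    , drop = FALSE],
    rpairs = ann$rpairs[ann$rpairs$a %in% sig_mets &
                          ann$rpairs$b %in% sig_mets, , drop = FALSE],
    compound_ec = ann$compound_ec[ann$compound_ec$metabolite %in% sig_mets,
                                  , drop = FALSE],
    gene_ec = ec_ann[intersect(gene_sel, names(ec_ann))],
    protein_ec = data.frame(
      protein = paste0("prot:", sig_prot_ec),
      ec = ann$ec_map$ec[match(sig_prot_ec, ann$ec_map$gene)],
      stringsAsFactors = FALSE),
    node_stats = node_stats, threshold = 0.7))
  communities <- detect_communities(graph, seed = config$seed)

  counts <- ann$lit_counts
  counts$available <- TRUE
  priority <- prioritize(meta, counts, diff_gene = diff_tr[[1]],
                         diff_protein = diff_prot,
                         threshold = understudied_threshold, top_n = top_n)
  protein_support <- cross_omics_protein_support(diff_prot, meta, counts,
                                                 alpha = alpha)

  if (!is.null(out_dir)) {
    for (i in seq_along(diff_tr))
      write_diff_tsv(diff_tr[[i]], out_path(sprintf("diff_study%02d.tsv", i)))
    write_diff_tsv(diff_prot, out_path("diff_proteins.tsv"))
    write_diff_tsv(diff_met, out_path("diff_metabolites.tsv"))
    jsonlite::write_json(summaries, out_path("summary_counts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(metabolic_genes, out_path("metabolic_genes.txt"))
    write_diff_tsv(meta, out_path("meta_analysis.tsv"))
    write_diff_tsv(enrichment, out_path("enrichment.tsv"))
    export_graph(graph, out_path("network.graphml"), format = "graphml")
    export_graph(graph, out_path("network.sif"), format = "sif")
    write_diff_tsv(data.frame(id = names(communities),
                              community = as.integer(communities)),
                   out_path("communities.tsv"))
    write_diff_tsv(priority, out_path("priority.tsv"))
    write_diff_tsv(protein_support, out_path("protein_support.tsv"))
  }

  invisible(list(diff_tables = diff_tr, diff_protein = diff_prot,
                 diff_metabolite = diff_met, summaries = summaries,
                 metabolic_genes = metabolic_genes, meta = meta,
                 enrichment = enrichment, graph = graph,
                 communities = communities, priority = priority,
                 protein_support = protein_support, truth = truth,
                 annotations = ann))
}
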