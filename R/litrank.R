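#' Retrieve per-gene literature counts (PubMed query counts)
#'
#' Counts of PubMed abstracts matching `"<SYMBOL>" AND "breast cancer"` per
#' gene. Two sources are supported: `"fixture"` reads a two-column TSV
#' (gene, count) — the reproducible path used by all tests — and `"live"`
#' queries the NCBI eutils esearch endpoint (requires network; results are
#' cached to `cache` if given). A failed live retrieval marks the gene
#' unavailable; it is never recorded as a fabricated zero.
#'
#' @param genes character vector of gene symbols.
#' @param source `"fixture"` or `"live"`.
#' @param fixture_path TSV with header columns `gene`, `n_papers` (fixture
#'   mode).
#' @param query_template query with `%s` placeholder for the symbol.
#' @param cache optional RDS-free TSV cache path for live mode.
#' @param delay seconds between live requests (eutils rate limit).
#' @return data frame with columns `gene`, `n_papers` (`NA` when
#'   unavailable), `query`, `source`, `available`.
#' @export
fetch_counts <- function(genes, source = c("fixture", "live"),
                         fixture_path = NULL,
                         query_template = "\"%s\" AND \"breast cancer\"",
                         cache = NULL, delay = 0.4) {
  source <- match.arg(source)
  genes <- as.character(genes)
  query <- sprintf(query_template, genes)
  if (length(genes) == 0)
    return(data.frame(gene = character(0), n_papers = integer(0),
                      query = character(0), source = character(0),
                      available = logical(0)))

  if (source == "fixture") {
    if (is.null(fixture_path))
      stop("fixture mode requires 'fixture_path'", call. = FALSE)
    fx <- utils::read.table(fixture_path, sep = "\t", header = TRUE,
                            quote = "", stringsAsFactors = FALSE)
    hit <- match(genes, fx$gene)
    out <- data.frame(gene = genes,
                      n_papers = as.integer(fx$n_papers[hit]),
                      query = query, source = "fixture",
                      available = !is.na(hit), stringsAsFactors = FALSE)
    return(out)
  }

  cached <- NULL
  if (!is.null(cache) && file.exists(cache))
    cached <- utils::read.table(cache, sep = "\t", header = TRUE,
                                quote = "", stringsAsFactors = FALSE)
  n_papers <- rep(NA_integer_, length(genes))
  for (i in seq_along(genes)) {
    if (!is.null(cached) && genes[i] %in% cached$gene) {
      n_papers[i] <- cached$n_papers[match(genes[i], cached$gene)]
      next
    }
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                  "esearch.fcgi?db=pubmed&rettype=count&retmode=json&term=",
                  utils::URLencode(query[i], reserved = TRUE))
    n_papers[i] <- tryCatch({
      res <- jsonlite::fromJSON(url)
      as.integer(res$esearchresult$count)
    }, error = function(e) NA_integer_)
    Sys.sleep(delay)
  }
  out <- data.frame(gene = genes, n_papers = n_papers, query = query,
                    source = "live", available = !is.na(n_papers),
                    stringsAsFactors = FALSE)
  if (!is.null(cache))
    utils::write.table(out[out$available, c("gene", "n_papers")], cache,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Prioritize metabolic candidate genes by meta-analysis and literature count
#'
#' Takes the `top_n` most significant genes of the meta-analysis (ascending
#' meta p, lexicographic gene tie-break), attaches per-omics anchor-cohort
#' p-values where present (`NA` for proteins not observed in the proteomics
#' panel), and flags as under-studied the genes with fewer than `threshold`
#' matching publications. Genes whose literature count is unavailable are
#' marked so and excluded from the under-studied set. Ranking is a pure
#' function of the inputs: shuffling input row order never changes it.
#'
#' @param meta meta-analysis table from [meta_analyze()].
#' @param counts literature counts from [fetch_counts()].
#' @param diff_gene,diff_protein optional anchor-cohort `diff_table`s whose
#'   `raw_p` is attached as `metacancer_gene_p` / `metacancer_protein_p`.
#' @param threshold under-studied cutoff: `n_papers < threshold`.
#' @param top_n number of top meta-analysis genes to keep.
#' @return data frame with columns `rank`, `gene`, `meta_p`,
#'   `metacancer_gene_p`, `metacancer_protein_p`, `n_papers`,
#'   `count_available`, `understudied`.
#' @export
prioritize <- function(meta, counts, diff_gene = NULL, diff_protein = NULL,
                       threshold = 5L, top_n = 50L) {
  if (nrow(meta) == 0) stop("empty meta-analysis table", call. = FALSE)
  ok <- meta[meta$status == "ok", , drop = FALSE]
  ok <- ok[order(ok$meta_p, ok$gene, method = "radix"), , drop = FALSE]
  top <- utils::head(ok, top_n)

  lookup_p <- function(tbl, genes) {
    if (is.null(tbl)) return(rep(NA_real_, length(genes)))
    tbl$raw_p[match(genes, tbl$feature_id)]
  }
  hit <- match(top$gene, counts$gene)
  n_papers <- counts$n_papers[hit]
  available <- !is.na(hit) & counts$available[hit]
  out <- data.frame(
    rank = seq_len(nrow(top)),
    gene = top$gene,
    meta_p = top$meta_p,
    metacancer_gene_p = lookup_p(diff_gene, top$gene),
    metacancer_protein_p = lookup_p(diff_protein, top$gene),
    n_papers = ifelse(available, n_papers, NA_integer_),
    count_available = available,
    understudied = available & !is.na(n_papers) & n_papers < threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Proteins supported by both proteomics and the gene-expression meta-analysis
#'
#' Selects proteins significant in the anchor-cohort proteomics
#' (`raw_p < alpha`) whose coding gene is also significant in the
#' meta-analysis (`meta_p < alpha`), partitions them by proteomics fold
#' direction, and annotates literature counts. Proteins that cannot be
#' mapped to a gene symbol are reported in `attr(, "unmapped")` and
#' excluded.
#'
#' @param prot_diff proteomics `diff_table`.
#' @param meta meta-analysis table from [meta_analyze()].
#' @param counts literature counts from [fetch_counts()] (keyed by gene).
#' @param alpha significance level applied to both layers.
#' @param protein_gene_map optional named character vector protein id ->
#'   gene symbol; identity if `NULL`.
#' @return data frame with columns `protein`, `gene`, `proteomics_p`,
#'   `meta_p`, `direction`, `n_papers`, sorted by direction (up first) then
#'   proteomics p.
#' @export
cross_omics_protein_support <- function(prot_diff, meta, counts,
                                        alpha = 0.05,
                                        protein_gene_map = NULL) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  prot <- as.data.frame(prot_diff)
  if (is.null(protein_gene_map)) {
    prot$gene <- prot$feature_id
    unmapped <- character(0)
  } else {
    prot$gene <- unname(protein_gene_map[prot$feature_id])
    unmapped <- prot$feature_id[is.na(prot$gene)]
    prot <- prot[!is.na(prot$gene), , drop = FALSE]
  }
  mp <- meta$meta_p[match(prot$gene, meta$gene)]
  keep <- !is.na(prot$raw_p) & prot$raw_p < alpha & !is.na(mp) & mp < alpha
  out <- data.frame(protein = prot$feature_id[keep],
                    gene = prot$gene[keep],
                    proteomics_p = prot$raw_p[keep],
                    meta_p = mp[keep],
                    direction = prot$direction[keep],
                    stringsAsFactors = FALSE)
  out$n_papers <- counts$n_papers[match(out$gene, counts$gene)]
  out <- out[order(out$direction != "up", out$proteomics_p, out$protein,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (length(unmapped) > 0)
    warning(length(unmapped), " unmapped protein(s) excluded", call. = FALSE)
  structure(out, unmapped = unmapped)
}
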