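#' One-sided Kolmogorov-Smirnov statistic D+ against Uniform(0,1)
#'
#' `D+ = max_i (i/n - p_(i))`, floored at zero, where `p_(i)` is the i-th
#' order statistic of the p-values. Large values indicate an excess of small
#' p-values relative to the uniform null, i.e. consistent differential
#' expression across studies.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`, length >= 1.
#' @return D+ in `[0, 1]`.
#' @export
ks_dplus <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector", call. = FALSE)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(pvals)
  max(0, max(seq_len(n) / n - sort(pvals)))
}

#' Exact one-sided KS tail probability (Birnbaum-Tingey/Smirnov)
#'
#' Computes `P(D+ >= d)` for a sample of `n` independent Uniform(0,1)
#' variables via the exact finite sum
#' `d * sum_{j=0}^{floor(n(1-d))} C(n,j) (d + j/n)^(j-1) (1 - d - j/n)^(n-j)`,
#' clamped to `[0, 1]`. The exact tail is used because study counts are
#' small (n around 10) and the interesting tail probabilities reach the
#' 1e-15 scale, far outside asymptotic validity. When `floor(n(1-d)) = 0`
#' the sum collapses to the closed form `(1-d)^n`.
#'
#' @param d observed D+ statistic in `[0, 1]`.
#' @param n sample size (number of studies), >= 1.
#' @return exact tail probability in `[0, 1]`.
#' @export
ks_exact_p <- function(d, n) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (is.na(d) || d < 0 || d > 1) stop("'d' must lie in [0, 1]", call. = FALSE)
  if (d == 0) return(1)
  if (d >= 1) return(0)
  jmax <- floor(n * (1 - d))
  j <- 0:jmax
  # term j: C(n,j) (d + j/n)^(j-1) (1 - d - j/n)^(n-j); computed in log
  # space for the magnitudes, signs are all positive
  a <- d + j / n
  b <- pmax(0, 1 - d - j / n)
  log_terms <- lchoose(n, j) + (j - 1) * log(a) +
    ifelse(b == 0 & n == j, 0, (n - j) * log(b))
  p <- d * sum(exp(log_terms))
  min(1, max(0, p))
}

#' Per-gene KS meta-analysis of raw p-values across studies
#'
#' For every gene of the universe, assembles the vector of raw p-values from
#' the studies in which the gene was measured and tests whether that vector
#' is stochastically smaller than Uniform(0,1) using the one-sided exact KS
#' tail (default). Genes measured in fewer than `min_studies` studies are
#' reported with status `"insufficient_evidence"` and `NA` statistics, not
#' silently dropped. With a single study the statistic degenerates to
#' `D+ = 1 - p` and the meta p-value to `p` itself.
#'
#' @param diff_tables list of `diff_table` objects (one per study) from
#'   [run_differential()].
#' @param gene_universe character vector of genes to analyze; defaults to
#'   the union of features across tables.
#' @param min_studies minimum number of studies a gene must appear in.
#' @param alternative `"greater"` (one-sided D+, default) or `"two.sided"`
#'   (D = max(D+, D-), tail bounded by twice the one-sided tail).
#' @return data frame with columns `gene`, `n_studies`, `d_plus`, `meta_p`,
#'   `status`, sorted ascending by `meta_p` with lexicographic gene-symbol
#'   tie-break; insufficient-evidence rows sort last.
#' @export
meta_analyze <- function(diff_tables, gene_universe = NULL, min_studies = 3L,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(diff_tables) < 1) stop("need at least one diff table",
                                    call. = FALSE)
  if (min_studies < 1) stop("'min_studies' must be >= 1", call. = FALSE)
  all_feat <- unlist(lapply(diff_tables, function(t) t$feature_id),
                     use.names = FALSE)
  if (is.null(gene_universe))
    gene_universe <- unique(all_feat)
  gene_universe <- sort(unique(gene_universe), method = "radix")
  if (length(gene_universe) == 0) {
    warning("empty gene universe", call. = FALSE)
    return(data.frame(gene = character(0), n_studies = integer(0),
                      d_plus = numeric(0), meta_p = numeric(0),
                      status = character(0)))
  }

  pmap <- new.env(parent = emptyenv())
  for (g in gene_universe) assign(g, numeric(0), envir = pmap)
  for (tbl in diff_tables) {
    hit <- tbl$feature_id %in% gene_universe
    for (i in which(hit)) {
      g <- tbl$feature_id[i]
      assign(g, c(get(g, envir = pmap), tbl$raw_p[i]), envir = pmap)
    }
  }

  n_st <- integer(length(gene_universe))
  dpl <- mp <- rep(NA_real_, length(gene_universe))
  for (k in seq_along(gene_universe)) {
    pv <- get(gene_universe[k], envir = pmap)
    n_st[k] <- length(pv)
    if (n_st[k] < min_studies) next
    d <- ks_dplus(pv)
    if (alternative == "two.sided") {
      n <- length(pv)
      dm <- max(0, max(sort(pv) - (seq_len(n) - 1) / n))
      d <- max(d, dm)
      mp[k] <- min(1, 2 * ks_exact_p(d, n))
    } else {
      mp[k] <- ks_exact_p(d, n_st[k])
    }
    dpl[k] <- d
  }

  out <- data.frame(gene = gene_universe, n_studies = n_st, d_plus = dpl,
                    meta_p = mp,
                    status = ifelse(n_st >= min_studies, "ok",
                                    "insufficient_evidence"),
                    stringsAsFactors = FALSE)
  ord <- order(is.na(out$meta_p), out$meta_p, out$gene, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
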