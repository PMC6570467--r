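#' Simulation configuration for a synthetic multi-study, multi-omics cohort
#'
#' Bundles every knob of the synthetic data generator into a validated
#' configuration object. The defaults emulate a meta-analysis design of ten
#' transcriptomics studies plus one proteomics and one metabolomics study on
#' the "anchor" cohort (study 1), with a planted fraction of features that
#' are truly differential between ERneg and ERpos tumor groups.
#'
#' Abundances are generated log2-normally: each feature has a baseline log2
#' mean, and truly differential features receive a shift of
#' `effect_size * sigma` log2 units (sign chosen at random per feature) in
#' the ERneg group. Differential genes and their directions are shared
#' across studies; `effect_jitter` optionally scales per-study, per-feature
#' effects by `1 + effect_jitter * N(0,1)` to model between-study
#' heterogeneity.
#'
#' @param n_studies number of transcriptomics studies in the collection.
#' @param n_genes,n_proteins,n_metabolites feature-universe sizes. Proteins
#'   are gene products: protein ids are the first `n_proteins` gene symbols
#'   and inherit the gene's differential status and direction.
#' @param n_neg,n_pos samples per group per study (ERneg / ERpos).
#' @param frac_diff fraction of truly differential features in `[0, 1]`.
#' @param effect_size mean log2 shift of differential features in the ERneg
#'   group, in standard-deviation units.
#' @param sigma residual standard deviation of log2 abundances.
#' @param panel_overlap fraction of the feature universe measured per study,
#'   in `(0, 1]`; each study's panel is an independent seeded subset.
#' @param missing_rate per-cell missingness probability for proteomics.
#' @param missing_mechanism `"mcar"` (completely at random, default) or
#'   `"mnar"` (missingness probability decreasing with intensity rank).
#' @param effect_jitter multiplicative per-study effect heterogeneity
#'   (standard deviation of the scale factor minus one); 0 disables it.
#' @param seed integer random seed; identical config + seed gives
#'   byte-identical output everywhere downstream.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_studies = 10, n_genes = 1000, n_proteins = 300,
                       n_metabolites = 150, n_neg = 30, n_pos = 30,
                       frac_diff = 0.1, effect_size = 1, sigma = 1,
                       panel_overlap = 0.8, missing_rate = 0.1,
                       missing_mechanism = c("mcar", "mnar"),
                       effect_jitter = 0, seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_studies = as.integer(n_studies), n_genes = as.integer(n_genes),
    n_proteins = as.integer(n_proteins),
    n_metabolites = as.integer(n_metabolites),
    n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
    frac_diff = frac_diff, effect_size = effect_size, sigma = sigma,
    panel_overlap = panel_overlap, missing_rate = missing_rate,
    missing_mechanism = missing_mechanism, effect_jitter = effect_jitter,
    seed = as.integer(seed)
  )
  counts <- c("n_studies", "n_genes", "n_proteins", "n_metabolites",
              "n_neg", "n_pos")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("'", nm, "' must be an integer >= 1", call. = FALSE)
  }
  if (cfg$n_proteins > cfg$n_genes)
    stop("'n_proteins' cannot exceed 'n_genes' (proteins are gene products)",
         call. = FALSE)
  for (nm in c("frac_diff", "missing_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$panel_overlap <= 0 || cfg$panel_overlap > 1)
    stop("'panel_overlap' must lie in (0, 1]", call. = FALSE)
  if (cfg$sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (cfg$effect_size < 0) stop("'effect_size' must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed derivation so that each (operation, study, platform)
# has an independent but reproducible RNG stream. Pure integer arithmetic in
# doubles; result always in [1, 2^31 - 2].
derive_seed <- function(seed, offset, study_index = 0L) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(offset) * 104729 +
          as.numeric(study_index) * 7919) %% m
  as.integer(s + 1)
}

platform_code <- function(platform) {
  match(platform, c("transcript", "protein", "metabolite"))
}

#' Construct an omics abundance matrix with group labels
#'
#' Container for one study/platform's feature-by-sample abundance matrix
#' (linear scale, non-negative; proteomics cells may be `NA`) together with
#' the ERneg/ERpos label of every sample.
#'
#' @param values numeric matrix, features in rows (unique rownames), samples
#'   in columns.
#' @param labels character or factor of `"ERneg"`/`"ERpos"`, one per column.
#' @param platform one of `"transcript"`, `"protein"`, `"metabolite"`.
#' @param study_id identifier for the study the matrix comes from.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, labels, platform, study_id = "study") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      anyDuplicated(rownames(values)))
    stop("row names must be present and unique", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("ERneg", "ERpos"))
  if (length(labels) != ncol(values))
    stop("one label per sample column is required", call. = FALSE)
  if (anyNA(labels))
    stop("labels must be 'ERneg' or 'ERpos' with no missing values",
         call. = FALSE)
  if (!all(c("ERneg", "ERpos") %in% labels))
    stop("both groups must be non-empty", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  platform <- match.arg(platform, c("transcript", "protein", "metabolite"))
  structure(list(values = values, labels = labels, platform = platform,
                 study_id = study_id),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s / %s: %d features x %d samples (%d ERneg, %d ERpos)\n",
              x$study_id, x$platform, nrow(x$values), ncol(x$values),
              sum(x$labels == "ERneg"), sum(x$labels == "ERpos")))
  invisible(x)
}

#' Ground-truth table for a simulated feature universe
#'
#' The truth table is shared across all studies of a collection: which
#' features are truly differential, their direction (ERneg relative to
#' ERpos), and their true log2 effect. Proteins inherit the status of their
#' coding gene; metabolites have an independent truth block.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns `feature_id`, `platform`,
#'   `is_differential`, `true_direction` (`"up"`/`"down"`/`"none"`),
#'   `true_log2_effect`, and `baseline_log2` (the feature's baseline mean).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  met_ids <- sprintf("met_%04d", seq_len(config$n_metabolites))

  draw_block <- function(ids, platform) {
    n <- length(ids)
    mu <- stats::runif(n, 6, 12)
    is_diff <- stats::runif(n) < config$frac_diff
    sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
    eff <- ifelse(is_diff, sign * config$effect_size * config$sigma, 0)
    data.frame(feature_id = ids, platform = platform,
               is_differential = is_diff,
               true_direction = ifelse(eff > 0, "up",
                                       ifelse(eff < 0, "down", "none")),
               true_log2_effect = eff, baseline_log2 = mu,
               stringsAsFactors = FALSE)
  }
  genes <- draw_block(gene_ids, "transcript")
  mets <- draw_block(met_ids, "metabolite")
  # proteins: same truth as the coding gene, own baseline abundance
  prot <- genes[seq_len(config$n_proteins), ]
  prot$platform <- "protein"
  prot$baseline_log2 <- stats::runif(config$n_proteins, 6, 12)
  rbind(genes, prot, mets)
}

#' Simulate one study's abundance matrix for a given platform
#'
#' Draws abundances as `2^(mu_f + delta_f * I[ERneg] + N(0, sigma))` per
#' feature, where `delta_f` is the feature's true log2 effect (optionally
#' jittered per study). The measured panel is a seeded random subset of the
#' platform's feature universe of size `panel_overlap * n_features`.
#' Proteomics cells are set missing with probability `missing_rate`.
#'
#' @param config a [sim_config()] object.
#' @param platform `"transcript"`, `"protein"` or `"metabolite"`.
#' @param study_index 1-based study index, `<= n_studies` for transcripts.
#' @return list with elements `matrix` (an [omics_matrix()]) and `truth`
#'   (the truth rows for the measured panel).
#' @export
simulate_study <- function(config, platform = c("transcript", "protein",
                                                "metabolite"),
                           study_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  platform <- match.arg(platform)
  study_index <- as.integer(study_index)
  if (platform == "transcript" && study_index > config$n_studies)
    stop("study_index exceeds n_studies", call. = FALSE)
  if (config$n_neg < 1L || config$n_pos < 1L)
    stop("both groups need at least one sample", call. = FALSE)

  truth <- simulate_truth(config)
  truth <- truth[truth$platform == platform, , drop = FALSE]

  set.seed(derive_seed(config$seed, 10L + platform_code(platform),
                       study_index))
  n_feat <- nrow(truth)
  n_panel <- max(1L, round(config$panel_overlap * n_feat))
  panel <- sort(sample.int(n_feat, n_panel))
  truth <- truth[panel, , drop = FALSE]

  n_samp <- config$n_neg + config$n_pos
  labels <- rep(c("ERneg", "ERpos"), c(config$n_neg, config$n_pos))
  sample_ids <- sprintf("s%02d_%s%03d", study_index,
                        ifelse(labels == "ERneg", "neg", "pos"),
                        c(seq_len(config$n_neg), seq_len(config$n_pos)))

  delta <- truth$true_log2_effect
  if (config$effect_jitter > 0) {
    delta <- delta * (1 + config$effect_jitter * stats::rnorm(n_panel))
  }
  shift <- outer(delta, as.numeric(labels == "ERneg"))
  log2_vals <- truth$baseline_log2 + shift +
    matrix(stats::rnorm(n_panel * n_samp, sd = config$sigma),
           n_panel, n_samp)
  vals <- 2^log2_vals
  dimnames(vals) <- list(truth$feature_id, sample_ids)

  if (platform == "protein" && config$missing_rate > 0) {
    if (config$missing_mechanism == "mcar") {
      drop <- matrix(stats::runif(n_panel * n_samp) < config$missing_rate,
                     n_panel, n_samp)
    } else {
      # MNAR: missingness twice as likely for the lowest intensities,
      # linearly decreasing with within-matrix intensity rank
      q <- matrix(rank(log2_vals) / length(log2_vals), n_panel, n_samp)
      drop <- matrix(stats::runif(n_panel * n_samp) <
                       pmin(1, 2 * config$missing_rate * (1 - q)),
                     n_panel, n_samp)
    }
    vals[drop] <- NA_real_
  }

  list(matrix = omics_matrix(vals, labels, platform,
                             study_id = sprintf("study%02d_%s", study_index,
                                                platform)),
       truth = truth)
}

#' Simulate a collection of transcriptomics studies with shared truth
#'
#' All studies share one gene-level truth table (same differential genes and
#' directions); the per-study measured panels are independent seeded subsets
#' of the gene universe.
#'
#' @param config a [sim_config()] object.
#' @return list with `matrices` (list of [omics_matrix()], one per study)
#'   and `truth` (the shared gene-level truth table).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mats <- lapply(seq_len(config$n_studies), function(i) {
    simulate_study(config, "transcript", i)$matrix
  })
  truth <- simulate_truth(config)
  list(matrices = mats,
       truth = truth[truth$platform == "transcript", , drop = FALSE])
}

#' Simulate annotation fixtures: EC map, pathways, compounds, literature counts
#'
#' Generates the side-inputs the prioritization workflow needs, with known
#' structure: a gene-to-EC map in which a stated fraction of genes carry
#' small-molecule ECs and a stated fraction carry excluded (protein/nucleic
#' acid substrate) EC classes; pathway sets partitioning the gene and
#' metabolite universes; compound records with fixed-length binary
#' fingerprints, symmetric reactant-pair links and EC links; and per-gene
#' literature counts drawn from a negative binomial, statistically
#' independent of differential status (so that significant-but-understudied
#' genes exist by construction).
#'
#' @param config a [sim_config()] object.
#' @param metabolic_fraction fraction of genes given small-molecule ECs.
#' @param excluded_fraction fraction of genes given only excluded-class ECs.
#' @param mixed_fraction fraction of metabolic genes that additionally carry
#'   an excluded EC (they remain metabolic under the ">= 1 small-molecule
#'   EC" rule).
#' @param pathway_size target number of members per pathway set (must be
#'   >= 1).
#' @param fp_bits fingerprint length in bits.
#' @param fp_density expected fraction of set bits per fingerprint.
#' @param lit_mu,lit_size negative-binomial mean and dispersion of
#'   literature counts.
#' @return list with `ec_map` (data frame gene, ec), `pathways` (named list
#'   of member-id vectors), `fingerprints` (logical matrix, metabolites in
#'   rows), `rpairs` (two-column data frame of symmetric reactant pairs),
#'   `compound_ec` (data frame metabolite, ec), and `lit_counts` (data frame
#'   gene, n_papers).
#' @export
simulate_annotations <- function(config, metabolic_fraction = 0.3,
                                 excluded_fraction = 0.1,
                                 mixed_fraction = 0.1,
                                 pathway_size = 25, fp_bits = 128,
                                 fp_density = 0.3, lit_mu = 20,
                                 lit_size = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (pathway_size < 1) stop("'pathway_size' must be >= 1", call. = FALSE)
  if (metabolic_fraction + excluded_fraction > 1)
    stop("metabolic_fraction + excluded_fraction cannot exceed 1",
         call. = FALSE)
  set.seed(derive_seed(config$seed, 2L))

  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  met_ids <- sprintf("met_%04d", seq_len(config$n_metabolites))

  small_molecule_pool <- c("1.1.1.%d", "2.7.1.%d", "4.2.1.%d", "1.14.11.%d",
                           "3.1.3.%d", "5.3.1.%d", "6.2.1.%d", "2.6.1.%d",
                           "1.2.4.%d", "2.3.1.%d")
  excluded_pool <- c("2.7.11.%d", "3.4.21.%d", "6.1.1.%d", "3.6.4.%d",
                     "2.7.7.7")
  draw_ec <- function(pool, n) {
    sprintf(sample(pool, n, replace = TRUE), sample.int(50, n, replace = TRUE))
  }

  n_met_genes <- round(metabolic_fraction * config$n_genes)
  n_exc_genes <- round(excluded_fraction * config$n_genes)
  annotated <- sample(gene_ids, n_met_genes + n_exc_genes)
  metabolic_genes <- annotated[seq_len(n_met_genes)]
  excluded_genes <- setdiff(annotated, metabolic_genes)

  ec_rows <- list(
    data.frame(gene = metabolic_genes,
               ec = draw_ec(small_molecule_pool, n_met_genes),
               stringsAsFactors = FALSE),
    data.frame(gene = excluded_genes,
               ec = draw_ec(excluded_pool, n_exc_genes),
               stringsAsFactors = FALSE)
  )
  n_mixed <- round(mixed_fraction * n_met_genes)
  if (n_mixed > 0) {
    mixed <- sample(metabolic_genes, n_mixed)
    ec_rows[[3]] <- data.frame(gene = mixed,
                               ec = draw_ec(excluded_pool, n_mixed),
                               stringsAsFactors = FALSE)
  }
  ec_map <- do.call(rbind, ec_rows)
  ec_map <- ec_map[order(ec_map$gene, ec_map$ec, method = "radix"), ]
  rownames(ec_map) <- NULL

  # pathway sets partition the shuffled joint gene + metabolite universe
  members <- sample(c(gene_ids, met_ids))
  n_pw <- max(1L, floor(length(members) / pathway_size))
  pw_idx <- rep(seq_len(n_pw), length.out = length(members))
  pathways <- split(members, sprintf("pw_%03d", pw_idx))
  pathways <- lapply(pathways, function(x) sort(x, method = "radix"))

  fingerprints <- matrix(stats::runif(config$n_metabolites * fp_bits) <
                           fp_density,
                         nrow = config$n_metabolites, ncol = fp_bits,
                         dimnames = list(met_ids, NULL))

  # symmetric reactant pairs: about one partner per metabolite
  n_pairs <- config$n_metabolites
  a <- sample(met_ids, n_pairs, replace = TRUE)
  b <- sample(met_ids, n_pairs, replace = TRUE)
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  rpairs <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  rpairs <- rpairs[order(rpairs$a, rpairs$b, method = "radix"), ]
  rownames(rpairs) <- NULL

  # metabolites link to a random small-molecule EC carried by some gene,
  # so entity-enzyme edges exist by construction
  met_ec_pool <- ec_map$ec[ec_map$gene %in% metabolic_genes]
  compound_ec <- data.frame(
    metabolite = met_ids,
    ec = sample(met_ec_pool, config$n_metabolites, replace = TRUE),
    stringsAsFactors = FALSE)

  lit_counts <- data.frame(
    gene = gene_ids,
    n_papers = stats::rnbinom(config$n_genes, size = lit_size, mu = lit_mu),
    stringsAsFactors = FALSE)

  list(ec_map = ec_map, pathways = pathways, fingerprints = fingerprints,
       rpairs = rpairs, compound_ec = compound_ec, lit_counts = lit_counts,
       metabolic_genes = sort(metabolic_genes, method = "radix"))
}
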