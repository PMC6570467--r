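test_that("simulation is deterministic for identical config and seed", {
  cfg <- tiny_config()
  a <- simulate_study(cfg, "transcript", 2)
  b <- simulate_study(cfg, "transcript", 2)
  expect_identical(a, b)
  expect_identical(simulate_collection(cfg)$matrices[[1]]$values,
                   simulate_collection(cfg)$matrices[[1]]$values)
  expect_identical(simulate_annotations(cfg), simulate_annotations(cfg))
  # different study index gives different data under the same truth
  c2 <- simulate_study(cfg, "transcript", 3)
  expect_false(identical(a$matrix$values, c2$matrix$values))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_neg = 0), "n_neg")
  expect_error(sim_config(frac_diff = 1.2), "frac_diff")
  expect_error(sim_config(panel_overlap = 0), "panel_overlap")
  expect_error(sim_config(n_proteins = 50, n_genes = 10), "n_proteins")
  cfg <- tiny_config()
  expect_error(simulate_study(cfg, "transcript", cfg$n_studies + 1),
               "study_index")
})

test_that("null configuration plants no effects", {
  cfg <- tiny_config(effect_size = 0)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$true_log2_effect == 0))
  expect_true(all(truth$true_direction == "none"))
})

test_that("planted differential fraction lands in the binomial band", {
  cfg <- sim_config(n_studies = 2, n_genes = 1000, frac_diff = 0.1,
                    seed = 3L)
  truth <- simulate_truth(cfg)
  genes <- truth[truth$platform == "transcript", ]
  n_diff <- sum(genes$is_differential)
  # Binomial(1000, 0.1): 3 sigma band around 100
  expect_gt(n_diff, 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(n_diff, 100 + 3 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(genes$true_direction[genes$is_differential] %in%
                    c("up", "down")))
  expect_identical(genes$true_direction == "up", genes$true_log2_effect > 0)
})

test_that("planted effect size is recovered in the observed fold changes", {
  # Monte-Carlo over seeds: mean |log2 fold| of differential features at
  # effect_size 1, sigma 1, 30 vs 30 should sit near 1
  effs <- vapply(1:50, function(s) {
    cfg <- sim_config(n_studies = 1, n_genes = 150, n_proteins = 50,
                      n_neg = 30, n_pos = 30, frac_diff = 0.3,
                      effect_size = 1, panel_overlap = 1, seed = s)
    st <- simulate_study(cfg, "transcript", 1)
    diff_ids <- st$truth$feature_id[st$truth$is_differential]
    neg <- st$matrix$labels == "ERneg"
    lf <- log2(rowMeans(st$matrix$values[diff_ids, neg]) /
                 rowMeans(st$matrix$values[diff_ids, !neg]))
    mean(abs(lf))
  }, numeric(1))
  expect_lt(abs(mean(effs) - 1), 0.1)
})

test_that("per-study panels follow the overlap fraction", {
  cfg <- sim_config(n_studies = 10, n_genes = 500, panel_overlap = 1,
                    seed = 5L)
  coll <- simulate_collection(cfg)
  counts <- table(unlist(lapply(coll$matrices,
                                function(m) rownames(m$values))))
  expect_true(all(counts == 10))

  cfg8 <- sim_config(n_studies = 10, n_genes = 500, panel_overlap = 0.8,
                     seed = 5L)
  coll8 <- simulate_collection(cfg8)
  ids <- sprintf("gene_%04d", 1:500)
  counts8 <- vapply(ids, function(g) {
    sum(vapply(coll8$matrices, function(m) g %in% rownames(m$values),
               logical(1)))
  }, numeric(1))
  # marginal per-gene study count is Binomial(10, 0.8): goodness of fit
  obs <- tabulate(counts8 + 1, nbins = 11)
  expected_p <- stats::dbinom(0:10, 10, 0.8)
  lump <- expected_p * 500 >= 5
  o <- c(sum(obs[!lump]), obs[lump])
  p <- c(sum(expected_p[!lump]), expected_p[lump])
  gof <- suppressWarnings(stats::chisq.test(o, p = p))
  expect_gt(gof$p.value, 1e-3)
})

test_that("proteomics missingness follows the configured rate and mechanism", {
  cfg <- tiny_config(n_genes = 300, n_proteins = 200, n_neg = 20,
                     n_pos = 20, missing_rate = 0.2)
  st <- simulate_study(cfg, "protein", 1)
  rate <- mean(is.na(st$matrix$values))
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / length(st$matrix$values)))

  cfg_mnar <- tiny_config(n_genes = 300, n_proteins = 200, n_neg = 20,
                          n_pos = 20, missing_rate = 0.2,
                          missing_mechanism = "mnar")
  st2 <- simulate_study(cfg_mnar, "protein", 1)
  v <- st2$matrix$values
  med <- stats::median(st2$truth$baseline_log2)
  low <- st2$truth$baseline_log2 < med
  expect_gt(mean(is.na(v[low, ])), mean(is.na(v[!low, ])))
})

test_that("annotation fixtures have the stated structure", {
  cfg <- sim_config(n_studies = 2, n_genes = 1000, n_metabolites = 50,
                    seed = 9L)
  ann <- simulate_annotations(cfg, metabolic_fraction = 0.1,
                              excluded_fraction = 0.1)
  sel <- select_metabolic_genes(
    lapply(split(ann$ec_map$ec, ann$ec_map$gene), unique))
  # exactly the genes given small-molecule ECs survive the default rules,
  # including the mixed-annotation genes
  expect_identical(sel, ann$metabolic_genes)
  expect_equal(length(sel), 100)
  expect_error(simulate_annotations(cfg, pathway_size = 0), "pathway_size")
  # pathway sets partition the joint feature universe
  members <- unlist(ann$pathways, use.names = FALSE)
  expect_setequal(members, c(sprintf("gene_%04d", 1:1000),
                             sprintf("met_%04d", 1:50)))
  expect_false(anyDuplicated(members) > 0)
  # reactant pairs are symmetric-unique with no self links
  expect_true(all(ann$rpairs$a != ann$rpairs$b))
  expect_false(anyDuplicated(ann$rpairs[, c("a", "b")]) > 0)
})

test_that("literature counts are independent of differential status", {
  cors <- vapply(1:20, function(s) {
    cfg <- sim_config(n_studies = 1, n_genes = 400, frac_diff = 0.2,
                      seed = s)
    truth <- simulate_truth(cfg)
    genes <- truth[truth$platform == "transcript", ]
    ann <- simulate_annotations(cfg)
    stats::cor(as.numeric(genes$is_differential),
               log1p(ann$lit_counts$n_papers))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("omics TSV writer round-trips matrices, labels and missing cells", {
  cfg <- tiny_config()
  st <- simulate_study(cfg, "protein", 1)$matrix
  mpath <- withr::local_tempfile(fileext = ".tsv")
  lpath <- withr::local_tempfile(fileext = ".tsv")
  write_omics_tsv(st, mpath, lpath)
  back <- read_omics_tsv(mpath, lpath, "protein", st$study_id)
  expect_equal(back$values, st$values, tolerance = 1e-12)
  expect_identical(as.character(back$labels), as.character(st$labels))
})
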