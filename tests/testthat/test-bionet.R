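bits <- function(on, len = 12) {
  v <- rep(FALSE, len)
  v[on] <- TRUE
  v
}

test_that("Tanimoto similarity follows set intersection over union", {
  a <- bits(1:3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(bits(1:3), bits(4:6)), 0)
  expect_equal(tanimoto(bits(1:3), bits(2:4)), 0.5)
  # symmetric, and all-zero pairs are defined as 0
  b <- bits(2:4)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_equal(tanimoto(bits(integer(0)), bits(integer(0))), 0)
  expect_error(tanimoto(bits(1, 8), bits(1, 12)), "length")
})

test_that("chemical edges require similarity strictly above the threshold", {
  # |intersection| = 7, |union| = 10: similarity exactly 0.7
  fp <- rbind(c1 = bits(1:8, 16), c2 = bits(c(1:7, 9, 10), 16))
  expect_equal(tanimoto(fp["c1", ], fp["c2", ]), 0.7)
  g_at <- build_network(fingerprints = fp, threshold = 0.7)
  expect_equal(igraph::ecount(g_at), 0)
  g_below <- build_network(fingerprints = fp, threshold = 0.69)
  expect_equal(igraph::ecount(g_below), 1)
  expect_equal(igraph::E(g_below)$weight, 0.7)
  expect_identical(igraph::E(g_below)$edge_class, "chemical-similarity")
})

test_that("edge count is non-increasing in the similarity threshold", {
  set.seed(4)
  fp <- matrix(stats::runif(20 * 32) < 0.4, 20, 32,
               dimnames = list(sprintf("c%02d", 1:20), NULL))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t) {
    igraph::ecount(build_network(fingerprints = fp, threshold = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("shared EC numbers produce entity-enzyme edges of each class", {
  g <- build_network(
    compound_ec = data.frame(metabolite = "met_sorbitol", ec = "1.1.1.14"),
    gene_ec = list(SORD = "1.1.1.14"),
    protein_ec = data.frame(protein = "prot_SORD", ec = "1.1.1.14"))
  expect_setequal(igraph::V(g)$name,
                  c("SORD", "prot_SORD", "met_sorbitol", "EC:1.1.1.14"))
  expect_setequal(igraph::E(g)$edge_class,
                  c("gene-enzyme", "protein-enzyme", "compound-enzyme"))
  # all three entities meet at the shared enzyme node
  expect_equal(igraph::degree(g, "EC:1.1.1.14"), c(`EC:1.1.1.14` = 3))
})

test_that("rpair edges are symmetric, deduplicated and loop-free", {
  rp <- data.frame(a = c("m1", "m2", "m1", "m3"),
                   b = c("m2", "m1", "m1", "m4"))
  g <- build_network(rpairs = rp)
  expect_equal(igraph::ecount(g), 2)  # m1-m2 once, m3-m4 once, no self loop
  expect_true(all(igraph::E(g)$edge_class == "rpair"))
})

test_that("nodes carry differential statistics, with neutral fallback", {
  stats_tbl <- data.frame(feature_id = "m1", fold_change = 2.5,
                          raw_p = 0.01, direction = "up")
  expect_warning(
    g <- build_network(rpairs = data.frame(a = "m1", b = "m2"),
                       node_stats = stats_tbl),
    "neutral")
  expect_equal(igraph::V(g)$fold_change[igraph::V(g)$name == "m1"], 2.5)
  expect_equal(igraph::V(g)$fold_change[igraph::V(g)$name == "m2"], 1)
  expect_identical(igraph::V(g)$direction[igraph::V(g)$name == "m2"],
                   "unchanged")
  # empty compound set still yields the gene/protein-enzyme backbone
  g2 <- build_network(gene_ec = list(G1 = "1.1.1.1"),
                      protein_ec = data.frame(protein = "P1", ec = "1.1.1.1"))
  expect_setequal(igraph::E(g2)$edge_class,
                  c("gene-enzyme", "protein-enzyme"))
})

test_that("network construction is a pure function of its inputs", {
  cfg <- tiny_config()
  ann <- simulate_annotations(cfg)
  build <- function() {
    build_network(fingerprints = ann$fingerprints, rpairs = ann$rpairs,
                  compound_ec = ann$compound_ec,
                  gene_ec = lapply(split(ann$ec_map$ec, ann$ec_map$gene),
                                   unique))
  }
  g1 <- build()
  g2 <- build()
  expect_identical(igraph::as_data_frame(g1, "both"),
                   igraph::as_data_frame(g2, "both"))
})

test_that("community detection labels every node and separates components", {
  clique <- function(n, prefix) {
    g <- igraph::make_full_graph(n)
    igraph::V(g)$name <- paste0(prefix, seq_len(n))
    g
  }
  two <- igraph::disjoint_union(clique(5, "a"), clique(4, "b"))
  mem <- detect_communities(two)
  expect_length(mem, 9)
  expect_equal(length(unique(mem[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(mem[paste0("b", 1:4)])), 1)
  expect_false(mem[["a1"]] == mem[["b1"]])

  one <- detect_communities(clique(6, "k"))
  expect_equal(length(unique(one)), 1)

  # two 10-cliques joined by a single bridge still split in two
  bridged <- igraph::add_edges(
    igraph::disjoint_union(clique(10, "x"), clique(10, "y")),
    c("x1", "y1"))
  memb <- detect_communities(bridged)
  expect_equal(length(unique(memb)), 2)
  expect_false(memb[["x1"]] == memb[["y1"]])

  expect_length(detect_communities(igraph::make_empty_graph(0)), 0)
})

test_that("GraphML export round-trips nodes, edges, classes and weights", {
  fp <- rbind(c1 = bits(1:6, 16), c2 = bits(1:5, 16), c3 = bits(10:16, 16))
  g <- suppressWarnings(build_network(
    fingerprints = fp,
    rpairs = data.frame(a = "c1", b = "c3"),
    gene_ec = list(G1 = "1.1.1.1"),
    node_stats = data.frame(feature_id = c("c1", "G1"),
                            fold_change = c(2, 0.5), raw_p = c(0.01, 0.2),
                            direction = c("up", "down"))))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  back <- read_graphml(path)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  key <- function(gr) {
    df <- igraph::as_data_frame(gr, "edges")
    df[order(df$edge_class, df$from, df$to, method = "radix"), ]
  }
  expect_equal(key(back)$edge_class, key(g)$edge_class)
  expect_equal(key(back)$weight, key(g)$weight)
  nd <- igraph::as_data_frame(back, "vertices")
  expect_equal(nd$fold_change[nd$name == "c1"], 2)
  expect_identical(nd$direction[nd$name == "G1"], "down")
})

test_that("SIF export writes one line per edge plus attribute tables", {
  g <- build_network(rpairs = data.frame(a = c("m1", "m2"),
                                         b = c("m2", "m3")))
  path <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, path, "sif")
  expect_length(readLines(path), igraph::ecount(g))
  nodes <- read.delim(paste0(path, ".nodes.tsv"))
  expect_setequal(nodes$name, c("m1", "m2", "m3"))
  # visual attributes: size follows fold change, color follows direction
  expect_equal(nodes$size, nodes$fold_change)
  expect_true(all(nodes$color %in% c("red", "blue", "grey")))
})

test_that("fingerprint hex TSV round-trips bit-exactly", {
  set.seed(2)
  fp <- matrix(stats::runif(6 * 20) < 0.5, 6, 20,
               dimnames = list(sprintf("cp%d", 1:6), NULL))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fp, path)
  back <- read_fingerprints(path, n_bits = 20)
  expect_identical(unname(back), unname(fp))
  expect_identical(rownames(back), rownames(fp))
})
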