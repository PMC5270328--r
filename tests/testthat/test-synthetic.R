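test_that("suite generation is byte-identical under a fixed seed", {
  s1 <- gen_suite(n_genes = 80, n_pathways = 2, genes_per_pathway = 10,
                  edges_per_pathway = 8, n_withheld = 3, seed = 41)
  s2 <- gen_suite(n_genes = 80, n_pathways = 2, genes_per_pathway = 10,
                  edges_per_pathway = 8, n_withheld = 3, seed = 41)
  expect_identical(s1, s2)
  s3 <- gen_suite(n_genes = 80, n_pathways = 2, genes_per_pathway = 10,
                  edges_per_pathway = 8, n_withheld = 3, seed = 42)
  expect_false(identical(s1$truth_edges, s3$truth_edges))
})

test_that("edgeless pathways and infeasible edge counts are handled", {
  s <- gen_truth(n_genes = 30, n_pathways = 1, genes_per_pathway = 6,
                 edges_per_pathway = 0, n_withheld = 0, seed = 1)
  expect_equal(nrow(s$pathways[[1]]$edges), 0)
  expect_equal(nrow(s$truth_edges), 0)
  kb <- suppressWarnings(build_knowledgebase(s$pathways))
  expect_equal(nrow(kb$relations), 0)

  expect_error(gen_truth(n_genes = 30, n_pathways = 1,
                         genes_per_pathway = 4, edges_per_pathway = 50,
                         multi_ko_prob = 0, seed = 1),
               "infeasible")
})

test_that("emitted KGML round-trips through the parser", {
  for (s in 1:5) {
    suite <- gen_suite(n_genes = 60, n_pathways = 2,
                       genes_per_pathway = 8, edges_per_pathway = 6,
                       n_withheld = 2, seed = s)
    for (i in seq_along(suite$pathways)) {
      truth <- suite$pathways[[i]]
      back <- parse_kgml(suite$kgml[[i]])
      expect_equal(lapply(back$nodes, `[[`, "kos"),
                   lapply(truth$nodes, `[[`, "kos"))
      expect_equal(back$edges[, c("from", "to", "rel_type")],
                   truth$edges[, c("from", "to", "rel_type")],
                   ignore_attr = TRUE)
      expect_equal(back$compounds, truth$compounds)
    }
  }
})

test_that("zero-coefficient networks learn almost nothing beyond whitelist", {
  suite <- gen_truth(n_genes = 40, n_pathways = 1, genes_per_pathway = 8,
                     edges_per_pathway = 6, n_withheld = 0, seed = 3)
  counts <- gen_expression(suite, beta_range = c(0, 0),
                           signature_sd = 0, n_conditions = 100,
                           seed = 4)
  data <- bn_data(filter_expressed(cpm_normalize(counts)))
  genes <- intersect(unique(c(suite$truth_edges$from,
                              suite$truth_edges$to)), colnames(data))
  out <- hill_climb(data[, genes, drop = FALSE],
                    config = learn_config(seed = 5))
  # independent genes: close to the empty graph up to the BIC null
  # false-positive rate (~1 expected over C(8,2) pairs at N = 100)
  expect_lte(nrow(bn_edges(out)), 3)
})

test_that("near-noiseless chains give strongly correlated parent-child pairs", {
  suite <- gen_truth(n_genes = 40, n_pathways = 1,
                     genes_per_pathway = 10, edges_per_pathway = 9,
                     n_withheld = 0, seed = 6)
  counts <- gen_expression(suite, beta_range = c(1, 1), sigma = 0.01,
                           seed = 7)
  latent <- attr(counts, "latent")
  betas <- attr(counts, "betas")
  for (i in seq_len(nrow(betas))) {
    dev_p <- latent[betas$from[i], ] - mean(latent[betas$from[i], ])
    dev_c <- latent[betas$to[i], ] - mean(latent[betas$to[i], ])
    if (sd(dev_p) > 0.1) {
      expect_gt(cor(dev_p, dev_c), 0.9)
    }
  }
})

test_that("default expression parameters keep true edges learnable", {
  cors <- c()
  for (s in 1:5) {
    suite <- gen_truth(n_genes = 60, n_pathways = 1,
                       genes_per_pathway = 12, edges_per_pathway = 10,
                       n_withheld = 0, seed = 10 + s)
    counts <- gen_expression(suite, seed = 20 + s)
    lc <- log_cpm(cpm_normalize(counts))
    betas <- attr(counts, "betas")
    strong <- betas[betas$beta > 0.9, ]
    for (i in seq_len(nrow(strong))) {
      cors <- c(cors, cor(lc[strong$from[i], ], lc[strong$to[i], ]))
    }
  }
  expect_gt(mean(cors), 0.5)
})

test_that("a stated fraction of genes fails the expression filter", {
  suite <- gen_suite(seed = 8)
  cpm <- cpm_normalize(suite$counts)
  f <- filter_expressed(cpm)
  frac <- attr(f, "n_removed") / nrow(cpm)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
  # no pathway gene is lost to the filter
  pw_genes <- unique(suite$gene_to_ko$gene_id)
  expect_true(all(pw_genes %in% rownames(f)))
})

test_that("planted GO annotations carry the pathway term at the set rate", {
  suite <- gen_suite(n_genes = 200, n_pathways = 3,
                     genes_per_pathway = 30, edges_per_pathway = 40,
                     n_withheld = 0, p_share = 0.6, seed = 12)
  ann <- suite$annotations
  hit <- 0; tot <- 0
  for (p in seq_along(suite$pathways)) {
    kos <- unlist(lapply(suite$pathways[[p]]$nodes, `[[`, "kos"))
    members <- unique(
      suite$gene_to_ko$gene_id[suite$gene_to_ko$ko %in% kos])
    term <- sprintf("GO:P%04d", p)
    hit <- hit + sum(members %in% ann$gene_id[ann$go_term == term])
    tot <- tot + length(members)
  }
  expect_gt(hit / tot, 0.45)
  expect_lt(hit / tot, 0.75)
  expect_s3_class(kbnpath:::validate_annotations(ann), "data.frame")
})

test_that("suites serialize to parseable plain-text artifacts", {
  suite <- gen_suite(n_genes = 50, n_pathways = 1, genes_per_pathway = 8,
                     edges_per_pathway = 6, n_withheld = 2, seed = 14)
  d <- withr::local_tempdir()
  files <- write_suite(suite, d)
  counts <- read_counts(file.path(d, "counts.tsv"))
  expect_equal(unclass(counts), unclass(suite$counts),
               ignore_attr = TRUE)
  g2k <- read_gene_to_ko(file.path(d, "gene2ko.tsv"))
  expect_equal(g2k, suite$gene_to_ko, ignore_attr = TRUE)
  ann <- read_annotations(file.path(d, "go.tsv"))
  expect_equal(nrow(ann), nrow(suite$annotations))
  pw <- parse_kgml(file.path(d, "pathway_1.kgml"))
  expect_equal(length(pw$nodes), length(suite$pathways[[1]]$nodes))
})
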