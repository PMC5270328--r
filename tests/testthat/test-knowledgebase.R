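test_that("minimal KGML parses into nodes, edges, reactions, compounds", {
  pw <- parse_kgml(tiny_kgml())
  expect_s3_class(pw, "Pathway")
  expect_equal(length(pw$nodes), 2)
  expect_equal(pw$nodes[["1"]]$kos, c("K00001", "K00002"))
  expect_equal(nrow(pw$edges), 1)
  expect_equal(pw$edges$rel_type, "ECrel")
  expect_true(all(c("C00010", "C00020") %in% pw$compounds))
  expect_true("R00001" %in% pw$reactions$reaction_id)
})

test_that("a pathway with no relations parses to an edgeless graph", {
  doc <- sub('<relation entry1="1" entry2="2" type="ECrel"/>', "",
             tiny_kgml(), fixed = TRUE)
  pw <- parse_kgml(doc)
  expect_equal(nrow(pw$edges), 0)
  expect_equal(length(pw$nodes), 2)
})

test_that("unknown relation types are kept as 'other' with a warning", {
  doc <- sub("ECrel", "XYrel", tiny_kgml(), fixed = TRUE)
  expect_warning(pw <- parse_kgml(doc), "not recognised")
  expect_equal(pw$edges$rel_type, "other")
})

test_that("malformed XML raises a parse error", {
  expect_error(parse_kgml("<pathway><entry id='1'"), "")
})

test_that("KGML write/parse round-trips nodes, edges and compounds", {
  pw <- parse_kgml(tiny_kgml())
  back <- parse_kgml(write_kgml(pw))
  expect_equal(lapply(back$nodes, `[[`, "kos"),
               lapply(pw$nodes, `[[`, "kos"))
  expect_equal(back$edges[, c("from", "to", "rel_type")],
               pw$edges[, c("from", "to", "rel_type")])
  expect_equal(back$compounds, pw$compounds)
  expect_equal(sort(unique(back$reactions$reaction_id)),
               sort(unique(pw$reactions$reaction_id)))
})

test_that("multi-KO nodes expand to one relation per KO pair", {
  pw <- parse_kgml(tiny_kgml())   # 2-KO node -> 1-KO node
  kb <- build_knowledgebase(list(pw))
  expect_equal(nrow(kb$relations), 2)
  expect_setequal(kb$relations$source_ko, c("K00001", "K00002"))
  expect_equal(unique(kb$relations$target_ko), "K00003")
})

test_that("identical relations from two pathways merge with provenance", {
  pw1 <- parse_kgml(tiny_kgml())
  doc2 <- sub("path:tst00001", "path:tst00002", tiny_kgml(), fixed = TRUE)
  doc2 <- sub('org="ref"', 'org="gmx"', doc2, fixed = TRUE)
  pw2 <- parse_kgml(doc2)
  kb <- build_knowledgebase(list(pw1, pw2))
  expect_equal(nrow(kb$relations), 2)
  expect_equal(unique(kb$relations$species), "gmx,ref")
  expect_true(all(grepl("tst00001", kb$relations$pathways)))
  expect_true(all(grepl("tst00002", kb$relations$pathways)))
})

test_that("disjoint pathways contribute additive relation counts", {
  pw1 <- chain_pathway(c("K10001", "K10002", "K10003", "K10004"),
                       rbind(c(1, 2), c(2, 3), c(3, 4)), "path:a")
  pw2 <- chain_pathway(c("K20001", "K20002", "K20003"),
                       rbind(c(1, 2), c(2, 3)), "path:b")
  kb <- build_knowledgebase(list(pw1, pw2))
  expect_equal(nrow(kb$relations), 5)
})

test_that("knowledgebase construction is order-independent", {
  pws <- lapply(1:4, function(i) {
    chain_pathway(sprintf("K%d000%d", i, 1:4),
                  rbind(c(1, 2), c(2, 3), c(1, 4)),
                  sprintf("path:p%d", i))
  })
  kb1 <- build_knowledgebase(pws)
  kb2 <- build_knowledgebase(rev(pws))
  expect_equal(kb1$relations, kb2$relations)
})

test_that("initial mapping assigns genes to KO-group nodes", {
  pw <- parse_kgml(tiny_kgml())
  g2k <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    ko = c("K00001", "K00002", "K00003", "K00003"))
  mapped <- initial_mapping(pw, g2k)
  expect_equal(mapped$nodes[["1"]]$genes, c("g1", "g2"))
  expect_equal(mapped$nodes[["2"]]$genes, c("g3", "g4"))
  expect_equal(attr(mapped, "empty_nodes"), character(0))

  empty <- initial_mapping(pw, g2k[0, ])
  expect_true(all(vapply(empty$nodes,
                         function(n) length(n$genes) == 0, logical(1))))
  expect_setequal(attr(empty, "empty_nodes"), c("1", "2"))

  expect_warning(initial_mapping(pw, data.frame(gene_id = "g9",
                                                ko = "notako")),
                 "malformed")
})

test_that("gene-level expansion enumerates member-gene pairs", {
  pw <- parse_kgml(tiny_kgml())
  g2k <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    ko = c("K00001", "K00002", "K00003", "K00003"))
  mapped <- initial_mapping(pw, g2k)
  ge <- gene_level_edges(mapped)
  # 2 source genes x 2 target genes, licensed by 2 KO pairs each
  expect_setequal(unique(paste(ge$from, ge$to)),
                  c("g1 g3", "g1 g4", "g2 g3", "g2 g4"))
})

test_that("the triangle drops exactly the last cycle-closing edge", {
  pw <- chain_pathway(c("K90001", "K90002", "K90003"),
                      rbind(c(1, 2), c(2, 3), c(3, 1)))
  g2k <- data.frame(gene_id = c("A", "B", "C"),
                    ko = c("K90001", "K90002", "K90003"))
  kb <- build_knowledgebase(list(pw))
  cs <- build_constraints(initial_mapping(pw, g2k), kb, g2k)
  expect_equal(cs$whitelist,
               data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(cs$dropped$from, "C")
  expect_equal(cs$dropped$to, "A")
  expect_equal(cs$dropped$reason, "cycle")
  expect_true(all(is_allowed(cs, cs$whitelist$from, cs$whitelist$to)))
})

test_that("relations observed only in the excluded organism are withheld", {
  pw <- chain_pathway(c("K91001", "K91002"), rbind(c(1, 2)),
                      org = "gmx")
  g2k <- data.frame(gene_id = c("u", "v"), ko = c("K91001", "K91002"))
  kb <- build_knowledgebase(list(pw))
  cs <- build_constraints(initial_mapping(pw, g2k), kb, g2k,
                          exclude_species = "gmx")
  expect_equal(nrow(cs$whitelist), 0)
  expect_equal(cs$dropped$reason, "species")
  # without exclusion the edge is whitelisted
  cs2 <- build_constraints(initial_mapping(pw, g2k), kb, g2k)
  expect_equal(nrow(cs2$whitelist), 1)
})

test_that("whitelists are always acyclic and inside the allowed set", {
  for (s in 1:25) {
    set.seed(s)
    g <- 8
    kos <- sprintf("K8%02d%02d", s, 1:g)
    # random candidate edges, cycles welcome
    pairs <- expand.grid(from = 1:g, to = 1:g)
    pairs <- pairs[pairs$from != pairs$to, ]
    sel <- pairs[sample(nrow(pairs), 20), ]
    pw <- chain_pathway(kos, as.matrix(sel), sprintf("path:r%d", s))
    g2k <- data.frame(gene_id = sprintf("x%02d_%d", s, 1:g), ko = kos)
    kb <- suppressWarnings(build_knowledgebase(list(pw)))
    cs <- build_constraints(initial_mapping(pw, g2k), kb, g2k)
    nodes <- unique(c(cs$whitelist$from, cs$whitelist$to))
    expect_true(kbnpath:::is_acyclic(cs$whitelist, nodes))
    expect_true(all(is_allowed(cs, cs$whitelist$from, cs$whitelist$to)))
  }
})
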