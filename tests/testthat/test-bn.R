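gauss_data <- function(n, genes, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * length(genes)), n, length(genes),
         dimnames = list(NULL, genes))
}

test_that("node BIC matches the independent least-squares oracle", {
  genes <- paste0("g", 1:5)
  dag <- random_dag(genes, 4, seed = 6)
  data <- sim_linear_gaussian(dag, genes, n = 50, seed = 7)
  parent_sets <- list(character(0), "g2", c("g2", "g3"),
                      c("g1", "g4", "g5"), setdiff(genes, "g1"))
  for (node in genes) {
    for (ps in parent_sets) {
      ps <- setdiff(ps, node)
      expect_equal(node_bic(data, node, ps), oracle_bic(data, node, ps),
                   tolerance = 1e-8)
    }
  }
})

test_that("the parent-free score has the closed Gaussian form", {
  data <- gauss_data(40, "y", seed = 3)
  y <- data[, "y"]
  n <- length(y)
  s2 <- mean((y - mean(y))^2)
  expected <- -n / 2 * (log(2 * pi * s2) + 1) - log(n)
  expect_equal(node_bic(data, "y"), expected, tolerance = 1e-10)
})

test_that("an independent candidate parent lowers the score", {
  data <- gauss_data(500, c("a", "b"), seed = 5)
  expect_lt(node_bic(data, "a", "b"), node_bic(data, "a"))
})

test_that("duplicated parent columns trigger the ridge fallback", {
  data <- gauss_data(30, c("a", "b"), seed = 9)
  data <- cbind(data, b2 = data[, "b"])
  expect_warning(s <- node_bic(data, "a", c("b", "b2")),
                 "rank-deficient")
  expect_true(is.finite(s))
})

test_that("structures validate acyclicity and score decomposably", {
  expect_error(bn_structure(c("a", "b"),
                            data.frame(from = c("a", "b"),
                                       to = c("b", "a"))),
               "cycle")
  data <- gauss_data(60, c("a", "b", "c"), seed = 2)
  s <- bn_structure(c("a", "b", "c"),
                    data.frame(from = c("a", "b"), to = c("b", "c")))
  s <- score_structure(data, s)
  expect_equal(s$total_score, sum(s$per_node_scores), tolerance = 1e-8)
})

test_that("two strongly coupled genes learn exactly one edge", {
  dag <- data.frame(from = "x", to = "y", beta = 1)
  data <- sim_linear_gaussian(dag, c("x", "y"), n = 200, sigma = 0.1,
                              seed = 13)
  # noise scale for y only; x keeps unit variance
  set.seed(13); x <- rnorm(200)
  data <- cbind(x = x, y = x + rnorm(200, 0, 0.1))
  out <- hill_climb(data, config = learn_config(seed = 1))
  edges <- bn_edges(out)
  expect_equal(nrow(edges), 1)
  expect_setequal(unlist(edges[, c("from", "to")]), c("x", "y"))
})

test_that("whitelist edges survive learning even without data support", {
  data <- gauss_data(100, c("a", "b", "c"), seed = 21)
  cs <- structure(list(
    whitelist = data.frame(from = "a", to = "b"),
    allowed = data.frame(from = c("a", "b", "a", "c", "b", "c"),
                         to = c("b", "a", "c", "a", "c", "b")),
    dropped = data.frame(from = character(0), to = character(0),
                         reason = character(0))), class = "ConstraintSet")
  seed_graph <- bn_structure(c("a", "b", "c"),
                             data.frame(from = "a", to = "b"))
  out <- hill_climb(data, seed_graph, cs, learn_config(seed = 1))
  edges <- bn_edges(out)
  expect_true(any(edges$from == "a" & edges$to == "b"))

  # a seed graph missing the whitelist edge is rejected
  expect_error(hill_climb(data, bn_structure(c("a", "b", "c")), cs),
               "whitelist")
})

test_that("a fully blacklisted search applies zero moves", {
  dag <- data.frame(from = "x", to = "y", beta = 1)
  data <- sim_linear_gaussian(dag, c("x", "y", "z"), n = 100, seed = 3)
  cs <- structure(list(
    whitelist = data.frame(from = character(0), to = character(0)),
    allowed = data.frame(from = character(0), to = character(0)),
    dropped = data.frame(from = character(0), to = character(0),
                         reason = character(0))), class = "ConstraintSet")
  out <- hill_climb(data, bn_structure(c("x", "y", "z")), cs)
  expect_equal(nrow(bn_edges(out)), 0)
  expect_length(attr(out, "score_trace"), 1)
})

test_that("the score trace increases strictly with each applied move", {
  genes <- paste0("g", 1:6)
  dag <- random_dag(genes, 6, seed = 17)
  data <- sim_linear_gaussian(dag, genes, n = 150, seed = 18)
  out <- hill_climb(data, config = learn_config(seed = 4))
  trace <- attr(out, "score_trace")
  expect_true(all(diff(trace) > 0))
})

test_that("hill climbing attains the exhaustive optimum on most 4-node data", {
  genes <- paste0("v", 1:4)
  dags <- enumerate_dags(genes)
  expect_length(dags, 543)
  hits <- 0
  for (s in 1:15) {
    dag <- random_dag(genes, 3, seed = 300 + s)
    data <- sim_linear_gaussian(dag, genes, n = 200, seed = 400 + s)
    hc <- hill_climb(data, config = learn_config(restarts = 3, seed = s))
    ex <- exhaustive_best(data, genes, dags = dags)
    expect_lte(hc$total_score, ex$total_score + 1e-9)
    if (abs(hc$total_score - ex$total_score) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 12)
})

test_that("expansion with zero rounds reduces to plain hill climbing", {
  suite <- gen_suite(n_genes = 60, n_pathways = 1, genes_per_pathway = 10,
                     edges_per_pathway = 8, n_withheld = 2, seed = 5)
  cpm <- filter_expressed(cpm_normalize(suite$counts))
  data <- bn_data(cpm)
  lc <- log_cpm(cpm)
  model <- suppressWarnings(fit_gmm(lc, 3, seed = 2))
  pw <- suite$pathways[[1]]
  g2k <- suite$gene_to_ko
  mapped <- suppressWarnings(initial_mapping(pw, g2k))
  cs <- build_constraints(mapped, build_knowledgebase(list(pw)), g2k)
  keep <- function(e) e[e$from %in% colnames(data) &
                          e$to %in% colnames(data), , drop = FALSE]
  cs$whitelist <- keep(cs$whitelist); cs$allowed <- keep(cs$allowed)
  nodes <- unique(c(cs$whitelist$from, cs$whitelist$to))
  if (length(nodes) < 2) skip("degenerate fixture")
  init <- bn_structure(nodes, cs$whitelist)
  plan <- make_plan(model, intersect(nodes, names(model$assignments)))
  cfg0 <- learn_config(seed = 9, expansion_rounds = 0)
  expect_equal(bn_edges(expand_network(data, init, cs, plan, model, cfg0)),
               bn_edges(hill_climb(data, init, cs, cfg0)))
})

test_that("pure-noise additions never attach to the network", {
  # pathway genes carry signal; sampled pool genes are independent noise
  genes <- c(paste0("p", 1:4), paste0("n", 1:6))
  dag <- data.frame(from = c("p1", "p2", "p3"),
                    to = c("p2", "p3", "p4"), beta = 1)
  data <- sim_linear_gaussian(dag, genes, n = 200, sigma = 1, seed = 31)
  allowed <- expand.grid(from = genes, to = genes,
                         stringsAsFactors = FALSE)
  allowed <- allowed[allowed$from != allowed$to, ]
  cs <- structure(list(whitelist = data.frame(from = dag$from,
                                              to = dag$to),
                       allowed = allowed,
                       dropped = data.frame(from = character(0),
                                            to = character(0),
                                            reason = character(0))),
                  class = "ConstraintSet")
  model <- toy_model_bn(genes)
  plan <- structure(list(pivot_cluster = 1, cluster_weights = 1,
                         batch_size = 6), class = "SamplingPlan")
  init <- bn_structure(paste0("p", 1:4), cs$whitelist)
  out <- expand_network(data, init, cs, plan, model,
                        learn_config(seed = 8, expansion_rounds = 1))
  edges <- bn_edges(out)
  noise_touching <- edges$from %in% paste0("n", 1:6) |
    edges$to %in% paste0("n", 1:6)
  # BIC keeps a small null false-positive rate at N = 200 (an edge is
  # accepted when |r| > 0.16, ~2% of null pairs over ~80 candidates), so
  # require near-zero rather than exactly zero attachments
  expect_lte(sum(noise_touching), 2)
  # edges over original genes unchanged
  orig <- edges[!noise_touching, ]
  expect_setequal(paste(orig$from, orig$to),
                  paste(dag$from, dag$to))
})

test_that("withheld signal genes are recovered by expansion", {
  wins <- 0
  for (s in 1:10) {
    genes <- paste0("g", 1:10)
    dag <- random_dag(genes, 12, seed = 500 + s)
    pool <- c(genes, paste0("z", 1:20))
    data <- cbind(sim_linear_gaussian(dag, genes, n = 300,
                                      seed = 600 + s),
                  gauss_data(300, paste0("z", 1:20), seed = 700 + s))
    held <- genes[7:10]
    visible <- setdiff(genes, held)
    wl <- dag[dag$from %in% visible & dag$to %in% visible,
              c("from", "to")]
    nodes <- unique(c(visible, wl$from, wl$to))
    allowed <- dag[, c("from", "to")]    # knowledge licenses true edges
    cs <- structure(list(whitelist = wl, allowed = allowed,
                         dropped = data.frame(from = character(0),
                                              to = character(0),
                                              reason = character(0))),
                    class = "ConstraintSet")
    model <- toy_model_bn(pool)
    plan <- structure(list(pivot_cluster = 1, cluster_weights = 1,
                           batch_size = 30), class = "SamplingPlan")
    init <- bn_structure(nodes, wl)
    out <- expand_network(data, init, cs, plan, model,
                          learn_config(seed = s, expansion_rounds = 1))
    edges <- bn_edges(out)
    truth_keys <- paste(dag$from, dag$to)
    rec_bn <- mean(truth_keys %in% paste(edges$from, edges$to))
    rec_init <- mean(truth_keys %in% paste(wl$from, wl$to))
    connected <- held %in% c(edges$from, edges$to)
    if (any(connected) && rec_bn > rec_init) wins <- wins + 1
  }
  expect_gte(wins, 6)
})
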