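# a linearly separable toy problem: two informative columns decide the label
separable_problem <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    vocab <- c("tgt", paste0("g", 1:10))
    ing <- lapply(seq_len(n), function(i) {
      pos <- i <= n / 2
      base <- sample(vocab[4:11], 3)
      if (pos) unique(c("tgt", "g1", "g2", base)) else setdiff(base, c("g1", "g2"))
    })
    products <- tibble::tibble(
      product_id = sprintf("m%03d", seq_len(n)),
      name = paste("Item", seq_len(n)),
      brand = sample(paste0("B", 1:8), n, TRUE),
      categories = list("c1"),
      price_min = 1, price_max = 2,
      ingredients = ing
    )
    cat <- new_catalog(products)
    labels <- as.integer(seq_len(n) <= n / 2)
    feats <- encode_features(cat, "tgt")
    split <- split_dataset(cat, seed = seed)
    list(catalog = cat, feats = feats, labels = labels, split = split)
  })
}

test_that("the MLP fits a separable problem to training accuracy 1", {
  sp <- separable_problem()
  sp$split$val <- sp$split$train  # monitor the fit itself for this capacity check
  cfg <- train_config(hidden_dim = 16, dropout = 0, max_epochs = 300,
                      patience = 100, seed = 3)
  m <- fit_node_classifier("mlp", sp$feats, sp$labels, sp$split, cfg)
  idx <- match(sp$split$train, sp$feats$row_index)
  p <- predict_proba(m, sp$feats)[idx]
  expect_equal(accuracy(as.integer(p > 0.5), sp$labels[idx]), 1.0)
})

test_that("all model kinds are deterministic given the seed", {
  sp <- separable_problem(n = 120, seed = 2)
  cfg <- train_config(hidden_dim = 8, max_epochs = 30, patience = 10, seed = 5)
  graph <- build_product_graph(sp$catalog, "brand", "tgt")
  for (kind in c("decision_tree", "gradient_boosting", "mlp", "graphsage")) {
    m1 <- fit_node_classifier(kind, sp$feats, sp$labels, sp$split, cfg,
                              graph = graph, brands = sp$catalog$products$brand)
    m2 <- fit_node_classifier(kind, sp$feats, sp$labels, sp$split, cfg,
                              graph = graph, brands = sp$catalog$products$brand)
    expect_identical(predict_proba(m1, sp$feats, graph = graph,
                                   brands = sp$catalog$products$brand),
                     predict_proba(m2, sp$feats, graph = graph,
                                   brands = sp$catalog$products$brand),
                     info = kind)
  }
})

test_that("probabilities are bounded and width mismatches error", {
  sp <- separable_problem(n = 100, seed = 4)
  cfg <- train_config(hidden_dim = 8, max_epochs = 20, patience = 5, seed = 1)
  m <- fit_node_classifier("gradient_boosting", sp$feats, sp$labels, sp$split, cfg)
  p <- predict_proba(m, sp$feats)
  expect_true(all(p >= 0 & p <= 1))
  narrower <- sp$feats
  narrower$matrix <- narrower$matrix[, 1:3]
  narrower$vocab <- narrower$vocab[1:3]
  expect_error(predict_proba(m, narrower), "vocabulary")
})

test_that("single-class training labels are rejected", {
  sp <- separable_problem(n = 80, seed = 6)
  expect_error(
    fit_node_classifier("mlp", sp$feats, rep(1L, 80), sp$split, train_config()),
    class = "degenerate-labels")
})

test_that("early stopping halts before the epoch cap", {
  sp <- separable_problem(n = 150, seed = 7)
  cfg <- train_config(hidden_dim = 16, dropout = 0.1, max_epochs = 400,
                      patience = 15, seed = 2)
  m <- fit_node_classifier("mlp", sp$feats, sp$labels, sp$split, cfg)
  expect_lt(max(m$history$epoch), 400)
  expect_equal(max(m$history$epoch), m$fit$best_epoch + cfg$patience)
})

test_that("the brand-concat regime tolerates unseen brands", {
  sp <- separable_problem(n = 120, seed = 8)
  cfg <- train_config(hidden_dim = 8, max_epochs = 30, patience = 10, seed = 4)
  m <- fit_node_classifier("mlp", sp$feats, sp$labels, sp$split, cfg,
                           brands = sp$catalog$products$brand,
                           input_regime = "ingredients_plus_brand")
  p <- predict_proba(m, sp$feats, brands = rep("NeverSeen", 120))
  expect_length(p, 120)
  expect_true(all(p >= 0 & p <= 1))
})

link_fixture_small <- function(seed = 11) {
  fx <- generate_substitution_fixture(
    sim_params(n_products = 250, n_brands = 10, n_ingredients = 100,
               n_categories = 5, seed = seed))
  fx
}

test_that("held-out positive links outscore fresh negatives after training", {
  fx <- link_fixture_small()
  feats <- encode_features(fx$catalog, "palm oil")
  cfg <- train_config(hidden_dim = 24, out_dim = 24, max_epochs = 60,
                      patience = 15, seed = 3)
  es <- split_edges(fx$graph, seed = 3)
  m <- fit_link_predictor(fx$graph, feats, es, cfg)
  neg <- sample_negative_edges(fx$graph, nrow(es$test), seed = 99)
  s_pos <- rowSums(m$embeddings[es$test[, 1], ] * m$embeddings[es$test[, 2], ])
  s_neg <- rowSums(m$embeddings[neg[, 1], ] * m$embeddings[neg[, 2], ])
  expect_gt(mean(s_pos), mean(s_neg) + 0.5)
})

test_that("link training is seed-deterministic and guards degenerate input", {
  fx <- link_fixture_small(seed = 12)
  feats <- encode_features(fx$catalog, "palm oil")
  cfg <- train_config(hidden_dim = 8, out_dim = 8, max_epochs = 15,
                      patience = 5, seed = 21)
  m1 <- fit_link_predictor(fx$graph, feats, cfg = cfg)
  m2 <- fit_link_predictor(fx$graph, feats, cfg = cfg)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  empty <- fx$graph
  empty$pos_edges <- empty$pos_edges[0, , drop = FALSE]
  expect_error(fit_link_predictor(empty, feats, cfg = cfg),
               class = "no-positives")
})

test_that("score_link is a directed probability with guarded ids", {
  fx <- link_fixture_small(seed = 13)
  feats <- encode_features(fx$catalog, "palm oil")
  cfg <- train_config(hidden_dim = 8, out_dim = 8, max_epochs = 10,
                      patience = 5, seed = 2)
  m <- fit_link_predictor(fx$graph, feats, cfg = cfg)
  e <- fx$graph$pos_edges[1, ]
  s <- score_link(m, e[1], e[2])
  expect_true(s > 0 && s < 1)
  expect_error(score_link(m, e[1], e[1]), "self")
  expect_error(score_link(m, "nope", e[2]), "unknown")
})

test_that("rank_substitutions returns criteria-eligible candidates only", {
  fx <- link_fixture_small(seed = 14)
  feats <- encode_features(fx$catalog, "palm oil")
  cfg <- train_config(hidden_dim = 8, out_dim = 8, max_epochs = 10,
                      patience = 5, seed = 2)
  m <- fit_link_predictor(fx$graph, feats, cfg = cfg)
  src_idx <- fx$graph$pos_edges[1, 1]
  src_id <- fx$graph$nodes[src_idx]
  ranked <- rank_substitutions(m, fx$catalog, src_id,
                               hmap = fx$truth$hierarchy)
  expect_gt(nrow(ranked), 0)
  expect_false(is.unsorted(rev(ranked$score)))
  valid_targets <- fx$graph$nodes[
    fx$graph$pos_edges[fx$graph$pos_edges[, 1] == src_idx, 2]]
  expect_true(all(ranked$candidate_id %in% valid_targets))
})
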