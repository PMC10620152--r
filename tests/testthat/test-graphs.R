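candy_bar_ingredients <- c(
  "Vanillin", "Vegetable Oil", "Peanut", "Chocolate", "Salt", "Flavoring",
  "Sugar", "Milk", "Whey", "Soy Lecithin", "Cocoa Butter", "Cocoa",
  "Emulsifier")

candy_catalog <- function() {
  new_catalog(tibble::tibble(
    product_id = c("c1", "c2"),
    name = c("Candy Bar", "Oil Jar"),
    brand = c("Sweeto", "Kitchen"),
    categories = list("candy", "pantry"),
    price_min = c(1, 4), price_max = c(1.5, 5),
    ingredients = list(normalize_token(candy_bar_ingredients),
                       c("palm oil", "salt"))
  ))
}

test_that("feature rows are binary with the target column masked", {
  cat <- candy_catalog()
  fm <- encode_features(cat, "palm oil")
  expect_equal(ncol(fm$matrix), length(cat$ingredient_vocab) - 1L)
  expect_false("palm oil" %in% fm$vocab)
  expect_equal(sum(fm$matrix["c1", ]), 13)  # the candy-bar row
  expect_true(all(fm$matrix@x %in% c(0, 1)))
})

test_that("feature encoding is invariant to the target's presence", {
  cat1 <- candy_catalog()
  cat2 <- candy_catalog()
  cat2$products$ingredients[[1]] <- c(cat2$products$ingredients[[1]], "palm oil")
  f1 <- encode_features(cat1, "palm oil", vocab = cat1$ingredient_vocab)
  f2 <- encode_features(cat2, "palm oil", vocab = cat1$ingredient_vocab)
  expect_equal(as.matrix(f1$matrix), as.matrix(f2$matrix))
})

test_that("unknown targets and out-of-vocabulary ingredients are handled", {
  cat <- candy_catalog()
  expect_error(encode_features(cat, "unobtainium"), class = "unknown-target")
  # evaluation tokens missing from the training vocabulary are ignored
  train_vocab <- c("palm oil", "salt", "sugar")
  fm <- encode_features(cat, "palm oil", vocab = train_vocab)
  expect_equal(ncol(fm$matrix), 2L)
  expect_equal(unname(fm$matrix["c2", "salt"]), 1)
})

test_that("brand topology is the union of per-brand cliques", {
  cat <- make_random_catalog(40, seed = 9)
  g <- build_product_graph(cat, "brand", "palmoil")
  sizes <- table(cat$products$brand)
  expect_equal(nrow(g$edges), sum(sizes * (sizes - 1) / 2))
  # brute force: an edge iff same brand
  brand <- cat$products$brand
  for (r in seq_len(nrow(g$edges))) {
    expect_equal(brand[g$edges[r, 1]], brand[g$edges[r, 2]])
  }
  expect_true(all(g$edges[, 1] < g$edges[, 2]))  # no self-loops, no dupes
})

test_that("all-distinct brands give an edgeless brand graph", {
  cat <- toy_catalog()
  cat$products$brand <- c("A", "B", "C")
  g <- build_product_graph(new_catalog(cat$products), "brand", "salt")
  expect_equal(nrow(g$edges), 0L)
})

test_that("shared-ingredient and shared-category topologies use set overlap", {
  cat <- toy_catalog()
  gi <- build_product_graph(cat, "shared-ingredient", "sugar")
  # a2 and a3 share "salt"; a1 shares nothing once sugar is masked
  expect_equal(unname(gi$edges), matrix(c(2L, 3L), 1))
  gc <- build_product_graph(cat, "shared-category", "sugar")
  expect_equal(nrow(gc$edges), 2L)  # candy: a1-a2; snack: a2-a3
})

test_that("node labels come from hierarchy-aware target containment", {
  cat <- candy_catalog()
  hmap <- hierarchy_map(stats::setNames(list(c("cocoa", "palm oil")),
                                        normalize_token("Chocolate")))
  g <- build_product_graph(cat, "brand", "palm oil", hmap)
  expect_equal(g$labels, c(1L, 1L))  # c1 via chocolate, c2 explicitly
})

test_that("check_substitution applies the four criteria", {
  mk <- function(id, ing, cat, pmin, pmax) {
    list(product_id = id, ingredients = list(ing), categories = list(cat),
         price_min = pmin, price_max = pmax)
  }
  src <- mk("s", c("palm oil", "sugar"), "candy", 1.00, 1.00)
  good <- mk("g", c("coconut oil", "sugar"), "candy", 1.05, 1.05)
  pricey <- mk("p", c("coconut oil", "sugar"), "candy", 1.20, 1.20)
  expect_true(check_substitution(src, good, "palm oil"))
  expect_false(check_substitution(src, pricey, "palm oil"))   # > 10% price gap
  bad <- mk("b", c("palm oil", "rice"), "candy", 1.00, 1.00)
  expect_false(check_substitution(src, bad, "palm oil"))      # still contains it
  other <- mk("o", c("rice"), "cereal", 1.00, 1.00)
  expect_false(check_substitution(src, other, "palm oil"))    # no shared category
  expect_false(check_substitution(good, src, "palm oil"))     # wrong direction
})

test_that("enumerate_substitutions equals the brute-force oracle", {
  for (seed in 1:8) {
    cat <- make_random_catalog(35, seed = seed)
    g <- enumerate_substitutions(cat, "palmoil")
    oracle <- oracle_substitutions(cat, "palmoil", list())
    expect_equal(g$pos_edges[order(g$pos_edges[, 1], g$pos_edges[, 2]), ,
                             drop = FALSE],
                 unname(oracle[order(oracle[, 1], oracle[, 2]), ,
                               drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("raising the price tolerance never removes an edge", {
  cat <- make_random_catalog(40, seed = 3)
  tight <- enumerate_substitutions(cat, "palmoil", cfg = criteria_config(0.05))
  loose <- enumerate_substitutions(cat, "palmoil", cfg = criteria_config(0.20))
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(tight$pos_edges) %in% key(loose$pos_edges)))
})

test_that("splits are disjoint, brand-exclusive and seed-deterministic", {
  cat <- make_random_catalog(80, seed = 4)
  sp <- split_dataset(cat, seed = 11)
  ids <- c(sp$train, sp$val, sp$test_decomposed, sp$test_nondecomposed)
  expect_equal(anyDuplicated(ids), 0L)
  br <- function(x) unique(cat$products$brand[match(x, cat$products$product_id)])
  expect_length(intersect(br(sp$test_nondecomposed), br(sp$train)), 0L)
  expect_identical(sp, split_dataset(cat, seed = 11))
  expect_false(identical(sp$train, split_dataset(cat, seed = 12)$train))
})

test_that("degenerate split requests are caught", {
  cat <- toy_catalog()
  one_brand <- cat$products
  one_brand$brand <- "Solo"
  expect_error(split_dataset(new_catalog(one_brand), brand_holdout = 0.5),
               class = "insufficient-brands")
  sp <- split_dataset(cat, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                      brand_holdout = 0)
  expect_length(sp$test_nondecomposed, 0L)
})

test_that("negative sampling avoids positives and self-loops, exact count", {
  cat <- make_random_catalog(25, seed = 6)
  g <- enumerate_substitutions(cat, "palmoil")
  pos_key <- paste(g$pos_edges[, 1], g$pos_edges[, 2])
  neg <- sample_negative_edges(g, 200, seed = 1)
  expect_equal(nrow(neg), 200L)
  expect_false(any(paste(neg[, 1], neg[, 2]) %in% pos_key))
  expect_false(any(neg[, 1] == neg[, 2]))
  expect_identical(neg, sample_negative_edges(g, 200, seed = 1))
})

test_that("exhausting the non-edge supply errors", {
  g <- structure(list(nodes = c("a", "b"),
                      pos_edges = cbind(source = c(1L, 2L), target = c(2L, 1L)),
                      labels = c(1L, 0L), criteria = criteria_config(),
                      target = "x"),
                 class = "substitution_graph")
  expect_error(sample_negative_edges(g, 1), class = "exhausted")
})
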