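pb_catalog <- function() {
  new_catalog(tibble::tibble(
    product_id = c("h1", "h2", "h3"),
    name = c("Brand Name Peanut Butter", "Choco Spread", "Candy Bar"),
    brand = c("Brand Name", "Sweeto", "Sweeto"),
    categories = list("spread", "spread", "candy"),
    price_min = c(2, 3, 1), price_max = c(2.5, 3.5, 1.5),
    ingredients = list(
      c("peanut", "palm oil", "salt"),
      c("sugar", "cocoa", "peanut butter"),
      c("sugar", "peanut butter", "milk")
    )
  ))
}

test_that("an ingredient matching a product name becomes a hierarchy entry", {
  hmap <- build_hierarchy(pb_catalog())
  expect_true("peanut butter" %in% names(hmap$entries))
  expect_setequal(hmap$entries[["peanut butter"]],
                  c("peanut", "palm oil", "salt"))
})

test_that("constituents require prevalence theta across matching products", {
  wines <- lapply(1:4, function(i) {
    ing <- c("sugar", "water", "grape", "sulphites")
    if (i == 1) ing <- c(ing, "oak essence")  # below-threshold extra
    ing
  })
  cat <- new_catalog(tibble::tibble(
    product_id = sprintf("w%d", 1:5),
    name = c("Vintner Wine", "Bodega Wine", "Cellar Wine", "Estate Wine",
             "Cooking Sauce"),
    brand = c("Vintner", "Bodega", "Cellar", "Estate", "Chef"),
    categories = list("wine", "wine", "wine", "wine", "sauce"),
    price_min = c(5, 6, 7, 8, 2), price_max = c(6, 7, 8, 9, 3),
    ingredients = c(
      lapply(wines, function(x) normalize_token(x, on_empty = "drop")),
      list(c("tomato", "wine"))
    )
  ))
  hmap <- build_hierarchy(cat, theta = 0.75)
  expect_true("wine" %in% names(hmap$entries))
  expect_setequal(hmap$entries[["wine"]],
                  normalize_token(c("sugar", "water", "grape", "sulphites")))
  expect_false("oak essenc" %in% hmap$entries[["wine"]])
})

test_that("catalogs without name matches give an empty map", {
  expect_length(build_hierarchy(toy_catalog())$entries, 0L)
})

test_that("decomposition reaches the recursive fixpoint and keeps compounds", {
  hmap <- hierarchy_map(list(
    "peanut butter" = c("peanut", "palm oil", "salt")))
  expect_setequal(decompose_ingredients("peanut butter", hmap),
                  c("peanut butter", "peanut", "palm oil", "salt"))
  two <- hierarchy_map(list(a = "b", b = "c"))
  expect_setequal(decompose_ingredients("a", two), c("a", "b", "c"))
  expect_setequal(decompose_ingredients(c("x", "y"), hierarchy_map()),
                  c("x", "y"))
})

test_that("cyclic hierarchies are rejected", {
  expect_error(hierarchy_map(list(a = "b", b = "a")), class = "cyclic-hierarchy")
  expect_error(hierarchy_map(list(a = "a")), NA)  # self-reference is stripped
  expect_length(hierarchy_map(list(a = "a"))$entries$a, 0L)
})

test_that("contains_target finds transitively implied ingredients", {
  hmap <- hierarchy_map(list("peanut butter" = c("peanut", "palm oil", "salt")))
  expect_true(contains_target("peanut butter", hmap, "palm oil"))
  expect_false(contains_target("salt", hierarchy_map(), "palm oil"))
  deep <- hierarchy_map(list(a = "b", b = "tgt"))
  expect_true(contains_target("a", deep, "tgt"))
})

test_that("decompose/contains agree with the transitive-closure oracle", {
  for (seed in 1:20) {
    entries <- make_random_hierarchy(k = 12, seed = seed)
    hmap <- hierarchy_map(entries)
    toks <- paste0("t", 1:12)
    input <- withr::with_seed(seed + 100, sample(toks, 3))
    expect_identical(sort(decompose_ingredients(input, hmap)),
                     oracle_decompose(input, entries))
    for (target in toks) {
      expect_identical(contains_target(input, hmap, target),
                       oracle_contains(input, entries, target))
    }
  }
})

test_that("decomposition is monotone and idempotent", {
  for (seed in 1:10) {
    hmap <- hierarchy_map(make_random_hierarchy(k = 10, seed = seed))
    input <- withr::with_seed(seed, sample(paste0("t", 1:10), 4))
    out <- decompose_ingredients(input, hmap)
    expect_true(all(input %in% out))
    expect_setequal(decompose_ingredients(out, hmap), out)
  }
})

test_that("hierarchy maps round-trip through JSON", {
  hmap <- hierarchy_map(list(wine = c("sugar", "water", "grape", "sulphit"),
                             "peanut butter" = c("peanut", "palm oil")))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(hmap, tmp)
  expect_equal(read_hierarchy(tmp)$entries, hmap$entries)
})
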