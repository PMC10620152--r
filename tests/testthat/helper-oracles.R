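# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# transitive-closure membership by repeated set expansion
oracle_decompose <- function(ingredients, entries) {
  out <- unique(ingredients)
  repeat {
    grown <- unique(c(out, unlist(entries[out[out %in% names(entries)]])))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

oracle_contains <- function(ingredients, entries, target) {
  target %in% oracle_decompose(ingredients, entries)
}

# brute-force O(n^2) evaluation of the four substitution criteria
oracle_substitutions <- function(catalog, target, entries, tol = 0.10) {
  p <- catalog$products
  n <- nrow(p)
  has <- vapply(p$ingredients, oracle_contains, logical(1),
                entries = entries, target = target)
  mid <- (p$price_min + p$price_max) / 2
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (!has[i] || has[j]) next
      if (length(intersect(p$categories[[i]], p$categories[[j]])) == 0) next
      if (abs(mid[j] - mid[i]) / mid[i] > tol) next
      out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# per-node loop implementation of the SAGE mean-aggregator layer
naive_sage <- function(X, neighbors, W, b = NULL, relu = TRUE) {
  n <- nrow(X)
  f <- ncol(X)
  out <- matrix(NA_real_, n, ncol(W))
  for (v in seq_len(n)) {
    nb <- neighbors[[v]]
    agg <- if (length(nb) == 0) rep(0, f) else colMeans(X[nb, , drop = FALSE])
    z <- c(X[v, ], agg) %*% W
    if (!is.null(b)) z <- z + b
    out[v, ] <- if (relu) pmax(z, 0) else z
  }
  out
}

# all-pairs Mann-Whitney formulation of the AUC
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# small random catalogs for property tests (independent of the simulator)
make_random_catalog <- function(n, seed, target = "palmoil", n_cats = 4,
                                n_brands = 5, vocab_size = 25) {
  withr::with_seed(seed, {
    vocab <- c(target, paste0("ing", seq_len(vocab_size)))
    cats <- paste0("cat", seq_len(n_cats))
    brands <- paste0("Brand", seq_len(n_brands))
    products <- tibble::tibble(
      product_id = sprintf("r%03d", seq_len(n)),
      name = paste("Item", seq_len(n)),
      brand = sample(brands, n, TRUE),
      categories = lapply(seq_len(n), function(i) sample(cats, sample(1:2, 1))),
      price_min = round(runif(n, 1, 10), 2),
      price_max = NA_real_,
      ingredients = lapply(seq_len(n), function(i) {
        ing <- sample(vocab[-1], sample(2:6, 1))
        if (runif(1) < 0.4) ing <- c(ing, target)
        unique(ing)
      })
    )
    products$price_max <- products$price_min * runif(n, 1, 1.15)
    new_catalog(products)
  })
}

# random acyclic hierarchy over a token alphabet: token i may only point to
# tokens with larger index, so acyclicity holds by construction
make_random_hierarchy <- function(k, seed, p_entry = 0.5) {
  withr::with_seed(seed, {
    toks <- paste0("t", seq_len(k))
    entries <- list()
    for (i in seq_len(k - 1)) {
      if (runif(1) < p_entry) {
        later <- seq(i + 1, k)
        m <- min(sample(1:3, 1), length(later))
        entries[[toks[i]]] <- toks[later[sample.int(length(later), m)]]
      }
    }
    entries
  })
}

# tiny deterministic catalog used across I/O tests
toy_catalog <- function() {
  new_catalog(tibble::tibble(
    product_id = c("a1", "a2", "a3"),
    name = c("Choco Bar", "Nut Mix, Deluxe", "Plain Crisps"),
    brand = c("Acme", "Acme", "Bolt"),
    categories = list("candy", c("candy", "snack"), "snack"),
    price_min = c(1, 2, 3),
    price_max = c(1.2, 2.4, 3.1),
    ingredients = list(c("sugar", "cocoa"), c("peanut", "salt"), c("potato", "salt"))
  ))
}
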