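#' Build the node-classification product graph
#'
#' The default topology links products made by the same brand (the union of
#' per-brand cliques); alternatives link products sharing at least one
#' ingredient (target masked) or at least one category. Node labels record
#' target-ingredient presence, determined through the compound hierarchy so
#' hidden dependencies count as positives.
#'
#' @param catalog a `food_catalog`.
#' @param topology `"brand"`, `"shared-ingredient"` or `"shared-category"`.
#' @param target normalized target ingredient token.
#' @param hmap a `hierarchy_map` used for labelling.
#' @return object of class `product_graph`: list with `nodes` (product ids),
#'   `edges` (2-column integer matrix of node indices, `i < j`, no
#'   self-loops), `labels` (0/1 integer per node) and `topology`.
#' @export
build_product_graph <- function(catalog,
                                topology = c("brand", "shared-ingredient",
                                             "shared-category"),
                                target, hmap = hierarchy_map()) {
  topology <- match.arg(topology)
  stopifnot(inherits(catalog, "food_catalog"))
  p <- catalog$products
  n <- nrow(p)
  labels <- vapply(p$ingredients, contains_target, logical(1),
                   hmap = hmap, target = target)

  edges <- switch(topology,
    "brand" = {
      by_brand <- split(seq_len(n), p$brand)
      do.call(rbind, lapply(by_brand, function(idx) {
        if (length(idx) < 2L) return(NULL)
        t(utils::combn(sort(idx), 2L))
      }))
    },
    "shared-ingredient" = incidence_edges(
      lapply(p$ingredients, setdiff, y = target), n),
    "shared-category" = incidence_edges(p$categories, n)
  )
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(
    list(nodes = p$product_id, edges = edges,
         labels = as.integer(labels), topology = topology, target = target),
    class = "product_graph"
  )
}

# pairs of rows whose attribute sets intersect, via sparse incidence crossprod
incidence_edges <- function(sets, n) {
  toks <- sort(unique(unlist(sets)))
  if (length(toks) == 0L) return(NULL)
  idx <- stats::setNames(seq_along(toks), toks)
  i <- rep(seq_len(n), lengths(sets))
  j <- idx[unlist(sets)]
  m <- Matrix::sparseMatrix(i = i, j = unname(j), x = 1,
                            dims = c(n, length(toks)))
  overlap <- as.matrix(Matrix::tcrossprod(m))
  tri <- which(overlap > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  if (nrow(tri) == 0L) NULL else unname(tri)
}

#' @export
print.product_graph <- function(x, ...) {
  cat(sprintf("<product_graph> topology=%s, %d nodes, %d undirected edges, %d positive labels\n",
              x$topology, length(x$nodes), nrow(x$edges), sum(x$labels)))
  invisible(x)
}

#' Substitution criteria configuration
#'
#' A substitution edge from product `s` to product `t` is valid when (1) `s`
#' contains the target ingredient, (2) `t` does not, (3) they share at least
#' one category, and (4) their price points are within `price_tolerance` of
#' each other, relative to the product being replaced. The price point of a
#' product collapses its `[price_min, price_max]` range to a single number
#' (midpoint by default).
#'
#' @param price_tolerance relative price band, in (0, 1); default 0.10.
#' @param price_point `"midpoint"` (only rule implemented).
#' @param category_rule `"intersect"` (only rule implemented).
#' @return object of class `criteria_config`.
#' @export
criteria_config <- function(price_tolerance = 0.10, price_point = "midpoint",
                            category_rule = "intersect") {
  stopifnot(price_tolerance > 0, price_tolerance < 1)
  price_point <- match.arg(price_point, "midpoint")
  category_rule <- match.arg(category_rule, "intersect")
  structure(list(price_tolerance = price_tolerance, price_point = price_point,
                 category_rule = category_rule),
            class = "criteria_config")
}

price_point_of <- function(price_min, price_max, cfg) (price_min + price_max) / 2

#' Is one product a criteria-valid substitution for another?
#'
#' Evaluates the four substitution criteria for a single ordered pair. `source`
#' is the product being replaced; `candidate` is the proposed replacement.
#' Both are single product records (one-row subsets of `catalog$products`, or
#' lists with the same fields).
#'
#' @param source,candidate product records.
#' @param target normalized target ingredient token.
#' @param hmap a `hierarchy_map` (hidden target presence counts).
#' @param cfg a [criteria_config()].
#' @return logical scalar.
#' @export
check_substitution <- function(source, candidate, target,
                               hmap = hierarchy_map(),
                               cfg = criteria_config()) {
  get1 <- function(rec, field) {
    v <- rec[[field]]
    if (is.list(v) && !is.null(dim(rec))) v <- v[[1]]
    v
  }
  src_ing <- unlist(get1(source, "ingredients"))
  cand_ing <- unlist(get1(candidate, "ingredients"))
  if (!contains_target(src_ing, hmap, target)) return(FALSE)
  if (contains_target(cand_ing, hmap, target)) return(FALSE)
  cats_s <- unlist(get1(source, "categories"))
  cats_c <- unlist(get1(candidate, "categories"))
  if (length(intersect(cats_s, cats_c)) == 0L) return(FALSE)
  m_s <- price_point_of(get1(source, "price_min"), get1(source, "price_max"), cfg)
  m_c <- price_point_of(get1(candidate, "price_min"), get1(candidate, "price_max"), cfg)
  abs(m_c - m_s) / m_s <= cfg$price_tolerance
}

#' Enumerate all criteria-valid substitution edges
#'
#' Computes the full directed ground-truth edge set: every ordered product
#' pair satisfying the four substitution criteria. Equivalent to (but much
#' faster than) evaluating [check_substitution()] over all ordered pairs.
#'
#' @inheritParams build_product_graph
#' @param cfg a [criteria_config()].
#' @return object of class `substitution_graph`: list with `nodes` (product
#'   ids), `pos_edges` (2-column integer matrix of node indices,
#'   source -> target), `labels` (target presence per node), `criteria`,
#'   `target`.
#' @export
enumerate_substitutions <- function(catalog, target, hmap = hierarchy_map(),
                                    cfg = criteria_config()) {
  stopifnot(inherits(catalog, "food_catalog"))
  p <- catalog$products
  n <- nrow(p)
  has_t <- vapply(p$ingredients, contains_target, logical(1),
                  hmap = hmap, target = target)
  mid <- price_point_of(p$price_min, p$price_max, cfg)

  src_idx <- which(has_t)
  dst_idx <- which(!has_t)
  edges <- matrix(integer(0), ncol = 2L)
  if (length(src_idx) > 0L && length(dst_idx) > 0L) {
    # category co-membership between sources and candidates
    toks <- sort(unique(unlist(p$categories)))
    tok_id <- stats::setNames(seq_along(toks), toks)
    inc <- Matrix::sparseMatrix(
      i = rep(seq_len(n), lengths(p$categories)),
      j = unname(tok_id[unlist(p$categories)]),
      x = 1, dims = c(n, length(toks)))
    overlap <- as.matrix(Matrix::tcrossprod(inc[src_idx, , drop = FALSE],
                                            inc[dst_idx, , drop = FALSE]))
    hits <- which(overlap > 0, arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      s <- src_idx[hits[, 1]]
      d <- dst_idx[hits[, 2]]
      ok <- abs(mid[d] - mid[s]) / mid[s] <= cfg$price_tolerance
      edges <- cbind(s[ok], d[ok])
    }
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("source", "target"))
  structure(
    list(nodes = p$product_id, pos_edges = edges,
         labels = as.integer(has_t), criteria = cfg, target = target),
    class = "substitution_graph"
  )
}

#' @export
print.substitution_graph <- function(x, ...) {
  cat(sprintf("<substitution_graph> %d nodes, %d directed substitution edges (target '%s')\n",
              length(x$nodes), nrow(x$pos_edges), x$target))
  invisible(x)
}

#' Split products into train / validation / two test sets
#'
#' The non-decomposed test set is formed by holding out whole brands, so its
#' brands never occur in training (an unseen-brand generalization test). The
#' remaining products are randomized into train, validation and the decomposed
#' test set. Deterministic given `seed`.
#'
#' @param catalog a `food_catalog`.
#' @param fractions named numeric: `train`, `val`, `test` fractions of the
#'   non-held-out products (positive, sum at most 1).
#' @param brand_holdout fraction of brands to hold out for the unseen-brand
#'   test set (0 disables it).
#' @param seed integer seed.
#' @return object of class `split_spec`: list of product-id character vectors
#'   `train`, `val`, `test_decomposed`, `test_nondecomposed`, plus `seed`.
#' @export
split_dataset <- function(catalog, fractions = c(train = 0.7, val = 0.1, test = 0.1),
                          brand_holdout = 0.1, seed = 1L) {
  stopifnot(inherits(catalog, "food_catalog"),
            all(fractions > 0), sum(fractions) <= 1 + 1e-9,
            brand_holdout >= 0, brand_holdout < 1)
  p <- catalog$products
  brands <- catalog$brand_vocab
  withr::with_seed(seed, {
    held_brands <- character(0)
    if (brand_holdout > 0) {
      k <- ceiling(brand_holdout * length(brands))
      if (k >= length(brands)) {
        stop_foodgraph("insufficient-brands",
                       "too few brands to hold out an unseen-brand test set")
      }
      held_brands <- sample(brands, k)
    }
    nondec <- p$product_id[p$brand %in% held_brands]
    rest <- setdiff(p$product_id, nondec)
    rest <- sample(rest)
    n <- length(rest)
    n_train <- floor(fractions[["train"]] * n)
    n_val <- floor(fractions[["val"]] * n)
    n_test <- min(floor(fractions[["test"]] * n), n - n_train - n_val)
    structure(
      list(train = sort(rest[seq_len(n_train)]),
           val = sort(rest[n_train + seq_len(n_val)]),
           test_decomposed = sort(rest[n_train + n_val + seq_len(n_test)]),
           test_nondecomposed = sort(nondec),
           seed = seed),
      class = "split_spec"
    )
  })
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> train=%d val=%d test_decomposed=%d test_nondecomposed=%d (seed %d)\n",
              length(x$train), length(x$val), length(x$test_decomposed),
              length(x$test_nondecomposed), x$seed))
  invisible(x)
}

#' Sample negative (non-existent) directed edges
#'
#' Draws `count` ordered node pairs uniformly from the pairs that are neither
#' positive substitution edges nor self-loops. Intended to be called fresh at
#' every training epoch so that, over training, the sampled set approximates
#' the full negative edge population while each epoch stays balanced.
#'
#' @param graph a `substitution_graph`.
#' @param count number of negative edges to draw.
#' @param seed optional integer seed for a reproducible draw; `NULL` uses the
#'   current RNG stream.
#' @return 2-column integer matrix (`source`, `target`) of node indices.
#' @export
sample_negative_edges <- function(graph, count, seed = NULL) {
  stopifnot(inherits(graph, "substitution_graph"), count >= 0)
  n <- length(graph$nodes)
  pos_keys <- (graph$pos_edges[, 1] - 1) * n + graph$pos_edges[, 2]
  n_avail <- n * (n - 1) - nrow(graph$pos_edges)
  if (count > n_avail) {
    stop_foodgraph("exhausted",
                   sprintf("requested %d negatives but only %d non-edges exist",
                           count, n_avail))
  }
  draw <- function() {
    if (count == 0L) return(matrix(integer(0), ncol = 2L))
    if (count > 0.25 * n_avail) {
      # dense regime: enumerate the complement exactly
      all_keys <- seq_len(n * n)
      self_keys <- (seq_len(n) - 1) * n + seq_len(n)
      avail <- setdiff(all_keys, c(self_keys, pos_keys))
      keys <- sample(avail, count)
    } else {
      keys <- integer(0)
      while (length(keys) < count) {
        cand_i <- sample.int(n, 2L * (count - length(keys)), replace = TRUE)
        cand_j <- sample.int(n, 2L * (count - length(keys)), replace = TRUE)
        k <- (cand_i - 1) * n + cand_j
        k <- k[cand_i != cand_j & !(k %in% pos_keys)]
        keys <- unique(c(keys, k))
      }
      keys <- keys[seq_len(count)]
    }
    cbind(source = as.integer((keys - 1) %/% n + 1),
          target = as.integer((keys - 1) %% n + 1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
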