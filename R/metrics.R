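#' Classification accuracy
#'
#' Fraction of predictions equal to the true labels.
#'
#' @param predicted,truth equal-length, non-empty vectors of class labels.
#' @return numeric scalar in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (length(truth) == 0L) stop("cannot compute accuracy of zero predictions")
  mean(predicted == truth)
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a uniformly chosen positive is scored above a
#' uniformly chosen negative, with ties counted one half: the Mann-Whitney
#' U statistic scaled to `[0, 1]`. Invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels 0/1 (or logical) true labels; both classes must be present.
#' @return numeric scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  y <- as.integer(as.logical(labels))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both a positive and a negative class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Multi-run evaluation protocol configuration
#'
#' Each target ingredient is evaluated over `n_runs` independently seeded
#' runs; the per-ingredient result is the median across runs, and the headline
#' numbers are the mean and standard deviation of those medians across
#' ingredients.
#'
#' @param n_runs runs per ingredient (default 25).
#' @param targets normalized target ingredient tokens (default: palm oil,
#'   wheat, milk, egg, soya).
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(n_runs = 25L,
                            targets = c("palm oil", "wheat", "milk", "egg",
                                        "soya")) {
  stopifnot(n_runs >= 1L, length(targets) >= 1L)
  structure(list(n_runs = as.integer(n_runs), targets = targets),
            class = "protocol_config")
}

#' Run one node-classification experiment
#'
#' Builds decomposed features for training and the decomposed test set,
#' non-decomposed features for the unseen-brand test set (hierarchy used only
#' for labels there), fits the requested model and reports accuracy and AUC on
#' both test sets.
#'
#' @param catalog a `food_catalog`.
#' @param target normalized target ingredient token.
#' @param kind model kind, see [fit_node_classifier()].
#' @param cfg a [train_config()]; `cfg$seed` drives the split and the fit.
#' @param hmap a `hierarchy_map`; `NULL` builds one from the catalog.
#' @param topology product-graph topology for `graphsage`.
#' @param input_regime MLP input regime.
#' @param split optional precomputed `split_spec`.
#' @return tibble with one row per test set: `test_set`, `accuracy`, `auc`,
#'   `n`.
#' @export
run_node_experiment <- function(catalog, target, kind = "graphsage",
                                cfg = train_config(), hmap = NULL,
                                topology = "brand",
                                input_regime = "ingredients_only",
                                split = NULL) {
  if (is.null(hmap)) hmap <- build_hierarchy(catalog)
  if (is.null(split)) split <- split_dataset(catalog, seed = cfg$seed)
  labels <- as.integer(vapply(catalog$products$ingredients, contains_target,
                              logical(1), hmap = hmap, target = target))
  feats_dec <- encode_features(catalog, target, decomposed = TRUE, hmap = hmap)
  feats_raw <- encode_features(catalog, target, decomposed = FALSE, hmap = hmap)
  graph <- if (kind == "graphsage") {
    build_product_graph(catalog, topology, target, hmap)
  } else NULL
  brands <- catalog$products$brand
  model <- fit_node_classifier(kind, feats_dec, labels, split, cfg,
                               graph = graph, brands = brands,
                               input_regime = input_regime)
  eval_set <- function(ids, feats) {
    idx <- match(ids, feats$row_index)
    p <- predict_proba(model, feats, graph = graph, brands = brands)[idx]
    y <- labels[idx]
    tibble::tibble(
      accuracy = accuracy(as.integer(p > 0.5), y),
      auc = if (length(unique(y)) == 2L) auc(p, y) else NA_real_,
      n = length(idx)
    )
  }
  dec <- eval_set(split$test_decomposed, feats_dec)
  out <- tibble::tibble(test_set = "decomposed", dec)
  if (length(split$test_nondecomposed) > 0L) {
    nondec <- eval_set(split$test_nondecomposed, feats_raw)
    out <- rbind(out, tibble::tibble(test_set = "non_decomposed", nondec))
  }
  attr(out, "model") <- model
  out
}

#' Run one link-prediction experiment
#'
#' Enumerates the ground-truth substitution edges (unless a precomputed graph
#' is given), splits them, fits the link predictor and evaluates on held-out
#' positives against an equal number of fixed, seeded negatives (not
#' resampled), so test metrics are comparable across runs.
#'
#' @inheritParams run_node_experiment
#' @param graph optional precomputed `substitution_graph`.
#' @param criteria a [criteria_config()].
#' @return tibble with `accuracy`, `auc`, `n` (edges evaluated).
#' @export
run_link_experiment <- function(catalog, target, cfg = train_config(),
                                hmap = NULL, criteria = criteria_config(),
                                graph = NULL) {
  if (is.null(hmap)) hmap <- build_hierarchy(catalog)
  if (is.null(graph)) {
    graph <- enumerate_substitutions(catalog, target, hmap, criteria)
  }
  feats <- encode_features(catalog, target, decomposed = FALSE, hmap = hmap)
  edge_split <- split_edges(graph, seed = cfg$seed)
  model <- fit_link_predictor(graph, feats, edge_split, cfg)
  neg_test <- sample_negative_edges(graph, nrow(edge_split$test),
                                    seed = cfg$seed + 2000L)
  pairs <- rbind(edge_split$test, neg_test)
  y <- c(rep(1L, nrow(edge_split$test)), rep(0L, nrow(neg_test)))
  s <- rowSums(model$embeddings[pairs[, 1], , drop = FALSE] *
                 model$embeddings[pairs[, 2], , drop = FALSE])
  p <- sigmoid(s)
  out <- tibble::tibble(accuracy = accuracy(as.integer(p > 0.5), y),
                        auc = auc(p, y), n = length(y))
  attr(out, "model") <- model
  out
}

#' The multi-run, multi-ingredient evaluation protocol
#'
#' For each target ingredient, runs the experiment `n_runs` times with seeds
#' `cfg$seed + 0 .. n_runs - 1`, takes the per-ingredient median of every
#' metric, and reports the mean and standard deviation of those medians across
#' ingredients. The full per-run table is returned alongside the aggregates.
#'
#' @param task `"node"` or `"link"`.
#' @param catalog a `food_catalog` containing every target ingredient.
#' @param protocol a [protocol_config()].
#' @param cfg a [train_config()]; `cfg$seed` is the base seed.
#' @param hmap a `hierarchy_map`; `NULL` builds one from the catalog.
#' @param ... forwarded to [run_node_experiment()] / [run_link_experiment()]
#'   (e.g. `kind`, `topology`, `input_regime`, `criteria`).
#' @return list with `per_run` (tibble: ingredient, run, seed, metrics),
#'   `per_ingredient` (medians) and `summary` (mean and sd across
#'   ingredients).
#' @export
run_protocol <- function(task = c("node", "link"), catalog,
                         protocol = protocol_config(), cfg = train_config(),
                         hmap = NULL, ...) {
  task <- match.arg(task)
  if (is.null(hmap)) hmap <- build_hierarchy(catalog)
  rows <- list()
  for (target in protocol$targets) {
    for (r in seq_len(protocol$n_runs)) {
      seed_r <- cfg$seed + (r - 1L)
      cfg_r <- cfg
      cfg_r$seed <- seed_r
      res <- if (task == "node") {
        m <- run_node_experiment(catalog, target, cfg = cfg_r, hmap = hmap, ...)
        m[m$test_set == "decomposed", c("accuracy", "auc", "n")]
      } else {
        run_link_experiment(catalog, target, cfg = cfg_r, hmap = hmap, ...)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ingredient = target, run = r, seed = seed_r, res)
    }
  }
  per_run <- do.call(rbind, rows)
  med <- stats::aggregate(cbind(accuracy, auc) ~ ingredient, data = per_run,
                          FUN = stats::median)
  summary <- tibble::tibble(
    metric = c("accuracy", "auc"),
    mean = c(mean(med$accuracy), mean(med$auc)),
    sd = c(stats::sd(med$accuracy), stats::sd(med$auc))
  )
  list(per_run = per_run, per_ingredient = tibble::as_tibble(med),
       summary = summary)
}
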