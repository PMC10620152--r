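#' Training configuration
#'
#' Hyperparameters shared by the node classifiers and the link predictor:
#' 128 hidden channels, dropout 0.5, learning rate 0.01 (node task) / 0.001
#' (link task) with weight decay 5e-3 under Adam, at most 400 epochs with
#' early stopping on the validation score; gradient boosting uses 100 stages
#' of depth-3 trees.
#'
#' @param hidden_dim hidden channels of the neural models.
#' @param out_dim output embedding width of the link-prediction encoder.
#' @param dropout dropout probability in `[0, 1)`.
#' @param lr_node,lr_link Adam learning rates for the two tasks.
#' @param weight_decay L2 penalty added to weight gradients.
#' @param max_epochs maximum training epochs for neural models.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed integer seed controlling initialization, dropout and negative
#'   sampling.
#' @param boosting_stages,tree_max_depth gradient-boosting ensemble size and
#'   tree depth.
#' @return object of class `train_config`.
#' @export
train_config <- function(hidden_dim = 128L, out_dim = 128L, dropout = 0.5,
                         lr_node = 0.01, lr_link = 0.001, weight_decay = 5e-3,
                         max_epochs = 400L, patience = 50L, seed = 1L,
                         boosting_stages = 100L, tree_max_depth = 3L) {
  stopifnot(hidden_dim > 0, out_dim > 0, dropout >= 0, dropout < 1,
            lr_node > 0, lr_link > 0, weight_decay >= 0, max_epochs > 0,
            patience > 0, boosting_stages > 0, tree_max_depth > 0)
  structure(as.list(environment()), class = "train_config")
}

#' Fit a node classifier for masked-ingredient prediction
#'
#' Four model kinds are supported: `decision_tree` (Gini impurity, via rpart),
#' `gradient_boosting` (100 depth-3 stages, via xgboost), `mlp` (two-layer
#' ReLU network trained with Adam, binary cross entropy, dropout and early
#' stopping) and `graphsage` (the same network with a mean-aggregator layer
#' over the product graph). The MLP can consume the ingredient vector alone or
#' concatenated with a brand one-hot (`input_regime`); unseen brands map to
#' the zero brand vector at prediction time. Tree models consume the
#' ingredients-only regime by default.
#'
#' @param kind one of `"decision_tree"`, `"gradient_boosting"`, `"mlp"`,
#'   `"graphsage"`.
#' @param features a `feature_matrix` (target masked).
#' @param labels 0/1 integer vector aligned with `features$row_index`.
#' @param split a `split_spec`; training uses `split$train`, early stopping
#'   uses `split$val`.
#' @param cfg a [train_config()].
#' @param graph a `product_graph` (required for `kind = "graphsage"`).
#' @param brands character vector of brands aligned with rows (required for
#'   `input_regime = "ingredients_plus_brand"`).
#' @param input_regime `"ingredients_only"` or `"ingredients_plus_brand"`.
#' @return object of class `node_classifier`.
#' @export
fit_node_classifier <- function(kind = c("decision_tree", "gradient_boosting",
                                         "mlp", "graphsage"),
                                features, labels, split, cfg = train_config(),
                                graph = NULL, brands = NULL,
                                input_regime = c("ingredients_only",
                                                 "ingredients_plus_brand")) {
  kind <- match.arg(kind)
  input_regime <- match.arg(input_regime)
  stopifnot(inherits(features, "feature_matrix"), inherits(split, "split_spec"))
  labels <- as.integer(labels)
  idx_train <- match(split$train, features$row_index)
  idx_val <- match(split$val, features$row_index)
  stopifnot(!anyNA(idx_train), !anyNA(idx_val))
  if (length(unique(labels[idx_train])) < 2L) {
    stop_foodgraph("degenerate-labels",
                   "training labels contain a single class")
  }
  X <- features$matrix
  brand_levels <- NULL
  if (kind == "mlp" && input_regime == "ingredients_plus_brand") {
    stopifnot(!is.null(brands), length(brands) == nrow(X))
    brand_levels <- sort(unique(brands[idx_train]))
    X <- cbind(X, brand_onehot(brands, brand_levels))
  }

  fit <- switch(kind,
    decision_tree = {
      df <- feat_df(X[idx_train, , drop = FALSE])
      df$.y <- factor(labels[idx_train], levels = c(0L, 1L))
      withr::with_seed(cfg$seed, rpart::rpart(.y ~ ., data = df, method = "class"))
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X[idx_train, , drop = FALSE],
                                     label = labels[idx_train])
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = cfg$tree_max_depth, eta = 0.1,
                      nthread = 1L, seed = cfg$seed),
        data = dtrain, nrounds = cfg$boosting_stages, verbose = 0L)
    },
    mlp = withr::with_seed(cfg$seed, train_sage_node(
      X, A = NULL, y = labels, idx_train = idx_train, idx_val = idx_val,
      hidden = cfg$hidden_dim, lr = cfg$lr_node,
      weight_decay = cfg$weight_decay, dropout = cfg$dropout,
      max_epochs = cfg$max_epochs, patience = cfg$patience)),
    graphsage = {
      stopifnot(!is.null(graph), inherits(graph, "product_graph"))
      A <- edges_to_aggregation(graph$edges, nrow(X))
      withr::with_seed(cfg$seed, train_sage_node(
        X, A = A, y = labels, idx_train = idx_train, idx_val = idx_val,
        hidden = cfg$hidden_dim, lr = cfg$lr_node,
        weight_decay = cfg$weight_decay, dropout = cfg$dropout,
        max_epochs = cfg$max_epochs, patience = cfg$patience))
    }
  )
  structure(
    list(kind = kind, fit = fit, input_regime = input_regime,
         vocab = features$vocab, target = features$target,
         brand_levels = brand_levels, cfg = cfg,
         history = if (kind %in% c("mlp", "graphsage")) fit$history else NULL),
    class = "node_classifier"
  )
}

feat_df <- function(X) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))
  df
}

brand_onehot <- function(brands, levels) {
  j <- match(brands, levels)  # unseen brands -> zero vector
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = which(keep), j = j[keep], x = 1,
                       dims = c(length(brands), length(levels)))
}

#' Predict target-ingredient probabilities
#'
#' @param model a `node_classifier`.
#' @param features a `feature_matrix` with the same vocabulary (width) as at
#'   training time.
#' @param graph for `graphsage`, the `product_graph` over the rows of
#'   `features` (its connectivity is the only brand information used).
#' @param brands brand per row, for the brand-concat MLP regime; unseen brands
#'   map to the zero vector.
#' @return numeric vector of probabilities in `[0, 1]`, one per row; the class
#'   decision is `p > 0.5`.
#' @export
predict_proba <- function(model, features, graph = NULL, brands = NULL) {
  stopifnot(inherits(model, "node_classifier"),
            inherits(features, "feature_matrix"))
  if (!identical(features$vocab, model$vocab)) {
    stop("feature vocabulary does not match the training vocabulary")
  }
  X <- features$matrix
  if (!is.null(model$brand_levels)) {
    stopifnot(!is.null(brands), length(brands) == nrow(X))
    X <- cbind(X, brand_onehot(brands, model$brand_levels))
  }
  switch(model$kind,
    decision_tree = unname(stats::predict(model$fit, newdata = feat_df(X))[, "1"]),
    gradient_boosting = stats::predict(model$fit, xgboost::xgb.DMatrix(X)),
    mlp = sigmoid(sage_net_forward(model$fit$net, X, A = NULL)$Z2[, 1]),
    graphsage = {
      stopifnot(!is.null(graph), inherits(graph, "product_graph"))
      A <- edges_to_aggregation(graph$edges, nrow(X))
      sigmoid(sage_net_forward(model$fit$net, X, A = A)$Z2[, 1])
    }
  )
}

#' Split positive substitution edges into train / validation / test sets
#'
#' @param graph a `substitution_graph`.
#' @param fractions named numeric `train`, `val`, `test` (positive, sum 1).
#' @param seed integer seed.
#' @return list of 2-column edge index matrices `train`, `val`, `test`.
#' @export
split_edges <- function(graph, fractions = c(train = 0.7, val = 0.15, test = 0.15),
                        seed = 1L) {
  stopifnot(inherits(graph, "substitution_graph"),
            abs(sum(fractions) - 1) < 1e-9)
  m <- nrow(graph$pos_edges)
  if (m == 0L) stop_foodgraph("no-positives", "graph has no positive edges")
  withr::with_seed(seed, {
    perm <- sample.int(m)
    n_tr <- floor(fractions[["train"]] * m)
    n_va <- floor(fractions[["val"]] * m)
    list(train = graph$pos_edges[perm[seq_len(n_tr)], , drop = FALSE],
         val = graph$pos_edges[perm[n_tr + seq_len(n_va)], , drop = FALSE],
         test = graph$pos_edges[perm[(n_tr + n_va + 1):m], , drop = FALSE])
  })
}

#' Fit the GraphSAGE link predictor for product substitution
#'
#' Two SAGE layers (hidden and output width from `cfg`) encode every product
#' from its masked ingredient vector; message passing uses only the
#' symmetrized training positives. An inner-product decoder with a sigmoid
#' turns an ordered embedding pair into the probability that the directed
#' substitution link is valid. Each epoch draws a fresh balanced set of
#' negative edges; early stopping monitors validation AUC against a fixed
#' seeded negative set, and the best-validation parameters are retained.
#'
#' @param graph a `substitution_graph`.
#' @param features a `feature_matrix` over the same products (ingredients
#'   only: cost and category never enter the feature vector).
#' @param edge_split output of [split_edges()].
#' @param cfg a [train_config()].
#' @return object of class `link_predictor` with the trained encoder, node
#'   embeddings and training history.
#' @export
fit_link_predictor <- function(graph, features, edge_split = NULL,
                               cfg = train_config()) {
  stopifnot(inherits(graph, "substitution_graph"),
            inherits(features, "feature_matrix"))
  if (nrow(graph$pos_edges) == 0L) {
    stop_foodgraph("no-positives", "substitution graph has no positive edges")
  }
  if (is.null(edge_split)) edge_split <- split_edges(graph, seed = cfg$seed)
  neg_val <- sample_negative_edges(graph, nrow(edge_split$val),
                                   seed = cfg$seed + 1000L)
  fit <- withr::with_seed(cfg$seed, train_sage_link(
    features$matrix, graph, edge_split$train, edge_split$val, neg_val,
    hidden = cfg$hidden_dim, out = cfg$out_dim, lr = cfg$lr_link,
    weight_decay = cfg$weight_decay, dropout = cfg$dropout,
    max_epochs = cfg$max_epochs, patience = cfg$patience))
  structure(
    list(net = fit$net, embeddings = fit$embeddings, nodes = graph$nodes,
         history = fit$history, best_epoch = fit$best_epoch,
         target = graph$target, cfg = cfg, edge_split = edge_split),
    class = "link_predictor"
  )
}

#' Score a directed candidate substitution link
#'
#' Probability (sigmoid of the inner product of the two node embeddings) that
#' replacing `source_id` with `target_id` is a valid substitution. Directed:
#' `score_link(m, u, v)` need not equal `score_link(m, v, u)`.
#'
#' @param model a `link_predictor`.
#' @param source_id,target_id product ids (or node indices).
#' @return probability in (0, 1).
#' @export
score_link <- function(model, source_id, target_id) {
  stopifnot(inherits(model, "link_predictor"))
  to_idx <- function(id) {
    if (is.numeric(id)) {
      i <- as.integer(id)
      if (i < 1L || i > length(model$nodes)) stop("unknown node index: ", id)
      return(i)
    }
    i <- match(id, model$nodes)
    if (is.na(i)) stop("unknown product id: ", id)
    i
  }
  i <- to_idx(source_id)
  j <- to_idx(target_id)
  if (i == j) stop("self-substitution (u, u) is not a valid link")
  unname(sigmoid(sum(model$embeddings[i, ] * model$embeddings[j, ])))
}

#' Rank criteria-eligible replacements for a product
#'
#' Filters candidates to those passing the four substitution criteria for
#' `product_id`, then ranks them by [score_link()].
#'
#' @param model a `link_predictor` trained on `catalog`.
#' @param catalog the `food_catalog`.
#' @param product_id product to replace (must contain the target).
#' @param hmap a `hierarchy_map`.
#' @param criteria a [criteria_config()].
#' @return tibble with `candidate_id` and `score`, sorted by descending score.
#' @export
rank_substitutions <- function(model, catalog, product_id,
                               hmap = hierarchy_map(),
                               criteria = criteria_config()) {
  stopifnot(inherits(model, "link_predictor"), inherits(catalog, "food_catalog"))
  p <- catalog$products
  i <- match(product_id, p$product_id)
  if (is.na(i)) stop("unknown product id: ", product_id)
  src <- p[i, ]
  ok <- vapply(seq_len(nrow(p)), function(j) {
    j != i && check_substitution(src, p[j, ], model$target, hmap, criteria)
  }, logical(1))
  cand <- p$product_id[ok]
  scores <- vapply(cand, function(cid) score_link(model, product_id, cid),
                   numeric(1))
  tibble::tibble(candidate_id = cand, score = unname(scores))[
    order(scores, decreasing = TRUE), ]
}
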