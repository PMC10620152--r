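#' GraphSAGE mean-aggregator layer
#'
#' Computes, for every node `v`, `activation(W %*% c(h_v, mean(h_u : u ~ v)))`
#' (+ bias): the node's own features concatenated with the elementwise mean of
#' its neighbours' features, linearly transformed and passed through the
#' activation. A node with no neighbours contributes an all-zero aggregation
#' term. Output rows are in input order, so relabelling nodes permutes the
#' output rows identically (permutation equivariance).
#'
#' @param features numeric matrix (or sparse `Matrix`), nodes x features.
#' @param adjacency either a list of integer neighbour vectors (one per node)
#'   or a square (sparse) 0/1 adjacency matrix.
#' @param weights list with `W` (a `2F x d` matrix) and optional `b` (length
#'   `d` bias).
#' @param activation `"relu"`, `"linear"`.
#' @return dense numeric matrix, nodes x d.
#' @export
sage_layer <- function(features, adjacency, weights,
                       activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  X <- as.matrix(features)
  n <- nrow(X)
  A <- aggregation_matrix(adjacency, n)
  f <- ncol(X)
  W <- weights$W
  if (nrow(W) != 2L * f) stop("weight matrix must have 2*ncol(features) rows")
  agg <- if (is.null(A)) matrix(0, n, f) else as.matrix(A %*% X)
  Z <- X %*% W[seq_len(f), , drop = FALSE] +
    agg %*% W[f + seq_len(f), , drop = FALSE]
  if (!is.null(weights$b)) Z <- sweep(Z, 2L, weights$b, "+")
  if (activation == "relu") Z <- pmax(Z, 0) else Z
}

# row-normalized neighbour-mean operator; NULL means "no edges"
aggregation_matrix <- function(adjacency, n) {
  if (is.null(adjacency)) return(NULL)
  if (is.list(adjacency)) {
    if (length(adjacency) != n) stop("adjacency list length must equal node count")
    deg <- lengths(adjacency)
    if (sum(deg) == 0L) return(NULL)
    i <- rep(seq_len(n), deg)
    j <- unlist(adjacency)
    if (any(j < 1L | j > n)) stop("adjacency index out of range")
    return(Matrix::sparseMatrix(i = i, j = j, x = rep(1 / pmax(deg, 1L), deg),
                                dims = c(n, n)))
  }
  if (!all(dim(adjacency) == c(n, n))) stop("adjacency must be n x n")
  deg <- Matrix::rowSums(adjacency != 0)
  if (sum(deg) == 0) return(NULL)
  Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% adjacency
}

# symmetrized, deduplicated row-normalized aggregation from an edge index matrix
edges_to_aggregation <- function(edges, n) {
  if (is.null(edges) || nrow(edges) == 0L) return(NULL)
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  keep <- !duplicated((i - 1) * n + j) & i != j
  i <- i[keep]; j <- j[keep]
  deg <- tabulate(i, nbins = n)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -35), 35)))

# ---- two-layer SAGE network (the MLP is the same network with A = NULL) ----

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

sage_net_init <- function(n_feat, hidden, out) {
  list(W1 = glorot(2L * n_feat, hidden), b1 = numeric(hidden),
       W2 = glorot(2L * hidden, out), b2 = numeric(out))
}

sage_net_forward <- function(net, X, A, dropout = 0, train = FALSE) {
  n <- nrow(X)
  f <- ncol(X)
  h <- ncol(net$W1)
  N0 <- if (is.null(A)) matrix(0, n, f) else as.matrix(A %*% X)
  Z1 <- as.matrix(X %*% net$W1[seq_len(f), , drop = FALSE]) +
    N0 %*% net$W1[f + seq_len(f), , drop = FALSE]
  Z1 <- sweep(Z1, 2L, net$b1, "+")
  H1 <- pmax(Z1, 0)
  M <- NULL
  D1 <- H1
  if (train && dropout > 0) {
    M <- matrix(stats::rbinom(n * h, 1L, 1 - dropout), n, h) / (1 - dropout)
    D1 <- H1 * M
  }
  N1 <- if (is.null(A)) matrix(0, n, h) else as.matrix(A %*% D1)
  Z2 <- D1 %*% net$W2[seq_len(h), , drop = FALSE] +
    N1 %*% net$W2[h + seq_len(h), , drop = FALSE]
  Z2 <- sweep(Z2, 2L, net$b2, "+")
  list(Z2 = Z2, cache = list(X = X, N0 = N0, Z1 = Z1, M = M, D1 = D1, N1 = N1))
}

sage_net_backward <- function(net, cache, dZ2, A, weight_decay = 0) {
  f <- ncol(cache$X)
  h <- ncol(net$W1)
  W2s <- net$W2[seq_len(h), , drop = FALSE]
  W2n <- net$W2[h + seq_len(h), , drop = FALSE]
  dW2 <- rbind(crossprod(cache$D1, dZ2), crossprod(cache$N1, dZ2))
  db2 <- colSums(dZ2)
  dD1 <- dZ2 %*% t(W2s)
  if (!is.null(A)) dD1 <- dD1 + as.matrix(Matrix::crossprod(A, dZ2 %*% t(W2n)))
  if (!is.null(cache$M)) dD1 <- dD1 * cache$M
  dZ1 <- dD1 * (cache$Z1 > 0)
  dW1 <- rbind(as.matrix(Matrix::crossprod(cache$X, dZ1)),
               crossprod(cache$N0, dZ1))
  db1 <- colSums(dZ1)
  if (weight_decay > 0) {
    dW1 <- dW1 + weight_decay * net$W1
    dW2 <- dW2 + weight_decay * net$W2
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_init <- function(net) {
  list(m = lapply(net, function(p) p * 0), v = lapply(net, function(p) p * 0),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(net)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = state)
}

# full-batch training for the node task; masks select supervised rows
train_sage_node <- function(X, A, y, idx_train, idx_val, hidden = 128,
                            lr = 0.01, weight_decay = 5e-3, dropout = 0.5,
                            max_epochs = 400, patience = 50) {
  net <- sage_net_init(ncol(X), hidden, 1L)
  state <- adam_init(net)
  best <- list(metric = -Inf, net = net, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  n_tr <- length(idx_train)
  for (epoch in seq_len(max_epochs)) {
    fw <- sage_net_forward(net, X, A, dropout = dropout, train = TRUE)
    p <- sigmoid(fw$Z2[, 1])
    loss <- -mean(y[idx_train] * log(pmax(p[idx_train], 1e-12)) +
                    (1 - y[idx_train]) * log(pmax(1 - p[idx_train], 1e-12)))
    dZ2 <- matrix(0, nrow(X), 1L)
    dZ2[idx_train, 1] <- (p[idx_train] - y[idx_train]) / n_tr
    grads <- sage_net_backward(net, fw$cache, dZ2, A, weight_decay)
    upd <- adam_step(net, grads, state, lr)
    net <- upd$net; state <- upd$state

    ev <- sage_net_forward(net, X, A, train = FALSE)
    val_acc <- mean((sigmoid(ev$Z2[idx_val, 1]) > 0.5) == (y[idx_val] == 1))
    history <- rbind(history, data.frame(epoch = epoch, train_loss = loss,
                                         val_accuracy = val_acc))
    if (val_acc > best$metric + 1e-12) {
      best <- list(metric = val_acc, net = net, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  list(net = best$net, history = history, best_epoch = best$epoch,
       best_val = best$metric)
}

# link-prediction training: SAGE encoder over training positives, inner-product
# decoder, fresh balanced negatives every epoch
train_sage_link <- function(X, graph, edges_train, edges_val, neg_val,
                            hidden = 128, out = 128, lr = 0.001,
                            weight_decay = 5e-3, dropout = 0.5,
                            max_epochs = 400, patience = 50) {
  n <- nrow(X)
  A <- edges_to_aggregation(edges_train, n)
  net <- sage_net_init(ncol(X), hidden, out)
  state <- adam_init(net)
  best <- list(metric = -Inf, net = net, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  m_pos <- nrow(edges_train)
  for (epoch in seq_len(max_epochs)) {
    neg <- sample_negative_edges(graph, m_pos)
    pairs <- rbind(edges_train, neg)
    yy <- c(rep(1, m_pos), rep(0, m_pos))
    fw <- sage_net_forward(net, X, A, dropout = dropout, train = TRUE)
    H <- fw$Z2
    s <- rowSums(H[pairs[, 1], , drop = FALSE] * H[pairs[, 2], , drop = FALSE])
    p <- sigmoid(s)
    loss <- -mean(yy * log(pmax(p, 1e-12)) + (1 - yy) * log(pmax(1 - p, 1e-12)))
    dscore <- (p - yy) / length(yy)
    dH <- matrix(0, n, ncol(H))
    add_s <- rowsum(dscore * H[pairs[, 2], , drop = FALSE], group = pairs[, 1])
    add_t <- rowsum(dscore * H[pairs[, 1], , drop = FALSE], group = pairs[, 2])
    dH[as.integer(rownames(add_s)), ] <- dH[as.integer(rownames(add_s)), ] + add_s
    dH[as.integer(rownames(add_t)), ] <- dH[as.integer(rownames(add_t)), ] + add_t
    grads <- sage_net_backward(net, fw$cache, dH, A, weight_decay)
    upd <- adam_step(net, grads, state, lr)
    net <- upd$net; state <- upd$state

    ev <- sage_net_forward(net, X, A, train = FALSE)
    Hv <- ev$Z2
    vp <- rbind(edges_val, neg_val)
    vy <- c(rep(1, nrow(edges_val)), rep(0, nrow(neg_val)))
    vs <- rowSums(Hv[vp[, 1], , drop = FALSE] * Hv[vp[, 2], , drop = FALSE])
    val_auc <- auc(vs, vy)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = loss,
                                         val_auc = val_auc))
    if (val_auc > best$metric + 1e-12) {
      best <- list(metric = val_auc, net = net, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  emb <- sage_net_forward(best$net, X, A, train = FALSE)$Z2
  list(net = best$net, embeddings = emb, aggregation = A, history = history,
       best_epoch = best$epoch, best_val = best$metric)
}
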