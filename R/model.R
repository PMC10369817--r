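# Message-passing GNN regressor with an absolute-activity head and a
# dedicated uncommon-node readout head, trained by pair-batched gradient
# descent (Adam). Forward and reverse passes are written directly in
# matrix form over a stacked (block-diagonal) graph: molecules never
# exchange messages, so a whole batch is one sparse graph. The analytic
# gradients also power the gradient-based attribution methods.
#
# Architecture
#   H0      = tanh(X W0 + b0)
#   H_t     = tanh(H_{t-1} Ws_t + (S H_{t-1}) Wn_t + (R Ef) We_t + b_t)
#   pooled  = mean over nodes of each graph (matrix P)
#   yhat    = w2' tanh(W1' pooled + b1) + b2          (head_hidden > 0)
#           = w' pooled + b                           (head_hidden == 0)
#   u       = xi(mean over masked nodes of H_T), xi a linear two-layer
#             perceptron (identity activations)
# where S sums transformed neighbor states and R routes edge features to
# their target node.

#' GNN configuration
#'
#' @param hidden_dim node embedding width d (default 64).
#' @param n_message_passes number of message-passing rounds (default 3).
#' @param head_hidden hidden width of the prediction head; 0 gives a purely
#'   linear head (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs training epochs (default 200).
#' @param batch_pairs pairs per mini-batch (default 32).
#' @param seed RNG seed for initialization and shuffling.
#' @param loss_mode `"MSE"`, `"MSE+AC"`, or `"MSE+UCN"`.
#' @param lambda auxiliary-loss weight (default 1).
#' @param activation node-update nonlinearity: `"tanh"` (default) or
#'   `"identity"` (a fully linear network, mainly a diagnostic for the
#'   closed-form attribution identities).
#' @return a `GNNConfig` list.
#' @export
gnn_config <- function(hidden_dim = 64L, n_message_passes = 3L,
                       head_hidden = 64L, learning_rate = 1e-3,
                       epochs = 200L, batch_pairs = 32L, seed = 1L,
                       loss_mode = c("MSE", "MSE+AC", "MSE+UCN"),
                       lambda = 1.0, activation = c("tanh", "identity")) {
  loss_mode <- match.arg(loss_mode)
  activation <- match.arg(activation)
  stopifnot(hidden_dim > 0, n_message_passes > 0, head_hidden >= 0,
            learning_rate > 0, epochs > 0, batch_pairs > 0, lambda >= 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_message_passes = as.integer(n_message_passes),
                 head_hidden = as.integer(head_hidden),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_pairs = as.integer(batch_pairs),
                 seed = as.integer(seed),
                 loss_mode = loss_mode,
                 lambda = lambda,
                 activation = activation),
            class = "GNNConfig")
}

# ---------------------------------------------------------------------------
# Stacked graphs

#' Stack molecular graphs into one block-diagonal sparse graph
#'
#' @param graphs list of `MolecularGraph` objects (see [featurize()]).
#' @return a `GraphStack`: node feature matrix `X`, neighbor-sum operator
#'   `S`, edge-routing operator applied to edge features `REf`, mean-pooling
#'   operator `P`, per-graph node index list `nodes`, and sizes.
#' @export
build_graph_stack <- function(graphs) {
  stopifnot(length(graphs) > 0L)
  ns <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offs <- c(0L, cumsum(ns))
  ntot <- sum(ns)
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  src <- integer(0); dst <- integer(0)
  Ef <- NULL
  for (k in seq_along(graphs)) {
    ei <- graphs[[k]]$edge_index
    if (nrow(ei) > 0L) {
      src <- c(src, ei[, 1] + offs[k])
      dst <- c(dst, ei[, 2] + offs[k])
    }
    Ef <- rbind(Ef, graphs[[k]]$edge_features)
  }
  ne <- length(src)
  S <- Matrix::sparseMatrix(i = dst, j = src, x = 1, dims = c(ntot, ntot))
  REf <- if (ne > 0L) {
    R <- Matrix::sparseMatrix(i = dst, j = seq_len(ne), x = 1,
                              dims = c(ntot, ne))
    as.matrix(R %*% Ef)
  } else {
    matrix(0, ntot, n_edge_features())
  }
  P <- Matrix::sparseMatrix(i = rep(seq_along(graphs), ns),
                            j = seq_len(ntot),
                            x = rep(1 / ns, ns),
                            dims = c(length(graphs), ntot))
  nodes <- lapply(seq_along(graphs), function(k) {
    seq(offs[k] + 1L, offs[k + 1L])
  })
  structure(list(X = X, S = S, REf = REf, P = P, nodes = nodes,
                 n_nodes = ntot, n_graphs = length(graphs), ns = ns),
            class = "GraphStack")
}

# ---------------------------------------------------------------------------
# Parameters

.init_params <- function(config, n_node = n_node_features(),
                         n_edge = n_edge_features()) {
  d <- config$hidden_dim
  hh <- config$head_hidden
  g <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  }
  p <- list(W0 = g(n_node, d), b0 = numeric(d))
  for (t in seq_len(config$n_message_passes)) {
    p[[paste0("Ws", t)]] <- g(d, d)
    p[[paste0("Wn", t)]] <- g(d, d)
    p[[paste0("We", t)]] <- g(n_edge, d)
    p[[paste0("bm", t)]] <- numeric(d)
  }
  if (hh > 0L) {
    p$W1 <- g(d, hh); p$b1 <- numeric(hh)
    p$w2 <- g(hh, 1L); p$b2 <- 0
    p$Wu1 <- g(d, hh); p$bu1 <- numeric(hh)
    p$wu2 <- g(hh, 1L); p$bu2 <- 0
  } else {
    p$w2 <- g(d, 1L); p$b2 <- 0
    p$wu2 <- g(d, 1L); p$bu2 <- 0
  }
  p
}

# Forward pass over a stacked graph, caching intermediates for backprop.
# `X` may override the stack's node features (used by IG / node masking).
.forward_cache <- function(params, config, sg, X = sg$X) {
  T <- config$n_message_passes
  act <- if (identical(config$activation, "identity")) identity else tanh
  Hs <- vector("list", T + 1L)
  Hs[[1]] <- act(sweep(X %*% params$W0, 2, params$b0, "+"))
  for (t in seq_len(T)) {
    Z <- Hs[[t]] %*% params[[paste0("Ws", t)]] +
      as.matrix(sg$S %*% Hs[[t]]) %*% params[[paste0("Wn", t)]] +
      sg$REf %*% params[[paste0("We", t)]]
    Z <- sweep(Z, 2, params[[paste0("bm", t)]], "+")
    Hs[[t + 1L]] <- act(Z)
  }
  HT <- Hs[[T + 1L]]
  pooled <- as.matrix(sg$P %*% HT)
  if (config$head_hidden > 0L) {
    Z1 <- tanh(sweep(pooled %*% params$W1, 2, params$b1, "+"))
    yhat <- drop(Z1 %*% params$w2) + params$b2
  } else {
    Z1 <- NULL
    yhat <- drop(pooled %*% params$w2) + params$b2
  }
  list(X = X, Hs = Hs, HT = HT, pooled = pooled, Z1 = Z1, yhat = yhat)
}

# UCN readout head applied to pre-pooled embedding rows `m` (K x d).
.ucn_head <- function(params, config, m) {
  if (config$head_hidden > 0L) {
    drop(sweep(m %*% params$Wu1, 2, params$bu1, "+") %*% params$wu2) +
      params$bu2
  } else {
    drop(m %*% params$wu2) + params$bu2
  }
}

# Reverse pass. dyhat: gradient of the loss in each graph's prediction
# (length G). du/Umask: optional UCN-readout gradients with their masking
# operator (K x n_nodes rows averaging each uncommon set). Returns
# parameter gradients plus dX (gradient in the node features).
.backward <- function(params, config, sg, cache, dyhat,
                      du = NULL, Umask = NULL) {
  T <- config$n_message_passes
  gr <- list()
  dHT <- matrix(0, sg$n_nodes, config$hidden_dim)
  if (config$head_hidden > 0L) {
    dZ1 <- outer(dyhat, drop(params$w2))
    gr$w2 <- t(cache$Z1) %*% dyhat
    gr$b2 <- sum(dyhat)
    dA1 <- dZ1 * (1 - cache$Z1^2)
    gr$W1 <- t(cache$pooled) %*% dA1
    gr$b1 <- colSums(dA1)
    dpool <- dA1 %*% t(params$W1)
  } else {
    gr$w2 <- t(cache$pooled) %*% dyhat
    gr$b2 <- sum(dyhat)
    dpool <- outer(dyhat, drop(params$w2))
  }
  dHT <- dHT + as.matrix(Matrix::crossprod(sg$P, dpool))

  if (!is.null(du) && length(du) > 0L) {
    m <- as.matrix(Umask %*% cache$HT)
    if (config$head_hidden > 0L) {
      dA <- outer(du, drop(params$wu2))
      gr$wu2 <- t(sweep(m %*% params$Wu1, 2, params$bu1, "+")) %*% du
      gr$bu2 <- sum(du)
      gr$Wu1 <- t(m) %*% dA
      gr$bu1 <- colSums(dA)
      dm <- dA %*% t(params$Wu1)
    } else {
      gr$wu2 <- t(m) %*% du
      gr$bu2 <- sum(du)
      dm <- outer(du, drop(params$wu2))
    }
    dHT <- dHT + as.matrix(Matrix::crossprod(Umask, dm))
  }

  linear <- identical(config$activation, "identity")
  dH <- dHT
  for (t in rev(seq_len(T))) {
    Hcur <- cache$Hs[[t + 1L]]
    Hprev <- cache$Hs[[t]]
    dZ <- if (linear) dH else dH * (1 - Hcur^2)
    gr[[paste0("Ws", t)]] <- t(Hprev) %*% dZ
    gr[[paste0("Wn", t)]] <- t(as.matrix(sg$S %*% Hprev)) %*% dZ
    gr[[paste0("We", t)]] <- t(sg$REf) %*% dZ
    gr[[paste0("bm", t)]] <- colSums(dZ)
    dH <- dZ %*% t(params[[paste0("Ws", t)]]) +
      as.matrix(Matrix::crossprod(sg$S, dZ %*% t(params[[paste0("Wn", t)]])))
  }
  dZ0 <- if (linear) dH else dH * (1 - cache$Hs[[1]]^2)
  gr$W0 <- t(cache$X) %*% dZ0
  gr$b0 <- colSums(dZ0)
  dX <- dZ0 %*% t(params$W0)
  list(grads = gr, dX = dX)
}

# ---------------------------------------------------------------------------
# Batch loss + gradient (the objective actually minimized)

# batch: list with graph index vectors gi, gj, labels y_i, y_j and (for UCN)
# Umask (2K x n_nodes sparse, row k = mask of pair k side i, row K+k side j)
# plus `ucn_ok` flagging pairs with both uncommon sets non-empty.
.loss_and_grad <- function(params, config, sg, batch) {
  K <- length(batch$gi)
  cache <- .forward_cache(params, config, sg)
  yhat_i <- cache$yhat[batch$gi]
  yhat_j <- cache$yhat[batch$gj]
  base <- (batch$y_i - yhat_i)^2 + (batch$y_j - yhat_j)^2
  dyhat <- numeric(sg$n_graphs)
  add <- function(v, idx, val) {
    for (k in seq_along(idx)) v[idx[k]] <- v[idx[k]] + val[k]
    v
  }
  dyhat <- add(dyhat, batch$gi, -2 * (batch$y_i - yhat_i) / K)
  dyhat <- add(dyhat, batch$gj, -2 * (batch$y_j - yhat_j) / K)

  aux <- numeric(K)
  du <- NULL
  u_i <- NULL; u_j <- NULL
  if (config$loss_mode == "MSE+AC") {
    resid <- (batch$y_i - batch$y_j) - (yhat_i - yhat_j)
    aux <- resid^2
    dyhat <- add(dyhat, batch$gi, -2 * resid * config$lambda / K)
    dyhat <- add(dyhat, batch$gj, 2 * resid * config$lambda / K)
  } else if (config$loss_mode == "MSE+UCN") {
    m <- as.matrix(batch$Umask %*% cache$HT)
    u <- .ucn_head(params, config, m)
    u_i <- u[seq_len(K)]
    u_j <- u[K + seq_len(K)]
    resid <- ((u_i - u_j) - (batch$y_i - batch$y_j)) * batch$ucn_ok
    aux <- resid^2
    du <- c(2 * resid, -2 * resid) * config$lambda / K
  }
  loss <- mean(base + config$lambda * aux)
  bk <- .backward(params, config, sg, cache, dyhat,
                  du = du, Umask = batch$Umask)
  list(loss = loss, grads = bk$grads, yhat = cache$yhat,
       u_i = u_i, u_j = u_j)
}

# ---------------------------------------------------------------------------
# Training

#' Train a GNN on the pairs of a benchmark split
#'
#' All three loss modes are trained over the same pair batches, so the data
#' exposure is identical and runs differ only in the objective. Training is
#' deterministic given `config$seed` (initialization and shuffling are keyed
#' to it; no early stopping).
#'
#' @param split a `BenchmarkSplit` (only `train_pairs` is used), or a
#'   `compound_pairs` list.
#' @param config a [gnn_config()].
#' @return a `TrainedGNN`: list with `params`, `config`, `training_log`
#'   (mean batch loss per epoch), `schema` (feature dimensions), and the
#'   compound ids seen in training.
#' @export
train_gnn <- function(split, config = gnn_config()) {
  pairs <- if (inherits(split, "BenchmarkSplit")) split$train_pairs else split
  if (length(pairs) == 0L) stop("empty training set")
  stopifnot(inherits(config, "GNNConfig"))

  ids <- unique(unlist(lapply(pairs, function(p) c(p$id_i, p$id_j))))
  mol_of <- list()
  for (p in pairs) {
    mol_of[[p$id_i]] <- p$mol_i
    mol_of[[p$id_j]] <- p$mol_j
  }
  graphs <- lapply(ids, function(id) featurize(mol_of[[id]]))
  sg <- build_graph_stack(graphs)

  K <- length(pairs)
  gi <- match(vapply(pairs, `[[`, character(1), "id_i"), ids)
  gj <- match(vapply(pairs, `[[`, character(1), "id_j"), ids)
  y_i <- vapply(pairs, `[[`, numeric(1), "activity_i")
  y_j <- vapply(pairs, `[[`, numeric(1), "activity_j")
  ucn_ok <- vapply(pairs, function(p) {
    length(p$uncommon_i) > 0L && length(p$uncommon_j) > 0L
  }, logical(1))
  # masking operator: row k averages pair k's uncommon atoms of side i,
  # row K+k those of side j; empty sets get a dummy self-row (zero weight
  # via ucn_ok)
  mask_row <- function(p, side, k) {
    unc <- if (side == "i") p$uncommon_i else p$uncommon_j
    g <- if (side == "i") gi[k] else gj[k]
    if (length(unc) == 0L) unc <- 1L
    cbind(sg$nodes[[g]][unc], 1 / length(unc))
  }
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (k in seq_len(K)) {
    ri <- mask_row(pairs[[k]], "i", k)
    rj <- mask_row(pairs[[k]], "j", k)
    trip_i <- c(trip_i, rep(k, nrow(ri)), rep(K + k, nrow(rj)))
    trip_j <- c(trip_j, ri[, 1], rj[, 1])
    trip_x <- c(trip_x, ri[, 2], rj[, 2])
  }
  Umask_all <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                    dims = c(2L * K, sg$n_nodes))

  model <- local_seed(config$seed, {
    params <- .init_params(config)
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    log <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(K)
      nb <- ceiling(K / config$batch_pairs)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        sel <- ord[seq((bi - 1L) * config$batch_pairs + 1L,
                       min(bi * config$batch_pairs, K))]
        batch <- list(gi = gi[sel], gj = gj[sel],
                      y_i = y_i[sel], y_j = y_j[sel],
                      ucn_ok = as.numeric(ucn_ok[sel]),
                      Umask = Umask_all[c(sel, K + sel), , drop = FALSE])
        lg <- .loss_and_grad(params, config, sg, batch)
        if (!is.finite(lg$loss)) {
          stop("non-finite loss at epoch ", epoch,
               " (learning rate too high?)")
        }
        ep_loss <- ep_loss + lg$loss * length(sel)
        step <- step + 1L
        for (nm in names(lg$grads)) {
          g <- lg$grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          mhat <- adam_m[[nm]] / (1 - b1^step)
          vhat <- adam_v[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      log[epoch] <- ep_loss / K
    }
    list(params = params, training_log = log)
  })

  structure(list(params = model$params, config = config,
                 training_log = model$training_log,
                 schema = list(n_node_features = n_node_features(),
                               n_edge_features = n_edge_features(),
                               version = 1L),
                 train_compounds = ids),
            class = "TrainedGNN")
}

#' @export
print.TrainedGNN <- function(x, ...) {
  cat("TrainedGNN:", x$config$loss_mode,
      sprintf("(d=%d, %d passes, %d epochs)\n", x$config$hidden_dim,
              x$config$n_message_passes, x$config$epochs))
  cat("  final training loss:",
      signif(utils::tail(x$training_log, 1), 4), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Inference

#' Forward pass on a single molecular graph
#'
#' @param model a `TrainedGNN`.
#' @param graph a `MolecularGraph`.
#' @return a `ForwardResult`: `node_embeddings` (N x d) and `prediction`.
#' @export
gnn_forward <- function(model, graph) {
  stopifnot(inherits(model, "TrainedGNN"), inherits(graph, "MolecularGraph"))
  if (ncol(graph$node_features) != model$schema$n_node_features) {
    stop("feature dimension mismatch: graph has ",
         ncol(graph$node_features), " node features, model expects ",
         model$schema$n_node_features)
  }
  sg <- build_graph_stack(list(graph))
  cache <- .forward_cache(model$params, model$config, sg)
  structure(list(node_embeddings = cache$HT,
                 prediction = unname(cache$yhat[1])),
            class = "ForwardResult")
}

#' Predict pIC50 for molecules
#'
#' Pure single-compound inference: no pair or mask information is used, so
#' prediction works on compounds outside any training series.
#'
#' @param model a `TrainedGNN`.
#' @param molecules a `Molecule`, a `MolecularGraph`, or a list of either.
#' @return numeric vector of predictions.
#' @export
gnn_predict <- function(model, molecules) {
  if (inherits(molecules, "Molecule") ||
      inherits(molecules, "MolecularGraph")) {
    molecules <- list(molecules)
  }
  graphs <- lapply(molecules, function(m) {
    if (inherits(m, "Molecule")) featurize(m) else m
  })
  sg <- build_graph_stack(graphs)
  cache <- .forward_cache(model$params, model$config, sg)
  unname(cache$yhat)
}

#' Uncommon-node readout
#'
#' Mean of the selected node-embedding rows passed through the dedicated
#' UCN head (a linear multilayer perceptron, separate from the prediction
#' head).
#'
#' @param model a `TrainedGNN`.
#' @param h node-embedding matrix (N x d), e.g. from [gnn_forward()].
#' @param uncommon non-empty vector of 1-based atom indices.
#' @return scalar readout.
#' @export
ucn_readout <- function(model, h, uncommon) {
  stopifnot(inherits(model, "TrainedGNN"))
  if (length(uncommon) == 0L) stop("empty uncommon-atom set")
  if (any(uncommon < 1L | uncommon > nrow(h))) stop("atom index out of range")
  m <- matrix(colMeans(h[uncommon, , drop = FALSE]), nrow = 1L)
  unname(.ucn_head(model$params, model$config, m))
}

# ---------------------------------------------------------------------------
# Checkpointing

#' Save / load a trained GNN
#'
#' The checkpoint stores parameters, configuration and the feature-schema
#' fingerprint; loading fails loudly if the schema does not match the
#' installed featurizer.
#'
#' @param model a `TrainedGNN`.
#' @param path file path.
#' @return `save_gnn` returns `path` invisibly; `load_gnn` the model.
#' @export
save_gnn <- function(model, path) {
  stopifnot(inherits(model, "TrainedGNN"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gnn
#' @export
load_gnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "TrainedGNN")) stop("not a TrainedGNN checkpoint")
  if (model$schema$n_node_features != n_node_features() ||
      model$schema$n_edge_features != n_edge_features()) {
    stop("checkpoint schema mismatch: featurizer dimensions changed")
  }
  model
}
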