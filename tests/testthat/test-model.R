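test_that("forward pass satisfies shape and symmetry contracts", {
  model <- random_model(1)
  single <- featurize(parse_molecule("C"))
  fr <- gnn_forward(model, single)
  expect_equal(nrow(fr$node_embeddings), 1L)
  expect_true(is.finite(fr$prediction))

  benz <- featurize(parse_molecule("c1ccccc1"))
  frb <- gnn_forward(model, benz)
  expect_equal(nrow(unique(round(frb$node_embeddings, 10))), 1L)
})

test_that("prediction is permutation-invariant, embeddings equivariant", {
  set.seed(4)
  for (s in sample(SMILES_POOL, 50, replace = TRUE)) {
    model <- random_model(7)
    g <- featurize(parse_molecule(s))
    n <- nrow(g$node_features)
    perm <- sample(n)
    gp <- permute_graph(g, perm)
    f1 <- gnn_forward(model, g)
    f2 <- gnn_forward(model, gp)
    expect_equal(f2$prediction, f1$prediction, tolerance = 1e-12)
    expect_equal(f2$node_embeddings, f1$node_embeddings[perm, , drop = FALSE],
                 tolerance = 1e-12)
  }
})

test_that("ucn_readout averages masked rows through the dedicated head", {
  model <- random_model(2)
  benz <- featurize(parse_molecule("c1ccccc1"))
  fr <- gnn_forward(model, benz)
  u_all <- ucn_readout(model, fr$node_embeddings, 1:6)
  u_one <- ucn_readout(model, fr$node_embeddings, 3L)
  expect_equal(u_all, u_one, tolerance = 1e-12)  # identical rows in benzene
  expect_error(ucn_readout(model, fr$node_embeddings, integer(0)), "empty")
  expect_error(ucn_readout(model, fr$node_embeddings, 99L), "range")
  # zero-weight head reads out exactly zero
  m0 <- model
  m0$params$Wu1[] <- 0; m0$params$bu1[] <- 0
  m0$params$wu2[] <- 0; m0$params$bu2 <- 0
  expect_equal(ucn_readout(m0, fr$node_embeddings, 1:3), 0)
  # permutation consistency of masked readout
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  frp <- gnn_forward(model, permute_graph(benz, perm))
  expect_equal(ucn_readout(model, frp$node_embeddings, match(1:2, perm)),
               ucn_readout(model, fr$node_embeddings, 1:2),
               tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  pr <- tiny_pairs()[1:2]
  ids <- unique(unlist(lapply(pr, function(p) c(p$id_i, p$id_j))))
  mol_of <- list()
  for (p in pr) { mol_of[[p$id_i]] <- p$mol_i; mol_of[[p$id_j]] <- p$mol_j }
  sg <- build_graph_stack(lapply(ids, function(id) featurize(mol_of[[id]])))
  gi <- match(vapply(pr, `[[`, character(1), "id_i"), ids)
  gj <- match(vapply(pr, `[[`, character(1), "id_j"), ids)
  K <- 2L
  trip <- NULL
  for (k in seq_len(K)) {
    p <- pr[[k]]
    trip <- rbind(
      trip,
      cbind(k, sg$nodes[[gi[k]]][p$uncommon_i], 1 / length(p$uncommon_i)),
      cbind(K + k, sg$nodes[[gj[k]]][p$uncommon_j],
            1 / length(p$uncommon_j)))
  }
  batch <- list(gi = gi, gj = gj,
                y_i = vapply(pr, `[[`, numeric(1), "activity_i"),
                y_j = vapply(pr, `[[`, numeric(1), "activity_j"),
                ucn_ok = c(1, 1),
                Umask = Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2],
                                             x = trip[, 3],
                                             dims = c(2L * K, sg$n_nodes)))
  for (mode in c("MSE", "MSE+AC", "MSE+UCN")) {
    cfg <- gnn_config(hidden_dim = 8L, n_message_passes = 2L,
                      head_hidden = 6L, seed = 5L, loss_mode = mode)
    params <- local({ set.seed(5); ucnbench:::.init_params(cfg) })
    lg <- ucnbench:::.loss_and_grad(params, cfg, sg, batch)
    set.seed(101)
    for (nm in names(lg$grads)) {
      idxs <- seq_along(params[[nm]])
      if (length(idxs) > 5) idxs <- sample(idxs, 5)
      for (ii in idxs) {
        h <- 1e-5
        pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + h
        lp <- ucnbench:::.loss_and_grad(pp, cfg, sg, batch)$loss
        pp[[nm]][ii] <- pp[[nm]][ii] - 2 * h
        lm <- ucnbench:::.loss_and_grad(pp, cfg, sg, batch)$loss
        num <- (lp - lm) / (2 * h)
        ana <- lg$grads[[nm]][ii]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and fits noiseless data", {
  model <- trained_mse()
  log <- model$training_log
  expect_lt(log[length(log)], 0.5 * log[1])
  split <- train_split()
  ids <- unique(unlist(lapply(split$train_pairs,
                              function(p) c(p$id_i, p$id_j))))
  mol_of <- list(); y <- numeric(0)
  for (p in split$train_pairs) {
    mol_of[[p$id_i]] <- p$mol_i; mol_of[[p$id_j]] <- p$mol_j
    y[p$id_i] <- p$activity_i; y[p$id_j] <- p$activity_j
  }
  yhat <- gnn_predict(model, mol_of[ids])
  expect_lt(rmse(y[ids], yhat), 0.2 * sd(y[ids]))
})

test_that("training is deterministic and lambda 0 reduces to plain MSE", {
  cfg <- trained_cfg("MSE", epochs = 15L)
  m1 <- train_gnn(tiny_split(), cfg)
  m2 <- train_gnn(tiny_split(), cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$training_log, m2$training_log)

  for (mode in c("MSE+UCN", "MSE+AC")) {
    cfg0 <- trained_cfg(mode, epochs = 15L)
    cfg0$lambda <- 0
    m0 <- train_gnn(tiny_split(), cfg0)
    expect_equal(m0$training_log, m1$training_log, tolerance = 1e-12)
    expect_equal(m0$params$W0, m1$params$W0, tolerance = 1e-12)
    expect_equal(m0$params$w2, m1$params$w2, tolerance = 1e-12)
  }
  expect_error(train_gnn(structure(list(), class = "compound_pairs"),
                         cfg), "empty training set")
})

test_that("predict matches forward, works on unseen molecules, is order-invariant", {
  model <- trained_mse()
  new_mol <- parse_molecule("Oc1ccc(cc1)C(=O)N(C)C")  # not in the series
  expect_false(new_mol$smiles %in%
                 vapply(train_series()$records$molecule, `[[`,
                        character(1), "smiles"))
  g <- featurize(new_mol)
  expect_equal(gnn_predict(model, new_mol),
               gnn_forward(model, g)$prediction)
  mols <- train_series()$records$molecule[1:5]
  p1 <- gnn_predict(model, mols)
  p2 <- gnn_predict(model, rev(mols))
  expect_equal(p1, rev(p2), tolerance = 1e-12)
})

test_that("checkpoints round-trip and fail loudly on schema mismatch", {
  model <- trained_mse()
  f <- tempfile(fileext = ".rds")
  save_gnn(model, f)
  back <- load_gnn(f)
  expect_identical(back$params, model$params)
  broken <- model
  broken$schema$n_node_features <- 99L
  save_gnn(broken, f)
  expect_error(load_gnn(f), "schema mismatch")
})

test_that("dimension mismatches are rejected", {
  model <- trained_mse()
  g <- featurize(parse_molecule("CCO"))
  g$node_features <- cbind(g$node_features, 0)
  expect_error(gnn_forward(model, g), "dimension mismatch")
})
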