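test_that("gradinput matches finite differences on random graphs", {
  model <- random_model(3)
  for (k in 1:5) {
    g <- random_graph(10L, seed = 100 + k)
    a <- attr_gradinput(model, g)
    expect_length(a$atom_scores, 10L)
    # finite-difference directional check per atom: mean_f(dy/dx * x)
    sg <- build_graph_stack(list(g))
    f <- function(X) ucnbench:::.forward_cache(model$params, model$config,
                                               sg, X = X)$yhat[1]
    h <- 1e-5
    for (v in c(1L, 4L, 9L)) {
      num <- vapply(seq_len(ncol(sg$X)), function(j) {
        Xp <- sg$X; Xp[v, j] <- Xp[v, j] + h
        Xm <- sg$X; Xm[v, j] <- Xm[v, j] - h
        (f(Xp) - f(Xm)) / (2 * h)
      }, numeric(1))
      expect_equal(a$atom_scores[v], mean(num * sg$X[v, ]),
                   tolerance = 1e-4)
    }
  }
})

test_that("constant model attributes zero everywhere", {
  model <- random_model(5)
  model$params$w2[] <- 0           # prediction head ignores embeddings
  g <- random_graph(8L, seed = 1)
  expect_equal(attr_gradinput(model, g)$atom_scores, rep(0, 8))
  expect_equal(attr_gradcam(model, g)$atom_scores, rep(0, 8))
})

test_that("IG equals GradInput for a linear model and converges with steps", {
  lin <- random_model(11, activation = "identity", head_hidden = 0L)
  g <- random_graph(9L, seed = 2)
  gi <- attr_gradinput(lin, g)
  ig <- attr_integrated_gradients(lin, g, steps = 16L)
  expect_equal(ig$atom_scores, gi$atom_scores, tolerance = 1e-6)
  comp <- attr(ig, "completeness")
  expect_equal(comp["sum_terms"], comp["delta_yhat"],
               tolerance = 1e-10, ignore_attr = TRUE)

  # nonlinear model: completeness residual shrinks as steps double
  model <- random_model(12)
  g2 <- random_graph(12L, seed = 3)
  res <- vapply(c(8L, 16L, 32L, 64L), function(s) {
    comp <- attr(attr_integrated_gradients(model, g2, steps = s),
                 "completeness")
    abs(comp["sum_terms"] - comp["delta_yhat"])
  }, numeric(1))
  expect_lt(res[4], res[1] + 1e-12)
})

test_that("IG completeness holds to 1e-3 relative on 50 random graphs", {
  model <- random_model(21)
  worst <- 0
  for (k in 1:50) {
    g <- random_graph(sample(4:14, 1), seed = 500 + k)
    comp <- attr(attr_integrated_gradients(model, g, steps = 128L),
                 "completeness")
    rel <- abs(comp["sum_terms"] - comp["delta_yhat"]) /
      max(1e-8, abs(comp["delta_yhat"]))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-3)
})

test_that("CAM satisfies the linear-head mean-score identity", {
  lin <- random_model(31, head_hidden = 0L)   # tanh embeddings, linear head
  for (s in c("Cc1ccccc1", "CC(=O)Nc1ccccc1", "CCOCC")) {
    g <- featurize(parse_molecule(s))
    a <- attr_cam(lin, g)
    fr <- gnn_forward(lin, g)
    expect_equal(mean(a$atom_scores), fr$prediction - lin$params$b2,
                 tolerance = 1e-10)
  }
  benz <- featurize(parse_molecule("c1ccccc1"))
  expect_equal(var(attr_cam(lin, benz)$atom_scores), 0, tolerance = 1e-20)
  # direct matrix-product oracle
  g <- random_graph(7L, seed = 9)
  fr <- gnn_forward(lin, g)
  expect_equal(attr_cam(lin, g)$atom_scores,
               drop(fr$node_embeddings %*% lin$params$w2),
               tolerance = 1e-12)
})

test_that("GradCAM is proportional to CAM for a linear head", {
  lin <- random_model(32, head_hidden = 0L)
  g <- random_graph(9L, seed = 4)
  cam <- attr_cam(lin, g)$atom_scores
  gc <- attr_gradcam(lin, g)$atom_scores
  expect_equal(gc, cam / 9, tolerance = 1e-10)   # alpha = w / N
  expect_equal(suppressWarnings(cor(cam, gc)), 1, tolerance = 1e-10)
})

test_that("GradCAM matches a forward-caching numeric-gradient oracle", {
  model <- random_model(33)
  g <- random_graph(8L, seed = 5)
  sg <- build_graph_stack(list(g))
  cache <- ucnbench:::.forward_cache(model$params, model$config, sg)
  # numeric dyhat/dH on the final embeddings, then the Grad-CAM formula
  p <- model$params
  f_head <- function(HT) {
    pooled <- colMeans(HT)
    z1 <- tanh(drop(pooled %*% p$W1) + p$b1)
    sum(z1 * p$w2) + p$b2
  }
  h <- 1e-6
  dH <- matrix(0, nrow(cache$HT), ncol(cache$HT))
  for (v in seq_len(nrow(dH))) {
    for (c in seq_len(ncol(dH))) {
      Hp <- cache$HT; Hp[v, c] <- Hp[v, c] + h
      Hm <- cache$HT; Hm[v, c] <- Hm[v, c] - h
      dH[v, c] <- (f_head(Hp) - f_head(Hm)) / (2 * h)
    }
  }
  alpha <- colMeans(dH)
  want <- drop(cache$HT %*% alpha)
  expect_equal(attr_gradcam(model, g)$atom_scores, want, tolerance = 1e-5)
})

test_that("node masking equals the two-forward-pass definition", {
  model <- random_model(41)
  g <- random_graph(7L, seed = 6)
  a <- attr_node_masking(model, g)
  sg <- build_graph_stack(list(g))
  f <- function(X) ucnbench:::.forward_cache(model$params, model$config,
                                             sg, X = X)$yhat[1]
  y <- f(sg$X)
  for (v in 1:7) {
    Xv <- sg$X; Xv[v, ] <- 0
    expect_equal(a$atom_scores[v], y - f(Xv), tolerance = 1e-12)
  }
  # a zero feature row scores exactly zero
  g$node_features[3, ] <- 0
  expect_equal(attr_node_masking(model, g)$atom_scores[3], 0)
})

test_that("all methods are permutation-equivariant", {
  model <- trained_mse()
  set.seed(8)
  for (s in sample(SMILES_POOL, 8)) {
    g <- featurize(parse_molecule(s))
    n <- nrow(g$node_features)
    perm <- sample(n)
    gp <- permute_graph(g, perm)
    for (method in c("CAM", "GradCAM", "GradInput", "NodeMasking")) {
      a <- attribute(model, g, method)$atom_scores
      ap <- attribute(model, gp, method)$atom_scores
      expect_equal(ap, a[perm], tolerance = 1e-9,
                   info = paste(method, s))
    }
    a <- attr_integrated_gradients(model, g, steps = 16L)$atom_scores
    ap <- attr_integrated_gradients(model, gp, steps = 16L)$atom_scores
    expect_equal(ap, a[perm], tolerance = 1e-9)
  }
})

test_that("random attribution is reproducible and centered", {
  g <- random_graph(10L, seed = 1)
  a1 <- attr_random(g, seed = 7)
  a2 <- attr_random(g, seed = 7)
  expect_identical(a1$atom_scores, a2$atom_scores)
  big <- unlist(lapply(1:1000, function(k) {
    attr_random(random_graph(100L, seed = 1), seed = k)$atom_scores
  }))
  expect_lt(abs(mean(big)), 3 / sqrt(length(big)))
})

test_that("attribution_table has one row per atom", {
  model <- random_model(51)
  g <- featurize(parse_molecule("CCO"))
  tab <- attribution_table(list(attr_cam(model, g, "c1"),
                                attr_gradinput(model, g, "c1")))
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$method), c("CAM", "GradInput"))
  expect_equal(tab$atom_index[1:3], 1:3)
})
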