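# Shared fixtures, built in code and memoized across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, builder(), envir = .fx)
  }
  get(key, envir = .fx, inherits = FALSE)
}

# Diverse, hand-written valid SMILES (non-canonical spellings on purpose).
SMILES_POOL <- c(
  "CCO", "OCC", "C(C)O", "c1ccccc1", "Cc1ccccc1", "Nc1ccccc1",
  "c1ccncc1", "CC(=O)O", "CC(=O)N", "C1CCCCC1", "C1CCNCC1", "CC#N",
  "ClCCCl", "FC(F)F", "CC(C)C", "CCOCC", "CSC", "CC(N)C(=O)O",
  "c1ccc2ccccc2c1", "Cc1ccncc1", "OC(=O)c1ccccc1", "CNC(=O)c1ccccc1",
  "COc1ccccc1", "CCN(CC)CC", "C1CC1", "C1CCC1", "O=C1CCCCC1",
  "Brc1ccccc1", "CC(=O)Nc1ccccc1", "Clc1ccc(N)cc1", "CC(O)C",
  "c1cnc2[nH]ccc2c1", "OCCO", "NCCN", "SCC", "C=CC=C", "CC=CC",
  "N#Cc1ccccc1", "OC1CCCCC1", "CC1CCCC1"
)

# Subset with at most 10 heavy atoms (for the exhaustive MCS oracle).
SMALL_POOL <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1", "Nc1ccccc1", "c1ccncc1",
  "C1CCCCC1", "CC#N", "ClCCCl", "CC(C)C", "CCOCC", "CSC", "C1CC1",
  "CC(=O)N", "OCCO", "NCCN", "CC=CC", "OC1CCCC1", "C1CCNCC1", "CC(O)C"
)

TINY_SUBS <- data.frame(
  fragment = c("", "C", "Cl", "OC", "C(F)(F)F", "N(C)C"),
  weight = c(0, 0.5, 1.1, -0.8, 1.3, -1.2),
  stringsAsFactors = FALSE
)

tiny_series <- function() memo("tiny_series", function() {
  generate_series(series_spec("c1cc([*:1])ccc1C(=O)N([*:2])C", TINY_SUBS,
                              base_activity = 6.5, noise_sd = 0,
                              n_compounds = 14L, seed = 3L))
})

tiny_pairs <- function() memo("tiny_pairs", function() {
  build_pairs(tiny_series()$records)
})

tiny_split <- function() memo("tiny_split", function() {
  split_pairs(tiny_pairs(), seed = 2L)
})

# A slightly larger noiseless series with a trained model per loss mode
# (shared by the model / attribution / metric tests).
train_series <- function() memo("train_series", function() {
  generate_series(series_spec("c1cc([*:1])ccc1C(=O)N([*:2])C", TINY_SUBS,
                              base_activity = 6.5, noise_sd = 0,
                              n_compounds = 25L, seed = 3L))
})

train_split <- function() memo("train_split", function() {
  split_pairs(build_pairs(train_series()$records), seed = 2L)
})

trained_cfg <- function(mode = "MSE", epochs = 150L, ...) {
  gnn_config(hidden_dim = 32L, n_message_passes = 2L, head_hidden = 32L,
             epochs = epochs, learning_rate = 3e-3, seed = 11L,
             loss_mode = mode, ...)
}

trained_mse <- function() memo("trained_mse", function() {
  train_gnn(train_split(), trained_cfg("MSE"))
})

trained_ucn <- function() memo("trained_ucn", function() {
  train_gnn(train_split(), trained_cfg("MSE+UCN"))
})

# ---------------------------------------------------------------------------
# Random molecular graphs (not molecules): random trees with one-hot-style
# features, for numerical attribution properties.
random_graph <- function(n, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_node_features()), n, n_node_features())
  if (n > 1) {
    parents <- vapply(2:n, function(v) sample(v - 1L, 1L), integer(1))
    ei <- cbind(c(2:n, parents), c(parents, 2:n))
    cls <- sample(4L, n - 1L, replace = TRUE)
    E <- matrix(0, 2 * (n - 1L), n_edge_features())
    E[cbind(seq_len(2 * (n - 1L)), rep(cls, 2L))] <- 1
  } else {
    ei <- matrix(integer(), ncol = 2)
    E <- matrix(numeric(), 0, n_edge_features())
  }
  structure(list(node_features = X, edge_index = ei, edge_features = E),
            class = "MolecularGraph")
}

# An untrained model with random parameters (optionally fully linear).
random_model <- function(seed, hidden_dim = 8L, n_message_passes = 2L,
                         head_hidden = 6L, activation = "tanh") {
  cfg <- gnn_config(hidden_dim = hidden_dim,
                    n_message_passes = n_message_passes,
                    head_hidden = head_hidden, seed = seed,
                    activation = activation)
  params <- local({
    set.seed(seed)
    ucnbench:::.init_params(cfg)
  })
  structure(list(params = params, config = cfg,
                 training_log = numeric(0),
                 schema = list(n_node_features = n_node_features(),
                               n_edge_features = n_edge_features(),
                               version = 1L),
                 train_compounds = character(0)),
            class = "TrainedGNN")
}

# Permute the atom order of a MolecularGraph.
permute_graph <- function(graph, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  ei <- graph$edge_index
  structure(list(node_features = graph$node_features[perm, , drop = FALSE],
                 edge_index = cbind(inv[ei[, 1]], inv[ei[, 2]]),
                 edge_features = graph$edge_features),
            class = "MolecularGraph")
}

# ---------------------------------------------------------------------------
# Mock compound pairs for metric tests (no chemistry needed).
mock_pair <- function(n_i, n_j, uncommon_i, uncommon_j, y_i, y_j,
                      pair_id = "p") {
  stopifnot(y_i >= y_j)
  p <- list(pair_id = pair_id, target_id = "T", id_i = "ci", id_j = "cj",
            mol_i = list(n_atoms = n_i), mol_j = list(n_atoms = n_j),
            activity_i = y_i, activity_j = y_j,
            delta_activity = y_i - y_j,
            uncommon_i = uncommon_i, uncommon_j = uncommon_j)
  p <- assign_ground_truth(p)
  class(p) <- "CompoundPair"
  p
}

mock_attr <- function(scores, method = "Mock") {
  structure(list(compound_id = NA_character_, method = method,
                 atom_scores = as.numeric(scores)),
            class = "Attribution")
}

# Straight-line independent recomputation of the two metrics.
brute_gdir <- function(pair, s_i, s_j) {
  mi <- sum(s_i[pair$uncommon_i]) / length(pair$uncommon_i)
  mj <- sum(s_j[pair$uncommon_j]) / length(pair$uncommon_j)
  d <- mi - mj
  sd_ <- if (abs(d) < 1e-12) 0 else if (d > 0) 1 else -1
  dy <- pair$activity_i - pair$activity_j
  sy <- if (abs(dy) < 1e-12) 0 else if (dy > 0) 1 else -1
  as.integer(sd_ == sy && sy != 0)
}

brute_ca <- function(pair, side, s) {
  unc <- if (side == "i") pair$uncommon_i else pair$uncommon_j
  gt <- if (side == "i") pair$ground_truth_i else pair$ground_truth_j
  vals <- vapply(unc, function(v) {
    sv <- if (abs(s[v]) < 1e-12) 0 else if (s[v] > 0) 1 else -1
    as.integer(sv == gt[v])
  }, integer(1))
  mean(vals)
}

# ---------------------------------------------------------------------------
# Exhaustive MCS oracle: largest connected induced common subgraph, by
# enumerating connected induced subgraphs of both molecules and testing
# colored isomorphism with igraph VF2 (independent of the package's
# branch-and-bound search).
.mol_igraph <- function(mol, lev) {
  g <- igraph::make_empty_graph(mol$n_atoms, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  g
}

.mol_vcol <- function(mol, lev) {
  match(paste(mol$element, mol$in_ring), lev)
}

.mol_ecol <- function(mol) {
  cls <- pmin(mol$bonds$order, 3L)
  cls[mol$bonds$aromatic] <- 4L
  cls
}

# All connected vertex subsets of size k.
.connected_subsets <- function(mol, k) {
  n <- mol$n_atoms
  adj <- lapply(seq_len(n), function(v) integer(0))
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # every connected subset is generated from its minimum vertex (the
  # anchor); deduplicated by key since the same set can be reached along
  # several growth orders
  out <- list()
  grow <- function(set, frontier, anchor) {
    if (length(set) == k) {
      key <- paste(sort(set), collapse = ",")
      if (is.null(out[[key]])) out[[key]] <<- sort(set)
      return()
    }
    cand <- setdiff(frontier, set)
    cand <- cand[cand > anchor]
    for (v in cand) {
      grow(c(set, v), union(frontier, adj[[v]]), anchor)
    }
  }
  for (start in seq_len(n)) {
    grow(start, adj[[start]], start)
  }
  unname(out)
}

mcs_oracle <- function(mol_a, mol_b) {
  lev <- unique(c(paste(mol_a$element, mol_a$in_ring),
                  paste(mol_b$element, mol_b$in_ring)))
  ga <- .mol_igraph(mol_a); gb <- .mol_igraph(mol_b)
  ca <- .mol_vcol(mol_a, lev); cb <- .mol_vcol(mol_b, lev)
  ea <- .mol_ecol(mol_a); eb <- .mol_ecol(mol_b)
  for (k in seq(min(mol_a$n_atoms, mol_b$n_atoms), 1L)) {
    sub_a <- .connected_subsets(mol_a, k)
    sub_b <- .connected_subsets(mol_b, k)
    if (length(sub_a) == 0L || length(sub_b) == 0L) next
    ind <- function(mol, g, vc, ec, set) {
      # induced subgraph with edge colors rebuilt from the bond table
      b <- mol$bonds
      keep <- b$i %in% set & b$j %in% set
      bb <- b[keep, , drop = FALSE]
      remap <- match(seq_len(mol$n_atoms), set)
      g2 <- igraph::make_empty_graph(length(set), directed = FALSE)
      if (nrow(bb) > 0) {
        g2 <- igraph::add_edges(g2, rbind(remap[bb$i], remap[bb$j]))
      }
      cls <- pmin(bb$order, 3L); cls[bb$aromatic] <- 4L
      list(g = g2, vc = vc[set], ec = cls)
    }
    ia <- lapply(sub_a, function(s) ind(mol_a, ga, ca, ea, s))
    ib <- lapply(sub_b, function(s) ind(mol_b, gb, cb, eb, s))
    sig <- function(x) paste(sort(x$vc), collapse = ",")
    sb <- vapply(ib, sig, character(1))
    for (xa in ia) {
      hits <- which(sb == sig(xa))
      for (h in hits) {
        iso <- igraph::isomorphic(xa$g, ib[[h]]$g, method = "vf2",
                                  vertex.color1 = xa$vc,
                                  vertex.color2 = ib[[h]]$vc,
                                  edge.color1 = xa$ec,
                                  edge.color2 = ib[[h]]$ec)
        if (iso) return(k)
      }
    }
  }
  0L
}
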