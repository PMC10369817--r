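test_that("compute_mcs matches spec examples", {
  eth <- parse_molecule("CCO")
  self <- compute_mcs(eth, eth)
  expect_equal(self$mcs_size, 3L)
  expect_setequal(self$common_atoms_i, 1:3)
  expect_equal(mcs_fraction(self, eth, eth), 1.0)

  tol <- parse_molecule("Cc1ccccc1")
  ani <- parse_molecule("Nc1ccccc1")
  m <- compute_mcs(tol, ani)
  expect_equal(m$mcs_size, 6L)
  expect_equal(mcs_fraction(m, tol, ani), 6 / 7)

  none <- compute_mcs(parse_molecule("C"), parse_molecule("N"))
  expect_equal(none$mcs_size, 0L)
  expect_equal(mcs_fraction(none, parse_molecule("C"), parse_molecule("N")),
               0)
})

test_that("compute_mcs equals the exhaustive oracle on small molecules", {
  set.seed(77)
  mols <- lapply(SMALL_POOL, parse_molecule)
  for (rep_k in seq_len(50)) {
    ab <- sample(length(mols), 2L, replace = TRUE)
    a <- mols[[ab[1]]]; b <- mols[[ab[2]]]
    got <- compute_mcs(a, b)$mcs_size
    want <- mcs_oracle(a, b)
    expect_equal(got, want,
                 info = paste(a$smiles, "vs", b$smiles))
  }
})

test_that("MCS mapping is a consistent induced common subgraph", {
  tol <- parse_molecule("Cc1ccccc1")
  pyr <- parse_molecule("Cc1ccncc1")
  m <- compute_mcs(tol, pyr)
  expect_equal(length(m$common_atoms_i), m$mcs_size)
  expect_equal(length(m$common_atoms_j), m$mcs_size)
  # matched atoms agree in element and ring membership
  expect_identical(tol$element[m$common_atoms_i],
                   pyr$element[m$common_atoms_j])
  expect_identical(tol$in_ring[m$common_atoms_i],
                   pyr$in_ring[m$common_atoms_j])
})

test_that("build_pairs applies both filters and orients pairs", {
  # three analogs of one series: activities 5.0, 6.5, 5.5
  subs <- data.frame(fragment = c("", "C", "OC"), weight = c(0, 1.5, 0.5))
  ser <- generate_series(series_spec("c1cc([*:1])ccc1C(=O)N([*:2])C",
                                     subs, base_activity = 5.0,
                                     noise_sd = 0, n_compounds = 9,
                                     seed = 1))
  recs <- ser$records
  # pick three with activities 5.0, 6.5, 5.5 (single-substituent analogs)
  idx <- c(which(abs(recs$activity - 5.0) < 1e-9)[1],
           which(abs(recs$activity - 6.5) < 1e-9)[1],
           which(abs(recs$activity - 5.5) < 1e-9)[1])
  expect_false(any(is.na(idx)))
  r3 <- recs[idx, ]
  class(r3) <- c("activity_records", "data.frame")
  pairs <- build_pairs(r3)
  expect_equal(length(pairs), 2L)
  deltas <- sort(vapply(pairs, `[[`, numeric(1), "delta_activity"))
  expect_equal(deltas, c(1.0, 1.5))   # Delta exactly 1.0 is included
  for (p in pairs) {
    expect_gte(p$activity_i, p$activity_j)
    expect_true(p$delta_activity >= 1.0)
    expect_gte(p$mcs_fraction, 0.5)
  }
})

test_that("identical compounds never pair and empty input yields none", {
  recs <- make_activity_records(c("CCO", "CCO"), c(6, 6), "T")
  pairs <- build_pairs(recs)
  expect_length(pairs, 0L)
  one <- make_activity_records("CCO", 6, "T")
  expect_length(build_pairs(one), 0L)
})

test_that("pair atom partitions are exact and ground truth is signed", {
  for (p in tiny_pairs()) {
    expect_setequal(c(p$uncommon_i, p$common_i), seq_len(p$mol_i$n_atoms))
    expect_length(intersect(p$uncommon_i, p$common_i), 0L)
    expect_setequal(c(p$uncommon_j, p$common_j), seq_len(p$mol_j$n_atoms))
    expect_true(all(p$ground_truth_i[p$uncommon_i] == 1L))
    expect_true(all(p$ground_truth_i[p$common_i] == 0L))
    expect_true(all(p$ground_truth_j[p$uncommon_j] == -1L))
    expect_true(all(p$ground_truth_j[p$common_j] == 0L))
  }
})

test_that("assign_ground_truth is antisymmetric and rejects zero deltas", {
  p <- tiny_pairs()[[1]]
  swapped <- p
  swapped[c("id_i", "id_j")] <- p[c("id_j", "id_i")]
  swapped[c("mol_i", "mol_j")] <- p[c("mol_j", "mol_i")]
  swapped[c("uncommon_i", "uncommon_j")] <- p[c("uncommon_j", "uncommon_i")]
  swapped <- assign_ground_truth(swapped)
  expect_identical(swapped$ground_truth_i[swapped$uncommon_i],
                   rep(1L, length(swapped$uncommon_i)))
  bad <- p
  bad$delta_activity <- 0
  expect_error(assign_ground_truth(bad), "zero activity difference")
})

test_that("build_pairs output is independent of record order", {
  ser <- tiny_series()
  recs <- ser$records
  shuf <- recs[rev(seq_len(nrow(recs))), ]
  class(shuf) <- c("activity_records", "data.frame")
  p1 <- build_pairs(recs)
  p2 <- build_pairs(shuf)
  expect_identical(vapply(p1, `[[`, character(1), "pair_id"),
                   vapply(p2, `[[`, character(1), "pair_id"))
  expect_identical(vapply(p1, `[[`, numeric(1), "delta_activity"),
                   vapply(p2, `[[`, numeric(1), "delta_activity"))
})

test_that("substitution sites count connected uncommon components", {
  tol <- parse_molecule("Cc1ccccc1")
  ani <- parse_molecule("Nc1ccccc1")
  recs <- make_activity_records(c("Cc1ccccc1", "Nc1ccccc1"), c(7, 5.5), "T")
  pairs <- build_pairs(recs)
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$sites_i, 1L)
  expect_equal(pairs[[1]]$sites_j, 1L)

  # para-xylene vs benzene-like pair: two methyls -> 2 sites on one side
  recs2 <- make_activity_records(c("Cc1ccc(C)cc1", "c1ccccc1"),
                                 c(7.5, 6), "T")
  pairs2 <- build_pairs(recs2)
  expect_length(pairs2, 1L)
  expect_equal(pairs2[[1]]$sites_i, 2L)
  expect_equal(pairs2[[1]]$sites_j, 0L)
  expect_false(pairs2[[1]]$evaluable)   # empty uncommon set on side j
})

test_that("split_pairs is deterministic, leakage-free, and never splits a pair", {
  pairs <- tiny_pairs()
  s1 <- split_pairs(pairs, seed = 42)
  s2 <- split_pairs(pairs, seed = 42)
  expect_identical(vapply(s1$train_pairs, `[[`, character(1), "pair_id"),
                   vapply(s2$train_pairs, `[[`, character(1), "pair_id"))
  for (seed in 1:50) {
    s <- split_pairs(pairs, seed = seed)
    tr <- unique(unlist(lapply(s$train_pairs,
                               function(p) c(p$id_i, p$id_j))))
    te <- unique(unlist(lapply(s$test_pairs,
                               function(p) c(p$id_i, p$id_j))))
    expect_length(intersect(tr, te), 0L)
    expect_equal(length(s$train_pairs) + length(s$test_pairs) + s$n_dropped,
                 length(pairs))
  }
  # a single pair is never split across sets
  one <- pairs[1]
  class(one) <- "compound_pairs"
  for (seed in 1:10) {
    s <- split_pairs(one, train_frac = 0.5, seed = seed)
    expect_true(length(s$train_pairs) + length(s$test_pairs) <= 1L)
  }
})

test_that("filter_targets enforces the minimum inclusively", {
  fake <- function(n) {
    structure(list(train_pairs = vector("list", n), test_pairs = list(),
                   target_id = paste0("t", n)), class = "BenchmarkSplit")
  }
  out <- filter_targets(list(fake(49), fake(50), fake(51)),
                        min_train_pairs = 50)
  expect_equal(vapply(out, `[[`, character(1), "target_id"),
               c("t50", "t51"))
  expect_length(filter_targets(list(), 50), 0L)
})

test_that("chemical_diversity is the scaffold-to-compound ratio", {
  recs <- tiny_series()$records
  # one shared scaffold for the whole series
  expect_equal(chemical_diversity(recs), 1 / nrow(recs))
  mix <- make_activity_records(
    c("CCCC", "CCO", "c1ccccc1", "c1ccncc1", "Cc1ccccc1"),
    rep(6, 5), "T")
  # scaffolds: none (x2, counted once), benzene (x2), pyridine
  expect_equal(chemical_diversity(mix), 3 / 5)
  empty <- make_activity_records(character(0), numeric(0), character(0))
  expect_error(chemical_diversity(empty), "empty")
})

test_that("pair_table emits one row per pair with JSON index sets", {
  tab <- pair_table(tiny_pairs())
  expect_equal(nrow(tab), length(tiny_pairs()))
  expect_true(all(c("pair_id", "delta_activity", "mcs_fraction",
                    "uncommon_i") %in% names(tab)))
  dec <- jsonlite::fromJSON(tab$uncommon_i[1])
  expect_identical(sort(dec), sort(tiny_pairs()[[1]]$uncommon_i))
})
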