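# Benchmark construction: MCS computation, compound-pair building with
# activity-cliff filtering, ground-truth atom coloring, substitution-site
# counting, leakage-free splitting, and diversity statistics.

#' Maximum common substructure of two molecules
#'
#' Connected maximum common induced subgraph under element identity and
#' bond-order class matching (single/double/triple/aromatic); ring atoms may
#' not match acyclic atoms. One embedding is returned, chosen by a
#' deterministic search order. If the search exceeds `timeout_s` the best
#' mapping found so far is returned with `timed_out = TRUE`.
#'
#' @param mol_a,mol_b `Molecule` objects.
#' @param timeout_s wall-clock budget in seconds (default 10).
#' @return an `MCSResult`: list with `common_atoms_i`, `common_atoms_j`
#'   (aligned 1-based index vectors: the k-th atom of each is matched),
#'   `mcs_size`, `timed_out`.
#' @export
compute_mcs <- function(mol_a, mol_b, timeout_s = 10) {
  stopifnot(inherits(mol_a, "Molecule"), inherits(mol_b, "Molecule"))
  lab <- function(m) {
    elt <- match(m$element, c(.ELEMENT_VOCAB, "other"))
    elt[is.na(elt)] <- length(.ELEMENT_VOCAB) + 1L
    # unseen elements beyond the vocabulary still need to distinguish
    # themselves: shift by a hash of the symbol
    oth <- which(m$element %in% setdiff(unique(m$element), .ELEMENT_VOCAB))
    if (length(oth) > 0L) {
      elt[oth] <- 100L + as.integer(factor(m$element[oth]))
    }
    elt * 2L + as.integer(m$in_ring)
  }
  bmat <- function(m) {
    B <- matrix(0L, m$n_atoms, m$n_atoms)
    if (nrow(m$bonds) > 0L) {
      cls <- .bond_class(m$bonds)
      B[cbind(m$bonds$i, m$bonds$j)] <- cls
      B[cbind(m$bonds$j, m$bonds$i)] <- cls
    }
    B
  }
  res <- .mcs_search_cpp(lab(mol_a), lab(mol_b), bmat(mol_a), bmat(mol_b),
                         timeout_s)
  structure(list(common_atoms_i = as.integer(res$map_a),
                 common_atoms_j = as.integer(res$map_b),
                 mcs_size = as.integer(res$size),
                 timed_out = isTRUE(res$timed_out)),
            class = "MCSResult")
}

#' Shared-structure fraction of an MCS
#'
#' The conservative fraction: `min(mcs_size / N_a, mcs_size / N_b)`, so a
#' threshold on it guarantees both compounds are covered at that level.
#'
#' @param pair_mcs an `MCSResult`.
#' @param mol_a,mol_b the two molecules.
#' @return a real in `[0, 1]`.
#' @export
mcs_fraction <- function(pair_mcs, mol_a, mol_b) {
  if (pair_mcs$mcs_size == 0L) return(0)
  min(pair_mcs$mcs_size / mol_a$n_atoms, pair_mcs$mcs_size / mol_b$n_atoms)
}

#' Assign ground-truth atom colors to a compound pair
#'
#' Uncommon atoms of the more potent compound (side i) are labelled +1,
#' uncommon atoms of the less potent compound (side j) -1; atoms in the
#' common substructure carry 0. Pairs where either uncommon set is empty
#' (one compound is a substructure of the other) are flagged
#' `evaluable = FALSE`.
#'
#' @param pair a `CompoundPair` (as built by [build_pairs()]).
#' @return the pair with `ground_truth_i`, `ground_truth_j`, `evaluable`
#'   fields populated.
#' @export
assign_ground_truth <- function(pair) {
  if (pair$delta_activity == 0) {
    stop("cannot assign ground truth to a pair with zero activity difference")
  }
  gt_i <- integer(pair$mol_i$n_atoms)
  gt_j <- integer(pair$mol_j$n_atoms)
  gt_i[pair$uncommon_i] <- 1L
  gt_j[pair$uncommon_j] <- -1L
  pair$ground_truth_i <- gt_i
  pair$ground_truth_j <- gt_j
  pair$evaluable <- length(pair$uncommon_i) > 0L &&
    length(pair$uncommon_j) > 0L
  pair
}

#' Count substitution sites of a compound pair
#'
#' A substitution site is a connected component of the subgraph induced by
#' the uncommon atoms of a molecule.
#'
#' @param pair a `CompoundPair`.
#' @return integer vector `c(sites_i, sites_j)`.
#' @export
count_substitution_sites <- function(pair) {
  n_comp <- function(mol, atoms) {
    if (length(atoms) == 0L) return(0L)
    b <- mol$bonds
    bk <- b[b$i %in% atoms & b$j %in% atoms, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(bk$i), to = as.character(bk$j)),
      directed = FALSE,
      vertices = data.frame(name = as.character(atoms)))
    igraph::components(g)$no
  }
  c(sites_i = n_comp(pair$mol_i, pair$uncommon_i),
    sites_j = n_comp(pair$mol_j, pair$uncommon_j))
}

#' Build activity-cliff compound pairs for one target
#'
#' Enumerates all unordered compound pairs of one target, keeps those with
#' an absolute activity difference of at least `min_delta` pIC50 log units
#' and a shared-structure fraction of at least `mcs_threshold`, orients each
#' pair so side i is the more potent compound, and assigns the ground-truth
#' atom coloring. The activity filter is applied before the (expensive) MCS
#' computation; the result is identical either way.
#'
#' @param records `activity_records` for a single target.
#' @param mcs_threshold minimum shared-structure fraction (default 0.5).
#' @param min_delta minimum absolute pIC50 difference (default 1.0,
#'   inclusive).
#' @param timeout_s per-pair MCS budget; timed-out pairs are dropped with a
#'   warning.
#' @return an object of class `compound_pairs`: list of `CompoundPair`
#'   objects with attributes `n_candidates`, `n_delta_pass`, `n_mcs_pass`,
#'   `n_timeout`.
#' @export
build_pairs <- function(records, mcs_threshold = 0.5, min_delta = 1.0,
                        timeout_s = 10) {
  stopifnot(inherits(records, "activity_records"))
  if (length(unique(records$target_id)) > 1L) {
    stop("build_pairs expects records of a single target; got ",
         length(unique(records$target_id)))
  }
  n <- nrow(records)
  out <- list()
  n_cand <- 0L; n_delta <- 0L; n_mcs <- 0L; n_timeout <- 0L
  if (n >= 2L) {
    target <- records$target_id[1]
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        n_cand <- n_cand + 1L
        dy <- records$activity[a] - records$activity[b]
        if (abs(dy) < min_delta) next
        n_delta <- n_delta + 1L
        # orient: i = more potent
        if (dy >= 0) { ii <- a; jj <- b } else { ii <- b; jj <- a }
        mol_i <- records$molecule[[ii]]
        mol_j <- records$molecule[[jj]]
        mcs <- compute_mcs(mol_i, mol_j, timeout_s = timeout_s)
        if (mcs$timed_out) {
          n_timeout <- n_timeout + 1L
          warning("MCS timeout for pair (", records$compound_id[ii], ", ",
                  records$compound_id[jj], "); pair dropped")
          next
        }
        frac <- mcs_fraction(mcs, mol_i, mol_j)
        if (frac < mcs_threshold) next
        n_mcs <- n_mcs + 1L
        pair <- list(
          pair_id = paste0(records$compound_id[ii], "|",
                           records$compound_id[jj]),
          target_id = target,
          id_i = records$compound_id[ii], id_j = records$compound_id[jj],
          smiles_i = records$smiles[ii], smiles_j = records$smiles[jj],
          mol_i = mol_i, mol_j = mol_j,
          activity_i = records$activity[ii],
          activity_j = records$activity[jj],
          delta_activity = abs(dy),
          mcs = mcs,
          mcs_fraction = frac,
          common_i = sort(mcs$common_atoms_i),
          common_j = sort(mcs$common_atoms_j),
          uncommon_i = setdiff(seq_len(mol_i$n_atoms), mcs$common_atoms_i),
          uncommon_j = setdiff(seq_len(mol_j$n_atoms), mcs$common_atoms_j)
        )
        pair <- assign_ground_truth(pair)
        sites <- count_substitution_sites(pair)
        pair$sites_i <- unname(sites[1])
        pair$sites_j <- unname(sites[2])
        class(pair) <- "CompoundPair"
        out[[length(out) + 1L]] <- pair
      }
    }
  }
  # deterministic order independent of input record order
  if (length(out) > 0L) {
    out <- out[order(vapply(out, `[[`, character(1), "pair_id"))]
  }
  structure(out, class = "compound_pairs",
            n_candidates = n_cand, n_delta_pass = n_delta,
            n_mcs_pass = n_mcs, n_timeout = n_timeout)
}

#' Leakage-free train/test split of compound pairs
#'
#' Compounds (not pairs) are randomly partitioned into train and test sets;
#' a pair belongs to the training set iff both its compounds are training
#' compounds, to the test set iff both are test compounds. Pairs straddling
#' the partition are dropped (counted in `n_dropped`), which guarantees no
#' compound appears in both a training and a test pair.
#'
#' @param pairs a `compound_pairs` list for one target.
#' @param train_frac fraction of compounds assigned to training
#'   (default 0.8).
#' @param seed integer seed; the split is deterministic given it.
#' @return a `BenchmarkSplit`: list with `train_pairs`, `test_pairs`,
#'   `target_id`, `train_compounds`, `test_compounds`, `n_dropped`.
#' @export
split_pairs <- function(pairs, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  ids <- sort(unique(unlist(lapply(pairs, function(p) c(p$id_i, p$id_j)))))
  target <- if (length(pairs) > 0L) pairs[[1]]$target_id else NA_character_
  n_train <- round(train_frac * length(ids))
  train_ids <- character(0)
  if (length(ids) > 0L && n_train > 0L) {
    train_ids <- local_seed(seed, sample(ids, n_train))
  }
  test_ids <- setdiff(ids, train_ids)
  in_train <- vapply(pairs, function(p) {
    p$id_i %in% train_ids && p$id_j %in% train_ids
  }, logical(1))
  in_test <- vapply(pairs, function(p) {
    p$id_i %in% test_ids && p$id_j %in% test_ids
  }, logical(1))
  structure(list(
    target_id = target,
    train_pairs = structure(pairs[in_train], class = "compound_pairs"),
    test_pairs = structure(pairs[in_test], class = "compound_pairs"),
    train_compounds = train_ids,
    test_compounds = test_ids,
    n_dropped = sum(!in_train & !in_test)
  ), class = "BenchmarkSplit")
}

#' Keep only targets with enough training pairs
#'
#' @param splits list of `BenchmarkSplit` objects.
#' @param min_train_pairs minimum number of training pairs (default 50,
#'   inclusive).
#' @return the retained splits.
#' @export
filter_targets <- function(splits, min_train_pairs = 50L) {
  keep <- vapply(splits, function(s) {
    length(s$train_pairs) >= min_train_pairs
  }, logical(1))
  splits[keep]
}

#' Scaffold diversity of a compound set
#'
#' Number of distinct Bemis-Murcko scaffolds (canonical SMILES; all acyclic
#' molecules share one sentinel "none" scaffold) divided by the number of
#' compounds.
#'
#' @param records `activity_records`.
#' @return a real in `(0, 1]`.
#' @export
chemical_diversity <- function(records) {
  stopifnot(inherits(records, "activity_records"))
  if (nrow(records) == 0L) stop("empty record set")
  scaff <- vapply(records$molecule, function(m) {
    s <- murcko_scaffold(m)
    if (is.null(s)) "none" else s$smiles
  }, character(1))
  length(unique(scaff)) / nrow(records)
}

#' Export compound pairs as a flat table
#'
#' @param pairs a `compound_pairs` list.
#' @return a data.frame with one row per pair; atom-index sets are
#'   JSON-encoded (1-based indices).
#' @export
pair_table <- function(pairs) {
  if (length(pairs) == 0L) {
    return(data.frame(pair_id = character(), target_id = character(),
                      id_i = character(), id_j = character(),
                      smiles_i = character(), smiles_j = character(),
                      delta_activity = numeric(), mcs_fraction = numeric(),
                      sites_i = integer(), sites_j = integer(),
                      evaluable = logical(),
                      common_i = character(), common_j = character(),
                      uncommon_i = character(), uncommon_j = character()))
  }
  enc <- function(v) as.character(jsonlite::toJSON(as.integer(v)))
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(pair_id = p$pair_id, target_id = p$target_id,
               id_i = p$id_i, id_j = p$id_j,
               smiles_i = p$smiles_i, smiles_j = p$smiles_j,
               delta_activity = p$delta_activity,
               mcs_fraction = p$mcs_fraction,
               sites_i = p$sites_i, sites_j = p$sites_j,
               evaluable = p$evaluable,
               common_i = enc(p$common_i), common_j = enc(p$common_j),
               uncommon_i = enc(p$uncommon_i), uncommon_j = enc(p$uncommon_j),
               stringsAsFactors = FALSE)
  }))
}
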