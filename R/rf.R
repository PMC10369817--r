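# Random-forest comparator: ECFP4 regression forest plus the atom-masking
# attribution (substitute an element absent from the training chemistry,
# re-fingerprint, and take the prediction difference).

.fp_matrix <- function(molecules, n_bits, radius) {
  t(vapply(molecules, function(m) ecfp4(m, n_bits, radius)$bits,
           integer(n_bits)))
}

#' Train the random-forest baseline on ECFP4 fingerprints
#'
#' @param records `activity_records` (at least 10).
#' @param n_trees forest size (default 500).
#' @param seed RNG seed; predictions are deterministic given it.
#' @param n_bits,radius fingerprint parameters (defaults 2048, 2 = ECFP4).
#' @return an `RFModel`: list with the fitted forest and the fingerprint
#'   settings.
#' @export
rf_train <- function(records, n_trees = 500L, seed = 1L,
                     n_bits = 2048L, radius = 2L) {
  stopifnot(inherits(records, "activity_records"))
  if (nrow(records) < 10L) {
    stop("rf_train needs at least 10 records, got ", nrow(records))
  }
  y <- records$activity
  if (stats::sd(y) == 0) {
    warning("constant activity labels; the forest will predict the mean")
  }
  X <- .fp_matrix(records$molecule, n_bits, radius)
  colnames(X) <- paste0("b", seq_len(n_bits))
  forest <- local_seed(seed, {
    randomForest::randomForest(x = X, y = y, ntree = n_trees)
  })
  structure(list(forest = forest, n_bits = as.integer(n_bits),
                 radius = as.integer(radius), n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "RFModel")
}

#' Predict pIC50 with the random-forest baseline
#'
#' @param model an `RFModel`.
#' @param molecules a `Molecule` or list of `Molecule`s.
#' @return numeric vector of predictions.
#' @export
rf_predict <- function(model, molecules) {
  stopifnot(inherits(model, "RFModel"))
  if (inherits(molecules, "Molecule")) molecules <- list(molecules)
  X <- .fp_matrix(molecules, model$n_bits, model$radius)
  colnames(X) <- paste0("b", seq_len(model$n_bits))
  unname(stats::predict(model$forest, X))
}

#' Atom-masking attribution for the random-forest baseline
#'
#' Each atom in turn is replaced by a sentinel element (xenon) never present
#' in drug-like training sets, the fingerprint is recomputed, and the score
#' is the drop in prediction:
#' `score_v = predict(original) - predict(masked_v)`.
#'
#' @param model an `RFModel`.
#' @param mol a `Molecule`.
#' @param compound_id optional id stamped on the result.
#' @param sentinel sentinel element symbol (default `"Xe"`).
#' @return an `Attribution` with method `"RFMasking"`.
#' @export
rf_atom_masking <- function(model, mol, compound_id = NA_character_,
                            sentinel = "Xe") {
  stopifnot(inherits(model, "RFModel"), inherits(mol, "Molecule"))
  variants <- lapply(seq_len(mol$n_atoms), function(v) {
    m <- mol
    m$element[v] <- sentinel
    m
  })
  preds <- rf_predict(model, c(list(mol), variants))
  .new_attribution(preds[1] - preds[-1], "RFMasking", compound_id)
}
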