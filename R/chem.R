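# Molecule parsing, featurization, fingerprints, scaffolds, table I/O.
# All structure perception (canonical SMILES, aromaticity, rings) is done by
# OpenBabel through ChemmineOB; this file only shapes the results into plain
# R containers the rest of the package consumes.

.ob <- local({
  env <- NULL
  function() {
    if (is.null(env)) env <<- asNamespace("ChemmineOB")
    env
  }
})

.ELEMENTS <- c(
  "1" = "H", "3" = "Li", "5" = "B", "6" = "C", "7" = "N", "8" = "O",
  "9" = "F", "11" = "Na", "12" = "Mg", "14" = "Si", "15" = "P", "16" = "S",
  "17" = "Cl", "19" = "K", "20" = "Ca", "26" = "Fe", "30" = "Zn",
  "33" = "As", "34" = "Se", "35" = "Br", "53" = "I", "54" = "Xe"
)

.element_symbol <- function(atomic_num) {
  sym <- .ELEMENTS[as.character(atomic_num)]
  ifelse(is.na(sym), paste0("El", atomic_num), unname(sym))
}

# OpenBabel silently repairs unbalanced parentheses/brackets, so malformed
# input must be rejected before it reaches the parser.
.smiles_syntax_ok <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  brk <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
    if (ch == "[") {
      brk <- brk + 1L
      if (brk > 1L) return(FALSE)
    }
    if (ch == "]") {
      brk <- brk - 1L
      if (brk < 0L) return(FALSE)
    }
  }
  depth == 0L && brk == 0L
}

#' Canonicalize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return the OpenBabel canonical SMILES, or an error for unparseable input.
#' @keywords internal
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  if (!.smiles_syntax_ok(smiles)) {
    stop("invalid SMILES (unbalanced parentheses or brackets): ", smiles)
  }
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- trimws(out)
  if (!nzchar(out)) stop("unparseable SMILES: ", smiles)
  out
}

#' Parse a SMILES string into a Molecule
#'
#' Builds a heavy-atom molecular graph from a SMILES string. The input is
#' canonicalized first, so atom indices are stable under
#' parse -> write -> parse round trips of the canonical SMILES. Hydrogens are
#' implicit; atom indices are 1-based.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `Molecule` with fields `smiles` (canonical),
#'   `n_atoms`, `element`, `charge`, `aromatic`, `in_ring`, `degree`, and
#'   `bonds` (data.frame with columns `i`, `j`, `order`, `aromatic`).
#' @examples
#' m <- parse_molecule("CCO")
#' m$n_atoms  # 3 heavy atoms
#' @export
parse_molecule <- function(smiles) {
  can <- canonical_smiles(smiles)
  .mol_from_smiles_raw(can)
}

# Build a Molecule from a SMILES string *without* canonicalizing first:
# atom order follows the SMILES token order. parse_molecule() feeds this the
# canonical SMILES; the synthetic generator uses it on assembled template
# strings to locate substituent atoms before canonicalization.
.mol_from_smiles_raw <- function(smiles) {
  ob <- .ob()
  res <- ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
    n <- ob$OBMol_NumAtoms(mol)
    nb <- ob$OBMol_NumBonds(mol)
    if (n < 1L) stop("unparseable SMILES: ", smiles)
    num <- integer(n); chg <- integer(n); aro <- logical(n); rng <- logical(n)
    for (k in seq_len(n)) {
      a <- ob$OBMol_GetAtom(mol, k)
      num[k] <- ob$OBAtom_GetAtomicNum(a)
      chg[k] <- ob$OBAtom_GetFormalCharge(a)
      aro[k] <- as.logical(ob$OBAtom_IsAromatic(a))
      rng[k] <- as.logical(ob$OBAtom_IsInRing(a))
    }
    if (nb > 0L) {
      bi <- integer(nb); bj <- integer(nb); bo <- integer(nb); ba <- logical(nb)
      for (k in seq_len(nb)) {
        b <- ob$OBMol_GetBond(mol, k - 1L)
        bi[k] <- ob$OBBond_GetBeginAtomIdx(b)
        bj[k] <- ob$OBBond_GetEndAtomIdx(b)
        bo[k] <- ob$OBBond_GetBondOrder(b)
        ba[k] <- as.logical(ob$OBBond_IsAromatic(b))
      }
      bonds <- data.frame(i = bi, j = bj, order = bo, aromatic = ba)
    } else {
      bonds <- data.frame(i = integer(), j = integer(),
                          order = integer(), aromatic = logical())
    }
    list(num = num, chg = chg, aro = aro, rng = rng, bonds = bonds)
  })[[1]]
  n <- length(res$num)
  degree <- integer(n)
  if (nrow(res$bonds) > 0L) {
    tab <- table(factor(c(res$bonds$i, res$bonds$j), levels = seq_len(n)))
    degree <- as.integer(tab)
  }
  structure(list(
    smiles = smiles,
    n_atoms = n,
    element = .element_symbol(res$num),
    charge = res$chg,
    aromatic = res$aro,
    in_ring = res$rng,
    degree = degree,
    bonds = res$bonds
  ), class = "Molecule")
}

#' @export
print.Molecule <- function(x, ...) {
  cat("Molecule:", x$smiles, "\n")
  cat(" ", x$n_atoms, "heavy atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Write the canonical SMILES of a Molecule
#' @param mol a `Molecule`.
#' @return the canonical SMILES string.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  mol$smiles
}

# ---------------------------------------------------------------------------
# Featurization

.ELEMENT_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

# Bond order classes: 1 single, 2 double, 3 triple, 4 aromatic.
.bond_class <- function(bonds) {
  cls <- pmin(bonds$order, 3L)
  cls[bonds$aromatic] <- 4L
  cls
}

#' Number of node feature columns produced by [featurize()]
#' @export
n_node_features <- function() length(.ELEMENT_VOCAB) + 1L + 4L

#' Number of edge feature columns produced by [featurize()]
#' @export
n_edge_features <- function() 4L

#' Featurize a Molecule into a graph for the GNN
#'
#' Node features: one-hot element over \{C, N, O, S, F, Cl, Br, I, P, other\},
#' heavy-atom degree (scaled by 1/4), formal charge, aromatic flag, ring flag.
#' Edge features: one-hot bond-order class (single/double/triple/aromatic).
#' Every bond appears in both directions in `edge_index`.
#'
#' @param mol a `Molecule`.
#' @return an object of class `MolecularGraph` with `node_features`
#'   (N x F_node matrix), `edge_index` (2E x 2 matrix of 1-based directed
#'   atom pairs), and `edge_features` (2E x F_edge matrix).
#' @export
featurize <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  n <- mol$n_atoms
  nv <- length(.ELEMENT_VOCAB)
  X <- matrix(0, nrow = n, ncol = nv + 5L)
  colnames(X) <- c(.ELEMENT_VOCAB, "other", "degree", "charge",
                   "aromatic", "ring")
  idx <- match(mol$element, .ELEMENT_VOCAB)
  for (v in seq_len(n)) {
    col <- if (is.na(idx[v])) nv + 1L else idx[v]
    X[v, col] <- 1
  }
  X[, "degree"] <- mol$degree / 4
  X[, "charge"] <- mol$charge
  X[, "aromatic"] <- as.numeric(mol$aromatic)
  X[, "ring"] <- as.numeric(mol$in_ring)

  nb <- nrow(mol$bonds)
  if (nb > 0L) {
    cls <- .bond_class(mol$bonds)
    ei <- cbind(c(mol$bonds$i, mol$bonds$j), c(mol$bonds$j, mol$bonds$i))
    E <- matrix(0, nrow = 2L * nb, ncol = 4L)
    E[cbind(seq_len(2L * nb), rep(cls, 2L))] <- 1
  } else {
    ei <- matrix(integer(), ncol = 2L)
    E <- matrix(numeric(), nrow = 0L, ncol = 4L)
  }
  colnames(E) <- c("single", "double", "triple", "aromatic")
  structure(list(node_features = X, edge_index = ei, edge_features = E),
            class = "MolecularGraph")
}

# ---------------------------------------------------------------------------
# Morgan-style circular fingerprint (extended-connectivity; radius 2 = ECFP4)

# 31-bit mixing hash over integer sequences; deterministic across platforms.
.hash_ints <- function(ints) {
  h <- 17
  for (v in ints) {
    h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  }
  h
}

#' Extended-connectivity (Morgan) fingerprint
#'
#' Circular fingerprint in the ECFP family: initial atom identifiers hash the
#' atom invariants (element, degree, charge, aromaticity, ring membership);
#' each iteration rehashes an atom's identifier with the sorted
#' (bond-class, neighbor-identifier) pairs. Identifiers from all iterations
#' are folded into a fixed-length bit vector. Environments whose bond set
#' duplicates one already recorded are skipped, as is standard for
#' extended-connectivity fingerprints. `radius = 2` corresponds to ECFP4.
#'
#' @param mol a `Molecule`.
#' @param n_bits fingerprint length (default 2048).
#' @param radius number of iterations (default 2).
#' @return an object of class `Fingerprint`: list with `bits` (0/1 integer
#'   vector of length `n_bits`), `n_bits`, `radius`.
#' @export
ecfp4 <- function(mol, n_bits = 2048L, radius = 2L) {
  stopifnot(inherits(mol, "Molecule"), n_bits >= 64L, radius >= 0L)
  n <- mol$n_atoms
  elt <- match(mol$element, .ELEMENT_VOCAB)
  elt[is.na(elt)] <- length(.ELEMENT_VOCAB) + match(
    mol$element[is.na(elt)], unique(mol$element[is.na(elt)]))
  ids <- vapply(seq_len(n), function(v) {
    .hash_ints(c(elt[v], mol$degree[v], mol$charge[v] + 8L,
                 as.integer(mol$aromatic[v]), as.integer(mol$in_ring[v])))
  }, numeric(1))

  nb <- nrow(mol$bonds)
  nbrs <- vector("list", n)
  if (nb > 0L) {
    cls <- .bond_class(mol$bonds)
    for (k in seq_len(nb)) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, cls[k], k))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, cls[k], k))
    }
  }

  all_ids <- ids                       # round 0: always kept
  env_sets <- character(0)             # bond-set keys of recorded envs (r>=1)
  # env_bonds[[v]] = bond indices within current radius of atom v
  env_bonds <- lapply(seq_len(n), function(v) integer(0))
  if (radius > 0L && n > 0L) {
    cur <- ids
    for (r in seq_len(radius)) {
      nxt <- numeric(n)
      nxt_env <- vector("list", n)
      for (v in seq_len(n)) {
        nb_v <- nbrs[[v]]
        if (is.null(nb_v)) {
          nxt[v] <- .hash_ints(c(r, cur[v]))
          nxt_env[[v]] <- env_bonds[[v]]
          next
        }
        ord <- order(nb_v[, 2], cur[nb_v[, 1]])
        pairs <- as.vector(t(cbind(nb_v[ord, 2], cur[nb_v[ord, 1]])))
        nxt[v] <- .hash_ints(c(r, cur[v], pairs))
        nxt_env[[v]] <- sort(unique(c(env_bonds[[v]], nb_v[, 3],
                                      unlist(lapply(nb_v[, 1], function(u) {
                                        env_bonds[[u]]
                                      })))))
      }
      for (v in seq_len(n)) {
        key <- paste(nxt_env[[v]], collapse = ",")
        if (!(key %in% env_sets)) {
          env_sets <- c(env_sets, key)
          all_ids <- c(all_ids, nxt[v])
        }
      }
      env_bonds <- nxt_env
      cur <- nxt
    }
  }
  bits <- integer(n_bits)
  bits[(all_ids %% n_bits) + 1L] <- 1L
  structure(list(bits = bits, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "Fingerprint")
}

# ---------------------------------------------------------------------------
# Bemis-Murcko scaffold

# Minimal V2000 MOL block for a subset of atoms (kekule bond orders).
.mol_block <- function(mol, keep) {
  keep <- sort(keep)
  remap <- match(seq_len(mol$n_atoms), keep)
  b <- mol$bonds
  bkeep <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  na <- length(keep); nbnd <- nrow(bkeep)
  header <- c("scaffold", "  ucnbench", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nbnd))
  atoms <- vapply(keep, function(v) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$element[v])
  }, character(1))
  bondl <- character(0)
  if (nbnd > 0L) {
    bondl <- vapply(seq_len(nbnd), function(k) {
      sprintf("%3d%3d%3d  0", remap[bkeep$i[k]], remap[bkeep$j[k]],
              bkeep$order[k])
    }, character(1))
  }
  chg <- which(mol$charge[keep] != 0L)
  chgl <- character(0)
  if (length(chg) > 0L) {
    chgl <- vapply(chg, function(k) {
      sprintf("M  CHG  1%4d%4d", k, mol$charge[keep[k]])
    }, character(1))
  }
  paste(c(header, atoms, bondl, chgl, "M  END", "$$$$", ""), collapse = "\n")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively removes terminal (degree-1) atoms that are not part of a ring,
#' leaving the ring systems plus the linkers connecting them. Acyclic
#' molecules have no scaffold and return `NULL`.
#'
#' @param mol a `Molecule`.
#' @return a `Molecule` holding the scaffold, or `NULL` for acyclic input.
#' @export
murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  if (!any(mol$in_ring)) return(NULL)
  keep <- seq_len(mol$n_atoms)
  b <- mol$bonds
  repeat {
    bk <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
    deg <- table(factor(c(bk$i, bk$j), levels = keep))
    drop <- keep[deg <= 1L & !mol$in_ring[keep]]
    if (length(drop) == 0L) break
    keep <- setdiff(keep, drop)
  }
  block <- .mol_block(mol, keep)
  smi <- trimws(suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", block)))
  smi <- sub("\\s.*$", "", smi)
  if (!nzchar(smi)) stop("scaffold extraction failed for ", mol$smiles)
  parse_molecule(smi)
}

# ---------------------------------------------------------------------------
# Activity table I/O

#' Read an activity table into activity records
#'
#' CSV input must have columns `smiles`, `activity`, `target_id`; an optional
#' `compound_id` column is used when present, otherwise ids are generated.
#' When `activities` is `"raw"`, values are IC50s in molar units and are
#' transformed to pIC50 = -log10(IC50); `"pic50"` passes values through.
#' Rows whose SMILES cannot be parsed are skipped with a warning and counted.
#'
#' @param path file path.
#' @param format `"csv"` or `"sdf"`.
#' @param activities `"pic50"` (default) or `"raw"`.
#' @param sdf_activity_field for SDF input, the property field holding the
#'   activity value.
#' @param sdf_target_field for SDF input, the property field holding the
#'   target id (default: all records assigned target `"T1"`).
#' @return a data.frame of class `activity_records` with columns
#'   `compound_id`, `target_id`, `activity` (pIC50), `smiles` (canonical), and
#'   a list column `molecule`; attribute `n_skipped` counts dropped rows.
#' @export
read_table <- function(path, format = c("csv", "sdf"),
                       activities = c("pic50", "raw"),
                       sdf_activity_field = "activity",
                       sdf_target_field = NULL) {
  format <- match.arg(format)
  activities <- match.arg(activities)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("smiles", "activity", "target_id")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("missing required columns: ", paste(miss, collapse = ", "))
    }
    if (!"compound_id" %in% names(df)) {
      df$compound_id <- sprintf("cpd%04d", seq_len(nrow(df)))
    }
  } else {
    df <- .read_sdf_table(path, sdf_activity_field, sdf_target_field)
  }
  act <- as.numeric(df$activity)
  if (activities == "raw") act <- -log10(act)
  recs <- make_activity_records(df$smiles, act, df$target_id, df$compound_id)
  recs
}

#' Build activity records from vectors
#'
#' @param smiles character vector of SMILES.
#' @param activity numeric vector of pIC50 values.
#' @param target_id character vector (recycled).
#' @param compound_id optional character vector of unique ids.
#' @return an `activity_records` data.frame; unparseable SMILES are skipped
#'   with a warning (count in attribute `n_skipped`).
#' @export
make_activity_records <- function(smiles, activity, target_id,
                                  compound_id = NULL) {
  n <- length(smiles)
  target_id <- rep_len(as.character(target_id), n)
  if (is.null(compound_id)) compound_id <- sprintf("cpd%04d", seq_len(n))
  mols <- vector("list", n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    m <- tryCatch(parse_molecule(smiles[k]), error = function(e) NULL)
    if (is.null(m) || !is.finite(activity[k])) {
      ok[k] <- FALSE
    } else {
      mols[[k]] <- m
      ok[k] <- TRUE
    }
  }
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) skipped (unparseable SMILES or ",
            "non-finite activity)")
  }
  out <- data.frame(
    compound_id = compound_id[ok],
    target_id = target_id[ok],
    activity = as.numeric(activity[ok]),
    smiles = vapply(mols[ok], `[[`, character(1), "smiles"),
    stringsAsFactors = FALSE
  )
  out$molecule <- mols[ok]
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("activity_records", "data.frame")
  out
}

.read_sdf_table <- function(path, activity_field, target_field) {
  txt <- readLines(path)
  # split on record delimiter
  ends <- grep("^\\$\\$\\$\\$", txt)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- Map(function(s, e) txt[s:e], starts, ends)
  get_field <- function(block, field) {
    hit <- grep(paste0("^>\\s*<", field, ">"), block)
    if (length(hit) == 0L) return(NA_character_)
    block[hit[1] + 1L]
  }
  smi <- vapply(recs, function(b) {
    s <- tryCatch(
      trimws(suppressWarnings(ChemmineOB::convertFormat(
        "SDF", "CAN", paste(c(b, ""), collapse = "\n")))),
      error = function(e) "")
    sub("\\s.*$", "", s)
  }, character(1))
  act <- vapply(recs, get_field, character(1), field = activity_field)
  tgt <- if (is.null(target_field)) rep("T1", length(recs)) else
    vapply(recs, get_field, character(1), field = target_field)
  data.frame(smiles = smi, activity = as.numeric(act), target_id = tgt,
             compound_id = sprintf("cpd%04d", seq_along(recs)),
             stringsAsFactors = FALSE)
}
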