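# Synthetic congeneric series with planted additive substituent effects.
# Compounds are built by splicing substituent fragments into a scaffold
# template at marked attachment sites; activity is base + sum of per-fragment
# contributions + Gaussian noise. The truth table records, per compound, the
# canonical atom indices of every substituent together with its planted
# weight — the ground truth that the attribution benchmark is scored against.

# Count heavy atoms in a SMILES segment (token scan; bracket atoms count 1).
.count_atoms <- function(s) {
  n <- 0L
  i <- 1L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(chars)
  while (i <= len) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= len && chars[j] != "]") j <- j + 1L
      n <- n + 1L
      i <- j + 1L
    } else if (ch %in% c("C", "B")) {
      # two-letter halogens
      if (i < len && ((ch == "C" && chars[i + 1L] == "l") ||
                      (ch == "B" && chars[i + 1L] == "r"))) {
        i <- i + 1L
      }
      n <- n + 1L
      i <- i + 1L
    } else if (ch %in% c("N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      n <- n + 1L
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  n
}

# One isomorphism between two orderings of the same molecule (VF2 with
# element+charge vertex colors and bond-class edge colors). Returns map such
# that atom t of `mol_from` corresponds to atom map[t] of `mol_to`.
.atom_map <- function(mol_from, mol_to) {
  key_f <- paste(mol_from$element, mol_from$charge)
  key_t <- paste(mol_to$element, mol_to$charge)
  lev <- unique(c(key_f, key_t))
  g <- function(mol, key) {
    gg <- igraph::make_empty_graph(n = mol$n_atoms, directed = FALSE)
    if (nrow(mol$bonds) > 0L) {
      gg <- igraph::add_edges(gg, rbind(mol$bonds$i, mol$bonds$j))
    }
    gg
  }
  gf <- g(mol_from); gt <- g(mol_to)
  maps <- igraph::isomorphisms(
    gf, gt, method = "vf2",
    vertex.color1 = match(key_f, lev), vertex.color2 = match(key_t, lev),
    edge.color1 = .bond_class(mol_from$bonds),
    edge.color2 = .bond_class(mol_to$bonds))
  if (length(maps) == 0L) stop("no isomorphism between molecule orderings")
  m <- as.integer(maps[[1]])
  # igraph indexes the returned map by the second graph; orient it so that
  # map[t] is the mol_to atom matched to atom t of mol_from, and validate
  # colors and bond classes under the chosen orientation.
  valid <- function(mm) {
    if (!all(key_f == key_t[mm])) return(FALSE)
    bf <- mol_from$bonds; bt <- mol_to$bonds
    key_bond <- function(i, j, cls) {
      paste(pmin(i, j), pmax(i, j), cls)
    }
    setequal(key_bond(mm[bf$i], mm[bf$j], .bond_class(bf)),
             key_bond(bt$i, bt$j, .bond_class(bt)))
  }
  inv <- integer(length(m))
  inv[m] <- seq_along(m)
  if (valid(inv)) return(inv)
  if (valid(m)) return(m)
  stop("inconsistent atom mapping")
}

#' Specification of one synthetic congeneric series
#'
#' @param scaffold_template SMILES with attachment sites written as
#'   parenthesized tokens `([*:1])`, `([*:2])`, ... A fragment replaces the
#'   token; the empty fragment (hydrogen) deletes it.
#' @param substituents data.frame with columns `fragment` (SMILES written
#'   attachment-atom first; `""` = hydrogen) and `weight` (additive activity
#'   contribution in pIC50 log units).
#' @param base_activity intercept pIC50 of the unsubstituted scaffold.
#' @param noise_sd standard deviation of the Gaussian label noise
#'   (pIC50 units).
#' @param n_compounds number of distinct analogs to generate.
#' @param seed integer RNG seed.
#' @return a `SeriesSpec` list.
#' @export
series_spec <- function(scaffold_template, substituents,
                        base_activity = 7.0, noise_sd = 0.1,
                        n_compounds = 40L, seed = 1L) {
  stopifnot(is.character(scaffold_template), nrow(substituents) >= 2L,
            all(c("fragment", "weight") %in% names(substituents)),
            noise_sd >= 0, n_compounds >= 2L)
  structure(list(scaffold_template = scaffold_template,
                 substituents = substituents,
                 base_activity = base_activity, noise_sd = noise_sd,
                 n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed)),
            class = "SeriesSpec")
}

# Assemble a compound SMILES from the template and one fragment per site.
# Returns the SMILES plus, per site, the atom-index range of its fragment
# in SMILES token order (NULL for hydrogen).
.assemble <- function(template, fragments) {
  site_rx <- "\\(\\[\\*:[0-9]+\\]\\)"
  m <- gregexpr(site_rx, template)[[1]]
  if (m[1] == -1L) stop("template has no attachment sites")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  n_sites <- length(starts)
  if (length(fragments) != n_sites) {
    stop("need ", n_sites, " fragments, got ", length(fragments))
  }
  parts <- character(n_sites + 1L)
  prev <- 1L
  for (k in seq_len(n_sites)) {
    parts[k] <- substr(template, prev, starts[k] - 1L)
    prev <- starts[k] + lens[k]
  }
  parts[n_sites + 1L] <- substr(template, prev, nchar(template))

  smi <- ""
  atom_pos <- 0L
  site_atoms <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    smi <- paste0(smi, parts[k])
    atom_pos <- atom_pos + .count_atoms(parts[k])
    frag <- fragments[k]
    if (nzchar(frag)) {
      na <- .count_atoms(frag)
      site_atoms[[k]] <- seq(atom_pos + 1L, atom_pos + na)
      atom_pos <- atom_pos + na
      smi <- paste0(smi, "(", frag, ")")
    }
  }
  smi <- paste0(smi, parts[n_sites + 1L])
  list(smiles = smi, site_atoms = site_atoms, n_sites = n_sites)
}

#' Generate one synthetic congeneric series
#'
#' Samples one substituent per attachment site and compound, splices them
#' into the scaffold template, and assigns
#' `activity = base + sum(site weights) + N(0, noise_sd)`. Compounds are
#' deduplicated by canonical SMILES. The truth table maps every compound to
#' its substituents' canonical atom indices and planted weights.
#'
#' @param spec a [series_spec()].
#' @param target_id target identifier stamped on the records.
#' @param id_prefix prefix for generated compound ids.
#' @return list with `records` (`activity_records`) and `truth` (named list:
#'   compound_id -> list of per-site entries with `site`, `fragment`,
#'   `weight`, `atoms`).
#' @export
generate_series <- function(spec, target_id = "T1", id_prefix = target_id) {
  stopifnot(inherits(spec, "SeriesSpec"))
  frags <- spec$substituents$fragment
  weights <- spec$substituents$weight
  n_sites <- .assemble(spec$scaffold_template,
                       rep("", length(gregexpr("\\[\\*:", spec$scaffold_template)[[1]])))$n_sites

  local_seed(spec$seed, {
    seen <- character(0)
    combos <- list()
    smiles_list <- character(0)
    tries <- 0L
    max_tries <- 60L * spec$n_compounds
    while (length(combos) < spec$n_compounds && tries < max_tries) {
      tries <- tries + 1L
      pick <- sample(length(frags), n_sites, replace = TRUE)
      key <- paste(pick, collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      asm <- .assemble(spec$scaffold_template, frags[pick])
      can <- tryCatch(canonical_smiles(asm$smiles), error = function(e) NA)
      if (is.na(can) || can %in% smiles_list) next
      combos[[length(combos) + 1L]] <- list(pick = pick, asm = asm, can = can)
      smiles_list <- c(smiles_list, can)
    }
    n <- length(combos)
    if (n < 2L) stop("could not generate at least 2 distinct compounds")
    noise <- stats::rnorm(n, 0, spec$noise_sd)

    ids <- sprintf("%s_c%03d", id_prefix, seq_len(n))
    act <- numeric(n)
    truth <- stats::setNames(vector("list", n), ids)
    mols <- vector("list", n)
    for (k in seq_len(n)) {
      cb <- combos[[k]]
      act[k] <- spec$base_activity + sum(weights[cb$pick]) + noise[k]
      raw <- .mol_from_smiles_raw(cb$asm$smiles)
      canmol <- .mol_from_smiles_raw(cb$can)
      amap <- .atom_map(raw, canmol)
      mols[[k]] <- canmol
      truth[[k]] <- lapply(seq_len(n_sites), function(s) {
        atoms <- cb$asm$site_atoms[[s]]
        list(site = s, fragment = frags[cb$pick[s]],
             weight = weights[cb$pick[s]],
             atoms = if (is.null(atoms)) integer(0) else
               sort(amap[atoms]))
      })
    }
    records <- data.frame(compound_id = ids,
                          target_id = target_id,
                          activity = act,
                          smiles = vapply(mols, `[[`, character(1), "smiles"),
                          stringsAsFactors = FALSE)
    records$molecule <- mols
    attr(records, "n_skipped") <- 0L
    class(records) <- c("activity_records", "data.frame")
    list(records = records, truth = truth)
  })
}

# Built-in scaffold templates for the multi-target benchmark (two
# substitution sites each; heteroatoms break ring symmetry so MCS
# embeddings stay cheap).
.BENCH_TEMPLATES <- c(
  "c1cc([*:1])ccc1C(=O)N([*:2])C",
  "c1cc([*:1])cnc1S(=O)(=O)N([*:2])C",
  "c1cc([*:1])ccc1Oc1ccc([*:2])cc1",
  "c1nc([*:1])nc(N([*:2])C)c1C",
  "c1cc([*:1])c2ccc([*:2])cc2c1"
)

.BENCH_FRAGMENTS <- c("", "C", "CC", "C(C)C", "O", "OC", "F", "Cl", "Br",
                      "C(F)(F)F", "C#N", "N(C)C")

#' Generate the multi-target synthetic benchmark
#'
#' Independent congeneric series, one per target, over built-in two-site
#' scaffold templates. Per-target substituent weights are drawn uniformly
#' from `weight_range` (hydrogen is the zero reference) and the base
#' activity from `base_range`; weights are resampled (bounded retries) until
#' the series yields at least `min_pairs` qualifying activity-cliff pairs
#' (potency difference >= `min_delta`, conservative shared-scaffold fraction
#' >= `mcs_threshold`).
#'
#' @param n_targets number of targets (default 5).
#' @param n_compounds analogs per target (default 80).
#' @param noise_sd label noise SD in pIC50 units (default 0.1).
#' @param seed master seed; per-target seeds are derived from it.
#' @param min_pairs minimum qualifying pairs per target (default 100, so a
#'   compound-level 80/20 split keeps well over 50 training pairs).
#' @param mcs_threshold,min_delta qualifying-pair thresholds (defaults 0.5
#'   and 1.0, matching the pairing module defaults).
#' @param weight_range,base_range sampling ranges for substituent weights
#'   and base activities (defaults keep pIC50 within roughly 4-10).
#' @param max_retries weight resampling budget per target.
#' @return list with `records` (all targets), `truth` (per target), and
#'   `scaffold_sizes` (heavy atoms per template).
#' @export
generate_benchmark <- function(n_targets = 5L, n_compounds = 80L,
                               noise_sd = 0.1, seed = 1L,
                               min_pairs = 100L,
                               mcs_threshold = 0.5, min_delta = 1.0,
                               weight_range = c(-1.05, 1.05),
                               base_range = c(6.6, 7.4),
                               max_retries = 20L) {
  stopifnot(n_targets >= 1L)
  templates <- rep_len(.BENCH_TEMPLATES, n_targets)
  all_records <- NULL
  truth <- list()
  scaffold_sizes <- integer(n_targets)
  for (t in seq_len(n_targets)) {
    tid <- sprintf("T%d", t)
    template <- templates[t]
    n_sites <- length(gregexpr("\\[\\*:", template)[[1]])
    bare <- .assemble(template, rep("", n_sites))
    scaffold_n <- .count_atoms(bare$smiles)
    scaffold_sizes[t] <- scaffold_n
    ok <- FALSE
    for (retry in seq_len(max_retries)) {
      sub_seed <- (seed * 1009L + t * 131L + retry) %% 2147483647L
      draws <- local_seed(sub_seed, {
        w <- stats::runif(length(.BENCH_FRAGMENTS) - 1L,
                          weight_range[1], weight_range[2])
        b <- stats::runif(1, base_range[1], base_range[2])
        list(w = w, b = b)
      })
      subs <- data.frame(fragment = .BENCH_FRAGMENTS,
                         weight = c(0, draws$w),
                         stringsAsFactors = FALSE)
      spec <- series_spec(template, subs, base_activity = draws$b,
                          noise_sd = noise_sd, n_compounds = n_compounds,
                          seed = sub_seed + 1L)
      ser <- generate_series(spec, target_id = tid)
      # cheap qualifying-pair count from the truth table: the MCS of two
      # analogs contains at least the scaffold, so min-fraction >=
      # scaffold_n / max(n_atoms)
      na <- vapply(ser$records$molecule, `[[`, integer(1), "n_atoms")
      act <- ser$records$activity
      qual <- 0L
      for (a in seq_len(length(act) - 1L)) {
        for (b2 in seq((a + 1L), length(act))) {
          if (abs(act[a] - act[b2]) >= min_delta &&
              scaffold_n / max(na[a], na[b2]) >= mcs_threshold) {
            qual <- qual + 1L
          }
        }
      }
      if (qual >= min_pairs) {
        all_records <- if (is.null(all_records)) ser$records else
          rbind(all_records, ser$records)
        truth[[tid]] <- ser$truth
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("target ", tid, ": could not reach ", min_pairs,
           " qualifying pairs within ", max_retries, " weight resamples")
    }
  }
  class(all_records) <- c("activity_records", "data.frame")
  attr(all_records, "n_skipped") <- 0L
  list(records = all_records, truth = truth, scaffold_sizes = scaffold_sizes)
}

#' Write a synthetic benchmark to disk
#'
#' Emits `dataset.csv` in the schema [read_table()] consumes plus
#' `truth.json` with the planted substituent ground truth.
#'
#' @param bench result of [generate_benchmark()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "dataset.csv")
  df <- bench$records[, c("smiles", "activity", "target_id", "compound_id")]
  utils::write.csv(df, csv, row.names = FALSE)
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(bench$truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
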