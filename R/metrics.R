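# Explainability metrics (global direction and color agreement), predictive
# metrics, and aggregation. Signs use a tolerance: values within eps of zero
# count as sign 0, which matches neither ground-truth sign — the
# conservative reading for an undefined case.

#' Global-direction metric for one pair
#'
#' Binary pair-level metric: 1 iff the difference of the mean attribution
#' over the uncommon atoms of the two compounds has the same sign as the
#' experimental activity difference.
#'
#' @param pair a `CompoundPair` (side i is the more potent compound).
#' @param attr_i,attr_j `Attribution`s covering all atoms of each compound.
#' @param eps zero tolerance for the sign (default 1e-12).
#' @return a `PairDirectionResult`: list with `pair_id`, `g_dir` (0/1),
#'   `mean_uncommon_i`, `mean_uncommon_j`.
#' @export
global_direction <- function(pair, attr_i, attr_j, eps = 1e-12) {
  if (length(pair$uncommon_i) == 0L || length(pair$uncommon_j) == 0L) {
    stop("pair ", pair$pair_id, " has an empty uncommon set; ",
         "it must be excluded from direction evaluation")
  }
  if (length(attr_i$atom_scores) != pair$mol_i$n_atoms ||
      length(attr_j$atom_scores) != pair$mol_j$n_atoms) {
    stop("attribution length does not match atom count")
  }
  mi <- mean(attr_i$atom_scores[pair$uncommon_i])
  mj <- mean(attr_j$atom_scores[pair$uncommon_j])
  dy <- pair$activity_i - pair$activity_j
  g <- as.integer(sign_eps(mi - mj, eps) == sign_eps(dy, eps) &&
                    sign_eps(dy, eps) != 0)
  structure(list(pair_id = pair$pair_id, g_dir = g,
                 mean_uncommon_i = mi, mean_uncommon_j = mj),
            class = "PairDirectionResult")
}

#' Color-agreement metric for one compound of a pair
#'
#' Per-atom agreement between the sign of the attribution score and the
#' ground-truth color (+1 on uncommon atoms of the more potent compound,
#' -1 on those of the less potent one), evaluated on the uncommon atoms.
#'
#' @param pair a `CompoundPair` with ground truth assigned.
#' @param compound_side `"i"` or `"j"`.
#' @param attr the compound's `Attribution`.
#' @param eps zero tolerance for the sign.
#' @return a `ColorAgreementResult`: list with `compound_id`,
#'   `per_atom_agreement` (0/1 vector over uncommon atoms), `mean`.
#' @export
color_agreement <- function(pair, compound_side = c("i", "j"), attr,
                            eps = 1e-12) {
  compound_side <- match.arg(compound_side)
  unc <- if (compound_side == "i") pair$uncommon_i else pair$uncommon_j
  gt <- if (compound_side == "i") pair$ground_truth_i else pair$ground_truth_j
  id <- if (compound_side == "i") pair$id_i else pair$id_j
  if (length(unc) == 0L) {
    stop("empty uncommon set on side ", compound_side, " of pair ",
         pair$pair_id)
  }
  agree <- as.integer(sign_eps(attr$atom_scores[unc], eps) == gt[unc])
  structure(list(compound_id = id, per_atom_agreement = agree,
                 mean = mean(agree)),
            class = "ColorAgreementResult")
}

#' Root mean squared error
#' @param y,yhat numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation coefficient
#'
#' Returns `NA` (with a warning) when either vector has zero variance.
#'
#' @param y,yhat numeric vectors of equal length (at least 2).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pcc <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(y, yhat)
}

#' Aggregate per-target metric values
#'
#' @param values numeric vector, one value per target (NAs dropped with
#'   their weights).
#' @param weights non-negative weights, typically test-pair counts.
#' @return list with `simple_mean`, `weighted_mean`, `sd`, `n`.
#' @export
aggregate_metric <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights))
  keep <- !is.na(values)
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0L) {
    return(list(simple_mean = NA_real_, weighted_mean = NA_real_,
                sd = NA_real_, n = 0L))
  }
  list(simple_mean = mean(values),
       weighted_mean = sum(values * weights) / sum(weights),
       sd = stats::sd(values),
       n = length(values))
}

#' Stratified metric summaries over per-pair results
#'
#' `mcs_threshold` strata are cumulative (pairs with shared-structure
#' fraction at least each grid value, mirroring a "minimum shared
#' substructure" sweep); `n_sites` contrasts single-site versus multi-site
#' pairs; `diversity_bin` cuts a per-pair diversity covariate into bins.
#'
#' @param pair_results data.frame with one row per evaluated pair; must
#'   contain the metric column and, depending on `by`, `mcs_fraction`,
#'   `n_sites`, or `diversity`.
#' @param by `"mcs_threshold"`, `"n_sites"`, or `"diversity_bin"`.
#' @param metric name of the metric column (default `"g_dir"`).
#' @param thresholds MCS grid (default `c(0.5, 0.6, 0.7, 0.8, 0.85, 0.9,
#'   0.95)`).
#' @param diversity_breaks breaks for the diversity bins.
#' @return data.frame with `stratum`, `n`, `mean` (NA for empty strata).
#' @export
stratify <- function(pair_results,
                     by = c("mcs_threshold", "n_sites", "diversity_bin"),
                     metric = "g_dir",
                     thresholds = c(0.5, 0.6, 0.7, 0.8, 0.85, 0.9, 0.95),
                     diversity_breaks = seq(0, 1, 0.25)) {
  by <- match.arg(by)
  stopifnot(metric %in% names(pair_results))
  val <- pair_results[[metric]]
  row <- function(stratum, idx) {
    data.frame(stratum = stratum, n = sum(idx),
               mean = if (sum(idx) > 0L) mean(val[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  if (by == "mcs_threshold") {
    out <- do.call(rbind, lapply(thresholds, function(th) {
      row(sprintf(">=%.2f", th), pair_results$mcs_fraction >= th)
    }))
  } else if (by == "n_sites") {
    out <- rbind(row("1", pair_results$n_sites == 1L),
                 row(">=2", pair_results$n_sites >= 2L))
  } else {
    bins <- cut(pair_results$diversity, breaks = diversity_breaks,
                include.lowest = TRUE)
    out <- do.call(rbind, lapply(levels(bins), function(lv) {
      row(lv, !is.na(bins) & bins == lv)
    }))
  }
  rownames(out) <- NULL
  out
}
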