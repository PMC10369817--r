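# The three training objectives: plain MSE on both pair members, the
# activity-cliff (AC) loss on the predicted potency difference, and the
# uncommon-node (UCN) loss tying the difference of masked substituent
# readouts to the experimental potency difference.

#' Pairwise MSE loss
#'
#' Squared prediction errors of both pair members:
#' `(y_i - yhat_i)^2 + (y_j - yhat_j)^2`.
#'
#' @param yhat_i,yhat_j predicted pIC50 of the two pair members.
#' @param y_i,y_j observed pIC50.
#' @return a non-negative scalar.
#' @export
mse_pair_loss <- function(yhat_i, yhat_j, y_i, y_j) {
  (y_i - yhat_i)^2 + (y_j - yhat_j)^2
}

#' Activity-cliff loss
#'
#' Squared error on the potency difference:
#' `((y_i - y_j) - (yhat_i - yhat_j))^2`. Invariant to a shared additive
#' shift of both predictions.
#'
#' @inheritParams mse_pair_loss
#' @return a non-negative scalar.
#' @export
ac_loss <- function(yhat_i, yhat_j, y_i, y_j) {
  ((y_i - y_j) - (yhat_i - yhat_j))^2
}

#' Uncommon-node loss
#'
#' Squared error between the difference of the two masked uncommon-node
#' readouts and the experimental potency difference:
#' `((u_i - u_j) - (y_i - y_j))^2`. This is the substructure-aware term: it
#' asks the atoms outside the pair's common substructure to explain the
#' activity difference.
#'
#' @param u_i,u_j uncommon-node readouts of the two pair members.
#' @param y_i,y_j observed pIC50.
#' @return a non-negative scalar.
#' @export
ucn_loss <- function(u_i, u_j, y_i, y_j) {
  if (is.null(u_i) || is.null(u_j) ||
      any(!is.finite(u_i)) || any(!is.finite(u_j))) {
    stop("ucn_loss requires both uncommon-node readouts")
  }
  ((u_i - u_j) - (y_i - y_j))^2
}

#' Total training loss for a batch of pairs
#'
#' `MSE` mode is the pairwise MSE alone; `MSE+AC` adds `lambda` times the
#' activity-cliff loss; `MSE+UCN` adds `lambda` times the uncommon-node
#' loss. The batch value is the mean over pairs, so `lambda` has the same
#' meaning at any batch size.
#'
#' @param yhat_i,yhat_j,y_i,y_j numeric vectors over the pairs of a batch.
#' @param u_i,u_j uncommon-node readouts (required for `MSE+UCN`).
#' @param mode one of `"MSE"`, `"MSE+AC"`, `"MSE+UCN"`.
#' @param lambda auxiliary-loss weight (default 1).
#' @return the scalar batch loss.
#' @export
total_loss <- function(yhat_i, yhat_j, y_i, y_j, u_i = NULL, u_j = NULL,
                       mode = c("MSE", "MSE+AC", "MSE+UCN"), lambda = 1.0) {
  mode <- match.arg(mode)
  base <- mse_pair_loss(yhat_i, yhat_j, y_i, y_j)
  aux <- switch(mode,
    "MSE" = 0,
    "MSE+AC" = ac_loss(yhat_i, yhat_j, y_i, y_j),
    "MSE+UCN" = ucn_loss(u_i, u_j, y_i, y_j)
  )
  mean(base + lambda * aux)
}
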