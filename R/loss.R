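# ---------------------------------------------------------------------------
# Training loss: squared-denominator DICE (weight 1) + binary cross-entropy
# (weight 0.25).
# ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @param dice_weight weight of the squared-denominator DICE term.
#' @param bce_weight weight of the pixel-mean binary cross-entropy term.
#' @return a `loss_config` list.
#' @export
loss_config <- function(dice_weight = 1.0, bce_weight = 0.25) {
  stopifnot(dice_weight >= 0, bce_weight >= 0)
  structure(list(dice_weight = dice_weight, bce_weight = bce_weight,
                 dice_variant = "squared_denominator"),
            class = "loss_config")
}

#' Squared-denominator DICE loss
#'
#' `1 - 2 * sum(p*t) / (sum(p^2) + sum(t^2))`, epsilon-guarded so an
#' all-empty pair is well defined. Zero iff prediction equals a binary
#' target exactly.
#'
#' @param pred probability raster in `[0, 1]`.
#' @param target binary raster of the same shape.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss_sq <- function(pred, target) {
  if (length(pred) == 0L || length(target) == 0L) stop("empty rasters")
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("pred and target shapes differ")
  eps <- 1e-7
  1 - 2 * sum(pred * target) / (sum(pred^2) + sum(target^2) + eps)
}

#' Combined DICE + BCE loss
#'
#' @param pred probability raster in `[0, 1]` (clipped internally for the
#'   BCE term).
#' @param target binary raster.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, cfg = loss_config()) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- mean(-target * log(p) - (1 - target) * log(1 - p))
  cfg$dice_weight * dice_loss_sq(pred, target) + cfg$bce_weight * bce
}

# autodiff version used by the training loop; takes logits for BCE stability
.ag_loss <- function(logits, target, cfg) {
  t_arr <- array(target, dim = dim(ag_val(logits)))
  tc <- ag_const(t_arr)
  p <- ag_sigmoid(logits)
  num <- ag_smul(ag_sum(ag_mul(p, tc)), 2)
  den <- ag_add(ag_add(ag_sum(ag_mul(p, p)), ag_const(sum(t_arr^2))), ag_const(1e-7))
  dice <- ag_sub(ag_const(1), ag_div(num, den))
  bce <- ag_bce_logits(logits, t_arr)
  ag_add(ag_smul(dice, cfg$dice_weight), ag_smul(bce, cfg$bce_weight))
}
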