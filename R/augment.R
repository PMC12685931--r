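# ---------------------------------------------------------------------------
# Episode augmentations: flips, rotations, contrast change, intensity
# flipping, blurring, Gaussian noise, and mask-edge targets. Geometric
# transforms are sampled once per episode and applied identically to every
# image and mask (masks with nearest-neighbour resampling); intensity
# transforms act on images only.
# ---------------------------------------------------------------------------

#' Augmentation configuration
#'
#' @param p default per-augmentation application probability.
#' @param p_mask_edge probability of the mask-edge-as-target augmentation
#'   (kept lower by default because it redefines the episode's target).
#' @return named numeric vector of probabilities.
#' @export
augment_config <- function(p = 0.25, p_mask_edge = 0.1) {
  c(hflip = p, vflip = p, rotate = p, contrast = p,
    intensity_flip = p, blur = p, noise = p, mask_edge = p_mask_edge)
}

.rot_matrix <- function(angle_deg, H, W) {
  th <- angle_deg * pi / 180
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  # EBImage::affine maps output px through m; build center rotation
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  off <- c(cx, cy) - R %*% c(cx, cy)
  rbind(R, t(off))
}

.apply_geom <- function(x, ops, is_mask) {
  for (op in ops) {
    x <- switch(op$name,
      hflip = x[, ncol(x):1],
      vflip = x[nrow(x):1, ],
      rotate = {
        filt <- if (is_mask) "none" else "bilinear"
        y <- EBImage::affine(x, .rot_matrix(op$angle, nrow(x), ncol(x)),
                             filter = filt, output.dim = dim(x), bg.col = 0)
        as.matrix(y)
      },
      x)
  }
  if (is_mask) x <- (x > 0.5) * 1
  x
}

.apply_intensity <- function(x, ops) {
  for (op in ops) {
    x <- switch(op$name,
      contrast = pmin(pmax(x, 0), 1)^op$gamma,
      intensity_flip = 1 - x,
      blur = as.matrix(EBImage::gblur(x, sigma = op$sigma)),
      noise = x + matrix(stats::rnorm(length(x), sd = op$sd), nrow(x)),
      x)
  }
  pmin(pmax(x, 0), 1)
}

#' Extract the boundary band of a mask
#'
#' Pixels of the mask within `band` pixels of its boundary (the mask minus
#' its erosion by a (2*band+1) box), used by the mask-edge-as-target
#' augmentation.
#'
#' @param mask binary matrix.
#' @param band band width in pixels.
#' @return binary matrix of the boundary band.
#' @export
mask_edge_band <- function(mask, band = 1L) {
  er <- as.matrix(EBImage::erode(mask, EBImage::makeBrush(2L * band + 1L, "box")))
  (mask > 0.5 & er < 0.5) * 1
}

#' Augment an episode
#'
#' Each augmentation is applied independently with its configured
#' probability, using the current R random number generator state.
#'
#' @param episode episode list (`query_image`, `query_mask`,
#'   `support_images`, `support_masks`).
#' @param cfg probabilities from [augment_config()].
#' @return augmented episode.
#' @export
augment <- function(episode, cfg = augment_config()) {
  on <- function(name) stats::runif(1) < cfg[[name]]
  geom <- list()
  if (on("hflip")) geom <- c(geom, list(list(name = "hflip")))
  if (on("vflip")) geom <- c(geom, list(list(name = "vflip")))
  if (on("rotate")) geom <- c(geom, list(list(name = "rotate",
                                              angle = stats::runif(1, -30, 30))))
  inten <- list()
  if (on("contrast")) inten <- c(inten, list(list(name = "contrast",
                                                  gamma = stats::runif(1, 0.7, 1.4))))
  if (on("intensity_flip")) inten <- c(inten, list(list(name = "intensity_flip")))
  if (on("blur")) inten <- c(inten, list(list(name = "blur",
                                              sigma = stats::runif(1, 0.5, 1.5))))
  if (on("noise")) inten <- c(inten, list(list(name = "noise",
                                               sd = stats::runif(1, 0, 0.05))))
  edge <- on("mask_edge")

  tx_img <- function(img) .apply_intensity(.apply_geom(img, geom, FALSE), inten)
  tx_msk <- function(m) {
    m <- .apply_geom(m, geom, TRUE)
    if (edge) m <- mask_edge_band(m)
    m
  }
  episode$query_image <- tx_img(episode$query_image)
  episode$query_mask <- tx_msk(episode$query_mask)
  episode$support_images <- lapply(episode$support_images, tx_img)
  episode$support_masks <- lapply(episode$support_masks, tx_msk)
  episode
}
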