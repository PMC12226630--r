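#' Augmentation specification
#'
#' The stochastic image transform family used both for contrastive view
#' generation and for the augmented-view voting ensemble: random horizontal
#' flips, rotations up to `max_rotation_deg` degrees, shifts up to
#' `max_shift_px` pixels along both axes, and brightness/contrast scaling
#' drawn from the given ranges (defaults 0.7-1.3).
#'
#' @param hflip_prob probability of a horizontal flip.
#' @param max_rotation_deg maximum absolute rotation, degrees.
#' @param max_shift_px maximum absolute shift, pixels (each axis).
#' @param brightness_range multiplicative brightness range; must contain 1.
#' @param contrast_range contrast-gain range about the image mean; must
#'   contain 1.
#' @param zoom_range scale range for a random centred zoom (the resized-crop
#'   analogue); must contain 1, default `c(1, 1)` (off).
#' @return an object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(hflip_prob = 0.5, max_rotation_deg = 15,
                              max_shift_px = 12,
                              brightness_range = c(0.7, 1.3),
                              contrast_range = c(0.7, 1.3),
                              zoom_range = c(1, 1)) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, max_rotation_deg >= 0,
            max_shift_px >= 0,
            brightness_range[1] <= 1, brightness_range[2] >= 1,
            contrast_range[1] <= 1, contrast_range[2] >= 1,
            zoom_range[1] <= 1, zoom_range[2] >= 1, zoom_range[1] > 0)
  structure(list(hflip_prob = hflip_prob,
                 max_rotation_deg = max_rotation_deg,
                 max_shift_px = max_shift_px,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 zoom_range = zoom_range),
            class = "augmentation_spec")
}

#' The identity member of the augmentation family
#' @return an `augmentation_spec` whose every transform is the identity.
#' @export
identity_augmentation <- function() {
  augmentation_spec(hflip_prob = 0, max_rotation_deg = 0, max_shift_px = 0,
                    brightness_range = c(1, 1), contrast_range = c(1, 1))
}

#' Apply one random augmentation draw to an image
#'
#' Geometric transforms (flip, rotation, shift) are applied before the
#' photometric ones; out-of-frame pixels are filled with 0 and the result is
#' clipped to `[0, 1]`. Transform parameters are drawn from the current RNG.
#' When every range collapses to the identity the input is returned
#' unmodified (bitwise), so an identity spec is exactly the identity map.
#'
#' @param img intensity matrix in `[0, 1]`.
#' @param aug an [augmentation_spec()].
#' @return a matrix with the same dimensions as `img`.
#' @export
random_augment <- function(img, aug) {
  if (aug$hflip_prob > 0 && runif(1) < aug$hflip_prob) {
    img <- img[, ncol(img):1, drop = FALSE]
  }
  if (diff(aug$zoom_range) > 0) {
    z <- runif(1, aug$zoom_range[1], aug$zoom_range[2])
    img <- center_zoom(img, z)
  }
  if (aug$max_rotation_deg > 0) {
    ang <- runif(1, -aug$max_rotation_deg, aug$max_rotation_deg)
    img <- EBImage::rotate(img, ang, output.dim = dim(img), bg.col = 0)
  }
  if (aug$max_shift_px > 0) {
    sh <- sample(seq(-aug$max_shift_px, aug$max_shift_px), 2, replace = TRUE)
    if (any(sh != 0)) img <- EBImage::translate(img, sh, bg.col = 0)
  }
  b <- if (diff(aug$brightness_range) > 0)
    runif(1, aug$brightness_range[1], aug$brightness_range[2]) else
      aug$brightness_range[1]
  if (b != 1) img <- img * b
  g <- if (diff(aug$contrast_range) > 0)
    runif(1, aug$contrast_range[1], aug$contrast_range[2]) else
      aug$contrast_range[1]
  if (g != 1) img <- mean(img) + g * (img - mean(img))
  if (b != 1 || g != 1 || aug$max_rotation_deg > 0 ||
      diff(aug$zoom_range) > 0) img <- clip01(img)
  img
}

# Zoom about the image centre by factor z (> 1 enlarges), keeping the
# original dimensions; out-of-frame pixels are background (0).
center_zoom <- function(img, z) {
  h <- nrow(img); w <- ncol(img)
  big <- EBImage::resize(img, w = max(2, round(h * z)),
                         h = max(2, round(w * z)))
  hb <- nrow(big); wb <- ncol(big)
  out <- matrix(0, h, w)
  if (z >= 1) {
    r0 <- floor((hb - h) / 2); c0 <- floor((wb - w) / 2)
    out <- big[r0 + seq_len(h), c0 + seq_len(w)]
  } else {
    r0 <- floor((h - hb) / 2); c0 <- floor((w - wb) / 2)
    out[r0 + seq_len(hb), c0 + seq_len(wb)] <- big
  }
  out
}

#' Generate a contrastive view pair
#'
#' Two independent random transforms of the same image; neither is forced
#' to be the identity.
#'
#' @param img intensity matrix.
#' @param aug an [augmentation_spec()].
#' @return list with elements `xi` and `xj`.
#' @export
make_simclr_views <- function(img, aug) {
  list(xi = random_augment(img, aug), xj = random_augment(img, aug))
}

#' Build the augmented-view ensemble of an image
#'
#' Returns `A(x) = {R_1(x) = x, R_2(x), ..., R_T(x)}`: the first view is
#' always the identity transform, the remaining `n_views - 1` are
#' independent random draws from the augmentation family.
#'
#' @param img intensity matrix.
#' @param aug an [augmentation_spec()].
#' @param n_views ensemble size T (>= 1).
#' @return list of `n_views` matrices.
#' @export
augmented_views <- function(img, aug, n_views) {
  stopifnot(n_views >= 1)
  c(list(img), lapply(seq_len(n_views - 1L),
                      function(i) random_augment(img, aug)))
}
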