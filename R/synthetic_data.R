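#' Acquisition-shift specification for a synthetic client
#'
#' Models the site-to-site appearance differences of ultrasound scanners
#' (different vendors, gain settings, probe characteristics) as a brightness
#' offset, a contrast gain and multiplicative speckle noise. The shift is
#' applied after the anatomical geometry is drawn, and the image is
#' re-clipped to `[0, 1]`.
#'
#' @param brightness_offset additive intensity shift.
#' @param contrast_gain multiplicative intensity factor.
#' @param speckle_sigma standard deviation of multiplicative Gaussian
#'   speckle, i.e. pixels are scaled by `1 + speckle_sigma * N(0, 1)`.
#' @return an object of class `client_shift`.
#' @export
client_shift <- function(brightness_offset = 0, contrast_gain = 1,
                         speckle_sigma = 0) {
  stopifnot(is.numeric(brightness_offset), is.numeric(contrast_gain),
            speckle_sigma >= 0)
  structure(list(brightness_offset = brightness_offset,
                 contrast_gain = contrast_gain,
                 speckle_sigma = speckle_sigma),
            class = "client_shift")
}

#' Default acquisition shift of the non-representative client
#'
#' A moderate cross-vendor photometric shift (brightness +0.03, contrast
#' gain 1.05, speckle 0.03) used as the default distribution shift of the
#' small client in experiments.
#'
#' @return a [client_shift()].
#' @export
default_norepr_shift <- function() {
  client_shift(brightness_offset = 0.03, contrast_gain = 1.05,
               speckle_sigma = 0.03)
}

apply_client_shift <- function(pixels, shift) {
  if (shift$speckle_sigma > 0) {
    pixels <- pixels * (1 + shift$speckle_sigma * matrix(rnorm(length(pixels)),
                                                         nrow(pixels)))
  }
  clip01(pixels * shift$contrast_gain + shift$brightness_offset)
}

# Rotated-ellipse interior mask on [-1,1]^2 coordinates.
ellipse_mask <- function(gx, gy, cx, cy, a, b, theta = 0) {
  xr <- (gx - cx) * cos(theta) + (gy - cy) * sin(theta)
  yr <- -(gx - cx) * sin(theta) + (gy - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate one synthetic standard-plane image
#'
#' Draws a grayscale image whose dominant geometric primitive is determined
#' by the class, mimicking the discriminative geometry of the four fetal
#' standard planes: abdomen (filled ellipse with a bright internal dot),
#' brain (bright elliptical ring), femur (bright elongated bar at a random
#' angle) and thorax (ellipse containing 2-4 dark chamber blobs). Position,
#' scale and orientation are jittered, then the client acquisition shift is
#' applied. Randomness is drawn from the current R random number generator;
#' wrap calls in [withr::with_seed()] (or use [gen_client_dataset()]) for
#' reproducibility.
#'
#' @param label class id in `0:3` (0 abdomen, 1 brain, 2 femur, 3 thorax).
#' @param shift a [client_shift()] object.
#' @param size image side length in pixels (square, at least 32).
#' @return a `size x size` matrix of intensities in `[0, 1]`.
#' @export
gen_plane_image <- function(label, shift = client_shift(), size = 64) {
  if (length(label) != 1 || !label %in% 0:3) {
    stop("`label` must be a single class id in 0:3")
  }
  stopifnot(size >= 32)
  ax <- seq(-1, 1, length.out = size)
  gx <- matrix(ax, size, size)
  gy <- matrix(ax, size, size, byrow = TRUE)

  cx <- runif(1, -0.1, 0.1)
  cy <- runif(1, -0.1, 0.1)
  s  <- runif(1, 0.9, 1.1)
  th <- runif(1, 0, pi)

  img <- matrix(0.05, size, size)
  if (label == 0L) {                     # abdomen: filled ellipse + stomach dot
    body <- ellipse_mask(gx, gy, cx, cy, 0.55 * s, 0.48 * s, th)
    img[body] <- 0.45
    da <- runif(1, 0, 2 * pi)
    dot <- ellipse_mask(gx, gy, cx + 0.2 * s * cos(da), cy + 0.2 * s * sin(da),
                        0.09 * s, 0.09 * s)
    img[dot & body] <- 0.95
  } else if (label == 1L) {              # brain: bright skull ring
    outer <- ellipse_mask(gx, gy, cx, cy, 0.62 * s, 0.46 * s, th)
    inner <- ellipse_mask(gx, gy, cx, cy, 0.45 * s, 0.31 * s, th)
    img[inner] <- 0.25
    img[outer & !inner] <- 0.95
  } else if (label == 2L) {              # femur: thin bright bar
    bar <- ellipse_mask(gx, gy, cx, cy, 0.55 * s, 0.06 * s, th)
    img[bar] <- 0.95
  } else {                               # thorax: ellipse with dark chambers
    body <- ellipse_mask(gx, gy, cx, cy, 0.6 * s, 0.52 * s, th)
    img[body] <- 0.8
    n_ch <- sample(2:4, 1)
    angs <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_ch) / n_ch
    for (a in angs) {
      ch <- ellipse_mask(gx, gy, cx + 0.24 * s * cos(a), cy + 0.24 * s * sin(a),
                         0.13 * s, 0.13 * s)
      img[ch & body] <- 0.08
    }
  }
  apply_client_shift(img, shift)
}

new_plane_dataset <- function(images, labels, client, country, split = NULL) {
  n <- length(images)
  structure(list(images = images,
                 labels = as.integer(labels),
                 client = rep_len(as.character(client), n),
                 country = rep_len(as.character(country), n),
                 split = if (is.null(split)) rep(NA_character_, n)
                         else rep_len(split, n)),
            class = "plane_dataset")
}

#' @export
length.plane_dataset <- function(x) length(x$images)

#' @export
print.plane_dataset <- function(x, ...) {
  cat("<plane_dataset> ", length(x), " images, ",
      nrow(x$images[[1]]), "x", ncol(x$images[[1]]), "\n", sep = "")
  cat("  clients:  ", paste(unique(x$client), collapse = ", "), "\n", sep = "")
  cat("  countries:", paste(unique(x$country), collapse = ", "), "\n")
  print(table(label = CLASS_NAMES[x$labels + 1], split = x$split,
              useNA = "ifany"))
  invisible(x)
}

#' Subset a plane dataset
#' @param x a `plane_dataset`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.plane_dataset` <- function(x, i, ...) {
  new_plane_dataset(x$images[i], x$labels[i], x$client[i], x$country[i],
                    x$split[i])
}

#' Concatenate plane datasets
#' @param ... `plane_dataset` objects.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  new_plane_dataset(do.call(c, lapply(ds, `[[`, "images")),
                    do.call(c, lapply(ds, `[[`, "labels")),
                    do.call(c, lapply(ds, `[[`, "client")),
                    do.call(c, lapply(ds, `[[`, "country")),
                    do.call(c, lapply(ds, `[[`, "split")))
}

#' Generate a balanced synthetic client dataset
#'
#' @param n_per_class number of images per class (>= 1).
#' @param shift a [client_shift()] describing the client's acquisition.
#' @param client client id string.
#' @param country country tag.
#' @param seed integer seed; the output is bit-reproducible.
#' @param size image side length.
#' @return a `plane_dataset` with `4 * n_per_class` images in shuffled order.
#' @export
gen_client_dataset <- function(n_per_class, shift = client_shift(),
                               client = "client", country = client,
                               seed = 1, size = 64) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  withr::with_seed(seed, {
    labels <- rep(0:3, each = n_per_class)
    labels <- labels[sample.int(length(labels))]
    images <- lapply(labels, gen_plane_image, shift = shift, size = size)
  })
  new_plane_dataset(images, labels, client, country)
}

#' Assign stratified train/val/test splits
#'
#' Splits are stratified jointly by label and country so that every
#' country's test portion contains every class it has samples of.
#'
#' @param ds a `plane_dataset`.
#' @param fractions named fractions for train/val/test, summing to 1.
#' @param seed integer seed.
#' @return the dataset with its `split` field populated.
#' @export
assign_splits <- function(ds, fractions = c(train = 0.7, val = 0.1, test = 0.2),
                          seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "val", "test") %in% names(fractions)))
  split <- rep(NA_character_, length(ds))
  withr::with_seed(seed, {
    for (g in split(seq_along(ds$labels),
                    paste(ds$labels, ds$country))) {
      g <- g[sample.int(length(g))]
      n <- length(g)
      n_test <- round(fractions[["test"]] * n)
      n_val <- round(fractions[["val"]] * n)
      take <- rep("train", n)
      if (n_test > 0) take[seq_len(n_test)] <- "test"
      if (n_val > 0) take[n_test + seq_len(min(n_val, n - n_test))] <- "val"
      split[g] <- take
    }
  })
  ds$split <- split
  ds
}

#' Inject symmetric label noise
#'
#' Selects exactly `round(rate * n)` positions by sampling without
#' replacement (so the realized noise rate equals the nominal rate), and
#' replaces each selected label. In `symmetric_exclusive` mode the new label
#' is drawn uniformly from the *other* classes; in `symmetric_inclusive`
#' mode it is drawn uniformly from all classes and may coincide with the
#' original.
#'
#' @param labels integer class ids.
#' @param rate noise fraction in `[0, 1]`.
#' @param model noise model.
#' @param seed integer seed.
#' @param classes class universe; defaults to the classes present.
#' @return the noisy label vector, with a logical attribute `"flipped"`
#'   marking the selected positions.
#' @export
inject_label_noise <- function(labels, rate,
                               model = c("symmetric_exclusive",
                                         "symmetric_inclusive"),
                               seed = 1, classes = NULL) {
  model <- match.arg(model)
  stopifnot(length(labels) > 0, rate >= 0, rate <= 1)
  labels <- as.integer(labels)
  classes <- as.integer(classes %||% sort(unique(labels)))
  if (rate > 0 && model == "symmetric_exclusive" && length(classes) < 2) {
    stop("exclusive noise requires at least 2 classes")
  }
  n <- length(labels)
  n_flip <- round(rate * n)
  flipped <- rep(FALSE, n)
  out <- labels
  if (n_flip > 0) {
    withr::with_seed(seed, {
      idx <- sample.int(n, n_flip)
      if (model == "symmetric_exclusive") {
        out[idx] <- vapply(labels[idx], function(y) {
          pool <- classes[classes != y]
          pool[sample.int(length(pool), 1)]
        }, integer(1))
      } else {
        out[idx] <- classes[sample.int(length(classes), n_flip, replace = TRUE)]
      }
    })
    flipped[idx] <- TRUE
  }
  attr(out, "flipped") <- flipped
  out
}

#' Generate Gaussian-mixture embeddings with equidistant class means
#'
#' Emulates the latent space produced by contrastive pretraining: one
#' isotropic Gaussian cluster per class. For `dim >= n_classes` the class
#' means are placed at `separation / sqrt(2)` along mutually orthogonal
#' axes, which makes all pairwise mean distances exactly `separation`.
#' For `dim < n_classes` the means fall back to equally spaced points
#' along the first axis (adjacent distance `separation`, non-adjacent
#' larger).
#'
#' @param n_classes number of classes (>= 2).
#' @param dim embedding dimension.
#' @param n_per_class points per class.
#' @param separation pairwise distance between class means (> 0).
#' @param sigma within-class standard deviation (> 0 per coordinate).
#' @param seed integer seed.
#' @return list with `embeddings` (n x dim matrix), `labels` (0-based ids)
#'   and `means` (n_classes x dim).
#' @export
gen_embedding_clusters <- function(n_classes = 4, dim = 32, n_per_class = 400,
                                   separation = 6, sigma = 1, seed = 1) {
  stopifnot(n_classes >= 2, separation > 0, sigma > 0, n_per_class >= 1,
            dim >= 1)
  means <- matrix(0, n_classes, dim)
  if (dim >= n_classes) {
    for (c in seq_len(n_classes)) means[c, c] <- separation / sqrt(2)
  } else {
    means[, 1] <- separation * (seq_len(n_classes) - 1)
  }
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  emb <- withr::with_seed(seed,
    means[labels + 1L, , drop = FALSE] + matrix(rnorm(n * dim, sd = sigma),
                                                n, dim))
  list(embeddings = emb, labels = labels, means = means)
}
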