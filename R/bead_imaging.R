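# Synthetic brightfield bead images and a counting pipeline.
#
# Beads (monodisperse, ~2.7 um) appear as dark disks on a bright background
# in brightfield; the counter reconstructs the classic recipe for such data:
# automatic intensity threshold, connected components, and an area filter
# that can split merged objects into multiples of the single-bead area.

#' Specification of a synthetic brightfield bead image
#'
#' Intensities are on a [0, 1] scale (1 = white background).
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size, um/px (default 0.325, a 20x
#'   objective on a typical sCMOS sensor).
#' @param bead_radius_um bead radius, um (default 1.35).
#' @param n_beads number of beads to place (>= 0).
#' @param background_level background intensity (default 0.85).
#' @param bead_contrast intensity drop at a bead centre (default 0.5).
#' @param noise_sd additive Gaussian noise SD (default 0).
#' @param min_separation_um minimum centre-to-centre distance; defaults to
#'   one bead diameter plus two pixels (non-overlapping).
#' @param seed optional integer seed.
#' @return an object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(width_px = 512, height_px = 512,
                                 pixel_size_um = 0.325, bead_radius_um = 1.35,
                                 n_beads = 100, background_level = 0.85,
                                 bead_contrast = 0.5, noise_sd = 0,
                                 min_separation_um = NULL, seed = NULL) {
  if (width_px < 1 || height_px < 1 || pixel_size_um <= 0 || bead_radius_um <= 0)
    stop_invalid("invalid image spec: dimensions must be positive")
  if (n_beads < 0) stop_invalid("invalid image spec: n_beads must be >= 0")
  if (noise_sd < 0) stop_invalid("invalid image spec: noise_sd must be >= 0")
  if (is.null(min_separation_um))
    min_separation_um <- 2 * bead_radius_um + 2 * pixel_size_um
  structure(list(width = as.integer(width_px), height = as.integer(height_px),
                 pixel_size = pixel_size_um, bead_radius = bead_radius_um,
                 n_beads = as.integer(n_beads),
                 background_level = background_level,
                 bead_contrast = bead_contrast, noise_sd = noise_sd,
                 min_separation = min_separation_um, seed = seed),
            class = "synthetic_image_spec")
}

#' Render a synthetic brightfield bead image
#'
#' Beads are drawn as dark anti-aliased disks (linear edge coverage) at
#' uniformly random positions honouring the minimum separation; Gaussian
#' noise is added last. Pixel convention: the matrix is indexed
#' `[y + 1, x + 1]` with the origin at the top-left pixel centre, x
#' rightward, y downward. The true centres are attached as
#' `attr(img, "centers")` (columns `x`, `y`, 0-based pixel coordinates).
#'
#' @param spec a [synthetic_image_spec()].
#' @return a `height x width` numeric matrix with values clipped to [0, 1].
#' @export
render_beads <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  r_px <- spec$bead_radius / spec$pixel_size
  sep_px <- spec$min_separation / spec$pixel_size
  img <- matrix(spec$background_level, nrow = spec$height, ncol = spec$width)
  centers <- with_seed_opt(spec$seed, {
    place_beads(spec$n_beads, spec$width, spec$height, r_px, sep_px)
  })
  if (spec$n_beads > 0) {
    for (i in seq_len(nrow(centers))) {
      img <- .stamp_disk(img, centers[i, 1], centers[i, 2], r_px,
                         spec$bead_contrast)
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + with_seed_opt(
      if (is.null(spec$seed)) NULL else spec$seed + 1L,
      matrix(rnorm(length(img), 0, spec$noise_sd), nrow = spec$height))
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "centers") <- centers
  img
}

# Rejection-sample n non-overlapping centres (0-based pixel coordinates),
# keeping each disk fully inside the frame.
place_beads <- function(n, width, height, r_px, sep_px) {
  centers <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  if (n == 0) return(centers)
  margin <- r_px + 1
  if (width - 2 * margin <= 0 || height - 2 * margin <= 0)
    stop_invalid("placement error: image too small for the bead radius")
  max_tries <- 500L * n
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop_invalid("placement error: could not place ", n, " beads at ",
                   "the requested minimum separation")
    cand <- c(runif(1, margin, width - 1 - margin),
              runif(1, margin, height - 1 - margin))
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
            sep_px^2)) {
      centers <- rbind(centers, cand)
    }
  }
  dimnames(centers) <- list(NULL, c("x", "y"))
  centers
}

# Subtract an anti-aliased disk of depth `contrast` centred at (cx, cy)
# (0-based) from the image; linear coverage ramp across the disk edge.
.stamp_disk <- function(img, cx, cy, r_px, contrast) {
  x0 <- max(0L, floor(cx - r_px - 1)); x1 <- min(ncol(img) - 1L, ceiling(cx + r_px + 1))
  y0 <- max(0L, floor(cy - r_px - 1)); y1 <- min(nrow(img) - 1L, ceiling(cy + r_px + 1))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov <- pmin(pmax(r_px + 0.5 - d, 0), 1)
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] - contrast * cov
  img
}

#' Count beads in a brightfield image
#'
#' Pipeline: normalise intensities, automatic Otsu threshold (beads dark),
#' connected-component labelling, then an area filter: objects within
#' `tolerance` of the expected single-bead area count as one bead; objects
#' near `k` times that area (k up to `cluster_cap`) count as `k` beads;
#' anything else is rejected with a reason. Normalisation makes the count
#' invariant to a global intensity offset.
#'
#' @param image numeric matrix (single-channel), as from [render_beads()] or
#'   [read_bead_image()].
#' @param pixel_size_um pixel size, um/px.
#' @param expected_radius_um expected bead radius, um (default 1.35).
#' @param tolerance fractional area tolerance (default 0.4).
#' @param cluster_cap maximum number of beads attributed to one merged
#'   object (default 3).
#' @return an object of class `bead_count_report`: a list with `count`,
#'   `centroids` (data frame, 0-based pixel coordinates, one row per
#'   counted bead) and `rejected_objects` (data frame with areas and
#'   reasons).
#' @export
count_beads <- function(image, pixel_size_um = 0.325,
                        expected_radius_um = 1.35, tolerance = 0.4,
                        cluster_cap = 3) {
  if (!is.matrix(image) || length(image) == 0 || any(!is.finite(image)))
    stop_invalid("invalid image: need a non-empty finite numeric matrix")
  rng <- range(image)
  report_empty <- function() {
    structure(list(count = 0L,
                   centroids = data.frame(x = numeric(0), y = numeric(0)),
                   rejected_objects = data.frame(area_px = numeric(0),
                                                 reason = character(0))),
              class = "bead_count_report")
  }
  if (diff(rng) == 0) return(report_empty())  # featureless frame
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm < thr                      # beads are dark
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(labels))
  n_obj <- max(lab)
  if (n_obj == 0) return(report_empty())
  areas <- tabulate(lab[lab > 0], nbins = n_obj)
  a_bead <- pi * (expected_radius_um / pixel_size_um)^2
  cx <- rep(0, n_obj); cy <- rep(0, n_obj)
  nz <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  cx <- tapply(nz[, "col"] - 1, lv, mean)
  cy <- tapply(nz[, "row"] - 1, lv, mean)
  mult <- rep(NA_integer_, n_obj)
  reason <- rep(NA_character_, n_obj)
  for (j in seq_len(n_obj)) {
    k <- round(areas[j] / a_bead)
    if (k >= 1 && k <= cluster_cap &&
        areas[j] >= k * a_bead * (1 - tolerance) &&
        areas[j] <= k * a_bead * (1 + tolerance)) {
      mult[j] <- k
    } else {
      reason[j] <- if (areas[j] < a_bead * (1 - tolerance)) "too_small"
                   else if (k > cluster_cap) "too_large"
                   else "ambiguous_area"
    }
  }
  counted <- which(!is.na(mult))
  centroids <- data.frame(
    x = rep(as.numeric(cx[as.character(counted)]), mult[counted]),
    y = rep(as.numeric(cy[as.character(counted)]), mult[counted]))
  rejected <- data.frame(area_px = areas[is.na(mult)],
                         reason = reason[is.na(mult)])
  structure(list(count = nrow(centroids), centroids = centroids,
                 rejected_objects = rejected),
            class = "bead_count_report")
}

#' @export
print.bead_count_report <- function(x, ...) {
  cat(sprintf("<bead_count_report> %d beads counted, %d objects rejected\n",
              x$count, nrow(x$rejected_objects)))
  invisible(x)
}

#' Write / read a bead image as 16-bit grayscale TIFF
#'
#' @param image numeric matrix with values in [0, 1].
#' @param path file path.
#' @return `write_bead_image` returns `path` invisibly; `read_bead_image`
#'   returns a numeric matrix in [0, 1].
#' @export
write_bead_image <- function(image, path) {
  if (!is.matrix(image)) stop_invalid("invalid image: need a matrix")
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_bead_image
#' @export
read_bead_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
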