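# VOI definition: SUV-threshold isocontours and concentric spherical VOIs.

new_voi_mask <- function(data, spacing, meta = list()) {
  structure(
    list(data = data, spacing = as.numeric(spacing), meta = meta),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(
    "<voi_mask> ", sum(x$data), " voxels, ",
    signif(voi_volume(x), 4), " ml\n",
    sep = ""
  )
  invisible(x)
}

check_alignment <- function(image, mask) {
  if (!all(dim(image$data) == dim(mask$data)) ||
    !isTRUE(all.equal(image$spacing, mask$spacing))) {
    abort("mask is not aligned with the image.", class = "pethet_format_error")
  }
}

# logical array marking voxels inside a world-mm box (list(lower, upper))
box_mask <- function(dim, spacing, box) {
  co <- grid_coords(dim, spacing)
  co$x >= box$lower[1] & co$x <= box$upper[1] &
    co$y >= box$lower[2] & co$y <= box$upper[2] &
    co$z >= box$lower[3] & co$z <= box$upper[3]
}

expand_box <- function(box, by_mm) {
  list(lower = box$lower - by_mm, upper = box$upper + by_mm)
}

#' Threshold-based lesion segmentation
#'
#' Isocontour segmentation of the lesion-like high-uptake volume: voxels
#' strictly above an absolute cut (patient convention, e.g. SUV = 2.5) or
#' above `threshold` times the background mean (phantom convention,
#' 2.5 x background), optionally restricted to a bounding box, keeping the
#' largest 26-connected component.
#'
#' @param image An `image_volume`.
#' @param mode `"relative"` (cut = `threshold` x background mean) or
#'   `"absolute"` (cut = `threshold` in image units).
#' @param threshold The threshold (default 2.5 in both conventions).
#' @param background Background estimate for relative mode: a `voi_mask`, a
#'   logical array, or a single numeric mean.  If `NULL` and `box` is given,
#'   the mean of a 10 mm-thick shell starting 20 mm outside the box is used.
#' @param box Optional bounding box, `list(lower=, upper=)` in world mm.
#' @param largest_component Keep only the largest 26-connected component?
#' @return A `voi_mask`; `meta` records the mode, cut value and background
#'   mean used.
#' @export
threshold_segment <- function(image, mode = c("relative", "absolute"),
                              threshold = 2.5, background = NULL, box = NULL,
                              largest_component = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "image_volume"))
  d <- dim(image$data)
  bg_mean <- NA_real_
  if (mode == "relative") {
    if (is.null(background)) {
      if (is.null(box)) {
        abort("relative mode needs a background region or a bounding box.",
          class = "pethet_segmentation_error"
        )
      }
      shell <- box_mask(d, image$spacing, expand_box(box, 30)) &
        !box_mask(d, image$spacing, expand_box(box, 20))
      if (!any(shell)) {
        abort("auto background shell is empty.", class = "pethet_segmentation_error")
      }
      bg_mean <- mean(image$data[shell])
    } else if (inherits(background, "voi_mask")) {
      bg_mean <- mean(image$data[background$data])
    } else if (is.logical(background)) {
      bg_mean <- mean(image$data[background])
    } else {
      bg_mean <- as.numeric(background)
    }
    if (!is.finite(bg_mean) || bg_mean <= 0) {
      abort("background mean must be positive in relative mode.",
        class = "pethet_segmentation_error"
      )
    }
    cut <- threshold * bg_mean
  } else {
    cut <- threshold
  }
  cand <- image$data > cut
  if (!is.null(box)) cand <- cand & box_mask(d, image$spacing, box)
  if (!any(cand)) {
    abort("no voxels above threshold.", class = "pethet_segmentation_error")
  }
  cand <- array(cand, d)
  if (largest_component) {
    lab <- label_components_26(cand)
    sizes <- tabulate(lab[lab > 0L])
    cand <- lab == which.max(sizes)
  }
  new_voi_mask(
    array(cand, d), image$spacing,
    meta = list(mode = mode, threshold = threshold, cut = cut, background_mean = bg_mean)
  )
}

#' Concentric spherical VOI
#'
#' Sphere of the requested volume centred at `center_mm`, used to probe
#' volume dependence on the homogeneous phantom with VOIs from 0.5 to
#' 1000 ml.  The sphere must fit inside the image grid and, when `within` is
#' supplied, inside the phantom, so that background never contaminates the
#' homogeneity curves.
#'
#' @param image An `image_volume`.
#' @param center_mm Sphere centre in world mm (default the grid centre).
#' @param volume_ml Requested volume in ml; the radius is
#'   `(3 V / 4 pi)^(1/3)`.
#' @param within Optional logical array (or `voi_mask`) the sphere must stay
#'   inside, typically the phantom interior.
#' @return A `voi_mask` containing the voxels whose centres lie within the
#'   radius.
#' @export
spherical_voi <- function(image, center_mm = c(0, 0, 0), volume_ml, within = NULL) {
  stopifnot(inherits(image, "image_volume"), volume_ml > 0)
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  d <- dim(image$data)
  half_extent <- d * image$spacing / 2
  if (any(abs(center_mm) + r > half_extent)) {
    abort("sphere exceeds the image grid.", class = "pethet_geometry_error")
  }
  co <- grid_coords(d, image$spacing)
  sel <- (co$x - center_mm[1])^2 + (co$y - center_mm[2])^2 +
    (co$z - center_mm[3])^2 <= r^2
  if (!is.null(within)) {
    w <- if (inherits(within, "voi_mask")) within$data else within
    if (any(sel & !w)) {
      abort("sphere exceeds the phantom boundary.", class = "pethet_geometry_error")
    }
  }
  new_voi_mask(
    array(sel, d), image$spacing,
    meta = list(center_mm = center_mm, volume_ml = volume_ml, radius_mm = r)
  )
}

#' VOI volume in ml
#'
#' @param mask A `voi_mask`.
#' @return Voxel count times voxel volume, in ml.
#' @export
voi_volume <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}
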