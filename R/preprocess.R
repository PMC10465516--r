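#' Clip and rescale CT intensities
#'
#' Clips Hounsfield-unit intensities to (−1024, 200) HU and maps that range
#' linearly onto (−1, 1): `x -> 2 * (clip(x) + 1024) / 1224 - 1`. −1024 HU
#' maps to −1, 200 HU to +1, and the midpoint −412 HU to 0.
#'
#' @param ct A [volume3d()] in HU, or a plain numeric array/vector.
#' @param clip_low,clip_high Clipping bounds in HU.
#' @return Same type as the input, values in `[-1, 1]`.
#' @export
clip_rescale_ct <- function(ct, clip_low = -1024, clip_high = 200) {
  f <- function(x) {
    x <- pmin(pmax(x, clip_low), clip_high)
    2 * (x - clip_low) / (clip_high - clip_low) - 1
  }
  if (inherits(ct, "volume3d")) {
    out <- ct
    out$data <- f(ct$data)
    out
  } else f(ct)
}

#' Per-lung bounding box
#'
#' Tightest axis-aligned box containing every voxel of the requested lung,
#' expanded by `margin` voxels and clamped to the volume bounds. Boxes use
#' 1-based inclusive `start` and exclusive `end` indices per axis.
#'
#' @param lung_mask [label_volume()] with 0 background, 1 left lung, 2 right
#'   lung.
#' @param side `"left"` or `"right"`.
#' @param margin Margin in voxels (default 2).
#' @return A `bounding_box`: list with integer `start`, `end` (length 3).
#' @export
lung_bounding_box <- function(lung_mask, side = c("left", "right"), margin = 2L) {
  stopifnot(inherits(lung_mask, "label_volume"))
  side <- match.arg(side)
  lab <- if (side == "left") 1L else 2L
  w <- which(lung_mask$data == lab, arr.ind = TRUE)
  if (nrow(w) == 0L)
    stop("lung_bounding_box: the ", side, " lung label (", lab,
         ") is empty in this mask")
  d <- dim(lung_mask$data)
  start <- pmax(1L, apply(w, 2, min) - as.integer(margin))
  end <- pmin(d, apply(w, 2, max) + as.integer(margin)) + 1L
  structure(list(start = as.integer(start), end = as.integer(end), side = side),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box%s> [%s) x [%s) x [%s)\n",
              if (!is.null(x$side)) paste0(" ", x$side) else "",
              paste(c(x$start[1], x$end[1]), collapse = ","),
              paste(c(x$start[2], x$end[2]), collapse = ","),
              paste(c(x$start[3], x$end[3]), collapse = ",")))
  invisible(x)
}

box_dims <- function(box) box$end - box$start

#' Crop / re-embed a volume at a bounding box
#'
#' `crop_volume()` extracts the box; `uncrop_volume()` re-embeds a cropped
#' array into a full-size volume filled with `fill`, restoring voxel values
#' exactly inside the box.
#'
#' @param vol A [volume3d()] / [label_volume()].
#' @param box A `bounding_box` from [lung_bounding_box()].
#' @param full_dim Dimensions of the full volume to embed into.
#' @param fill Fill value outside the box.
#' @return A volume of the same class.
#' @export
crop_volume <- function(vol, box) {
  stopifnot(inherits(vol, "volume3d"), inherits(box, "bounding_box"))
  d <- dim(vol$data)
  if (any(box$start < 1L) || any(box$end > d + 1L) || any(box$start >= box$end))
    stop("crop_volume: box exceeds volume bounds")
  arr <- vol$data[box$start[1]:(box$end[1] - 1L),
                  box$start[2]:(box$end[2] - 1L),
                  box$start[3]:(box$end[3] - 1L), drop = FALSE]
  out <- vol
  out$data <- arr
  out$origin <- vol$origin + (box$start - 1L) * vol$spacing
  out
}

#' @rdname crop_volume
#' @export
uncrop_volume <- function(vol, box, full_dim, fill = 0) {
  stopifnot(inherits(vol, "volume3d"), inherits(box, "bounding_box"))
  if (!identical(as.integer(dim(vol$data)), as.integer(box_dims(box))))
    stop("uncrop_volume: cropped dims do not match the box")
  arr <- array(if (is_label(vol)) as.integer(fill) else fill, full_dim)
  arr[box$start[1]:(box$end[1] - 1L),
      box$start[2]:(box$end[2] - 1L),
      box$start[3]:(box$end[3] - 1L)] <- vol$data
  out <- vol
  out$data <- arr
  out$origin <- vol$origin - (box$start - 1L) * vol$spacing
  if (is_label(out)) out$labels <- sort(unique(c(as.integer(fill), out$labels)))
  out
}

#' Assemble the two-channel network input for one lung
#'
#' Crops the CT and the fissure probability map to the per-lung bounding box
#' and concatenates them along a channel dimension: channel 1 is the clipped,
#' rescaled CT in `[-1, 1]`; channel 2 the fissure probability in `[0, 1]`.
#' The right-lung input is shared by the right oblique and right horizontal
#' assessments.
#'
#' @param ct CT [volume3d()] in HU.
#' @param fissure_prob Probability [volume3d()] in `[0, 1]` on the same grid.
#' @param lung_mask Lung [label_volume()] (0/1/2) on the same grid.
#' @param side `"left"` or `"right"`.
#' @param margin Bounding-box margin in voxels.
#' @return A `network_input`: list with `data` (4D array x,y,z,2), `box`,
#'   `side`, `spacing`.
#' @export
make_network_input <- function(ct, fissure_prob, lung_mask,
                               side = c("left", "right"), margin = 2L) {
  side <- match.arg(side)
  assert_same_grid(ct, fissure_prob, lung_mask)
  box <- lung_bounding_box(lung_mask, side, margin)
  ct_c <- clip_rescale_ct(crop_volume(ct, box))
  pr_c <- crop_volume(fissure_prob, box)
  d <- dim(ct_c$data)
  data <- array(0, c(d, 2L))
  data[, , , 1L] <- ct_c$data
  data[, , , 2L] <- pmin(pmax(pr_c$data, 0), 1)
  structure(list(data = data, box = box, side = side, spacing = ct$spacing,
                 full_dim = dim(ct$data)),
            class = "network_input")
}

#' @export
print.network_input <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<network_input %s> %s voxels x %d channels\n", x$side,
              paste(d[1:3], collapse = "x"), d[4]))
  invisible(x)
}

#' Random fixed-size training crop
#'
#' Crops a network input and its ground-truth integrity mask to a fixed
#' spatial size, zero-padding first when the lung crop is smaller than the
#' target on any axis (CT channel padded with −1, probability with 0, target
#' with background). The crop offset is uniform over valid positions; with
#' probability `fg_prob` the offset is resampled from positions whose crop
#' contains at least one complete-fissure voxel, because the fissure occupies
#' a thin sheet that uniform crops frequently miss.
#'
#' @param input A `network_input`.
#' @param target Integrity-mask [label_volume()] on the same crop grid as
#'   `input` (i.e. already cropped to `input$box`).
#' @param size Integer length-3 crop size; default `c(128, 128, 64)`.
#' @param fg_prob Probability of forcing a fissure-containing crop.
#' @return List with `data` (4D array), `target` (3D integer array), `offset`.
#' @export
random_crop <- function(input, target, size = c(128L, 128L, 64L),
                        fg_prob = 0.5) {
  stopifnot(inherits(input, "network_input"))
  size <- as.integer(size)
  x <- input$data
  tg <- if (inherits(target, "label_volume")) target$data else target
  if (!identical(dim(x)[1:3], dim(tg)))
    stop("random_crop: input and target grids differ")
  d <- dim(x)[1:3]
  pad <- pmax(0L, size - d)
  if (any(pad > 0L)) {
    nd <- pmax(d, size)
    xp <- array(0, c(nd, 2L))
    xp[, , , 1L] <- -1  # padded CT
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    tp <- array(0L, nd)
    tp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- tg
    x <- xp; tg <- tp; d <- nd
  }
  max_off <- d - size  # 0-based offsets in 0..max_off
  pick_uniform <- function() sapply(max_off, function(m) sample.int(m + 1L, 1L) - 1L)
  off <- pick_uniform()
  if (stats::runif(1) < fg_prob) {
    fg <- which(tg > 0L, arr.ind = TRUE)
    if (nrow(fg) > 0L) {
      v <- fg[sample.int(nrow(fg), 1L), ]
      # choose an offset uniform among those whose crop window contains v
      lo <- pmax(0L, v - size)        # v must satisfy off < v <= off + size
      hi <- pmin(max_off, v - 1L)
      off <- ifelse(hi >= lo, lo + floor(stats::runif(3) * (hi - lo + 1L)), off)
      off <- as.integer(pmin(pmax(off, 0L), max_off))
    }
  }
  ix <- (off[1] + 1L):(off[1] + size[1])
  iy <- (off[2] + 1L):(off[2] + size[2])
  iz <- (off[3] + 1L):(off[3] + size[3])
  list(data = x[ix, iy, iz, , drop = FALSE], target = tg[ix, iy, iz],
       offset = as.integer(off))
}
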