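#' Post-processing configuration
#'
#' Controls the three-step morphological cleanup of a raw network labeling:
#' neighbourhood connectivity (26 by default; a thin oblique digital surface
#' is 26-connected but often 6-disconnected), the fill tie-break class, the
#' maximum number of fill passes, and whether smoothing includes the centre
#' voxel's own label in the vote (neighbours-only by default).
#'
#' @param connectivity 6, 18 or 26.
#' @param tie_break Class assigned on a tied fill vote: `"incomplete"`
#'   (default; conservative for collateral-ventilation screening) or
#'   `"intact"`.
#' @param fill_max_iters Maximum synchronous fill passes.
#' @param smooth_include_center Include the centre label in the smoothing vote.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(connectivity = 26L,
                               tie_break = c("incomplete", "intact"),
                               fill_max_iters = 100L,
                               smooth_include_center = FALSE) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("postprocess_config: connectivity must be 6, 18 or 26")
  structure(list(connectivity = as.integer(connectivity),
                 tie_break = match.arg(tie_break),
                 fill_max_iters = as.integer(fill_max_iters),
                 smooth_include_center = isTRUE(smooth_include_center)),
            class = "postprocess_config")
}

as_mask_array <- function(m) if (inherits(m, "volume3d")) m$data else m
rewrap_mask <- function(arr, template) {
  if (inherits(template, "volume3d"))
    label_volume(arr, spacing = template$spacing, origin = template$origin,
                 labels = 0:2)
  else arr
}

#' Remove off-surface false positives
#'
#' Assigns every voxel outside the complete fissure surface to background;
#' voxels on the surface are unchanged.
#'
#' @param raw Raw integrity labeling (labels 0/1/2).
#' @param complete Binary complete-fissure surface on the same grid.
#' @return Cleaned mask of the same type as `raw`.
#' @export
remove_false_positives <- function(raw, complete) {
  r <- as_mask_array(raw); s <- as_mask_array(complete) != 0L
  if (!identical(dim(r), dim(s)))
    stop("remove_false_positives: mask and surface grids differ")
  out <- r
  out[!s] <- 0L
  rewrap_mask(out, raw)
}

#' Fill on-surface false negatives
#'
#' Every surface voxel labeled background is assigned the majority class
#' among its neighbours (under `cfg$connectivity`) labeled intact or
#' incomplete, ties going to `cfg$tie_break`. Passes are synchronous (all
#' updates computed from the previous pass) and repeat until no background
#' remains on the surface or `cfg$fill_max_iters` is reached; any stragglers
#' (background surface voxels with no labeled voxel within reach) then take
#' the class of the nearest labeled surface voxel by Euclidean distance.
#'
#' @param mask Integrity mask already confined to the surface.
#' @param complete Binary complete-fissure surface.
#' @param cfg A [postprocess_config()].
#' @return Mask with no background voxels on the surface.
#' @export
fill_false_negatives <- function(mask, complete, cfg = postprocess_config()) {
  m <- as_mask_array(mask); s <- as_mask_array(complete) != 0L
  if (!identical(dim(m), dim(s)))
    stop("fill_false_negatives: mask and surface grids differ")
  if (!any(s)) return(rewrap_mask(m, mask))
  if (!any(m[s] > 0L))
    stop("fill_false_negatives: surface is non-empty but the mask contains ",
         "no intact or incomplete voxels to propagate")
  d <- dim(m)
  for (it in seq_len(cfg$fill_max_iters)) {
    bg <- s & m == 0L
    if (!any(bg)) break
    cnt <- neighbor_label_counts(m, d, c(1L, 2L), cfg$connectivity)
    c1 <- array(cnt[, , , 1L], d); c2 <- array(cnt[, , , 2L], d)
    upd <- bg & (c1 + c2) > 0L
    if (!any(upd)) break
    newm <- m
    win1 <- if (cfg$tie_break == "incomplete") c1 > c2 else c1 >= c2
    newm[upd & win1] <- 1L
    newm[upd & !win1] <- 2L
    m <- newm
  }
  bg <- s & m == 0L
  if (any(bg)) {
    lab_idx <- which(m > 0L & s, arr.ind = TRUE)
    bg_idx <- which(bg, arr.ind = TRUE)
    lab_val <- m[m > 0L & s]
    for (i in seq_len(nrow(bg_idx))) {
      dd <- (lab_idx[, 1] - bg_idx[i, 1])^2 + (lab_idx[, 2] - bg_idx[i, 2])^2 +
            (lab_idx[, 3] - bg_idx[i, 3])^2
      m[bg_idx[i, 1], bg_idx[i, 2], bg_idx[i, 3]] <- lab_val[which.min(dd)]
    }
  }
  rewrap_mask(m, mask)
}

#' Smooth surface labels by neighbourhood majority vote
#'
#' One simultaneous pass: each surface voxel's label is replaced by the
#' majority over its non-background neighbours within the connectivity
#' neighbourhood (optionally including its own label in the vote). Ties keep
#' the original label; voxels with no labeled neighbour keep their label.
#'
#' @inheritParams fill_false_negatives
#' @return Smoothed mask.
#' @export
smooth_labels <- function(mask, complete, cfg = postprocess_config()) {
  m <- as_mask_array(mask); s <- as_mask_array(complete) != 0L
  if (!identical(dim(m), dim(s)))
    stop("smooth_labels: mask and surface grids differ")
  d <- dim(m)
  cnt <- neighbor_label_counts(m, d, c(1L, 2L), cfg$connectivity)
  c1 <- array(cnt[, , , 1L], d); c2 <- array(cnt[, , , 2L], d)
  if (cfg$smooth_include_center) {
    c1 <- c1 + (m == 1L)
    c2 <- c2 + (m == 2L)
  }
  out <- m
  on <- s & m > 0L
  out[on & c1 > c2] <- 1L
  out[on & c2 > c1] <- 2L
  # ties (including isolated voxels) keep the original label
  rewrap_mask(out, mask)
}

#' Full three-step post-processing pipeline
#'
#' Composition of [remove_false_positives()], [fill_false_negatives()] and
#' [smooth_labels()]. The result carries labels 1/2 exactly on the complete
#' fissure surface and 0 elsewhere.
#'
#' @param raw Raw network labeling (argmax classes 0/1/2).
#' @param complete Binary complete-fissure surface.
#' @param cfg A [postprocess_config()].
#' @return Final integrity mask.
#' @export
postprocess_prediction <- function(raw, complete, cfg = postprocess_config()) {
  m <- remove_false_positives(raw, complete)
  m <- fill_false_negatives(m, complete, cfg)
  smooth_labels(m, complete, cfg)
}
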