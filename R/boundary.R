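#' Lobe label scheme and fissure definitions
#'
#' The five-lobe segmentation uses 0 = background, 1 = left upper lobe (LUL),
#' 2 = left lower lobe (LLL), 3 = right upper lobe (RUL), 4 = right middle
#' lobe (RML), 5 = right lower lobe (RLL).
#'
#' Each of the three fissures is defined by the lobe adjacencies it separates:
#' the left oblique (LOBL) separates LUL from LLL; the right horizontal (RHOR)
#' separates RUL from RML; the right oblique (ROBL) separates RML from RLL
#' anteriorly and RUL from RLL posteriorly. The first lobe of each pair is the
#' reference lobe whose voxels carry the extracted surface.
#'
#' @return `lobe_labels()`: a named integer vector. `fissure_kinds()`: a named
#'   list with, per fissure, the adjacency `pairs` (reference lobe first) and
#'   the lung `side`.
#' @export
lobe_labels <- function() {
  c(background = 0L, LUL = 1L, LLL = 2L, RUL = 3L, RML = 4L, RLL = 5L)
}

#' @rdname lobe_labels
#' @export
fissure_kinds <- function() {
  list(
    LOBL = list(name = "LOBL", side = "left",
                pairs = list(c(1L, 2L))),
    ROBL = list(name = "ROBL", side = "right",
                pairs = list(c(4L, 5L), c(3L, 5L))),
    RHOR = list(name = "RHOR", side = "right",
                pairs = list(c(3L, 4L)))
  )
}

as_fissure_kind <- function(kind) {
  if (is.character(kind)) {
    kinds <- fissure_kinds()
    if (!kind %in% names(kinds))
      stop("unknown fissure kind '", kind, "'; expected one of ",
           paste(names(kinds), collapse = ", "))
    kinds[[kind]]
  } else kind
}

# logical array of voxels with label `ref` that touch label `partner` through
# a face (6-adjacency), computed by shifting the label array along each axis
shift_touch <- function(lab, ref, partner) {
  d <- dim(lab)
  is_ref <- lab == ref
  part <- lab == partner
  touch <- array(FALSE, d)
  sub <- function(a, idx) do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  put <- function(a, idx, val) do.call(`[<-`, c(list(a), idx, list(val)))
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    idx_lo <- lapply(d, seq_len); idx_hi <- idx_lo
    idx_lo[[ax]] <- 1:(n - 1L); idx_hi[[ax]] <- 2:n
    # partner in +ax direction, then partner in -ax direction
    touch <- touch | put(array(FALSE, d), idx_lo,
                         sub(is_ref, idx_lo) & sub(part, idx_hi))
    touch <- touch | put(array(FALSE, d), idx_hi,
                         sub(is_ref, idx_hi) & sub(part, idx_lo))
  }
  touch
}

#' Extract the complete fissure surface from a lobe segmentation
#'
#' The complete fissure (intact plus incomplete lobar boundary) is the set of
#' voxels of the reference lobe of each adjacency pair that are face-adjacent
#' (6-connectivity) to a voxel of the partner lobe, united over the fissure's
#' pairs. The result is a one-voxel-thick digital surface carried on the
#' reference-lobe side; set `two_sided = TRUE` to include both sides.
#'
#' @param lobes A [label_volume()] using the [lobe_labels()] scheme.
#' @param kind A fissure name (`"LOBL"`, `"ROBL"`, `"RHOR"`) or an entry of
#'   [fissure_kinds()].
#' @param two_sided Include partner-lobe voxels as well (default `FALSE`).
#' @return A binary [label_volume()] (1 on the surface).
#' @export
extract_complete_fissure <- function(lobes, kind, two_sided = FALSE) {
  stopifnot(inherits(lobes, "label_volume"))
  kind <- as_fissure_kind(kind)
  lab <- lobes$data
  present <- unique(as.integer(lab))
  any_pair <- FALSE
  surf <- array(FALSE, dim(lab))
  for (p in kind$pairs) {
    if (!all(p %in% present)) next
    any_pair <- TRUE
    surf <- surf | shift_touch(lab, p[1], p[2])
    if (two_sided) surf <- surf | shift_touch(lab, p[2], p[1])
  }
  if (!any_pair) {
    missing <- setdiff(unique(unlist(kind$pairs)), present)
    stop("extract_complete_fissure: lobe segmentation lacks the lobes needed ",
         "for ", kind$name, " (absent label(s): ",
         paste(missing, collapse = ", "), ")")
  }
  label_volume(array(as.integer(surf), dim(lab)), spacing = lobes$spacing,
               origin = lobes$origin, labels = c(0L, 1L))
}

#' Encode a ground-truth integrity mask
#'
#' Combines the complete fissure surface with the visible (intact) portion
#' into a 3-class mask: 0 background, 1 intact fissure, 2 incomplete fissure.
#'
#' @param complete Binary [label_volume()], the complete fissure surface.
#' @param intact Binary [label_volume()] of intact voxels; must be a subset of
#'   `complete`.
#' @param kind Fissure name or kind; stored on the result.
#' @return An integrity mask: [label_volume()] with labels 0/1/2 and a
#'   `fissure` attribute.
#' @export
encode_ground_truth <- function(complete, intact, kind = NULL) {
  stopifnot(inherits(complete, "label_volume"), inherits(intact, "label_volume"))
  assert_same_grid(complete, intact)
  comp <- complete$data != 0L
  inta <- intact$data != 0L
  if (any(inta & !comp))
    stop("encode_ground_truth: intact voxels found outside the complete ",
         "fissure surface (", sum(inta & !comp), " voxel(s))")
  out <- array(0L, dim(comp))
  out[comp] <- 2L
  out[inta] <- 1L
  m <- label_volume(out, spacing = complete$spacing, origin = complete$origin,
                    labels = 0:2)
  if (!is.null(kind)) m$fissure <- as_fissure_kind(kind)$name
  m
}
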