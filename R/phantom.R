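#' Synthetic thoracic phantom specification
#'
#' The phantom emulates the output contract of an upstream lung/fissure/lobe
#' segmentation pipeline: a CT-like volume in HU, a binary lung mask, a
#' five-lobe segmentation whose lobar boundaries carry one-voxel-thick bright
#' fissure sheets, and a fissure probability map that is high only where the
#' fissure is radiographically visible. Lungs are two ellipsoids; fissure
#' surfaces are smoothly undulating height fields `z = f(x, y)` (oblique:
#' tilted plane plus sinusoidal perturbation; horizontal: near-axial plane in
#' the right lung). A contiguous patch covering `gap_fraction` of each
#' boundary surface is marked incomplete: there the CT sheet is absent and
#' the probability is low.
#'
#' @param shape Integer length-3 grid dimensions; every axis must be >= 32.
#' @param spacing Isotropic voxel size in mm.
#' @param gap_fraction Named numeric (LOBL, ROBL, RHOR) in `[0, 1]`: fraction
#'   of each boundary surface lacking visible fissure.
#' @param fissure_undulation Amplitude of the sinusoidal surface deformation,
#'   in voxels.
#' @param noise_sd Additive Gaussian CT noise in HU (default 30).
#' @param prob_blur Gaussian smoothing scale of the probability map, voxels.
#' @param seed Integer seed controlling the geometry (gap placement,
#'   undulation phases).
#' @param noise_seed Optional separate seed for the CT noise; defaults to a
#'   value derived from `seed`, so that regenerating with the same `seed` but
#'   a different `noise_seed` yields identical geometry under fresh noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 32L), spacing = 1,
                         gap_fraction = c(LOBL = 0.2, ROBL = 0.2, RHOR = 0.2),
                         fissure_undulation = 2, noise_sd = 30,
                         prob_blur = 1, seed = 1L, noise_seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom_spec: shape must have 3 axes, each >= 32")
  gf <- rep(0, 3); names(gf) <- c("LOBL", "ROBL", "RHOR")
  if (is.null(names(gap_fraction)) && length(gap_fraction) %in% c(1L, 3L))
    gf[] <- gap_fraction
  else gf[names(gap_fraction)] <- gap_fraction
  if (any(gf < 0 | gf > 1))
    stop("phantom_spec: gap_fraction must lie in [0, 1]")
  structure(list(shape = shape, spacing = spacing, gap_fraction = gf,
                 fissure_undulation = fissure_undulation, noise_sd = noise_sd,
                 prob_blur = prob_blur, seed = as.integer(seed),
                 noise_seed = if (is.null(noise_seed)) NULL
                              else as.integer(noise_seed)),
            class = "phantom_spec")
}

# separable Gaussian blur of a 3D array (truncated at 3 sigma)
gauss_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    n <- d[ax]
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- max(1L, 1L + off):min(n, n + off)
      dst <- src - off
      idx_s <- lapply(d, seq_len); idx_s[[ax]] <- src
      idx_d <- lapply(d, seq_len); idx_d[[ax]] <- dst
      piece <- do.call(`[`, c(list(arr), idx_s, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), idx_d,
                              list(do.call(`[`, c(list(out), idx_d,
                                                  list(drop = FALSE))) +
                                   k[j] * piece)))
    }
    arr <- out
  }
  arr
}

# grow a contiguous patch of `target` voxels on the surface voxel set by
# breadth-first search under 26-adjacency, reseeding if a component exhausts
grow_patch <- function(surf_idx, dims, target) {
  n <- nrow(surf_idx)
  if (target <= 0L) return(integer(0))
  if (target >= n) return(seq_len(n))
  key <- function(ix) (ix[, 1] - 1L) + dims[1] * ((ix[, 2] - 1L) +
                        dims[2] * (ix[, 3] - 1L))
  kmap <- new.env(hash = TRUE, size = n)
  keys <- key(surf_idx)
  for (i in seq_len(n)) assign(as.character(keys[i]), i, envir = kmap)
  visited <- logical(n)
  picked <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(picked) < target) {
    remaining <- which(!visited)
    seed_i <- remaining[sample.int(length(remaining), 1L)]
    queue <- seed_i; visited[seed_i] <- TRUE
    while (length(queue) > 0L && length(picked) < target) {
      cur <- queue[1L]; queue <- queue[-1L]
      picked <- c(picked, cur)
      nb <- sweep(offs, 2, as.integer(surf_idx[cur, ]), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
            nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nbk <- as.character(key(nb[ok, , drop = FALSE]))
      for (s in nbk) {
        j <- kmap[[s]]
        if (!is.null(j) && !visited[j]) { visited[j] <- TRUE; queue <- c(queue, j) }
      }
    }
  }
  picked[seq_len(target)]
}

#' Generate a synthetic thoracic case
#'
#' Builds the full input/ground-truth bundle for one synthetic subject: CT,
#' lung mask (1 left, 2 right), five-lobe segmentation, per-side fissure
#' probability maps, per-fissure ground-truth integrity masks, and the true
#' FI% per fissure. Deterministic given the spec's seeds. The left lung is
#' split into two lobes by one smooth surface and the right lung into three
#' by two surfaces; gap patches are grown as contiguous regions on each
#' boundary surface until the requested area fraction is met.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_case`: list with `ct`, `lung_mask`, `lobes`,
#'   `fissure_prob` (list `left`/`right`), `gt` (list per fissure),
#'   `true_fi` (named vector), `spec`.
#' @export
generate_case <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  d <- spec$shape; nx <- d[1]; ny <- d[2]; nz <- d[3]
  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  X <- array(rep(xs, times = ny * nz), d)
  Y <- array(rep(rep(ys, each = nx), times = nz), d)
  Z <- array(rep(zs, each = nx * ny), d)
  inside_ellipsoid <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  left <- inside_ellipsoid(0.30 * nx, 0.52 * ny, 0.50 * nz,
                           0.17 * nx, 0.36 * ny, 0.42 * nz)
  right <- inside_ellipsoid(0.70 * nx, 0.52 * ny, 0.50 * nz,
                            0.19 * nx, 0.38 * ny, 0.44 * nz)
  lung <- array(0L, d); lung[left] <- 1L; lung[right] <- 2L

  und <- spec$fissure_undulation
  ph <- stats::runif(6, 0, 2 * pi)
  surf <- function(z0, slope, p1, p2) {
    z0 + slope * (Y - 0.52 * ny) +
      und * sin(2 * pi * X / (0.9 * nx) + p1) +
      und * sin(2 * pi * Y / (1.1 * ny) + p2)
  }
  f_lo <- surf(0.50 * nz, 0.40, ph[1], ph[2])   # left oblique
  f_ro <- surf(0.34 * nz, 0.42, ph[3], ph[4])   # right oblique
  f_rh <- surf(0.62 * nz, 0.00, ph[5], ph[6])   # right horizontal

  lobes <- array(0L, d)
  lobes[left & Z >= f_lo] <- 1L                 # LUL
  lobes[left & Z < f_lo] <- 2L                  # LLL
  lobes[right & Z < f_ro] <- 5L                 # RLL
  lobes[right & Z >= f_ro & Z >= f_rh] <- 3L    # RUL
  lobes[right & Z >= f_ro & Z < f_rh] <- 4L     # RML
  counts <- table(factor(lobes, levels = 0:5))
  if (any(counts[as.character(1:5)] < 50L))
    stop("generate_case: infeasible geometry - lobe(s) too thin to separate (",
         paste(names(counts)[counts < 50L], collapse = ", "), ")")
  lobes_v <- label_volume(lobes, spacing = rep(spec$spacing, 3), labels = 0:5)

  kinds <- fissure_kinds()
  gt <- list(); true_fi <- c(LOBL = NA_real_, ROBL = NA_real_, RHOR = NA_real_)
  intact_all <- array(FALSE, d)
  for (nm in names(kinds)) {
    comp <- extract_complete_fissure(lobes_v, nm)
    sidx <- which(comp$data == 1L, arr.ind = TRUE)
    n_s <- nrow(sidx)
    if (n_s == 0L)
      stop("generate_case: infeasible geometry - no ", nm, " boundary surface")
    k <- round(spec$gap_fraction[[nm]] * n_s)
    gap_rows <- grow_patch(sidx, d, k)
    intact <- array(0L, d)
    if (n_s > length(gap_rows)) {
      keep <- sidx[setdiff(seq_len(n_s), gap_rows), , drop = FALSE]
      intact[keep] <- 1L
    }
    intact_v <- label_volume(intact, spacing = rep(spec$spacing, 3),
                             labels = c(0L, 1L))
    gt[[nm]] <- encode_ground_truth(comp, intact_v, nm)
    true_fi[[nm]] <- fi_percent(gt[[nm]])
    intact_all <- intact_all | (intact == 1L)
  }

  # CT: chest wall 0 HU, parenchyma -850 HU, visible fissure sheet -650 HU
  ct <- array(0, d)
  ct[lung > 0L] <- -850
  ct[intact_all] <- -650
  noise_seed <- spec$noise_seed %||% ((spec$seed + 1000003L) %% 2147483629L)
  set.seed(noise_seed)
  ct <- ct + array(stats::rnorm(length(ct), sd = spec$noise_sd), d)
  ct_v <- volume3d(ct, spacing = rep(spec$spacing, 3))

  # probability maps: blurred visible-fissure indicator, gain-normalized so a
  # flat sheet interior reaches ~1, clipped to [0, 1]
  prob_from <- function(ind) {
    b <- gauss_blur3(array(as.numeric(ind), d), spec$prob_blur)
    gain <- if (spec$prob_blur > 0) {
      r <- max(1L, ceiling(3 * spec$prob_blur))
      kk <- exp(-((-r):r)^2 / (2 * spec$prob_blur^2)); kk <- kk / sum(kk)
      1 / max(kk)                     # sheet normal crosses one axis kernel
    } else 1
    pmin(pmax(b * gain, 0), 1)
  }
  prob_left <- prob_from(intact_all & gt$LOBL$data > 0L)
  prob_right <- prob_from(intact_all &
                          (gt$ROBL$data > 0L | gt$RHOR$data > 0L))
  structure(list(
    ct = ct_v,
    lung_mask = label_volume(lung, spacing = rep(spec$spacing, 3),
                             labels = 0:2),
    lobes = lobes_v,
    fissure_prob = list(
      left = volume3d(prob_left, spacing = rep(spec$spacing, 3)),
      right = volume3d(prob_right, spacing = rep(spec$spacing, 3))),
    gt = gt,
    true_fi = true_fi,
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, seed %d\n",
              paste(dim(x$ct$data), collapse = "x"), x$spec$seed))
  cat("  true FI%:", paste(sprintf("%s=%.1f", names(x$true_fi), x$true_fi),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Generate a cohort of phantom cases
#'
#' Draws per-case, per-fissure gap fractions uniformly from `gap_range` and
#' generates `n` cases with seeds derived reproducibly from `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param gap_range Length-2 range for the gap fractions, or a named list of
#'   per-fissure ranges.
#' @param seed Integer master seed.
#' @param spec Template [phantom_spec()] supplying all other fields.
#' @return List of `phantom_case`.
#' @export
generate_cohort <- function(n, gap_range = c(0, 0.6), seed = 1L,
                            spec = phantom_spec()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("generate_cohort: n must be >= 1")
  n <- as.integer(n)
  ranges <- if (is.list(gap_range)) gap_range
            else list(LOBL = gap_range, ROBL = gap_range, RHOR = gap_range)
  for (r in ranges)
    if (length(r) != 2L || r[2] < r[1])
      stop("generate_cohort: each gap range must be c(lo, hi) with hi >= lo")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gfs <- lapply(seq_len(n), function(i)
    vapply(c("LOBL", "ROBL", "RHOR"),
           function(f) stats::runif(1, ranges[[f]][1], ranges[[f]][2]), 1))
  case_seeds <- (as.integer(seed) + 7919L * seq_len(n)) %% 2147483629L
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$gap_fraction[] <- gfs[[i]]
    sp$seed <- case_seeds[i]
    sp$noise_seed <- NULL
    generate_case(sp)
  })
}

#' Write / read a phantom case as NIfTI files plus a JSON sidecar
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return `write_case()`: `dir` invisibly; `read_case()`: a `phantom_case`
#'   (without the generating spec's RNG detail beyond what the sidecar holds).
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$ct, file.path(dir, "ct.nii.gz"))
  write_volume(case$lung_mask, file.path(dir, "lung.nii.gz"))
  write_volume(case$lobes, file.path(dir, "lobes.nii.gz"))
  write_volume(case$fissure_prob$left, file.path(dir, "fissure_prob_left.nii.gz"))
  write_volume(case$fissure_prob$right, file.path(dir, "fissure_prob_right.nii.gz"))
  for (nm in names(case$gt))
    write_volume(case$gt[[nm]], file.path(dir, sprintf("gt_%s.nii.gz", nm)))
  sidecar <- list(true_fi = as.list(case$true_fi),
                  spec = unclass(case$spec))
  jsonlite::write_json(sidecar, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  need <- c("ct.nii.gz", "lung.nii.gz", "lobes.nii.gz",
            "fissure_prob_left.nii.gz", "fissure_prob_right.nii.gz")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("read_case: missing ", f, " in ", dir)
  sc_path <- file.path(dir, "case.json")
  sidecar <- if (file.exists(sc_path)) jsonlite::read_json(sc_path) else NULL
  gt <- list()
  for (nm in c("LOBL", "ROBL", "RHOR")) {
    p <- file.path(dir, sprintf("gt_%s.nii.gz", nm))
    if (file.exists(p)) gt[[nm]] <- read_volume(p, as_labels = TRUE)
  }
  structure(list(
    ct = read_volume(file.path(dir, "ct.nii.gz"), as_labels = FALSE),
    lung_mask = read_volume(file.path(dir, "lung.nii.gz"), as_labels = TRUE),
    lobes = read_volume(file.path(dir, "lobes.nii.gz"), as_labels = TRUE),
    fissure_prob = list(
      left = read_volume(file.path(dir, "fissure_prob_left.nii.gz"),
                         as_labels = FALSE),
      right = read_volume(file.path(dir, "fissure_prob_right.nii.gz"),
                          as_labels = FALSE)),
    gt = gt,
    true_fi = if (!is.null(sidecar)) unlist(sidecar$true_fi) else NULL,
    spec = if (!is.null(sidecar)) sidecar$spec else NULL),
    class = "phantom_case")
}
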