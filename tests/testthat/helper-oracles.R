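# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each definition so they share no code path
# with the package implementation they check.

# all voxels of `ref` label 6-adjacent to a voxel of `partner`, by explicit
# per-voxel neighbour enumeration
oracle_surface_scan <- function(lab, ref, partner) {
  d <- dim(lab)
  out <- array(FALSE, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(lab == ref, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    for (k in 1:6) {
      n <- v + offs[k, ]
      if (any(n < 1L) || any(n > d)) next
      if (lab[n[1], n[2], n[3]] == partner) {
        out[v[1], v[2], v[3]] <- TRUE
        break
      }
    }
  }
  out
}

oracle_complete_fissure <- function(lab, kind_name, two_sided = FALSE) {
  kind <- fissure_kinds()[[kind_name]]
  out <- array(FALSE, dim(lab))
  for (p in kind$pairs) {
    out <- out | oracle_surface_scan(lab, p[1], p[2])
    if (two_sided) out <- out | oracle_surface_scan(lab, p[2], p[1])
  }
  out
}

# neighbours of voxel v under a connectivity, as an index matrix
oracle_neighbors <- function(v, d, connectivity = 26) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  nb <- sweep(offs, 2, as.integer(v), `+`)
  nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
     nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
}

# literal re-implementation of the three post-processing steps under the
# same declared conventions (synchronous fill passes, tie -> incomplete,
# one smoothing pass, neighbours-only vote, ties keep label)
oracle_postprocess <- function(raw, surf, connectivity = 26,
                               fill_max_iters = 100) {
  d <- dim(raw)
  m <- raw
  m[!surf] <- 0L
  stopifnot(any(m[surf] > 0L))
  for (it in seq_len(fill_max_iters)) {
    bg <- which(surf & m == 0L, arr.ind = TRUE)
    if (nrow(bg) == 0L) break
    newm <- m
    changed <- FALSE
    for (r in seq_len(nrow(bg))) {
      nb <- oracle_neighbors(bg[r, ], d, connectivity)
      labs <- m[nb]
      n1 <- sum(labs == 1L); n2 <- sum(labs == 2L)
      if (n1 + n2 > 0L) {
        newm[bg[r, 1], bg[r, 2], bg[r, 3]] <- if (n1 > n2) 1L else 2L
        changed <- TRUE
      }
    }
    m <- newm
    if (!changed) break
  }
  bg <- which(surf & m == 0L, arr.ind = TRUE)
  if (nrow(bg) > 0L) {
    lab_idx <- which(m > 0L & surf, arr.ind = TRUE)
    for (r in seq_len(nrow(bg))) {
      dd <- colSums((t(lab_idx) - bg[r, ])^2)
      w <- lab_idx[which.min(dd), ]
      m[bg[r, 1], bg[r, 2], bg[r, 3]] <- m[w[1], w[2], w[3]]
    }
  }
  sm <- m
  on <- which(surf & m > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(on))) {
    nb <- oracle_neighbors(on[r, ], d, connectivity)
    labs <- m[nb]
    n1 <- sum(labs == 1L); n2 <- sum(labs == 2L)
    if (n1 > n2) sm[on[r, 1], on[r, 2], on[r, 3]] <- 1L
    if (n2 > n1) sm[on[r, 1], on[r, 2], on[r, 3]] <- 2L
  }
  sm
}

# rank-free AUC by exhaustive pair enumeration
oracle_auc <- function(score, pos) {
  s1 <- score[pos]; s0 <- score[!pos]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# independently coded soft multi-class Dice loss: sum_c 1 - 2|P.G|/(|P|+|G|)
oracle_dice_loss <- function(P, G, smooth) {
  loss <- 0
  for (c in seq_len(ncol(P))) {
    inter <- sum(P[, c] * G[, c])
    loss <- loss + 1 - (2 * inter + 2 * smooth) /
      (sum(P[, c]) + sum(G[, c]) + 2 * smooth)
  }
  loss
}

# random integrity mask supported on a random thin surface
random_surface_mask <- function(d = c(12L, 12L, 12L), p_intact = 0.5,
                                 n_blobs = 3L) {
  z0 <- sample(2:(d[3] - 1), 1)
  surf <- array(FALSE, d)
  surf[, , z0] <- TRUE
  # perturb the sheet height to make it non-planar
  for (i in seq_len(d[1])) {
    dz <- sample(-1:1, 1)
    surf[i, , ] <- FALSE
    surf[i, , min(max(z0 + dz, 1), d[3])] <- TRUE
  }
  m <- array(0L, d)
  m[surf] <- ifelse(stats::runif(sum(surf)) < p_intact, 1L, 2L)
  list(surf = surf, mask = m)
}

# small deterministic phantom spec for tests
tiny_spec <- function(...) phantom_spec(shape = c(48L, 48L, 32L), ...)
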