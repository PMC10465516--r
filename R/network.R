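#' Network and loss configuration
#'
#' The fissure-integrity network is a 3D attention U-Net: `levels` encoding
#' steps (each two 3x3x3 convolutions with instance normalization and ReLU,
#' followed by 2x2x2 max pooling), a bottleneck, and a mirrored decoding path
#' with nearest-neighbour upsampling, a 1x1x1 channel-halving projection, and
#' additive attention gates filtering each skip connection with the coarser
#' decoder features as gating signal. Channel counts double per level from
#' `base_filters`. The head is a 1x1x1 convolution to `out_classes` followed
#' by a per-voxel softmax.
#'
#' The Tversky loss generalizes soft Dice with asymmetric false-positive
#' (`alpha`) and false-negative (`beta = 1 - alpha`) weights; `alpha = 0.05`
#' counters the extreme class imbalance of a thin fissure sheet against
#' background by penalizing missed fissure voxels far more than spurious
#' ones.
#'
#' @param in_channels Input channels (CT + fissure probability = 2).
#' @param out_classes Output classes (background/intact/incomplete = 3).
#' @param levels Number of encoding steps (poolings); default 4.
#' @param base_filters Filter count at the highest resolution.
#' @param attention_gates Use attention gates on skip connections.
#' @param alpha False-positive weight of the Tversky index.
#' @param beta False-negative weight; must satisfy `alpha + beta = 1`.
#' @param smooth Additive stabilizer in numerator and denominator.
#' @return A `network_config` / `loss_config` list.
#' @export
network_config <- function(in_channels = 2L, out_classes = 3L, levels = 4L,
                           base_filters = 16L, attention_gates = TRUE) {
  stopifnot(levels >= 1L, base_filters >= 4L, out_classes == 3L)
  structure(list(in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 attention_gates = isTRUE(attention_gates)),
            class = "network_config")
}

#' @rdname network_config
#' @export
loss_config <- function(alpha = 0.05, beta = 1 - alpha, smooth = 1) {
  stopifnot(alpha > 0, beta > 0, smooth >= 0)
  if (abs(alpha + beta - 1) > 1e-12)
    stop("loss_config: alpha + beta must equal 1")
  structure(list(alpha = alpha, beta = beta, smooth = smooth),
            class = "loss_config")
}

# ---- parameter initialization -------------------------------------------

he_w <- function(fan_in, n_out, n_rows) {
  matrix(stats::rnorm(n_rows * n_out, sd = sqrt(2 / fan_in)), n_rows, n_out)
}

init_cbr <- function(par, pre, cin, cout) {
  par[[paste0(pre, ".W")]] <- he_w(27 * cin, cout, 27 * cin)
  par[[paste0(pre, ".b")]] <- numeric(cout)
  par[[paste0(pre, ".g")]] <- rep(1, cout)
  par[[paste0(pre, ".be")]] <- numeric(cout)
  par
}

#' Build a 3D attention U-Net
#'
#' Initializes the model parameters (He-normal convolution weights,
#' unit-gain instance norms) deterministically from `seed`. The model is
#' fully convolutional: it maps a 2-channel volume of any spatial size
#' divisible by `2^levels` to a 3-channel probability volume of identical
#' spatial size.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `unet3d` model handle.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- cfg$levels; F1 <- cfg$base_filters
  fl <- F1 * 2^(seq_len(L) - 1L)          # channels per encoder level
  fb <- F1 * 2^L                          # bottleneck channels
  par <- list()
  cin <- cfg$in_channels
  for (i in seq_len(L)) {
    par <- init_cbr(par, sprintf("enc%d.c1", i), cin, fl[i])
    par <- init_cbr(par, sprintf("enc%d.c2", i), fl[i], fl[i])
    cin <- fl[i]
  }
  par <- init_cbr(par, "bot.c1", fl[L], fb)
  par <- init_cbr(par, "bot.c2", fb, fb)
  cprev <- fb
  for (i in rev(seq_len(L))) {
    par[[sprintf("dec%d.proj.W", i)]] <- he_w(cprev, fl[i], cprev)
    par[[sprintf("dec%d.proj.b", i)]] <- numeric(fl[i])
    if (cfg$attention_gates) {
      fint <- max(4L, fl[i] %/% 2L)
      par[[sprintf("att%d.Wg", i)]] <- he_w(fl[i], fint, fl[i])
      par[[sprintf("att%d.Wx", i)]] <- he_w(fl[i], fint, fl[i])
      par[[sprintf("att%d.bx", i)]] <- numeric(fint)
      par[[sprintf("att%d.Wpsi", i)]] <- he_w(fint, 1L, fint)
      par[[sprintf("att%d.bpsi", i)]] <- numeric(1L)
    }
    par <- init_cbr(par, sprintf("dec%d.c1", i), 2L * fl[i], fl[i])
    par <- init_cbr(par, sprintf("dec%d.c2", i), fl[i], fl[i])
    cprev <- fl[i]
  }
  par[["out.W"]] <- he_w(fl[1], cfg$out_classes, fl[1])
  # bias the head toward the class priors of a thin-sheet segmentation task
  # (background dominates); spares the optimizer the prior-calibration phase
  par[["out.b"]] <- log(c(0.90, rep(0.10 / (cfg$out_classes - 1),
                                    cfg$out_classes - 1)))
  structure(list(cfg = cfg, par = par), class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  np <- sum(vapply(x$par, length, 1L))
  cat(sprintf(paste0("<unet3d> %d levels, base %d filters, attention %s, ",
                     "%s parameters\n"),
              x$cfg$levels, x$cfg$base_filters,
              if (x$cfg$attention_gates) "on" else "off",
              format(np, big.mark = ",")))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- layer primitives (R side) ------------------------------------------

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}
as_arr <- function(x, sp) { dim(x) <- c(sp, ncol(x)); x }

inorm_f <- function(x, g, be, eps = 1e-5) {
  m <- as_mat(x)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, be, `+`)
  list(y = as_arr(y, dim(x)[1:3]), xhat = xhat, inv = inv)
}

inorm_b <- function(dy, cache, g) {
  dm <- as_mat(dy)
  xhat <- cache$xhat
  dg <- colSums(dm * xhat)
  dbe <- colSums(dm)
  dxh <- sweep(dm, 2, g, `*`)
  n <- nrow(dxh)
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(xhat, 2, colMeans(dxh * xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(dx = as_arr(dx, dim(dy)[1:3]), dg = dg, dbe = dbe)
}

# conv(3x3x3) + instance norm + ReLU
cbr_f <- function(x, par, pre, cache = NULL) {
  z <- conv3d_fw(x, dim(x)[1:3], par[[paste0(pre, ".W")]],
                 par[[paste0(pre, ".b")]])
  nc <- inorm_f(z, par[[paste0(pre, ".g")]], par[[paste0(pre, ".be")]])
  y <- nc$y
  mask <- y > 0
  y[!mask] <- 0
  if (!is.null(cache)) {
    cache[[paste0(pre, ".x")]] <- x
    cache[[paste0(pre, ".in")]] <- nc[c("xhat", "inv")]
    cache[[paste0(pre, ".mask")]] <- mask
  }
  y
}

cbr_b <- function(dy, par, pre, cache, grads) {
  dy[!cache[[paste0(pre, ".mask")]]] <- 0
  nb <- inorm_b(dy, cache[[paste0(pre, ".in")]], par[[paste0(pre, ".g")]])
  grads[[paste0(pre, ".g")]] <- grads[[paste0(pre, ".g")]] + nb$dg
  grads[[paste0(pre, ".be")]] <- grads[[paste0(pre, ".be")]] + nb$dbe
  x <- cache[[paste0(pre, ".x")]]
  cb <- conv3d_bw(x, nb$dx, dim(x)[1:3], par[[paste0(pre, ".W")]])
  grads[[paste0(pre, ".W")]] <- grads[[paste0(pre, ".W")]] + cb$dW
  grads[[paste0(pre, ".b")]] <- grads[[paste0(pre, ".b")]] + as.vector(cb$db)
  cb$dx
}

conv1_f <- function(x, W, b = NULL) {
  m <- as_mat(x) %*% W
  if (!is.null(b)) m <- sweep(m, 2, b, `+`)
  as_arr(m, dim(x)[1:3])
}

# ---- forward / backward --------------------------------------------------

check_divisible <- function(sp, levels) {
  if (any(sp %% 2^levels != 0))
    stop("network: spatial size (", paste(sp, collapse = "x"),
         ") must be divisible by 2^levels = ", 2^levels)
}

#' Network forward pass
#'
#' Runs the attention U-Net on a 4D array `(x, y, z, channel)` and returns
#' per-voxel class probabilities `(x, y, z, class)` summing to 1. Spatial
#' dimensions must be divisible by `2^levels`; [predict_integrity()] handles
#' padding for arbitrary sizes.
#'
#' @param model A `unet3d` from [build_network()].
#' @param x Input array `(nx, ny, nz, in_channels)`.
#' @param cache Internal: an environment collecting intermediates for the
#'   backward pass.
#' @return Probability array `(nx, ny, nz, out_classes)`.
#' @export
network_forward <- function(model, x, cache = NULL) {
  cfg <- model$cfg; par <- model$par
  sp <- dim(x)[1:3]
  check_divisible(sp, cfg$levels)
  L <- cfg$levels
  skips <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    cur <- cbr_f(cur, par, sprintf("enc%d.c1", i), cache)
    cur <- cbr_f(cur, par, sprintf("enc%d.c2", i), cache)
    skips[[i]] <- cur
    p <- maxpool3d_fw(cur, dim(cur)[1:3])
    if (!is.null(cache)) {
      cache[[sprintf("pool%d.idx", i)]] <- p$idx
      cache[[sprintf("pool%d.dims", i)]] <- dim(cur)[1:3]
    }
    cur <- p$y
  }
  cur <- cbr_f(cur, par, "bot.c1", cache)
  cur <- cbr_f(cur, par, "bot.c2", cache)
  for (i in rev(seq_len(L))) {
    up <- upsample3d_fw(cur)
    proj <- conv1_f(up, par[[sprintf("dec%d.proj.W", i)]],
                    par[[sprintf("dec%d.proj.b", i)]])
    sk <- skips[[i]]
    if (cfg$attention_gates) {
      qg <- as_mat(proj) %*% par[[sprintf("att%d.Wg", i)]]
      qx <- sweep(as_mat(sk) %*% par[[sprintf("att%d.Wx", i)]], 2,
                  par[[sprintf("att%d.bx", i)]], `+`)
      q <- qg + qx
      qmask <- q > 0
      q[!qmask] <- 0
      psi <- q %*% par[[sprintf("att%d.Wpsi", i)]] +
        par[[sprintf("att%d.bpsi", i)]][1]
      a <- 1 / (1 + exp(-psi))
      xs <- as_arr(as_mat(sk) * as.vector(a), dim(sk)[1:3])
      if (!is.null(cache)) {
        cache[[sprintf("att%d.up", i)]] <- up
        cache[[sprintf("att%d.proj", i)]] <- proj
        cache[[sprintf("att%d.sk", i)]] <- sk
        cache[[sprintf("att%d.q", i)]] <- q
        cache[[sprintf("att%d.qmask", i)]] <- qmask
        cache[[sprintf("att%d.a", i)]] <- a
      }
    } else {
      xs <- sk
      if (!is.null(cache)) cache[[sprintf("att%d.up", i)]] <- up
    }
    ci <- dim(xs)[4]
    cat_ <- array(0, c(dim(xs)[1:3], 2L * ci))
    cat_[, , , seq_len(ci)] <- xs
    cat_[, , , ci + seq_len(ci)] <- proj
    cur <- cbr_f(cat_, par, sprintf("dec%d.c1", i), cache)
    cur <- cbr_f(cur, par, sprintf("dec%d.c2", i), cache)
  }
  logits <- conv1_f(cur, par[["out.W"]], par[["out.b"]])
  if (!is.null(cache)) cache[["out.x"]] <- cur
  m <- as_mat(logits)
  m <- exp(m - apply(m, 1, max))
  p <- m / rowSums(m)
  if (!is.null(cache)) cache[["probs"]] <- p
  as_arr(p, sp)
}

# Backward pass: dprobs is dL/dp (same shape as the forward output).
# Returns a flat named list of parameter gradients.
network_backward <- function(model, dprobs, cache) {
  cfg <- model$cfg; par <- model$par
  L <- cfg$levels
  grads <- list2env(lapply(par, function(p) array(0, dim(p) %||% length(p))),
                    parent = emptyenv())
  # softmax backward
  p <- cache[["probs"]]
  dP <- as_mat(dprobs)
  dz <- p * (dP - rowSums(dP * p))
  # output 1x1x1 conv
  xo <- cache[["out.x"]]
  grads[["out.W"]] <- grads[["out.W"]] + t(as_mat(xo)) %*% dz
  grads[["out.b"]] <- grads[["out.b"]] + colSums(dz)
  dcur <- as_arr(dz %*% t(par[["out.W"]]), dim(xo)[1:3])
  dskips <- vector("list", L)
  for (i in seq_len(L)) {           # decoder ran L..1, so backward runs 1..L
    dcur <- cbr_b(dcur, par, sprintf("dec%d.c2", i), cache, grads)
    dcat <- cbr_b(dcur, par, sprintf("dec%d.c1", i), cache, grads)
    ci <- dim(dcat)[4] / 2L
    dxs <- dcat[, , , seq_len(ci), drop = FALSE]
    dproj <- dcat[, , , ci + seq_len(ci), drop = FALSE]
    if (cfg$attention_gates) {
      sk <- cache[[sprintf("att%d.sk", i)]]
      a <- cache[[sprintf("att%d.a", i)]]
      dxs_m <- as_mat(dxs)
      dsk_m <- dxs_m * as.vector(a)
      da <- rowSums(dxs_m * as_mat(sk))
      dpsi <- da * as.vector(a) * (1 - as.vector(a))
      q <- cache[[sprintf("att%d.q", i)]]
      Wpsi <- par[[sprintf("att%d.Wpsi", i)]]
      grads[[sprintf("att%d.Wpsi", i)]] <-
        grads[[sprintf("att%d.Wpsi", i)]] + t(q) %*% dpsi
      grads[[sprintf("att%d.bpsi", i)]] <-
        grads[[sprintf("att%d.bpsi", i)]] + sum(dpsi)
      dq <- dpsi %*% t(Wpsi)
      dq[!cache[[sprintf("att%d.qmask", i)]]] <- 0
      proj <- cache[[sprintf("att%d.proj", i)]]
      grads[[sprintf("att%d.Wg", i)]] <-
        grads[[sprintf("att%d.Wg", i)]] + t(as_mat(proj)) %*% dq
      grads[[sprintf("att%d.Wx", i)]] <-
        grads[[sprintf("att%d.Wx", i)]] + t(as_mat(sk)) %*% dq
      grads[[sprintf("att%d.bx", i)]] <-
        grads[[sprintf("att%d.bx", i)]] + colSums(dq)
      dproj_m <- as_mat(dproj) + dq %*% t(par[[sprintf("att%d.Wg", i)]])
      dsk_m <- dsk_m + dq %*% t(par[[sprintf("att%d.Wx", i)]])
      dskips[[i]] <- as_arr(dsk_m, dim(sk)[1:3])
      dproj <- as_arr(dproj_m, dim(sk)[1:3])
    } else {
      dskips[[i]] <- dxs
    }
    up <- cache[[sprintf("att%d.up", i)]]
    Wp <- par[[sprintf("dec%d.proj.W", i)]]
    grads[[sprintf("dec%d.proj.W", i)]] <-
      grads[[sprintf("dec%d.proj.W", i)]] + t(as_mat(up)) %*% as_mat(dproj)
    grads[[sprintf("dec%d.proj.b", i)]] <-
      grads[[sprintf("dec%d.proj.b", i)]] + colSums(as_mat(dproj))
    dup <- as_arr(as_mat(dproj) %*% t(Wp), dim(up)[1:3])
    dcur <- upsample3d_bw(dup)
  }
  dcur <- cbr_b(dcur, par, "bot.c2", cache, grads)
  dcur <- cbr_b(dcur, par, "bot.c1", cache, grads)
  for (i in rev(seq_len(L))) {
    dpre <- maxpool3d_bw(dcur, cache[[sprintf("pool%d.idx", i)]],
                         cache[[sprintf("pool%d.dims", i)]])
    dpre <- dpre + dskips[[i]]
    dpre <- cbr_b(dpre, par, sprintf("enc%d.c2", i), cache, grads)
    dcur <- cbr_b(dpre, par, sprintf("enc%d.c1", i), cache, grads)
  }
  as.list(grads)
}

# ---- Tversky loss --------------------------------------------------------

one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  m
}

#' Tversky loss
#'
#' For each class c the Tversky index is
#' `TI_c = (sum(p_c g_c) + s) / (sum(p_c g_c) + alpha sum(p_c (1-g_c)) +
#' beta sum((1-p_c) g_c) + s)` and the loss is `sum_c (1 - TI_c)`, summed
#' uniformly over all classes including background. At
#' `alpha = beta = 0.5` each per-class term equals the soft Dice loss.
#'
#' @param pred Per-voxel class probabilities: array `(..., C)` or matrix
#'   `(n, C)` with rows summing to 1.
#' @param truth Integer labels in `0..C-1` (array or vector), or a one-hot
#'   array/matrix of the same shape as `pred`.
#' @param cfg A [loss_config()].
#' @param grad Also return the gradient `dL/dpred`.
#' @return The scalar loss, or (with `grad = TRUE`) a list `(loss, grad)`.
#' @export
tversky_loss <- function(pred, truth, cfg = loss_config(), grad = FALSE) {
  P <- if (!is.null(dim(pred)) && length(dim(pred)) > 2L) as_mat(pred)
       else as.matrix(pred)
  C <- ncol(P)
  G <- if (length(truth) == length(P)) {         # one-hot, same shape as pred
    m <- truth; dim(m) <- dim(P); m
  } else if (length(truth) == nrow(P)) {         # integer class labels
    one_hot(as.vector(truth), C)
  } else stop("tversky_loss: pred and truth shapes are incompatible")
  a <- cfg$alpha; b <- cfg$beta; s <- cfg$smooth
  S <- colSums(P * G)
  FP <- colSums(P * (1 - G))
  FN <- colSums((1 - P) * G)
  D <- S + a * FP + b * FN
  TI <- (S + s) / (D + s)
  loss <- sum(1 - TI)
  if (!grad) return(loss)
  # d(1-TI_c)/dP_{v,c} = -[G (D+s) - (S+s)(G + a(1-G) - b G)] / (D+s)^2
  dP <- matrix(0, nrow(P), C)
  for (c in seq_len(C)) {
    g <- G[, c]
    dD <- g + a * (1 - g) - b * g
    dP[, c] <- -(g * (D[c] + s) - (S[c] + s) * dD) / (D[c] + s)^2
  }
  list(loss = loss, grad = dP)
}

# ---- prediction ----------------------------------------------------------

pad_to_divisible <- function(x, levels) {
  sp <- dim(x)[1:3]
  m <- 2^levels
  target <- as.integer(ceiling(sp / m) * m)
  if (all(target == sp)) return(list(x = x, sp = sp))
  xp <- array(0, c(target, dim(x)[4]))
  xp[, , , 1] <- -1                      # CT padding convention
  xp[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), ] <- x
  list(x = xp, sp = sp)
}

#' Predict per-voxel integrity probabilities
#'
#' Pads the input to a spatial size divisible by `2^levels` (CT channel with
#' −1, probability channel with 0), runs the network, and removes the padding
#' so the output matches the un-padded crop.
#'
#' @param model A `unet3d`.
#' @param input A `network_input` from [make_network_input()], or a bare 4D
#'   array.
#' @return List with `probs` (array `(nx, ny, nz, 3)`) and `mask` (integer
#'   array of argmax labels 0/1/2).
#' @export
predict_integrity <- function(model, input) {
  x <- if (inherits(input, "network_input")) input$data else input
  pd <- pad_to_divisible(x, model$cfg$levels)
  probs <- network_forward(model, pd$x)
  sp <- pd$sp
  probs <- probs[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), , drop = FALSE]
  pm <- as_mat(probs)
  mask <- array(max.col(pm, ties.method = "first") - 1L, sp)
  list(probs = probs, mask = mask)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file containing the network configuration and
#' all parameters (plus optional training history).
#'
#' @param model A `unet3d`.
#' @param path Checkpoint path.
#' @param history Optional training history to embed.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: a
#'   `unet3d` with any embedded history in `$history`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  stopifnot(inherits(model, "unet3d"))
  saveRDS(list(cfg = unclass(model$cfg), par = model$par, history = history),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(network_config, x$cfg)
  structure(list(cfg = cfg, par = x$par, history = x$history),
            class = "unet3d")
}
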