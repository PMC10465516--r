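small_cfg <- function(att = TRUE)
  network_config(levels = 2L, base_filters = 4L, attention_gates = att)

test_that("network maps 2-channel input to normalized 3-class output of same size", {
  m <- build_network(small_cfg(), seed = 1)
  set.seed(1)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  p <- network_forward(m, x)
  expect_equal(dim(p), c(16, 16, 8, 3))
  sums <- apply(p, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(p >= 0 & p <= 1))
  # full convolutionality: another divisible size works with the same weights
  x2 <- array(rnorm(8 * 12 * 4 * 2), c(8, 12, 4, 2))
  expect_equal(dim(network_forward(m, x2)), c(8, 12, 4, 3))
})

test_that("non-divisible spatial sizes raise a shape error before computation", {
  m <- build_network(network_config(levels = 4L, base_filters = 4L), seed = 1)
  x <- array(0, c(100, 100, 50, 2))
  expect_error(network_forward(m, x), "divisible")
})

test_that("initialization and prediction are deterministic given the seed", {
  m1 <- build_network(small_cfg(), seed = 42)
  m2 <- build_network(small_cfg(), seed = 42)
  expect_identical(m1$par, m2$par)
  m3 <- build_network(small_cfg(), seed = 43)
  expect_false(identical(m1$par, m3$par))
  set.seed(5)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  expect_identical(network_forward(m1, x), network_forward(m2, x))
})

test_that("prediction pads arbitrary sizes and strips the padding", {
  m <- build_network(small_cfg(), seed = 2)
  set.seed(2)
  x <- array(rnorm(13 * 9 * 6 * 2), c(13, 9, 6, 2))
  out <- predict_integrity(m, x)
  expect_equal(dim(out$probs), c(13, 9, 6, 3))
  expect_equal(dim(out$mask), c(13, 9, 6))
  expect_true(all(out$mask %in% 0:2))
})

test_that("Tversky loss at alpha=beta=0.5 equals soft Dice on random tensors", {
  set.seed(21)
  cfg <- loss_config(alpha = 0.5, beta = 0.5, smooth = 0.5)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    P <- matrix(stats::rexp(n * 3), n, 3)
    P <- P / rowSums(P)
    G <- lungfissure:::one_hot(sample(0:2, n, TRUE), 3)
    expect_equal(tversky_loss(P, G, cfg), oracle_dice_loss(P, G, cfg$smooth),
                 tolerance = 1e-6)
  }
})

test_that("perfect prediction yields near-zero loss bounded by the stabilizer", {
  set.seed(22)
  labels <- sample(0:2, 200, TRUE)
  P <- lungfissure:::one_hot(labels, 3)
  s <- 1
  l <- tversky_loss(P, labels, loss_config(smooth = s))
  expect_lte(l, 3 * s / (min(table(factor(labels, levels = 0:2))) + s) + 1e-12)
  expect_gte(l, 0)
})

test_that("hand-expanded two-voxel Tversky example matches the implementation", {
  # truth = [class1, class0]; pred rows (0.6, 0.4) for class0/class1
  P <- rbind(c(0.6, 0.4), c(0.6, 0.4))
  G <- rbind(c(0, 1), c(1, 0))
  a <- 0.05; b <- 0.95
  # class0: S = 0.6, FP = 0.6, FN = 0.4 -> TI = .6/(.6 + .05*.6 + .95*.4)
  ti0 <- 0.6 / (0.6 + a * 0.6 + b * 0.4)
  # class1: S = 0.4, FP = 0.4, FN = 0.6 -> TI = .4/(.4 + .05*.4 + .95*.6)
  ti1 <- 0.4 / (0.4 + a * 0.4 + b * 0.6)
  want <- (1 - ti0) + (1 - ti1)
  got <- tversky_loss(P, G, loss_config(alpha = a, beta = b, smooth = 0))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("loss is permutation-equivariant over voxels", {
  set.seed(23)
  n <- 60
  P <- matrix(stats::rexp(n * 3), n, 3); P <- P / rowSums(P)
  G <- lungfissure:::one_hot(sample(0:2, n, TRUE), 3)
  perm <- sample(n)
  expect_equal(tversky_loss(P, G), tversky_loss(P[perm, ], G[perm, ]),
               tolerance = 1e-12)
})

test_that("moving probability mass toward the true class lowers the loss", {
  set.seed(24)
  for (i in 1:10) {
    n <- 40
    P <- matrix(stats::rexp(n * 3), n, 3); P <- P / rowSums(P)
    labels <- sample(0:2, n, TRUE)
    G <- lungfissure:::one_hot(labels, 3)
    v <- sample(n, 1)
    wrong <- which(G[v, ] == 0)[1]
    P2 <- P
    delta <- 0.5 * P2[v, wrong]
    P2[v, wrong] <- P2[v, wrong] - delta
    P2[v, labels[v] + 1] <- P2[v, labels[v] + 1] + delta
    expect_lt(tversky_loss(P2, G), tversky_loss(P, G))
  }
})

test_that("a fissure false negative costs more than a symmetric false positive", {
  # 100 voxels: 10 fissure-class (class 1), 90 background (class 0), 2 classes
  n_f <- 10; n_b <- 90
  G <- rbind(matrix(rep(c(0, 1), n_f), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 0), n_b), ncol = 2, byrow = TRUE))
  P0 <- G  # perfect
  eps <- 0.2
  # false negative: fissure voxel loses eps to background
  Pfn <- P0; Pfn[1, ] <- c(eps, 1 - eps)
  # false positive: background voxel gains eps of fissure
  Pfp <- P0; Pfp[n_f + 1, ] <- c(1 - eps, eps)
  cfg <- loss_config(alpha = 0.05, beta = 0.95, smooth = 0)
  base <- tversky_loss(P0, G, cfg)
  expect_gt(tversky_loss(Pfn, G, cfg) - base,
            tversky_loss(Pfp, G, cfg) - base)
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(42)
  cfg <- small_cfg()
  m <- build_network(cfg, seed = 3)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  truth <- array(sample(0:2, 8 * 8 * 4, TRUE), c(8, 8, 4))
  lc <- loss_config()
  cache <- new.env(parent = emptyenv())
  p <- network_forward(m, x, cache)
  tl <- tversky_loss(p, truth, lc, grad = TRUE)
  dp <- tl$grad; dim(dp) <- dim(p)
  g <- lungfissure:::network_backward(m, dp, cache)
  eps <- 1e-5
  for (nm in names(m$par)) {
    pa <- m$par[[nm]]
    for (i in sample(length(pa), min(2, length(pa)))) {
      m2 <- m
      m2$par[[nm]][i] <- pa[i] + eps
      l1 <- tversky_loss(network_forward(m2, x), truth, lc)
      m2$par[[nm]][i] <- pa[i] - eps
      l0 <- tversky_loss(network_forward(m2, x), truth, lc)
      num <- (l1 - l0) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i])),
                1e-3, label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip weights and config", {
  tmp <- withr::local_tempfile(fileext = ".rds")
  m <- build_network(small_cfg(), seed = 7)
  hist <- data.frame(epoch = 1:2, train_loss = c(1, 0.5), val_loss = c(1, 0.6))
  save_checkpoint(m, tmp, history = hist)
  m2 <- load_checkpoint(tmp)
  expect_identical(m2$par, m$par)
  expect_equal(unclass(m2$cfg), unclass(m$cfg))
  expect_equal(m2$history, hist)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  expect_identical(network_forward(m, x), network_forward(m2, x))
})
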