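planar_surface <- function(d = c(8L, 8L, 3L), z = 2L) {
  s <- array(FALSE, d); s[, , z] <- TRUE; s
}

test_that("false-positive removal zeroes everything off the surface only", {
  surf <- planar_surface()
  raw <- array(0L, dim(surf))
  raw[, , 1] <- 1L             # stray off-surface intact labels
  raw[, , 2] <- rep(c(1L, 2L), length.out = 64)
  out <- remove_false_positives(raw, array(as.integer(surf), dim(surf)))
  expect_true(all(out[, , 1] == 0L))
  expect_identical(out[, , 2], raw[, , 2])
  expect_identical(remove_false_positives(out, array(as.integer(surf), dim(surf))),
                   out)  # idempotent
})

test_that("fill assigns strict majority and breaks ties toward incomplete", {
  surf <- array(FALSE, c(5, 5, 1)); surf[1:5, 1, 1] <- TRUE
  m <- array(0L, c(5, 5, 1))
  m[1:2, 1, 1] <- 1L; m[4, 1, 1] <- 2L
  # voxel 3 has neighbours {1 (from 2), 2 (from 4)} -> tie -> incomplete
  out <- fill_false_negatives(m, array(as.integer(surf), dim(surf)))
  expect_equal(out[3, 1, 1], 2L)
  expect_true(all(out[surf] > 0L))

  m2 <- array(0L, c(3, 3, 3))
  surf2 <- array(TRUE, c(3, 3, 3))
  m2[] <- 1L; m2[2, 2, 2] <- 0L; m2[1, 1, 1] <- 2L
  # centre sees 25 intact + 1 incomplete -> strict majority intact
  out2 <- fill_false_negatives(m2, array(1L, c(3, 3, 3)))
  expect_equal(out2[2, 2, 2], 1L)
})

test_that("fill propagates along a line and errors with nothing to propagate", {
  surf <- array(FALSE, c(1, 8, 1)); surf[1, , 1] <- TRUE
  m <- array(0L, c(1, 8, 1))
  m[1, 1:2, 1] <- 1L; m[1, 6:8, 1] <- 2L
  out <- fill_false_negatives(m, array(as.integer(surf), dim(surf)))
  expect_identical(as.vector(out[1, , 1]), c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
  empty <- array(0L, c(1, 8, 1))
  expect_error(fill_false_negatives(empty, array(as.integer(surf), dim(surf))),
               "no intact or incomplete")
})

test_that("stragglers disconnected from labels take the nearest label's class", {
  surf <- array(FALSE, c(9, 1, 1)); surf[c(1, 2, 9), 1, 1] <- TRUE
  m <- array(0L, c(9, 1, 1)); m[1:2, 1, 1] <- 2L
  # voxel 9 is not 26-connected to any labeled voxel through the surface
  out <- fill_false_negatives(m, array(as.integer(surf), dim(surf)),
                              postprocess_config(fill_max_iters = 3))
  expect_equal(out[9, 1, 1], 2L)
})

test_that("smoothing flips isolated specks and fixes uniform surfaces", {
  surf <- planar_surface(c(5, 5, 3), 2)
  m <- array(0L, c(5, 5, 3))
  m[, , 2] <- 1L
  sm <- smooth_labels(m, array(as.integer(surf), dim(surf)))
  expect_identical(sm, m)  # uniform surface is a fixed point
  m[3, 3, 2] <- 2L         # single incomplete voxel amid 8 intact neighbours
  sm2 <- smooth_labels(m, array(as.integer(surf), dim(surf)))
  expect_equal(sm2[3, 3, 2], 1L)
})

test_that("full pipeline fixes support exactly on the surface; perfect input unchanged", {
  set.seed(81)
  rs <- random_surface_mask(c(14L, 14L, 10L), p_intact = 0.7)
  surf_int <- array(as.integer(rs$surf), dim(rs$surf))
  out <- postprocess_prediction(rs$mask, surf_int)
  expect_identical(out > 0L, rs$surf)
  # a mask that is already smooth and complete is a fixed point
  flat <- array(0L, c(6, 6, 3)); flat[, , 2] <- 1L
  fs <- array(0L, c(6, 6, 3)); fs[, , 2] <- 1L
  expect_identical(postprocess_prediction(flat, fs), flat)
  # all-background raw with non-empty surface errors in the fill step
  expect_error(postprocess_prediction(array(0L, c(6, 6, 3)), fs),
               "no intact or incomplete")
})

test_that("three-step pipeline matches the literal re-implementation on random masks", {
  set.seed(77)
  for (i in 1:20) {
    rs <- random_surface_mask(c(12L, 12L, 8L), p_intact = stats::runif(1, .2, .8))
    m <- rs$mask
    # corrupt: delete some labels, add off-surface noise
    drop <- stats::runif(length(m)) < 0.3
    m[drop & rs$surf] <- 0L
    noise <- stats::runif(length(m)) < 0.05
    m[noise & !rs$surf] <- sample(1:2, sum(noise & !rs$surf), TRUE)
    if (!any(m[rs$surf] > 0L)) next
    got <- postprocess_prediction(m, array(as.integer(rs$surf), dim(rs$surf)))
    want <- oracle_postprocess(m, rs$surf)
    expect_identical(got, want, label = sprintf("instance %d", i))
  }
})

test_that("pipeline is label-permutation equivariant on tie-free inputs", {
  set.seed(91)
  surf <- planar_surface(c(10, 10, 3), 2)
  m <- array(0L, c(10, 10, 3))
  m[, , 2] <- ifelse(stats::runif(100) < 0.5, 1L, 2L)
  m[2:3, 2:3, 2] <- 0L  # holes to fill
  surf_int <- array(as.integer(surf), dim(surf))
  a <- postprocess_prediction(m, surf_int)
  swap <- function(x) { y <- x; y[x == 1L] <- 2L; y[x == 2L] <- 1L; y }
  cfg_swap <- postprocess_config(tie_break = "intact")  # mirror the tie rule
  b <- postprocess_prediction(swap(m), surf_int, cfg_swap)
  expect_identical(swap(a), b)
})

test_that("connectivity validation rejects unsupported neighbourhoods", {
  expect_error(postprocess_config(connectivity = 10), "6, 18 or 26")
  expect_s3_class(postprocess_config(connectivity = 6), "postprocess_config")
})
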