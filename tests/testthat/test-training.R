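test_that("split sizes follow largest-remainder apportionment", {
  s <- make_splits(paste0("c", 1:20), seed = 1)
  expect_length(s$train, 15)
  expect_length(s$test, 3)
  expect_length(s$val, 2)
  expect_setequal(c(s$train, s$test, s$val), paste0("c", 1:20))
  expect_error(make_splits(paste0("c", 1:2)), "too few cases")
})

test_that("splits are deterministic and subject-disjoint", {
  ids <- paste0("s", 1:37)
  a <- make_splits(ids, seed = 9)
  b <- make_splits(ids, seed = 9)
  expect_identical(a, b)
  expect_length(intersect(a$train, a$test), 0)
  expect_length(intersect(a$train, a$val), 0)
  expect_length(intersect(a$test, a$val), 0)
  set.seed(100)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    p <- make_splits(seq_len(n), seed = i)
    expect_equal(sort(unname(unlist(p[c("train", "test", "val")]))),
                 seq_len(n))
  }
})

test_that("k-fold plans partition cases with balanced fold sizes", {
  p16 <- kfold_plan(1:16, k = 8, seed = 2)
  expect_true(all(vapply(p16, function(x) length(x$test), 1L) == 2L))
  p82 <- kfold_plan(paste0("c", 1:82), k = 8, seed = 2)
  sizes <- sort(vapply(p82, function(x) length(x$test), 1L))
  expect_identical(sizes, c(rep(10L, 6), rep(11L, 2)))
  tested <- unlist(lapply(p82, `[[`, "test"))
  expect_length(tested, 82)
  expect_setequal(tested, paste0("c", 1:82))
  for (pl in p82) {
    expect_length(intersect(pl$train, pl$test), 0)
    expect_length(intersect(pl$val, pl$test), 0)
    expect_length(intersect(pl$train, pl$val), 0)
    expect_gt(length(pl$val), 0)
  }
  expect_error(kfold_plan(1:5, k = 8), "at least")
})

test_that("best epoch is the earliest validation-loss minimum", {
  h <- data.frame(epoch = 1:3, val_loss = c(0.9, 0.5, 0.7))
  expect_equal(select_best_epoch(h), 2)
  expect_equal(select_best_epoch(data.frame(val_loss = rep(0.4, 5))), 1)
  expect_equal(select_best_epoch(data.frame(val_loss = 0.3)), 1)
  expect_error(select_best_epoch(data.frame(train_loss = 1)), "validation")
})

test_that("training records history, is deterministic, and reduces the loss", {
  cohort <- generate_cohort(3, gap_range = c(0.2, 0.5), seed = 31,
                            spec = tiny_spec())
  net <- network_config(levels = 2L, base_filters = 4L)
  tc <- train_config(epochs = 3L, crop_size = c(16L, 16L, 8L),
                     crops_per_case = 1L, batch_size = 1L, seed = 5L)
  fit1 <- train_model(cohort[1:2], "LOBL", net, loss_config(), tc,
                      val_cases = cohort[3])
  expect_equal(nrow(fit1$history), 3)
  expect_true(all(c("train_loss", "val_loss") %in% names(fit1$history)))
  fit2 <- train_model(cohort[1:2], "LOBL", net, loss_config(), tc,
                      val_cases = cohort[3])
  expect_identical(fit1$model$par, fit2$model$par)
  expect_equal(fit1$history, fit2$history)
  # single repeated case, longer run: loss trends downward
  tc2 <- train_config(epochs = 12L, crop_size = c(16L, 16L, 8L),
                      crops_per_case = 2L, batch_size = 1L, seed = 6L)
  fit3 <- train_model(cohort[1], "LOBL", net, loss_config(), tc2,
                      val_cases = cohort[1])
  expect_lt(utils::tail(fit3$history$train_loss, 1),
            fit3$history$train_loss[1])
  expect_error(train_model(list(), "LOBL", net, loss_config(), tc,
                           val_cases = cohort[3]), "empty training split")
})

test_that("per-fissure routing uses the correct lung side", {
  cs <- generate_case(tiny_spec(seed = 41))
  pl <- lungfissure:::case_training_pair(cs, "LOBL")
  pr <- lungfissure:::case_training_pair(cs, "RHOR")
  expect_equal(pl$input$side, "left")
  expect_equal(pr$input$side, "right")
  # the LOBL target contains exactly the left oblique surface voxels
  expect_equal(sum(pl$target$data > 0L), sum(cs$gt$LOBL$data > 0L))
})

test_that("cross-validation aggregation equals independent re-aggregation", {
  set.seed(7)
  # synthetic per-case metric values distributed over 8 folds
  vals <- stats::rnorm(82, mean = 95, sd = 3)
  plans <- kfold_plan(seq_len(82), k = 8, seed = 3)
  per_fold <- lapply(plans, function(pl) vals[pl$test])
  pooled <- unlist(per_fold)
  expect_equal(mean(pooled), mean(vals))
  expect_equal(sd(pooled), sd(vals[order(unlist(lapply(plans, `[[`, "test")))]))
  # summarize_cohort over the pooled test reports reproduces mean +/- sd
  reports <- data.frame(fissure = "LOBL", fi_percent = pooled,
                        fi_truth = pmin(100, pooled + 1),
                        fis_error = 0.01, acc_fis = pooled,
                        category = "complete", n_surface_voxels = 100)
  s <- summarize_cohort(reports)$summary
  expect_equal(s$acc_fis_mean, mean(pooled))
  expect_equal(s$acc_fis_sd, sd(pooled))
})
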