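#' Training configuration
#'
#' Adam optimization with a static learning rate of 0.0002, random fixed-size
#' crops of (128, 128, 64) by default, and subject-level train/test/validation
#' split proportions 0.75/0.15/0.10.
#'
#' @param learning_rate Static Adam learning rate.
#' @param epochs Number of epochs.
#' @param batch_size Crops per optimizer step.
#' @param crop_size Integer length-3 training crop size.
#' @param crops_per_case Random crops drawn from each case per epoch.
#' @param fg_crop_prob Probability a crop is forced to contain fissure voxels.
#' @param proportions Train/test/validation proportions (sum to 1).
#' @param seed Integer seed controlling initialization, splits and cropping.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, epochs = 20L, batch_size = 2L,
                         crop_size = c(128L, 128L, 64L), crops_per_case = 4L,
                         fg_crop_prob = 0.5,
                         proportions = c(train = 0.75, test = 0.15, val = 0.10),
                         seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("train_config: proportions must be positive and sum to 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size),
                 crops_per_case = as.integer(crops_per_case),
                 fg_crop_prob = fg_crop_prob,
                 proportions = proportions, seed = as.integer(seed)),
            class = "train_config")
}

# largest-remainder apportionment of n into parts proportional to p
apportion <- function(n, p) {
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Subject-level random split
#'
#' Randomly partitions case identifiers into train/test/validation sets with
#' sizes apportioned by largest remainder. The split is at the subject level
#' (never at the crop level) and deterministic given `seed`.
#'
#' @param case_ids Character or integer identifiers.
#' @param proportions Named proportions (`train`, `test`, `val`) summing to 1.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `train`, `test`, `val`.
#' @export
make_splits <- function(case_ids,
                        proportions = c(train = 0.75, test = 0.15, val = 0.10),
                        seed = 1L) {
  n <- length(case_ids)
  sizes <- apportion(n, proportions)
  if (any(sizes < 1L))
    stop("make_splits: too few cases (", n, ") for non-empty splits; need at ",
         "least ", ceiling(1 / min(proportions)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(case_ids)
  structure(list(train = perm[seq_len(sizes[1])],
                 test = perm[sizes[1] + seq_len(sizes[2])],
                 val = perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
            class = "split_plan")
}

#' k-fold cross-validation plan
#'
#' Shuffles the cases into `k` folds whose sizes differ by at most one; plan
#' `i` uses fold `i` as its test set, with a validation carve-out (the `val`
#' proportion, default 0.10) taken from the remaining training portion.
#'
#' @param case_ids Identifiers.
#' @param k Number of folds (default 8).
#' @param seed Integer seed.
#' @param val_prop Validation fraction carved from each fold's training set.
#' @return List of `k` `split_plan` objects; each case appears in exactly one
#'   test fold.
#' @export
kfold_plan <- function(case_ids, k = 8L, seed = 1L, val_prop = 0.10) {
  n <- length(case_ids)
  if (n < k) stop("kfold_plan: need at least k = ", k, " cases, got ", n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(case_ids)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- perm[starts[i]:ends[i]]
    rest <- setdiff(perm, test)
    n_val <- max(1L, round(val_prop * length(rest)))
    val <- rest[seq_len(n_val)]
    structure(list(train = setdiff(rest, val), test = test, val = val,
                   fold = i), class = "split_plan")
  })
}

#' Select the best epoch from a training history
#'
#' The epoch (1-based) with the minimum validation loss; ties break toward
#' the earlier epoch.
#'
#' @param history Data frame with a `val_loss` column.
#' @return Integer epoch index.
#' @export
select_best_epoch <- function(history) {
  if (is.null(history$val_loss) || nrow(history) == 0L ||
      all(is.na(history$val_loss)))
    stop("select_best_epoch: history has no validation entries")
  which.min(history$val_loss)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(par, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(par = par, state = state)
}

# ---- case plumbing ------------------------------------------------------

# Per-fissure training pair: two-channel lung crop + ground truth cropped to
# the same box. LOBL uses the left-lung input; ROBL/RHOR share the right one.
case_training_pair <- function(case, kind, margin = 2L) {
  kind <- as_fissure_kind(kind)
  prob <- case$fissure_prob[[kind$side]]
  input <- make_network_input(case$ct, prob, case$lung_mask, kind$side, margin)
  gt_full <- case$gt[[kind$name]]
  target <- crop_volume(gt_full, input$box)
  list(input = input, target = target, kind = kind$name)
}

#' Train a fissure-integrity network
#'
#' Trains one attention U-Net for a single fissure on a set of cases under
#' the Tversky loss with Adam. Each epoch draws `crops_per_case` random crops
#' per training case; validation loss is evaluated on whole (padded) lung
#' inputs after every epoch and the weights of the best validation epoch are
#' returned. Fully deterministic given `train_cfg$seed`.
#'
#' @param cases List of `phantom_case` (or equivalent bundles).
#' @param kind Fissure name: `"LOBL"`, `"ROBL"` or `"RHOR"`.
#' @param net_cfg A [network_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param val_cases Optional held-out cases for validation; if `NULL`, a
#'   validation carve-out is taken from `cases` by the configured proportions.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best-epoch weights), `history` (data frame of
#'   per-epoch `train_loss`/`val_loss`), `best_epoch`.
#' @export
train_model <- function(cases, kind, net_cfg = network_config(),
                        loss_cfg = loss_config(),
                        train_cfg = train_config(), val_cases = NULL,
                        verbose = FALSE) {
  kind <- as_fissure_kind(kind)
  if (is.null(val_cases)) {
    nv <- max(1L, round(train_cfg$proportions[["val"]] * length(cases)))
    if (length(cases) - nv < 1L)
      stop("train_model: empty training split")
    val_cases <- cases[seq_len(nv)]
    cases <- cases[-seq_len(nv)]
  }
  if (length(cases) == 0L) stop("train_model: empty training split")
  pairs <- lapply(cases, case_training_pair, kind = kind)
  val_pairs <- lapply(val_cases, case_training_pair, kind = kind)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(train_cfg$seed)
  model <- build_network(net_cfg, seed = train_cfg$seed)
  state <- adam_init(model$par)
  best <- list(val = Inf, par = model$par, epoch = NA_integer_)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  n_crops <- length(pairs) * train_cfg$crops_per_case
  for (ep in seq_len(train_cfg$epochs)) {
    order_ <- rep(sample(seq_along(pairs)), times = train_cfg$crops_per_case)
    losses <- numeric(0)
    batch_grads <- NULL; batch_n <- 0L; batch_loss <- 0
    for (ci in order_) {
      pr <- pairs[[ci]]
      rc <- random_crop(pr$input, pr$target, size = train_cfg$crop_size,
                        fg_prob = train_cfg$fg_crop_prob)
      cache <- new.env(parent = emptyenv())
      probs <- network_forward(model, rc$data, cache)
      tl <- tversky_loss(probs, rc$target, loss_cfg, grad = TRUE)
      dprobs <- tl$grad; dim(dprobs) <- dim(probs)
      g <- network_backward(model, dprobs, cache)
      batch_loss <- batch_loss + tl$loss
      batch_grads <- if (is.null(batch_grads)) g
                     else mapply(`+`, batch_grads, g, SIMPLIFY = FALSE)
      batch_n <- batch_n + 1L
      if (batch_n == train_cfg$batch_size) {
        batch_grads <- lapply(batch_grads, `/`, batch_n)
        st <- adam_step(model$par, batch_grads, state, train_cfg$learning_rate)
        model$par <- st$par; state <- st$state
        losses <- c(losses, batch_loss / batch_n)
        batch_grads <- NULL; batch_n <- 0L; batch_loss <- 0
      }
    }
    if (batch_n > 0L) {
      batch_grads <- lapply(batch_grads, `/`, batch_n)
      st <- adam_step(model$par, batch_grads, state, train_cfg$learning_rate)
      model$par <- st$par; state <- st$state
      losses <- c(losses, batch_loss / batch_n)
    }
    val_loss <- mean(vapply(val_pairs, function(pr) {
      pred <- predict_integrity(model, pr$input)
      tversky_loss(pred$probs, pr$target$data, loss_cfg)
    }, 1))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = val_loss))
    if (val_loss < best$val) best <- list(val = val_loss, par = model$par,
                                          epoch = ep)
    if (verbose)
      message(sprintf("[%s] epoch %d/%d train %.4f val %.4f", kind$name, ep,
                      train_cfg$epochs, mean(losses), val_loss))
  }
  model$par <- best$par
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Assess fissure integrity for one case
#'
#' Runs the full inference pipeline per fissure: preprocessing (per-lung crop
#' and channel assembly), network prediction, three-step post-processing
#' confined to the complete fissure surface extracted from the lobe
#' segmentation, and metric computation against ground truth when available.
#'
#' @param case A `phantom_case` (or equivalent bundle with `ct`, `lung_mask`,
#'   `lobes`, `fissure_prob`, optionally `gt`).
#' @param models Named list of `unet3d` models (names among LOBL/ROBL/RHOR).
#' @param pp_cfg A [postprocess_config()].
#' @param margin Bounding-box margin in voxels.
#' @return List with `report` (data frame, one row per fissure) and `masks`
#'   (final integrity masks per fissure, full grid).
#' @export
assess_case <- function(case, models, pp_cfg = postprocess_config(),
                        margin = 2L) {
  kinds <- fissure_kinds()
  reports <- list(); masks <- list()
  for (nm in names(models)) {
    kind <- kinds[[nm]]
    if (is.null(kind)) stop("assess_case: unknown fissure '", nm, "'")
    input <- make_network_input(case$ct, case$fissure_prob[[kind$side]],
                                case$lung_mask, kind$side, margin)
    pred <- predict_integrity(models[[nm]], input)
    raw_crop <- label_volume(pred$mask,
                             spacing = case$ct$spacing,
                             origin = case$ct$origin +
                               (input$box$start - 1L) * case$ct$spacing,
                             labels = 0:2)
    raw_full <- uncrop_volume(raw_crop, input$box, input$full_dim, fill = 0L)
    raw_full$origin <- case$ct$origin
    complete <- extract_complete_fissure(case$lobes, nm)
    final <- postprocess_prediction(raw_full, complete, pp_cfg)
    masks[[nm]] <- final
    if (!is.null(case$gt[[nm]]))
      reports[[nm]] <- fissure_report(final, case$gt[[nm]], nm)
    else
      reports[[nm]] <- data.frame(fissure = nm, fi_percent = fi_percent(final),
                                  fi_truth = NA_real_, fis_error = NA_real_,
                                  acc_fis = NA_real_,
                                  category = categorize_fissure(fi_percent(final)),
                                  n_surface_voxels = sum(final$data > 0L),
                                  stringsAsFactors = FALSE)
  }
  list(report = do.call(rbind, reports), masks = masks)
}
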