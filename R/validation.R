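#' Phantom parameter-recovery study
#'
#' End-to-end validation on synthetic data: generates a cohort of thoracic
#' phantoms with known per-fissure gap fractions, trains one small attention
#' U-Net per fissure on the training portion, and evaluates predicted versus
#' true FI% on held-out cases after full post-processing. This is the
#' package's scaled-down analog of a clinical correlation study: it
#' establishes that the pipeline recovers the generating parameter (fissure
#' integrity) from images alone.
#'
#' Default problem sizes are chosen so the whole study runs on a single CPU
#' in minutes: 40 cases on a 64x64x32 grid with gap fractions uniform in
#' `[0, 0.8]`, 30 training cases (3 of them carved out for validation), 10
#' test cases, a 3-level network with 8 base filters, and 20 epochs of two
#' 24x24x16 foreground-biased crops per case with single-crop Adam steps.
#'
#' @param seed Integer seed controlling cohort generation, initialization
#'   and cropping.
#' @param n_cases Cohort size.
#' @param n_test Held-out test cases.
#' @param shape Phantom grid.
#' @param gap_range Range of gap fractions.
#' @param fissures Fissures to train and evaluate.
#' @param epochs,base_filters,levels,crop_size,crops_per_case,batch_size
#'   Training-scale knobs passed through to [train_config()] /
#'   [network_config()].
#' @param verbose Print progress.
#' @return A `validation_study`: list with `reports` (per test case x
#'   fissure), `r2` (pooled predicted-vs-true FI% coefficient of
#'   determination), `mean_abs_fi_error`, `per_fissure` summary, `models`,
#'   `test_cases`, and the `seed`.
#' @export
run_validation_study <- function(seed = 1L, n_cases = 40L, n_test = 10L,
                                 shape = c(64L, 64L, 32L),
                                 gap_range = c(0, 0.8),
                                 fissures = c("LOBL", "ROBL", "RHOR"),
                                 epochs = 20L, base_filters = 8L, levels = 3L,
                                 crop_size = c(24L, 24L, 16L),
                                 crops_per_case = 2L, batch_size = 1L,
                                 verbose = FALSE) {
  seed <- as.integer(seed) %% 2147480000L
  cohort <- generate_cohort(n_cases, gap_range = gap_range, seed = seed,
                            spec = phantom_spec(shape = shape, seed = seed))
  n_train <- n_cases - n_test
  train_cases <- cohort[seq_len(n_train)]
  test_cases <- cohort[n_train + seq_len(n_test)]
  n_val <- max(1L, round(0.10 * n_train))
  val_cases <- train_cases[n_train - seq_len(n_val) + 1L]
  fit_cases <- train_cases[seq_len(n_train - n_val)]
  net_cfg <- network_config(levels = levels, base_filters = base_filters)
  models <- list()
  for (k in seq_along(fissures)) {
    nm <- fissures[k]
    if (verbose) message("training ", nm, " ...")
    fit <- train_model(fit_cases, nm, net_cfg, loss_config(),
                       train_config(epochs = epochs, crop_size = crop_size,
                                    crops_per_case = crops_per_case,
                                    batch_size = batch_size,
                                    seed = seed + 101L * k),
                       val_cases = val_cases, verbose = verbose)
    models[[nm]] <- fit$model
  }
  reports <- list()
  for (i in seq_along(test_cases)) {
    out <- assess_case(test_cases[[i]], models)
    out$report$case <- i
    reports[[i]] <- out$report
  }
  reports <- do.call(rbind, reports)
  pred <- reports$fi_percent
  truth <- reports$fi_truth
  r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  mae <- mean(abs(pred - truth))
  per_fissure <- do.call(rbind, lapply(split(reports, reports$fissure),
    function(r) data.frame(fissure = r$fissure[1],
                           mean_abs_fi_error = mean(abs(r$fi_percent - r$fi_truth)),
                           acc_fis_mean = mean(r$acc_fis))))
  structure(list(reports = reports, r2 = r2, mean_abs_fi_error = mae,
                 per_fissure = per_fissure, models = models,
                 test_cases = test_cases, seed = seed),
            class = "validation_study")
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf("<validation_study> %d test reports, R^2 = %.3f, mean |FI%% error| = %.2f\n",
              nrow(x$reports), x$r2, x$mean_abs_fi_error))
  print(x$per_fissure, row.names = FALSE)
  invisible(x)
}

#' Reproducibility study on regenerated phantoms
#'
#' Re-generates the study's test phantoms with identical geometry seeds but
#' fresh CT noise, re-runs the trained models, and reports the per-fissure
#' absolute difference in predicted FI% between the two runs — the synthetic
#' analog of repeating a subject's scan at a later timepoint under the
#' assumption that fissure integrity has not changed.
#'
#' @param study A `validation_study` from [run_validation_study()].
#' @param noise_offset Integer added to each case's seed to derive the new
#'   noise seed.
#' @return List with `diffs` (per case x fissure data frame of
#'   `fi_first`/`fi_second`/`abs_diff`) and `mean_abs_diff`.
#' @export
run_reproducibility_study <- function(study, noise_offset = 31337L) {
  stopifnot(inherits(study, "validation_study"))
  rows <- list()
  for (i in seq_along(study$test_cases)) {
    cs <- study$test_cases[[i]]
    spec2 <- cs$spec
    spec2$noise_seed <- (spec2$seed + noise_offset) %% 2147483629L
    cs2 <- generate_case(spec2)
    stopifnot(identical(cs2$lobes$data, cs$lobes$data))  # same geometry
    out2 <- assess_case(cs2, study$models)
    first <- study$reports[study$reports$case == i, ]
    m <- merge(first[, c("fissure", "fi_percent")],
               out2$report[, c("fissure", "fi_percent")],
               by = "fissure", suffixes = c("_first", "_second"))
    m$case <- i
    rows[[i]] <- m
  }
  diffs <- do.call(rbind, rows)
  diffs$abs_diff <- abs(diffs$fi_percent_first - diffs$fi_percent_second)
  list(diffs = diffs, mean_abs_diff = mean(diffs$abs_diff))
}
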