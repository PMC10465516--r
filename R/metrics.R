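#' Fissure integrity percentage
#'
#' FI% is the percentage of the complete fissure surface labeled intact:
#' `100 * #intact / #(intact + incomplete)`.
#'
#' @param mask Integrity mask ([label_volume()] or integer array) with labels
#'   0 background, 1 intact, 2 incomplete.
#' @return FI% in `[0, 100]`.
#' @export
fi_percent <- function(mask) {
  m <- if (inherits(mask, "volume3d")) mask$data else mask
  n_int <- sum(m == 1L)
  n_surf <- n_int + sum(m == 2L)
  if (n_surf == 0L)
    stop("fi_percent: mask has no fissure-surface voxels; FI% is undefined")
  100 * n_int / n_surf
}

#' Fissure integrity score error
#'
#' Relative error of the predicted FI% with respect to ground truth:
#' `(fi_pred - fi_truth) / fi_truth`, in `[-1, 1]` when both lie in
#' `[0, 100]`. Undefined when the ground-truth FI% is 0.
#'
#' @param fi_pred,fi_truth FI percentages.
#' @return Signed relative error.
#' @export
fis_error <- function(fi_pred, fi_truth) {
  if (any(fi_truth == 0))
    stop("fis_error: ground-truth FI% of 0 makes the relative error undefined")
  (fi_pred - fi_truth) / fi_truth
}

#' Voxelwise labeling accuracy along the complete fissure
#'
#' `100 * #correctly labeled surface voxels / #surface voxels`, evaluated on
#' the complete fissure surface, which must be identical in prediction and
#' ground truth (post-processing guarantees this).
#'
#' @param pred,truth Integrity masks on the same grid with the same surface
#'   support.
#' @return Accuracy percentage in `[0, 100]`.
#' @export
acc_fis <- function(pred, truth) {
  p <- if (inherits(pred, "volume3d")) pred$data else pred
  g <- if (inherits(truth, "volume3d")) truth$data else truth
  if (!identical(dim(p), dim(g)))
    stop("acc_fis: prediction and truth grids differ")
  sp <- p > 0L; sg <- g > 0L
  if (!identical(sp, sg))
    stop("acc_fis: prediction and truth cover different fissure surfaces (",
         sum(xor(sp, sg)), " discrepant voxel(s))")
  n <- sum(sg)
  if (n == 0L) stop("acc_fis: empty fissure surface")
  100 * sum(p[sg] == g[sg]) / n
}

#' Categorize a fissure by completeness
#'
#' `complete` if FI% >= 90 (the positive class for ROC analysis), `partial`
#' if 10 <= FI% < 90, `missing` if FI% < 10.
#'
#' @param fi FI percentage(s) in `[0, 100]`.
#' @return Character vector of categories.
#' @export
categorize_fissure <- function(fi) {
  stopifnot(all(fi >= 0 & fi <= 100))
  ifelse(fi >= 90, "complete", ifelse(fi >= 10, "partial", "missing"))
}

#' ROC AUC for complete-fissure detection
#'
#' Rank-based (Mann-Whitney) area under the ROC curve with the predicted FI%
#' as the continuous score and truth-category `complete` as the positive
#' class; ties contribute 1/2.
#'
#' @param score Numeric scores (predicted FI%).
#' @param truth_category Character vector of truth categories
#'   (`"complete"` / `"partial"` / `"missing"`) or a logical positive
#'   indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_complete <- function(score, truth_category) {
  pos <- if (is.logical(truth_category)) truth_category
         else truth_category == "complete"
  stopifnot(length(score) == length(pos))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("auc_complete: need at least one positive and one negative case")
  r <- rank(score)  # average ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Longitudinal reproducibility of FI%
#'
#' Per-case absolute difference in FI percentage points between pairs of
#' timepoints, summarized as mean and sample SD per pair. Cases missing a
#' timepoint are excluded with a warning. Set `relative = TRUE` for the
#' relative variant (difference divided by the first timepoint's FI%).
#'
#' @param fi_by_timepoint Data frame with columns `case`, `timepoint`, `fi`.
#' @param pairs Optional list of length-2 character vectors naming timepoint
#'   pairs; defaults to all unordered pairs.
#' @param relative Report relative instead of absolute differences.
#' @return Data frame with columns `pair`, `n`, `mean_abs_diff`, `sd_abs_diff`.
#' @export
reproducibility <- function(fi_by_timepoint, pairs = NULL, relative = FALSE) {
  df <- as.data.frame(fi_by_timepoint)
  stopifnot(all(c("case", "timepoint", "fi") %in% names(df)))
  tps <- unique(as.character(df$timepoint))
  if (is.null(pairs)) {
    if (length(tps) < 2L) stop("reproducibility: need at least two timepoints")
    pairs <- utils::combn(tps, 2, simplify = FALSE)
  }
  out <- lapply(pairs, function(p) {
    a <- df[df$timepoint == p[1], c("case", "fi")]
    b <- df[df$timepoint == p[2], c("case", "fi")]
    m <- merge(a, b, by = "case", suffixes = c("_a", "_b"))
    dropped <- setdiff(union(a$case, b$case), m$case)
    if (length(dropped) > 0L)
      warning("reproducibility: excluding case(s) missing a timepoint: ",
              paste(dropped, collapse = ", "))
    d <- abs(m$fi_a - m$fi_b)
    if (relative) d <- d / m$fi_a
    data.frame(pair = paste(p, collapse = " vs "), n = nrow(m),
               mean_abs_diff = mean(d),
               sd_abs_diff = if (nrow(m) > 1L) stats::sd(d) else 0)
  })
  do.call(rbind, out)
}

#' Per-fissure quantitative report
#'
#' Bundles the metrics for one predicted/ground-truth mask pair.
#'
#' @param pred,truth Integrity masks sharing one surface.
#' @param kind Fissure name.
#' @return A one-row data frame: `fissure`, `fi_percent`, `fi_truth`,
#'   `fis_error` (signed; `NA` when truth FI% is 0), `acc_fis`, `category`,
#'   `n_surface_voxels`.
#' @export
fissure_report <- function(pred, truth, kind = NA_character_) {
  fi_p <- fi_percent(pred)
  fi_t <- fi_percent(truth)
  data.frame(
    fissure = if (is.character(kind)) kind else as_fissure_kind(kind)$name,
    fi_percent = fi_p,
    fi_truth = fi_t,
    fis_error = if (fi_t > 0) fis_error(fi_p, fi_t) else NA_real_,
    acc_fis = acc_fis(pred, truth),
    category = categorize_fissure(fi_p),
    n_surface_voxels = sum((if (inherits(truth, "volume3d")) truth$data else truth) > 0L),
    stringsAsFactors = FALSE)
}

#' Cohort summary of fissure reports
#'
#' Mean and sample (n−1) SD of each metric per fissure and optional grouping,
#' plus the overall complete-vs-rest AUC per fissure. FIS error is aggregated
#' as the mean of absolute values (signed mean also reported); cases with
#' ground-truth FI% = 0 are excluded from FIS-error aggregation and counted
#' in `n_fis_excluded`.
#'
#' @param reports Data frame of rows from [fissure_report()].
#' @param grouping Optional factor/character vector (one entry per report row).
#' @return A list with `summary` (per fissure x group) and `auc` (per
#'   fissure; `NA` where only one truth class is present).
#' @export
summarize_cohort <- function(reports, grouping = NULL) {
  stopifnot(nrow(reports) > 0L)
  reports$group <- if (is.null(grouping)) "all" else as.character(grouping)
  sd1 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  keys <- unique(reports[, c("fissure", "group")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    r <- reports[reports$fissure == keys$fissure[i] &
                 reports$group == keys$group[i], ]
    fe <- r$fis_error[!is.na(r$fis_error)]
    data.frame(
      fissure = keys$fissure[i], group = keys$group[i], n = nrow(r),
      fi_mean = mean(r$fi_percent), fi_sd = sd1(r$fi_percent),
      fis_error_mean_abs = if (length(fe)) mean(abs(fe)) else NA_real_,
      fis_error_sd_abs = if (length(fe)) sd1(abs(fe)) else NA_real_,
      fis_error_mean_signed = if (length(fe)) mean(fe) else NA_real_,
      n_fis_excluded = sum(is.na(r$fis_error)),
      acc_fis_mean = mean(r$acc_fis), acc_fis_sd = sd1(r$acc_fis),
      stringsAsFactors = FALSE)
  })
  auc <- lapply(unique(reports$fissure), function(f) {
    r <- reports[reports$fissure == f, ]
    truth_pos <- categorize_fissure(r$fi_truth) == "complete"
    a <- if (length(unique(truth_pos)) < 2L) NA_real_
         else auc_complete(r$fi_percent, truth_pos)
    data.frame(fissure = f, auc = a, n_pos = sum(truth_pos),
               n_neg = sum(!truth_pos), stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), auc = do.call(rbind, auc))
}
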