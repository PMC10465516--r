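test_that("phantom geometry honours the label scheme and lung sides", {
  cs <- generate_case(tiny_spec(seed = 1))
  expect_setequal(unique(as.vector(cs$lobes$data)), 0:5)
  expect_setequal(unique(as.vector(cs$lung_mask$data)), 0:2)
  # left lobes inside left lung, right lobes inside right lung
  expect_true(all(cs$lung_mask$data[cs$lobes$data %in% 1:2] == 1L))
  expect_true(all(cs$lung_mask$data[cs$lobes$data %in% 3:5] == 2L))
  # parenchyma dark, chest wall bright (well beyond noise)
  expect_lt(mean(cs$ct$data[cs$lung_mask$data > 0L]),
            mean(cs$ct$data[cs$lung_mask$data == 0L]) - 500)
})

test_that("ground-truth masks live exactly on the extracted boundary surfaces", {
  cs <- generate_case(tiny_spec(seed = 3,
                                gap_fraction = c(LOBL = .4, ROBL = .2,
                                                 RHOR = .6)))
  for (nm in c("LOBL", "ROBL", "RHOR")) {
    comp <- extract_complete_fissure(cs$lobes, nm)
    expect_identical(cs$gt[[nm]]$data > 0L, comp$data == 1L, label = nm)
    expect_equal(cs$true_fi[[nm]], fi_percent(cs$gt[[nm]]), label = nm)
  }
})

test_that("gap fractions steer the true FI%", {
  cs0 <- generate_case(tiny_spec(seed = 5, gap_fraction = 0))
  expect_equal(unname(cs0$true_fi), rep(100, 3))
  cs1 <- generate_case(tiny_spec(seed = 5, gap_fraction = c(LOBL = 1, ROBL = 0,
                                                            RHOR = 0)))
  expect_equal(cs1$true_fi[["LOBL"]], 0)
  cs30 <- generate_case(tiny_spec(seed = 7, gap_fraction = c(LOBL = 0,
                                                             ROBL = 0.30,
                                                             RHOR = 0)))
  expect_lt(abs(cs30$true_fi[["ROBL"]] - 70), 5)
})

test_that("achieved FI% decreases monotonically with requested gap fraction", {
  fis <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(g)
    generate_case(tiny_spec(seed = 11,
                            gap_fraction = c(LOBL = g, ROBL = 0,
                                             RHOR = 0)))$true_fi[["LOBL"]], 1)
  expect_true(all(diff(fis) < 0))
})

test_that("incomplete patches are contiguous and the CT sheet is absent there", {
  cs <- generate_case(tiny_spec(seed = 13,
                                gap_fraction = c(LOBL = .35, ROBL = 0,
                                                 RHOR = 0), noise_sd = 0))
  g <- cs$gt$LOBL$data
  # fissure sheet bright only on intact voxels
  expect_equal(mean(cs$ct$data[g == 1L]), -650, tolerance = 1e-9)
  expect_equal(mean(cs$ct$data[g == 2L]), -850, tolerance = 1e-9)
  # contiguity: incomplete patch is one 26-connected component
  idx <- which(g == 2L, arr.ind = TRUE)
  comp_id <- integer(nrow(idx)); comp_id[1] <- 1L
  frontier <- 1L; next_id <- 1L
  remaining <- seq_len(nrow(idx))[-1]
  while (length(remaining) > 0L && length(frontier) > 0L) {
    dmat <- abs(outer(idx[frontier, 1], idx[remaining, 1], `-`)) <= 1 &
            abs(outer(idx[frontier, 2], idx[remaining, 2], `-`)) <= 1 &
            abs(outer(idx[frontier, 3], idx[remaining, 3], `-`)) <= 1
    hit <- remaining[colSums(dmat) > 0]
    if (length(hit) == 0L) break
    comp_id[hit] <- 1L
    frontier <- hit
    remaining <- setdiff(remaining, hit)
  }
  expect_equal(sum(comp_id == 1L), nrow(idx))
})

test_that("probability maps separate intact from incomplete fissure", {
  cs <- generate_case(tiny_spec(seed = 17,
                                gap_fraction = c(LOBL = .3, ROBL = .3,
                                                 RHOR = .3)))
  for (nm in c("LOBL", "ROBL", "RHOR")) {
    side <- fissure_kinds()[[nm]]$side
    p <- cs$fissure_prob[[side]]$data
    g <- cs$gt[[nm]]$data
    expect_gte(mean(p[g == 1L]) - mean(p[g == 2L]), 0.4)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("generation is deterministic given the seed and separates noise", {
  a <- generate_case(tiny_spec(seed = 23))
  b <- generate_case(tiny_spec(seed = 23))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$lobes$data, b$lobes$data)
  # same geometry seed, different noise seed: labels identical, CT differs
  c2 <- generate_case(tiny_spec(seed = 23, noise_seed = 999))
  expect_identical(a$lobes$data, c2$lobes$data)
  expect_identical(a$gt$LOBL$data, c2$gt$LOBL$data)
  expect_false(identical(a$ct$data, c2$ct$data))
})

test_that("cohorts are reproducible and span the requested FI range", {
  co1 <- generate_cohort(6, gap_range = c(0, 0.6), seed = 4,
                         spec = tiny_spec())
  co2 <- generate_cohort(6, gap_range = c(0, 0.6), seed = 4,
                         spec = tiny_spec())
  for (i in seq_along(co1)) {
    expect_identical(co1[[i]]$ct$data, co2[[i]]$ct$data)
    expect_identical(co1[[i]]$gt$LOBL$data, co2[[i]]$gt$LOBL$data)
  }
  fis <- unlist(lapply(co1, function(cs) cs$true_fi))
  expect_gte(max(fis) - min(fis), 30)
  expect_error(generate_cohort(0), "n must be")
  expect_error(generate_cohort(2, gap_range = c(0.5, 0.1)), "hi >= lo")
})

test_that("infeasible specs are rejected", {
  expect_error(phantom_spec(shape = c(16, 64, 64)), ">= 32")
  expect_error(phantom_spec(gap_fraction = c(LOBL = 1.2, ROBL = 0, RHOR = 0)),
               "\\[0, 1\\]")
})

test_that("cases round-trip through the on-disk layout", {
  tmp <- withr::local_tempdir()
  cs <- generate_case(tiny_spec(seed = 29))
  d <- file.path(tmp, "case_001")
  write_case(cs, d)
  expect_setequal(list.files(d),
                  c("ct.nii.gz", "lung.nii.gz", "lobes.nii.gz",
                    "fissure_prob_left.nii.gz", "fissure_prob_right.nii.gz",
                    "gt_LOBL.nii.gz", "gt_ROBL.nii.gz", "gt_RHOR.nii.gz",
                    "case.json"))
  back <- read_case(d)
  expect_identical(back$lobes$data, cs$lobes$data)
  expect_identical(back$gt$RHOR$data, cs$gt$RHOR$data)
  expect_equal(unname(back$true_fi), unname(cs$true_fi), tolerance = 1e-9)
})
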