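fake_profile <- function(values, cell_id = "c", length_um = NA_real_) {
  structure(list(cell_id = cell_id, values = values, n = length(values),
                 length_um = length_um, normalized = NULL),
            class = "axis_profile")
}

test_that("profile normalization implements I*n/sum(I) with its identities", {
  expect_equal(normalize_profile(fake_profile(c(2, 2, 2, 2)))$normalized,
               c(1, 1, 1, 1))
  expect_equal(normalize_profile(fake_profile(c(1, 3)))$normalized,
               c(0.5, 1.5))
  withr::local_seed(8)
  for (rep in 1:20) {
    v <- runif(sample(5:80, 1), min = 0.01, max = 100)
    p <- normalize_profile(fake_profile(v))
    expect_lt(abs(sum(p$normalized) - p$n), 1e-9)
    expect_equal(mean(p$normalized), 1)
  }
  expect_error(normalize_profile(fake_profile(c(0, 0, 0))), "not positive")
})

test_that("medial axis of an axis-aligned rectangle recovers its length and width", {
  mask <- rect_mask(h = 10, w = 50)
  ax <- medial_axis(mask, 1L, pixel_size = 0.1)
  expect_equal(ax$length_um, 5.0, tolerance = 0.2 / 5.0)
  expect_equal(ax$mean_width_um, 1.0, tolerance = 0.1)
  expect_false(ax$non_rod)
  expect_false(ax$on_border)
})

test_that("a disk is measured but flagged as non-rod", {
  mask <- disk_mask(d = 11)
  ax <- medial_axis(mask, 1L, pixel_size = 0.1)
  expect_true(ax$non_rod)
  expect_equal(ax$length_um, 1.1, tolerance = 0.15)
  # the axis-averaged chord of a disk of diameter d is (pi/4) d
  expect_equal(ax$mean_width_um, 1.1 * pi / 4, tolerance = 0.15)
})

test_that("tiny cells are skipped with a warning; border cells are flagged", {
  mask <- matrix(0L, 30, 30)
  mask[15:16, 15:17] <- 1L
  expect_warning(expect_null(medial_axis(mask, 1L, pixel_size = 0.1)),
                 "minimum area")
  mask2 <- matrix(0L, 30, 60)
  mask2[1:8, 5:45] <- 1L  # touches row 1
  ax <- medial_axis(mask2, 1L, pixel_size = 0.1)
  expect_true(ax$on_border)
})

test_that("axis profiles sum 5 perpendicular pixels and track point sources", {
  mask <- rect_mask(h = 11, w = 41)
  ax <- medial_axis(mask, 1L, pixel_size = 0.1)
  img <- matrix(7, nrow(mask), ncol(mask))
  pr <- axis_profile(img, ax)
  expect_identical(pr$n, ax$n)
  interior <- 4:(pr$n - 3)
  expect_true(all(abs(pr$values[interior] - 35) < 1e-9))

  # single bright pixel on the axis peaks the profile at that position
  img2 <- matrix(0, nrow(mask), ncol(mask))
  k <- round(ax$n / 2)
  img2[round(ax$polyline[k, 2]), round(ax$polyline[k, 1])] <- 100
  pr2 <- axis_profile(img2, ax)
  expect_equal(which.max(pr2$values), k, tolerance = 1)
})

test_that("demograph rows are length-sorted, centred and sentinel-padded", {
  ps <- list(fake_profile(rep(1, 20), "a", 2.0),
             fake_profile(rep(1, 10), "b", 1.0),
             fake_profile(rep(1, 30), "c", 3.0))
  ps <- lapply(ps, normalize_profile)
  dg <- build_demograph(ps)
  expect_identical(dg$cell_ids, c("b", "a", "c"))
  expect_identical(dg$lengths, c(1.0, 2.0, 3.0))
  expect_false(is.unsorted(dg$lengths))
  for (i in 1:3) {
    span <- range(which(!is.na(dg$matrix[i, ])))
    expect_identical(diff(span) + 1L, c(10L, 20L, 30L)[i])   # contiguous
    expect_lte(abs(mean(span) - dg$midcell_col), 1)          # centred
  }
  # identical cells give identical rows
  same <- lapply(1:3, function(i) normalize_profile(
    fake_profile(c(1, 2, 3, 2, 1), paste0("s", i), 0.5)))
  dg2 <- build_demograph(same)
  expect_true(all(dg2$matrix[1, ] == dg2$matrix[2, ], na.rm = TRUE))
  expect_error(build_demograph(list()), "no profiles")
  expect_error(build_demograph(list(fake_profile(1:5))), "normalized")
})

test_that("midcell intensity is ~0 on uniform images and <=0 for bright poles", {
  mask <- rect_mask(h = 11, w = 51)
  ax <- medial_axis(mask, 1L, pixel_size = 0.1)
  img <- matrix(50, nrow(mask), ncol(mask))
  mc <- midcell_intensity(img, mask, ax)
  expect_equal(mc$net, 0)

  # bright poles: background >= midcell, net strictly negative
  img2 <- matrix(10, nrow(mask), ncol(mask))
  img2[, 1:25] <- 200
  img2[, (ncol(mask) - 24):ncol(mask)] <- 200
  mc2 <- midcell_intensity(img2, mask, ax)
  expect_lt(mc2$net, 0)

  # symmetric poles: one-sided and two-sided backgrounds agree
  mc3 <- midcell_intensity(img2, mask, ax, quarter = "one")
  expect_equal(mc3$net, mc2$net)
})

test_that("very short axes skip the midcell measure with a flag", {
  mask <- rect_mask(h = 5, w = 8, pad = 4)
  ax <- medial_axis(mask, 1L, pixel_size = 0.1, min_area_px = 10)
  mc <- midcell_intensity(matrix(1, nrow(mask), ncol(mask)), mask, ax)
  expect_identical(mc$flag, "short")
  expect_true(is.na(mc$net))
})

test_that("relative midcell intensity normalizes per replicate to the reference median", {
  meas <- data.frame(
    net = c(2, 4, 6, 10, 20, 5),
    sample_id = c("WT", "WT", "WT", "WT", "WT", "mut"),
    replicate_id = c("r1", "r1", "r1", "r2", "r2", "r2"))
  out <- relative_midcell(meas, "WT")
  expect_equal(out$relative[1:3], c(0.5, 1.0, 1.5))
  # replicate 2 normalizes independently by its own WT median (15)
  expect_equal(out$relative[4:6], c(10, 20, 5) / 15)

  bad <- data.frame(net = 1, sample_id = "mut", replicate_id = "r9")
  expect_error(relative_midcell(bad, "WT"), "r9")
})

test_that("length statistics report n, mean and SD per group", {
  st <- length_stats(c(1, 2, 3), groups = "wt")
  expect_identical(st$n, 3L)
  expect_equal(st$mean_um, 2)
  expect_equal(st$sd_um, 1)
  st2 <- length_stats(c(1, 2, 3, 5), groups = c("a", "a", "a", "b"))
  expect_identical(st2$flag, c("", "n=1"))
  expect_equal(st2$sd_um[st2$group == "b"], 0)
  raw <- attr(st2, "lengths")
  expect_identical(nrow(raw), 4L)
})

test_that("rotating a cell by 90 degrees changes length and net intensity by <2%", {
  # noise-free field: the check targets the isotropy of the measurement
  # procedure itself, not resampling of an independent noise realization
  sim <- generate_cells(cell_sim_config(n_cells = 6, model = "septal",
                                        noise_sd = 0), seed = 31)
  res <- analyze_cells(sim$mask, sim$fluor, 0.1)
  res_rot <- analyze_cells(rotate90(sim$mask), rotate90(sim$fluor), 0.1)
  m <- merge(res$cells, res_rot$cells, by = "cell_id",
             suffixes = c("", "_rot"))
  expect_identical(nrow(m), nrow(res$cells))
  expect_true(all(abs(m$length_um_rot - m$length_um) / m$length_um < 0.02))
  expect_true(all(abs(m$net_rot - m$net) / abs(m$net) < 0.02))
})
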