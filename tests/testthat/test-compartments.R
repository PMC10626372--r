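test_that("26-connected labelling agrees with a graph-based oracle", {
  set.seed(101)
  for (rep in 1:20) {
    arr <- array(runif(6 * 6 * 4) < 0.3, c(6, 6, 4))
    if (!any(arr)) next
    ours <- petcu:::label_components_26(arr)
    ref <- oracle_components(arr)
    expect_equal(max(ours), max(ref))
    # same partition: every pair of voxels is co-labelled identically
    idx <- which(arr)
    expect_true(all(outer(ours[idx], ours[idx], "==") ==
                      outer(ref[idx], ref[idx], "==")))
  }
})

test_that("box dilation matches a per-voxel neighbourhood scan", {
  set.seed(102)
  for (rep in 1:10) {
    arr <- array(runif(7 * 7 * 5) < 0.15, c(7, 7, 5))
    r <- sample(1:2, 1)
    ours <- petcu:::dilate_box(arr, r)
    ref <- array(FALSE, dim(arr))
    for (i in 1:7) for (j in 1:7) for (k in 1:5) {
      nb <- arr[max(1, i - r):min(7, i + r),
                max(1, j - r):min(7, j + r),
                max(1, k - r):min(5, k + r)]
      ref[i, j, k] <- any(nb)
    }
    expect_identical(ours, ref)
  }
})

test_that("target-lesion selection picks the most prominent component", {
  # single component returned unchanged
  one <- make_mask(array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2)))
  expect_identical(select_target_lesion(one)$values, one$values)
  expect_error(select_target_lesion(make_mask(array(FALSE, c(2, 2, 2)))),
               "empty")

  # larger component wins: 100 vs 32 voxels
  arr <- two_blob_mask(c(14, 14, 6), size_a = c(5, 5, 4), size_b = c(4, 4, 2))
  sel <- select_target_lesion(make_mask(arr))
  expect_equal(sum(sel$values), 100)
  expect_true(all(which(sel$values) %in% which(arr)))

  # equal sizes: tie broken by the higher contained peak SUV
  eq <- two_blob_mask(c(14, 14, 6), size_a = c(4, 4, 2), size_b = c(4, 4, 2))
  vals <- array(1, c(14, 14, 6))
  vals[14, 14, 6] <- 3.1   # inside blob b
  vals[1, 1, 1] <- 2.4     # inside blob a
  sel2 <- select_target_lesion(make_mask(eq), make_volume(vals))
  expect_true(sel2$values[14, 14, 6])
  expect_false(sel2$values[1, 1, 1])
  # oracle agreement on which voxels form the chosen component
  ref <- oracle_components(eq)
  chosen <- ref[14, 14, 6]
  expect_identical(which(sel2$values), which(ref == chosen))
})

test_that("exclusion is exact set difference", {
  m <- make_mask(array(c(rep(TRUE, 10), rep(FALSE, 17)), c(3, 3, 3)))
  none <- make_mask(array(FALSE, c(3, 3, 3)), label = "exclusion")
  expect_identical(exclude_regions(m, none)$values, m$values)
  ex <- make_mask(array(c(rep(TRUE, 3), rep(FALSE, 24)), c(3, 3, 3)),
                  label = "exclusion")
  expect_equal(sum(exclude_regions(m, ex)$values), 7)
  all_ex <- make_mask(array(TRUE, c(3, 3, 3)), label = "exclusion")
  expect_warning(res <- exclude_regions(m, all_ex), "entire mask")
  expect_equal(sum(res$values), 0)
})

test_that("lesion SUVmax is the hottest voxel (with a robust-peak option)", {
  vals <- array(1, c(4, 4, 4))
  m <- make_mask(array(FALSE, c(4, 4, 4)))
  m$values[1:3, 1, 1] <- TRUE
  vals[1:3, 1, 1] <- c(1, 5, 3)
  v <- make_volume(vals)
  expect_equal(lesion_suv_max(v, m), 5)
  const <- make_volume(array(2, c(4, 4, 4)))
  expect_equal(lesion_suv_max(const, m), 2)
  expect_error(lesion_suv_max(v, make_mask(array(FALSE, c(4, 4, 4)))), "empty")
  # neighbourhood-averaged peak is never above the single-voxel maximum
  expect_lte(lesion_suv_max(v, m, robust_peak = TRUE), 5)
  expect_equal(lesion_suv_max(const, m, robust_peak = TRUE), 2)
})

test_that("isocontour bands select inclusive closed ranges of the maximum", {
  vals <- array(0, c(5, 1, 1))
  vals[, 1, 1] <- c(10, 8, 7.5, 6, 5)
  v <- make_volume(vals)
  all_m <- make_mask(array(TRUE, c(5, 1, 1)))
  band <- isocontour_mask(v, all_m, 0.60, 0.75, 10)
  expect_identical(which(band$values), c(3L, 4L))  # 7.5 and 6
  central <- isocontour_mask(v, all_m, 0.80, 1.00, 10)
  expect_identical(which(central$values), c(1L, 2L))  # 10 and 8
  expect_error(isocontour_mask(v, all_m, 0.8, 0.6, 10), "lower_frac")
  # boundary ties: exactly 0.75max is peripheral, exactly 0.80max is central
  expect_true(band$values[3, 1, 1])      # 7.5 = 0.75 * 10
  expect_true(central$values[2, 1, 1])   # 8.0 = 0.80 * 10
})

test_that("isocontour masks equal the brute-force voxel scan on random volumes", {
  set.seed(103)
  for (rep in 1:25) {
    v <- random_volume(c(8, 8, 8))
    m <- random_mask(c(8, 8, 8), p = 0.6)
    lo <- runif(1, 0.1, 0.7)
    hi <- runif(1, lo, 1)
    mx <- max(v$values)
    ours <- isocontour_mask(v, m, lo, hi, mx)$values
    expect_identical(ours, oracle_isocontour(v$values, m$values, lo, hi, mx))
  }
})

test_that("lowering the lower bound never removes voxels from a band", {
  set.seed(104)
  for (rep in 1:10) {
    v <- random_volume(c(8, 8, 8))
    m <- random_mask(c(8, 8, 8), p = 0.7)
    mx <- max(v$values)
    hi <- runif(1, 0.6, 1)
    lows <- sort(runif(3, 0.05, hi))
    prev <- NULL
    for (lo in rev(lows)) {
      cur <- isocontour_mask(v, m, lo, hi, mx)$values
      if (!is.null(prev)) expect_true(all(cur[prev]))
      prev <- cur
    }
  }
})

test_that("compartment extraction nests bands and is rescale-invariant", {
  ph <- render_phantom(small_phantom())
  set <- extract_compartments(ph$volume, ph$lesion, background = 1)
  expect_true(all(set$roi60$values <= set$mtv60$values))
  expect_true(all(set$roi80$values <= set$mtv60$values))
  expect_false(any(set$roi60$values & set$roi80$values))
  expect_equal(set$suv_max, 3)
  expect_named(set$thresholds_used,
               c("mtv60", "roi60_upper", "roi80", "mtv_abs"))
  # global intensity rescaling by 3x leaves all relative masks identical
  v3 <- ph$volume
  v3$values <- v3$values * 3
  set3 <- extract_compartments(v3, ph$lesion, background = 3)
  expect_identical(set3$mtv60$values, set$mtv60$values)
  expect_identical(set3$roi60$values, set$roi60$values)
  expect_identical(set3$roi80$values, set$roi80$values)
})

test_that("degenerate lesions yield a single-voxel MTV60 and an empty-ROI error", {
  vals <- array(1, c(9, 9, 9))
  lesion <- array(FALSE, c(9, 9, 9))
  lesion[3:5, 3:5, 3:5] <- TRUE
  vals[4, 4, 4] <- 10  # everything else far below 60% of max
  v <- make_volume(vals)
  m <- make_mask(lesion)
  expect_warning(set <- extract_compartments(v, m, background = 1),
                 "ROI60")
  expect_equal(sum(set$mtv60$values), 1)
  expect_equal(sum(set$roi80$values), 1)

  # SUVmax taken before exclusion + excluded peak -> no central compartment
  ex <- array(FALSE, c(9, 9, 9))
  ex[4, 4, 4] <- TRUE
  vals2 <- array(1, c(9, 9, 9))
  vals2[3:5, 3:5, 3:5] <- 5
  vals2[4, 4, 4] <- 10
  expect_error(
    extract_compartments(make_volume(vals2), m,
                         exclusion = make_mask(ex, label = "exclusion"),
                         background = 1, suvmax_before_exclusion = TRUE),
    "no central compartment")
})

test_that("the absolute MTV uses k times the background mean", {
  vals <- array(seq(0.5, 3, length.out = 27), c(3, 3, 3))
  v <- make_volume(vals)
  all_m <- make_mask(array(TRUE, c(3, 3, 3)))
  m18 <- absolute_mtv(v, all_m, background_mean = 1, k = 1.8)
  expect_identical(m18$values, array(vals >= 1.8, c(3, 3, 3)))
  expect_equal(sum(absolute_mtv(v, all_m, 1, k = 0)$values), 27)
  expect_error(absolute_mtv(v, all_m, background_mean = 0), "positive")
  # phantom at suv_max = 2x background: MTVabs (>=1.8) strictly inside MTV60 (>=1.2)
  ph <- render_phantom(small_phantom(suv_max = 2))
  set <- extract_compartments(ph$volume, ph$lesion, background = 1)
  expect_true(all(which(set$mtv_abs$values) %in% which(set$mtv60$values)))
  expect_lt(sum(set$mtv_abs$values), sum(set$mtv60$values))
})

test_that("the mirrored background ROI lands contralaterally on the peak slice", {
  # off-center lesion in x so the mirror lands in clean background
  spec <- phantom_spec(v_central = 0.3, v_peripheral = 1.0,
                       grid_shape = c(64, 64, 24), spacing_mm = c(1, 1, 2.3),
                       center_mm = c(16, 32, 23))
  ph <- render_phantom(spec)
  set <- extract_compartments(ph$volume, ph$lesion)
  bg <- set$background
  expect_s3_class(bg, "background_roi")
  # slice through the lesion center maximizes mean uptake
  expect_equal(bg$slice_index, round(23 / 2.3) + 1)
  expect_equal(bg$mean_suv, 1.0)
  # mirror preserves area when no shift is needed
  tumor_slice <- ph$lesion$values[, , bg$slice_index]
  expect_equal(bg$area_mm2, sum(tumor_slice) * 1)
  expect_false(any(bg$mask2d & tumor_slice))
})
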