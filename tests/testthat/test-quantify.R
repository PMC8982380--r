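test_that("four well-separated nuclei are segmented with accurate centroids", {
  img <- demo_animal(seed = 41)
  seg <- segment_nuclei(img$stack)
  expect_length(seg$nuclei, 4L)
  expect_false(any(c("dim-marker", "merged-nuclei", "fragmented") %in% seg$flags))
  cen <- t(vapply(seg$nuclei, function(n) n$centroid, numeric(3)))
  tc <- as.matrix(img$truth[, c("cx", "cy", "cz")])
  for (i in seq_len(4)) {
    d <- sqrt(min(rowSums((tc - matrix(cen[i, ], 4, 3, byrow = TRUE))^2)))
    expect_lt(d, 1)
  }
  # every nucleus spans at least 5 slices at default geometry
  expect_true(all(vapply(seg$nuclei, function(n) length(n$zs), numeric(1)) >= 5))
})

test_that("nuclei closer than one radius raise the merged-nuclei QC flag", {
  nuc <- tibble::tibble(
    cell_id = c("alpha1", "alpha2"),
    cx = c(20, 23), cy = c(16, 16), cz = c(10, 10),
    radius = 4, true_gfp = 5000, true_mcherry = 5e5
  )
  img <- make_animal_image(nuc, seed = 8)
  seg <- segment_nuclei(img$stack, expected_n = 2)
  expect_true("merged-nuclei" %in% seg$flags || "merged-split" %in% seg$flags)
  m <- quantify_stack(img$stack, expected_n = 2, truth = img$truth)
  expect_true(all(m$excluded))
  expect_true(all(m$exclusion_reason == "merged-nuclei"))
})

test_that("an empty mCherry channel yields zero segments and a dim-marker flag", {
  st <- blank_stack()
  seg <- segment_nuclei(st)
  expect_length(seg$nuclei, 0L)
  expect_true("dim-marker" %in% seg$flags)
  m <- quantify_stack(st, truth = tibble::tibble(
    animal_id = "a1", cell_id = "alpha1", fate = "AC", stabilized = FALSE,
    true_gfp = 1, cx = 6, cy = 5, cz = 4
  ))
  expect_true(all(m$excluded))
  expect_equal(unique(m$exclusion_reason), "dim-marker")
})

test_that("method A subtracts the outside-larva region and is shift-invariant", {
  d <- c(10, 8, 6)
  gfp <- array(0, d)
  gfp[3, 3, 1:4] <- 250            # nucleus column: sums to 1000
  gfp[6:10, , ] <- 25              # outside-larva area; bg region sums to 100
  mch <- array(0, d); mch[3, 3, 1:4] <- 100
  mask <- array(FALSE, d); mask[1:5, , ] <- TRUE
  st <- new_image_stack(gfp, mch, mask)
  nuc <- nucleus_from_coords(st, cbind(3, 3, 1:4))
  m <- measure_sumproj_bgcorr(st, nuc)
  expect_equal(m$gfp_value, 1000 - 100)
  expect_false(m$negative_value)

  # adding a constant everywhere cancels exactly
  st2 <- new_image_stack(gfp + 7.3, mch, mask)
  m2 <- measure_sumproj_bgcorr(st2, nucleus_from_coords(st2, cbind(3, 3, 1:4)))
  expect_equal(m2$gfp_value, m$gfp_value, tolerance = 1e-9)

  # negative corrected values are reported as-is and flagged
  gfp3 <- gfp; gfp3[3, 3, 1:4] <- 10
  st3 <- new_image_stack(gfp3, mch, mask)
  m3 <- measure_sumproj_bgcorr(st3, nucleus_from_coords(st3, cbind(3, 3, 1:4)))
  expect_equal(m3$gfp_value, 40 - 100)
  expect_true(m3$negative_value)

  # a background region overlapping the larva is refused
  bad_bg <- list(x0 = 3L, y0 = 3L, footprint = matrix(TRUE, 1, 1))
  expect_error(measure_sumproj_bgcorr(st, nuc, bad_bg), "larva mask")
})

test_that("a noise-free nucleus measured over its own support recovers the truth", {
  nuc_spec <- tibble::tibble(cell_id = "alpha1", cx = 20, cy = 16, cz = 10,
                             radius = 4, true_gfp = 10000, true_mcherry = 5000)
  img <- make_animal_image(nuc_spec, background_level = 0,
                           noise = noise_params(FALSE, 0, 0), seed = 1)
  st <- img$stack
  support <- which(st$gfp > 0, arr.ind = TRUE)
  nuc <- nucleus_from_coords(st, support)
  m <- measure_sumproj_bgcorr(st, nuc)
  expect_lt(abs(m$gfp_value - 10000) / 10000, 0.01)
})

test_that("method B selects the top 5 marker slices and sums their GFP", {
  fx <- column_nucleus_stack(gfp_by_z = c(0, 2, 4, 6, 4, 2, 0),
                             mch_by_z = c(1, 5, 9, 10, 9, 5, 1))
  m <- measure_top5(fx$stack, fx$nucleus)
  expect_equal(m$gfp_value, 18)
  expect_equal(m$n_slices_used, 5L)
  expect_false(m$short_span)

  # full tie: the 5 lowest slices win
  fx2 <- column_nucleus_stack(gfp_by_z = 1:7, mch_by_z = rep(3, 7))
  m2 <- measure_top5(fx2$stack, fx2$nucleus)
  expect_equal(m2$gfp_value, sum(1:5))

  # exactly five slices: everything is summed
  fx3 <- column_nucleus_stack(gfp_by_z = c(1, 2, 3, 4, 5),
                              mch_by_z = c(9, 1, 5, 5, 9))
  expect_equal(measure_top5(fx3$stack, fx3$nucleus)$gfp_value, 15)

  # short span: all slices used and flagged
  fx4 <- column_nucleus_stack(gfp_by_z = c(4, 4, 4), mch_by_z = c(1, 2, 3))
  m4 <- measure_top5(fx4$stack, fx4$nucleus)
  expect_equal(m4$gfp_value, 12)
  expect_equal(m4$n_slices_used, 3L)
  expect_true(m4$short_span)
})

test_that("top-5 selection attains the brute-force best 5-subset of slices", {
  withr::with_seed(99, {
    for (case in 1:50) {
      nz <- sample(5:8, 1)
      mch <- round(stats::runif(nz, 0, 10), sample(0:1, 1)) # allow ties
      gfp <- round(stats::runif(nz, 0, 20), 2)
      fx <- column_nucleus_stack(gfp_by_z = gfp, mch_by_z = mch)
      sel <- acvu:::top5_slices(fx$nucleus)
      subsets <- utils::combn(nz, min(5, nz))
      best_mch <- max(colSums(matrix(mch[subsets], nrow = min(5, nz))))
      expect_equal(sum(mch[sel]), best_mch)
    }
  })
})

test_that("both measurement methods are linear in the GFP channel", {
  img <- demo_animal(seed = 43)
  st <- img$stack
  seg <- segment_nuclei(st)
  nuc <- seg$nuclei[[1]]
  st_c <- new_image_stack(st$gfp * 4, st$mcherry, st$larva_mask)
  expect_equal(measure_top5(st_c, nuc)$gfp_value,
               4 * measure_top5(st, nuc)$gfp_value, tolerance = 1e-10)
  expect_equal(measure_sumproj_bgcorr(st_c, nuc)$gfp_value,
               4 * measure_sumproj_bgcorr(st, nuc)$gfp_value, tolerance = 1e-10)
})

test_that("background region selection is raster-first, exact-shape, and can fail", {
  d <- c(10, 8, 4)
  mask <- array(FALSE, d); mask[1:5, , ] <- TRUE
  st <- new_image_stack(array(0, d), array(0, d), mask)
  fp <- matrix(TRUE, 2, 2)
  reg <- select_background_region(st, fp)
  expect_equal(reg$x0, 6L)
  expect_equal(reg$y0, 1L)
  expect_equal(sum(reg$footprint), 4L)

  full <- new_image_stack(array(0, d), array(0, d), array(TRUE, d))
  expect_error(select_background_region(full, fp), "no outside-larva region")
  expect_error(background_stats(full, fp), "no outside-larva region")
})
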