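test_that("a nucleus with zero GFP renders an all-zero GFP channel", {
  nuc <- tibble::tibble(cell_id = "alpha1", cx = 20, cy = 16, cz = 10,
                        radius = 4, true_gfp = 0, true_mcherry = 1000)
  img <- make_animal_image(nuc, background_level = 0,
                           noise = noise_params(shot = FALSE, read_sd = 0,
                                                offset = 0),
                           seed = 1)
  expect_true(all(img$stack$gfp == 0))
  expect_gt(sum(img$stack$mcherry), 0)
})

test_that("rendered blob intensity sums to the true total (noise off)", {
  nuc <- tibble::tibble(cell_id = "alpha1", cx = 20.3, cy = 15.7, cz = 10.2,
                        radius = 4, true_gfp = 10000, true_mcherry = 5000)
  img <- make_animal_image(nuc, background_level = 0,
                           noise = noise_params(FALSE, 0, 0), seed = 1)
  expect_gte(sum(img$stack$gfp), 9900)
  expect_lte(sum(img$stack$gfp), 10100)
})

test_that("total intensity is conserved: blob totals plus background over the mask", {
  spec <- sample_condition(condition_lacz(n_animals = 1), seed = 3)
  img <- make_animal_image(spec, background_level = 2,
                           noise = noise_params(FALSE, 0, 0), seed = 1)
  expected <- sum(spec$true_gfp) + 2 * sum(img$stack$larva_mask)
  expect_lt(abs(sum(img$stack$gfp) - expected) / expected, 0.01)
  expected_m <- sum(spec$true_mcherry) + 2 * sum(img$stack$larva_mask)
  expect_lt(abs(sum(img$stack$mcherry) - expected_m) / expected_m, 0.01)
})

test_that("the larva mask covers every rendered signal voxel", {
  spec <- sample_condition(condition_lacz(n_animals = 1), seed = 4)
  img <- make_animal_image(spec, background_level = 0,
                           noise = noise_params(FALSE, 0, 0), seed = 1)
  expect_true(all(img$stack$larva_mask[img$stack$gfp > 0]))
  expect_true(all(img$stack$larva_mask[img$stack$mcherry > 0]))
  expect_lt(mean(img$stack$larva_mask), 1) # an outside-larva region exists
})

test_that("nuclei closer than one radius are flagged overlapping; others are not", {
  nuc <- tibble::tibble(
    cell_id = c("alpha1", "alpha2", "beta1"),
    cx = c(15, 18, 30), cy = c(16, 16, 16), cz = c(10, 10, 10),
    radius = 4, true_gfp = 1000, true_mcherry = 1000
  )
  img <- make_animal_image(nuc, seed = 1)
  expect_equal(img$truth$overlapping, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(img$overlaps), 1L)
})

test_that("a nucleus outside the grid is rejected with its coordinates", {
  nuc <- tibble::tibble(cell_id = "alpha1", cx = 99, cy = 16, cz = 10,
                        radius = 4, true_gfp = 10, true_mcherry = 10)
  expect_error(make_animal_image(nuc, seed = 1), "99")
})

test_that("identical seeds give identical images; noise-free scaling is linear", {
  spec <- sample_condition(condition_lacz(n_animals = 1), seed = 5)
  a <- make_animal_image(spec, seed = 77)
  b <- make_animal_image(spec, seed = 77)
  expect_identical(a$stack$gfp, b$stack$gfp)
  expect_identical(a$stack$mcherry, b$stack$mcherry)

  spec2 <- spec
  spec2$true_gfp <- spec2$true_gfp * 3
  g1 <- make_animal_image(spec, background_level = 0,
                          noise = noise_params(FALSE, 0, 0), seed = 1)$stack$gfp
  g3 <- make_animal_image(spec2, background_level = 0,
                          noise = noise_params(FALSE, 0, 0), seed = 1)$stack$gfp
  expect_equal(g3, 3 * g1, tolerance = 1e-12)
})

test_that("stabilization penetrance controls the fraction of AC-level VU cells", {
  p0 <- condition_lacz(n_animals = 50)
  s0 <- sample_condition(p0, seed = 9)
  expect_false(any(s0$stabilized))

  p1 <- condition_params("x", n_animals = 50, stabilization_penetrance = 1)
  s1 <- sample_condition(p1, seed = 9)
  expect_true(all(s1$stabilized[s1$fate == "VU"]))

  ph <- condition_params("h", n_animals = 2000, stabilization_penetrance = 0.5)
  sh <- sample_condition(ph, seed = 10)
  frac <- mean(sh$stabilized[sh$fate == "VU"])
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("condition parameters are validated", {
  expect_error(condition_params("x", stabilization_penetrance = 1.2), "penetrance")
  expect_error(condition_params("x", n_animals = 0), "n_animals")
  expect_error(condition_params("x", vu_sdlog = -1), "scale")
})

test_that("sister pairing partitions the four cells symmetrically", {
  spec <- sample_condition(condition_lacz(n_animals = 3), seed = 12)
  for (an in unique(spec$animal_id)) {
    sub <- spec[spec$animal_id == an, ]
    expect_setequal(sub$cell_id, c("alpha1", "alpha2", "beta1", "beta2"))
    # symmetric pairing
    for (i in seq_len(4)) {
      sis <- sub$sister_id[i]
      expect_equal(sub$sister_id[sub$cell_id == sis], sub$cell_id[i])
    }
    expect_setequal(sub$sister_id[sub$cell_id %in% c("alpha1", "beta1")],
                    c("beta1", "alpha1"))
  }
})

test_that("screen dataset generation validates controls and stores truth labels", {
  design <- screen_design(n_clones = 2, n_planted = 1, n_animals = 2)
  bad <- design[design$type != "positive_control", ]
  expect_error(make_screen_dataset(bad, seed = 1), "round 1")

  ds <- make_screen_dataset(design, seed = 2)
  expect_s3_class(ds, "screen_dataset")
  expect_equal(sum(ds$clones$planted_hit), 1L)
  expect_setequal(unique(ds$cells$clone_id), design$clone_id)

  ds2 <- make_screen_dataset(design, seed = 2)
  expect_identical(ds$cells, ds2$cells)
})

test_that("a controls-only design yields a controls-only dataset", {
  design <- screen_design(n_clones = 0, n_planted = 0, n_animals = 2)
  ds <- make_screen_dataset(design, seed = 4)
  expect_setequal(unique(ds$cells$type),
                  c("negative_control", "positive_control"))
  expect_equal(sum(ds$clones$planted_hit), 0L)
})
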