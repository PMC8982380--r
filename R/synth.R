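#' Noise model parameters for synthetic image stacks
#'
#' The camera model applied to the expected (noise-free) photon signal:
#' optional Poisson shot noise on the expected intensity, then a constant
#' camera offset plus additive Gaussian read noise, with negative values
#' clamped at zero. Setting `shot = FALSE`, `read_sd = 0`, `offset = 0`
#' disables noise entirely (used by the conservation tests).
#'
#' @param shot Apply Poisson shot noise to the expected intensity?
#' @param read_sd Standard deviation of additive Gaussian read noise
#'   (arbitrary intensity units, AU, per voxel). The default is set so that
#'   a VU-level nucleus sits below the visibility cut of
#'   [call_gfp_positive()] while an AC-level nucleus is far above it.
#' @param offset Constant camera offset (AU per voxel), applied everywhere.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(shot = TRUE, read_sd = 80, offset = 150) {
  stopifnot(is.logical(shot), read_sd >= 0, offset >= 0)
  structure(list(shot = shot, read_sd = read_sd, offset = offset),
            class = "noise_params")
}

#' Condition parameters for synthetic gonad-primordium populations
#'
#' Encodes the statistical structure of one experimental condition: how many
#' animals, which cells adopt the AC fate, what fraction of VU-fated cells
#' have their reporter ectopically stabilized (the penetrance of an RNAi
#' clone), and the per-fate log-normal fluorescence distributions.
#'
#' Cells with AC fate, and VU-fated cells that are stabilized, draw their
#' true GFP total from the AC-level distribution; unstabilized VU-fated
#' cells draw from the VU-level distribution.
#'
#' @param name Condition label (e.g. `"lacZ"`, `"lin-12"`, a clone id).
#' @param n_animals Number of animals to simulate (>= 1).
#' @param stabilization_penetrance Probability that a VU-fated cell receives
#'   an AC-level GFP draw (in `[0, 1]`).
#' @param alpha_fate `"decide"`: exactly one alpha cell (chosen at random)
#'   adopts the AC fate, the other becomes a VU — the wild-type outcome of
#'   the Notch-mediated AC/VU decision. `"both_ac"`: both alpha cells adopt
#'   the AC fate, as in a Notch-null background.
#' @param beta_ac_prob Probability that each beta cell adopts the AC fate
#'   (non-zero only in Notch-null-like conditions).
#' @param ac_meanlog,ac_sdlog Log-normal parameters of the AC-level GFP
#'   total (AU).
#' @param vu_meanlog,vu_sdlog Log-normal parameters of the VU-level GFP
#'   total (AU).
#' @param mch_meanlog,mch_sdlog Log-normal parameters of the nuclear
#'   segmentation-marker (mCherry) total (AU).
#' @return A list of class `condition_params`.
#' @seealso [condition_lacz()], [condition_lin12_rnai()],
#'   [condition_lin12_null()], [condition_recovery()]
#' @export
condition_params <- function(name,
                             n_animals = 20,
                             stabilization_penetrance = 0,
                             alpha_fate = c("decide", "both_ac"),
                             beta_ac_prob = 0,
                             ac_meanlog = log(30000), ac_sdlog = 0.25,
                             vu_meanlog = log(3000), vu_sdlog = 0.25,
                             mch_meanlog = log(5e5), mch_sdlog = 0.15) {
  alpha_fate <- match.arg(alpha_fate)
  if (!is.numeric(stabilization_penetrance) ||
      stabilization_penetrance < 0 || stabilization_penetrance > 1) {
    stop("stabilization_penetrance must be in [0, 1]")
  }
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (ac_sdlog < 0 || vu_sdlog < 0 || mch_sdlog < 0) {
    stop("distribution scale parameters must be >= 0")
  }
  if (beta_ac_prob < 0 || beta_ac_prob > 1) stop("beta_ac_prob must be in [0, 1]")
  structure(list(
    name = name, n_animals = as.integer(n_animals),
    stabilization_penetrance = stabilization_penetrance,
    alpha_fate = alpha_fate, beta_ac_prob = beta_ac_prob,
    ac_meanlog = ac_meanlog, ac_sdlog = ac_sdlog,
    vu_meanlog = vu_meanlog, vu_sdlog = vu_sdlog,
    mch_meanlog = mch_meanlog, mch_sdlog = mch_sdlog
  ), class = "condition_params")
}

#' @rdname condition_params
#' @param ... Passed on to [condition_params()].
#' @export
condition_lacz <- function(n_animals = 20, ...) {
  condition_params("lacZ", n_animals = n_animals,
                   stabilization_penetrance = 0, ...)
}

#' @rdname condition_params
#' @param penetrance Stabilization penetrance of the positive control.
#' @export
condition_lin12_rnai <- function(n_animals = 20, penetrance = 0.95, ...) {
  condition_params("lin-12", n_animals = n_animals,
                   stabilization_penetrance = penetrance, ...)
}

#' @rdname condition_params
#' @export
condition_lin12_null <- function(n_animals = 20, ...) {
  condition_params("lin-12(0)", n_animals = n_animals,
                   alpha_fate = "both_ac", beta_ac_prob = 0.1, ...)
}

#' @rdname condition_params
#' @details `condition_recovery()` is a calibration-series-style condition:
#'   every cell draws its true GFP total from one wide log-normal spanning
#'   the pipeline's dynamic range, so that measured-versus-true agreement
#'   can be assessed across the full range rather than within narrow
#'   per-role clusters.
#' @export
condition_recovery <- function(n_animals = 50, ...) {
  condition_params("recovery", n_animals = n_animals,
                   ac_meanlog = log(20000), ac_sdlog = 1.0,
                   vu_meanlog = log(20000), vu_sdlog = 1.0, ...)
}

cell_positions <- function(dim) {
  cx <- dim[1] / 2
  tibble::tibble(
    cell_id = c("alpha1", "alpha2", "beta1", "beta2"),
    sister_id = c("beta1", "beta2", "alpha1", "alpha2"),
    base_x = cx + c(-9, 9, -9, 9),
    base_y = dim[2] / 2 + c(-5, -5, 5, 5),
    base_z = dim[3] / 2
  )
}

#' Sample per-animal nucleus specifications for one condition
#'
#' Draws `n_animals` animals, each with the four AC-competent cells
#' (alpha1, alpha2 and their lineage sisters beta1, beta2) positioned in a
#' fixed quartet layout with a small random jitter, assigns cell fates and
#' stabilization status, and draws true per-nucleus GFP and mCherry totals.
#'
#' @param params A [condition_params()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @param dim Stack dimensions `(x, y, z)` in voxels the nuclei are placed in.
#' @param radius Nucleus radius in voxels.
#' @param jitter Uniform positional jitter half-width (voxels).
#' @return A tibble with one row per cell: `condition`, `animal_id`,
#'   `cell_id`, `sister_id`, `cx`, `cy`, `cz`, `radius`, `fate`
#'   (`"AC"` or `"VU"`), `stabilized`, `true_gfp`, `true_mcherry`.
#' @export
sample_condition <- function(params, seed, dim = c(44, 32, 20),
                             radius = 4, jitter = 1.5) {
  stopifnot(inherits(params, "condition_params"))
  pos <- cell_positions(dim)
  withr::with_seed(as.integer(split_seed(seed, "sample")), {
    animals <- purrr::map(seq_len(params$n_animals), function(i) {
      df <- pos
      fate <- character(4)
      if (params$alpha_fate == "decide") {
        ac_alpha <- sample(1:2, 1)
        fate[1:2] <- ifelse(seq_len(2) == ac_alpha, "AC", "VU")
      } else {
        fate[1:2] <- "AC"
      }
      fate[3:4] <- ifelse(stats::runif(2) < params$beta_ac_prob, "AC", "VU")
      stabilized <- fate == "VU" &
        stats::runif(4) < params$stabilization_penetrance
      ac_like <- fate == "AC" | stabilized
      true_gfp <- ifelse(
        ac_like,
        stats::rlnorm(4, params$ac_meanlog, params$ac_sdlog),
        stats::rlnorm(4, params$vu_meanlog, params$vu_sdlog)
      )
      tibble::tibble(
        condition = params$name,
        animal_id = sprintf("%s_%03d", params$name, i),
        cell_id = df$cell_id, sister_id = df$sister_id,
        cx = df$base_x + stats::runif(4, -jitter, jitter),
        cy = df$base_y + stats::runif(4, -jitter, jitter),
        cz = df$base_z + stats::runif(4, -jitter, jitter),
        radius = radius,
        fate = fate, stabilized = stabilized,
        true_gfp = true_gfp,
        true_mcherry = stats::rlnorm(4, params$mch_meanlog, params$mch_sdlog)
      )
    })
    dplyr::bind_rows(animals)
  })
}

# Render one nucleus as a 3D Gaussian blob (sigma = radius / 2, truncated at
# 3 sigma) into `arr`, normalized so the in-grid blob sums exactly to `total`.
render_blob <- function(arr, center, radius, total) {
  if (total <= 0) return(arr)
  d <- dim(arr)
  sigma <- radius / 2
  half <- ceiling(3 * sigma)
  c0 <- round(center)
  xs <- max(1L, c0[1] - half):min(d[1], c0[1] + half)
  ys <- max(1L, c0[2] - half):min(d[2], c0[2] + half)
  zs <- max(1L, c0[3] - half):min(d[3], c0[3] + half)
  wx <- exp(-(xs - center[1])^2 / (2 * sigma^2))
  wy <- exp(-(ys - center[2])^2 / (2 * sigma^2))
  wz <- exp(-(zs - center[3])^2 / (2 * sigma^2))
  k <- outer(outer(wx, wy), wz)
  r2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
              (zs - center[3])^2, `+`)
  k[r2 > (3 * sigma)^2] <- 0
  k <- k / sum(k) * total
  arr[xs, ys, zs] <- arr[xs, ys, zs] + k
  arr
}

ellipsoid_mask <- function(dim, center, semi) {
  x <- ((seq_len(dim[1]) - center[1]) / semi[1])^2
  y <- ((seq_len(dim[2]) - center[2]) / semi[2])^2
  z <- ((seq_len(dim[3]) - center[3]) / semi[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

#' Render a synthetic two-channel animal image
#'
#' Renders each nucleus as an isotropic 3D Gaussian blob (sigma = radius/2,
#' truncated at 3 sigma) whose noise-free summed intensity equals its true
#' channel total, adds uniform background inside an axis-aligned ellipsoidal
#' larva mask enclosing all nuclei, and applies the camera noise model.
#'
#' @param nuclei A tibble of nucleus specifications for one animal, as one
#'   animal's rows from [sample_condition()] (columns `cell_id`, `cx`, `cy`,
#'   `cz`, `radius`, `true_gfp`, `true_mcherry`, optionally fate columns).
#' @param background_level Background (autofluorescence) level in AU per
#'   voxel, added inside the larva mask only, both channels.
#' @param noise A [noise_params()] object.
#' @param seed Integer seed.
#' @param dim Stack dimensions `(x, y, z)` in voxels.
#' @param z_spacing_nm Axial slice spacing in nanometres.
#' @return A list with elements `stack` (an `image_stack`: `gfp`, `mcherry`,
#'   `larva_mask`, `z_spacing_nm`), `truth` (the input tibble plus an
#'   `overlapping` flag per nucleus), `overlaps` (tibble of flagged pairs)
#'   and `seed`.
#' @export
make_animal_image <- function(nuclei, background_level = 0.5,
                              noise = noise_params(), seed,
                              dim = c(44, 32, 20), z_spacing_nm = 260) {
  stopifnot(nrow(nuclei) >= 1, inherits(noise, "noise_params"))
  centers <- as.matrix(nuclei[, c("cx", "cy", "cz")])
  out_of_grid <- centers[, 1] < 1 | centers[, 1] > dim[1] |
    centers[, 2] < 1 | centers[, 2] > dim[2] |
    centers[, 3] < 1 | centers[, 3] > dim[3]
  if (any(out_of_grid)) {
    bad <- centers[which(out_of_grid)[1], ]
    stop(sprintf("nucleus center outside grid: (%.1f, %.1f, %.1f)",
                 bad[1], bad[2], bad[3]))
  }

  gfp <- array(0, dim)
  mch <- array(0, dim)
  for (i in seq_len(nrow(nuclei))) {
    gfp <- render_blob(gfp, centers[i, ], nuclei$radius[i], nuclei$true_gfp[i])
    mch <- render_blob(mch, centers[i, ], nuclei$radius[i], nuclei$true_mcherry[i])
  }

  # Larva mask: ellipsoid around the nuclei, unioned with each nucleus's
  # rendered support so the mask provably covers all signal voxels.
  bb_min <- apply(centers, 2, min)
  bb_max <- apply(centers, 2, max)
  mask <- ellipsoid_mask(dim, (bb_min + bb_max) / 2,
                         (bb_max - bb_min) / 2 + 1.5 * max(nuclei$radius) + 2)
  mask <- mask | (gfp > 0) | (mch > 0)

  # Pairwise overlap flags: centers closer than the mean of the two radii.
  n <- nrow(nuclei)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    dists <- sqrt(rowSums((centers[pairs[1, ], , drop = FALSE] -
                             centers[pairs[2, ], , drop = FALSE])^2))
    lim <- (nuclei$radius[pairs[1, ]] + nuclei$radius[pairs[2, ]]) / 2
    ov <- dists < lim
    overlaps <- tibble::tibble(
      cell_a = nuclei$cell_id[pairs[1, ov]],
      cell_b = nuclei$cell_id[pairs[2, ov]],
      distance = dists[ov]
    )
  } else {
    overlaps <- tibble::tibble(cell_a = character(), cell_b = character(),
                               distance = numeric())
  }

  gfp <- gfp + background_level * mask
  mch <- mch + background_level * mask
  withr::with_seed(as.integer(split_seed(seed, "noise")), {
    if (noise$shot) {
      gfp <- array(stats::rpois(length(gfp), gfp), dim)
      mch <- array(stats::rpois(length(mch), mch), dim)
    }
    if (noise$read_sd > 0) {
      gfp <- gfp + stats::rnorm(length(gfp), 0, noise$read_sd)
      mch <- mch + stats::rnorm(length(mch), 0, noise$read_sd)
    }
  })
  gfp <- pmax(gfp + noise$offset, 0)
  mch <- pmax(mch + noise$offset, 0)

  truth <- nuclei
  truth$overlapping <- truth$cell_id %in% c(overlaps$cell_a, overlaps$cell_b)

  list(
    stack = new_image_stack(gfp, mch, mask, z_spacing_nm),
    truth = truth,
    overlaps = overlaps,
    seed = seed
  )
}

#' Build an RNAi screen design table
#'
#' One screening round holds one negative control (`lacZ`), one positive
#' control (`lin-12`), and a set of experimental clones, a subset of which
#' are "planted" hits with a given stabilization penetrance.
#'
#' @param n_clones Experimental clones per round.
#' @param n_planted Number of planted hit clones per round.
#' @param planted_penetrance Stabilization penetrance of planted hits.
#' @param n_animals Animals per clone.
#' @param n_rounds Number of rounds.
#' @param positive_penetrance Penetrance of the positive control.
#' @return A design tibble with columns `round`, `clone_id`, `type`,
#'   `penetrance`, `n_animals`.
#' @export
screen_design <- function(n_clones = 10, n_planted = 2,
                          planted_penetrance = 0.9, n_animals = 20,
                          n_rounds = 1, positive_penetrance = 0.95) {
  stopifnot(n_planted <= n_clones)
  purrr::map_dfr(seq_len(n_rounds), function(r) {
    tibble::tibble(
      round = r,
      clone_id = c("lacZ", "lin-12",
                   sprintf("clone_%02d", seq_len(n_clones))),
      type = c("negative_control", "positive_control",
               rep("experimental", n_clones)),
      penetrance = c(0, positive_penetrance,
                     rep(planted_penetrance, n_planted),
                     rep(0, n_clones - n_planted)),
      n_animals = n_animals
    )
  })
}

#' Generate a synthetic screen dataset with known ground truth
#'
#' For every clone in the design, simulates `n_animals` animals under the
#' clone's condition, renders each animal's two-channel stack, segments and
#' measures it with the no-background-correction top-slice method
#' ([measure_top5()]), and stores per-cell measurements together with the
#' generating ground truth. Voxel data are not retained.
#'
#' @param design A design tibble as from [screen_design()]. Every round must
#'   contain exactly one negative and one positive control.
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @param background_level,noise,dim Passed to [make_animal_image()].
#' @return A `screen_dataset`: list with `cells` (per-cell measurement
#'   tibble), `clones` (per-clone truth labels: `planted_hit`), `design`,
#'   and `seed`.
#' @export
make_screen_dataset <- function(design, seed, background_level = 0.5,
                                noise = noise_params(), dim = c(44, 32, 20)) {
  req <- c("round", "clone_id", "type", "penetrance", "n_animals")
  stopifnot(all(req %in% names(design)))
  for (r in unique(design$round)) {
    sub <- design[design$round == r, ]
    if (sum(sub$type == "negative_control") != 1 ||
        sum(sub$type == "positive_control") != 1) {
      stop(sprintf("round %s must contain exactly one negative and one positive control", r))
    }
  }
  cells <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    # Animals failing segmentation QC are excluded from scoring, so extra
    # animals are simulated and scoring continues until n_animals animals
    # pass QC — mirroring a protocol that scores a fixed number of
    # individuals per clone. Excluded animals are retained, flagged.
    n_extra <- ceiling(row$n_animals * 0.3) + 3
    params <- condition_params(
      name = row$clone_id, n_animals = row$n_animals + n_extra,
      stabilization_penetrance = row$penetrance
    )
    cond_seed <- split_seed(seed, "screen", i)
    spec <- sample_condition(params, cond_seed, dim = dim)
    per_animal <- split(spec, spec$animal_id)
    n_complete <- 0L
    out <- list()
    for (j in seq_along(per_animal)) {
      if (n_complete >= row$n_animals) break
      nuc <- per_animal[[j]]
      img <- make_animal_image(nuc, background_level = background_level,
                               noise = noise,
                               seed = split_seed(cond_seed, "animal", j),
                               dim = dim)
      meas <- quantify_stack(img$stack, expected_n = 4, method = "top5",
                             truth = img$truth)
      if (!any(meas$excluded)) n_complete <- n_complete + 1L
      out[[length(out) + 1L]] <- meas
    }
    meas <- dplyr::bind_rows(out)
    meas$round <- row$round
    meas$clone_id <- row$clone_id
    meas$type <- row$type
    meas
  })
  clones <- design |>
    dplyr::mutate(planted_hit = .data$type == "experimental" & .data$penetrance > 0) |>
    dplyr::select("round", "clone_id", "type", "penetrance", "n_animals",
                  "planted_hit")
  structure(list(cells = cells, clones = clones, design = design, seed = seed),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("<screen_dataset>", nrow(x$clones), "clones,",
      length(unique(x$cells$animal_id)), "animals, seed", x$seed, "\n")
  invisible(x)
}
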