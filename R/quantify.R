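# Nuclear segmentation from the mCherry marker channel and per-nucleus GFP
# quantification by the two measurement methods:
#   A. sum z-projection over the nucleus's slices, background-corrected
#      against a same-shaped region outside the larva;
#   B. sum of the GFP integrated intensity over the 5 slices with the
#      highest per-slice integrated mCherry, no background correction.

new_segmented_nucleus <- function(label, voxels, stack) {
  d <- dim(stack$mcherry)
  co <- arrayInd(voxels, d)
  mch_by_z <- rowsum(stack$mcherry[voxels], co[, 3])
  fp <- matrix(FALSE, d[1], d[2])
  fp[unique(co[, 1:2, drop = FALSE])] <- TRUE
  structure(list(
    label = label,
    voxels = voxels,
    coords = co,
    dim = d,
    centroid = colMeans(co),
    zs = as.integer(rownames(mch_by_z)),
    per_slice_mcherry = tibble::tibble(
      z = as.integer(rownames(mch_by_z)),
      mcherry = as.numeric(mch_by_z)
    ),
    footprint = fp
  ), class = "segmented_nucleus")
}

#' @export
print.segmented_nucleus <- function(x, ...) {
  cat(sprintf("<segmented_nucleus> label %d, %d voxels, %d z-slices, centroid (%.1f, %.1f, %.1f)\n",
              x$label, length(x$voxels), length(x$zs),
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Segment nuclei from the mCherry channel
#'
#' Gaussian-smooths the segmentation-marker channel, applies a global Otsu
#' threshold, labels 3D connected components (26-connectivity), and splits
#' components whose volume exceeds `split_factor` times the median component
#' volume using local-maximum seeds and nearest-seed assignment (a
#' marker-based watershed stand-in for the interactive boundaries drawn in
#' the original protocol). Raises the three segmentation QC flags used for
#' exclusions: `"merged-nuclei"` (an oversized component that could not be
#' split), `"fragmented"` (more components than expected nuclei) and
#' `"dim-marker"` (marker signal too weak to segment).
#'
#' @param stack An `image_stack`.
#' @param expected_n Expected number of nuclei.
#' @param smooth_sigma Gaussian smoothing sigma (voxels).
#' @param split_factor Volume ratio (to the median component volume) above
#'   which a component is considered a candidate merge.
#' @param min_voxels Components smaller than this are discarded as specks.
#' @param expected_radius Expected nucleus radius (voxels); minimum
#'   separation of watershed seeds.
#' @param boundary_frac Relative-intensity contour level defining each
#'   nucleus's final boundary: voxels above this fraction of the nucleus's
#'   background-subtracted smoothed peak.
#' @return A list with `nuclei` (list of `segmented_nucleus`), `flags`
#'   (character vector of animal-level QC flags) and `threshold` (the Otsu
#'   cut on the smoothed marker).
#' @export
segment_nuclei <- function(stack, expected_n = 4, smooth_sigma = 1,
                           split_factor = 1.8, min_voxels = 10,
                           expected_radius = 4, boundary_frac = 0.3) {
  stopifnot(inherits(stack, "image_stack"))
  sm <- smooth3d(stack$mcherry, smooth_sigma)
  flags <- character()
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  if (sum(fg) < min_voxels) {
    return(list(nuclei = list(), flags = "dim-marker", threshold = thr))
  }
  # Weak-contrast guard: segmenting pure noise produces a cut with almost no
  # separation between the classes.
  mu_fg <- mean(sm[fg])
  bg_vals <- sm[!fg]
  if ((mu_fg - mean(bg_vals)) < 4 * stats::sd(bg_vals)) {
    return(list(nuclei = list(), flags = "dim-marker", threshold = thr))
  }

  lab <- label_components_3d(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  comp_vox <- lapply(keep, function(l) which(lab == l))
  if (!length(comp_vox)) {
    return(list(nuclei = list(), flags = "dim-marker", threshold = thr))
  }

  # Watershed-style split: attempted for oversized components, and for every
  # component when fewer components than expected nuclei were found (e.g.
  # two sister pairs merging symmetrically leaves the median volume
  # uninformative). A component with a single intensity maximum never splits.
  med_vol <- stats::median(lengths(comp_vox))
  need_split <- length(comp_vox) < expected_n
  out_vox <- list()
  for (v in comp_vox) {
    if (need_split || length(v) > split_factor * med_vol) {
      seeds <- local_maxima_3d(sm, v, min_sep = expected_radius)
      if (length(seeds) >= 2L) {
        d <- dim(sm)
        sc <- arrayInd(seeds, d)
        vc <- arrayInd(v, d)
        d2 <- sapply(seq_len(nrow(sc)), function(i) {
          rowSums((vc - matrix(sc[i, ], nrow(vc), 3, byrow = TRUE))^2)
        })
        assign <- max.col(-d2, ties.method = "first")
        pieces <- split(v, assign)
        flags <- c(flags, "merged-split")
        out_vox <- c(out_vox, unname(pieces))
        next
      }
      if (length(v) > split_factor * med_vol) flags <- c(flags, "merged-nuclei")
    }
    out_vox <- c(out_vox, list(v))
  }

  if (length(out_vox) > expected_n) flags <- c(flags, "fragmented")
  if (length(out_vox) < expected_n) flags <- c(flags, "merged-nuclei")

  # Refine each component to a per-nucleus relative-intensity contour:
  # voxels above `boundary_frac` of the nucleus's own background-subtracted
  # smoothed peak. This is the automated stand-in for a hand-drawn marker
  # boundary, and makes the boundary's extent depend on nucleus geometry
  # rather than on marker brightness (so a dim and a bright nucleus of the
  # same size get the same-sized boundary).
  base <- stats::median(sm[!fg])
  out_vox <- lapply(out_vox, function(v) {
    cut <- base + boundary_frac * (max(sm[v]) - base)
    r <- v[sm[v] >= cut]
    if (length(r) >= min_voxels) r else v
  })

  nuclei <- purrr::imap(out_vox, function(v, i) {
    new_segmented_nucleus(as.integer(i), v, stack)
  })
  list(nuclei = nuclei, flags = unique(flags), threshold = thr)
}

footprint_indices <- function(footprint, x0 = NULL, y0 = NULL) {
  co <- which(footprint, arr.ind = TRUE)
  if (!is.null(x0)) {
    co[, 1] <- co[, 1] - min(co[, 1]) + x0
    co[, 2] <- co[, 2] - min(co[, 2]) + y0
  }
  co
}

sum_region <- function(arr, co_xy, zs) {
  d <- dim(arr)
  lin2d <- (co_xy[, 2] - 1L) * d[1] + co_xy[, 1]
  tot <- 0
  for (z in zs) tot <- tot + sum(arr[lin2d + (z - 1L) * d[1] * d[2]])
  tot
}

#' Select a background region outside the larva
#'
#' Finds the first raster-order placement (x fastest, then y) of the given
#' planar footprint that lies wholly outside the larva mask (outside its
#' full z-projection).
#'
#' @param stack An `image_stack`.
#' @param footprint Logical matrix: the planar shape to place (typically a
#'   nucleus boundary footprint).
#' @return A list with `x0`, `y0` (1-based offsets of the footprint bounding
#'   box) and `footprint` (cropped to its bounding box).
#' @export
select_background_region <- function(stack, footprint) {
  stopifnot(inherits(stack, "image_stack"), is.logical(footprint), any(footprint))
  mask2d <- apply(stack$larva_mask, c(1, 2), any)
  co <- which(footprint, arr.ind = TRUE)
  fp <- footprint[min(co[, 1]):max(co[, 1]), min(co[, 2]):max(co[, 2]), drop = FALSE]
  w <- nrow(fp); h <- ncol(fp)
  d <- dim(mask2d)
  for (y0 in seq_len(d[2] - h + 1L)) {
    for (x0 in seq_len(d[1] - w + 1L)) {
      if (!any(mask2d[x0:(x0 + w - 1L), y0:(y0 + h - 1L)] & fp)) {
        return(list(x0 = x0, y0 = y0, footprint = fp))
      }
    }
  }
  stop("no outside-larva region fits")
}

#' Background statistics from outside-larva regions
#'
#' Places disjoint copies of a region of the same dimensions as a nucleus
#' boundary at every position fully outside the larva mask (tiling x, y and
#' z), and summarizes the per-region GFP sums. The region is given either
#' as a planar footprint with a slice count, or — matching the support of a
#' top-slice measurement exactly, so that constant camera terms cancel
#' voxel-for-voxel — as an explicit set of 3D voxel coordinates. These
#' statistics drive the visibility call in [call_gfp_positive()].
#'
#' @param stack An `image_stack`.
#' @param region Logical planar footprint matrix, or a 3-column integer
#'   matrix of (x, y, z) voxel coordinates defining the region's shape.
#' @param n_slices Number of z-slices per region (footprint form only).
#' @return A list with `m` (median region sum), `s` (SD of region sums) and
#'   `n_regions`.
#' @export
background_stats <- function(stack, region, n_slices = 5) {
  d <- dim(stack$gfp)
  if (is.logical(region)) {
    fpc <- which(region, arr.ind = TRUE)
    n_slices <- min(n_slices, d[3])
    pat <- cbind(fpc[rep(seq_len(nrow(fpc)), n_slices), , drop = FALSE],
                 rep(seq_len(n_slices), each = nrow(fpc)))
  } else {
    pat <- as.matrix(region)
    stopifnot(ncol(pat) == 3)
  }
  pat <- sweep(pat, 2, apply(pat, 2, min)) + 1L  # 1-based relative pattern
  ext <- apply(pat, 2, max)
  mask2d <- apply(stack$larva_mask, c(1, 2), any)
  fp2d <- matrix(FALSE, ext[1], ext[2])
  fp2d[unique(pat[, 1:2, drop = FALSE])] <- TRUE
  fp2d_idx <- which(fp2d, arr.ind = TRUE)
  zs <- seq(1L, d[3] - ext[3] + 1L, by = ext[3])
  plane <- d[1] * d[2]
  collect <- function(stride_x, stride_y) {
    xs <- seq(1L, d[1] - ext[1] + 1L, by = stride_x)
    ys <- seq(1L, d[2] - ext[2] + 1L, by = stride_y)
    sums <- c()
    for (x0 in xs) for (y0 in ys) {
      if (any(mask2d[(fp2d_idx[, 2] + y0 - 2L) * d[1] + fp2d_idx[, 1] + x0 - 1L])) next
      for (z0 in zs) {
        lin <- (pat[, 3] + z0 - 2L) * plane + (pat[, 2] + y0 - 2L) * d[1] +
          (pat[, 1] + x0 - 1L)
        sums <- c(sums, sum(stack$gfp[lin]))
      }
    }
    sums
  }
  # disjoint tiling preferred; overlapping placements as a fallback when the
  # outside-larva margin is too narrow to tile
  sums <- collect(ext[1], ext[2])
  if (length(sums) < 2L) sums <- collect(1L, 1L)
  if (length(sums) < 2L) stop("no outside-larva region fits")
  list(m = stats::median(sums), s = stats::sd(sums), n_regions = length(sums))
}

#' Measure nuclear GFP: background-corrected sum projection (method A)
#'
#' Integrates GFP inside the nucleus's planar boundary on the sum
#' z-projection restricted to the nucleus's slices, then subtracts the GFP
#' integrated over a same-shaped region outside the larva on the same
#' slices. Values may be negative; they are retained and flagged.
#'
#' @param stack An `image_stack`.
#' @param nucleus A `segmented_nucleus`.
#' @param bg_region A background region from [select_background_region()];
#'   found automatically if `NULL`.
#' @return A one-row tibble (`label`, `gfp_value`, `method`, `n_slices_used`,
#'   `negative_value`, `excluded`, `exclusion_reason`).
#' @export
measure_sumproj_bgcorr <- function(stack, nucleus, bg_region = NULL) {
  stopifnot(inherits(nucleus, "segmented_nucleus"))
  if (is.null(bg_region)) {
    bg_region <- select_background_region(stack, nucleus$footprint)
  }
  mask2d <- apply(stack$larva_mask, c(1, 2), any)
  fpc <- which(bg_region$footprint, arr.ind = TRUE)
  bg_xy <- cbind(fpc[, 1] + bg_region$x0 - 1L, fpc[, 2] + bg_region$y0 - 1L)
  if (any(mask2d[bg_xy])) stop("background region intersects the larva mask")
  in_xy <- footprint_indices(nucleus$footprint)
  zs <- nucleus$zs
  value <- sum_region(stack$gfp, in_xy, zs) - sum_region(stack$gfp, bg_xy, zs)
  tibble::tibble(
    label = nucleus$label,
    gfp_value = value,
    method = "sumproj_bgcorr",
    n_slices_used = length(zs),
    negative_value = value < 0,
    short_span = FALSE,
    excluded = FALSE,
    exclusion_reason = ""
  )
}

#' Measure nuclear GFP: top-5 marker slices, no background correction (method B)
#'
#' Ranks the nucleus's z-slices by their integrated mCherry, selects the top
#' 5 (ties resolved toward lower z; all slices when the nucleus spans fewer
#' than 5, flagged `short_span`), and sums the GFP integrated intensity
#' inside the nucleus boundary over exactly those slices. No background
#' subtraction is applied.
#'
#' @inheritParams measure_sumproj_bgcorr
#' @return A one-row tibble as in [measure_sumproj_bgcorr()] with
#'   `method = "top5"`.
#' @export
top5_slices <- function(nucleus, n = 5L) {
  ps <- nucleus$per_slice_mcherry
  ps$z[order(-ps$mcherry, ps$z)][seq_len(min(n, nrow(ps)))]
}

measure_top5 <- function(stack, nucleus) {
  stopifnot(inherits(nucleus, "segmented_nucleus"))
  ps <- nucleus$per_slice_mcherry
  sel <- top5_slices(nucleus)
  n_take <- length(sel)
  in_slice <- nucleus$coords[, 3] %in% sel
  value <- sum(stack$gfp[nucleus$voxels[in_slice]])
  tibble::tibble(
    label = nucleus$label,
    gfp_value = value,
    method = "top5",
    n_slices_used = n_take,
    negative_value = FALSE,
    short_span = nrow(ps) < 5L,
    excluded = FALSE,
    exclusion_reason = ""
  )
}

match_to_truth <- function(nuclei, truth) {
  # Greedy one-to-one assignment of segments to truth nuclei by centroid
  # distance (n is at most a few cells, so greedy = optimal in practice).
  if (!length(nuclei)) return(integer(0))
  cen <- t(vapply(nuclei, function(n) n$centroid, numeric(3)))
  tc <- as.matrix(truth[, c("cx", "cy", "cz")])
  dmat <- outer(seq_len(nrow(cen)), seq_len(nrow(tc)),
                Vectorize(function(i, j) sqrt(sum((cen[i, ] - tc[j, ])^2))))
  assign <- rep(NA_integer_, length(nuclei))
  repeat {
    if (all(is.infinite(dmat)) || !any(is.finite(dmat))) break
    ij <- arrayInd(which.min(dmat), dim(dmat))
    assign[ij[1]] <- ij[2]
    dmat[ij[1], ] <- Inf
    dmat[, ij[2]] <- Inf
    if (all(!is.na(assign)) || all(is.infinite(dmat))) break
  }
  assign
}

#' Segment and measure one animal's stack
#'
#' The per-animal quantification pipeline: segment nuclei from the mCherry
#' channel, compute per-nucleus background statistics, measure GFP by the
#' requested method(s), and apply the exclusion rules (dim marker, merged
#' nuclei, fragmented nuclei, wrong segment count). When ground truth is
#' supplied (synthetic data), segments are matched one-to-one to truth
#' nuclei by centroid distance and truth columns are carried through;
#' truth-flagged overlapping nuclei are excluded as merged.
#'
#' @param stack An `image_stack`.
#' @param expected_n Expected nucleus count.
#' @param method `"top5"`, `"sumproj_bgcorr"` or `"both"`.
#' @param truth Optional truth tibble (one animal's rows from
#'   [sample_condition()], optionally with `overlapping`).
#' @param k_bg Unused reserved parameter kept for config stability.
#' @return A tibble with one row per cell and method: measurement columns
#'   plus `bg_m`, `bg_s`, truth columns when available, and `excluded` /
#'   `exclusion_reason`.
#' @export
quantify_stack <- function(stack, expected_n = 4,
                           method = c("top5", "sumproj_bgcorr", "both"),
                           truth = NULL, k_bg = NULL) {
  method <- match.arg(method)
  methods <- if (method == "both") c("top5", "sumproj_bgcorr") else method
  seg <- segment_nuclei(stack, expected_n = expected_n)
  if (!is.null(truth)) {
    # optional truth columns default to NA so partial truth tables work
    if (!"animal_id" %in% names(truth)) truth$animal_id <- NA_character_
    if (!"fate" %in% names(truth)) truth$fate <- NA_character_
    if (!"stabilized" %in% names(truth)) truth$stabilized <- NA
    if (!"true_gfp" %in% names(truth)) truth$true_gfp <- NA_real_
    if (!"overlapping" %in% names(truth)) truth$overlapping <- FALSE
  }
  animal_id <- if (!is.null(truth)) truth$animal_id[1] else NA_character_

  empty_row <- function(reason, cell = NULL) {
    tibble::tibble(
      animal_id = animal_id,
      cell_id = if (is.null(cell)) NA_character_ else cell$cell_id,
      fate = if (is.null(cell)) NA_character_ else cell$fate,
      stabilized = if (is.null(cell)) NA else cell$stabilized,
      true_gfp = if (is.null(cell)) NA_real_ else cell$true_gfp,
      label = NA_integer_, gfp_value = NA_real_,
      method = methods[1], n_slices_used = 0L,
      negative_value = FALSE, short_span = FALSE,
      cx = NA_real_, cy = NA_real_, cz = NA_real_,
      bg_m = NA_real_, bg_s = NA_real_,
      excluded = TRUE, exclusion_reason = reason
    )
  }

  hard_flags <- intersect(seg$flags, c("dim-marker", "merged-nuclei", "fragmented"))
  if (length(seg$nuclei) != expected_n || length(hard_flags)) {
    reason <- if (length(hard_flags)) hard_flags[1] else "segment-count"
    if (!is.null(truth)) {
      out <- purrr::map_dfr(seq_len(nrow(truth)), function(i) empty_row(reason, truth[i, ]))
    } else {
      out <- empty_row(reason)
    }
    attr(out, "qc_flags") <- seg$flags
    return(out)
  }

  assign <- if (!is.null(truth)) match_to_truth(seg$nuclei, truth) else
    rep(NA_integer_, length(seg$nuclei))

  rows <- purrr::map_dfr(seq_along(seg$nuclei), function(i) {
    nuc <- seg$nuclei[[i]]
    sel <- top5_slices(nuc)
    bg <- tryCatch(
      background_stats(stack, nuc$coords[nuc$coords[, 3] %in% sel, ,
                                         drop = FALSE]),
      error = function(e) list(m = NA_real_, s = NA_real_, n_regions = 0L)
    )
    meas <- purrr::map_dfr(methods, function(m) {
      if (m == "top5") measure_top5(stack, nuc) else
        measure_sumproj_bgcorr(stack, nuc)
    })
    meas$animal_id <- animal_id
    meas$cx <- nuc$centroid[1]
    meas$cy <- nuc$centroid[2]
    meas$cz <- nuc$centroid[3]
    meas$bg_m <- bg$m
    meas$bg_s <- bg$s
    if (is.na(bg$m)) {
      meas$excluded <- TRUE
      meas$exclusion_reason <- "no-background-region"
    }
    ti <- assign[i]
    if (!is.null(truth) && !is.na(ti)) {
      meas$cell_id <- truth$cell_id[ti]
      meas$fate <- truth$fate[ti]
      meas$stabilized <- truth$stabilized[ti]
      meas$true_gfp <- truth$true_gfp[ti]
      if (isTRUE(truth$overlapping[ti])) {
        meas$excluded <- TRUE
        meas$exclusion_reason <- "merged-nuclei"
      }
    } else {
      meas$cell_id <- NA_character_
      meas$fate <- NA_character_
      meas$stabilized <- NA
      meas$true_gfp <- NA_real_
    }
    meas
  })
  out <- dplyr::relocate(rows, "animal_id", "cell_id", "fate", "stabilized",
                         "true_gfp", "label", "gfp_value", "method")
  attr(out, "qc_flags") <- seg$flags
  out
}
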