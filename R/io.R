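#' Construct a two-channel image stack
#'
#' The raw unit of analysis: GFP and mCherry voxel grids of identical shape,
#' a boolean larva mask, and the axial slice spacing.
#'
#' @param gfp,mcherry 3D non-negative numeric arrays of identical dimensions.
#' @param larva_mask 3D logical array marking voxels inside the animal.
#' @param z_spacing_nm Axial slice spacing in nanometres.
#' @return An object of class `image_stack`.
#' @export
new_image_stack <- function(gfp, mcherry, larva_mask, z_spacing_nm = 260) {
  stopifnot(
    length(dim(gfp)) == 3, identical(dim(gfp), dim(mcherry)),
    identical(dim(gfp), dim(larva_mask)),
    all(is.finite(gfp)), all(is.finite(mcherry)),
    all(gfp >= 0), all(mcherry >= 0),
    is.numeric(z_spacing_nm), z_spacing_nm > 0
  )
  structure(
    list(gfp = gfp, mcherry = mcherry,
         larva_mask = larva_mask == TRUE, z_spacing_nm = z_spacing_nm),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$gfp)
  cat(sprintf("<image_stack> %d x %d x %d voxels, 2 channels, z-spacing %g nm\n",
              d[1], d[2], d[3], x$z_spacing_nm))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$gfp)

#' Write an image stack to disk
#'
#' Writes a multi-page 16-bit unsigned TIFF (one page per z-slice per
#' channel, all GFP slices first, then all mCherry slices), a JSON metadata
#' sidecar (`<path>.json`: `z_spacing_nm`, `shape`, channel order, optional
#' `seed`) and a CSV mask/truth sidecar when supplied. Intensities are
#' rounded to integers; values above 65535 are clipped with a warning.
#' Coordinates in sidecar files are 0-based voxel indices in (x, y, z) order.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param truth Optional nucleus ground-truth tibble written to
#'   `<path>.truth.csv` (coordinates converted to 0-based).
#' @param seed Optional seed recorded in the metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$gfp)
  to_pages <- function(a) {
    a <- round(a)
    if (any(a > 65535)) {
      warning("intensities above 65535 clipped at the 16-bit limit")
      a <- pmin(a, 65535)
    }
    lapply(seq_len(d[3]), function(z) a[, , z] / 65535)
  }
  pages <- c(to_pages(stack$gfp), to_pages(stack$mcherry))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(
    z_spacing_nm = stack$z_spacing_nm,
    shape = as.integer(d),
    channels = c("gfp", "mcherry"),
    coordinate_order = "xyz_0based"
  )
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  # Mask stored run-length-free as the ellipsoid is re-derivable; we keep it
  # explicit as an extra page set would double file size, so store indices.
  mask_idx <- which(stack$larva_mask) - 1L
  writeLines(as.character(mask_idx), paste0(path, ".mask.txt"))
  if (!is.null(truth)) {
    tr <- truth
    for (col in c("cx", "cy", "cz")) {
      if (col %in% names(tr)) tr[[col]] <- tr[[col]] - 1
    }
    readr::write_csv(tr, paste0(path, ".truth.csv"))
  }
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Round-trips integer intensities bit-exactly. Errors if the file does not
#' hold exactly two channels or the metadata sidecar is absent or incomplete.
#'
#' @param path TIFF path (expects `<path>.json` and `<path>.mask.txt` beside it).
#' @return An `image_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("metadata sidecar missing: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$z_spacing_nm)) stop("z_spacing_nm missing")
  if (is.null(meta$shape)) stop("shape missing")
  d <- as.integer(meta$shape)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L * d[3]) {
    stop(sprintf("format error: expected 2 channels x %d slices, found %d pages",
                 d[3], length(pages)))
  }
  from_pages <- function(pp) {
    a <- array(0, d)
    for (z in seq_len(d[3])) a[, , z] <- round(pp[[z]] * 65535)
    a
  }
  gfp <- from_pages(pages[seq_len(d[3])])
  mch <- from_pages(pages[d[3] + seq_len(d[3])])
  mask <- array(FALSE, d)
  mask_path <- paste0(path, ".mask.txt")
  if (file.exists(mask_path)) {
    idx <- as.integer(readLines(mask_path))
    mask[idx + 1L] <- TRUE
  }
  new_image_stack(gfp, mch, mask, meta$z_spacing_nm)
}

#' Write analysis reports
#'
#' Emits a per-cell CSV, a per-clone CSV and a JSON summary with a stable
#' schema. Empty inputs produce headers-only CSVs.
#'
#' @param cells Per-cell measurement tibble (may have zero rows).
#' @param clones Per-clone result tibble (may have zero rows, or `NULL`).
#' @param path Output directory (created if needed).
#' @param summary Optional named list merged into the JSON summary.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(cells, clones = NULL, path, summary = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cells_path <- file.path(path, "cells.csv")
  readr::write_csv(cells, cells_path)
  out <- c(cells = cells_path)
  if (!is.null(clones)) {
    clones_path <- file.path(path, "clones.csv")
    readr::write_csv(clones, clones_path)
    out <- c(out, clones = clones_path)
  }
  summary <- c(list(
    n_cells = nrow(cells),
    n_animals = length(unique(cells$animal_id %||% character())),
    n_clones = if (is.null(clones)) 0L else nrow(clones)
  ), summary)
  summary_path <- file.path(path, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(out, summary = summary_path))
}
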