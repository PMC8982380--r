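# Cell naming, AC inference, the "AC-like" fluorescence threshold, the
# beta-cell fate-transformation correction, and the formal surrogate for
# by-eye "visible GFP" scoring.

#' Name the four AC-competent cells by fluorescence
#'
#' Within each animal, the alpha cell with the higher GFP value is named
#' `alpha1` (the presumptive AC), the other `alpha2`; `beta1` is the lineage
#' sister of `alpha1` and `beta2` the sister of `alpha2`. If sister identity
#' is unavailable (no `sister_id`/`cell_id` columns), each beta cell is
#' paired to an alpha by centroid distance using the one-to-one assignment
#' minimizing total distance. Alpha ties are broken toward the lower
#' centroid x and flagged `"alpha-tie"`. Animals with missing or excluded
#' cells get `role = "unknown"` and an `"incomplete"` flag.
#'
#' @param cells Measurement tibble (one or more animals) with columns
#'   `animal_id`, `gfp_value`, `excluded`, a cell-class indicator (either
#'   `cell_class` in `{"alpha","beta"}` or truth `cell_id` starting with
#'   `alpha`/`beta`), and optionally `sister_id`, `cx`, `cy`, `cz`.
#' @return `cells` with added columns `role` (alpha1/alpha2/beta1/beta2 or
#'   unknown) and `animal_flag`.
#' @export
name_cells <- function(cells) {
  stopifnot("animal_id" %in% names(cells), "gfp_value" %in% names(cells))
  if (!"cell_class" %in% names(cells)) {
    stopifnot("cell_id" %in% names(cells))
    cells$cell_class <- ifelse(grepl("^alpha", cells$cell_id), "alpha",
                               ifelse(grepl("^beta", cells$cell_id), "beta", NA))
  }
  one_animal <- function(df) {
    df$role <- "unknown"
    df$animal_flag <- ""
    a <- which(df$cell_class == "alpha")
    b <- which(df$cell_class == "beta")
    bad <- length(a) != 2L || length(b) != 2L ||
      any(df$excluded[c(a, b)]) || any(is.na(df$gfp_value[c(a, b)]))
    if (bad) {
      df$animal_flag <- "incomplete"
      return(df)
    }
    g <- df$gfp_value[a]
    tie <- isTRUE(all.equal(g[1], g[2]))
    if (tie) {
      first <- a[order(df$cx[a])[1]]
      df$animal_flag <- "alpha-tie"
    } else {
      first <- a[which.max(g)]
    }
    a1 <- first
    a2 <- setdiff(a, a1)
    df$role[a1] <- "alpha1"
    df$role[a2] <- "alpha2"
    if ("sister_id" %in% names(df) && !anyNA(df$sister_id) &&
        "cell_id" %in% names(df) && !anyNA(df$cell_id)) {
      df$role[df$cell_id == df$sister_id[a1]] <- "beta1"
      df$role[df$cell_id == df$sister_id[a2]] <- "beta2"
    } else {
      # Pair each beta to the nearest alpha, minimizing total distance over
      # the two possible one-to-one assignments.
      dd <- function(i, j) sqrt((df$cx[i] - df$cx[j])^2 +
                                  (df$cy[i] - df$cy[j])^2 +
                                  (df$cz[i] - df$cz[j])^2)
      if (dd(a1, b[1]) + dd(a2, b[2]) <= dd(a1, b[2]) + dd(a2, b[1])) {
        df$role[b[1]] <- "beta1"; df$role[b[2]] <- "beta2"
      } else {
        df$role[b[2]] <- "beta1"; df$role[b[1]] <- "beta2"
      }
    }
    df
  }
  cells |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ one_animal(.x)) |>
    dplyr::ungroup()
}

#' Infer the anchor cell from the two alpha measurements
#'
#' The alpha cell expressing the higher GFP level is inferred to be the AC
#' (it equals `alpha1` from [name_cells()] by construction). Ties are broken
#' toward the lower centroid x and flagged.
#'
#' @param gfp_values Numeric length-2: GFP values of the two alpha cells.
#' @param centroid_x Optional length-2 centroid x coordinates for tie-breaks.
#' @return Integer index (1 or 2) of the inferred AC, with attribute `tie`.
#' @export
infer_ac <- function(gfp_values, centroid_x = NULL) {
  stopifnot(length(gfp_values) == 2)
  tie <- isTRUE(all.equal(gfp_values[1], gfp_values[2]))
  idx <- if (tie) {
    if (is.null(centroid_x)) 1L else which.min(centroid_x)[1]
  } else {
    which.max(gfp_values)
  }
  structure(as.integer(idx), tie = tie)
}

#' Fit the AC-like fluorescence threshold
#'
#' From the GFP values of ACs scored in the negative control: the threshold
#' is the control-AC mean minus one sample standard deviation (n - 1
#' denominator).
#'
#' @param control_ac_values Numeric vector of control AC GFP values (>= 2).
#' @return An object of class `ac_threshold` with fields `mu_ac`,
#'   `sigma_ac`, `threshold`, `n`.
#' @export
fit_ac_threshold <- function(control_ac_values) {
  v <- control_ac_values[!is.na(control_ac_values)]
  if (length(v) < 2) stop("need at least 2 control AC values")
  mu <- mean(v)
  sigma <- stats::sd(v)
  structure(list(mu_ac = mu, sigma_ac = sigma, threshold = mu - sigma,
                 n = length(v)),
            class = "ac_threshold")
}

#' @export
print.ac_threshold <- function(x, ...) {
  cat(sprintf("<ac_threshold> mu_ac = %.4g, sigma_ac = %.4g, threshold = %.4g (n = %d)\n",
              x$mu_ac, x$sigma_ac, x$threshold, x$n))
  invisible(x)
}

#' Classify cells against the AC-like threshold
#'
#' A cell is AC-like iff its GFP value is strictly greater than the
#' threshold.
#'
#' @param values Numeric GFP values.
#' @param model An `ac_threshold` from [fit_ac_threshold()].
#' @return A tibble with `gfp_value` and `ac_like`; the attribute
#'   `fraction` holds the AC-like fraction.
#' @export
classify_ac_like <- function(values, model) {
  stopifnot(inherits(model, "ac_threshold"))
  ac_like <- values > model$threshold
  out <- tibble::tibble(gfp_value = values, ac_like = ac_like)
  attr(out, "fraction") <- mean(ac_like, na.rm = TRUE)
  out
}

#' Per-role AC-like table excluding the presumptive AC
#'
#' The percentage of cells with AC-like GFP per role, excluding `alpha1`
#' (the presumptive AC), as displayed above per-condition scatter columns.
#'
#' @param cells Tibble with `role` and `gfp_value` (from [name_cells()]),
#'   optionally `condition`.
#' @param model An `ac_threshold`.
#' @return A tibble with `role`, `n`, `n_ac_like`, `pct_ac_like` (and
#'   `condition` when present).
#' @export
ac_like_table <- function(cells, model) {
  stopifnot(inherits(model, "ac_threshold"))
  if (!"condition" %in% names(cells) && "clone_id" %in% names(cells)) {
    cells$condition <- cells$clone_id
  }
  grp <- intersect(c("condition", "role"), names(cells))
  cells |>
    dplyr::filter(.data$role != "alpha1", .data$role != "unknown",
                  !.data$excluded) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_ac_like = sum(.data$gfp_value > model$threshold),
      pct_ac_like = 100 * .data$n_ac_like / .data$n,
      .groups = "drop"
    )
}

#' Exclude the top fraction of values
#'
#' Removes the `ceiling(f * n)` largest values (ties resolved toward the
#' larger value first, then input order) — the correction for beta cells
#' that adopt the AC fate in a Notch-null background, where the highest-
#' expressing fraction of beta cells is excluded before comparing VU-fated
#' populations.
#'
#' @param values Numeric vector.
#' @param f Fraction to exclude, in `[0, 1)`.
#' @return A list with `retained` (values, input order preserved) and
#'   `excluded_idx` (indices of the removed values).
#' @export
exclude_top_fraction <- function(values, f) {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f >= 1) {
    stop("f must be in [0, 1)")
  }
  n <- length(values)
  k <- ceiling(f * n)
  if (k == 0) return(list(retained = values, excluded_idx = integer(0)))
  excl <- order(-values, seq_len(n))[seq_len(k)]
  list(retained = values[-excl], excluded_idx = sort(excl))
}

#' Formal surrogate for by-eye "visible GFP" scoring
#'
#' A cell is called GFP-positive iff its measured GFP value exceeds the
#' median of the outside-larva per-region background sums by more than `k`
#' dispersions (see [background_stats()]). `k = 5` mimics a confident
#' by-eye call.
#'
#' @param gfp_value Numeric vector of measured GFP values.
#' @param bg_m,bg_s Background median and dispersion (recycled).
#' @param k Number of dispersions above the background median.
#' @return Logical vector.
#' @export
call_gfp_positive <- function(gfp_value, bg_m, bg_s, k = 5) {
  if (anyNA(bg_m) || anyNA(bg_s)) stop("missing background statistics")
  gfp_value > bg_m + k * bg_s
}
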