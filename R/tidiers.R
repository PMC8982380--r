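#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an AC-like threshold model
#'
#' @param x An `ac_threshold`.
#' @param ... Unused.
#' @return A tibble with one row per model quantity (`term`, `estimate`).
#' @method tidy ac_threshold
#' @export
tidy.ac_threshold <- function(x, ...) {
  tibble::tibble(
    term = c("mu_ac", "sigma_ac", "threshold"),
    estimate = c(x$mu_ac, x$sigma_ac, x$threshold)
  )
}

#' @rdname tidy.ac_threshold
#' @return For `glance()`: a one-row tibble (`mu_ac`, `sigma_ac`,
#'   `threshold`, `n`).
#' @method glance ac_threshold
#' @export
glance.ac_threshold <- function(x, ...) {
  tibble::tibble(mu_ac = x$mu_ac, sigma_ac = x$sigma_ac,
                 threshold = x$threshold, n = x$n)
}

#' Tidy a screen report
#'
#' @param x A `screen_report` from [run_screen()].
#' @param ... Unused.
#' @return Per-clone results as a tibble.
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) x$clones

#' @rdname tidy.screen_report
#' @return For `glance()`: a one-row summary (clone, hit and QC counts,
#'   plus recovery columns when ground truth was available).
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  out <- tibble::tibble(
    n_clones = nrow(x$clones),
    n_scoreable = sum(x$clones$scoreable),
    n_hits = sum(x$clones$hit),
    n_rounds = nrow(x$qc),
    n_rounds_valid = sum(x$qc$round_valid)
  )
  if (!is.null(x$confusion)) out <- dplyr::bind_cols(out, x$confusion)
  out
}
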