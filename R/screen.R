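# RNAi-screen logic: per-animal GFP-positive cell counts, control QC gates,
# strict/lenient hit criteria, triplicate confirmation, and the screened-
# library coverage arithmetic.

#' Count GFP-positive cells in one animal
#'
#' Counts the non-excluded cells called GFP-positive by
#' [call_gfp_positive()]. At most 4 AC-competent cells exist per animal;
#' more indicates an upstream segmentation fault and is an error.
#'
#' @param animal_cells One animal's measurement tibble (columns `gfp_value`,
#'   `bg_m`, `bg_s`, `excluded`).
#' @param k Visibility constant passed to [call_gfp_positive()].
#' @return Integer count in `[0, 4]`.
#' @export
count_gfp_cells <- function(animal_cells, k = 5) {
  live <- animal_cells[!animal_cells$excluded, , drop = FALSE]
  if (nrow(live) > 4) stop("more than 4 non-excluded cells in one animal")
  if (nrow(live) == 0) return(0L)
  sum(call_gfp_positive(live$gfp_value, live$bg_m, live$bg_s, k = k))
}

#' Evaluate the control QC gates of a screening round
#'
#' The negative gate passes iff at least 50% of negative-control (lacZ)
#' animals have exactly one GFP-positive cell; the positive gate passes iff
#' strictly more than 50% of positive-control (lin-12) animals have more
#' than one (supernumerary cells, showing the RNAi conditions worked). A
#' round is valid iff both gates pass.
#'
#' @param lacz_counts,lin12_counts Integer per-animal counts.
#' @return A tibble row: `negative_pass`, `positive_pass`, `round_valid`.
#' @export
evaluate_controls <- function(lacz_counts, lin12_counts) {
  if (!length(lacz_counts) || !length(lin12_counts)) {
    stop("control count lists must be non-empty")
  }
  negative_pass <- mean(lacz_counts == 1) >= 0.5
  positive_pass <- mean(lin12_counts > 1) > 0.5
  tibble::tibble(
    negative_pass = negative_pass,
    positive_pass = positive_pass,
    round_valid = negative_pass && positive_pass
  )
}

#' Strict hit criterion
#'
#' A clone is a strict hit iff the average number of GFP-positive somatic
#' gonad cells per animal is at least 2.
#'
#' @param counts Integer per-animal counts (non-empty).
#' @return Logical.
#' @export
call_strict <- function(counts) {
  stopifnot(length(counts) > 0)
  mean(counts) >= 2
}

#' Lenient hit criterion
#'
#' A clone is a lenient hit iff (1) at least one animal has all 4 cells
#' GFP-positive and (2) at least half the animals have more than 1.
#'
#' @inheritParams call_strict
#' @return Logical.
#' @export
call_lenient <- function(counts) {
  stopifnot(length(counts) > 0)
  any(counts == 4) && mean(counts > 1) >= 0.5
}

#' Triplicate confirmation of a candidate
#'
#' A candidate identified in the primary screen is retested in triplicate;
#' it is confirmed if the replicates again meet a hit criterion. The default
#' rule requires a majority (at least 2 of 3) of replicates to satisfy
#' strict or lenient; `rule = "all"` requires all three.
#'
#' @param replicate_counts List of exactly 3 per-animal count vectors.
#' @param rule `"majority"` or `"all"`.
#' @return A list: `confirmed` (logical) and `replicates` (tibble of
#'   per-replicate strict/lenient/hit calls).
#' @export
confirm_candidate <- function(replicate_counts, rule = c("majority", "all")) {
  rule <- match.arg(rule)
  if (length(replicate_counts) != 3) stop("exactly 3 replicates required")
  reps <- purrr::map_dfr(seq_along(replicate_counts), function(i) {
    cts <- replicate_counts[[i]]
    tibble::tibble(
      replicate = i,
      strict_hit = call_strict(cts),
      lenient_hit = call_lenient(cts)
    )
  })
  reps$hit <- reps$strict_hit | reps$lenient_hit
  need <- if (rule == "majority") 2L else 3L
  list(confirmed = sum(reps$hit) >= need, replicates = reps)
}

#' Run the screen analysis on a dataset
#'
#' Computes per-animal GFP-positive counts (animals with any excluded cell
#' are dropped before counting), evaluates the control QC gates per round,
#' and calls strict/lenient hits for scoreable clones (at least
#' `min_animals` counted animals) in valid rounds. When the dataset carries
#' planted ground truth, a confusion summary (sensitivity, false positives)
#' is included.
#'
#' @param dataset A `screen_dataset` from [make_screen_dataset()], or a list
#'   with compatible `cells` and `clones` elements.
#' @param k Visibility constant for [call_gfp_positive()].
#' @param min_animals Minimum counted animals for a clone to be scoreable.
#' @return An object of class `screen_report`: list with `clones` (per-clone
#'   results), `qc` (per-round gate outcomes), `counts` (per-animal counts)
#'   and, with ground truth, `confusion`.
#' @export
run_screen <- function(dataset, k = 5, min_animals = 20) {
  cells <- dataset$cells
  stopifnot(all(c("round", "clone_id", "type", "animal_id", "gfp_value",
                  "bg_m", "bg_s", "excluded") %in% names(cells)))

  counts <- cells |>
    dplyr::group_by(.data$round, .data$clone_id, .data$type, .data$animal_id) |>
    dplyr::summarise(
      any_excluded = any(.data$excluded),
      count = if (any(.data$excluded)) NA_integer_ else
        count_gfp_cells(dplyr::pick(dplyr::everything()), k = k),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$any_excluded) |>
    dplyr::select(-"any_excluded")

  qc <- purrr::map_dfr(sort(unique(counts$round)), function(r) {
    sub <- counts[counts$round == r, ]
    lacz <- sub$count[sub$type == "negative_control"]
    lin12 <- sub$count[sub$type == "positive_control"]
    if (!length(lacz) || !length(lin12)) {
      return(tibble::tibble(round = r, negative_pass = FALSE,
                            positive_pass = FALSE, round_valid = FALSE))
    }
    dplyr::bind_cols(tibble::tibble(round = r),
                     evaluate_controls(lacz, lin12))
  })

  clone_res <- counts |>
    dplyr::group_by(.data$round, .data$clone_id, .data$type) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      mean_count = mean(.data$count),
      has_four = any(.data$count == 4),
      frac_gt1 = mean(.data$count > 1),
      strict_hit = call_strict(.data$count),
      lenient_hit = call_lenient(.data$count),
      .groups = "drop"
    ) |>
    dplyr::left_join(qc[, c("round", "round_valid")], by = "round") |>
    dplyr::mutate(
      scoreable = .data$n_animals >= min_animals & .data$round_valid,
      hit = .data$scoreable & .data$type == "experimental" &
        (.data$strict_hit | .data$lenient_hit)
    )

  report <- list(clones = clone_res, qc = qc, counts = counts, k = k)

  if (!is.null(dataset$clones) && "planted_hit" %in% names(dataset$clones)) {
    truth <- dataset$clones[, c("round", "clone_id", "planted_hit")]
    joined <- dplyr::left_join(clone_res, truth, by = c("round", "clone_id")) |>
      dplyr::filter(.data$type == "experimental")
    report$confusion <- tibble::tibble(
      n_planted = sum(joined$planted_hit),
      n_called = sum(joined$hit),
      true_positives = sum(joined$hit & joined$planted_hit),
      false_positives = sum(joined$hit & !joined$planted_hit),
      false_negatives = sum(!joined$hit & joined$planted_hit),
      sensitivity = ifelse(.data$n_planted > 0,
                           .data$true_positives / .data$n_planted, NA_real_)
    )
  }
  structure(report, class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", nrow(x$clones), "clones;",
      sum(x$clones$hit), "hits;",
      sum(x$qc$round_valid), "of", nrow(x$qc), "rounds valid\n")
  if (!is.null(x$confusion)) {
    cat(sprintf("  planted-hit recovery: sensitivity %.2f, %d false positive(s)\n",
                x$confusion$sensitivity, x$confusion$false_positives))
  }
  invisible(x)
}

#' Screened ubiquitin-related gene library coverage
#'
#' Arithmetic of the screened-library composition: an orthology-filtered set
#' of conserved ubiquitin-related genes plus literature additions gives the
#' conserved total; the subset with available feeding-RNAi clones gives the
#' screened count and the coverage percentage.
#'
#' @param n_ortholist Conserved genes from the orthology screen.
#' @param n_literature Literature additions (one E2 plus the RBR-family E3s).
#' @param n_covered Genes covered by available RNAi clones.
#' @param n_clones Number of available clones covering them.
#' @return A one-row tibble: `genes_total`, `genes_screened`, `n_clones`,
#'   `coverage_pct`.
#' @export
library_coverage <- function(n_ortholist = 239, n_literature = 1 + 7,
                             n_covered = 232, n_clones = 260) {
  total <- n_ortholist + n_literature
  tibble::tibble(
    genes_total = total,
    genes_screened = n_covered,
    n_clones = n_clones,
    coverage_pct = 100 * n_covered / total
  )
}
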